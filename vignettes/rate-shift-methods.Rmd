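---
title: "Methods: reference-normalized substitution-rate-shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-normalized substitution-rate-shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rateshift)
```

## The question and the model

A de novo gene is born from sequence that was, until recently, ordinary
intergenic DNA. If parts of the locus show deep conservation, the
interesting question is *when* constraint arrived: with the gene, or
earlier, for instance when a chromosomal inversion repositioned the
sequence. `rateshift` operationalizes this as a piecewise-constant
substitution-rate model on the fixed four-taxon phylogeny
`(((mouse,rat),human),dog)` with divergence times
`t_mr < t_hr < t_hd`.

The test region carries three stage rates — `r0` before the inversion,
`r1` between inversion and gene birth, `r2` after — while the exons of
flanking genes evolve at one rate `rR` on every branch and act as a
molecular clock. Two fractions time the events: the inversion sits at
time `(1 - k1) * t_hr` before present and must fall on the rodent stem
(only the rodent lineage experienced it), and gene birth falls within
the last `(1 - k2)` fraction of the mouse–rat path. Because each
pairwise distance is a path integral of rate over time, dividing
test-region distances by reference distances cancels the (poorly known)
absolute times and yields three dimensionless normalized rates:

$$
r^{aver}_{HD} = \rho_0,\qquad
r^{aver}_{HR} = \tfrac{1}{2}\left[(1+k_1)\rho_0 + (1-k_1)\rho_1\right],\qquad
r^{aver}_{MR} = \tfrac{1}{2}\left[(1+k_2)\rho_1 + (1-k_2)\rho_2\right],
$$

with $\rho_i = r_i / r_R$. Two sanity properties anchor this form: with
no rate change ($\rho_0=\rho_1=\rho_2$) all three ratios equal the
common $\rho$, and as $k_1 \to 1$ (inversion at the present, no time
spent at $r_1$ on the human–rat path) $r^{aver}_{HR} \to r^{aver}_{HD}$.
Both properties require the divisor 2 in the mixture terms — the factor
arises mechanically from dividing the two-lineage test path by the
two-lineage reference path $2 r_R t$. Some presentations of this model
omit the divisor; `solve_rate_ratios(..., printed_form = TRUE)` inverts
that uncorrected variant for comparison, but the corrected form is the
default everywhere because the uncorrected one fails both sanity
properties.

The qualitative decision rule (`infer_ordering()`) compares
$r^{aver}_{HR}$ against $r^{aver}_{HD}$: lower means the rate dropped
after the inversion ($\rho_1 < \rho_0$). The gene-birth direction
compares $r^{aver}_{MR}$ against $r^{aver}_{HR}$ the same way. Any such
call needs an explicit "unchanged" band; the default is a 2% relative
tolerance, chosen because the differences this analysis cares about (a
quarter or more of the ratio) dwarf it while pair-sampling noise on
multi-kilobase alignments stays inside it. It is a flag, not a constant.

Given $(k_1, k_2)$, the three equations invert in closed form
(`solve_rate_ratios()`), and the inversion is exact to machine
precision — the test suite checks a forward–inverse round trip to
1e-10 relative error over 1000 random parameter draws. The timings
themselves are *not* identified by three ratios, so
`rate_ratio_scan()` tabulates the solution over a $(k_1,k_2)$ grid
(default step 0.05 — fine enough to map the feasible region, coarse
enough to stay at 361 points) and flags grid points where any
$\rho \le 0$ as infeasible. The scan is how a time *interval* for an
event, rather than a point, is reported.

## What the simulator emulates

`simulate_locus()` realizes the model generatively so every downstream
stage can be tested against known truth:

* **Substitution process: JC69** (equal rates, equal base frequencies),
  root drawn i.i.d. uniform over A/C/G/T, no indels — columns are
  positional identity. JC69 keeps the simulator and the default
  distance estimator a matched, closed-form pair; nothing in the rate
  model depends on the substitution model beyond the distances being
  consistent.
* **Event placement.** The inversion changepoint sits on the rodent
  stem at `(1 - k1) * t_hr`; parameter validation rejects $(k_1,
  t)$ combinations that would push it below the mouse–rat split. Gene
  birth is realized as a simultaneous rate change on *both* rodent
  terminal branches at time `(1 - k2) * t_mr / 2`, so the mouse–rat
  path carries exactly the `(1 - k2) * t_mr` stretch of $r_2$ the model
  equation states. This symmetric convention reproduces the HD and MR
  expectations exactly; on the HR path it introduces a small
  approximation, because the $r_2$ segment on the rat terminal branch
  lies on the human–rat path too: the realized expectation is lower
  than the mixture formula by $(1-k_2)\,(t_{mr}/2)\,(r_1-r_2)$ in
  distance. Under the default study conditions (rates 2/1/0.5,
  $k_1=k_2=0.5$, times 0.05/0.2/0.25) that is 1.734 realized versus
  1.75 nominal for $r^{aver}_{HR}$ — a 0.9% effect, well inside the 5%
  recovery band the tests use. Biologically, gene birth in one lineage
  only would put the whole $r_2$ stretch on the mouse branch; the
  mixture equation treats mouse and rat symmetrically, and we follow
  it. Users preferring another convention can pass a raw per-segment
  `test_schedule`.
* **Seeding.** One integer seed fully determines the output; the seed
  is recorded in the returned object and identical inputs are
  bit-reproducible (tested).

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: indels and alignment error (real
orthologous sequences must be aligned, and misalignment inflates
apparent rates), substitution-model misspecification (real data are not
JC69; transition bias, CpG hypermutability and rate variation across
sites all distort distances differentially), GC-content drift, and
lineage-specific rate variation in the *reference* exons (the model
assumes the flanking-gene clock is shared by all four species). On real
alignments, conclusions inherit all of these caveats.

## Alignment handling

Manual curation of alignments is replaced by a deterministic
`filter_policy()`: gap-containing columns are removed first, then the
gap-free columns are tiled into windows of `window_len` (default 10)
and a window is dropped whole when its mean pairwise identity falls
below `min_window_identity` (default 0.5). Evaluating windows on the
gap-free alignment with all-or-nothing removal makes the filter
idempotent (re-filtering the output is a no-op; property-tested), and
the per-column keep mask is attached to the result for audit. The
defaults suit diverged real alignments; for simulated gap-free data the
identity filter is pointless and biased (it preferentially deletes the
most diverged windows, shrinking distance estimates), so analyses of
simulated loci in this package's tests and acceptance script pass
`min_window_identity = 0` deliberately.

Reference exon alignments are concatenated (`concat_alignments()`) into
a single clock alignment before distance estimation, with per-source
offsets recorded so the concatenation is reversible.

## Distances and trees

`p_distance()`, `jc69_distance()` and `k80_distance()` implement the
standard closed forms with pairwise deletion of gapped/ambiguous sites;
they are cross-checked against `ape::dist.dna` to 1e-12 in the test
suite. `distance_matrix()` defaults to K80 — on real data transition
bias is ubiquitous and K80 captures it at no cost — while analyses of
JC69-simulated data use `model = "jc69"` for estimator/simulator
consistency. Saturation ($p \ge 3/4$, or the K80 log arguments reaching
zero) raises an error naming the offending species pair rather than
returning `NaN`.

`nj_tree()` is a from-scratch Saitou–Nei neighbor joining with one
deliberate addition: ties in the Q criterion are broken by the
lexicographically smallest pair of subtree labels, making the output
deterministic on degenerate inputs. It is validated three ways on
random additive matrices: against the generating topology, against a
brute-force least-squares fit over all three unrooted four-taxon
topologies, and against `ape::nj`.

## Region mapping choices

* **Inversion calling** (`detect_inversions()`): the majority
  orientation of a query species is computed over its blocks weighted
  by reference-interval length (ties resolve to `+`); maximal runs of
  consecutive minority-strand blocks become inversion intervals, and
  adjacent flipped blocks merge across reference gaps up to `max_gap`
  (default 1000 bp) because whole-genome aligners fragment single
  events into adjacent blocks. The call is invariant to input row
  order.
* **Feature coverage** (`feature_coverage()`): covered fraction is the
  union of block overlaps divided by feature length; `covered` requires
  0.5 of the feature by default (exposed), anything positive but below
  is `partial`, and features touched by any minority-strand block are
  flagged `inverted`.
* **TE composition** (`te_feature_overlap()`): any overlap of at least
  1 bp under half-open coordinates counts — composition tables list
  containment, not fractions. The bundled TE census fixture encodes
  eleven ancestral elements A–K with their repeat classes and carrier
  species plus two single-species decoys that the shared-TE filter
  (`shared_te_filter()`, "at least two species including mouse") must
  reject. One published composition row lists element I twice where the
  census defines a distinct element J; both readings are constructible
  via `make_te_fixture(exon5_duplicate_i = )`, defaulting to the
  J reading, which is the one consistent with eleven distinct elements.
* **ORF scanning** (`find_orfs()`): AUG-initiated, stop-terminated,
  standard code, sense-strand by default with a six-frame option;
  minimum length 30 aa by default (a common ORF-finder floor; exposed
  because the original web tools' default is version-dependent). The
  scanner is property-tested against an exhaustive brute-force oracle.

## Synthetic stand-ins for external data

Two inputs of the original analysis are external downloads (a curated
supplementary alignment; a transcript accession). The package ships
*generators*, not copies:

* `make_ce_standins()` builds conserved-element-like alignments whose
  stage rates are obtained by algebraically inverting the reported
  normalized-rate triples — (2.5971, 2.0603, 1.406) for the element
  inside the inversion, (1.6694, 2.1832, 1.5047) for the one outside —
  at early event timings $k_1=k_2=0.05$. The timing matters: at
  $k_1=k_2=0.5$ the second triple implies $\rho_2 < 0$ (infeasible),
  and feasibility for both triples requires small $k$; this is itself
  an informative property of the model's feasible region. Test
  alignments are 20,000 sites and the four flanking-gene references
  total 4,600 sites — large enough that the qualitative patterns
  (HD > HR > MR inside the inversion; HR > HD > MR outside) are stable,
  sized like a desk-scale version of a real locus.
* `make_transcript_fixture()` constructs a 2.9 kb transcript carrying a
  designed ORF architecture — longest ORF 104 aa, preceded by exactly
  two AUGs opening 70 and 72 aa frames. The construction is provably
  tight: untranslated stretches are `TTAA` repeats (stop codons in all
  three sense frames, no AUG on either strand, and the repeat is its
  own reverse complement), ORF bodies use T-free codons (no internal
  AUG or stop in any frame of either strand), and all stops are `TAA`
  (a `TGA` after an A-ending codon would create a spurious `ATG` at the
  junction). The scanner's output on it is therefore known exactly.

Both are labelled synthetic in their documentation; conclusions about
the *real* locus require the real files.

## Problem sizes and runtime posture

The test and acceptance workloads use 10^5-site simulations for
parameter recovery (20 replicates; pair-distance standard errors around
0.6%, so means are tight), 2×10^4-site stand-ins for the qualitative
patterns, 100 random additive matrices for NJ, 50 planted-inversion
fixtures, and 100 random sequences for the ORF oracle — sizes at which
every stochastic check has comfortable margin while the full suite runs
in well under a minute.

## Known limitations

The model is deliberately minimal: three rate stages, shared reference
clock, no site-rate heterogeneity, no statistical test on the ratios
(the output is an effect direction and magnitude, not a p-value). The
timing fractions are unidentified — only the feasible region and
per-timing solutions are reported. Absolute time calibration, ML tree
estimation, whole-genome synteny inference, and running the upstream
annotation tools (RepeatMasker, aligners) are out of scope; their
outputs are this package's inputs.
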