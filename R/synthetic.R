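# Synthetic fixtures: toy alignment-block chains with planted
# inversions, a transposable-element annotation table mirroring the
# locus's TE census, the locus feature map, a synthetic transcript with
# a designed ORF architecture, and synthetic stand-ins for the curated
# conserved-element alignments.

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                ""))
}

random_dna <- function(n) paste0(sample(BASES, n, replace = TRUE),
                                 collapse = "")

#' Toy alignment-block chain with planted inversions
#'
#' Builds a colinear chain of alignment blocks between a reference
#' species and one query species on toy chromosomes, in which exactly
#' the requested blocks carry a flipped query strand. Adjacent blocks
#' are separated by a small reference gap so that consecutive flipped
#' blocks merge into a single inversion interval under the default merge
#' distance of [detect_inversions()].
#'
#' @param n_blocks Number of blocks in the chain.
#' @param inverted Integer vector of 1-based block indices to flip on
#'   the query.
#' @param seed Integer seed for the block sequences.
#' @param block_len,gap Block length and inter-block reference gap (bp).
#' @param ref_species,query_species Species labels.
#' @return A block tibble as returned by [read_maf()]: one row per
#'   (block, species) with columns `block`, `species`, `chrom`, `start`,
#'   `end`, `strand`, `src_size`, `text`.
#' @examples
#' make_block_fixture(5, inverted = 2, seed = 1)
#' @export
make_block_fixture <- function(n_blocks, inverted = integer(), seed = 1,
                               block_len = 200, gap = 50,
                               ref_species = "mouse",
                               query_species = "human") {
  if (length(inverted) > 0 &&
      (min(inverted) < 1 || max(inverted) > n_blocks)) {
    abort("inverted indices out of [1, n_blocks]",
          class = "rateshift_error_param")
  }
  set.seed(as.integer(seed))
  src_size <- as.integer(1e6)
  rows <- purrr::map(seq_len(n_blocks), function(i) {
    s <- 1000 + (i - 1) * (block_len + gap)
    txt <- random_dna(block_len)
    inv <- i %in% inverted
    tibble(
      block = i,
      species = c(ref_species, query_species),
      chrom = c("chr10", "chr5"),
      start = c(s, 5000 + (i - 1) * (block_len + gap)),
      end = c(s + block_len, 5000 + (i - 1) * (block_len + gap) + block_len),
      strand = c("+", if (inv) "-" else "+"),
      src_size = src_size,
      text = c(txt, if (inv) revcomp(txt) else txt)
    )
  })
  list_rbind(rows)
}

#' Transposable-element census fixture for the locus
#'
#' Encodes the eleven ancestral transposable elements (symbols A-K)
#' found at the lncRNA locus, with their repeat family, collapsed repeat
#' class, carrier species, and toy mouse-locus coordinates laid out so
#' that the TE/feature composition of the locus is reproduced exactly
#' (see [locus_features()]). Two decoy elements present in only one
#' species each (mouse-only, rat-only) are appended; they must be
#' removed by the shared-TE filter.
#'
#' @param exon5_duplicate_i The published composition table lists
#'   element "I" twice in the last lncRNA exon while the TE census
#'   defines a distinct element "J" there; `FALSE` (default) uses J,
#'   `TRUE` encodes a second copy of I at J's position.
#' @return A TE annotation tibble: `symbol`, `name`, `repeat_class`,
#'   `species`, `chrom`, `start`, `end` (one row per symbol x species).
#' @export
make_te_fixture <- function(exon5_duplicate_i = FALSE) {
  def <- tibble(
    symbol = LETTERS[1:11],
    name = c("MIR", "MIR", "Chap1_Mam", "MER91A", "URR1B", "MTEb",
             "MIR3", "MT2B2", "B1F", "PB1D10", "L1MD3"),
    repeat_class = c("SINE", "SINE", "DNA", "DNA", "DNA", "LTR",
                     "SINE", "LTR", "SINE", "SINE", "LINE"),
    species_set = list(
      c("mouse", "rat", "human", "dog"),   # A
      c("mouse", "rat", "human", "dog"),   # B
      c("mouse", "human"),                 # C
      c("mouse", "rat", "human", "dog"),   # D
      c("mouse", "rat"),                   # E
      c("mouse", "rat"),                   # F
      c("mouse", "rat", "human"),          # G
      c("mouse", "rat"),                   # H
      c("mouse", "rat"),                   # I
      c("mouse", "rat"),                   # J
      c("mouse", "human", "dog")           # K
    ),
    start = c(8850, 7400, 7700, 6000, 2600, 3000,
              1050, 1300, 1500, 1700, 1900),
    end = c(9050, 7600, 7900, 6200, 2800, 3200,
            1200, 1400, 1600, 1800, 2100)
  )
  if (exon5_duplicate_i) {
    def$symbol[def$symbol == "J"] <- "I"
    def$name[def$name == "PB1D10"] <- "B1F"
  }
  decoys <- tibble(
    symbol = c("DecoyM", "DecoyR"),
    name = c("B1_Mus1", "ID_Rn1"),
    repeat_class = c("SINE", "SINE"),
    species_set = list("mouse", "rat"),
    start = c(12000, 12300),
    end = c(12150, 12450)
  )
  bind_rows(def, decoys) |>
    tidyr::unnest_longer("species_set", values_to = "species") |>
    mutate(chrom = "chr10") |>
    select("symbol", "name", "repeat_class", "species", "chrom",
           "start", "end")
}

#' Exon/intron feature map of the toy locus
#'
#' Feature intervals (0-based half-open, mouse toy coordinates) for the
#' two overlapping antisense lncRNA genes: the sense gene with 3 exons
#' and 2 introns, and its antisense partner with 5 exons and 4 introns.
#' The layout reproduces the locus's TE/feature composition together
#' with [make_te_fixture()].
#'
#' @return A feature tibble: `id`, `chrom`, `start`, `end`, `strand`.
#' @export
locus_features <- function() {
  ak <- tibble(
    id = paste0("Ak158810.", c("exon5", "intron4", "exon4", "intron3",
                               "exon3", "intron2", "exon2", "intron1",
                               "exon1")),
    start = c(1000, 2500, 4000, 4150, 5500, 5800, 7200, 7350, 8600),
    end = c(2500, 4000, 4150, 5500, 5800, 7200, 7350, 8600, 8800),
    strand = "-"
  )
  pldi <- tibble(
    id = paste0("Pldi.", c("exon1", "intron1", "exon2", "intron2", "exon3")),
    start = c(5850, 5950, 9100, 9300, 10500),
    end = c(5950, 9100, 9300, 10500, 10800),
    strand = "+"
  )
  bind_rows(pldi, ak) |>
    mutate(chrom = "chr10") |>
    select("id", "chrom", "start", "end", "strand")
}

# T-free codons ({A,C,G}^3) cannot contain a stop or a start codon in
# any reading frame of either strand; bodies built from them guarantee
# the designed ORFs are the only ones present.
tfree_codons <- function() {
  g <- expand.grid(c("A", "C", "G"), c("A", "C", "G"), c("A", "C", "G"))
  apply(g, 1, paste0, collapse = "")
}

#' Synthetic transcript with the locus transcript's ORF architecture
#'
#' Builds a 2.9 kb synthetic transcript engineered to carry the ORF
#' structure reported for the locus's antisense EST: a longest
#' AUG-initiated ORF of 104 amino acids (shorter than 110), preceded by
#' exactly two upstream AUG codons opening reading frames of about 70
#' amino acids (70 and 72 aa). Untranslated stretches are built from a
#' `TTAA` repeat (stop codons in all frames, no AUG on either strand)
#' and ORF bodies from T-free codons, so the designed ORFs are provably
#' the only AUG-initiated frames in the sequence. This is a synthetic
#' stand-in, not the real EST sequence.
#'
#' @param seed Integer seed for the body codon draw.
#' @param length_nt Total transcript length (default 2900).
#' @return A single DNA string.
#' @examples
#' tx <- make_transcript_fixture(seed = 1)
#' find_orfs(tx, min_aa = 30)
#' @export
make_transcript_fixture <- function(seed = 1, length_nt = 2900) {
  set.seed(as.integer(seed))
  codons <- tfree_codons()
  body <- function(n_codons) {
    # last codon fixed so no CAT (reverse-strand AUG) forms at the
    # body/stop junction
    paste0(
      paste0(sample(codons, n_codons - 1, replace = TRUE), collapse = ""),
      "GGA"
    )
  }
  # stop is always TAA: a TGA stop after a body ending in A would create
  # a spurious ATG trinucleotide at the junction
  orf <- function(n_aa) paste0("ATG", body(n_aa - 1), "TAA")
  filler <- function(n_nt) {
    strtrim(paste(rep("TTAA", ceiling(n_nt / 4)), collapse = ""), n_nt)
  }
  parts <- c(
    filler(160),
    orf(70),
    filler(40),
    orf(72),
    filler(40),
    orf(104)
  )
  head_part <- paste0(parts, collapse = "")
  if (nchar(head_part) > length_nt) {
    abort("length_nt too short for the designed ORF architecture",
          class = "rateshift_error_param")
  }
  paste0(head_part, filler(length_nt - nchar(head_part)))
}

#' Synthetic stand-ins for the curated conserved-element alignments
#'
#' Generates gap-free synthetic alignments emulating the measured rate
#' regimes of the locus's two conserved elements: CE1 (inside the
#' inversion; normalized rates decreasing from the human-dog to the
#' mouse-rat comparison) and CE2 (outside the inversion; human-rat rate
#' exceeding human-dog). Stage rates are obtained by algebraically
#' inverting the reported normalized-rate triples at an early-event
#' timing (`k1 = k2 = 0.05`, the regime in which both triples are
#' feasible), and four constant-rate reference alignments play the role
#' of the flanking-gene exons. These are synthetic data, not the
#' published curated alignments.
#'
#' @param seed Integer seed.
#' @param tree A [species_tree()].
#' @param ce1_ratios,ce2_ratios Normalized-rate triples
#'   `(r_aver_hd, r_aver_hr, r_aver_mr)` the stand-ins emulate;
#'   defaults are the values reported for the locus.
#' @param k Event-timing fraction used for both changepoints.
#' @param length_ce Test alignment length (sites).
#' @param ref_lengths Lengths of the four reference alignments.
#' @return A list with `ce1`, `ce2` (`mult_aln` test alignments),
#'   `refs` (list of four `mult_aln`), and `params` (list of the two
#'   `rate_params` used).
#' @export
make_ce_standins <- function(seed = 1, tree = species_tree(),
                             ce1_ratios = c(2.5971, 2.0603, 1.406),
                             ce2_ratios = c(1.6694, 2.1832, 1.5047),
                             k = 0.05,
                             length_ce = 20000,
                             ref_lengths = c(1200, 900, 1500, 1000)) {
  params_for <- function(ratios) {
    sol <- solve_rate_ratios(
      normalized_rates_from_values(ratios[1], ratios[2], ratios[3]),
      k1 = k, k2 = k
    )
    if (!sol$feasible) {
      abort("target ratios infeasible at this k", class = "rateshift_error_param")
    }
    rate_params(r0 = sol$rho0, r1 = sol$rho1, r2 = sol$rho2, rR = 1,
                k1 = k, k2 = k, tree = tree)
  }
  p1 <- params_for(ce1_ratios)
  p2 <- params_for(ce2_ratios)
  seeds <- as.integer(seed) + 0:5
  ce1 <- simulate_locus(tree, p1, length_ce, 10, seed = seeds[1])$test
  ce2 <- simulate_locus(tree, p2, length_ce, 10, seed = seeds[2])$test
  refs <- purrr::map2(ref_lengths, seeds[3:6], function(len, s) {
    simulate_locus(tree, p1, 10, len, seed = s)$ref
  })
  list(ce1 = ce1, ce2 = ce2, refs = refs, params = list(ce1 = p1, ce2 = p2))
}
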