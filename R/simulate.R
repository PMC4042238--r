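# Seeded phylogenetic sequence simulation under the two-changepoint
# rate model: JC69 substitutions, no indels, root drawn uniformly over
# {A,C,G,T}, so alignment columns are positional identity.

BASES <- c("A", "C", "G", "T")

# one JC69 branch: expected distance d substitutions/site
jc69_evolve <- function(parent, d) {
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  flip <- runif(length(parent)) < p_change
  nflip <- sum(flip)
  if (nflip > 0) {
    parent[flip] <- ((parent[flip] - 1L + sample.int(3L, nflip, replace = TRUE)) %% 4L) + 1L
  }
  parent
}

# expected substitutions/site on one branch under a schedule
branch_length_from_schedule <- function(schedule, br) {
  rows <- schedule[schedule$branch == br, , drop = FALSE]
  sum((rows$t_old - rows$t_young) * rows$rate)
}

simulate_on_schedule <- function(tree, schedule, length) {
  bl <- setNames(
    map_dbl(tree_branches(tree)$branch,
            ~ branch_length_from_schedule(schedule, .x)),
    tree_branches(tree)$branch
  )
  root <- sample.int(4L, length, replace = TRUE)
  hr_anc <- jc69_evolve(root, bl[["hr_to_root"]])
  dog <- jc69_evolve(root, bl[["dog"]])
  human <- jc69_evolve(hr_anc, bl[["human"]])
  mr_anc <- jc69_evolve(hr_anc, bl[["rodent_stem"]])
  mouse <- jc69_evolve(mr_anc, bl[["mouse"]])
  rat <- jc69_evolve(mr_anc, bl[["rat"]])
  multiple_alignment(c(
    mouse = paste0(BASES[mouse], collapse = ""),
    rat = paste0(BASES[rat], collapse = ""),
    human = paste0(BASES[human], collapse = ""),
    dog = paste0(BASES[dog], collapse = "")
  ))
}

#' Simulate a test locus and its constant-rate reference
#'
#' Evolves gap-free orthologous sequences on the fixed four-taxon tree.
#' The test alignment follows the piecewise-constant regime: rate `r0`
#' on every lineage segment older than the inversion changepoint (placed
#' on the rodent stem at time `(1 - k1) * t_hr` before present), `r1`
#' on the rodent lineage between the changepoints, and `r2` on both
#' rodent terminal branches from time `(1 - k2) * t_mr / 2` to the
#' present, so that the expected mouse-rat path carries a total `r2`
#' stretch of `(1 - k2) * t_mr`. Non-rodent lineages stay at `r0`
#' throughout (they never experienced either event). The reference
#' alignment evolves at the constant rate `rR` on every branch.
#'
#' Users preferring a different event convention can pass a raw
#' `test_schedule`: a tibble with columns `branch` (one of `mouse`,
#' `rat`, `human`, `dog`, `rodent_stem`, `hr_to_root`), `t_young`,
#' `t_old` (time before present) and `rate`, which overrides the regime
#' derived from `params`.
#'
#' @inheritParams expected_distances
#' @param length_test,length_ref Alignment lengths in sites (>= 1).
#' @param seed Integer seed; fully determines the output.
#' @param test_schedule Optional raw per-segment rate schedule (see
#'   Details).
#' @return A `simulated_locus` object: list with `test` and `ref`
#'   (`mult_aln`), `params`, `tree`, `seed`.
#' @examples
#' loc <- simulate_locus(species_tree(), rate_params(2, 1, 0.5),
#'                       length_test = 200, length_ref = 200, seed = 1)
#' loc$test
#' @export
simulate_locus <- function(tree, params, length_test, length_ref, seed,
                           test_schedule = NULL) {
  for (len in c(length_test, length_ref)) {
    if (!is.numeric(len) || len < 1) {
      abort("alignment lengths must be >= 1 site",
            class = "rateshift_error_param")
    }
  }
  stopifnot(inherits(tree, "species_tree"), inherits(params, "rate_params"))
  # re-check feasibility against this tree (params may carry another tree's k1)
  if ((1 - params$k1) * tree$t_hr < tree$t_mr) {
    abort("infeasible (k1, times): inversion changepoint below the rodent stem",
          class = "rateshift_error_param")
  }
  schedule <- test_schedule %||% rate_schedule(tree, params)
  set.seed(as.integer(seed))
  test <- simulate_on_schedule(tree, schedule, as.integer(length_test))
  ref <- simulate_on_schedule(tree, reference_schedule(tree, params),
                              as.integer(length_ref))
  structure(
    list(test = test, ref = ref, params = params, tree = tree,
         seed = as.integer(seed)),
    class = "simulated_locus"
  )
}

#' @export
print.simulated_locus <- function(x, ...) {
  cat(sprintf(
    "Simulated locus (seed %d): test %d sites, reference %d sites\n",
    x$seed, aln_width(x$test), aln_width(x$ref)
  ))
  print(x$params)
  invisible(x)
}
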