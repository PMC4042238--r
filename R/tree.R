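#' Four-species phylogeny for the rate-shift model
#'
#' The analysis is defined on a fixed four-taxon topology,
#' `(((mouse,rat),human),dog)`, parameterized by the three pairwise
#' divergence times. Times are in arbitrary units (the model works with
#' rate x time products, so only ratios matter); the defaults are
#' approximate divergence times in units of 100 My (mouse-rat ~ 0.05 x
#' 100 My around the rodent radiation, human-rodent ~ 0.2, human-dog
#' ~ 0.25).
#'
#' @param t_mr Mouse-rat divergence time (> 0).
#' @param t_hr Human-rodent divergence time (> `t_mr`).
#' @param t_hd Human-dog divergence time (> `t_hr`).
#'
#' @return A `species_tree` object: a list with elements `taxa` (the four
#'   labels in the fixed order mouse, rat, human, dog), `t_mr`, `t_hr`,
#'   `t_hd`.
#' @examples
#' species_tree()
#' species_tree(t_mr = 0.04, t_hr = 0.18, t_hd = 0.22)
#' @export
species_tree <- function(t_mr = 0.05, t_hr = 0.2, t_hd = 0.25) {
  if (!is.numeric(t_mr) || !is.numeric(t_hr) || !is.numeric(t_hd)) {
    abort("divergence times must be numeric", class = "rateshift_error_param")
  }
  if (!(0 < t_mr && t_mr < t_hr && t_hr < t_hd)) {
    abort(
      "divergence times must satisfy 0 < t_mr < t_hr < t_hd",
      class = "rateshift_error_param"
    )
  }
  structure(
    list(
      taxa = c("mouse", "rat", "human", "dog"),
      t_mr = t_mr, t_hr = t_hr, t_hd = t_hd
    ),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree (((mouse,rat),human),dog)\n")
  cat(sprintf(
    "  t_mr = %g, t_hr = %g, t_hd = %g\n", x$t_mr, x$t_hr, x$t_hd
  ))
  invisible(x)
}

#' Stage rates and event timings for the two-changepoint model
#'
#' The test region evolves under three constant substitution rates: `r0`
#' before the inversion, `r1` between the inversion and the birth of the
#' lncRNA gene, and `r2` after gene birth. Flanking-gene reference exons
#' evolve at a single rate `rR` on every branch. Two dimensionless
#' fractions place the events: the inversion occurred `k1` of the way
#' back from the human-rodent ancestor, i.e. at time `(1 - k1) * t_hr`
#' before present (it must fall on the rodent stem, so
#' `t_mr <= (1 - k1) * t_hr` is required); gene birth occurred within the
#' last `(1 - k2)` fraction of the mouse-rat path.
#'
#' @param r0,r1,r2 Test-region stage rates, substitutions per site per
#'   time unit (> 0).
#' @param rR Reference rate (> 0).
#' @param k1,k2 Event-timing fractions, strictly inside (0, 1).
#' @param tree A [species_tree()]; used to check that the inversion
#'   changepoint implied by `k1` lies on the rodent stem.
#'
#' @return A `rate_params` object (a named list).
#' @examples
#' rate_params(r0 = 2, r1 = 1, r2 = 0.5, rR = 1, k1 = 0.5, k2 = 0.5)
#' @export
rate_params <- function(r0, r1, r2, rR = 1, k1 = 0.5, k2 = 0.5,
                        tree = species_tree()) {
  rates <- c(r0 = r0, r1 = r1, r2 = r2, rR = rR)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("all rates must be finite and > 0", class = "rateshift_error_param")
  }
  for (k in c(k1, k2)) {
    if (!is.finite(k) || k <= 0 || k >= 1) {
      abort("k1 and k2 must lie strictly in (0, 1)",
            class = "rateshift_error_param")
    }
  }
  inv_time <- (1 - k1) * tree$t_hr
  if (inv_time < tree$t_mr) {
    abort(
      sprintf(
        paste0(
          "infeasible timing: the inversion changepoint (1 - k1) * t_hr = %g ",
          "predates the mouse-rat split only if >= t_mr = %g; ",
          "it must lie on the rodent stem"
        ),
        inv_time, tree$t_mr
      ),
      class = "rateshift_error_param"
    )
  }
  structure(
    list(r0 = r0, r1 = r1, r2 = r2, rR = rR, k1 = k1, k2 = k2),
    class = "rate_params"
  )
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf(
    "Rate parameters: r0 = %g, r1 = %g, r2 = %g, rR = %g (k1 = %g, k2 = %g)\n",
    x$r0, x$r1, x$r2, x$rR, x$k1, x$k2
  ))
  invisible(x)
}

# Branch segments of the fixed topology, as intervals of time before
# present [t_young, t_old). The rodent stem runs from t_hr down to t_mr;
# the basal branch joins the human-rodent ancestor to the root.
tree_branches <- function(tree) {
  tibble(
    branch = c("mouse", "rat", "human", "dog", "rodent_stem", "hr_to_root"),
    t_young = c(0, 0, 0, 0, tree$t_mr, tree$t_hr),
    t_old = c(tree$t_mr, tree$t_mr, tree$t_hr, tree$t_hd, tree$t_hr, tree$t_hd)
  )
}

# Piecewise-constant rate schedule realized on each branch.
# Test regime: inversion on the rodent stem at a1 = (1 - k1) * t_hr;
# gene birth on both rodent terminals at a2 = (1 - k2) * t_mr / 2.
# All non-rodent lineage segments stay at r0.
rate_schedule <- function(tree, params) {
  a1 <- (1 - params$k1) * tree$t_hr
  a2 <- (1 - params$k2) * tree$t_mr / 2
  seg <- function(branch, t_young, t_old, rate) {
    tibble(branch = branch, t_young = t_young, t_old = t_old, rate = rate)
  }
  terminals <- purrr::map(c("mouse", "rat"), function(b) {
    bind_rows(
      seg(b, a2, tree$t_mr, params$r1),
      seg(b, 0, a2, params$r2)
    )
  })
  bind_rows(
    seg("dog", 0, tree$t_hd, params$r0),
    seg("human", 0, tree$t_hr, params$r0),
    seg("hr_to_root", tree$t_hr, tree$t_hd, params$r0),
    seg("rodent_stem", a1, tree$t_hr, params$r0),
    seg("rodent_stem", tree$t_mr, a1, params$r1),
    list_rbind(terminals)
  ) |>
    filter(.data$t_old > .data$t_young)
}

reference_schedule <- function(tree, params) {
  tree_branches(tree) |>
    mutate(rate = params$rR) |>
    select("branch", "t_young", "t_old", "rate")
}

# Path from taxon to taxon: which branches connect each species pair.
pair_paths <- list(
  hd = c("human", "hr_to_root", "dog"),
  hr = c("human", "rodent_stem", "rat"),
  mr = c("mouse", "rat")
)

#' Expected pairwise distances under a rate schedule
#'
#' Integrates the piecewise-constant substitution rate along the tree
#' path connecting each species pair of interest (human-dog, human-rat,
#' mouse-rat), for both the test-region regime and the constant-rate
#' reference regime. These are the exact expectations that the JC69
#' distance estimator converges to as alignment length grows.
#'
#' @inheritParams rate_params
#' @param params A [rate_params()] object.
#' @return A tibble with columns `pair`, `d_test`, `d_ref`, and their
#'   ratio `r_aver`.
#' @examples
#' expected_distances(species_tree(), rate_params(2, 1, 0.5))
#' @export
expected_distances <- function(tree, params) {
  integrate_path <- function(schedule, branches) {
    schedule |>
      filter(.data$branch %in% branches) |>
      summarise(d = sum((.data$t_old - .data$t_young) * .data$rate)) |>
      pull("d")
  }
  test_s <- rate_schedule(tree, params)
  ref_s <- reference_schedule(tree, params)
  tibble(
    pair = names(pair_paths),
    d_test = map_dbl(pair_paths, ~ integrate_path(test_s, .x)),
    d_ref = map_dbl(pair_paths, ~ integrate_path(ref_s, .x))
  ) |>
    mutate(r_aver = .data$d_test / .data$d_ref)
}
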