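# The core computation: normalized average substitution rates per
# species pair, qualitative rate-shift calls, and algebraic recovery of
# the stage rates relative to the reference rate.
#
# With the inversion at fraction k1 of the human-rodent time and gene
# birth at fraction k2 of the mouse-rat time, the expected test
# distances are
#   d_test_HD = 2 r0 t_HD
#   d_test_HR = (1 + k1) r0 t_HR + (1 - k1) r1 t_HR
#   d_test_MR = (1 + k2) r1 t_MR + (1 - k2) r2 t_MR
# and the references d_ref_XY = 2 rR t_XY, so the normalized rates are
#   r_aver_HD = rho0
#   r_aver_HR = [(1 + k1) rho0 + (1 - k1) rho1] / 2
#   r_aver_MR = [(1 + k2) rho1 + (1 - k2) rho2] / 2
# with rho_i = r_i / rR. The divisor 2 makes r_aver_HR -> r_aver_HD as
# k1 -> 1 (no post-inversion time) and gives (1, 1, 1) when all rates
# are equal; `printed_form = TRUE` drops it for comparison with sources
# that omit it.

extract_value <- function(x) {
  if (is.data.frame(x)) x$value[1] else as.numeric(x)
}

#' Normalized average substitution rates
#'
#' Divides each test-region pairwise distance by the reference-exon
#' distance for the same species pair, giving the dimensionless
#' normalized rates `r_aver_hd`, `r_aver_hr`, `r_aver_mr`.
#'
#' @param d_test_hd,d_test_hr,d_test_mr Test-region distances
#'   (human-dog, human-rat, mouse-rat); numbers or one-row distance
#'   tibbles from [jc69_distance()] and friends.
#' @param d_ref_hd,d_ref_hr,d_ref_mr Matching reference distances
#'   (all must be > 0).
#' @return A `normalized_rates` tibble (one row, three columns).
#' @examples
#' normalized_rates(0.52, 0.4, 0.14, 0.20, 0.20, 0.10)
#' @export
normalized_rates <- function(d_test_hd, d_test_hr, d_test_mr,
                             d_ref_hd, d_ref_hr, d_ref_mr) {
  test <- vapply(list(d_test_hd, d_test_hr, d_test_mr), extract_value, 0)
  ref <- vapply(list(d_ref_hd, d_ref_hr, d_ref_mr), extract_value, 0)
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    abort("reference distances must all be > 0 (reference uninformative)",
          class = "rateshift_error_reference")
  }
  normalized_rates_from_values(test[1] / ref[1], test[2] / ref[2],
                               test[3] / ref[3])
}

#' @rdname normalized_rates
#' @param r_aver_hd,r_aver_hr,r_aver_mr Already-formed ratios.
#' @export
normalized_rates_from_values <- function(r_aver_hd, r_aver_hr, r_aver_mr) {
  out <- tibble(
    r_aver_hd = r_aver_hd, r_aver_hr = r_aver_hr, r_aver_mr = r_aver_mr
  )
  if (any(!is.finite(unlist(out))) || any(unlist(out) <= 0)) {
    abort("normalized rates must be finite and > 0",
          class = "rateshift_error_param")
  }
  class(out) <- c("normalized_rates", class(out))
  out
}

direction_call <- function(lhs, rhs, tolerance) {
  if (lhs < rhs * (1 - tolerance)) "reduced"
  else if (lhs > rhs * (1 + tolerance)) "increased"
  else "unchanged"
}

#' Qualitative rate-shift call from normalized rates
#'
#' The inversion effect compares the post-inversion mixture `r_aver_hr`
#' against the pre-inversion rate `r_aver_hd`: a lower `r_aver_hr` means
#' the rate dropped after the rearrangement (`r1 < r0`). The gene-birth
#' effect compares `r_aver_mr` against `r_aver_hr` in the same way. A
#' relative tolerance band defines "unchanged".
#'
#' @param nr A `normalized_rates` row.
#' @param tolerance Relative half-width of the "unchanged" band
#'   (default 0.02).
#' @return A tibble with `inversion_effect`, `birth_effect` (each one of
#'   `"reduced"`, `"increased"`, `"unchanged"`) and `tolerance`.
#' @examples
#' infer_ordering(normalized_rates_from_values(2.5971, 2.0603, 1.406))
#' @export
infer_ordering <- function(nr, tolerance = 0.02) {
  tibble(
    inversion_effect = direction_call(nr$r_aver_hr, nr$r_aver_hd, tolerance),
    birth_effect = direction_call(nr$r_aver_mr, nr$r_aver_hr, tolerance),
    tolerance = tolerance
  )
}

#' Recover stage-rate ratios from normalized rates at given timings
#'
#' Inverts the normalized-rate equations at fixed event timings
#' `(k1, k2)`:
#' `rho0 = r_aver_hd`,
#' `rho1 = (2 r_aver_hr - (1 + k1) rho0) / (1 - k1)`,
#' `rho2 = (2 r_aver_mr - (1 + k2) rho1) / (1 - k2)`.
#' A solution with any non-positive rho is algebraically exact but
#' physically infeasible (rates must be positive) and is flagged.
#'
#' @inheritParams infer_ordering
#' @param k1,k2 Event-timing fractions, strictly in (0, 1).
#' @param printed_form If `TRUE`, invert the uncorrected form of the
#'   mixture equations (no divisor 2): `rho1 = (r_aver_hr - (1 + k1)
#'   rho0) / (1 - k1)` etc. Default `FALSE`.
#' @return A one-row tibble: `k1`, `k2`, `rho0`, `rho1`, `rho2`,
#'   `feasible`.
#' @examples
#' solve_rate_ratios(normalized_rates_from_values(2, 1.75, 0.875),
#'                   k1 = 0.5, k2 = 0.5)
#' @export
solve_rate_ratios <- function(nr, k1, k2, printed_form = FALSE) {
  for (k in c(k1, k2)) {
    if (!is.finite(k) || k <= 0 || k >= 1) {
      abort("k1 and k2 must lie strictly in (0, 1)",
            class = "rateshift_error_param")
    }
  }
  mult <- if (printed_form) 1 else 2
  rho0 <- nr$r_aver_hd
  rho1 <- (mult * nr$r_aver_hr - (1 + k1) * rho0) / (1 - k1)
  rho2 <- (mult * nr$r_aver_mr - (1 + k2) * rho1) / (1 - k2)
  tibble(
    k1 = k1, k2 = k2, rho0 = rho0, rho1 = rho1, rho2 = rho2,
    feasible = rho0 > 0 & rho1 > 0 & rho2 > 0
  )
}

#' Stage-rate solutions over a grid of event timings
#'
#' The event timings are not identified by the three normalized rates,
#' so the solution is scanned over a `(k1, k2)` grid; the feasible
#' region and the range of each rho over it summarize what the data can
#' say about the stage rates.
#'
#' @inheritParams solve_rate_ratios
#' @param grid_step Grid spacing in (0, 1); grid points run from
#'   `grid_step` to `1 - grid_step`.
#' @return A `rate_scan` tibble: one row per grid point with the
#'   [solve_rate_ratios()] columns.
#' @examples
#' scan <- rate_ratio_scan(normalized_rates_from_values(2, 1.75, 0.875))
#' glance(scan)
#' @export
rate_ratio_scan <- function(nr, grid_step = 0.05, printed_form = FALSE) {
  if (!is.finite(grid_step) || grid_step <= 0 || grid_step >= 1) {
    abort("grid_step must lie strictly in (0, 1)",
          class = "rateshift_error_param")
  }
  ks <- seq(grid_step, 1 - grid_step / 2, by = grid_step)
  ks <- ks[ks < 1]
  grid <- tidyr::expand_grid(k1 = ks, k2 = ks)
  out <- purrr::pmap(grid, function(k1, k2) {
    solve_rate_ratios(nr, k1, k2, printed_form = printed_form)
  }) |> list_rbind()
  class(out) <- c("rate_scan", class(out))
  out
}

#' @exportS3Method generics::glance
glance.rate_scan <- function(x, ...) {
  feas <- dplyr::filter(as_tibble(x), .data$feasible)
  tibble(
    n_grid = nrow(x),
    n_feasible = nrow(feas),
    rho0_min = min(feas$rho0), rho0_max = max(feas$rho0),
    rho1_min = min(feas$rho1), rho1_max = max(feas$rho1),
    rho2_min = min(feas$rho2), rho2_max = max(feas$rho2)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rate_scan <- function(object, rho = "rho1", ...) {
  df <- as_tibble(object)
  df$value <- df[[rho]]
  df$value[!df$feasible] <- NA_real_
  ggplot(df, aes(x = .data$k1, y = .data$k2, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(fill = rho,
         title = sprintf("%s over event timings (grey = infeasible)", rho)) +
    theme_minimal()
}

aln_pair_distance <- function(aln, sp1, sp2, model) {
  dm <- function(a, b) switch(model,
    p = p_distance(a, b), jc69 = jc69_distance(a, b), k80 = k80_distance(a, b)
  )
  rows <- unclass(aln)
  if (!all(c(sp1, sp2) %in% names(rows))) {
    abort(sprintf("alignment lacks species %s/%s", sp1, sp2),
          class = "rateshift_error_alignment")
  }
  dm(rows[[sp1]], rows[[sp2]])
}

model_pair_distances <- function(aln, model) {
  pairs <- tibble(
    pair = c("hd", "hr", "mr"),
    sp1 = c("human", "human", "mouse"),
    sp2 = c("dog", "rat", "rat")
  )
  pairs |>
    mutate(est = map2(.data$sp1, .data$sp2,
                      ~ aln_pair_distance(aln, .x, .y, model))) |>
    tidyr::unnest("est")
}

#' End-to-end normalized-rate analysis of a test region
#'
#' Runs the full pipeline: filter the test alignment and each reference
#' alignment with the column-filter policy, concatenate the references
#' into one alignment, estimate the three pairwise distances
#' (human-dog, human-rat, mouse-rat) on test and reference, form the
#' normalized rates, call the qualitative rate shifts, and scan the
#' stage-rate solutions over event timings.
#'
#' @param test_aln A `mult_aln` over mouse, rat, human, dog.
#' @param ref_alns A list of reference `mult_aln` objects (flanking-gene
#'   exon alignments) over the same four species.
#' @param policy A [filter_policy()].
#' @param model Distance model: `"k80"` (default), `"jc69"`, or `"p"`.
#' @param tolerance Relative band for [infer_ordering()].
#' @param grid_step Grid spacing for [rate_ratio_scan()].
#' @return A `rate_analysis` object: list with `distances` (tibble of
#'   the six pairwise estimates), `normalized` (the rate triple),
#'   `ordering`, `scan`, `model`, and the filtered alignment widths.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' loc <- simulate_locus(species_tree(), rate_params(2, 1, 0.5),
#'                       5000, 5000, seed = 1)
#' fit <- run_rate_analysis(loc$test, list(loc$ref), model = "jc69")
#' glance(fit)
#' @export
run_rate_analysis <- function(test_aln, ref_alns,
                              policy = filter_policy(),
                              model = c("k80", "jc69", "p"),
                              tolerance = 0.02, grid_step = 0.05) {
  model <- match.arg(model)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
            class = "rateshift_error_pipeline")
    })
  }
  test_f <- stage("filter test alignment", filter_columns(test_aln, policy))
  refs_f <- stage("filter reference alignments",
                  purrr::map(ref_alns, filter_columns, policy = policy))
  ref_cat <- stage("concatenate references", concat_alignments(refs_f))
  d_test <- stage("test distances", model_pair_distances(test_f, model))
  d_ref <- stage("reference distances", model_pair_distances(ref_cat, model))
  nr <- stage("normalized rates", normalized_rates(
    d_test$value[d_test$pair == "hd"],
    d_test$value[d_test$pair == "hr"],
    d_test$value[d_test$pair == "mr"],
    d_ref$value[d_ref$pair == "hd"],
    d_ref$value[d_ref$pair == "hr"],
    d_ref$value[d_ref$pair == "mr"]
  ))
  structure(
    list(
      distances = bind_rows(
        mutate(d_test, role = "test"),
        mutate(d_ref, role = "reference")
      ),
      normalized = nr,
      ordering = infer_ordering(nr, tolerance),
      scan = rate_ratio_scan(nr, grid_step),
      model = model,
      test_width = aln_width(test_f),
      ref_width = aln_width(ref_cat)
    ),
    class = "rate_analysis"
  )
}

#' @export
print.rate_analysis <- function(x, ...) {
  cat(sprintf("Rate-shift analysis (%s distances)\n", x$model))
  cat(sprintf("  test: %d columns after filtering; reference: %d columns\n",
              x$test_width, x$ref_width))
  cat(sprintf("  normalized rates: HD %.4f, HR %.4f, MR %.4f\n",
              x$normalized$r_aver_hd, x$normalized$r_aver_hr,
              x$normalized$r_aver_mr))
  cat(sprintf("  after inversion: %s; after gene birth: %s (tolerance %g)\n",
              x$ordering$inversion_effect, x$ordering$birth_effect,
              x$ordering$tolerance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rate_analysis <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x$normalized),
    cols = dplyr::everything(),
    names_to = "statistic", values_to = "estimate"
  )
}

#' @exportS3Method generics::glance
glance.rate_analysis <- function(x, ...) {
  dplyr::bind_cols(
    as_tibble(x$normalized),
    x$ordering[, c("inversion_effect", "birth_effect")],
    tibble(model = x$model, test_width = x$test_width,
           ref_width = x$ref_width)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rate_analysis <- function(object, ...) {
  df <- tidy(object)
  df$statistic <- factor(
    df$statistic,
    levels = c("r_aver_hd", "r_aver_hr", "r_aver_mr"),
    labels = c("human-dog", "human-rat", "mouse-rat")
  )
  ggplot(df, aes(x = .data$statistic, y = .data$estimate, group = 1)) +
    geom_line(colour = "grey50") +
    geom_point(size = 3) +
    labs(x = "species pair (time depth decreasing)",
         y = "normalized substitution rate",
         title = "Normalized average substitution rates") +
    theme_minimal()
}

#' Serialize a rate analysis to JSON / TSV
#'
#' @param x A `rate_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_report <- function(x, path) {
  obj <- list(
    model = x$model,
    test_width = x$test_width,
    ref_width = x$ref_width,
    distances = x$distances,
    normalized = as_tibble(x$normalized),
    ordering = x$ordering,
    scan_summary = glance(x$scan),
    scan = as_tibble(x$scan)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  tsv <- sub("\\.json$", ".tsv", path)
  if (tsv != path) {
    utils::write.table(as_tibble(x$scan), tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
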