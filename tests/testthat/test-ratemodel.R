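# Normalized rates, ordering calls, algebraic stage-rate recovery, and
# the end-to-end pipeline.

# forward model evaluated independently of the package's solver
forward_ratios <- function(rho0, rho1, rho2, k1, k2) {
  c(hd = rho0,
    hr = ((1 + k1) * rho0 + (1 - k1) * rho1) / 2,
    mr = ((1 + k2) * rho1 + (1 - k2) * rho2) / 2)
}

test_that("normalized rates are test over reference, per pair", {
  nr <- normalized_rates(0.52, 0.4, 0.14, 0.20, 0.20, 0.10)
  expect_equal(nr$r_aver_hd, 2.6)
  expect_equal(nr$r_aver_hr, 2.0)
  expect_equal(nr$r_aver_mr, 1.4)
  expect_error(normalized_rates(0.5, 0.4, 0.1, 0, 0.2, 0.1),
               class = "rateshift_error_reference")
  # distance-tibble inputs work too
  nr2 <- normalized_rates(jc69_distance("ACGT", "ACGA"), 0.4, 0.14,
                          0.2, 0.2, 0.1)
  expect_equal(nr2$r_aver_hd, 0.3040988 / 0.2, tolerance = 1e-6)
})

test_that("normalized rates are scale invariant in the distances", {
  base <- normalized_rates(0.52, 0.4, 0.14, 0.2, 0.2, 0.1)
  scaled <- normalized_rates(5.2, 4.0, 1.4, 2.0, 2.0, 1.0)
  expect_equal(as.numeric(base[1, ]), as.numeric(scaled[1, ]))
})

test_that("ordering calls reproduce the conserved-element directions", {
  # inside the inversion: HD > HR means the rate dropped after the event
  ce1 <- infer_ordering(normalized_rates_from_values(2.5971, 2.0603, 1.406),
                        tolerance = 0)
  expect_identical(ce1$inversion_effect, "reduced")
  # outside the inversion the tendency is opposite
  ce2 <- infer_ordering(normalized_rates_from_values(1.6694, 2.1832, 1.5047),
                        tolerance = 0)
  expect_identical(ce2$inversion_effect, "increased")
  flat <- infer_ordering(normalized_rates_from_values(1, 1, 1),
                         tolerance = 0.1)
  expect_identical(flat$inversion_effect, "unchanged")
  expect_identical(flat$birth_effect, "unchanged")
})

test_that("the ordering call depends only on the sign outside the band", {
  set.seed(31)
  for (i in 1:50) {
    hd <- stats::runif(1, 0.5, 3)
    hr <- stats::runif(1, 0.5, 3)
    tol <- stats::runif(1, 0, 0.1)
    call <- infer_ordering(
      normalized_rates_from_values(hd, hr, 1), tolerance = tol
    )$inversion_effect
    expected <- if (hr < hd * (1 - tol)) "reduced"
                else if (hr > hd * (1 + tol)) "increased" else "unchanged"
    expect_identical(call, expected)
  }
})

test_that("stage-rate recovery inverts the forward model", {
  nr <- normalized_rates_from_values(2.0, 1.75, 0.875)
  sol <- solve_rate_ratios(nr, 0.5, 0.5)
  expect_equal(c(sol$rho0, sol$rho1, sol$rho2), c(2, 1, 0.5),
               tolerance = 1e-12)
  flat <- solve_rate_ratios(normalized_rates_from_values(1, 1, 1), 0.3, 0.7)
  expect_equal(c(flat$rho0, flat$rho1, flat$rho2), c(1, 1, 1),
               tolerance = 1e-12)
  expect_error(solve_rate_ratios(nr, 1, 0.5),
               class = "rateshift_error_param")
})

test_that("forward then inverse recovers random feasible stage rates", {
  set.seed(12)
  for (i in 1:200) {
    rho <- stats::runif(3, 0.2, 3)
    k <- stats::runif(2, 0.05, 0.95)
    fr <- unname(forward_ratios(rho[1], rho[2], rho[3], k[1], k[2]))
    sol <- solve_rate_ratios(
      normalized_rates_from_values(fr[1], fr[2], fr[3]),
      k[1], k[2]
    )
    expect_true(sol$feasible)
    expect_equal(c(sol$rho0, sol$rho1, sol$rho2), unname(rho),
                 tolerance = 1e-10)
  }
})

test_that("the printed (uncorrected) form is available and differs", {
  nr <- normalized_rates_from_values(1, 1, 1)
  corr <- solve_rate_ratios(nr, 0.5, 0.5)
  printed <- solve_rate_ratios(nr, 0.5, 0.5, printed_form = TRUE)
  expect_equal(corr$rho1, 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(printed$rho1, corr$rho1)))
})

test_that("the timing scan covers the grid and is internally consistent", {
  flat <- rate_ratio_scan(normalized_rates_from_values(1, 1, 1),
                          grid_step = 0.1)
  expect_true(all(abs(flat$rho0 - 1) < 1e-12))
  expect_true(all(abs(flat$rho1 - 1) < 1e-12))
  expect_true(all(abs(flat$rho2 - 1) < 1e-12))

  nr <- normalized_rates_from_values(2.0, 1.75, 0.875)
  scan <- rate_ratio_scan(nr, grid_step = 0.05)
  hit <- scan[abs(scan$k1 - 0.5) < 1e-9 & abs(scan$k2 - 0.5) < 1e-9, ]
  expect_equal(c(hit$rho0, hit$rho1, hit$rho2), c(2, 1, 0.5),
               tolerance = 1e-12)
  # rho1 is monotone in k1 at fixed k2 (sign of d rho1/d k1 is the sign
  # of 2*(r_hr - r_hd))
  one_k2 <- scan[abs(scan$k2 - 0.5) < 1e-9, ]
  one_k2 <- one_k2[order(one_k2$k1), ]
  expect_true(all(diff(one_k2$rho1) < 0))
  gl <- glance(scan)
  expect_equal(gl$n_grid, nrow(scan))
  expect_lte(gl$n_feasible, gl$n_grid)
})

test_that("the pipeline calls no change when no change was simulated", {
  tree <- species_tree()
  pars <- rate_params(1, 1, 1, rR = 1, tree = tree)
  loc <- simulate_locus(tree, pars, 6e4, 6e4, seed = 77)
  fit <- run_rate_analysis(loc$test, list(loc$ref), model = "jc69",
                           policy = filter_policy(min_window_identity = 0),
                           tolerance = 0.05)
  expect_identical(fit$ordering$inversion_effect, "unchanged")
  expect_identical(fit$ordering$birth_effect, "unchanged")
})

test_that("the pipeline recovers a simulated rate drop end to end", {
  tree <- species_tree()
  pars <- rate_params(2, 1, 0.5, rR = 1, k1 = 0.5, k2 = 0.5, tree = tree)
  loc <- simulate_locus(tree, pars, 1e5, 1e5, seed = 2024)
  fit <- run_rate_analysis(loc$test, list(loc$ref), model = "jc69",
                           policy = filter_policy(min_window_identity = 0))
  expect_identical(fit$ordering$inversion_effect, "reduced")
  hit <- fit$scan[abs(fit$scan$k1 - 0.5) < 1e-9 &
                    abs(fit$scan$k2 - 0.5) < 1e-9, ]
  expect_equal(c(hit$rho0, hit$rho1, hit$rho2), c(2, 1, 0.5),
               tolerance = 0.1)
  td <- tidy(fit)
  expect_identical(td$statistic,
                   c("r_aver_hd", "r_aver_hr", "r_aver_mr"))
  gl <- glance(fit)
  expect_s3_class(gl, "tbl_df")
  expect_identical(gl$model, "jc69")
})

test_that("pipeline errors name the failing stage", {
  tree <- species_tree()
  pars <- rate_params(1, 1, 1, rR = 1, tree = tree)
  loc <- simulate_locus(tree, pars, 500, 500, seed = 3)
  no_dog <- multiple_alignment(unclass(loc$test)[c("mouse", "rat", "human")])
  expect_error(
    run_rate_analysis(no_dog, list(loc$ref), model = "jc69",
                      policy = filter_policy(min_window_identity = 0)),
    regexp = "stage 'test distances'",
    class = "rateshift_error_pipeline"
  )
})

test_that("reports serialize to JSON with all intermediates", {
  tree <- species_tree()
  pars <- rate_params(2, 1, 0.5, rR = 1, tree = tree)
  loc <- simulate_locus(tree, pars, 2000, 2000, seed = 5)
  fit <- run_rate_analysis(loc$test, list(loc$ref), model = "jc69",
                           policy = filter_policy(min_window_identity = 0))
  f <- withr::local_tempfile(fileext = ".json")
  write_rate_report(fit, f)
  obj <- jsonlite::read_json(f)
  expect_named(obj, c("model", "test_width", "ref_width", "distances",
                      "normalized", "ordering", "scan_summary", "scan"))
  expect_equal(obj$normalized[[1]]$r_aver_hd, fit$normalized$r_aver_hd,
               tolerance = 1e-9)
})
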