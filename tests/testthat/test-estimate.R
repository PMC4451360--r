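test_that("variance-weighted errors follow their definitions", {
  # identical prediction: zero error
  tc <- tibble::tibble(metabolite = "M", time_s = c(1, 2),
                       value = c(0.5, 0.3), variance = c(0.01, 0.03))
  pred0 <- tibble::tibble(metabolite = "M", time_s = c(1, 2),
                          value = c(0.5, 0.3))
  expect_equal(vwss_time(pred0, tc), 0)

  # metabolite-mean variance weighting: mean var 0.02, error (0.01+0.01)/0.02
  pred <- tibble::tibble(metabolite = "M", time_s = c(1, 2),
                         value = c(0.4, 0.2))
  expect_equal(vwss_time(pred, tc), 1.0)

  # doubling variances halves the error
  tc2 <- dplyr::mutate(tc, variance = variance * 2)
  expect_equal(vwss_time(pred, tc2), 0.5)

  expect_error(vwss_time(pred[1, ], tc), "grid")

  expect_equal(vwss_content(c(P = 100), c(P = 100), c(P = 10)), 0)
  expect_equal(vwss_content(c(P = 110), c(P = 100), c(P = 10)), 1)
  expect_error(vwss_content(c(P = 1), c(P = 1), c(P = 0)), "positive")
})

test_that("degrees of freedom use the N - P - 1 convention", {
  expect_equal(degrees_of_freedom(98, 24), 73L)
  expect_equal(degrees_of_freedom(116, 42), 73L)
  expect_equal(degrees_of_freedom(10, 4), 5L)
  expect_error(degrees_of_freedom(10, 9), "nonpositive")
})

test_that("chi-square acceptance intervals are the 5th/95th percentiles", {
  expect_equal(unname(round(chi2_interval(73))), c(54, 94))
  expect_equal(unname(round(chi2_interval(59))), c(42, 78))
  expect_equal(unname(round(chi2_interval(1), 4)), c(0.0039, 3.8415))
  expect_error(chi2_interval(0))
})

test_that("scenario specifications encode the documented masks and bounds", {
  ds <- test_dataset_clean()
  basis <- test_basis()
  sa <- scenario_spec("A", ds, basis)
  sb <- scenario_spec("B", ds, basis)
  sc <- scenario_spec("C", ds, basis)

  expect_equal(sa$n_params, 24)  # 11 flux + 13 inactive fractions
  expect_equal(sb$n_params, 42)  # + 18 contents
  expect_equal(sc$n_params, 37)  # 9 flux + 13 phi + 15 contents
  expect_equal(sa$df, 73L)
  expect_equal(sb$df, 73L)
  expect_equal(sc$df, 59L)
  expect_equal(sa$objective, "t")
  expect_equal(sb$objective, "all")
  expect_equal(sc$objective, "t")

  # A fixes every content at its measured value
  ca <- sa$pars[sa$pars$type == "content", ]
  expect_true(all(!ca$free))
  expect_equal(setNames(ca$value, ca$target),
               setNames(ds$contents$mean, ds$contents$pool))

  # B bounds: mean +/- 4 sd, floored
  cb <- sb$pars[sb$pars$target == "3PGA" & sb$pars$type == "content", ]
  expect_equal(cb$lower, 600.3 - 4 * 135)
  expect_equal(cb$upper, 600.3 + 4 * 135)

  # C: combined pool fixed, wide bounds elsewhere, capped exchanges fixed
  cc <- sc$pars[sc$pars$type == "content", ]
  expect_true(all(!cc$free[cc$target %in% c("3PGA", "DHAP", "2PGA")]))
  free_cc <- cc[cc$free, ]
  expect_true(all(free_cc$lower == 1e-5 & free_cc$upper == 4e4))
  ec <- sc$pars[sc$pars$type == "exchange", ]
  expect_true(all(!ec$free[ec$target %in% c("pga_dhap", "pga_2pga")]))

  # the trehalose-branch inactive fraction is fixed to zero everywhere
  for (s in list(sa, sb, sc)) {
    ph <- s$pars[s$pars$name == "phi_Tre6P", ]
    expect_false(ph$free)
    expect_equal(ph$value, 0)
  }
})

test_that("fitted scenarios honor their content masks", {
  fitA <- fitA_clean()
  ds <- test_dataset_clean()
  expect_equal(fitA$params$contents[ds$contents$pool],
               setNames(ds$contents$mean, ds$contents$pool))
  fitC <- fitC_cap()
  meas <- setNames(fitC$dataset$contents$mean, fitC$dataset$contents$pool)
  expect_equal(fitC$params$contents[c("3PGA", "DHAP", "2PGA")],
               meas[c("3PGA", "DHAP", "2PGA")])
})

test_that("the objective decomposes exactly as VWSS_all = VWSS_t + VWSS_c", {
  fitB <- fitB_noisy()
  expect_identical(fitB$vwss_all, fitB$vwss_t + fitB$vwss_c)
  # and the components agree with the public error functions
  expect_equal(vwss_time(fitB$predicted, fitB$dataset), fitB$vwss_t,
               tolerance = 1e-10)
  expect_equal(
    vwss_content(fitB$params$contents,
                 setNames(fitB$dataset$contents$mean,
                          fitB$dataset$contents$pool),
                 setNames(fitB$dataset$contents$std,
                          fitB$dataset$contents$pool)),
    fitB$vwss_c, tolerance = 1e-10)
})

test_that("fast objective path agrees with the public constructors", {
  ds <- test_dataset_clean()
  spec <- scenario_spec("B", ds, test_basis())
  ctl <- instmfa:::default_fit_control(list())
  prep <- instmfa:::fit_prep(ds, spec, test_input_models(), ctl)
  fast <- instmfa:::build_fast_model(spec, prep)
  withr::with_seed(5, {
    for (i in 1:3) {
      th <- instmfa:::sample_start_theta(spec)
      r_fast <- fast$residuals(th, 1e-8, 1e-10, 1e3)
      r_slow <- instmfa:::fit_residuals(th, spec, prep)
      # identical model, possibly different solver step sequences
      expect_equal(unname(r_fast), unname(r_slow), tolerance = 1e-6)
    }
  })
})

test_that("a warm start at the generating truth reproduces it exactly", {
  ds <- test_dataset_clean()
  truth <- test_truth()
  spec <- scenario_spec("A", ds, test_basis())
  th <- instmfa:::pack_params(truth, spec)
  fit <- quiet(fit_scenario(ds, spec, restarts = 1, seed = 1,
                            warm_theta = th,
                            control = list(nm_maxit = 0,
                                           refine_cycles = 0)))
  expect_lt(fit$vwss_t, 1e-3)
  expect_equal(fit$params$weights, truth$weights, tolerance = 1e-4)
})

test_that("Scenario C refits reach the same error from a scaled start", {
  # only ratios of fluxes and free pool sizes are identifiable; the fixed
  # combined 3PGA-DHAP-2PGA pool normalizes the scale, so a start with all
  # free contents and weights doubled converges back to the same optimum
  fitC <- fitC_cap()
  spec <- fitC$spec
  p2 <- fitC$params
  p2$weights <- p2$weights * 2
  free_pools <- setdiff(names(p2$contents), c("3PGA", "DHAP", "2PGA"))
  p2$contents[free_pools] <- p2$contents[free_pools] * 2
  refit <- quiet(fit_scenario(
    fitC$dataset, spec, restarts = 1, seed = 2,
    warm_theta = instmfa:::pack_params(p2, spec),
    control = list(nm_maxit = 0, refine_cycles = 2)))
  expect_lt(abs(refit$vwss_t - fitC$vwss_t), 0.05 * (1 + fitC$vwss_t))
})

test_that("Monte-Carlo confidence reports are deterministic in the seed", {
  fit <- fitA_clean()
  ci1 <- quiet(monte_carlo_ci(fit, replicates = 3, seed = 11, restarts = 1))
  ci2 <- quiet(monte_carlo_ci(fit, replicates = 3, seed = 11, restarts = 1))
  expect_equal(as.data.frame(ci1), as.data.frame(ci2))
})

test_that("vanishing observation noise collapses the Monte-Carlo intervals", {
  ds <- test_dataset_clean()
  ds$timecourse$variance <- 1e-12
  ds$contents$std <- 1e-9          # content measurements noise-free too
  fit <- quiet(fit_scenario(
    ds, "A", test_basis(), restarts = 1, seed = 1,
    warm_theta = instmfa:::pack_params(test_truth(),
                                       scenario_spec("A", ds, test_basis())),
    control = list(nm_maxit = 0, refine_cycles = 0)))
  ci <- quiet(monte_carlo_ci(fit, replicates = 3, seed = 2, restarts = 1))
  w <- ci[grepl("^weight_", ci$quantity), ]
  expect_true(all((w$upper - w$lower) / pmax(w$optimum, 1e-12) < 1e-3))
})

test_that("tidy and glance summarize fits in the broom idiom", {
  fit <- fitA_clean()
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(fit$spec$pars))
  expect_true(all(c("term", "type", "estimate", "free") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$df, 73L)
  expect_true(all(c("vwss_t", "vwss_all", "accepted") %in% names(gl)))
})
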