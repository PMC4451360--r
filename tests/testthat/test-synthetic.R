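test_that("ground truths are reproducible and respect their presets", {
  t1 <- make_truth(5, "table1_like")
  t2 <- make_truth(5, "table1_like")
  expect_identical(t1, t2)
  expect_equal(round(sum(t1$weights), 2), 13.31)
  expect_equal(t1$phi[["Tre6P"]], 0)

  ref <- reference_contents()
  expect_equal(nrow(ref), 18)
  expect_equal(setNames(ref$mean, ref$pool)[names(t1$contents)],
               t1$contents)

  withr::with_seed(9, {
    for (i in 1:100) {
      tr <- make_truth(sample.int(1e6, 1), "random")
      expect_true(all(tr$weights > 0))
      expect_true(all(tr$exchange_raw >= 0 & tr$exchange_raw < 1))
      expect_true(all(tr$phi >= 0 & tr$phi < 1))
      expect_true(all(tr$contents > 0))
    }
  })
})

test_that("RuBP labeling kinetics are binomial in the per-carbon probability", {
  truth <- test_truth()
  rb0 <- simulate_rubp_labeling(truth, times = 0)
  expect_equal(rb0$m0, 1)

  # at the time where u = 0.5 the unlabeled fraction is 0.5^5
  t_half <- log((1 - truth$rubp$phi_R) / (0.5 - truth$rubp$phi_R)) /
    truth$rubp$lambda
  rb <- simulate_rubp_labeling(truth, times = t_half)
  expect_equal(rb$m0, 0.03125, tolerance = 1e-10)

  rb7 <- simulate_rubp_labeling(truth, reference_times())
  sums <- rowSums(rb7[paste0("m", 0:5)])
  expect_equal(sums, rep(1, 7), tolerance = 1e-12)
  validate_mass_isotopomers(rb7)
})

test_that("noise-free datasets equal the forward model exactly", {
  truth <- test_truth()
  gen <- make_dataset(truth, noise_cv = 0)
  ds <- gen$dataset
  expect_equal(nrow(ds$timecourse), 98)   # 14 metabolites x 7 times
  expect_equal(length(unique(ds$timecourse$metabolite)), 14)

  im <- fit_rubp_input_models(ds$rubp)
  sim <- simulate_labeling(truth, test_basis(), im, reference_times())
  joined <- dplyr::inner_join(ds$timecourse, sim$predicted,
                              by = c("metabolite", "time_s"))
  expect_equal(joined$value.x, joined$value.y, tolerance = 1e-12)
  expect_equal(setNames(ds$contents$mean, ds$contents$pool),
               truth$contents)
})

test_that("datasets are reproducible from their seed", {
  truth <- test_truth()
  d1 <- make_dataset(truth, noise_cv = 0.05, seed = 4)$dataset
  d2 <- make_dataset(truth, noise_cv = 0.05, seed = 4)$dataset
  expect_identical(d1$timecourse, d2$timecourse)
  expect_identical(d1$contents, d2$contents)
  d3 <- make_dataset(truth, noise_cv = 0.05, seed = 5)$dataset
  expect_false(identical(d1$timecourse$value, d3$timecourse$value))
})

test_that("fast-turnover metabolites plateau at their inactive fraction", {
  truth <- test_truth()
  ds <- test_dataset_clean()
  fd <- flux_from_modes(truth, test_basis())
  sizes <- active_pool_sizes(truth$contents, truth$phi,
                             test_basis()$network)
  k <- setNames(fd$pools$turnover, fd$pools$pool) /
    setNames(sizes$active, sizes$pool)
  # metabolites whose every pool has k * 3600 >> 1
  fast_mets <- sizes |>
    dplyr::mutate(k = unname(k[pool])) |>
    dplyr::group_by(metabolite) |>
    dplyr::summarise(kmin = min(k), .groups = "drop") |>
    dplyr::filter(kmin * 3600 > 20)
  expect_gt(nrow(fast_mets), 3)
  late <- ds$timecourse[ds$timecourse$time_s == 3600, ]
  for (m in fast_mets$metabolite) {
    expect_lt(abs(late$value[late$metabolite == m] - truth$phi[[m]]), 0.02)
  }
})

test_that("recovery reports compare fits with their generating truth", {
  fit <- fitA_clean()
  truth <- test_truth()
  rr <- recovery_report(fit, truth)
  expect_true(all(c("quantity", "truth", "estimate", "rel_error")
                  %in% names(rr)))
  # contents are fixed to the (noise-free) measured truth in Scenario A
  cc <- rr[grepl("^content_", rr$quantity), ]
  expect_true(all(cc$rel_error < 1e-12))
  rr_ci <- recovery_report(fitA_noisy(), truth, ci_noisy())
  expect_true("in_ci" %in% names(rr_ci))
  expect_true(is.logical(rr_ci$in_ci))
})
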