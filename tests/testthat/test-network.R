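test_that("reference network has the expected pools and reactions", {
  net <- build_reference_network()
  sim <- simulated_pools(net)
  expect_equal(nrow(sim), 18)
  expect_setequal(
    sim$id,
    c("3PGA", "DHAP", "FBPpl", "F6Ppl", "G6Ppl", "G1Ppl", "ADPG",
      "FBPcyt", "F6Pcyt", "G6Pcyt", "G1Pcyt", "UDPG", "Suc6P", "Tre6P",
      "Gly", "Ser", "Glyc", "2PGA")
  )
  expect_equal(sum(net$reactions$reversible), 7)
  expect_setequal(
    net$reactions$id[net$reactions$reversible],
    c("pga_dhap", "pgm_pl", "pgi_cyt", "pgm_cyt", "ugpase", "ser_glyc",
      "pga_2pga")
  )
  # every reaction carbon-balanced (audit_network errors otherwise)
  expect_silent(audit_network(net))
  # RuBP, CO2 and the sinks are not simulated state variables
  externals <- net$pools$id[!net$pools$simulated]
  expect_true(all(c("RuBP", "CO2", "starch", "sucrose", "trehalose")
                  %in% externals))
})

test_that("audit_network rejects broken networks", {
  net <- build_reference_network()
  bad <- net
  bad$reactions$sub[[1]] <- c(RuBP = 4, CO2 = 1)   # unbalanced carboxylation
  expect_error(audit_network(bad), "carbon balanced")
  bad2 <- net
  bad2$reactions$hrules[[2]][["3PGA"]][[1]]$f <- "nonsense"
  expect_error(audit_network(bad2), "invalid h-rule")
})

test_that("elementary-mode enumeration matches a brute-force oracle on toy networks", {
  # linear chain A -> B -> C with external in/out: one mode
  chain <- matrix(c(1, -1, 0,
                    0, 1, -1), nrow = 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
  rays <- instmfa:::extreme_rays(chain)
  expect_equal(ncol(rays), 1)
  expect_equal(ncol(brute_force_efms(chain)), 1)

  # diamond A -> B -> D and A -> C -> D: two modes
  diamond <- matrix(0, 3, 4,
                    dimnames = list(c("B", "C", "D"),
                                    c("ab", "ac", "bd", "cd")))
  diamond["B", "ab"] <- 1; diamond["B", "bd"] <- -1
  diamond["C", "ac"] <- 1; diamond["C", "cd"] <- -1
  diamond["D", "bd"] <- 1; diamond["D", "cd"] <- 1
  # D is drained by an external sink reaction
  diamond <- cbind(diamond, sink = c(0, 0, -1))
  rays <- instmfa:::extreme_rays(diamond)
  oracle <- brute_force_efms(diamond)
  expect_equal(ncol(rays), 2)
  expect_equal(ncol(oracle), 2)
  # same rays up to column order and scale
  match_cols <- vapply(seq_len(ncol(rays)), function(j) {
    any(vapply(seq_len(ncol(oracle)), function(k) {
      a <- rays[, j] / max(rays[, j]); b <- oracle[, k] / max(oracle[, k])
      max(abs(a - b)) < 1e-8
    }, logical(1)))
  }, logical(1))
  expect_true(all(match_cols))
})

test_that("the reference net network has exactly 4 elementary modes", {
  modes <- enumerate_net_modes(build_reference_network())
  expect_equal(ncol(modes), 4)
})

test_that("each net mode routes all carbon to a single terminus", {
  basis <- test_basis()
  for (m in basis$mode_names) {
    w <- setNames(numeric(4), basis$mode_names)
    w[m] <- 1
    fd <- flux_from_modes(list(weights = w, exchange_raw = rep(0, 7)),
                          basis, scale = 1)
    term_rates <- c(
      starch = fd$reactions$net[fd$reactions$reaction == "starch_syn"],
      sucrose = fd$reactions$net[fd$reactions$reaction == "spp"],
      trehalose = fd$reactions$net[fd$reactions$reaction == "tpp"],
      photorespiration = fd$reactions$net_extent[
        fd$reactions$reaction == "gly_ser"]
    )
    expect_equal(unname(term_rates[m]), 1, tolerance = 1e-9)
    expect_equal(unname(sum(term_rates[setdiff(names(term_rates), m)])), 0,
                 tolerance = 1e-9)
  }
})

test_that("exchange transform is hyperbolic with a finite cap", {
  expect_equal(exchange_transform(0, 5), 0)
  expect_equal(exchange_transform(0.5, 10), 10)
  expect_equal(exchange_transform(1 - 1e-9, 1), 1e4)  # capped
  expect_error(exchange_transform(1, 1), "\\[0, 1\\)")
  expect_error(exchange_transform(-0.1, 1), "\\[0, 1\\)")
  # monotone
  r <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(exchange_transform(r, 3)) > 0))
})

test_that("flux_from_modes reproduces the flux-table arithmetic", {
  basis <- test_basis()
  fd0 <- flux_from_modes(list(weights = rep(0, 4),
                              exchange_raw = rep(0.3, 7)), basis)
  expect_true(all(abs(fd0$reactions$forward) < 1e-12))

  fd <- flux_from_modes(
    list(weights = c(2.39, 6.99, 0.00059, 3.93),
         exchange_raw = rep(0.5, 7)), basis)
  expect_equal(round(fd$gross_fixation, 2), 13.31)
  expect_equal(fd$net_fixation, fd$gross_fixation - 3.93)

  fd2 <- flux_from_modes(list(weights = c(1, 1, 0, 0),
                              exchange_raw = rep(0, 7)), basis)
  expect_equal(fd2$gross_fixation, 2)
})

test_that("steady state and fixation sum hold for random parameter draws", {
  basis <- test_basis()
  withr::with_seed(99, {
    for (i in 1:100) {
      w <- exp(runif(4, log(1e-3), log(20)))
      raw <- runif(7, 0, 0.99)
      fd <- flux_from_modes(list(weights = w, exchange_raw = raw), basis)
      expect_equal(fd$gross_fixation, sum(w))
      mism <- abs(fd$pools$turnover - fd$pools$outflux)
      expect_true(all(mism <= 1e-9 * pmax(fd$pools$turnover, 1)))
      # influx ratios sum to one wherever there is flux
      sums <- fd$alpha |>
        dplyr::group_by(pool) |>
        dplyr::summarise(s = sum(alpha), .groups = "drop")
      expect_true(all(abs(sums$s - 1) < 1e-9))
    }
  })
})

test_that("forward = net + backward on reversible reactions", {
  basis <- test_basis()
  fd <- flux_from_modes(
    list(weights = c(2, 6, 0.1, 3), exchange_raw = runif(7, 0, 0.9)),
    basis)
  rev <- fd$reactions[fd$reactions$reversible, ]
  expect_equal(rev$forward, rev$net + rev$backward)
  irr <- fd$reactions[!fd$reactions$reversible, ]
  expect_true(all(irr$backward == 0))
})
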