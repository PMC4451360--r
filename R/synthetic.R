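#' Reference sampling grid of the labeling experiment
#'
#' Harvest times of the labeling design: 5 and 10 s and 1, 3, 10, 20 and
#' 60 min after the switch to 13CO2.
#'
#' @return Numeric vector of 7 times in seconds.
#' @export
reference_times <- function() {
  c(5, 10, 60, 180, 600, 1200, 3600)
}

#' Measured compartmentalized contents of the 18 simulated pools
#'
#' Means and standard deviations of the compartmentalized metabolic
#' contents (nmol C gFW^-1) used as the measurement fixture: the packaged
#' values for the 18 pools of the reference network.
#'
#' @return Tibble with columns `pool`, `mean`, `std`.
#' @export
reference_contents <- function() {
  tibble::tribble(
    ~pool,     ~mean,   ~std,
    "3PGA",    600.3,   135,
    "DHAP",    47.6,    1.8,
    "FBPpl",   37.5,    9.7,
    "F6Ppl",   176.2,   29.8,
    "G6Ppl",   176.4,   52,
    "G1Ppl",   5.6,     1.1,
    "ADPG",    3.3,     0.3,
    "FBPcyt",  16.1,    4.1,
    "F6Pcyt",  342,     57.8,
    "G6Pcyt",  861.1,   254,
    "G1Pcyt",  64.5,    13.3,
    "UDPG",    214.5,   34.2,
    "Suc6P",   9.8,     4.3,
    "Tre6P",   1.9,     0.5,
    "Gly",     1086.3,  118,
    "Ser",     12793.9, 978,
    "Glyc",    506.5,   195,
    "2PGA",    60,      13.5
  )
}

# default inactive fractions per observed metabolite: low plateaus for
# Calvin-cycle intermediates, higher for the photorespiratory amino acids,
# zero for the trehalose branch (no plateau observed there)
default_inactive_fractions <- function() {
  c(`3PGA` = 0.15, DHAP = 0.15, FBP = 0.30, F6P = 0.25, G6P = 0.25,
    G1P = 0.25, ADPG = 0.10, UDPG = 0.20, Suc6P = 0.30, Tre6P = 0,
    Gly = 0.20, Ser = 0.45, Glyc = 0.40, `2PGA` = 0.20)
}

# default raw exchange parameters: 3PGA<->DHAP effectively at the cap
# (rapid equilibrium), 3PGA<->2PGA moderate, hexose-phosphate exchanges high
default_exchange_raw <- function() {
  c(ser_glyc = 0.95, pga_dhap = 0.9999, pgm_pl = 0.95, pgi_cyt = 0.27,
    pgm_cyt = 0.95, ugpase = 0.90, pga_2pga = 0.70)
}

#' Ground truth for synthetic labeling experiments
#'
#' Generates a complete parameter set (net-mode weights, exchange
#' parameters, compartmentalized contents, inactive fractions, RuBP
#' labeling kinetics and a noise specification) from which synthetic
#' datasets can be simulated.
#'
#' The `"table1_like"` preset uses net-mode weights of 2.39 (starch), 6.99
#' (sucrose), 0.00059 (trehalose) and 3.93 (photorespiration) nmol C
#' gFW^-1 s^-1 and places contents at the measured means of
#' [reference_contents()].  The `"random"` preset samples weights, contents,
#' exchange parameters and inactive fractions within the fitting bounds.
#'
#' @param seed Integer seed (reproducible truth).
#' @param preset `"table1_like"` or `"random"`.
#' @param noise_cv Coefficient of variation of the time-course noise.
#' @return Object of class `mfa_truth`: list with `weights`,
#'   `exchange_raw`, `contents`, `phi`, `rubp` (fields `lambda`, `phi_R` of
#'   the per-carbon unlabeled probability
#'   `u(t) = phi_R + (1 - phi_R) exp(-lambda t)`), `noise` and `seed`.
#' @export
make_truth <- function(seed = 1, preset = c("table1_like", "random"),
                       noise_cv = 0.05) {
  preset <- match.arg(preset)
  ref <- reference_contents()
  withr::with_seed(seed, {
    if (preset == "table1_like") {
      weights <- c(starch = 2.39, sucrose = 6.99, trehalose = 0.00059,
                   photorespiration = 3.93)
      contents <- setNames(ref$mean, ref$pool)
      phi <- default_inactive_fractions()
      exchange_raw <- default_exchange_raw()
    } else {
      weights <- setNames(
        exp(runif(4, log(1e-2), log(10))),
        c("starch", "sucrose", "trehalose", "photorespiration")
      )
      contents <- setNames(
        ref$mean * exp(rnorm(nrow(ref), 0, 0.3)), ref$pool
      )
      phi <- default_inactive_fractions()
      free_phi <- setdiff(names(phi), "Tre6P")
      phi[free_phi] <- runif(length(free_phi), 0, 0.6)
      exchange_raw <- default_exchange_raw()
      exchange_raw[] <- runif(length(exchange_raw), 0, 0.95)
    }
    structure(
      list(weights = weights, exchange_raw = exchange_raw,
           contents = contents, phi = phi,
           rubp = list(lambda = 0.02, phi_R = 0.05),
           noise = list(cv = noise_cv, floor = 0.005),
           seed = seed),
      class = "mfa_truth"
    )
  })
}

#' Simulate binomial RuBP mass-isotopomer labeling kinetics
#'
#' Realizes the uniform-labeling assumption with a per-carbon unlabeled
#' probability `u(t) = phi_R + (1 - phi_R) exp(-lambda t)`: the mass
#' isotopomer fractions are binomial,
#' `x_i(t) = choose(5, i) (1 - u)^i u^(5 - i)`.
#'
#' @param truth An `mfa_truth` (fields `rubp$lambda`, `rubp$phi_R`).
#' @param times Times in seconds.
#' @return Tibble with columns `time_s`, `m0` .. `m5` (each row sums to 1).
#' @export
simulate_rubp_labeling <- function(truth, times = reference_times()) {
  lam <- truth$rubp$lambda
  phiR <- truth$rubp$phi_R
  u <- phiR + (1 - phiR) * exp(-lam * times)
  out <- tibble::tibble(time_s = times)
  for (i in 0:5) {
    out[[paste0("m", i)]] <- choose(5, i) * (1 - u)^i * u^(5 - i)
  }
  out
}

#' Generate a synthetic labeling dataset from a ground truth
#'
#' Runs the full forward model (flux construction, input-model fitting from
#' the simulated RuBP series, stiff integration, observation model) and
#' adds Gaussian measurement noise: time-course values receive noise with
#' standard deviation `noise_cv * value` (floored at `truth$noise$floor`)
#' and are clipped to `[0, 1]`; content measurements receive noise with the
#' packaged per-pool standard deviations.  With `noise_cv = 0` the dataset
#' equals the model prediction exactly.
#'
#' The RuBP input models used for the forward simulation are fitted from
#' the generated mass-isotopomer series exactly as the estimation pipeline
#' fits them, so a noise-free dataset is reproduced exactly by the fitted
#' model at the true parameters.
#'
#' @param truth An `mfa_truth`.
#' @param times Sampling grid (seconds).
#' @param noise_cv Time-course noise coefficient of variation; defaults to
#'   the truth's noise spec.
#' @param seed Integer seed for the measurement noise.
#' @param basis Optional precomputed `flux_mode_basis`.
#' @return List with `dataset` (class `mfa_dataset`: tibbles `timecourse`
#'   (`metabolite`, `time_s`, `value`, `variance`), `contents` (`pool`,
#'   `mean`, `std`), `rubp`, and `times`) and `truth`.
#' @export
make_dataset <- function(truth, times = reference_times(),
                         noise_cv = truth$noise$cv, seed = 1,
                         basis = NULL) {
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (is.null(basis)) basis <- flux_mode_basis()
  rubp <- simulate_rubp_labeling(truth, times)
  input_models <- fit_rubp_input_models(rubp)
  sim <- simulate_labeling(truth, basis, input_models, times)
  ref <- reference_contents()
  sd_c <- setNames(ref$std, ref$pool)
  floor_sd <- truth$noise$floor

  withr::with_seed(seed, {
    tc <- sim$predicted
    if (noise_cv > 0) {
      sd_t <- pmax(noise_cv * tc$value, floor_sd)
      tc$value <- pmin(pmax(tc$value + rnorm(nrow(tc), 0, sd_t), 0), 1)
    }
    tc$variance <- pmax(noise_cv * tc$value, floor_sd)^2
    cmeas <- truth$contents
    if (noise_cv > 0) {
      pert <- rnorm(length(cmeas), 0, sd_c[names(cmeas)])
      cmeas <- pmax(cmeas + pert, 0.05 * truth$contents)
    }
    contents <- tibble::tibble(
      pool = names(cmeas), mean = unname(cmeas),
      std = unname(sd_c[names(cmeas)])
    )
    dataset <- structure(
      list(timecourse = tc, contents = contents, rubp = rubp,
           times = times),
      class = "mfa_dataset"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.mfa_dataset <- function(x, ...) {
  cat("Synthetic/observed labeling dataset\n")
  cat(sprintf("  %d time-course points (%d metabolites x %d times)\n",
              nrow(x$timecourse),
              length(unique(x$timecourse$metabolite)), length(x$times)))
  cat(sprintf("  %d content measurements\n", nrow(x$contents)))
  invisible(x)
}

#' Compare a fit against the generating ground truth
#'
#' @param fit An `mfa_fit`.
#' @param truth The `mfa_truth` the dataset was generated from.
#' @param ci Optional confidence report (from [monte_carlo_ci()]); adds an
#'   inside-interval flag per quantity.
#' @return Tibble with columns `quantity`, `truth`, `estimate`,
#'   `rel_error` and (with `ci`) `in_ci`.
#' @export
recovery_report <- function(fit, truth, ci = NULL) {
  tq <- truth_quantities(truth)
  eq <- fit_quantities(fit)
  common <- intersect(names(tq), names(eq))
  out <- tibble::tibble(
    quantity = common,
    truth = unname(tq[common]),
    estimate = unname(eq[common]),
    rel_error = ifelse(tq[common] != 0,
                       abs(eq[common] - tq[common]) / abs(tq[common]),
                       abs(eq[common] - tq[common]))
  )
  if (!is.null(ci)) {
    out <- dplyr::left_join(out, ci[, c("quantity", "lower", "upper")],
                            by = "quantity") |>
      dplyr::mutate(in_ci = .data$truth >= .data$lower &
                      .data$truth <= .data$upper)
  }
  out
}

# scalar summary of a ground truth, on the same names as fit_quantities()
truth_quantities <- function(truth) {
  w <- truth$weights
  gross <- sum(w)
  c(setNames(unname(w), paste0("weight_", names(w))),
    gross_fixation = gross,
    net_fixation = gross - w[["photorespiration"]],
    photorespiration_fraction = unname(w[["photorespiration"]] / gross),
    setNames(unname(truth$contents), paste0("content_", names(truth$contents))),
    setNames(unname(truth$phi), paste0("phi_", names(truth$phi))))
}
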