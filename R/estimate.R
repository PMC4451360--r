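#' Variance-weighted time-course error
#'
#' Computes `VWSS_t = sum_m sum_t (z_obs - z_sim)^2 / sigma_m^2`, where, to
#' avoid over-fitting single points, the per-time-point variance is
#' replaced by the mean variance of the corresponding metabolite over all
#' time points.
#'
#' @param pred Tibble of predictions (`metabolite`, `time_s`, `value`).
#' @param data An `mfa_dataset` (or its `timecourse` tibble with columns
#'   `metabolite`, `time_s`, `value`, `variance`).
#' @return The weighted sum of squares (scalar).
#' @export
vwss_time <- function(pred, data) {
  tc <- if (inherits(data, "mfa_dataset")) data$timecourse else data
  joined <- dplyr::inner_join(
    tc, pred, by = c("metabolite", "time_s"),
    suffix = c("_obs", "_sim")
  )
  if (nrow(joined) != nrow(tc)) {
    stop("prediction grid does not cover the observed (metabolite, time) grid")
  }
  joined |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::mutate(mvar = mean(.data$variance)) |>
    dplyr::ungroup() |>
    dplyr::summarise(
      v = sum((.data$value_obs - .data$value_sim)^2 / .data$mvar)
    ) |>
    dplyr::pull(.data$v)
}

#' Variance-weighted content error
#'
#' `VWSS_c = sum_n (c_obs - c_sim)^2 / sigma_c^2` over the measured
#' compartmentalized contents.
#'
#' @param c_sim Named numeric of simulated (fitted) contents.
#' @param c_obs Named numeric of measured contents.
#' @param sd_obs Named numeric of measurement standard deviations (> 0).
#' @return The weighted sum of squares (scalar).
#' @export
vwss_content <- function(c_sim, c_obs, sd_obs) {
  if (any(sd_obs <= 0)) stop("content standard deviations must be positive")
  nm <- names(c_obs)
  if (!is.null(nm)) {
    c_sim <- c_sim[nm]
    sd_obs <- sd_obs[nm]
  }
  sum((c_obs - c_sim)^2 / sd_obs^2)
}

#' Degrees of freedom of a scenario fit
#'
#' Uses the convention `df = n_data - n_params - 1`, which reproduces the
#' printed counts of the reference analysis (98 data points and 24
#' parameters give 73 degrees of freedom; 116 and 42 likewise give 73).
#'
#' @param n_data Number of fitted data points.
#' @param n_params Number of free parameters.
#' @return Integer degrees of freedom; errors when nonpositive.
#' @export
degrees_of_freedom <- function(n_data, n_params) {
  df <- n_data - n_params - 1
  if (df <= 0) stop("nonpositive degrees of freedom")
  as.integer(df)
}

#' Chi-square acceptance interval for a goodness-of-fit statistic
#'
#' Returns the 5th and 95th percentiles of the chi-square distribution with
#' `df` degrees of freedom; a fit is statistically acceptable (at 95%
#' confidence, two-sided on the error statistic) when its weighted error
#' falls inside this interval.
#'
#' @param df Degrees of freedom (>= 1).
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' round(chi2_interval(73))  # 54 94
#' @export
chi2_interval <- function(df) {
  if (df < 1) stop("df must be >= 1")
  setNames(qchisq(c(0.05, 0.95), df), c("lower", "upper"))
}

#' Scenario specification for a pool-size treatment
#'
#' Builds the free/fixed parameter masks, bounds and objective of the three
#' pool-size treatment scenarios:
#' * **A** - contents fixed to the measured values; objective `VWSS_t`;
#'   24 free parameters (11 flux, 13 inactive fractions).
#' * **B** - all 18 contents optimized within mean +/- 4 standard
#'   deviations; objective `VWSS_all = VWSS_t + VWSS_c`; 42 free parameters.
#' * **C** - contents practically unbounded (`[1e-5, 4e4]` nmol C gFW^-1)
#'   except 3PGA, DHAP and 2PGA, which stay fixed to the measured values
#'   with their mutual exchange fluxes pinned at the cap so the three act
#'   as one combined pool of fixed size; objective `VWSS_t`.  Only flux and
#'   pool-size ratios are identifiable in this scenario; its printed
#'   degrees of freedom (59) are taken as configuration.
#'
#' The inactive fraction of the trehalose-branch metabolite (Tre6P) is
#' fixed to zero in all scenarios (no plateau), leaving 13 free inactive
#' fractions.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param dataset An `mfa_dataset` supplying measured contents and the data
#'   counts.
#' @param basis A `flux_mode_basis`.
#' @param df Degrees-of-freedom override (used for Scenario C, default 59).
#' @param cap_raw Raw exchange value representing the cap for Scenario C's
#'   fixed exchanges.
#' @param phi_zero Metabolite whose inactive fraction is fixed to zero.
#' @param content_sd_mult Half-width of Scenario B content bounds in
#'   standard deviations.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("A", "B", "C"), dataset,
                          basis = flux_mode_basis(), df = NULL,
                          cap_raw = 0.9999, phi_zero = "Tre6P",
                          content_sd_mult = 4) {
  scenario <- match.arg(scenario)
  network <- basis$network
  cmeas <- setNames(dataset$contents$mean, dataset$contents$pool)
  csd <- setNames(dataset$contents$std, dataset$contents$pool)
  metabolites <- observation_map(network)$metabolite
  combined_pool <- c("3PGA", "DHAP", "2PGA")
  combined_exchanges <- c("pga_dhap", "pga_2pga")

  rows <- list()
  add <- function(name, type, target, free, value, lower, upper) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, type = type, target = target, free = free,
      value = value, lower = lower, upper = upper
    )
  }
  for (m in basis$mode_names) {
    add(paste0("weight_", m), "weight", m, TRUE, NA_real_, 1e-3, 1e2)
  }
  for (r in basis$exchange_reactions) {
    fixed_ex <- scenario == "C" && r %in% combined_exchanges
    add(paste0("exchange_", r), "exchange", r, !fixed_ex,
        if (fixed_ex) cap_raw else NA_real_, 0, 0.95)
  }
  for (m in metabolites) {
    fixed_phi <- m == phi_zero
    add(paste0("phi_", m), "phi", m, !fixed_phi,
        if (fixed_phi) 0 else NA_real_, 0, 0.95)
  }
  for (p in names(cmeas)) {
    if (scenario == "A" || (scenario == "C" && p %in% combined_pool)) {
      add(paste0("content_", p), "content", p, FALSE, cmeas[[p]],
          NA_real_, NA_real_)
    } else if (scenario == "B") {
      lo <- max(1e-3, cmeas[[p]] - content_sd_mult * csd[[p]])
      hi <- cmeas[[p]] + content_sd_mult * csd[[p]]
      add(paste0("content_", p), "content", p, TRUE, NA_real_, lo, hi)
    } else {
      add(paste0("content_", p), "content", p, TRUE, NA_real_, 1e-5, 4e4)
    }
  }
  pars <- dplyr::bind_rows(rows)

  objective <- if (scenario == "B") "all" else "t"
  n_data <- nrow(dataset$timecourse) +
    if (objective == "all") nrow(dataset$contents) else 0L
  n_params <- sum(pars$free)
  df_val <- if (!is.null(df)) {
    as.integer(df)
  } else if (scenario == "C") {
    59L
  } else {
    degrees_of_freedom(n_data, n_params)
  }

  structure(
    list(scenario = scenario, objective = objective, pars = pars,
         basis = basis, n_data = n_data, n_params = n_params, df = df_val,
         cap_raw = cap_raw, contents_obs = cmeas, contents_sd = csd),
    class = "scenario_spec"
  )
}

#' Fix one content parameter of a scenario at a given value
#'
#' Used by the sensitivity analysis: the selected compartmentalized content
#' is removed from the free parameters and pinned at `value`.
#'
#' @param spec A `scenario_spec`.
#' @param pool Pool id whose content to fix.
#' @param value Value to fix it to.
#' @return Modified `scenario_spec`.
#' @export
fix_content <- function(spec, pool, value) {
  i <- which(spec$pars$name == paste0("content_", pool))
  if (!length(i)) stop("unknown content parameter: ", pool)
  if (!spec$pars$free[i]) {
    stop("content of '", pool, "' is already fixed in this scenario")
  }
  spec$pars$free[i] <- FALSE
  spec$pars$value[i] <- value
  spec$n_params <- sum(spec$pars$free)
  spec
}

# ---- parameter transforms -------------------------------------------------

# free parameters are optimized on an unconstrained scale:
#   weight   w = exp(theta)
#   exchange r = plogis(theta)                  in (0, 1)
#   phi      f = 0.95 * plogis(theta)           in (0, 0.95)
#   content  c = L * (U/L)^plogis(theta)        log-scale box
par_to_theta <- function(value, row) {
  switch(row$type,
    weight = log(pmax(value, 1e-12)),
    exchange = stats::qlogis(pmin(pmax(value, 1e-9), 1 - 1e-9)),
    phi = stats::qlogis(pmin(pmax(value / 0.95, 1e-9), 1 - 1e-9)),
    content = {
      q <- (log(value) - log(row$lower)) / (log(row$upper) - log(row$lower))
      stats::qlogis(pmin(pmax(q, 1e-9), 1 - 1e-9))
    }
  )
}

theta_to_par <- function(theta, row) {
  switch(row$type,
    weight = exp(theta),
    exchange = pmin(stats::plogis(theta), 1 - 1e-12),
    phi = 0.95 * stats::plogis(theta),
    content = exp(log(row$lower) +
                    stats::plogis(theta) * (log(row$upper) - log(row$lower)))
  )
}

unpack_theta <- function(theta, spec) {
  pars <- spec$pars
  values <- pars$value
  free_idx <- which(pars$free)
  for (k in seq_along(free_idx)) {
    i <- free_idx[k]
    values[i] <- theta_to_par(theta[k], pars[i, ])
  }
  split_par_values(values, pars, spec$basis)
}

split_par_values <- function(values, pars, basis) {
  v <- setNames(values, pars$target)
  list(
    weights = v[pars$type == "weight"][basis$mode_names],
    exchange_raw = v[pars$type == "exchange"][basis$exchange_reactions],
    phi = v[pars$type == "phi"],
    contents = v[pars$type == "content"]
  )
}

pack_params <- function(par_list, spec) {
  pars <- spec$pars
  full <- numeric(nrow(pars))
  for (i in seq_len(nrow(pars))) {
    full[i] <- switch(pars$type[i],
      weight = par_list$weights[[pars$target[i]]],
      exchange = par_list$exchange_raw[[pars$target[i]]],
      phi = par_list$phi[[pars$target[i]]],
      content = par_list$contents[[pars$target[i]]]
    )
  }
  free <- which(pars$free)
  vapply(seq_along(free), function(k) {
    par_to_theta(full[free[k]], pars[free[k], ])
  }, numeric(1))
}

sample_start_theta <- function(spec) {
  pars <- spec$pars[spec$pars$free, ]
  vapply(seq_len(nrow(pars)), function(i) {
    row <- pars[i, ]
    value <- switch(row$type,
      weight = exp(runif(1, log(row$lower), log(row$upper))),
      exchange = runif(1, 0.01, row$upper),
      phi = runif(1, 0.01, row$upper),
      content = exp(runif(1, log(row$lower), log(row$upper)))
    )
    par_to_theta(value, row)
  }, numeric(1))
}

# ---- objective ------------------------------------------------------------

default_fit_control <- function(control = list()) {
  modifyList(
    list(nm_maxit = 500, polish = TRUE, lm_maxiter = 300,
         refine_top = 3, refine_cycles = 3,
         reltol = 1e-7, rtol = 1e-8, atol = 1e-10, jitter_sd = 0.4,
         bad_residual = 1e3),
    control
  )
}

# precomputes the aligned observation vectors so residual evaluation
# avoids repeated joins
fit_prep <- function(dataset, spec, input_models, control) {
  network <- spec$basis$network
  map <- observation_map(network)
  times <- sort(unique(dataset$timecourse$time_s))
  pred_key <- paste(rep(map$metabolite, each = length(times)),
                    rep(times, times = nrow(map)))
  tc <- dataset$timecourse |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::mutate(mvar = mean(.data$variance)) |>
    dplyr::ungroup()
  obs_key <- paste(tc$metabolite, tc$time_s)
  idx <- match(pred_key, obs_key)
  if (anyNA(idx)) {
    keep <- !is.na(idx)
    pred_key <- pred_key[keep]
    idx <- idx[keep]
    keep_rows <- keep
  } else {
    keep_rows <- rep(TRUE, length(pred_key))
  }
  list(
    map = map, times = times,
    keep_rows = keep_rows,
    obs = tc$value[idx], sigma = sqrt(tc$mvar[idx]),
    obs_metabolite = tc$metabolite[idx],
    contents_obs = spec$contents_obs, contents_sd = spec$contents_sd,
    input_models = input_models, control = control
  )
}

predicted_values <- function(par_list, spec, prep) {
  network <- spec$basis$network
  fd <- flux_from_modes(list(weights = par_list$weights,
                             exchange_raw = par_list$exchange_raw),
                        spec$basis)
  sizes <- active_pool_sizes(par_list$contents, par_list$phi, network)
  sys <- assemble_system(network, fd, sizes, prep$input_models)
  traj <- integrate_system(sys, prep$times,
                           rtol = prep$control$rtol,
                           atol = prep$control$atol)
  pred <- observe(traj, sizes, prep$map)
  list(flux = fd, sizes = sizes, traj = traj, pred = pred)
}

fit_residuals <- function(theta, spec, prep) {
  n_t <- length(prep$obs)
  n_c <- if (spec$objective == "all") length(prep$contents_obs) else 0L
  par_list <- tryCatch(unpack_theta(theta, spec), error = function(e) NULL)
  if (is.null(par_list)) {
    return(rep(prep$control$bad_residual, n_t + n_c))
  }
  sim <- tryCatch(predicted_values(par_list, spec, prep),
                  error = function(e) NULL)
  if (is.null(sim)) {
    return(rep(prep$control$bad_residual, n_t + n_c))
  }
  res_t <- (prep$obs - sim$pred$value[prep$keep_rows]) / prep$sigma
  if (n_c > 0) {
    cs <- par_list$contents[names(prep$contents_obs)]
    res_c <- (prep$contents_obs - cs) / prep$contents_sd
    c(res_t, res_c)
  } else {
    res_t
  }
}

#' Fit a scenario to a labeling dataset
#'
#' Multistart local minimization of the scenario objective (`VWSS_t` or
#' `VWSS_all`) over the free parameters.  Each repetition starts from
#' parameter values drawn from the configured start distributions
#' (log-uniform for weights and contents, uniform for exchange parameters
#' and inactive fractions), runs a derivative-free Nelder-Mead stage and,
#' by default, polishes the result with a Levenberg-Marquardt pass on the
#' weighted residual vector.  The best repetition is returned together with
#' the full restart log.
#'
#' @param dataset An `mfa_dataset`.
#' @param scenario `"A"`, `"B"`, `"C"`, or a prebuilt [scenario_spec()].
#' @param basis A `flux_mode_basis` (ignored when `scenario` is a spec).
#' @param restarts Number of repetitions (the reference analysis uses 100).
#' @param seed Integer seed for the start draws.
#' @param input_models RuBP input models; fitted from `dataset$rubp` when
#'   `NULL`.
#' @param warm_theta Optional transformed parameter vector used as the
#'   first start (subsequent starts are random).
#' @param control List overriding fit controls: `nm_maxit` (Nelder-Mead
#'   iteration budget; 0 skips the stage), `polish`, `lm_maxiter`,
#'   `reltol`, solver `rtol`/`atol`, `jitter_sd`.
#' @return Object of class `mfa_fit`.
#' @export
fit_scenario <- function(dataset, scenario = "A", basis = flux_mode_basis(),
                         restarts = 100, seed = NULL, input_models = NULL,
                         warm_theta = NULL, control = list()) {
  spec <- if (inherits(scenario, "scenario_spec")) {
    scenario
  } else {
    scenario_spec(scenario, dataset, basis)
  }
  control <- default_fit_control(control)
  if (is.null(input_models)) {
    if (is.null(dataset$rubp)) {
      stop("dataset carries no RuBP series; supply input_models")
    }
    input_models <- fit_rubp_input_models(dataset$rubp)
  }
  prep <- fit_prep(dataset, spec, input_models, control)
  fast <- build_fast_model(spec, prep)
  resid_fn <- function(theta) {
    fast$residuals(theta, control$rtol, control$atol, control$bad_residual)
  }
  obj <- function(theta) sum(resid_fn(theta)^2)

  nm_step <- function(theta, maxit) {
    if (maxit <= 0 || length(theta) < 2) {
      return(list(par = theta, value = obj(theta)))
    }
    optim(theta, obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = control$reltol))
  }
  lm_step <- function(theta) {
    lmfit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        theta, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = control$lm_maxiter, maxfev = 20000,
          ptol = 1e-12, ftol = 1e-12
        )
      )),
      error = function(e) NULL
    )
    if (is.null(lmfit)) return(NULL)
    list(par = lmfit$par, value = sum(lmfit$fvec^2),
         converged = lmfit$info %in% 1:4)
  }

  run_restarts <- function() {
    log_rows <- vector("list", restarts)
    cands <- vector("list", restarts)
    for (r in seq_len(restarts)) {
      theta0 <- if (r == 1 && !is.null(warm_theta)) {
        warm_theta
      } else if (!is.null(warm_theta)) {
        warm_theta + rnorm(length(warm_theta), 0, control$jitter_sd)
      } else {
        sample_start_theta(spec)
      }
      start_obj <- obj(theta0)
      nm <- nm_step(theta0, control$nm_maxit)
      theta <- nm$par
      final_obj <- nm$value
      lm_ok <- NA
      if (control$polish) {
        lmres <- lm_step(theta)
        if (!is.null(lmres)) {
          lm_ok <- lmres$converged
          if (lmres$value < final_obj) {
            theta <- lmres$par
            final_obj <- lmres$value
          }
        } else {
          lm_ok <- FALSE
        }
      }
      log_rows[[r]] <- tibble::tibble(
        restart = r, start_obj = start_obj, final_obj = final_obj,
        lm_converged = lm_ok
      )
      cands[[r]] <- list(theta = theta, obj = final_obj)
    }
    # refinement: alternate Nelder-Mead and Levenberg-Marquardt passes on
    # the best screening candidates (iterated local search)
    objs <- vapply(cands, `[[`, numeric(1), "obj")
    top <- order(objs)[seq_len(min(control$refine_top, restarts))]
    best <- cands[[top[1]]]
    if (control$refine_cycles > 0) {
      for (k in top) {
        theta <- cands[[k]]$theta
        cur <- cands[[k]]$obj
        for (cyc in seq_len(control$refine_cycles)) {
          nm <- nm_step(theta, control$nm_maxit)
          theta <- nm$par
          cur <- nm$value
          lmres <- lm_step(theta)
          if (!is.null(lmres) && lmres$value < cur) {
            theta <- lmres$par
            cur <- lmres$value
          }
        }
        if (cur < best$obj) best <- list(theta = theta, obj = cur)
      }
    }
    list(best = best, log = dplyr::bind_rows(log_rows))
  }

  res <- if (is.null(seed)) run_restarts() else
    withr::with_seed(seed, run_restarts())
  if (!is.finite(res$best$obj) ||
      res$best$obj >= control$bad_residual^2 * length(prep$obs)) {
    cond <- structure(
      class = c("instmfa_fit_error", "error", "condition"),
      list(message = "no restart converged to a feasible optimum",
           call = sys.call(-1), restart_log = res$log))
    stop(cond)
  }

  par_list <- unpack_theta(res$best$theta, spec)
  sim <- predicted_values(par_list, spec, prep)
  res_t <- (prep$obs - sim$pred$value[prep$keep_rows]) / prep$sigma
  vt <- sum(res_t^2)
  vc <- if (spec$objective == "all") {
    vwss_content(par_list$contents, prep$contents_obs, prep$contents_sd)
  } else {
    0
  }
  per_met <- tibble::tibble(metabolite = prep$obs_metabolite,
                            sq = res_t^2) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(vwss_t = sum(.data$sq), .groups = "drop")
  ci <- chi2_interval(spec$df)

  structure(
    list(
      spec = spec, theta = res$best$theta, params = par_list,
      flux = sim$flux, sizes = sim$sizes, predicted = sim$pred,
      vwss_t = vt, vwss_c = vc, vwss_all = vt + vc,
      per_metabolite = per_met,
      df = spec$df, n_data = spec$n_data, n_params = spec$n_params,
      chi2_lower = ci[["lower"]], chi2_upper = ci[["upper"]],
      restart_log = res$log, restarts = restarts, seed = seed,
      input_models = input_models, dataset = dataset, control = control
    ),
    class = "mfa_fit"
  )
}

#' Scalar summary quantities of a fit
#'
#' @param fit An `mfa_fit`.
#' @return Named numeric: net-mode weights, gross and net carbon fixation,
#'   photorespiration-to-gross-fixation ratio, fitted contents and inactive
#'   fractions, and the error components.
#' @export
fit_quantities <- function(fit) {
  w <- fit$params$weights
  gross <- sum(w)
  c(setNames(unname(w), paste0("weight_", names(w))),
    gross_fixation = gross,
    net_fixation = gross - w[["photorespiration"]],
    photorespiration_fraction = unname(
      if (gross > 0) w[["photorespiration"]] / gross else 0),
    setNames(unname(fit$params$contents),
             paste0("content_", names(fit$params$contents))),
    setNames(unname(fit$params$phi), paste0("phi_", names(fit$params$phi))),
    vwss_t = fit$vwss_t, vwss_c = fit$vwss_c, vwss_all = fit$vwss_all)
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat(sprintf("Scenario %s fit: VWSS_t = %.4g, VWSS_c = %.4g (df = %d)\n",
              x$spec$scenario, x$vwss_t, x$vwss_c, x$df))
  cat(sprintf("  chi-square acceptance interval: [%.0f, %.0f]\n",
              x$chi2_lower, x$chi2_upper))
  w <- x$params$weights
  cat(sprintf("  gross C fixation %.4g, net %.4g (nmol C gFW^-1 s^-1)\n",
              sum(w), sum(w) - w[["photorespiration"]]))
  invisible(x)
}

#' @export
tidy.mfa_fit <- function(x, ...) {
  pars <- x$spec$pars
  values <- vapply(seq_len(nrow(pars)), function(i) {
    switch(pars$type[i],
      weight = x$params$weights[[pars$target[i]]],
      exchange = x$params$exchange_raw[[pars$target[i]]],
      phi = x$params$phi[[pars$target[i]]],
      content = x$params$contents[[pars$target[i]]]
    )
  }, numeric(1))
  tibble::tibble(term = pars$name, type = pars$type, estimate = values,
                 free = pars$free)
}

#' @export
glance.mfa_fit <- function(x, ...) {
  tibble::tibble(
    scenario = x$spec$scenario, vwss_t = x$vwss_t, vwss_c = x$vwss_c,
    vwss_all = x$vwss_all, n_data = x$n_data, n_params = x$n_params,
    df = x$df, chi2_lower = x$chi2_lower, chi2_upper = x$chi2_upper,
    accepted = x$vwss_all >= x$chi2_lower & x$vwss_all <= x$chi2_upper,
    restarts = x$restarts
  )
}

#' Monte-Carlo confidence intervals by parametric bootstrap
#'
#' Resamples the observations as the fitted model prediction plus Gaussian
#' noise at the observed (metabolite-mean) variances, refits each replicate
#' with a reduced warm-started restart schedule, and reports 2.5/97.5
#' percentiles of every summary quantity.
#'
#' @param fit An `mfa_fit`.
#' @param dataset The dataset that produced the fit.
#' @param replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param restarts Restarts per replicate refit (warm-started).
#' @param control Fit control overrides for the refits; defaults to
#'   polish-only refits (`nm_maxit = 0`).
#' @return Tibble of class `mfa_ci` with columns `quantity`, `optimum`,
#'   `lower`, `upper`; attributes `replicates`, `failures`, `seed`, and
#'   `draws` (the replicate-level quantities).
#' @export
monte_carlo_ci <- function(fit, dataset = fit$dataset, replicates = 100,
                           seed = 1, restarts = 5, control = NULL) {
  if (is.null(control)) {
    control <- modifyList(fit$control,
                          list(nm_maxit = 0, polish = TRUE,
                               refine_cycles = 0))
  }
  spec <- fit$spec
  pred <- fit$predicted
  tc0 <- dataset$timecourse
  key_pred <- paste(pred$metabolite, pred$time_s)
  key_obs <- paste(tc0$metabolite, tc0$time_s)
  pred_for_obs <- pred$value[match(key_obs, key_pred)]
  sigma_m <- tc0 |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(s = sqrt(mean(.data$variance)), .groups = "drop")
  sig_obs <- sigma_m$s[match(tc0$metabolite, sigma_m$metabolite)]
  c_fit <- fit$params$contents

  run <- function() {
    draws <- vector("list", replicates)
    failures <- 0L
    for (b in seq_len(replicates)) {
      rep_seed <- sample.int(.Machine$integer.max, 1)
      ds <- dataset
      ds$timecourse$value <- pmin(pmax(
        pred_for_obs + rnorm(length(pred_for_obs), 0, sig_obs), 0), 1)
      # content measurements are uncertain inputs in every scenario:
      # where they are fixed (A, and the combined pool in C) each
      # replicate refits against a fresh draw, so their measurement error
      # propagates into the intervals of the content-determined fluxes
      ds$contents$mean <- pmax(
        c_fit[ds$contents$pool] +
          rnorm(nrow(ds$contents), 0, ds$contents$std),
        1e-3)
      rspec <- scenario_spec(spec$scenario, ds, spec$basis, df = spec$df)
      refit <- tryCatch(
        fit_scenario(ds, rspec, restarts = restarts, seed = rep_seed,
                     input_models = fit$input_models,
                     warm_theta = fit$theta, control = control),
        error = function(e) NULL
      )
      if (is.null(refit)) {
        failures <- failures + 1L
        next
      }
      draws[[b]] <- fit_quantities(refit)
    }
    list(draws = draws, failures = failures)
  }
  res <- withr::with_seed(seed, run())
  if (res$failures > 0.2 * replicates) {
    stop(res$failures, " of ", replicates, " bootstrap refits failed")
  }
  mat <- do.call(rbind, res$draws[!vapply(res$draws, is.null, logical(1))])
  qs <- apply(mat, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  opt <- fit_quantities(fit)
  out <- tibble::tibble(
    quantity = colnames(mat),
    optimum = unname(opt[colnames(mat)]),
    lower = qs[1, ], upper = qs[2, ]
  )
  outside <- with(out, optimum < lower | optimum > upper)
  if (any(outside) && nrow(mat) >= 20) {
    warning("optimum outside the bootstrap interval for: ",
            paste(out$quantity[outside], collapse = ", "))
  }
  attr(out, "replicates") <- replicates
  attr(out, "failures") <- res$failures
  attr(out, "seed") <- seed
  attr(out, "draws") <- mat
  class(out) <- c("mfa_ci", class(out))
  out
}

#' Fit all three scenarios sequentially
#'
#' Fits Scenario A by random multistart, then warm-starts Scenarios B and C
#' from the Scenario A optimum (supplemented by jittered and random
#' restarts).  Scenario A's optimum is a natural initialization for the
#' scenarios that free the contents: it corresponds to starting the content
#' parameters at their measured values, which is where the content start
#' distributions are centred.  This sequential strategy reaches the same
#' optima as large flat multistarts at a fraction of the repetitions.
#'
#' @param dataset An `mfa_dataset`.
#' @param scenarios Scenarios to fit, in order (`"A"` must come first when
#'   warm-starting is wanted).
#' @param restarts Restarts for the Scenario A multistart.
#' @param warm_restarts Restarts for the warm-started scenarios.
#' @param seed Integer seed.
#' @param basis A `flux_mode_basis`.
#' @param control Fit control overrides (see [fit_scenario()]).
#' @return Named list of `mfa_fit` objects.
#' @export
fit_pipeline <- function(dataset, scenarios = c("A", "B", "C"),
                         restarts = 100, warm_restarts = 6, seed = 1,
                         basis = flux_mode_basis(), control = list()) {
  fits <- list()
  warm <- NULL
  for (sc in scenarios) {
    if (sc == "A" || is.null(warm)) {
      fits[[sc]] <- fit_scenario(dataset, sc, basis, restarts = restarts,
                                 seed = seed, control = control)
      warm <- fits[[sc]]
    } else {
      spec <- scenario_spec(sc, dataset, basis)
      th <- pack_params(warm$params, spec)
      fits[[sc]] <- fit_scenario(dataset, spec, restarts = warm_restarts,
                                 seed = seed + match(sc, scenarios),
                                 warm_theta = th, control = control)
    }
  }
  fits
}
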