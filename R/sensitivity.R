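#' Canonical perturbation grid for the pool-size sensitivity analysis
#'
#' @return The 14 relative perturbation levels 50, 60, 70, 80, 90, 95, 99,
#'   101, 105, 110, 120, 130, 140 and 150 percent, as multipliers.
#' @export
perturbation_grid <- function() {
  c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95, 0.99,
    1.01, 1.05, 1.10, 1.20, 1.30, 1.40, 1.50)
}

#' Sensitivity of a fitted quantity to one metabolic content
#'
#' Fixes the selected compartmentalized content at each perturbation level
#' times its fitted optimum, re-optimizes all remaining parameters
#' (warm-started from the unperturbed optimum), and regresses the relative
#' change of the quantity of interest on the relative change of the
#' content.  The reported sensitivity is the regression slope, set to zero
#' when the absolute correlation coefficient falls below 0.5 (in which case
#' the slope estimate is unreliable and always small).
#'
#' @param fit An `mfa_fit` whose scenario optimizes the chosen content.
#' @param pool Pool id of the perturbed content.
#' @param quantity Quantity selector: a name understood by
#'   [fit_quantities()] (e.g. `"weight_trehalose"`, `"gross_fixation"`,
#'   `"vwss_t"`).
#' @param levels Perturbation multipliers (default [perturbation_grid()]).
#' @param restarts Warm-started restarts per re-optimization.
#' @param seed Integer seed.
#' @param control Fit control overrides for the re-optimizations.
#' @return One-row tibble of class `sensitivity_record`: `pool`,
#'   `quantity`, `slope`, `r`, `sensitivity`, `n_levels`; attribute
#'   `levels` holds the per-level responses.
#' @export
local_sensitivity <- function(fit, pool, quantity,
                              levels = perturbation_grid(), restarts = 3,
                              seed = 1, control = NULL) {
  spec <- fit$spec
  i <- which(spec$pars$name == paste0("content_", pool))
  if (!length(i) || !spec$pars$free[i]) {
    stop("content of '", pool, "' is not an optimized parameter in ",
         "scenario ", spec$scenario)
  }
  if (is.null(control)) {
    control <- modifyList(fit$control,
                          list(nm_maxit = 0, polish = TRUE,
                               refine_cycles = 0))
  }
  c_opt <- fit$params$contents[[pool]]
  q_opt <- fit_quantities(fit)[[quantity]]
  if (is.null(q_opt)) stop("unknown quantity: ", quantity)

  # warm start: drop the fixed content's coordinate from the optimum
  free_names <- spec$pars$name[spec$pars$free]
  drop_k <- match(paste0("content_", pool), free_names)

  rows <- withr::with_seed(seed, {
    purrr::map(levels, function(lv) {
      pspec <- fix_content(spec, pool, lv * c_opt)
      refit <- tryCatch(
        fit_scenario(fit$dataset, pspec, restarts = restarts,
                     seed = sample.int(.Machine$integer.max, 1),
                     input_models = fit$input_models,
                     warm_theta = fit$theta[-drop_k], control = control),
        error = function(e) NULL
      )
      if (is.null(refit)) {
        return(tibble::tibble(level = lv, value = NA_real_,
                              vwss = NA_real_))
      }
      tibble::tibble(level = lv,
                     value = fit_quantities(refit)[[quantity]],
                     vwss = refit$vwss_all)
    }) |> dplyr::bind_rows()
  })

  ok <- !is.na(rows$value)
  if (sum(!ok) > length(levels) / 2) {
    stop("re-optimization failed at more than half of the perturbation ",
         "levels for pool ", pool)
  }
  rows <- rows[ok, ]
  reg <- sensitivity_from_responses(rows$level, rows$value, q_opt)
  out <- tibble::tibble(
    pool = pool, quantity = quantity, slope = reg$slope,
    r = reg$r, sensitivity = reg$sensitivity,
    n_levels = nrow(rows)
  )
  attr(out, "levels") <- rows
  class(out) <- c("sensitivity_record", class(out))
  out
}

#' Full sensitivity matrix over pools and quantities
#'
#' Crosses the requested optimized contents with the requested quantities
#' (fluxes and the time-related error); contents fixed by the scenario are
#' skipped with a message.
#'
#' @param fit An `mfa_fit`.
#' @param pools Pool ids; defaults to every content optimized in the
#'   scenario.
#' @param quantities Quantity selectors; defaults to the four net-mode
#'   weights and `vwss_t`.
#' @param levels Perturbation multipliers.
#' @param restarts,seed,control Passed to [local_sensitivity()].
#' @return Tibble of class `sensitivity_matrix` with one
#'   record per (pool, quantity).
#' @export
sensitivity_matrix <- function(fit, pools = NULL,
                               quantities = c("weight_starch",
                                              "weight_sucrose",
                                              "weight_trehalose",
                                              "weight_photorespiration",
                                              "vwss_t"),
                               levels = perturbation_grid(), restarts = 3,
                               seed = 1, control = NULL) {
  spec <- fit$spec
  optimized <- spec$pars$target[spec$pars$type == "content" & spec$pars$free]
  if (is.null(pools)) pools <- optimized
  skipped <- setdiff(pools, optimized)
  if (length(skipped)) {
    message("skipping content(s) fixed by the scenario: ",
            paste(skipped, collapse = ", "))
    pools <- intersect(pools, optimized)
  }
  grid <- tidyr::expand_grid(pool = pools, quantity = quantities)
  out <- purrr::map2(grid$pool, grid$quantity, function(p, q) {
    rec <- local_sensitivity(fit, p, q, levels = levels,
                             restarts = restarts, seed = seed,
                             control = control)
    attr(rec, "levels") <- NULL
    class(rec) <- class(rec)[-1]
    rec
  }) |> dplyr::bind_rows()
  class(out) <- c("sensitivity_matrix", class(out))
  out
}

#' Heatmap of a sensitivity matrix
#'
#' @param object A `sensitivity_matrix`.
#' @param ... Unused.
#' @return A ggplot: pools x quantities tile map of sensitivities.
#' @export
autoplot.sensitivity_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$quantity, y = .data$pool,
                               fill = .data$sensitivity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "perturbed content",
                  fill = "sensitivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Regression step of the sensitivity procedure
#'
#' Fits an ordinary least-squares line through the relative change of the
#' perturbed content (`level - 1`) and the relative change of the
#' re-optimized quantity, and applies the correlation zeroing rule: when
#' the absolute correlation coefficient is below 0.5 the reported
#' sensitivity is set to zero (in that regime the slope estimate is always
#' small and unreliable).
#'
#' @param levels Perturbation multipliers actually used.
#' @param values Re-optimized quantity values at those levels.
#' @param optimum Unperturbed quantity value.
#' @return List with `slope`, `r` and `sensitivity`.
#' @export
sensitivity_from_responses <- function(levels, values, optimum) {
  dx <- levels - 1
  dy <- if (optimum != 0) (values - optimum) / optimum else values
  r <- suppressWarnings(cor(dx, dy))
  slope <- unname(coef(lm(dy ~ dx))[2])
  list(slope = slope,
       r = ifelse(is.na(r), 0, r),
       sensitivity = if (is.na(r) || abs(r) < 0.5) 0 else slope)
}
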