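#' Uniform-labeling weight of a mass isotopomer in a cumomer fraction
#'
#' Under the assumption that label is uniformly distributed within each
#' mass isotopomer, the contribution of the `i`-th mass isotopomer of an
#' `N`-carbon metabolite to a size-`s` cumomer (the fraction of molecules
#' unlabeled at a given set of `s` positions) is the hypergeometric ratio
#' `choose(N - s, i) / choose(N, i)`, independent of time.
#'
#' @param N Number of carbon atoms (5 for RuBP).
#' @param s Cumomer size, `1 <= s <= N`.
#' @param i Mass state, `0 <= i <= N`.
#' @return Weight in `[0, 1]`; zero whenever `i > N - s`.
#' @examples
#' theta_weight(5, 3, 1)  # choose(2,1)/choose(5,1) = 0.4
#' @export
theta_weight <- function(N, s, i) {
  if (any(s < 1 | s > N)) stop("cumomer size s must satisfy 1 <= s <= N")
  if (any(i < 0 | i > N)) stop("mass state i must satisfy 0 <= i <= N")
  choose(N - s, i) / choose(N, i)
}

#' Full theta table for an N-carbon metabolite
#'
#' @param N Number of carbon atoms.
#' @return Tibble with columns `s`, `i`, `theta`.
#' @export
theta_table <- function(N = 5) {
  tidyr::expand_grid(s = seq_len(N), i = 0:N) |>
    dplyr::mutate(theta = theta_weight(N, .data$s, .data$i))
}

#' Validate a mass-isotopomer time series
#'
#' @param series Tibble with a `time_s` column and mass-isotopomer fraction
#'   columns `m0`, `m1`, ... `mN`.
#' @param tol Tolerance on the per-time-point sum.
#' @return The series, invisibly; errors on violations.
#' @export
validate_mass_isotopomers <- function(series, tol = 1e-6) {
  mcols <- grep("^m[0-9]+$", names(series), value = TRUE)
  if (length(mcols) < 2 || !"time_s" %in% names(series)) {
    stop("expected columns time_s and m0..mN")
  }
  x <- as.matrix(series[mcols])
  if (any(x < -tol | x > 1 + tol)) {
    stop("mass-isotopomer fractions must lie in [0, 1]")
  }
  sums <- rowSums(x)
  if (any(abs(sums - 1) > tol)) {
    stop("mass-isotopomer fractions must sum to 1 at every time point")
  }
  invisible(series)
}

#' Cumomer time course from mass-isotopomer fractions
#'
#' Applies the uniform-labeling weights to map a measured mass-isotopomer
#' time series to the time course of a size-`s` cumomer fraction,
#' `y_s(t) = sum_i theta_s^i * x^i(t)`.
#'
#' @param series Mass-isotopomer tibble (`time_s`, `m0`..`mN`).
#' @param s Cumomer size.
#' @return Tibble with columns `time_s`, `s`, `y`.
#' @examples
#' ser <- tibble::tibble(time_s = 0, m0 = 0.5, m1 = 0, m2 = 0, m3 = 0,
#'                       m4 = 0, m5 = 0.5)
#' cumomers_from_mass_isotopomers(ser, 2)$y  # 0.5
#' @export
cumomers_from_mass_isotopomers <- function(series, s) {
  validate_mass_isotopomers(series)
  mcols <- sort(grep("^m[0-9]+$", names(series), value = TRUE))
  N <- length(mcols) - 1L
  if (s < 1 || s > N) stop("cumomer size s must satisfy 1 <= s <= N")
  th <- theta_weight(N, s, 0:N)
  tibble::tibble(
    time_s = series$time_s,
    s = s,
    y = as.numeric(as.matrix(series[mcols]) %*% th)
  )
}

#' Evaluate a two-exponential input model
#'
#' @param model List (or one-row tibble) with fields `A`, `a`, `B`, `b`;
#'   the model is `A * exp(-a t) + B * exp(-b t)` with `A + B = 1`.
#' @param t Times in seconds, `t >= 0`.
#' @return Model values.
#' @export
eval_input_model <- function(model, t) {
  model$A * exp(-model$a * t) + model$B * exp(-model$b * t)
}

#' Fit a two-exponential input model to a cumomer time course
#'
#' Least-squares fit of `y(t) = A exp(-a t) + B exp(-b t)` under the
#' constraints `A + B = 1`, `a, b >= 0`, `A` in `[0, 1]`.  The fit is run
#' from a small multistart grid of log-spaced rate pairs and the best
#' constrained optimum is returned.  A degenerate, non-decaying series
#' returns `a = b = 0` with a warning rather than an error.
#'
#' @param series Tibble with columns `time_s` and `y` (values in `[0, 1]`),
#'   at least 4 time points.  A column `s` (cumomer size) is carried
#'   through if present.
#' @param n_starts Number of multistart rate pairs.
#' @return A one-row tibble of class `input_model` with columns `s`, `A`,
#'   `a`, `B`, `b`, `rss`.
#' @export
fit_input_model <- function(series, n_starts = 10) {
  if (nrow(series) < 4) stop("need at least 4 time points")
  if (any(series$y < -1e-9 | series$y > 1 + 1e-9)) {
    stop("cumomer values must lie in [0, 1]")
  }
  t <- series$time_s
  y <- series$y
  s_val <- if ("s" %in% names(series)) series$s[[1]] else NA_integer_

  if (diff(range(y)) < 1e-12) {
    warning("degenerate (constant) series; returning a = b = 0")
    return(new_input_model(s_val, A = 1, a = 0, B = 0, b = 0, rss = 0))
  }

  # parameters: qA = logit(A), la = log a, lb = log b
  unpack <- function(p) {
    A <- stats::plogis(p[1])
    list(A = A, a = exp(p[2]), B = 1 - A, b = exp(p[3]))
  }
  resid_fn <- function(p) {
    m <- unpack(p)
    m$A * exp(-m$a * t) + m$B * exp(-m$b * t) - y
  }

  tmax <- max(t)
  rates <- exp(seq(log(0.2 / tmax), log(50 / tmax), length.out = n_starts))
  best <- NULL
  for (k in seq_len(n_starts)) {
    p0 <- c(stats::qlogis(0.6), log(rates[k]),
            log(rates[max(1, n_starts + 1 - k)] / 10))
    ft <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(ft)) next
    rss <- sum(ft$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = ft$par, rss = rss)
  }
  if (is.null(best)) stop("input-model fit failed from all starts")
  m <- unpack(best$par)
  # order so the dominant (larger-amplitude) term comes first
  if (m$B > m$A) m <- list(A = m$B, a = m$b, B = m$A, b = m$a)
  new_input_model(s_val, A = m$A, a = m$a, B = m$B, b = m$b, rss = best$rss)
}

new_input_model <- function(s, A, a, B, b, rss) {
  out <- tibble::tibble(s = s, A = A, a = a, B = B, b = b, rss = rss)
  class(out) <- c("input_model", class(out))
  out
}

#' Fit RuBP input models for the cumomer sizes a network needs
#'
#' Maps a RuBP mass-isotopomer series to cumomer time courses and fits a
#' two-exponential input model for each requested size.
#'
#' @param rubp RuBP mass-isotopomer tibble (`time_s`, `m0`..`m5`).
#' @param sizes Cumomer sizes to model; the reference network references
#'   sizes 2 (the oxygenation fragment) and 3 (the carboxylation fragment).
#' @return Named list (`"y2"`, `"y3"`, ...) of `input_model` rows.
#' @export
fit_rubp_input_models <- function(rubp, sizes = c(2, 3)) {
  models <- lapply(sizes, function(s) {
    fit_input_model(cumomers_from_mass_isotopomers(rubp, s))
  })
  names(models) <- paste0("y", sizes)
  models
}
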