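#' Active pool sizes from compartmentalized contents and inactive fractions
#'
#' Splits each compartmentalized content `c_n` into an active pool
#' `p_n = c_n * (1 - phi_m)` and an inactive remainder, where `phi_m` is
#' the inactive fraction of pool `n`'s metabolite (compartment twins share
#' one inactive fraction).
#'
#' @param contents Named numeric: compartmentalized content per simulated
#'   pool (nmol C gFW^-1), all positive.
#' @param phi Named numeric: inactive fraction per observed metabolite, in
#'   `[0, 1)`.
#' @param network An `mfa_network`.
#' @return Tibble with columns `pool`, `metabolite`, `content`, `phi`,
#'   `active`.
#' @export
active_pool_sizes <- function(contents, phi, network) {
  sim <- simulated_pools(network)
  missing_c <- setdiff(sim$id, names(contents))
  if (length(missing_c)) {
    stop("missing contents for pool(s): ", paste(missing_c, collapse = ", "))
  }
  if (any(contents[sim$id] <= 0)) stop("contents must be positive")
  missing_p <- setdiff(unique(sim$metabolite), names(phi))
  if (length(missing_p)) {
    stop("missing inactive fraction for metabolite(s): ",
         paste(missing_p, collapse = ", "))
  }
  if (any(phi < 0 | phi >= 1)) stop("inactive fractions must lie in [0, 1)")
  phi_n <- phi[sim$metabolite]
  tibble::tibble(
    pool = sim$id,
    metabolite = sim$metabolite,
    content = unname(contents[sim$id]),
    phi = unname(phi_n),
    active = unname(contents[sim$id]) * (1 - unname(phi_n))
  )
}

#' Observation map of the reference network
#'
#' Lists, for each observed metabolite, the simulated pools contributing to
#' its measured content.  FBP, F6P, G6P and G1P are observed as
#' plastid/cytosol two-pool mixtures; the remaining ten metabolites map to
#' a single pool, giving 14 observed metabolites in total.
#'
#' @param network An `mfa_network`.
#' @return Tibble with columns `metabolite` and list-column `pools`.
#' @export
observation_map <- function(network) {
  sim <- simulated_pools(network)
  sim |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(pools = list(.data$id), .groups = "drop") |>
    dplyr::arrange(match(.data$metabolite, unique(sim$metabolite)))
}

#' Assemble the labeling ODE system
#'
#' Builds the right-hand side of the mass-state-zero cumomer balance
#' equations for all simulated pools: for pool `n`,
#' `dx_n/dt = (1/p_n) * (sum_r F_in_{r,n} h_{r,n}(t) - F_n x_n)`, where the
#' unlabeled-production terms `h` are products over source unlabeled
#' fractions (simulated pools, RuBP cumomer input models, or CO2 which is
#' labeled from time zero).  The system is flattened into the parameter
#' vector consumed by the package's compiled derivative function.
#'
#' @param network An `mfa_network`.
#' @param flux A `flux_distribution` at steady state.
#' @param pool_sizes Named numeric of active pool sizes `p_n` (nmol C
#'   gFW^-1) for all simulated pools, or the tibble returned by
#'   [active_pool_sizes()].
#' @param input_models Named list of RuBP input models (`"y2"`, `"y3"`,
#'   ...), as from [fit_rubp_input_models()].
#' @return Object of class `ode_system`.
#' @export
assemble_system <- function(network, flux, pool_sizes, input_models) {
  if (is.data.frame(pool_sizes)) {
    pool_sizes <- setNames(pool_sizes$active, pool_sizes$pool)
  }
  sim_ids <- network$pools$id[network$pools$simulated]
  missing_p <- setdiff(sim_ids, names(pool_sizes))
  if (length(missing_p)) {
    stop("missing pool size for: ", paste(missing_p, collapse = ", "))
  }
  p <- pool_sizes[sim_ids]

  turn <- setNames(flux$pools$turnover, flux$pools$pool)[sim_ids]
  zero_p <- p <= 0
  if (any(zero_p & turn > 0)) {
    stop("pool with influx but nonpositive pool size: ",
         paste(sim_ids[zero_p & turn > 0], collapse = ", "))
  }
  if (any(zero_p)) {
    stop("nonpositive pool size for: ",
         paste(sim_ids[zero_p], collapse = ", "))
  }
  kout <- setNames(flux$pools$outflux, flux$pools$pool)[sim_ids] / p

  rxns <- network$reactions
  fwd <- setNames(flux$reactions$forward_extent, flux$reactions$reaction)
  bwd <- setNames(flux$reactions$backward_extent, flux$reactions$reaction)

  terms <- list()
  add_term <- function(target, influx, w, factors) {
    if (any(factors == "co2")) return(invisible(NULL))  # labeled source
    terms[[length(terms) + 1L]] <<- tibble::tibble(
      target = target, coef = influx * w / p[[target]],
      f1 = if (length(factors) >= 1) factors[[1]] else "",
      f2 = if (length(factors) >= 2) factors[[2]] else ""
    )
  }
  for (i in seq_len(nrow(rxns))) {
    id <- rxns$id[i]
    if (fwd[[id]] > 0) {
      hr <- rxns$hrules[[i]]
      for (tgt in names(rxns$prod[[i]])) {
        if (!tgt %in% sim_ids) next
        influx <- fwd[[id]] * rxns$prod[[i]][[tgt]]
        for (term in hr[[tgt]]) add_term(tgt, influx, term$w, term$f)
      }
    }
    if (rxns$reversible[i] && bwd[[id]] > 0) {
      src <- names(rxns$prod[[i]])   # reversible reactions are 1:1
      for (tgt in names(rxns$sub[[i]])) {
        if (!tgt %in% sim_ids) next
        influx <- bwd[[id]] * rxns$sub[[i]][[tgt]]
        add_term(tgt, influx, 1, src)
      }
    }
  }
  terms <- if (length(terms)) dplyr::bind_rows(terms) else
    tibble::tibble(target = character(), coef = numeric(),
                   f1 = character(), f2 = character())
  terms <- dplyr::filter(terms, .data$coef != 0)

  make_ode_system(kout, terms, input_models, states = sim_ids)
}

#' Low-level constructor of a labeling ODE system
#'
#' Exposes the flattened representation the compiled right-hand side
#' integrates: per-state linear drain rates and a list of production terms
#' `coef * f1 * f2`, where each factor is a state, a two-exponential input
#' model, or the constant 1 (empty string).  Useful for building small toy
#' systems in tests and examples; [assemble_system()] builds on it.
#'
#' @param kout Named numeric of drain rates `F_n / p_n` (1/s) per state.
#' @param terms Tibble with columns `target`, `coef`, `f1`, `f2`.
#' @param input_models Named list of input models (`A`, `a`, `B`, `b`).
#' @param states State names; defaults to `names(kout)`.
#' @return Object of class `ode_system`: list with `states`, `y0`, `kout`,
#'   `terms`, `input_models` and the flattened `parms` vector.
#' @export
make_ode_system <- function(kout, terms, input_models = list(),
                            states = names(kout)) {
  stopifnot(!is.null(states), all(names(kout) %in% states))
  kvec <- setNames(rep(0, length(states)), states)
  kvec[names(kout)] <- kout
  input_names <- names(input_models)

  encode_factor <- function(f) {
    if (is.na(f) || f == "") return(c(0, 0))
    if (f %in% states) return(c(1, match(f, states) - 1))
    if (f %in% input_names) return(c(2, match(f, input_names) - 1))
    stop("unknown factor in ODE term: '", f, "'")
  }

  nT <- nrow(terms)
  term_block <- numeric(0)
  if (nT > 0) {
    enc <- matrix(0, nT, 6)
    for (i in seq_len(nT)) {
      if (!terms$target[i] %in% states) {
        stop("unknown target state: ", terms$target[i])
      }
      enc[i, 1] <- match(terms$target[i], states) - 1
      enc[i, 2] <- terms$coef[i]
      enc[i, 3:4] <- encode_factor(terms$f1[i])
      enc[i, 5:6] <- encode_factor(terms$f2[i])
    }
    term_block <- as.numeric(t(enc))
  }
  input_block <- unlist(lapply(input_models, function(m) {
    c(m$A, m$a, m$B, m$b)
  }), use.names = FALSE)
  if (is.null(input_block)) input_block <- numeric(0)

  parms <- c(length(states), nT, length(input_models),
             unname(kvec), term_block, input_block)
  if (length(parms) > .instmfa_maxparms) {
    stop("flattened ODE system exceeds the compiled parameter buffer")
  }
  parms <- c(parms, rep(0, .instmfa_maxparms - length(parms)))

  structure(
    list(states = states, y0 = setNames(rep(1, length(states)), states),
         kout = kvec, terms = terms, input_models = input_models,
         parms = parms),
    class = "ode_system"
  )
}

#' Integrate a labeling ODE system
#'
#' Integrates the system with a stiff implicit multistep (BDF) method from
#' the fully unlabeled initial condition `x(0) = 1`.
#'
#' @param system An `ode_system`.
#' @param times Sorted nonnegative times (seconds) at which trajectories
#'   are returned.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method (default `"bdf"`).
#' @return Object of class `trajectory_set`: list with `times` and matrix
#'   `x` (times x states) of unlabeled fractions.
#' @export
integrate_system <- function(system, times, rtol = 1e-8, atol = 1e-10,
                             method = "bdf") {
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and nonnegative")
  }
  tt <- unique(c(0, times))
  sol <- deSolve::ode(
    y = system$y0, times = tt, func = "instmfa_derivs",
    parms = system$parms, dllname = "instmfa",
    initfunc = "instmfa_initmod", method = method,
    rtol = rtol, atol = atol, maxsteps = 50000
  )
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("ODE integration failed (istate = ", diagn[1], ")")
  }
  x <- sol[match(times, tt), system$states, drop = FALSE]
  if (anyNA(x) || any(!is.finite(x))) {
    stop("ODE integration produced non-finite trajectory values")
  }
  rownames(x) <- NULL
  structure(list(times = times, x = x), class = "trajectory_set")
}

#' @export
tidy.trajectory_set <- function(x, ...) {
  tibble::as_tibble(x$x) |>
    dplyr::mutate(time_s = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time_s", names_to = "pool", values_to = "value")
}

#' Apply the observation model to simulated trajectories
#'
#' Maps simulated per-pool unlabeled fractions to observed-level unlabeled
#' fractional contents: single-pool metabolites as
#' `z = (1 - phi) * x + phi`, two-pool metabolites as the active-size
#' weighted mean of the two pools before the inactive-fraction offset.
#'
#' @param traj A `trajectory_set`.
#' @param sizes Tibble from [active_pool_sizes()] (columns `pool`,
#'   `metabolite`, `phi`, `active`).
#' @param map Observation map tibble (from [observation_map()]); defaults
#'   to grouping `sizes` by metabolite.
#' @return Tibble with columns `metabolite`, `time_s`, `value`.
#' @export
observe <- function(traj, sizes, map = NULL) {
  if (is.null(map)) {
    map <- sizes |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(pools = list(.data$pool), .groups = "drop")
  }
  p <- setNames(sizes$active, sizes$pool)
  phi <- setNames(sizes$phi, sizes$metabolite)
  out <- purrr::map2(map$metabolite, map$pools, function(m, pls) {
    missing <- setdiff(pls, colnames(traj$x))
    if (length(missing)) {
      stop("observed metabolite '", m, "' references unsimulated pool(s): ",
           paste(missing, collapse = ", "))
    }
    ph <- phi[[m]]
    if (ph < 0 || ph >= 1) stop("inactive fraction out of [0, 1) for ", m)
    w <- p[pls] / sum(p[pls])
    xbar <- drop(traj$x[, pls, drop = FALSE] %*% w)
    tibble::tibble(metabolite = m, time_s = traj$times,
                   value = (1 - ph) * xbar + ph)
  })
  dplyr::bind_rows(out)
}

#' Simulate observed unlabeled fractional contents for given parameters
#'
#' Convenience wrapper chaining [flux_from_modes()], [active_pool_sizes()],
#' [assemble_system()], [integrate_system()] and [observe()].
#'
#' @param params List with `weights`, `exchange_raw`, `contents` (named,
#'   18 pools) and `phi` (named, 14 metabolites).
#' @param basis A `flux_mode_basis`.
#' @param input_models Named list of RuBP input models.
#' @param times Output times (seconds).
#' @param rtol,atol Solver tolerances.
#' @return List with `flux` (`flux_distribution`), `trajectories`
#'   (`trajectory_set`) and `predicted` (tibble `metabolite`, `time_s`,
#'   `value`).
#' @export
simulate_labeling <- function(params, basis, input_models, times,
                              rtol = 1e-8, atol = 1e-10) {
  network <- basis$network
  fd <- flux_from_modes(params, basis)
  sizes <- active_pool_sizes(params$contents, params$phi, network)
  sys <- assemble_system(network, fd, sizes, input_models)
  traj <- integrate_system(sys, times, rtol = rtol, atol = atol)
  list(flux = fd, trajectories = traj,
       predicted = observe(traj, sizes, observation_map(network)))
}
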