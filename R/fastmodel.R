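# Internal fast evaluation path for the fit objective.
#
# The public constructors (flux_from_modes, assemble_system, observe) build
# tidy per-call objects, which is convenient for reporting but too slow
# inside a multistart optimization.  build_fast_model() precomputes every
# index structure of the reference network once per fit; fast_residuals()
# then evaluates the weighted residual vector with plain numeric operations
# and a single call into the compiled ODE solver.  Tests assert that the
# fast path and the public path agree to solver precision.

build_fast_model <- function(spec, prep) {
  basis <- spec$basis
  network <- basis$network
  rxns <- network$reactions
  sim_ids <- network$pools$id[network$pools$simulated]
  n <- length(sim_ids)
  nr <- nrow(rxns)
  pool_idx <- setNames(seq_len(n), sim_ids)

  # carbon-flow matrices: influx/outflux per pool as linear maps of the
  # forward/backward extent vectors
  IN_f <- matrix(0, n, nr); IN_b <- matrix(0, n, nr)
  OUT_f <- matrix(0, n, nr); OUT_b <- matrix(0, n, nr)
  for (j in seq_len(nr)) {
    for (p in names(rxns$prod[[j]])) {
      if (p %in% sim_ids) {
        IN_f[pool_idx[[p]], j] <- rxns$prod[[j]][[p]]
        if (rxns$reversible[j]) OUT_b[pool_idx[[p]], j] <- rxns$prod[[j]][[p]]
      }
    }
    for (p in names(rxns$sub[[j]])) {
      if (p %in% sim_ids) {
        OUT_f[pool_idx[[p]], j] <- rxns$sub[[j]][[p]]
        if (rxns$reversible[j]) IN_b[pool_idx[[p]], j] <- rxns$sub[[j]][[p]]
      }
    }
  }

  input_names <- names(prep$input_models)
  encode_factor <- function(f) {
    if (is.na(f) || f == "" ) return(c(0, 0))
    if (f == "co2") return(c(-1, 0))          # marks a dropped term
    if (f %in% sim_ids) return(c(1, pool_idx[[f]] - 1))
    if (f %in% input_names) return(c(2, match(f, input_names) - 1))
    stop("unknown factor: ", f)
  }

  # structural term list: one row per (unidirectional flux, product, h-term)
  t_rxn <- integer(0); t_dir <- integer(0); t_tgt <- integer(0)
  t_const <- numeric(0); t_enc <- matrix(0, 0, 4)
  for (j in seq_len(nr)) {
    hr <- rxns$hrules[[j]]
    for (tgt in names(rxns$prod[[j]])) {
      if (!tgt %in% sim_ids) next
      for (term in hr[[tgt]]) {
        f1 <- encode_factor(if (length(term$f) >= 1) term$f[[1]] else "")
        f2 <- encode_factor(if (length(term$f) >= 2) term$f[[2]] else "")
        if (f1[1] < 0 || f2[1] < 0) next     # CO2-bearing product: h = 0
        t_rxn <- c(t_rxn, j); t_dir <- c(t_dir, 1L)
        t_tgt <- c(t_tgt, pool_idx[[tgt]])
        t_const <- c(t_const, rxns$prod[[j]][[tgt]] * term$w)
        t_enc <- rbind(t_enc, c(f1, f2))
      }
    }
    if (rxns$reversible[j]) {
      src <- names(rxns$prod[[j]])[1]
      for (tgt in names(rxns$sub[[j]])) {
        if (!tgt %in% sim_ids) next
        f1 <- encode_factor(src)
        t_rxn <- c(t_rxn, j); t_dir <- c(t_dir, 2L)
        t_tgt <- c(t_tgt, pool_idx[[tgt]])
        t_const <- c(t_const, rxns$sub[[j]][[tgt]])
        t_enc <- rbind(t_enc, c(f1, 0, 0))
      }
    }
  }
  nT <- length(t_rxn)

  # template parameter vector for the compiled derivative function
  parms <- numeric(.instmfa_maxparms)
  parms[1] <- n; parms[2] <- nT; parms[3] <- length(prep$input_models)
  base_terms <- 3 + n
  for (i in seq_len(nT)) {
    off <- base_terms + 6 * (i - 1)
    parms[off + 1] <- t_tgt[i] - 1
    parms[off + 3] <- t_enc[i, 1]; parms[off + 4] <- t_enc[i, 2]
    parms[off + 5] <- t_enc[i, 3]; parms[off + 6] <- t_enc[i, 4]
  }
  base_inputs <- base_terms + 6 * nT
  im_block <- unlist(lapply(prep$input_models, function(m) {
    c(m$A, m$a, m$B, m$b)
  }), use.names = FALSE)
  if (length(im_block)) {
    parms[base_inputs + seq_along(im_block)] <- im_block
  }
  kout_slots <- 3 + seq_len(n)
  coef_slots <- base_terms + 6 * (seq_len(nT) - 1) + 2

  # exchange bookkeeping
  exch_cols <- match(basis$exchange_reactions, rxns$id)
  cflux_exch <- basis$cflux[basis$exchange_reactions]

  # observation structure: metabolite -> pool indices, phi index
  map <- prep$map
  met_names <- map$metabolite
  met_pools <- lapply(map$pools, function(p) unname(pool_idx[p]))
  pool_met_idx <- match(
    network$pools$metabolite[network$pools$simulated], met_names)

  # parameter unpacking structure
  pars <- spec$pars
  full_values <- pars$value
  free_idx <- which(pars$free)
  free_type <- pars$type[free_idx]
  free_lower <- pars$lower[free_idx]
  free_upper <- pars$upper[free_idx]
  slot_of <- function(type, targets) {
    match(paste0(switch(type, weight = "weight_", exchange = "exchange_",
                        phi = "phi_", content = "content_"), targets),
          pars$name)
  }
  w_slots <- slot_of("weight", basis$mode_names)
  ex_slots <- slot_of("exchange", basis$exchange_reactions)
  phi_slots <- slot_of("phi", met_names)
  c_slots <- slot_of("content", sim_ids)

  times <- prep$times
  nt <- length(times)
  n_c <- if (spec$objective == "all") length(prep$contents_obs) else 0L
  contents_obs <- unname(prep$contents_obs[sim_ids])
  contents_sd <- unname(prep$contents_sd[sim_ids])

  unpack_fast <- function(theta) {
    v <- full_values
    v[free_idx] <- ifelse(
      free_type == "weight", exp(theta),
      ifelse(free_type == "exchange",
             pmin(stats::plogis(theta), 1 - 1e-12),
        ifelse(free_type == "phi", 0.95 * stats::plogis(theta),
          exp(log(free_lower) +
                stats::plogis(theta) * (log(free_upper) - log(free_lower))))))
    v
  }

  predict_fast <- function(theta, rtol, atol) {
    v <- unpack_fast(theta)
    w <- v[w_slots]
    raw <- v[ex_slots]
    phi <- v[phi_slots]
    contents <- v[c_slots]
    if (any(!is.finite(w)) || any(!is.finite(contents))) return(NULL)

    scale <- sum(w)
    net_ext <- drop(basis$net %*% w)
    bwd <- numeric(nr)
    if (scale > 0) {
      E <- pmin(scale * raw / (1 - raw), 1e4 * scale)
      bwd[exch_cols] <- E / cflux_exch
    }
    fwd <- net_ext + bwd

    p <- contents * (1 - phi[pool_met_idx])
    outflux <- drop(OUT_f %*% fwd + OUT_b %*% bwd)
    kout <- outflux / p

    ext_term <- ifelse(t_dir == 1L, fwd[t_rxn], bwd[t_rxn])
    coefs <- ext_term * t_const / p[t_tgt]

    pv <- parms
    pv[kout_slots] <- kout
    pv[coef_slots] <- coefs

    sol <- tryCatch(
      deSolve::ode(y = rep(1, n), times = c(0, times),
                   func = "instmfa_derivs", parms = pv,
                   dllname = "instmfa", initfunc = "instmfa_initmod",
                   method = "bdf", rtol = rtol, atol = atol,
                   maxsteps = 50000),
      error = function(e) NULL,
      warning = function(w) NULL
    )
    if (is.null(sol) || nrow(sol) != nt + 1) return(NULL)
    x <- sol[-1, -1, drop = FALSE]
    if (anyNA(x) || any(!is.finite(x))) return(NULL)

    # observation model: active-size weighted mixing + inactive offset
    z <- matrix(0, nt, length(met_names))
    for (m in seq_along(met_names)) {
      ip <- met_pools[[m]]
      if (length(ip) == 1) {
        xb <- x[, ip]
      } else {
        pw <- p[ip] / sum(p[ip])
        xb <- drop(x[, ip, drop = FALSE] %*% pw)
      }
      z[, m] <- (1 - phi[m]) * xb + phi[m]
    }
    list(pred = as.vector(z), contents = contents, values = v)
  }

  residuals_fast <- function(theta, rtol, atol, bad) {
    out <- predict_fast(theta, rtol, atol)
    if (is.null(out)) {
      return(rep(bad, length(prep$obs) + n_c))
    }
    res_t <- (prep$obs - out$pred[prep$keep_rows]) / prep$sigma
    if (n_c > 0) {
      res_c <- (contents_obs - out$contents) / contents_sd
      c(res_t, res_c)
    } else {
      res_t
    }
  }

  list(predict = predict_fast, residuals = residuals_fast,
       n_res = length(prep$obs) + n_c)
}
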