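#' Enumerate elementary flux modes of the net reaction system
#'
#' Enumerates the extreme rays of the flux cone \{v >= 0 : S v = 0\} of the
#' network with all reversible reactions collapsed to their net direction,
#' i.e. the elementary flux modes of the irreversible net system.  For the
#' reference network the balanced species are the simulated pools (minus the
#' pure-exchange 2PGA appendage) plus RuBP, whose regeneration from 3PGA
#' closes the Calvin-Benson cycle; the dead-end 3PGA/2PGA exchange reaction
#' is excluded because it can carry no net flux.
#'
#' The algorithm is the classical double-description tableau: constraints
#' (species balances) are processed one at a time, combining positive and
#' negative rays and discarding rays of non-minimal support.
#'
#' @param network An `mfa_network`.
#' @param drop_reactions Reaction ids excluded from enumeration (default:
#'   the dead-end `pga_2pga` exchange).
#' @param drop_species Balanced-species ids excluded (default `"2PGA"`).
#' @return Numeric matrix, reactions x modes, in reaction-extent units;
#'   rows are ordered and named as `network$reactions$id` (excluded
#'   reactions appear with zero rows).  Each column is scaled to a maximum
#'   coefficient of 1.
#' @export
enumerate_net_modes <- function(network, drop_reactions = "pga_2pga",
                                drop_species = "2PGA") {
  pools <- network$pools
  internal <- setdiff(c(pools$id[pools$simulated],
                        pools$id[pools$role == "input" & pools$id == "RuBP"]),
                      drop_species)
  rxn_ids <- setdiff(network$reactions$id, drop_reactions)
  S <- stoich_matrix(network, internal, rxn_ids)
  rays <- extreme_rays(S)
  if (ncol(rays) == 0) {
    stop("stoichiometric system admits no nonzero steady-state mode")
  }
  out <- matrix(0, nrow(network$reactions), ncol(rays),
                dimnames = list(network$reactions$id, NULL))
  out[rxn_ids, ] <- rays
  out
}

# Extreme rays of {v >= 0 : S v = 0} by the tableau (double description)
# method; returns an n x k matrix of rays scaled to max coefficient 1.
extreme_rays <- function(S, tol = 1e-10) {
  n <- ncol(S)
  R <- diag(n)              # candidate rays, one per row
  V <- R %*% t(S)           # residual constraint values
  for (j in seq_len(nrow(S))) {
    colj <- V[, j]
    zero <- which(abs(colj) <= tol * pmax(1, apply(abs(R), 1, max)))
    pos <- which(colj > 0 & !seq_along(colj) %in% zero)
    neg <- which(colj < 0 & !seq_along(colj) %in% zero)
    newR <- R[zero, , drop = FALSE]
    newV <- V[zero, , drop = FALSE]
    if (length(pos) && length(neg)) {
      combos_r <- vector("list", length(pos) * length(neg))
      combos_v <- vector("list", length(pos) * length(neg))
      idx <- 1L
      for (p in pos) {
        for (q in neg) {
          w <- (-colj[q]) * R[p, ] + colj[p] * R[q, ]
          v <- (-colj[q]) * V[p, ] + colj[p] * V[q, ]
          s <- max(w)
          combos_r[[idx]] <- w / s
          combos_v[[idx]] <- v / s
          idx <- idx + 1L
        }
      }
      newR <- rbind(newR, do.call(rbind, combos_r))
      newV <- rbind(newV, do.call(rbind, combos_v))
    }
    keep <- minimal_support_rows(newR, tol)
    R <- newR[keep, , drop = FALSE]
    V <- newV[keep, , drop = FALSE]
    if (nrow(R) == 0) break
  }
  if (nrow(R) == 0) {
    return(matrix(0, n, 0))
  }
  R <- R / apply(R, 1, max)
  t(R)
}

# indices of rows whose support is minimal (no other row's support is a
# proper subset); among identical supports only the first row is kept
minimal_support_rows <- function(R, tol = 1e-10) {
  if (nrow(R) == 0) return(integer(0))
  supp <- R > tol * pmax(1, apply(abs(R), 1, max))
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i]) next
    for (k in seq_len(nrow(R))) {
      if (k == i || !keep[k]) next
      if (all(supp[k, ] <= supp[i, ])) {
        if (all(supp[i, ] <= supp[k, ])) {
          keep[max(i, k)] <- FALSE        # duplicate support
        } else {
          keep[i] <- FALSE                # i is non-minimal
          break
        }
      }
    }
  }
  which(keep)
}

#' Flux-mode basis of the reference network
#'
#' Builds the 11-dimensional steady-state flux parameterization: four net
#' elementary flux modes, each normalized so that its weight equals its
#' terminal carbon rate (C atoms per second into starch, sucrose or
#' trehalose, or C atoms released by photorespiration), plus one exchange
#' (futile) cycle per reversible reaction.  Because each net mode carries
#' exactly one carboxylation per terminal C atom, the gross carbon fixation
#' of any weight vector equals the sum of the four net-mode weights.
#'
#' @param network An `mfa_network`; defaults to [build_reference_network()].
#' @return An object of class `flux_mode_basis`: list with `net` (reactions
#'   x 4 extent-unit matrix with columns `starch`, `sucrose`, `trehalose`,
#'   `photorespiration`), `mode_names`, `exchange_reactions` (the 7
#'   reversible reaction ids), `cflux` (C-atom throughput per unit extent,
#'   per reaction) and the `network` itself.
#' @export
flux_mode_basis <- function(network = build_reference_network()) {
  modes <- enumerate_net_modes(network)
  cflux <- reaction_cflux(network)
  release <- setNames(network$reactions$release, network$reactions$id)

  terminus_of <- function(v) {
    term <- character(0)
    if (v["starch_syn"] > 1e-9) term <- c(term, "starch")
    if (v["spp"] > 1e-9) term <- c(term, "sucrose")
    if (v["tpp"] > 1e-9) term <- c(term, "trehalose")
    if (sum(v * release) > 1e-9) term <- c(term, "photorespiration")
    term
  }
  terms <- lapply(seq_len(ncol(modes)), function(j) terminus_of(modes[, j]))
  if (any(lengths(terms) != 1)) {
    stop("net modes do not each route carbon to a single terminus")
  }
  terms <- unlist(terms)
  wanted <- c("starch", "sucrose", "trehalose", "photorespiration")
  if (!setequal(terms, wanted)) {
    stop("expected one net mode per terminus (starch, sucrose, trehalose, ",
         "photorespiration); got: ", paste(terms, collapse = ", "))
  }
  modes <- modes[, match(wanted, terms), drop = FALSE]
  colnames(modes) <- wanted

  terminal_rate <- c(
    starch = unname(modes["starch_syn", "starch"] * cflux["starch_syn"]),
    sucrose = unname(modes["spp", "sucrose"] * cflux["spp"]),
    trehalose = unname(modes["tpp", "trehalose"] * cflux["tpp"]),
    photorespiration = unname(sum(modes[, "photorespiration"] * release))
  )
  modes <- sweep(modes, 2, terminal_rate, "/")

  structure(
    list(net = modes, mode_names = wanted,
         exchange_reactions = network$reactions$id[network$reactions$reversible],
         cflux = cflux, network = network),
    class = "flux_mode_basis"
  )
}

#' Hyperbolic transform of an exchange parameter
#'
#' Maps a raw exchange parameter in `[0, 1)` to an exchange flux:
#' `scale * raw / (1 - raw)`.  The transform is monotone, zero at `raw = 0`
#' and diverges as `raw -> 1`; fluxes beyond `cap_factor * scale` are
#' capped and reported as `"Inf."` in flux tables.
#'
#' @param raw Numeric in `[0, 1)`.
#' @param scale Positive flux scale (nmol C gFW^-1 s^-1); typically the
#'   current gross carbon fixation.
#' @param cap_factor Cap on the transform, in units of `scale`.
#' @return Exchange flux, same units as `scale`.
#' @examples
#' exchange_transform(0, 10)    # 0
#' exchange_transform(0.5, 10)  # 10
#' @export
exchange_transform <- function(raw, scale, cap_factor = 1e4) {
  if (any(raw < 0 | raw >= 1)) {
    stop("raw exchange parameter must lie in [0, 1)")
  }
  pmin(scale * raw / (1 - raw), cap_factor * scale)
}

#' Steady-state flux distribution from mode weights
#'
#' Combines the four net-mode weights and seven raw exchange parameters
#' into per-reaction net, forward and backward fluxes, per-pool turnover
#' fluxes and influx ratios, and the derived gross/net carbon fixation.
#' The internal steady state holds exactly by construction of the basis.
#'
#' @param params List with `weights` (4 nonnegative net-mode weights, nmol C
#'   gFW^-1 s^-1, in basis order or named) and `exchange_raw` (7 values in
#'   `[0, 1)`, in `basis$exchange_reactions` order or named).
#' @param basis A `flux_mode_basis`.
#' @param scale Flux scale for the exchange transform; defaults to the
#'   gross fixation `sum(weights)`.
#' @param cap_factor Exchange cap in units of `scale` (capped fluxes print
#'   as `"Inf."`).
#' @return Object of class `flux_distribution`: list with tibbles
#'   `reactions` (net/forward/backward in C-atom units and extent units,
#'   `capped` flag), `pools` (turnover flux `F_n` and outflux per simulated
#'   pool), `alpha` (per unidirectional influx: carbon influx and influx
#'   ratio), scalars `gross_fixation` and `net_fixation`, and the inputs.
#' @examples
#' basis <- flux_mode_basis()
#' fd <- flux_from_modes(
#'   list(weights = c(2.39, 6.99, 0.00059, 3.93), exchange_raw = rep(0.5, 7)),
#'   basis
#' )
#' fd$gross_fixation  # 13.31
#' @export
flux_from_modes <- function(params, basis, scale = NULL, cap_factor = 1e4) {
  w <- params$weights
  if (length(w) != ncol(basis$net)) {
    stop("expected ", ncol(basis$net), " net-mode weights")
  }
  if (!is.null(names(w))) w <- w[basis$mode_names]
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("net-mode weights must be finite and nonnegative")
  }
  w <- setNames(as.numeric(w), basis$mode_names)

  raw <- params$exchange_raw
  if (length(raw) != length(basis$exchange_reactions)) {
    stop("expected ", length(basis$exchange_reactions),
         " raw exchange parameters")
  }
  if (!is.null(names(raw))) raw <- raw[basis$exchange_reactions]
  raw <- setNames(as.numeric(raw), basis$exchange_reactions)

  if (is.null(scale)) scale <- sum(w)
  exch_c <- if (scale > 0) {
    exchange_transform(raw, scale, cap_factor)
  } else {
    setNames(rep(0, length(raw)), names(raw))
  }
  capped <- scale > 0 & (raw / (1 - raw) >= cap_factor)

  network <- basis$network
  rxns <- network$reactions
  cflux <- basis$cflux

  net_extent <- setNames(drop(basis$net %*% w), rxns$id)
  if (any(net_extent < -1e-9 * max(1, sum(w)))) {
    stop("negative net flux on an irreversible reaction")
  }
  net_extent <- pmax(net_extent, 0)

  back_extent <- setNames(rep(0, nrow(rxns)), rxns$id)
  back_extent[names(exch_c)] <- exch_c / cflux[names(exch_c)]
  fwd_extent <- net_extent + back_extent

  reactions <- tibble::tibble(
    reaction = rxns$id,
    reversible = rxns$reversible,
    net = unname(net_extent * cflux),
    backward = unname(back_extent * cflux),
    forward = unname((net_extent + back_extent) * cflux),
    net_extent = unname(net_extent),
    forward_extent = unname(fwd_extent),
    backward_extent = unname(back_extent),
    capped = unname(rxns$id %in% names(capped)[capped])
  )

  # unidirectional carbon influxes per pool
  flows <- list()
  for (i in seq_len(nrow(rxns))) {
    id <- rxns$id[i]
    if (fwd_extent[id] > 0) {
      for (p in names(rxns$prod[[i]])) {
        flows[[length(flows) + 1L]] <- tibble::tibble(
          reaction = id, direction = "forward", pool = p,
          influx = fwd_extent[[id]] * rxns$prod[[i]][[p]]
        )
      }
    }
    if (back_extent[id] > 0) {
      for (p in names(rxns$sub[[i]])) {
        flows[[length(flows) + 1L]] <- tibble::tibble(
          reaction = id, direction = "backward", pool = p,
          influx = back_extent[[id]] * rxns$sub[[i]][[p]]
        )
      }
    }
  }
  empty_flow <- tibble::tibble(reaction = character(),
                               direction = character(),
                               pool = character(), influx = numeric())
  alpha <- dplyr::bind_rows(c(list(empty_flow), flows))

  # per-pool carbon outflux
  outs <- list()
  for (i in seq_len(nrow(rxns))) {
    id <- rxns$id[i]
    if (fwd_extent[id] > 0) {
      for (p in names(rxns$sub[[i]])) {
        outs[[length(outs) + 1L]] <- tibble::tibble(
          pool = p, outflux = fwd_extent[[id]] * rxns$sub[[i]][[p]]
        )
      }
    }
    if (back_extent[id] > 0) {
      for (p in names(rxns$prod[[i]])) {
        outs[[length(outs) + 1L]] <- tibble::tibble(
          pool = p, outflux = back_extent[[id]] * rxns$prod[[i]][[p]]
        )
      }
    }
  }
  out_tbl <- dplyr::bind_rows(c(
    list(tibble::tibble(pool = character(), outflux = numeric())), outs)) |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(outflux = sum(.data$outflux), .groups = "drop")

  sim_ids <- network$pools$id[network$pools$simulated]
  pools <- tibble::tibble(pool = sim_ids) |>
    dplyr::left_join(
      alpha |>
        dplyr::group_by(.data$pool) |>
        dplyr::summarise(turnover = sum(.data$influx), .groups = "drop"),
      by = "pool"
    ) |>
    dplyr::left_join(out_tbl, by = "pool") |>
    dplyr::mutate(
      turnover = dplyr::coalesce(.data$turnover, 0),
      outflux = dplyr::coalesce(.data$outflux, 0)
    )

  bad <- abs(pools$turnover - pools$outflux) >
    1e-9 * pmax(pools$turnover, 1)
  if (any(bad)) {
    stop("steady state violated for pool(s): ",
         paste(pools$pool[bad], collapse = ", "))
  }

  alpha <- alpha |>
    dplyr::filter(.data$pool %in% sim_ids) |>
    dplyr::left_join(pools[, c("pool", "turnover")], by = "pool") |>
    dplyr::mutate(alpha = ifelse(.data$turnover > 0,
                                 .data$influx / .data$turnover, 0)) |>
    dplyr::select(-"turnover")

  structure(
    list(
      reactions = reactions, pools = pools, alpha = alpha,
      gross_fixation = sum(w),
      net_fixation = sum(w) - w[["photorespiration"]],
      weights = w, exchange_raw = raw, exchange_flux = exch_c,
      scale = scale, cap_factor = cap_factor, basis = basis
    ),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Steady-state flux distribution (nmol C gFW^-1 s^-1)\n")
  cat(sprintf("  gross C fixation: %.4g   net C fixation: %.4g\n",
              x$gross_fixation, x$net_fixation))
  cat("  net-mode weights:\n")
  for (m in names(x$weights)) {
    cat(sprintf("    %-18s %.5g\n", m, x$weights[[m]]))
  }
  invisible(x)
}

#' Tidy a flux distribution into a flux-table report
#'
#' @param x A `flux_distribution`.
#' @param ... Unused.
#' @return Tibble with one row per reaction: net, forward and backward
#'   fluxes in C-atom units, with capped exchange fluxes flagged.
#' @export
tidy.flux_distribution <- function(x, ...) {
  x$reactions |>
    dplyr::select("reaction", "reversible", "net", "forward", "backward",
                  "capped")
}

#' Net-mode weights as fractions of gross carbon fixation
#'
#' @param fd A `flux_distribution`.
#' @return Named numeric: each net-mode weight divided by gross fixation.
#' @export
gross_fixation_fractions <- function(fd) {
  if (fd$gross_fixation == 0) {
    return(setNames(rep(0, length(fd$weights)), names(fd$weights)))
  }
  fd$weights / fd$gross_fixation
}
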