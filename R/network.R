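#' Reference metabolic network for photoautotrophic labeling dynamics
#'
#' Constructs the simplified central-carbon network used throughout the
#' package: the Calvin-Benson cycle condensed to a single
#' RuBP-carboxylation/regeneration interface, a simplified photorespiratory
#' pathway (Gly, Ser, Glyc), and the plastidic starch and cytosolic
#' sucrose/trehalose synthesis chains.  Eighteen pools are simulated state
#' variables; RuBP and CO2 drive the system (RuBP through fitted cumomer
#' input models, CO2 fully labeled from time zero) and starch, sucrose,
#' trehalose and the Calvin-cycle regeneration flux act as sinks.
#'
#' All stoichiometry is carried in carbon-atom units: a reaction of extent
#' one transfers the listed number of C atoms between pools, so fluxes and
#' pool sizes are expressed in nmol C per g fresh weight (per second).
#'
#' @return An object of class `mfa_network`: a list with elements
#'   * `pools` - tibble with columns `id`, `metabolite`, `compartment`,
#'     `carbons`, `simulated`, `role` (`"state"`, `"input"` or `"sink"`),
#'   * `reactions` - tibble with columns `id`, `reversible`, `release`
#'     (C atoms released as CO2 per unit extent) and list-columns `sub`,
#'     `prod` (named numeric: C atoms consumed/produced per unit extent)
#'     and `hrules` (per product pool, the unlabeled-production rule: a
#'     list of terms, each a weight and a vector of factors drawn from
#'     simulated pool ids, RuBP cumomer inputs `"y1"`..`"y5"`, or `"co2"`).
#' @examples
#' net <- build_reference_network()
#' sum(net$pools$simulated)           # 18 simulated pools
#' sum(net$reactions$reversible)      # 7 reversible reactions
#' @export
build_reference_network <- function() {
  pools <- tibble::tribble(
    ~id,       ~metabolite, ~compartment, ~carbons, ~simulated, ~role,
    "3PGA",    "3PGA",      "unassigned", 3L, TRUE,  "state",
    "DHAP",    "DHAP",      "unassigned", 3L, TRUE,  "state",
    "FBPpl",   "FBP",       "plastid",    6L, TRUE,  "state",
    "F6Ppl",   "F6P",       "plastid",    6L, TRUE,  "state",
    "G6Ppl",   "G6P",       "plastid",    6L, TRUE,  "state",
    "G1Ppl",   "G1P",       "plastid",    6L, TRUE,  "state",
    "ADPG",    "ADPG",      "plastid",    6L, TRUE,  "state",
    "FBPcyt",  "FBP",       "cytosol",    6L, TRUE,  "state",
    "F6Pcyt",  "F6P",       "cytosol",    6L, TRUE,  "state",
    "G6Pcyt",  "G6P",       "cytosol",    6L, TRUE,  "state",
    "G1Pcyt",  "G1P",       "cytosol",    6L, TRUE,  "state",
    "UDPG",    "UDPG",      "cytosol",    6L, TRUE,  "state",
    "Suc6P",   "Suc6P",     "cytosol",    12L, TRUE, "state",
    "Tre6P",   "Tre6P",     "cytosol",    12L, TRUE, "state",
    "Gly",     "Gly",       "unassigned", 2L, TRUE,  "state",
    "Ser",     "Ser",       "unassigned", 3L, TRUE,  "state",
    "Glyc",    "Glyc",      "unassigned", 3L, TRUE,  "state",
    "2PGA",    "2PGA",      "unassigned", 3L, TRUE,  "state",
    "RuBP",    "RuBP",      "plastid",    5L, FALSE, "input",
    "CO2",     "CO2",       "unassigned", 1L, FALSE, "input",
    "starch",  "starch",    "plastid",    6L, FALSE, "sink",
    "sucrose", "sucrose",   "cytosol",    12L, FALSE, "sink",
    "trehalose", "trehalose", "cytosol",  12L, FALSE, "sink",
    "CBCregen", "CBCregen", "plastid",    15L, FALSE, "sink"
  )

  h <- function(w, f) list(w = w, f = f)
  rxn <- function(id, sub, prod, hrules, reversible = FALSE, release = 0) {
    tibble::tibble(
      id = id, reversible = reversible, release = release,
      sub = list(sub), prod = list(prod), hrules = list(hrules)
    )
  }

  reactions <- dplyr::bind_rows(
    # RuBisCO carboxylation: RuBP + CO2 -> 2x 3PGA.  One product molecule is
    # the C1-C3 fragment of RuBP (unlabeled with probability y3); the other
    # carries the newly fixed CO2 and is labeled from time zero.
    rxn("rbc", c(RuBP = 5, CO2 = 1), c(`3PGA` = 6),
        list(`3PGA` = list(h(0.5, "y3"), h(0.5, c("y2", "co2"))))),
    # RuBisCO oxygenation: RuBP -> 3PGA + 2C glycolate unit -> Gly
    rxn("ox", c(RuBP = 5), c(`3PGA` = 3, Gly = 2),
        list(`3PGA` = list(h(1, "y3")), Gly = list(h(1, "y2")))),
    # glycine decarboxylase + SHMT: 2 Gly -> Ser + CO2 released
    rxn("gly_ser", c(Gly = 4), c(Ser = 3),
        list(Ser = list(h(1, c("Gly", "Gly")))), release = 1),
    rxn("ser_glyc", c(Ser = 3), c(Glyc = 3),
        list(Glyc = list(h(1, "Ser"))), reversible = TRUE),
    rxn("glyc_pga", c(Glyc = 3), c(`3PGA` = 3),
        list(`3PGA` = list(h(1, "Glyc")))),
    rxn("pga_dhap", c(`3PGA` = 3), c(DHAP = 3),
        list(DHAP = list(h(1, "3PGA"))), reversible = TRUE),
    # aldolase condensations draw both trioses from the simulated DHAP pool
    rxn("fbp_pl", c(DHAP = 6), c(FBPpl = 6),
        list(FBPpl = list(h(1, c("DHAP", "DHAP"))))),
    rxn("fbpase_pl", c(FBPpl = 6), c(F6Ppl = 6),
        list(F6Ppl = list(h(1, "FBPpl")))),
    rxn("pgi_pl", c(F6Ppl = 6), c(G6Ppl = 6),
        list(G6Ppl = list(h(1, "F6Ppl")))),
    rxn("pgm_pl", c(G6Ppl = 6), c(G1Ppl = 6),
        list(G1Ppl = list(h(1, "G6Ppl"))), reversible = TRUE),
    rxn("agpase", c(G1Ppl = 6), c(ADPG = 6),
        list(ADPG = list(h(1, "G1Ppl")))),
    rxn("starch_syn", c(ADPG = 6), c(starch = 6),
        list(starch = list(h(1, "ADPG")))),
    rxn("fbp_cyt", c(DHAP = 6), c(FBPcyt = 6),
        list(FBPcyt = list(h(1, c("DHAP", "DHAP"))))),
    rxn("fbpase_cyt", c(FBPcyt = 6), c(F6Pcyt = 6),
        list(F6Pcyt = list(h(1, "FBPcyt")))),
    rxn("pgi_cyt", c(F6Pcyt = 6), c(G6Pcyt = 6),
        list(G6Pcyt = list(h(1, "F6Pcyt"))), reversible = TRUE),
    rxn("pgm_cyt", c(G6Pcyt = 6), c(G1Pcyt = 6),
        list(G1Pcyt = list(h(1, "G6Pcyt"))), reversible = TRUE),
    rxn("ugpase", c(G1Pcyt = 6), c(UDPG = 6),
        list(UDPG = list(h(1, "G1Pcyt"))), reversible = TRUE),
    rxn("sps", c(UDPG = 6, F6Pcyt = 6), c(Suc6P = 12),
        list(Suc6P = list(h(1, c("UDPG", "F6Pcyt"))))),
    rxn("spp", c(Suc6P = 12), c(sucrose = 12),
        list(sucrose = list(h(1, "Suc6P")))),
    rxn("tps", c(UDPG = 6, G6Pcyt = 6), c(Tre6P = 12),
        list(Tre6P = list(h(1, c("UDPG", "G6Pcyt"))))),
    rxn("tpp", c(Tre6P = 12), c(trehalose = 12),
        list(trehalose = list(h(1, "Tre6P")))),
    # dead-end exchange appendage: 2PGA only communicates with 3PGA
    rxn("pga_2pga", c(`3PGA` = 3), c(`2PGA` = 3),
        list(`2PGA` = list(h(1, "3PGA"))), reversible = TRUE),
    # regeneration of RuBP by the condensed Calvin-Benson cycle:
    # 5 x 3PGA (15 C) -> 3 x RuBP (15 C)
    rxn("cbc_regen", c(`3PGA` = 15), c(RuBP = 15),
        list(RuBP = list(h(1, "3PGA"))))
  )

  net <- structure(list(pools = pools, reactions = reactions),
                   class = "mfa_network")
  audit_network(net)
  net
}

#' Audit a metabolic network definition
#'
#' Checks carbon balance of every reaction (after accounting for CO2
#' release), uniqueness of pool ids, and that every unlabeled-production
#' rule only references simulated pools, RuBP cumomer inputs or CO2.
#'
#' @param network An `mfa_network`.
#' @return The network, invisibly; errors describe the first violation.
#' @export
audit_network <- function(network) {
  pools <- network$pools
  if (anyDuplicated(pools$id) > 0) {
    stop("duplicate pool ids in network")
  }
  valid_factors <- c(pools$id[pools$simulated], paste0("y", 1:5), "co2")
  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions[i, ]
    c_in <- sum(r$sub[[1]])
    c_out <- sum(r$prod[[1]]) + r$release
    if (abs(c_in - c_out) > 1e-9) {
      stop(sprintf("reaction '%s' is not carbon balanced (%g in, %g out)",
                   r$id, c_in, c_out))
    }
    unknown <- setdiff(c(names(r$sub[[1]]), names(r$prod[[1]])), pools$id)
    if (length(unknown)) {
      stop(sprintf("reaction '%s' references unknown pool(s): %s",
                   r$id, paste(unknown, collapse = ", ")))
    }
    for (p in names(r$hrules[[1]])) {
      for (term in r$hrules[[1]][[p]]) {
        bad <- setdiff(term$f, valid_factors)
        if (length(bad)) {
          stop(sprintf(
            "reaction '%s', product '%s': invalid h-rule factor(s): %s",
            r$id, p, paste(bad, collapse = ", ")))
        }
      }
    }
  }
  invisible(network)
}

#' Simulated pools of a network
#'
#' @param network An `mfa_network`.
#' @return Tibble of the simulated (state-variable) pools.
#' @export
simulated_pools <- function(network) {
  dplyr::filter(network$pools, .data$simulated)
}

#' Stoichiometric matrix in carbon-atom units
#'
#' @param network An `mfa_network`.
#' @param species Character vector of pool ids to balance (rows).
#' @param reactions Character vector of reaction ids (columns); defaults to
#'   all reactions.
#' @return Numeric matrix, `species` x `reactions`; entry = C atoms produced
#'   minus C atoms consumed per unit reaction extent.
#' @export
stoich_matrix <- function(network, species, reactions = NULL) {
  rxns <- network$reactions
  if (!is.null(reactions)) {
    rxns <- rxns[match(reactions, rxns$id), ]
  }
  S <- matrix(0, length(species), nrow(rxns),
              dimnames = list(species, rxns$id))
  for (j in seq_len(nrow(rxns))) {
    sub <- rxns$sub[[j]]
    prod <- rxns$prod[[j]]
    for (p in names(sub)) {
      if (p %in% species) S[p, j] <- S[p, j] - sub[[p]]
    }
    for (p in names(prod)) {
      if (p %in% species) S[p, j] <- S[p, j] + prod[[p]]
    }
  }
  S
}

# carbon throughput per unit extent (C atoms delivered to products),
# used to convert between reaction extents and C-atom flux units
reaction_cflux <- function(network) {
  vapply(network$reactions$prod, function(p) sum(p), numeric(1)) |>
    setNames(network$reactions$id)
}
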