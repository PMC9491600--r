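#' Waste species of an SDAS given its motifs
#'
#' Waste species are byproducts: species produced by the reactions of the
#' supplied autocatalytic motifs, internal to the SDAS, but not members of
#' any motif (a member is consumed and regenerated by the motif).
#'
#' @param sdas An `sdas`.
#' @param motifs List of `motif` objects belonging to the SDAS.
#' @param net The `reaction_network` the SDAS lives in.
#' @return Character vector of waste species ids.
#' @export
find_waste <- function(sdas, motifs, net) {
  stopifnot(inherits(sdas, "sdas"))
  rx <- unique(unlist(lapply(motifs, `[[`, "reactions")))
  if (length(setdiff(rx, sdas$reactions)))
    stop("motif reactions outside the SDAS", call. = FALSE)
  produced <- unique(unlist(lapply(net$reactions[rx], function(r)
    names(r$products))))
  members <- unique(unlist(lapply(motifs, `[[`, "members")))
  setdiff(intersect(produced, sdas$species), members)
}

# food species actually consumed by an SDAS's reactions (reactants external
# to the SDAS itself)
consumed_food <- function(sdas, net) {
  cons <- unique(unlist(lapply(net$reactions[sdas$reactions], function(r)
    names(r$reactants))))
  setdiff(cons, sdas$species)
}

consumed_any <- function(sdas, net) {
  unique(unlist(lapply(net$reactions[sdas$reactions], function(r)
    names(r$reactants))))
}

#' Classify the ecological interaction between two SDASs
#'
#' Pairwise inter-SDAS relationships mirror ecological symbioses:
#' \describe{
#'   \item{competition}{both SDASs consume a common food species (external
#'     to each).}
#'   \item{predation-parasitism}{the higher SDAS consumes a member species
#'     of an autocatalytic motif of the lower SDAS.}
#'   \item{mutualism}{the higher SDAS consumes a waste species of the lower
#'     SDAS's motifs.}
#'   \item{catalytic-facilitation}{a species of the higher SDAS is consumed
#'     by one reaction and regenerated by another such that the pair's net
#'     conversion duplicates a single lower-SDAS reaction — a candidate
#'     composite catalytic path (no rate comparison is attempted).}
#' }
#' Multiple labels may apply simultaneously. When no motifs are supplied,
#' all species of the lower SDAS are conservatively treated as members,
#' which suppresses mutualism labels.
#'
#' @param low The lower-tier `sdas`.
#' @param high The higher-tier `sdas`.
#' @param net The `reaction_network` both live in.
#' @param low_motifs Optional list of `motif`s for the lower SDAS.
#' @return A list of class `interaction_report`: `pair`, `labels`
#'   (character subset of the four above), and `evidence` (per-label
#'   species/reaction witnesses).
#' @export
classify_interaction <- function(low, high, net, low_motifs = NULL) {
  stopifnot(inherits(low, "sdas"), inherits(high, "sdas"))
  if (is.null(low_motifs) || length(low_motifs) == 0L) {
    members <- low$species
    waste <- character(0)
  } else {
    members <- unique(unlist(lapply(low_motifs, `[[`, "members")))
    waste <- find_waste(low, low_motifs, net)
  }
  high_cons <- consumed_any(high, net)
  labels <- character(0)
  evidence <- list()

  shared_food <- intersect(consumed_food(low, net), consumed_food(high, net))
  if (length(shared_food)) {
    labels <- c(labels, "competition")
    evidence$competition <- shared_food
  }
  prey <- intersect(high_cons, members)
  if (length(prey)) {
    labels <- c(labels, "predation-parasitism")
    evidence$`predation-parasitism` <- prey
  }
  fed_waste <- intersect(high_cons, waste)
  if (length(fed_waste)) {
    labels <- c(labels, "mutualism")
    evidence$mutualism <- fed_waste
  }
  facil <- facilitation_paths(low, high, net)
  if (length(facil)) {
    labels <- c(labels, "catalytic-facilitation")
    evidence$`catalytic-facilitation` <- facil
  }
  structure(list(pair = c(low = low$id, high = high$id), labels = labels,
                 evidence = evidence),
            class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat(sprintf("<interaction %s -> %s: %s>\n", x$pair[["low"]],
              x$pair[["high"]],
              if (length(x$labels)) paste(x$labels, collapse = ", ")
              else "none"))
  invisible(x)
}

# candidate composite catalytic paths: a higher-SDAS species c consumed by
# reaction r1 and regenerated by r2 such that net(r1) + net(r2) equals the
# net of a single reaction of the lower SDAS
facilitation_paths <- function(low, high, net, max_pairs = 20000L) {
  low_nets <- lapply(net$reactions[low$reactions], reaction_net)
  out <- list()
  tried <- 0L
  for (cand in high$species) {
    uses <- names(Filter(function(r) cand %in% names(r$reactants),
                         net$reactions))
    makes <- names(Filter(function(r) cand %in% names(r$products),
                          net$reactions))
    for (r1 in uses) for (r2 in setdiff(makes, r1)) {
      tried <- tried + 1L
      if (tried > max_pairs) return(out)
      comb <- add_nets(reaction_net(net$reactions[[r1]]),
                       reaction_net(net$reactions[[r2]]))
      hit <- names(low_nets)[vapply(low_nets, function(v)
        same_net(comb, v), logical(1))]
      if (length(hit))
        out[[length(out) + 1L]] <- list(catalyst = cand,
                                        path = c(r1, r2),
                                        replaces = hit)
    }
  }
  out
}

reaction_net <- function(r) {
  ids <- union(names(r$reactants), names(r$products))
  v <- stats::setNames(numeric(length(ids)), ids)
  v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
  v[names(r$products)] <- v[names(r$products)] + r$products
  v[abs(v) > 1e-9]
}

add_nets <- function(a, b) {
  ids <- union(names(a), names(b))
  v <- stats::setNames(numeric(length(ids)), ids)
  v[names(a)] <- v[names(a)] + a
  v[names(b)] <- v[names(b)] + b
  v[abs(v) > 1e-9]
}

same_net <- function(a, b) {
  ids <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(ids)), ids); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(ids)), ids); bv[names(b)] <- b
  all(abs(av - bv) < 1e-9)
}

#' Re-test a seed after reaction removal (scaffolding/ablation)
#'
#' Deletes the given reactions, recomputes the food closure and the
#' seed-induced partition, and re-runs the linear-programming certification.
#' Used to test scaffolding: a lower-tier structure needed to activate, but
#' not to maintain, a higher-tier one.
#'
#' @param net A `reaction_network`.
#' @param food Character vector of food species ids (expanded to a closure
#'   after removal).
#' @param seed Character vector of seed species.
#' @param removed_reactions Reaction ids to delete (must exist in `net`).
#' @return A list: `feasible`, `lp` (`lp_result`, or `NULL` when the seed
#'   induces nothing), `sdas` (the induced `sdas` when feasible), and
#'   `removed`.
#' @export
robustness_to_removal <- function(net, food, seed,
                                  removed_reactions = character()) {
  net2 <- if (length(removed_reactions))
    drop_reactions(net, removed_reactions) else net
  fc <- network_expand(net2, intersect(food, species_ids(net2)))
  if (all(seed %in% fc$species))
    return(list(feasible = FALSE, lp = NULL, sdas = NULL,
                removed = removed_reactions,
                note = "seed already in the food closure"))
  rec <- detect_seed(net2, fc, seed)
  list(feasible = !is.null(rec$sdas), lp = rec$lp, sdas = rec$sdas,
       removed = removed_reactions)
}
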