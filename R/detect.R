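#' Partition a seed-induced subnetwork into a stoichiometric matrix
#'
#' Expands the food closure together with a candidate seed and builds the
#' partitioned matrix in which the food species/reactions are external and
#' the newly induced species/reactions internal. The internal subnetwork
#' `(S1, R1)` is the closure of food-plus-seed minus the food closure.
#'
#' @param net A `reaction_network`.
#' @param food_closure A `closure` from [tier0()] or [network_expand()]
#'   giving the external food system.
#' @param seed Character vector of candidate seed species (disjoint from the
#'   food closure).
#' @return A `stoich_matrix`; its attribute `"closure"` carries the
#'   food-plus-seed closure used to build it.
#' @export
internal_partition <- function(net, food_closure, seed) {
  stopifnot(inherits(net, "reaction_network"), inherits(food_closure, "closure"))
  seed <- unique(as.character(seed))
  if (length(seed) == 0L) stop("empty seed", call. = FALSE)
  if (all(seed %in% food_closure$species))
    stop("seed is food: ", paste(seed, collapse = ", "), call. = FALSE)
  cl <- network_expand(net, union(food_closure$species, seed))
  M <- build_stoich_matrix(
    net,
    external_species = intersect(cl$species, food_closure$species),
    external_reactions = intersect(cl$reactions, food_closure$reactions),
    species = cl$species, reactions = cl$reactions)
  attr(M, "closure") <- cl
  M
}

new_seed_set <- function(members, kind = c("singleton", "composite"),
                         support = c("supported", "unsupported", "not-a-seed")) {
  structure(list(members = as.character(members),
                 kind = match.arg(kind), support = match.arg(support)),
            class = "seed_set")
}

new_sdas <- function(species, reactions, tier, food, seeds, certificate,
                     id = NA_character_) {
  structure(list(id = id, species = species, reactions = reactions,
                 tier = tier, food = food, seeds = seeds,
                 certificate = certificate),
            class = "sdas")
}

#' @export
print.sdas <- function(x, ...) {
  cat(sprintf("<SDAS%s: tier %s, %d species, %d reactions, %d known seed(s)>\n",
              if (is.na(x$id)) "" else paste0(" ", x$id), x$tier,
              length(x$species), length(x$reactions), length(x$seeds)))
  invisible(x)
}

# run the full detection for one candidate seed over a food closure;
# returns list(seed_set, sdas (or NULL), lp, fingerprint)
detect_seed <- function(net, food_closure, seed, tier = 1L) {
  M <- internal_partition(net, food_closure, seed)
  cl <- attr(M, "closure")
  kind <- if (length(seed) > 1L) "composite" else "singleton"
  if (M$n < M$q) {                      # no induced reactions
    return(list(seed = new_seed_set(seed, kind, "not-a-seed"), sdas = NULL,
                lp = NULL,
                fingerprint = closure_fingerprint(cl$species, cl$reactions)))
  }
  lp <- is_autocatalytic(M)
  if (lp$feasible) {
    sd <- new_sdas(species = internal_species(M),
                   reactions = internal_reactions(M),
                   tier = tier, food = food_closure$species,
                   seeds = list(new_seed_set(seed, kind, "supported")),
                   certificate = lp)
    list(seed = new_seed_set(seed, kind, "supported"), sdas = sd, lp = lp,
         fingerprint = closure_fingerprint(cl$species, cl$reactions))
  } else {
    list(seed = new_seed_set(seed, kind, "not-a-seed"), sdas = NULL, lp = lp,
         fingerprint = closure_fingerprint(cl$species, cl$reactions))
  }
}

#' Scan singleton candidate seeds for supported seeds
#'
#' Each candidate is expanded together with the food, the induced internal
#' subnetwork is partitioned, and stoichiometric autocatalysis is certified
#' by linear programming. Candidates inducing identical closures share one
#' cached LP verdict, so results are independent of candidate order.
#'
#' @param net A `reaction_network`.
#' @param food_closure The external food system (a `closure`).
#' @param candidates Candidate species ids; defaults to all non-food species
#'   of the network. Must be disjoint from the food closure.
#' @param tier Tier index recorded on detected SDASs.
#' @return A list with one record per candidate: `seed` (a `seed_set` with
#'   support `"supported"` or `"not-a-seed"`), `sdas` (or `NULL`), and the
#'   closure `fingerprint`.
#' @export
scan_singleton_seeds <- function(net, food_closure, candidates = NULL,
                                 tier = 1L) {
  stopifnot(inherits(net, "reaction_network"), inherits(food_closure, "closure"))
  if (is.null(candidates))
    candidates <- setdiff(species_ids(net), food_closure$species)
  if (any(candidates %in% food_closure$species))
    stop("candidates must be disjoint from the food closure", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  out <- vector("list", length(candidates))
  names(out) <- candidates
  for (cd in candidates) {
    cl <- network_expand(net, union(food_closure$species, cd))
    fp <- closure_fingerprint(cl$species, cl$reactions)
    hit <- get0(fp, envir = cache, ifnotfound = NULL)
    if (is.null(hit)) {
      hit <- detect_seed(net, food_closure, cd, tier = tier)
      assign(fp, hit, envir = cache)
    }
    rec <- hit
    rec$seed <- new_seed_set(cd, "singleton", hit$seed$support)
    if (!is.null(rec$sdas)) rec$sdas$seeds <- list(rec$seed)
    out[[cd]] <- rec
  }
  out
}

#' Search species pairs for composite supported seeds
#'
#' A composite seed must jointly induce an autocatalytic subnetwork while
#' being minimal: no proper subset may itself be a seed. By default the
#' search is restricted to pairs of candidates that individually failed the
#' singleton scan; pairs containing a singleton seed are rejected as
#' non-minimal.
#'
#' @param net A `reaction_network`.
#' @param food_closure The external food system.
#' @param pairs Optional list of character pairs; defaults to all pairs of
#'   non-food species that are not singleton seeds.
#' @param singleton_scan Optional result of [scan_singleton_seeds()] reused
#'   for the minimality check (recomputed if missing).
#' @param tier Tier index recorded on detected SDASs.
#' @return A list of records (`seed`, `sdas`, `fingerprint`) for the pairs
#'   certified as composite supported seeds.
#' @export
find_composite_seeds <- function(net, food_closure, pairs = NULL,
                                 singleton_scan = NULL, tier = 1L) {
  stopifnot(inherits(net, "reaction_network"), inherits(food_closure, "closure"))
  if (is.null(singleton_scan))
    singleton_scan <- scan_singleton_seeds(net, food_closure, tier = tier)
  is_seed <- vapply(singleton_scan, function(r)
    identical(r$seed$support, "supported"), logical(1))
  failed <- names(singleton_scan)[!is_seed]
  if (is.null(pairs)) {
    if (length(failed) < 2L) return(list())
    pairs <- utils::combn(sort(failed), 2L, simplify = FALSE)
  }
  out <- list()
  for (pr in pairs) {
    pr <- unique(as.character(pr))
    if (length(pr) != 2L) next
    if (any(pr %in% food_closure$species)) next
    # minimality: neither member may be a singleton seed on its own
    known <- pr %in% names(singleton_scan)
    single_ok <- vapply(pr, function(sp) {
      if (sp %in% names(singleton_scan))
        !identical(singleton_scan[[sp]]$seed$support, "supported")
      else
        !identical(detect_seed(net, food_closure, sp, tier)$seed$support,
                   "supported")
    }, logical(1))
    if (!all(single_ok)) next
    rec <- detect_seed(net, food_closure, pr, tier = tier)
    if (identical(rec$seed$support, "supported")) out[[length(out) + 1L]] <- rec
  }
  out
}

#' Group supported seeds into cliques
#'
#' Two supported seeds are in the same clique when their food-plus-seed
#' closures are identical, i.e. they induce the same SDAS. Grouping is by
#' exact equality of the closure fingerprint (sorted-id hash).
#'
#' @param scan Result of [scan_singleton_seeds()] (optionally concatenated
#'   with [find_composite_seeds()] output).
#' @return A list of cliques: each has `seeds` (list of `seed_set`s),
#'   `members` (ids of the singleton seeds), and `sdas` (the shared SDAS,
#'   with all member seeds attached).
#' @export
group_cliques <- function(scan) {
  sup <- Filter(function(r) identical(r$seed$support, "supported"), scan)
  if (length(sup) == 0L) return(list())
  fps <- vapply(sup, `[[`, character(1), "fingerprint")
  out <- lapply(split(sup, fps), function(grp) {
    seeds <- lapply(grp, `[[`, "seed")
    sd <- grp[[1]]$sdas
    sd$seeds <- seeds
    singles <- unlist(lapply(seeds, function(s)
      if (s$kind == "singleton") s$members else character()))
    list(seeds = seeds, members = sort(unique(singles)), sdas = sd)
  })
  names(out) <- NULL
  out[order(vapply(out, function(cl) -length(cl$members), numeric(1)),
            vapply(out, function(cl) paste(cl$members, collapse = ","),
                   character(1)))]
}

#' Classify unsupported seeds against known SDASs
#'
#' A species `X` (not food, not a supported seed) is an unsupported seed of
#' SDAS `Y` when `X` is not among `Y`'s species yet expanding food plus `X`
#' fires every reaction of `Y`. When several nested SDASs qualify, `X` is
#' assigned to the maximal one by reaction-set inclusion.
#'
#' @param net A `reaction_network`.
#' @param food_closure The external food system the SDASs were detected over.
#' @param known_sdass List of `sdas` objects.
#' @param candidates Candidate species ids (non-food, non-supported-seed).
#' @return A named list mapping each qualifying candidate to the `sdas` it
#'   is an unsupported seed for; non-qualifying candidates are omitted.
#' @export
classify_unsupported_seeds <- function(net, food_closure, known_sdass,
                                       candidates) {
  stopifnot(inherits(food_closure, "closure"))
  out <- list()
  for (cd in candidates) {
    if (cd %in% food_closure$species) next
    cl <- network_expand(net, union(food_closure$species, cd))
    hits <- Filter(function(sd) {
      !(cd %in% sd$species) && all(sd$reactions %in% cl$reactions)
    }, known_sdass)
    if (length(hits) == 0L) next
    nr <- vapply(hits, function(sd) length(sd$reactions), integer(1))
    out[[cd]] <- hits[[which.max(nr)]]
  }
  out
}

#' Build the trophic hierarchy of SDASs
#'
#' Computes the tier-0 food closure, then repeatedly scans singleton
#' candidates over the current food, certifies SDASs, and (by default)
#' activates all detected SDASs so that their species become food for the
#' next tier. Stops when a scan finds no seeds or `max_tier` is reached.
#'
#' @param net A `reaction_network`.
#' @param ultimate_food Character vector of ultimate food species ids.
#' @param whitelist Always-available species merged into the food.
#' @param max_tier Maximum tier index to scan (default 3).
#' @param pairs Optional list of species pairs to test as composite seeds at
#'   tier 1.
#' @return A list of class `sdas_tiers`: element `tier0` (the food
#'   `closure`) and `tiers`, a list with one record per detected tier:
#'   `tier`, `scan`, `cliques`, `sdass` (SDASs labelled
#'   `"sdas-t<tier>-<k>"`), and `food_closure` used at that tier.
#' @export
build_tiers <- function(net, ultimate_food, whitelist = character(),
                        max_tier = 3L, pairs = NULL) {
  t0 <- tier0(net, ultimate_food, whitelist)
  food <- t0
  tiers <- list()
  for (t in seq_len(max_tier)) {
    candidates <- setdiff(species_ids(net), food$species)
    if (length(candidates) == 0L) break
    scan <- scan_singleton_seeds(net, food, candidates, tier = t)
    if (t == 1L && !is.null(pairs))
      scan <- c(scan, find_composite_seeds(net, food, pairs = pairs,
                                           singleton_scan = scan, tier = t))
    cliques <- group_cliques(scan)
    if (length(cliques) == 0L) break
    sdass <- lapply(seq_along(cliques), function(k) {
      sd <- cliques[[k]]$sdas
      sd$id <- sprintf("sdas-t%d-%d", t, k)
      sd
    })
    tiers[[length(tiers) + 1L]] <-
      list(tier = t, scan = scan, cliques = cliques, sdass = sdass,
           food_closure = food)
    activated <- unique(unlist(lapply(sdass, `[[`, "species")))
    food <- network_expand(net, union(food$species, activated))
  }
  structure(list(tier0 = t0, tiers = tiers), class = "sdas_tiers")
}

#' @export
print.sdas_tiers <- function(x, ...) {
  cat(sprintf("<sdas_tiers: tier-0 %d species / %d reactions; %d seeded tier(s)>\n",
              length(x$tier0$species), length(x$tier0$reactions),
              length(x$tiers)))
  for (tr in x$tiers)
    cat(sprintf("  tier %d: %d clique(s), %d SDAS(s)\n", tr$tier,
                length(tr$cliques), length(tr$sdass)))
  invisible(x)
}
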