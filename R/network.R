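#' Assemble a reaction network
#'
#' A network is a set of species and a set of unidirectional reactions. The
#' species set is the union of every id referenced by a reaction (reactant,
#' product, or catalyst) plus any declared extra species (e.g. food that no
#' reaction touches). Species metadata (name, formula, mass, pseudo-species
#' flag) is optional; energy carriers such as visible light are ordinary
#' species with `is_pseudo = TRUE` and no mass.
#'
#' @param reactions List of `sdas_reaction` objects (unique ids). Reversible
#'   reactions are split with [split_reversible()] when `split = TRUE`.
#' @param species Optional data frame with columns among
#'   `id`, `name`, `formula`, `mass`, `is_pseudo`; rows for species not
#'   referenced by any reaction declare extra species.
#' @param split Split reversible reactions into `.a`/`.b` halves
#'   (default `TRUE`).
#' @return An object of class `reaction_network` with elements `species`
#'   (data frame) and `reactions` (named list).
#' @export
reaction_network <- function(reactions, species = NULL, split = TRUE) {
  stopifnot(is.list(reactions))
  if (length(reactions) && !all(vapply(reactions, inherits, logical(1), "sdas_reaction")))
    stop("all elements of 'reactions' must be sdas_reaction objects", call. = FALSE)
  if (split) {
    reactions <- unlist(lapply(reactions, function(r) {
      if (isTRUE(r$reversible)) split_reversible(r) else list(r)
    }), recursive = FALSE)
    if (is.null(reactions)) reactions <- list()
  } else if (any(vapply(reactions, function(r) isTRUE(r$reversible), logical(1)))) {
    stop("network contains unsplit reversible reactions; use split = TRUE",
         call. = FALSE)
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(reactions) <- ids

  referenced <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products), r$catalysts))))
  declared <- if (is.null(species)) character() else as.character(species$id)
  all_ids <- union(referenced, declared)

  k <- length(all_ids)
  tbl <- data.frame(id = all_ids, name = all_ids,
                    formula = rep(NA_character_, k),
                    mass = rep(NA_real_, k), is_pseudo = rep(FALSE, k),
                    stringsAsFactors = FALSE)
  if (!is.null(species)) {
    i <- match(species$id, tbl$id)
    for (col in intersect(c("name", "formula", "mass", "is_pseudo"),
                          names(species)))
      tbl[[col]][i] <- species[[col]]
  }
  if (any(!is.na(tbl$mass) & tbl$mass < 0))
    stop("species mass must be non-negative", call. = FALSE)
  rownames(tbl) <- NULL
  structure(list(species = tbl, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %d species, %d reactions>\n",
              nrow(x$species), length(x$reactions)))
  invisible(x)
}

#' Species ids of a network
#' @param net A `reaction_network`.
#' @return Character vector of species ids.
#' @export
species_ids <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  net$species$id
}

#' Reaction ids of a network
#' @param net A `reaction_network`.
#' @return Character vector of reaction ids.
#' @export
reaction_ids <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  names(net$reactions)
}

#' Remove reactions from a network
#'
#' Used by ablation analyses; species are kept (a removed reaction's species
#' may still be declared food elsewhere).
#'
#' @param net A `reaction_network`.
#' @param ids Reaction ids to delete; unknown ids are an error.
#' @return The reduced `reaction_network`.
#' @export
drop_reactions <- function(net, ids) {
  stopifnot(inherits(net, "reaction_network"))
  missing <- setdiff(ids, reaction_ids(net))
  if (length(missing))
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  net$reactions <- net$reactions[setdiff(reaction_ids(net), ids)]
  net
}

#' Merge an always-available catalyst whitelist into a food set
#'
#' Freely available environmental catalysts (e.g. metals and minerals) are
#' modelled as species appended to every food set before expansion and
#' detection.
#'
#' @param food Character vector of food species ids.
#' @param whitelist Character vector of always-available species ids.
#' @return The union, in stable order.
#' @export
with_whitelist <- function(food, whitelist = character()) {
  union(as.character(food), as.character(whitelist))
}
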