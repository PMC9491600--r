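#' Catalyst-aware network expansion
#'
#' Iteratively adds every reaction whose reactants *and* catalysts are all
#' available, then adds its products, until a fixpoint is reached. The
#' fixpoint is unique and independent of the order in which reactions are
#' examined; coefficients are irrelevant (presence/absence semantics).
#' Catalysts gate firing exactly like reactants but are never added as
#' products of the gated reaction.
#'
#' The implementation keeps, for each reaction, a count of its unmet
#' requirements and a reverse index from species to the reactions that
#' require them, so a full-database closure costs time near-linear in total
#' reaction arity.
#'
#' @param net A `reaction_network`.
#' @param start Character vector of starting species ids (must exist in the
#'   network universe).
#' @param reactions Optional subset of reaction ids to expand over
#'   (defaults to all).
#' @return An object of class `closure`: a list with `start_species`,
#'   `species`, `reactions` (ids, in order of addition), and `generation`
#'   (named integer vector; iteration at which each reaction fired,
#'   provenance only).
#' @examples
#' net <- reaction_network(list(parse_reaction("A + F -> 2 A", id = "R1")))
#' network_expand(net, "F")           # seed absent: nothing fires
#' network_expand(net, c("F", "A"))   # fixpoint contains R1
#' @export
network_expand <- function(net, start, reactions = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  start <- unique(as.character(start))
  unknown <- setdiff(start, species_ids(net))
  if (length(unknown))
    stop("unknown starting species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(reactions)) reactions <- reaction_ids(net)
  rs <- net$reactions[reactions]

  needs <- lapply(rs, function(r) unique(c(names(r$reactants), r$catalysts)))
  n_unmet <- lengths(needs)
  # reverse index: species id -> indices of reactions requiring it
  by_sp <- new.env(parent = emptyenv())
  for (i in seq_along(needs)) for (sp in needs[[i]]) {
    assign(sp, c(get0(sp, envir = by_sp, ifnotfound = integer()), i),
           envir = by_sp)
  }
  avail <- new.env(parent = emptyenv())
  fired <- logical(length(rs))
  gen <- integer(0)
  added <- character(0)
  frontier <- start
  for (sp in start) assign(sp, TRUE, envir = avail)
  iter <- 0L
  # zero-requirement reactions (none in practice) fire in generation 1
  ready <- which(n_unmet == 0L)

  repeat {
    iter <- iter + 1L
    for (sp in frontier) {
      for (i in get0(sp, envir = by_sp, ifnotfound = integer())) {
        n_unmet[i] <- n_unmet[i] - 1L
        if (n_unmet[i] == 0L) ready <- c(ready, i)
      }
    }
    if (length(ready) == 0L) break
    new_sp <- character(0)
    for (i in ready) {
      if (fired[i]) next
      fired[i] <- TRUE
      added <- c(added, names(rs)[i])
      gen[names(rs)[i]] <- iter
      prods <- names(rs[[i]]$products)
      for (sp in prods) {
        if (is.null(get0(sp, envir = avail, ifnotfound = NULL))) {
          assign(sp, TRUE, envir = avail)
          new_sp <- c(new_sp, sp)
        }
      }
    }
    ready <- integer(0)
    if (length(new_sp) == 0L) break
    frontier <- new_sp
  }
  structure(list(start_species = start,
                 species = union(start, ls(avail)),
                 reactions = added,
                 generation = gen),
            class = "closure")
}

#' @export
print.closure <- function(x, ...) {
  cat(sprintf("<closure: %d species (%d starting), %d reactions>\n",
              length(x$species), length(x$start_species),
              length(x$reactions)))
  invisible(x)
}

#' Tier-0 food closure
#'
#' Expands the ultimate food set: everything reachable without any seed.
#' The result is the external food system against which tier-1 seeds are
#' scanned.
#'
#' @param net A `reaction_network`.
#' @param ultimate_food Character vector of ultimate food species ids.
#' @param whitelist Always-available species (e.g. environmental catalysts)
#'   merged into the food before expansion.
#' @return A `closure` with attribute `tier = 0`.
#' @export
tier0 <- function(net, ultimate_food, whitelist = character()) {
  cl <- network_expand(net, with_whitelist(ultimate_food, whitelist))
  attr(cl, "tier") <- 0L
  cl
}

closure_fingerprint <- function(species, reactions) {
  paste(paste(sort(species), collapse = "\001"),
        paste(sort(reactions), collapse = "\001"), sep = "\002")
}
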