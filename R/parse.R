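#' Construct a unidirectional (or reversible, pre-split) reaction
#'
#' A reaction transforms a multiset of reactant species into a multiset of
#' product species, optionally requiring explicit catalysts. Catalysts are
#' required for the reaction to fire but are not consumed: in the
#' stoichiometric matrix they contribute a zero entry, and the dependence is
#' recorded separately. A species listed with equal coefficients on both
#' sides is normalised into the catalyst set; unequal coefficients keep only
#' the net difference on the appropriate side.
#'
#' @param id Unique reaction identifier (non-empty string).
#' @param reactants Named numeric vector of strictly positive coefficients
#'   (names are species ids).
#' @param products Named numeric vector of strictly positive coefficients.
#' @param catalysts Character vector of species ids required but not consumed.
#' @param reversible Logical; reversible reactions must be split with
#'   [split_reversible()] before analysis.
#' @param origin Optional source-database annotation.
#' @param tol Coefficients closer to zero than `tol` are rejected.
#' @return An object of class `sdas_reaction`.
#' @seealso [parse_reaction()], [split_reversible()]
#' @export
reaction <- function(id, reactants, products, catalysts = character(),
                     reversible = FALSE, origin = NA_character_, tol = 1e-9) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("reaction id must be a non-empty string", call. = FALSE)
  reactants <- collapse_coefs(reactants)
  products <- collapse_coefs(products)
  if (any(reactants <= tol) || any(products <= tol))
    stop(sprintf("reaction '%s': coefficients must be strictly positive", id),
         call. = FALSE)
  catalysts <- unique(as.character(catalysts))

  # a species with equal coefficients on both sides is explicit catalysis:
  # required, regenerated, net entry zero. Unequal coefficients stay as
  # written (A + F -> 2A keeps A as a required reactant; the matrix builder
  # nets them to +1), since expansion must demand the species' presence.
  both <- intersect(names(reactants), names(products))
  for (sp in both) {
    d <- products[[sp]] - reactants[[sp]]
    if (abs(d) <= tol) {
      catalysts <- union(catalysts, sp)
      reactants <- reactants[names(reactants) != sp]
      products <- products[names(products) != sp]
    }
  }
  if (length(reactants) == 0L || length(products) == 0L)
    stop(sprintf("reaction '%s': no net transformation (empty %s side)", id,
                 if (length(reactants) == 0L) "reactant" else "product"),
         call. = FALSE)
  if (any(catalysts %in% names(reactants)))
    stop(sprintf("reaction '%s': a catalyst may not be consumed", id),
         call. = FALSE)

  structure(
    list(id = id, reactants = reactants, products = products,
         catalysts = catalysts, reversible = isTRUE(reversible),
         origin = origin),
    class = "sdas_reaction"
  )
}

collapse_coefs <- function(x) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("coefficient vectors must be named by species id", call. = FALSE)
  ids <- unique(names(x))
  sums <- vapply(ids, function(s) sum(x[names(x) == s]), numeric(1))
  stats::setNames(as.numeric(sums), ids)
}

#' @export
print.sdas_reaction <- function(x, ...) {
  cat(sprintf("<reaction %s%s> %s\n", x$id,
              if (x$reversible) ", reversible" else "",
              format_reaction(x)))
  invisible(x)
}

#' Render a reaction back to its plain-text equation
#'
#' @param r An `sdas_reaction`.
#' @return A single equation string in the grammar accepted by
#'   [parse_reaction()]; parsing it recovers the reaction.
#' @export
format_reaction <- function(r) {
  side <- function(v) paste(
    ifelse(abs(v - 1) < 1e-12, names(v), paste(fmt_num(v), names(v))),
    collapse = " + ")
  eq <- paste(side(r$reactants), if (r$reversible) "<=>" else "->",
              side(r$products))
  if (length(r$catalysts)) eq <- paste0(eq, " | cat: ",
                                        paste(r$catalysts, collapse = ", "))
  eq
}

fmt_num <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x)), format(x))
}

#' Parse a plain-text reaction equation
#'
#' Accepts the grammar
#' `<coef?> <species> (+ ...) (-> | <=>) <coef?> <species> (+ ...)
#' [| cat: <species>, ...]` with coefficients defaulting to 1. Species ids
#' are the literal tokens; no chemical interpretation is attempted.
#'
#' @param text One equation string, e.g. `"A + F -> 2 A"`.
#' @param id Reaction identifier to assign (default `"r1"`).
#' @param origin Optional source annotation.
#' @return An `sdas_reaction`; the reversible flag is set for `<=>`.
#' @examples
#' parse_reaction("A + F -> 2 A")
#' parse_reaction("B + C <=> A")
#' parse_reaction("F -> A | cat: U")
#' @export
parse_reaction <- function(text, id = "r1", origin = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  catalysts <- character()
  if (grepl("|", text, fixed = TRUE)) {
    parts <- strsplit(text, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed catalyst annotation in: ", raw, call. = FALSE)
    text <- parts[1]
    cat_part <- sub("^\\s*cat\\s*:", "", parts[2])
    if (identical(cat_part, parts[2]))
      stop("catalyst annotation must start with 'cat:' in: ", raw, call. = FALSE)
    catalysts <- trimws(strsplit(cat_part, ",", fixed = TRUE)[[1]])
    catalysts <- catalysts[nzchar(catalysts)]
  }
  reversible <- grepl("<=>", text, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L || grepl("->", sides[1], fixed = TRUE) ||
      grepl("->", sides[2], fixed = TRUE))
    stop("malformed arrow in: ", raw, call. = FALSE)
  reaction(id,
           reactants = parse_side(sides[1], raw),
           products = parse_side(sides[2], raw),
           catalysts = catalysts, reversible = reversible, origin = origin)
}

parse_side <- function(side, raw) {
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  if (length(terms) == 0L || any(!nzchar(terms)))
    stop("empty side or term in: ", raw, call. = FALSE)
  coefs <- numeric(0)
  for (term in terms) {
    # a leading number is a coefficient when space-separated ("2 A") or when
    # glued to an uppercase species id in the paper's inline style ("2B");
    # otherwise it belongs to the species name (e.g. "2-oxoglutarate")
    m <- regmatches(term, regexec("^([0-9]+(?:\\.[0-9]+)?)\\s+(\\S.*)$", term))[[1]]
    if (length(m) == 0L)
      m <- regmatches(term, regexec("^([0-9]+)([A-Z].*)$", term))[[1]]
    if (length(m) == 3L) {
      coef <- as.numeric(m[2]); sp <- m[3]
    } else {
      coef <- 1; sp <- term
    }
    if (!nzchar(sp))
      stop("cannot parse term '", term, "' in: ", raw, call. = FALSE)
    if (!is.finite(coef) || coef <= 0)
      stop("non-positive coefficient in term '", term, "' in: ", raw,
           call. = FALSE)
    coefs <- c(coefs, stats::setNames(coef, sp))
  }
  coefs
}

#' Split a reversible reaction into two unidirectional reactions
#'
#' The forward copy keeps the stated direction and gains the suffix `.a`;
#' the reverse copy swaps reactants and products and gains `.b`. Catalysts
#' are preserved on both halves.
#'
#' @param r A reversible `sdas_reaction`.
#' @return A list of two irreversible `sdas_reaction`s, `<id>.a` and `<id>.b`.
#' @export
split_reversible <- function(r) {
  stopifnot(inherits(r, "sdas_reaction"))
  if (!isTRUE(r$reversible))
    stop("split_reversible() called on an irreversible reaction: ", r$id,
         call. = FALSE)
  list(
    reaction(paste0(r$id, ".a"), r$reactants, r$products,
             catalysts = r$catalysts, reversible = FALSE, origin = r$origin),
    reaction(paste0(r$id, ".b"), r$products, r$reactants,
             catalysts = r$catalysts, reversible = FALSE, origin = r$origin)
  )
}
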