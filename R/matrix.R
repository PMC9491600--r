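#' Build the partitioned stoichiometric matrix
#'
#' Rows are species, columns are reactions, entries are net coefficients
#' (products minus reactants); catalysts contribute exactly zero but are
#' recorded per column in `catalyst_requirements`. The matrix is ordered so
#' that external (food) rows and external columns come first: rows
#' `1..p-1` and columns `1..q-1` are external, rows `p..m` and columns
#' `q..n` internal. The internal-rows by external-columns block must be
#' identically zero — an external reaction may not touch an internal
#' species.
#'
#' @param net A `reaction_network`.
#' @param external_species Character vector of food species ids.
#' @param external_reactions Character vector of food-side reaction ids.
#' @param species Optional row universe (defaults to all species touched by
#'   the selected reactions plus `external_species`).
#' @param reactions Optional column universe (defaults to all reactions of
#'   `net`).
#' @return An object of class `stoich_matrix` with elements `S` (dense
#'   numeric matrix with dimnames), `p`, `q`, `m`, `n` (1-based indices as
#'   described above), and `catalyst_requirements` (named list of species-id
#'   vectors per column).
#' @export
build_stoich_matrix <- function(net, external_species = character(),
                                external_reactions = character(),
                                species = NULL, reactions = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(reactions)) reactions <- reaction_ids(net)
  missing_r <- setdiff(c(external_reactions, reactions), reaction_ids(net))
  if (length(missing_r))
    stop("unknown reaction id(s): ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  rs <- net$reactions[reactions]
  touched <- unique(unlist(lapply(rs, function(r)
    c(names(r$reactants), names(r$products), r$catalysts))))
  if (is.null(species)) species <- union(external_species, touched)
  bad_sp <- setdiff(external_species, species)
  if (length(bad_sp))
    stop("external species outside the row universe: ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  if (!all(external_reactions %in% reactions))
    stop("external reactions must belong to the column universe", call. = FALSE)

  row_ids <- c(intersect(species, external_species),
               setdiff(species, external_species))
  col_ids <- c(intersect(reactions, external_reactions),
               setdiff(reactions, external_reactions))
  S <- matrix(0, nrow = length(row_ids), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    r <- rs[[col_ids[j]]]
    S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    S[names(r$products), j] <- S[names(r$products), j] + r$products
  }
  p <- length(external_species) + 1L
  q <- length(external_reactions) + 1L
  m <- length(row_ids)
  n <- length(col_ids)

  # the Fig-2 partition: external columns may not touch internal rows
  if (q > 1L && p <= m) {
    ext_cols <- seq_len(q - 1L)
    viol <- vapply(ext_cols, function(j) {
      r <- rs[[col_ids[j]]]
      sp <- c(names(r$reactants), names(r$products), r$catalysts)
      any(!sp %in% row_ids[seq_len(p - 1L)])
    }, logical(1))
    if (any(viol))
      stop("external reaction(s) touch internal species: ",
           paste(col_ids[ext_cols][viol], collapse = ", "), call. = FALSE)
  }
  creq <- lapply(rs[col_ids], function(r) r$catalysts)
  # raw reactant sets per column: a species consumed and over-regenerated
  # (e.g. A in A + F -> 2A) has a positive net entry yet is still consumed
  cons <- lapply(rs[col_ids], function(r) names(r$reactants))
  structure(list(S = S, p = p, q = q, m = m, n = n,
                 catalyst_requirements = creq, consumed = cons),
            class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat(sprintf(paste0("<stoich_matrix: %d species (%d external), ",
                     "%d reactions (%d external)>\n"),
              x$m, x$p - 1L, x$n, x$q - 1L))
  invisible(x)
}

#' Internal rows/columns of a partitioned matrix
#'
#' Convenience accessors for the seed-induced block used by detection and
#' motif search.
#'
#' @param M A `stoich_matrix`.
#' @return `internal_block()`: the internal-rows by internal-columns dense
#'   submatrix; `internal_species()`/`internal_reactions()`: the
#'   corresponding id vectors.
#' @export
internal_block <- function(M) {
  stopifnot(inherits(M, "stoich_matrix"))
  M$S[seq.int(M$p, length.out = M$m - M$p + 1L),
      seq.int(M$q, length.out = M$n - M$q + 1L), drop = FALSE]
}

#' @rdname internal_block
#' @export
internal_species <- function(M) rownames(M$S)[seq.int(M$p, length.out = M$m - M$p + 1L)]

#' @rdname internal_block
#' @export
internal_reactions <- function(M) colnames(M$S)[seq.int(M$q, length.out = M$n - M$q + 1L)]

#' Internal species involved in an internal reaction (Omega_j)
#'
#' All internal species with a nonzero net coefficient in column `j`, plus
#' internal catalysts of the reaction: a motif that uses a catalysed
#' reaction must sustain its internal catalyst. External catalysts are
#' ignored.
#'
#' @param M A `stoich_matrix`.
#' @param j An internal reaction id.
#' @return Character vector of internal species ids.
#' @export
involved_internal <- function(M, j) {
  int_sp <- internal_species(M)
  nz <- int_sp[abs(M$S[int_sp, j]) > 1e-12]
  union(nz, intersect(M$catalyst_requirements[[j]], int_sp))
}
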