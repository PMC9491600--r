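#' Configuration for autocatalytic motif search
#'
#' @param beta Per-reaction upper bound on flux levels; a single number is
#'   recycled over all internal reactions. The bound enters the big-M
#'   constants of the integer program, so it should comfortably exceed any
#'   plausible flux level.
#' @param min_reactions Require at least this many reactions in a motif
#'   (the `D` of the cardinality constraint).
#' @param max_solutions Cap on the number of motifs enumerated.
#' @param max_nodes Branch-and-bound node budget.
#' @param tol Integrality/feasibility tolerance.
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(beta = 1000, min_reactions = 1L,
                         max_solutions = 100L, max_nodes = 200000L,
                         tol = 1e-6) {
  stopifnot(all(beta > 0), min_reactions >= 1L)
  structure(list(beta = beta, min_reactions = as.integer(min_reactions),
                 max_solutions = as.integer(max_solutions),
                 max_nodes = as.integer(max_nodes), tol = tol),
            class = "motif_config")
}

# feasibility of a fixed reaction subset as a motif: every involved internal
# species must be net-produced with level >= 1 under the box 0 <= x <= beta
motif_subset_feasible <- function(Sint, omega, T_idx, beta, tol = 1e-7) {
  rows <- sort(unique(unlist(omega[T_idx])))
  if (length(rows) == 0L) return(NULL)  # no internal species involved
  A <- Sint[rows, T_idx, drop = FALSE]
  k <- length(T_idx)
  res <- lp_solve(obj = rep(0, k),
                  A = rbind(A, diag(1, k)),
                  rel = c(rep(">=", length(rows)), rep("<=", k)),
                  rhs = c(rep(1, length(rows)), beta[T_idx]))
  if (res$status != "optimal") return(NULL)
  x <- res$x
  if (any(as.vector(A %*% x) < 1 - tol)) return(NULL)
  x
}

build_motif_problem <- function(M, cfg) {
  Sint <- internal_block(M)
  nc <- ncol(Sint); nr <- nrow(Sint)
  if (nc == 0L) stop("no internal reactions to search", call. = FALSE)
  beta <- rep_len(cfg$beta, nc)
  cols <- colnames(Sint)
  omega <- lapply(seq_len(nc), function(j)
    match(involved_internal(M, cols[j]), rownames(Sint)))
  bigM <- vapply(seq_len(nr), function(i) {
    neg <- Sint[i, ] < 0
    1 - sum(beta[neg] * Sint[i, neg])
  }, numeric(1))
  pb <- list(Sint = Sint, nc = nc, nr = nr, beta = beta, omega = omega,
             bigM = bigM, rows = rownames(Sint), cols = cols)
  attr(pb, "creq") <- M$catalyst_requirements[cols]
  attr(pb, "cons") <- M$consumed[cols]
  pb
}

# LP relaxation of the motif integer program; vars are [x, z, y] with
# z, y relaxed to [0, 1]; `fix` is a named numeric vector over binary
# variable indices (nc+1 .. 2nc+nr) pinning branched variables
motif_lp_relax <- function(pb, D, cuts, fix) {
  nc <- pb$nc; nr <- pb$nr
  nx <- nc; ntot <- 2L * nc + nr
  zi <- function(j) nx + j
  yi <- function(i) nx + nc + i
  rows_A <- list(); rel <- character(0); rhs <- numeric(0)
  add <- function(a, r, b) {
    rows_A[[length(rows_A) + 1L]] <<- a
    rel <<- c(rel, r); rhs <<- c(rhs, b)
  }
  for (j in seq_len(nc)) {            # x_j <= beta_j z_j
    a <- numeric(ntot); a[j] <- 1; a[zi(j)] <- -pb$beta[j]
    add(a, "<=", 0)
  }
  for (j in seq_len(nc)) {            # z_j <= 1
    a <- numeric(ntot); a[zi(j)] <- 1; add(a, "<=", 1)
  }
  for (i in seq_len(nr)) {            # y_i <= 1
    a <- numeric(ntot); a[yi(i)] <- 1; add(a, "<=", 1)
  }
  for (i in seq_len(nr)) {            # sum_j x_j s_ij >= 1 - M_i (1 - y_i)
    a <- numeric(ntot); a[seq_len(nc)] <- pb$Sint[i, ]
    a[yi(i)] <- -pb$bigM[i]
    add(a, ">=", 1 - pb$bigM[i])
  }
  for (j in seq_len(nc)) for (i in pb$omega[[j]]) {   # y_i >= z_j
    a <- numeric(ntot); a[yi(i)] <- 1; a[zi(j)] <- -1
    add(a, ">=", 0)
  }
  a <- numeric(ntot); a[nx + seq_len(nc)] <- 1        # sum z_j >= D
  add(a, ">=", D)
  for (j in seq_len(nc)) {
    # a reaction involving no internal species can never be part of an
    # autocatalytic motif (nothing internal to sustain); bar it from T
    if (length(pb$omega[[j]]) == 0L) {
      a <- numeric(ntot); a[zi(j)] <- 1; add(a, "==", 0)
    }
  }
  for (ct in cuts) {                  # no-good cuts on previous motifs
    a <- numeric(ntot); a[nx + ct] <- 1
    add(a, "<=", length(ct) - 1)
  }
  if (length(fix)) {
    for (k in seq_along(fix)) {
      a <- numeric(ntot); a[as.integer(names(fix)[k])] <- 1
      add(a, "==", fix[[k]])
    }
  }
  obj <- c(rep(0, nc), rep(1, nc), rep(0, nr))
  lp_solve(obj, do.call(rbind, rows_A), rel, rhs)
}

# depth-first branch-and-bound on the binary z/y variables; returns the best
# integral motif (smallest sum z) respecting `cuts`, or NULL if none exists
# within `ub_limit` (prune nodes whose bound exceeds it)
motif_bnb <- function(pb, D, cuts, cfg, ub_limit = Inf) {
  nc <- pb$nc; nr <- pb$nr
  best <- NULL; best_obj <- ub_limit
  nodes <- list(stats::setNames(numeric(0), character(0)))
  n_explored <- 0L
  while (length(nodes)) {
    fix <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    n_explored <- n_explored + 1L
    if (n_explored > cfg$max_nodes)
      stop("motif search exceeded the node budget; raise max_nodes",
           call. = FALSE)
    res <- motif_lp_relax(pb, D, cuts, fix)
    if (res$status != "optimal") next
    # integer objective: a subtree can only help if its bound allows an
    # integer value strictly below the incumbent
    if (res$value > best_obj - 1 + cfg$tol) next
    bin <- res$x[(nc + 1L):(2L * nc + nr)]
    fr <- abs(bin - round(bin))
    if (all(fr <= cfg$tol)) {
      zsel <- which(round(res$x[(nc + 1L):(2L * nc)]) == 1)
      xflux <- motif_subset_feasible(pb$Sint, pb$omega, zsel, pb$beta)
      if (is.null(xflux)) next         # numerically spurious integral point
      obj <- length(zsel)
      if (obj < best_obj) {
        best_obj <- obj
        best <- list(T_idx = zsel, x = xflux, obj = obj)
      }
      next
    }
    v <- which.max(fr)                # most fractional binary
    vidx <- nc + v                    # variable index in [x, z, y]
    first <- round(bin[v])            # explore the nearer bound first
    for (val in c(1 - first, first)) {
      child <- fix
      child[[as.character(vidx)]] <- val
      nodes[[length(nodes) + 1L]] <- child
    }
  }
  best
}

new_motif <- function(pb, T_idx, x, optimal = TRUE, cfg = motif_config()) {
  ids <- pb$cols[T_idx]
  o <- order(ids)
  ids <- ids[o]; T_idx <- T_idx[o]; x <- x[o]
  involved_idx <- sort(unique(unlist(pb$omega[T_idx])))
  # members are the regenerated cycle constituents: internal species consumed
  # (as reactant or catalyst) by some selected reaction; produced-only
  # involved species are waste
  consumed <- sort(unique(unlist(lapply(T_idx, function(j)
    match(intersect(union(attr(pb, "cons")[[j]], attr(pb, "creq")[[j]]),
                    pb$rows), pb$rows)))))
  members <- pb$rows[intersect(involved_idx, consumed)]
  waste <- setdiff(pb$rows[involved_idx], members)
  net <- as.vector(pb$Sint[involved_idx, T_idx, drop = FALSE] %*% x)
  flux_norm <- if (length(net) && min(net) > 0) x / min(net) else x
  if (any(x > 0.99 * pb$beta[T_idx]))
    warning("motif flux within 1% of its beta bound; the bound may be binding",
            call. = FALSE)
  structure(list(reactions = ids,
                 flux = stats::setNames(x, ids),
                 flux_normalized = stats::setNames(flux_norm, ids),
                 involved = pb$rows[involved_idx],
                 members = members, waste = waste,
                 size = length(ids), optimal = optimal),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif: %d reactions, %d members, %d waste%s>\n", x$size,
              length(x$members), length(x$waste),
              if (x$optimal) ", optimal" else ""))
  invisible(x)
}

#' Find one minimum-cardinality autocatalytic motif
#'
#' Solves the motif integer program: binary selectors `z_j` choose a
#' reaction subset `T`, binaries `y_i` mark involved internal species, and
#' big-M constraints require a flux `x` (with `0 <= x_j <= beta_j z_j`)
#' giving every involved internal species a net production of at least 1.
#' The objective minimises `sum(z)` subject to `sum(z) >= min_reactions`.
#' Solved by depth-first branch and bound over the binaries on the LP
#' relaxation; optimality is proven (the search is exhaustive up to
#' pruning by bound). The returned flux is re-checked arithmetically
#' against the production constraints before returning.
#'
#' @param M A `stoich_matrix` certified autocatalytic (see
#'   [is_autocatalytic()]).
#' @param cfg A [motif_config()].
#' @return A `motif` object: `reactions` (ids, sorted), `flux` and
#'   `flux_normalized` (scaled so the smallest net production is 1),
#'   `involved` (the `y = 1` species), `members` (involved species consumed
#'   by the motif: the regenerated cycle constituents, including internal
#'   catalysts), `waste` (involved species that are produced only), `size`,
#'   `optimal`.
#' @export
find_min_motif <- function(M, cfg = motif_config()) {
  pb <- build_motif_problem(M, cfg)
  best <- motif_bnb(pb, cfg$min_reactions, list(), cfg)
  if (is.null(best))
    stop("no autocatalytic motif with at least min_reactions reactions; ",
         "on a certified SDAS this means min_reactions exceeds what the ",
         "internal columns allow, or beta is too small", call. = FALSE)
  new_motif(pb, best$T_idx, best$x, optimal = TRUE, cfg = cfg)
}

#' Enumerate all minimum-cardinality autocatalytic motifs
#'
#' Repeatedly solves the motif integer program, adding a no-good cut
#' (`sum of z over the found set <= size - 1`) after each solution, until
#' the optimum cardinality increases or `max_solutions` is reached. The
#' result is sorted lexicographically by reaction-id set for determinism.
#'
#' @inheritParams find_min_motif
#' @return A list of `motif` objects, all of the optimal cardinality.
#' @export
enumerate_min_motifs <- function(M, cfg = motif_config()) {
  pb <- build_motif_problem(M, cfg)
  first <- motif_bnb(pb, cfg$min_reactions, list(), cfg)
  if (is.null(first))
    stop("no autocatalytic motif with at least min_reactions reactions; ",
         "on a certified SDAS this means min_reactions exceeds what the ",
         "internal columns allow, or beta is too small", call. = FALSE)
  kstar <- first$obj
  sols <- list(first)
  cuts <- list(first$T_idx)
  while (length(sols) < cfg$max_solutions) {
    nxt <- motif_bnb(pb, cfg$min_reactions, cuts, cfg, ub_limit = kstar + 1L)
    if (is.null(nxt) || nxt$obj > kstar) break
    sols[[length(sols) + 1L]] <- nxt
    cuts[[length(cuts) + 1L]] <- nxt$T_idx
  }
  motifs <- lapply(sols, function(s)
    new_motif(pb, s$T_idx, s$x, optimal = TRUE, cfg = cfg))
  keys <- vapply(motifs, function(m) paste(m$reactions, collapse = "\001"),
                 character(1))
  motifs[order(keys)]
}

#' Brute-force minimal-motif oracle
#'
#' Enumerates reaction subsets by increasing cardinality and keeps those
#' whose involved-internal-species system admits a flux with every involved
#' species net-produced (the restricted feasibility LP). Returns all
#' minimal-cardinality feasible subsets. Intended as an independent testing
#' oracle for small instances.
#'
#' @param M A `stoich_matrix` with at most `max_internal` internal columns.
#' @param max_size Largest subset size to try (default: all columns).
#' @param cfg A [motif_config()] (beta and min_reactions are honoured).
#' @param max_internal Guard on the number of internal columns (default 15).
#' @return A list of `motif` objects (possibly empty), sorted
#'   lexicographically.
#' @export
brute_force_motifs <- function(M, max_size = NULL, cfg = motif_config(),
                               max_internal = 15L) {
  pb <- build_motif_problem(M, cfg)
  if (pb$nc > max_internal)
    stop("brute force limited to ", max_internal, " internal reactions",
         call. = FALSE)
  if (is.null(max_size)) max_size <- pb$nc
  for (k in seq.int(cfg$min_reactions, max_size)) {
    subsets <- utils::combn(pb$nc, k, simplify = FALSE)
    hits <- list()
    for (T_idx in subsets) {
      x <- motif_subset_feasible(pb$Sint, pb$omega, T_idx, pb$beta)
      if (!is.null(x))
        hits[[length(hits) + 1L]] <- new_motif(pb, T_idx, x, optimal = TRUE,
                                               cfg = cfg)
    }
    if (length(hits)) {
      keys <- vapply(hits, function(m) paste(m$reactions, collapse = "\001"),
                     character(1))
      return(hits[order(keys)])
    }
  }
  list()
}
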