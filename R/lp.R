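#' Solve a small dense linear program
#'
#' Minimises `obj %*% x` subject to `A x (<=|>=|==) rhs` and `x >= 0`, by a
#' two-phase primal simplex with Bland's anti-cycling rule. Written for the
#' modest, dense systems that arise from seed-induced subnetworks and motif
#' relaxations; not intended as a general-purpose solver.
#'
#' @param obj Numeric objective coefficients (length `n`).
#' @param A Constraint matrix (`m` by `n`).
#' @param rel Character vector of `"<="`, `">="`, `"=="` per row.
#' @param rhs Right-hand sides (length `m`).
#' @param tol Pivoting/feasibility tolerance.
#' @param maxit Iteration cap per phase.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxit"`), `x` (length `n`, when solved), and `value`.
#' @keywords internal
#' @export
lp_solve <- function(obj, A, rel, rhs, tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rel) == m, length(rhs) == m,
            all(rel %in% c("<=", ">=", "==")))
  if (m == 0L)
    return(list(status = "optimal", x = numeric(n), value = 0))
  # normalise rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    rel[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[rel[neg]]
  }
  n_slack <- sum(rel != "==")
  n_art <- sum(rel != "<=")
  N <- n + n_slack + n_art
  T <- matrix(0, m, N + 1L)
  T[, seq_len(n)] <- A
  T[, N + 1L] <- rhs
  basis <- integer(m)
  s_at <- n; a_at <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (rel[i] == "<=") {
      s_at <- s_at + 1L; T[i, s_at] <- 1; basis[i] <- s_at
    } else if (rel[i] == ">=") {
      s_at <- s_at + 1L; T[i, s_at] <- -1
      a_at <- a_at + 1L; T[i, a_at] <- 1; basis[i] <- a_at
      art_cols <- c(art_cols, a_at)
    } else {
      a_at <- a_at + 1L; T[i, a_at] <- 1; basis[i] <- a_at
      art_cols <- c(art_cols, a_at)
    }
  }

  run_phase <- function(T, basis, cost, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(T = T, basis = basis, status = "maxit"))
      cB <- cost[basis]
      d <- cost - as.vector(cB %*% T[, seq_len(ncol(T) - 1L), drop = FALSE])
      cand <- allowed[d[allowed] < -tol]
      if (length(cand) == 0L)
        return(list(T = T, basis = basis, status = "optimal"))
      j <- min(cand)                     # Bland: smallest eligible index
      a <- T[, j]
      pos <- which(a > tol)
      if (length(pos) == 0L)
        return(list(T = T, basis = basis, status = "unbounded"))
      ratios <- T[pos, ncol(T)] / a[pos]
      rmin <- min(ratios)
      tie <- pos[ratios <= rmin + tol]
      pr <- tie[which.min(basis[tie])]   # Bland tie-break on leaving index
      T[pr, ] <- T[pr, ] / T[pr, j]
      other <- setdiff(seq_len(nrow(T)), pr)
      T[other, ] <- T[other, , drop = FALSE] -
        outer(T[other, j], T[pr, ])
      basis[pr] <- j
    }
  }

  # phase 1: drive artificials to zero
  if (n_art > 0L) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- run_phase(T, basis, cost1, seq_len(N))
    if (ph1$status == "maxit") return(list(status = "maxit", x = NULL, value = NA_real_))
    T <- ph1$T; basis <- ph1$basis
    if (sum(T[basis %in% art_cols, N + 1L]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # pivot remaining zero-level artificials out of the basis where possible
    keep_rows <- rep(TRUE, m)
    for (i in seq_len(m)) {
      if (!basis[i] %in% art_cols) next
      nonart <- setdiff(seq_len(N), art_cols)
      piv <- nonart[abs(T[i, nonart]) > tol][1]
      if (!is.na(piv)) {
        T[i, ] <- T[i, ] / T[i, piv]
        other <- setdiff(seq_len(m), i)
        T[other, ] <- T[other, , drop = FALSE] - outer(T[other, piv], T[i, ])
        basis[i] <- piv
      } else {
        keep_rows[i] <- FALSE            # redundant constraint
      }
    }
    T <- T[keep_rows, , drop = FALSE]
    basis <- basis[keep_rows]
  }

  cost2 <- c(obj, rep(0, n_slack), rep(0, n_art))
  ph2 <- run_phase(T, basis, cost2, setdiff(seq_len(N), art_cols))
  if (ph2$status == "maxit") return(list(status = "maxit", x = NULL, value = NA_real_))
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = -Inf))
  T <- ph2$T; basis <- ph2$basis
  x <- numeric(N)
  x[basis] <- T[, ncol(T)]
  xs <- x[seq_len(n)]
  list(status = "optimal", x = xs, value = sum(obj * xs))
}

#' Test a partitioned matrix for stoichiometric autocatalysis
#'
#' A seed-induced internal subnetwork is autocatalytic if there is a
#' non-negative flux vector `x` over the internal reactions giving every
#' internal species a strictly positive net production; by scaling, this is
#' equivalent to requiring net production of at least 1 for every internal
#' row, which is the feasibility system tested here. External rows are
#' unconstrained: food is assumed freely available.
#'
#' @param M A `stoich_matrix` with at least one internal row.
#' @param tol Feasibility tolerance.
#' @param probe_unbounded Also run the growth-objective cross-check
#'   (maximise net production of the first internal species under a box on
#'   total flux, then under the doubled box): an autocatalytic system's
#'   objective scales with the box, a non-autocatalytic one's does not.
#' @return An object of class `lp_result`: list with `feasible`, `flux`
#'   (named non-negative vector over internal reactions, entries below 1e-9
#'   clipped to zero; `NULL` when infeasible), `solver_status`, and
#'   optionally `objective_unbounded`.
#' @export
is_autocatalytic <- function(M, tol = 1e-7, probe_unbounded = FALSE) {
  stopifnot(inherits(M, "stoich_matrix"))
  if (M$m < M$p)
    stop("matrix has no internal rows", call. = FALSE)
  Sint <- internal_block(M)
  if (ncol(Sint) == 0L)
    return(structure(list(feasible = FALSE, flux = NULL,
                          objective_unbounded = FALSE,
                          solver_status = "empty-internal"),
                     class = "lp_result"))
  res <- lp_solve(obj = rep(0, ncol(Sint)), A = Sint,
                  rel = rep(">=", nrow(Sint)), rhs = rep(1, nrow(Sint)))
  if (res$status == "maxit")
    stop("LP solver hit the iteration cap (status maxit)", call. = FALSE)
  feasible <- res$status == "optimal"
  flux <- NULL
  if (feasible) {
    flux <- res$x
    flux[flux < 1e-9] <- 0
    names(flux) <- colnames(Sint)
    if (any(as.vector(Sint %*% flux) < 1 - tol))
      stop("internal error: LP solution fails the production constraints",
           call. = FALSE)
  }
  unb <- NA
  if (probe_unbounded) unb <- probe_growth_unbounded(Sint)
  structure(list(feasible = feasible, flux = flux,
                 objective_unbounded = unb,
                 solver_status = res$status),
            class = "lp_result")
}

#' @export
print.lp_result <- function(x, ...) {
  cat(sprintf("<lp_result: %s (%s)>\n",
              if (x$feasible) "feasible / autocatalytic" else "infeasible",
              x$solver_status))
  invisible(x)
}

# growth-objective probe: maximise net production of the first internal
# species subject to the production constraints and sum(x) <= B; for an
# autocatalytic system the optimum scales linearly with B
probe_growth_unbounded <- function(Sint, B = 1e4) {
  n <- ncol(Sint)
  run <- function(box) {
    lp_solve(obj = -Sint[1, ], A = rbind(Sint, rep(1, n)),
             rel = c(rep(">=", nrow(Sint)), "<="), rhs = c(rep(1, nrow(Sint)), box))
  }
  r1 <- run(B)
  if (r1$status != "optimal") return(FALSE)
  r2 <- run(2 * B)
  r2$status == "optimal" && (-r2$value) > 1.5 * (-r1$value) - 1e-6
}
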