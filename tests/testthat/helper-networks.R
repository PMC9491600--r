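# shared fixtures and independent oracles for the test suite

supported_names <- function(scan) {
  names(Filter(function(r) identical(r$seed$support, "supported"), scan))
}

# fabricate a stoich_matrix with no external rows/columns from a plain
# internal matrix (rows = internal species, cols = internal reactions)
as_internal_matrix <- function(Sint) {
  if (is.null(rownames(Sint))) rownames(Sint) <- sprintf("s%d", seq_len(nrow(Sint)))
  if (is.null(colnames(Sint))) colnames(Sint) <- sprintf("r%d", seq_len(ncol(Sint)))
  cons <- lapply(seq_len(ncol(Sint)), function(j)
    rownames(Sint)[Sint[, j] < 0])
  names(cons) <- colnames(Sint)
  creq <- lapply(seq_len(ncol(Sint)), function(j) character(0))
  names(creq) <- colnames(Sint)
  structure(list(S = Sint, p = 1L, q = 1L, m = nrow(Sint), n = ncol(Sint),
                 catalyst_requirements = creq, consumed = cons),
            class = "stoich_matrix")
}

# brute-force oracle for stoichiometric autocatalysis: search non-negative
# integer flux vectors with entries <= bound for net production >= 1 of
# every internal species; independent of the LP implementation
oracle_autocat <- function(Sint, bound = 12L) {
  m <- nrow(Sint); n <- ncol(Sint)
  stopifnot(n <= 8L)
  posmax <- matrix(0, m, n + 1L)
  for (k in n:1) posmax[, k] <- posmax[, k + 1L] + bound * pmax(Sint[, k], 0)
  rec <- function(k, cur) {
    if (all(cur >= 1)) return(TRUE)
    if (k > n) return(FALSE)
    if (any(cur + posmax[, k] < 1)) return(FALSE)   # optimistic bound
    for (v in 0:bound) if (rec(k + 1L, cur + v * Sint[, k])) return(TRUE)
    FALSE
  }
  rec(1L, numeric(m))
}

# random internal stoichiometric systems (small integer coefficients) for
# LP-vs-oracle agreement; rows are internal species, columns reactions
random_internal_system <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1L)
  n <- sample(1:8, 1L)
  repeat {
    S <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), m * n, replace = TRUE,
                       prob = c(.1, .3, .2, .3, .1)), m, n)
    # every reaction consumes and produces something (possibly external,
    # so all-zero columns are allowed only rarely); keep non-degenerate
    if (any(S != 0)) break
  }
  S
}

# random sparse reaction networks over a small species pool, for expansion
# property tests
random_reaction_network <- function(seed, n_species = 10L, n_reactions = 12L) {
  set.seed(seed)
  pool <- sprintf("s%d", seq_len(n_species))
  rx <- vector("list", n_reactions)
  for (i in seq_len(n_reactions)) {
    k_r <- sample(1:2, 1L); k_p <- sample(1:2, 1L)
    re <- sample(pool, k_r)
    pr <- sample(setdiff(pool, re), k_p)
    cats <- if (stats::runif(1) < 0.2)
      sample(setdiff(pool, c(re, pr)), 1L) else character(0)
    rx[[i]] <- reaction(sprintf("r%d", i),
                        stats::setNames(sample(1:2, k_r, TRUE), re),
                        stats::setNames(sample(1:2, k_p, TRUE), pr),
                        catalysts = cats)
  }
  reaction_network(rx)
}

closure_equal <- function(a, b) {
  setequal(a$species, b$species) && setequal(a$reactions, b$reactions)
}

# independent LP oracle: scipy.optimize.linprog ("highs") through the
# python interpreter on PATH
scipy_feasible <- function(Sint) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(S = apply(Sint, 1, as.numeric, simplify = FALSE)),
                       f, digits = NA)
  code <- paste(
    "import json, sys, numpy as np",
    "from scipy.optimize import linprog",
    "S = np.array(json.load(open(sys.argv[1]))['S'], dtype=float)",
    "if S.ndim == 1: S = S.reshape(1, -1)",
    "r = linprog(np.zeros(S.shape[1]), A_ub=-S, b_ub=-np.ones(S.shape[0]),",
    "            bounds=(0, None), method='highs')",
    "print('feasible' if r.status == 0 else 'infeasible')",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(code), f), stdout = TRUE)
  identical(tail(out, 1), "feasible")
}
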