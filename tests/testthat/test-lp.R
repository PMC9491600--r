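test_that("the simplex solver agrees with scipy linprog on random LPs", {
  # independent cross-check of the in-package solver against the HiGHS
  # implementation behind scipy.optimize.linprog
  set.seed(11)
  cases <- lapply(1:40, function(i) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    list(obj = sample(-3:3, n, TRUE),
         A = matrix(sample(-3:3, m * n, TRUE), m, n),
         rel = sample(c("<=", ">=", "=="), m, TRUE),
         rhs = sample(-4:4, m, TRUE))
  })
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(cases, function(p)
    list(obj = p$obj, A = apply(p$A, 1, as.numeric, simplify = FALSE),
         rel = p$rel, rhs = p$rhs)), f, digits = NA)
  code <- paste(
    "import json, sys, numpy as np",
    "from scipy.optimize import linprog",
    "out = []",
    "for p in json.load(open(sys.argv[1])):",
    "    A = np.array(p['A'], dtype=float)",
    "    Aub, bub, Aeq, beq = [], [], [], []",
    "    for i, r in enumerate(p['rel']):",
    "        if r == '<=': Aub.append(A[i]); bub.append(p['rhs'][i])",
    "        elif r == '>=': Aub.append(-A[i]); bub.append(-p['rhs'][i])",
    "        else: Aeq.append(A[i]); beq.append(p['rhs'][i])",
    "    r = linprog(p['obj'], A_ub=np.array(Aub) if Aub else None,",
    "                b_ub=bub or None, A_eq=np.array(Aeq) if Aeq else None,",
    "                b_eq=beq or None, bounds=(0, None), method='highs')",
    "    st = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, '?')",
    "    out.append({'status': st, 'value': r.fun if r.status == 0 else None})",
    "print(json.dumps(out))",
    sep = "\n")
  ref <- jsonlite::fromJSON(
    system2("python", c("-c", shQuote(code), f), stdout = TRUE),
    simplifyDataFrame = FALSE)
  for (i in seq_along(cases)) {
    p <- cases[[i]]
    mine <- lp_solve(p$obj, p$A, p$rel, p$rhs)
    expect_identical(mine$status, ref[[i]]$status, label = paste("case", i))
    if (mine$status == "optimal")
      expect_equal(mine$value, ref[[i]]$value, tolerance = 1e-7)
  }
  unlink(f)
})

test_that("autocatalysis certification matches the printed toy verdicts", {
  run <- function(name) {
    net <- toy_network(name)
    t0 <- tier0(net, attr(net, "food"))
    scan <- scan_singleton_seeds(net, t0)
    length(supported_names(scan)) > 0L
  }
  expect_true(run("simple_autocat"))
  expect_true(run("non_raf_cycle"))
  expect_true(run("sdas_not_pseudoraf"))
  expect_false(run("catalyzed_chain"))
  expect_false(run("raf_not_stoich"))
  expect_false(run("pseudoraf_not_stoich"))
})

test_that("a feasible certificate satisfies the rescaled production system", {
  net <- toy_network("fig1_like")
  t0 <- tier0(net, c("F0", "F2"))
  M <- internal_partition(net, t0, "A1")
  lp <- is_autocatalytic(M)
  expect_true(lp$feasible)
  expect_true(all(lp$flux >= 0))
  net_prod <- as.vector(internal_block(M) %*% lp$flux)
  expect_true(all(net_prod >= 1 - 1e-7))

  # any strictly positive production vector, rescaled by its minimum,
  # meets the >= 1 form
  x <- c(R1 = 4, R2 = 5, R3 = 1)
  prod <- as.vector(internal_block(M)[, names(x)] %*% x)
  expect_true(all(prod > 0))
  expect_true(all(prod / min(prod) >= 1))
})

test_that("an empty internal column set is infeasible by convention", {
  net <- reaction_network(list(parse_reaction("A -> B", id = "R1")))
  M <- build_stoich_matrix(net, external_species = character())
  M$n <- 0L; M$q <- 1L  # simulate a partition with no internal columns
  M$S <- M$S[, 0, drop = FALSE]
  res <- is_autocatalytic(M)
  expect_false(res$feasible)
  expect_identical(res$solver_status, "empty-internal")
})

test_that("LP verdicts agree with the brute-force integer-flux oracle", {
  # toys first
  for (name in c("simple_autocat", "clique_pair", "non_raf_cycle",
                 "sdas_not_pseudoraf", "pseudoraf_not_stoich")) {
    net <- toy_network(name)
    t0 <- tier0(net, attr(net, "food"))
    for (cand in setdiff(species_ids(net), t0$species)) {
      M <- internal_partition(net, t0, cand)
      if (M$n < M$q) next
      Sint <- internal_block(M)
      expect_identical(is_autocatalytic(M)$feasible, oracle_autocat(Sint),
                       label = paste(name, cand))
    }
  }
  # random internal systems with up to 8 reactions
  for (s in 1:40) {
    Sint <- random_internal_system(s)
    M <- as_internal_matrix(Sint)
    expect_identical(is_autocatalytic(M)$feasible, oracle_autocat(Sint),
                     label = paste("random system", s))
  }
})

test_that("the growth-objective probe corroborates feasibility verdicts", {
  net <- toy_network("simple_autocat")
  t0 <- tier0(net, "F")
  lp <- is_autocatalytic(internal_partition(net, t0, "A"),
                         probe_unbounded = TRUE)
  expect_true(lp$feasible)
  expect_true(lp$objective_unbounded)

  net <- toy_network("pseudoraf_not_stoich")
  t0 <- tier0(net, attr(net, "food"))
  lp <- is_autocatalytic(internal_partition(net, t0, "B"),
                         probe_unbounded = TRUE)
  expect_false(lp$feasible)
  expect_false(lp$objective_unbounded)
})
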