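fig1_partition <- function() {
  net <- toy_network("fig1_like")
  t0 <- tier0(net, c("F0", "F2"))
  internal_partition(net, t0, "A1")
}

test_that("a single-reaction SDAS has itself as the unique minimal motif", {
  net <- toy_network("simple_autocat")
  M <- internal_partition(net, tier0(net, "F"), "A")
  mots <- enumerate_min_motifs(M)
  expect_length(mots, 1L)
  expect_identical(mots[[1]]$reactions, "R1")
  expect_identical(mots[[1]]$members, "A")
  expect_length(mots[[1]]$waste, 0L)
  expect_true(mots[[1]]$optimal)
})

test_that("derived minimal motifs match the exhaustive subset oracle", {
  # two-reaction loop: both split halves of A + F <=> B plus B + F -> 2A;
  # the minimal motif is the forward pair
  net <- toy_network("clique_pair")
  M <- internal_partition(net, tier0(net, "F"), "A")
  bf <- brute_force_motifs(M)
  expect_length(bf, 1L)
  expect_setequal(bf[[1]]$reactions, c("R1.a", "R2"))
  il <- enumerate_min_motifs(M)
  expect_identical(lapply(il, `[[`, "reactions"), lapply(bf, `[[`, "reactions"))

  # three-reaction cycle where the whole set is the unique minimal motif
  net <- toy_network("sdas_not_pseudoraf")
  M <- internal_partition(net, tier0(net, attr(net, "food")), "A")
  bf <- brute_force_motifs(M)
  expect_length(bf, 1L)
  expect_setequal(bf[[1]]$reactions, c("R1", "R2", "R3"))
  il <- enumerate_min_motifs(M)
  expect_identical(lapply(il, `[[`, "reactions"), lapply(bf, `[[`, "reactions"))
})

test_that("integer programming agrees with brute force on random systems", {
  checked <- 0L
  for (s in 1:40) {
    Sint <- random_internal_system(s)
    M <- as_internal_matrix(Sint)
    if (!is_autocatalytic(M)$feasible) next
    bf <- brute_force_motifs(M)
    il <- enumerate_min_motifs(M)
    key <- function(ms) sort(vapply(ms, function(m)
      paste(m$reactions, collapse = ","), character(1)))
    expect_identical(key(il), key(bf), label = paste("system", s))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("every enumerated motif independently passes the restricted LP", {
  M <- fig1_partition()
  for (m in enumerate_min_motifs(M)) {
    sub <- M
    sub$S <- M$S[, c(colnames(M$S)[seq_len(M$q - 1L)], m$reactions),
                 drop = FALSE]
    keep_rows <- c(rownames(M$S)[seq_len(M$p - 1L)], m$involved)
    sub$S <- sub$S[keep_rows, , drop = FALSE]
    sub$m <- length(keep_rows)
    sub$n <- ncol(sub$S)
    sub$catalyst_requirements <- M$catalyst_requirements[colnames(sub$S)]
    sub$consumed <- M$consumed[colnames(sub$S)]
    expect_true(is_autocatalytic(sub)$feasible)
    # and the reported flux satisfies the production constraints directly
    net_prod <- as.vector(internal_block(M)[m$involved, m$reactions,
                                            drop = FALSE] %*% m$flux)
    expect_true(all(net_prod >= 1 - 1e-7))
    expect_equal(min(as.vector(
      internal_block(M)[m$involved, m$reactions, drop = FALSE] %*%
        m$flux_normalized)), 1, tolerance = 1e-9)
  }
})

test_that("the hierarchical example's minimal motif excludes the appendage", {
  # A3 is derived from the motif but takes no part in regeneration
  M <- fig1_partition()
  mots <- enumerate_min_motifs(M)
  expect_length(mots, 1L)
  expect_setequal(mots[[1]]$reactions, c("R1", "R2"))
  expect_setequal(mots[[1]]$members, c("A1", "A2"))
  expect_false("A3" %in% mots[[1]]$involved)
})

test_that("raising the minimum size never shrinks the optimum", {
  M <- fig1_partition()
  sizes <- vapply(1:3, function(D)
    find_min_motif(M, motif_config(min_reactions = D))$size, numeric(1))
  expect_identical(sizes, c(2, 2, 3))
  # D above the internal column count is infeasible
  expect_error(find_min_motif(M, motif_config(min_reactions = 4)),
               "min_reactions")
})

test_that("motifs using catalysed reactions must sustain internal catalysts", {
  # R3 needs internal catalyst U; a motif containing R3 must also produce U
  net <- reaction_network(list(
    parse_reaction("F1 + A -> 2 A", id = "R1"),
    parse_reaction("A + F2 -> U", id = "R2"),
    parse_reaction("F1 -> B | cat: U", id = "R3")))
  t0 <- tier0(net, c("F1", "F2"))
  M <- internal_partition(net, t0, "A")
  pb <- sdasnet:::build_motif_problem(M, motif_config())
  j3 <- match("R3", pb$cols)
  expect_true(match("U", pb$rows) %in% pb$omega[[j3]])
  # {R3} alone cannot sustain U
  expect_null(sdasnet:::motif_subset_feasible(pb$Sint, pb$omega, j3, pb$beta))
  # {R1, R2, R3} can: A feeds U production
  expect_false(is.null(sdasnet:::motif_subset_feasible(
    pb$Sint, pb$omega, match(c("R1", "R2", "R3"), pb$cols), pb$beta)))
})

test_that("big-M constants deactivate the production constraint validly", {
  # for y_i = 0 the relaxed bound must hold for every x in the box [0, beta]
  set.seed(21)
  for (s in c(2, 7, 19)) {
    Sint <- random_internal_system(s)
    M <- as_internal_matrix(Sint)
    pb <- sdasnet:::build_motif_problem(M, motif_config(beta = 50))
    for (rep in 1:20) {
      x <- runif(pb$nc, 0, pb$beta)
      lhs <- as.vector(pb$Sint %*% x)
      relaxed_rhs <- 1 - pb$bigM
      expect_true(all(lhs >= relaxed_rhs - 1e-9))
    }
  }
})

test_that("networks with no feasible subset yield no motifs", {
  net <- toy_network("pseudoraf_not_stoich")
  t0 <- tier0(net, attr(net, "food"))
  M <- internal_partition(net, t0, "B")
  expect_length(brute_force_motifs(M), 0L)
})
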