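test_that("the seed-induced partition separates food from internal blocks", {
  net <- reaction_network(list(parse_reaction("A + F -> 2 A", id = "R1")))
  t0 <- tier0(net, "F")
  M <- internal_partition(net, t0, "A")
  expect_identical(internal_species(M), "A")
  expect_identical(internal_reactions(M), "R1")

  net <- toy_network("fig1_like")
  t0 <- tier0(net, c("F0", "F2"))
  M <- internal_partition(net, t0, "A1")
  expect_setequal(internal_species(M), c("A1", "A2", "A3"))
  expect_setequal(internal_reactions(M), c("R1", "R2", "R3"))

  expect_error(internal_partition(net, t0, "F1"), "seed is food")

  # a candidate inducing nothing yields an empty internal column set
  M <- internal_partition(net, t0, "C1")
  expect_length(internal_reactions(M), 0L)
})

test_that("singleton scans find supported seeds and are order-independent", {
  net <- toy_network("fig1_like")
  t0 <- tier0(net, c("F0", "F2"))
  cands <- setdiff(species_ids(net), t0$species)
  scan1 <- scan_singleton_seeds(net, t0, cands)
  scan2 <- scan_singleton_seeds(net, t0, rev(cands))
  expect_setequal(supported_names(scan1), c("A1", "A2"))
  expect_setequal(supported_names(scan1), supported_names(scan2))
  for (cd in cands)
    expect_identical(scan1[[cd]]$seed$support, scan2[[cd]]$seed$support)

  expect_error(scan_singleton_seeds(net, t0, c("F1", "A1")), "disjoint")
  expect_length(scan_singleton_seeds(net, t0, character(0)), 0L)
})

test_that("supported seeds are self-produced and their SDASs seed-dependent", {
  net <- toy_network("fig1_like")
  t0 <- tier0(net, c("F0", "F2"))
  scan <- scan_singleton_seeds(net, t0)
  for (nm in supported_names(scan)) {
    sd <- scan[[nm]]$sdas
    expect_true(nm %in% sd$species)                     # clique soundness
    refood <- network_expand(net, t0$species)
    expect_length(intersect(refood$reactions, sd$reactions), 0L)
    expect_true(scan[[nm]]$lp$feasible)
  }
})

test_that("clique grouping partitions seeds by induced closure", {
  net <- toy_network("clique_pair")
  t0 <- tier0(net, "F")
  cl <- group_cliques(scan_singleton_seeds(net, t0))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c("A", "B"))
  expect_true(all(cl[[1]]$members %in% cl[[1]]$sdas$species))

  net <- toy_network("non_raf_cycle")
  t0 <- tier0(net, "A")
  cl <- group_cliques(scan_singleton_seeds(net, t0))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c("B", "C"))

  # a single seed forms a singleton clique
  net <- toy_network("simple_autocat")
  cl <- group_cliques(scan_singleton_seeds(net, tier0(net, "F")))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$members, "A")
})

test_that("composite seeds require joint induction and minimality", {
  net <- toy_network("composite_seed")
  t0 <- tier0(net, "F")
  scan <- scan_singleton_seeds(net, t0)
  expect_false("B" %in% supported_names(scan))
  expect_false("C" %in% supported_names(scan))

  comp <- find_composite_seeds(net, t0, singleton_scan = scan)
  expect_length(comp, 1L)
  expect_setequal(comp[[1]]$seed$members, c("B", "C"))
  expect_identical(comp[[1]]$seed$kind, "composite")
  expect_identical(comp[[1]]$seed$support, "supported")

  # a pair containing a singleton seed is rejected as non-minimal
  comp2 <- find_composite_seeds(net, t0, pairs = list(c("A", "B")),
                                singleton_scan = scan)
  expect_length(comp2, 0L)
})

test_that("unsupported seeds are assigned to the maximal induced SDAS", {
  # B <=> A + C makes B convertible to the supported seed A, but B itself
  # cannot be regenerated (C is lost), so B is an unsupported seed
  net <- reaction_network(list(
    parse_reaction("A + F -> 2 A", id = "R1"),
    parse_reaction("B <=> A + C", id = "R2")))
  t0 <- tier0(net, "F")
  scan <- scan_singleton_seeds(net, t0)
  expect_identical(supported_names(scan), "A")
  sdas_a <- scan[["A"]]$sdas

  uns <- classify_unsupported_seeds(net, t0, list(sdas_a),
                                    setdiff(names(scan), "A"))
  expect_identical(names(uns), "B")
  expect_identical(uns[["B"]]$reactions, sdas_a$reactions)

  # nested SDASs: the larger reaction set wins
  small <- sdas_a
  small$reactions <- character(0)
  small$species <- character(0)
  uns2 <- classify_unsupported_seeds(net, t0, list(small, sdas_a), "B")
  expect_identical(uns2[["B"]]$reactions, sdas_a$reactions)
})

test_that("tier construction climbs the trophic hierarchy", {
  net <- toy_network("fig1_like")
  tiers <- build_tiers(net, c("F0", "F2"), max_tier = 4)
  expect_length(tiers$tiers, 3L)
  expect_setequal(tiers$tiers[[1]]$sdass[[1]]$species, c("A1", "A2", "A3"))
  expect_setequal(tiers$tiers[[2]]$sdass[[1]]$species, c("B1", "B3"))
  expect_identical(tiers$tiers[[2]]$sdass[[1]]$reactions, "R4")
  t3_species <- unlist(lapply(tiers$tiers[[3]]$sdass, `[[`, "species"))
  expect_setequal(t3_species, c("C1", "D1"))
  expect_equal(vapply(tiers$tiers, `[[`, integer(1), "tier"), 1:3)

  # max_tier truncates the climb
  expect_length(build_tiers(net, c("F0", "F2"), max_tier = 1)$tiers, 1L)

  # a network with no seeds stops at tier 0
  net0 <- toy_network("catalyzed_chain")
  tiers0 <- build_tiers(net0, attr(net0, "food"))
  expect_length(tiers0$tiers, 0L)
})
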