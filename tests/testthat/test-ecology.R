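fig1_setup <- function() {
  net <- toy_network("fig1_like")
  tiers <- build_tiers(net, c("F0", "F2"), max_tier = 4)
  t3 <- tiers$tiers[[3]]$sdass
  MB <- internal_partition(net, tiers$tiers[[2]]$food_closure, "B1")
  list(net = net, tiers = tiers,
       sdA = tiers$tiers[[1]]$sdass[[1]],
       sdB = tiers$tiers[[2]]$sdass[[1]],
       sdC = t3[[which(vapply(t3, function(s) "C1" %in% s$species, logical(1)))]],
       sdD = t3[[which(vapply(t3, function(s) "D1" %in% s$species, logical(1)))]],
       motsB = enumerate_min_motifs(MB))
}

test_that("waste identification separates byproducts from motif members", {
  fx <- fig1_setup()
  expect_identical(find_waste(fx$sdB, fx$motsB, fx$net), "B3")

  # a motif whose every product is a member has no waste
  net <- toy_network("simple_autocat")
  t0 <- tier0(net, "F")
  M <- internal_partition(net, t0, "A")
  mots <- enumerate_min_motifs(M)
  sd <- scan_singleton_seeds(net, t0)[["A"]]$sdas
  expect_length(find_waste(sd, mots, net), 0L)

  # motif reactions must belong to the SDAS
  expect_error(find_waste(sd, fx$motsB, net), "outside the SDAS")
})

test_that("waste, members and food partition the species a motif touches", {
  fx <- fig1_setup()
  m <- fx$motsB[[1]]
  touched <- unique(unlist(lapply(fx$net$reactions[m$reactions], function(r)
    c(names(r$reactants), names(r$products), r$catalysts))))
  food_part <- setdiff(touched, fx$sdB$species)
  expect_setequal(touched, c(m$members, m$waste, food_part))
  expect_length(intersect(m$members, m$waste), 0L)
  expect_length(intersect(food_part, fx$sdB$species), 0L)
})

test_that("consuming a motif's waste is mutualism; a member, predation", {
  fx <- fig1_setup()
  rep_bc <- classify_interaction(fx$sdB, fx$sdC, fx$net, fx$motsB)
  expect_identical(rep_bc$labels, "mutualism")
  expect_identical(rep_bc$evidence$mutualism, "B3")

  rep_bd <- classify_interaction(fx$sdB, fx$sdD, fx$net, fx$motsB)
  expect_identical(rep_bd$labels, "predation-parasitism")
  expect_identical(rep_bd$evidence$`predation-parasitism`, "B1")

  # without motif information all species count as members, so the waste
  # consumer is conservatively labelled a predator rather than a mutualist
  rep_nm <- classify_interaction(fx$sdB, fx$sdC, fx$net)
  expect_identical(rep_nm$labels, "predation-parasitism")
})

test_that("shared consumed food yields a competition label", {
  net <- reaction_network(list(
    parse_reaction("A + F -> 2 A", id = "R1"),
    parse_reaction("B + F -> 2 B", id = "R2")))
  t0 <- tier0(net, "F")
  scan <- scan_singleton_seeds(net, t0)
  sdA <- scan[["A"]]$sdas; sdB <- scan[["B"]]$sdas
  rep_ab <- classify_interaction(sdA, sdB, net)
  expect_true("competition" %in% rep_ab$labels)
  expect_identical(rep_ab$evidence$competition, "F")
})

test_that("composite paths through a higher-tier species flag facilitation", {
  # the pair Rb (F + c -> E) and Rc (E + A -> 2 A + c) nets the lower
  # reaction R1 (A + F -> 2 A) while regenerating c: a candidate catalyst
  net <- reaction_network(list(
    parse_reaction("A + F -> 2 A", id = "R1"),
    parse_reaction("A + G -> 2 C", id = "R2"),
    parse_reaction("F + C -> E", id = "Rb"),
    parse_reaction("E + A -> 2 A + C", id = "Rc")))
  t0 <- tier0(net, c("F", "G"))
  scan <- scan_singleton_seeds(net, t0)
  sdA <- scan[["A"]]$sdas
  sdC <- structure(list(id = "high", species = c("C", "E"),
                        reactions = c("R2", "Rb", "Rc"), tier = 2L,
                        food = t0$species, seeds = list(),
                        certificate = NULL), class = "sdas")
  rep_ac <- classify_interaction(sdA, sdC, net)
  expect_true("catalytic-facilitation" %in% rep_ac$labels)
  wit <- rep_ac$evidence$`catalytic-facilitation`[[1]]
  expect_identical(wit$catalyst, "C")
  expect_identical(wit$replaces, "R1")
})

test_that("ablation distinguishes essential from dispensable reactions", {
  fx <- fig1_setup()
  food <- union(fx$tiers$tier0$species, fx$sdA$species)

  # removing nothing reproduces plain detection
  r0 <- robustness_to_removal(fx$net, food, "B1")
  expect_true(r0$feasible)
  expect_setequal(r0$sdas$reactions, "R4")

  # removing a reaction outside the SDAS leaves the certificate intact
  r1 <- robustness_to_removal(fx$net, food, "B1", "R6")
  expect_true(r1$feasible)
  expect_identical(r1$sdas$reactions, r0$sdas$reactions)
  expect_equal(r1$lp$flux, r0$lp$flux)

  # removing the SDAS's only reaction destroys it
  r2 <- robustness_to_removal(fx$net, food, "B1", "R4")
  expect_false(r2$feasible)

  # scaffolding: with the lower tier inactive the same seed has no food
  r3 <- robustness_to_removal(fx$net, fx$tiers$tier0$species, "B1",
                              c("R1", "R2", "R3"))
  expect_false(r3$feasible)
})

test_that("removing a toy SDAS's only reaction is fatal", {
  net <- toy_network("simple_autocat")
  r <- robustness_to_removal(net, "F", "A", "R1")
  expect_false(r$feasible)
  expect_error(robustness_to_removal(net, "F", "A", "nope"),
               "unknown reaction")
})
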