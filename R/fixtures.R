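#' Embedded toy reaction networks
#'
#' A registry of small printed networks used throughout the literature on
#' stoichiometric autocatalysis, RAF theory and seed dependence. Each toy
#' carries its food set and the expected verdicts as attributes
#' (`food`, `expected`), so tests and demos can assert against them.
#'
#' Registry:
#' \describe{
#'   \item{simple_autocat}{`A + F -> 2A`, food `F`; autocatalytic, supported
#'     seed `A`.}
#'   \item{composite_seed}{`B + C <=> A`, `A + F -> 2A`, food `F`; `{B, C}`
#'     is a composite seed.}
#'   \item{clique_pair}{`A + F <=> B`, `B + F -> 2A`, food `F`; seeds `A`
#'     and `B` form one clique.}
#'   \item{catalyzed_chain}{`A <=> B` (cat `U`), `B <=> C` (cat `V`), food
#'     `{U, V, A}`; a RAF, but everything expands from food — no seed, not
#'     stoichiometrically autocatalytic.}
#'   \item{non_raf_cycle}{`A + B <=> C`, `C + A <=> 2B`, food `A`;
#'     autocatalytic though no reaction is explicitly catalysed.}
#'   \item{sdas_not_pseudoraf}{`A + F1 -> B + C`, `B + F2 -> A + D`,
#'     `C + D -> A`, food `{F1, F2}`; autocatalytic with seed `A`, yet no
#'     reaction is explicitly catalysed, so it is not a pseudo-RAF.}
#'   \item{raf_not_stoich}{`F1 -> A` (cat `F2`), `F3 -> B` (cat `A`), food
#'     `{F1, F2, F3}`; a RAF but not stoichiometrically autocatalytic (all
#'     reactions fire from food alone).}
#'   \item{pseudoraf_not_stoich}{`F1 -> A` (cat `F2`), `B -> C` (cat `A`),
#'     `C -> B` (cat `A`), food `{F1, F2}`; a pseudo-RAF whose `B/C` loop
#'     has no potential for stoichiometric increase.}
#'   \item{fig1_like}{A reconstruction of a hierarchical multi-SDAS network:
#'     food closure `{F0, F1, F2}` with one food reaction, a tier-1 SDAS
#'     `({A1, A2, A3}, {R1, R2, R3})` seeded by `A1` whose flux `(4, 5, 1)`
#'     over `(R1, R2, R3)` nets `4 F1 + 5 F2 -> A1 + A2 + A3`, a tier-2
#'     single-reaction SDAS (seed `B1`) producing waste `B3`, and two
#'     higher SDASs consuming the waste (`C1`, mutualist) or the member
#'     (`D1`, predator). Species carry integer pseudo-masses; all reactions
#'     are mass balanced. This is a reconstruction satisfying the published
#'     description of such a network, not a transcription of any figure.}
#' }
#'
#' @param name One of the registry names; see Details.
#' @return A `reaction_network` with attributes `food` (ultimate food ids)
#'   and `expected` (named list of expected verdicts).
#' @export
toy_network <- function(name) {
  reg <- toy_registry()
  if (!name %in% names(reg))
    stop("unknown toy '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  spec <- reg[[name]]
  rx <- lapply(seq_along(spec$eq), function(i)
    parse_reaction(spec$eq[i], id = names(spec$eq)[i]))
  net <- reaction_network(rx, species = spec$species)
  attr(net, "food") <- spec$food
  attr(net, "expected") <- spec$expected
  net
}

#' @rdname toy_network
#' @export
toy_names <- function() names(toy_registry())

toy_registry <- function() {
  list(
    simple_autocat = list(
      eq = c(R1 = "A + F -> 2 A"),
      food = "F",
      expected = list(autocatalytic = TRUE, seeds = "A")),
    composite_seed = list(
      eq = c(R1 = "B + C <=> A", R2 = "A + F -> 2 A"),
      food = "F",
      expected = list(autocatalytic = TRUE, composite_seed = c("B", "C"),
                      non_seeds = c("B", "C"))),
    clique_pair = list(
      eq = c(R1 = "A + F <=> B", R2 = "B + F -> 2 A"),
      food = "F",
      expected = list(autocatalytic = TRUE, clique = c("A", "B"))),
    catalyzed_chain = list(
      eq = c(R1 = "A <=> B | cat: U", R2 = "B <=> C | cat: V"),
      food = c("U", "V", "A"),
      expected = list(autocatalytic = FALSE, seeds = character(0))),
    non_raf_cycle = list(
      eq = c(R1 = "A + B <=> C", R2 = "C + A <=> 2B"),
      food = "A",
      expected = list(autocatalytic = TRUE, clique = c("B", "C"))),
    sdas_not_pseudoraf = list(
      eq = c(R1 = "A + F1 -> B + C", R2 = "B + F2 -> A + D",
             R3 = "C + D -> A"),
      food = c("F1", "F2"),
      expected = list(autocatalytic = TRUE, seeds = "A")),
    raf_not_stoich = list(
      eq = c(R1 = "F1 -> A | cat: F2", R2 = "F3 -> B | cat: A"),
      food = c("F1", "F2", "F3"),
      expected = list(autocatalytic = FALSE, seeds = character(0))),
    pseudoraf_not_stoich = list(
      eq = c(R1 = "F1 -> A | cat: F2", R2 = "B -> C | cat: A",
             R3 = "C -> B | cat: A"),
      food = c("F1", "F2"),
      expected = list(autocatalytic = FALSE, seeds = character(0))),
    fig1_like = list(
      eq = c(R0 = "F0 -> F1",
             R1 = "F1 + 2 A1 -> 3 A2",
             R2 = "F2 + 2 A2 -> 2 A1",
             R3 = "A1 + A2 -> A3",
             R4 = "B1 + A3 -> 2 B1 + B3",
             R5 = "C1 + B3 -> 2 C1",
             R6 = "D1 + B1 -> 2 D1"),
      species = data.frame(
        id = c("F0", "F1", "F2", "A1", "A2", "A3", "B1", "B3", "C1", "D1"),
        mass = c(1, 1, 2, 4, 3, 7, 5, 2, 2, 5),
        stringsAsFactors = FALSE),
      food = c("F0", "F2"),
      expected = list(
        autocatalytic = TRUE,
        tier0 = list(species = c("F0", "F1", "F2"), reactions = "R0"),
        tier1 = list(seed = "A1", species = c("A1", "A2", "A3"),
                     reactions = c("R1", "R2", "R3"),
                     certificate = c(R1 = 4, R2 = 5, R3 = 1)),
        tier2 = list(seed = "B1", species = c("B1", "B3"),
                     reactions = "R4", waste = "B3"),
        tier3_seeds = c("C1", "D1")))
  )
}

#' Parameters for the synthetic tiered-network generator
#'
#' @param n_tiers Number of tiers with a planted autocatalytic cycle
#'   (0 gives a decoy-only network).
#' @param species_per_tier Species budget per tier (cycle + waste + decoys
#'   must fit).
#' @param motif_size_range Two integers; each tier's planted cycle length is
#'   drawn uniformly from this range.
#' @param waste_fraction Fraction of cycle reactions that also emit a waste
#'   byproduct (in `[0, 1]`).
#' @param cross_tier_food_edges How many distinct lower-tier species a
#'   tier's cycle consumes as food (tiers above 1).
#' @param rng_seed Integer seed; identical parameters and seed give an
#'   identical network.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_tiers = 2L, species_per_tier = 8L,
                             motif_size_range = c(2L, 4L),
                             waste_fraction = 0.3,
                             cross_tier_food_edges = 2L, rng_seed = 1L) {
  stopifnot(n_tiers >= 0, species_per_tier >= 1,
            length(motif_size_range) == 2L,
            motif_size_range[1] >= 1,
            motif_size_range[2] >= motif_size_range[1],
            waste_fraction >= 0, waste_fraction <= 1,
            cross_tier_food_edges >= 1)
  structure(list(n_tiers = as.integer(n_tiers),
                 species_per_tier = as.integer(species_per_tier),
                 motif_size_range = as.integer(motif_size_range),
                 waste_fraction = waste_fraction,
                 cross_tier_food_edges = as.integer(cross_tier_food_edges),
                 rng_seed = as.integer(rng_seed)),
            class = "generator_params")
}

#' Generate a synthetic tiered network with planted autocatalytic cycles
#'
#' Each tier `t >= 1` receives one planted autocatalytic cycle of length
#' `k_t` drawn from `motif_size_range`: reactions
#' `C_i + food -> 2 C_(i+1)` closing back on `C_1`, so the all-ones flux
#' nets +1 of every cycle species and the cycle is minimal (any proper
#' subset leaves some reactant unproduced). A fraction of cycle reactions
#' additionally emit a waste byproduct (consuming an extra food unit to
#' stay mass balanced). The remaining species budget becomes decoy chains
#' `D + food -> D'`, which are seed-dependent but not autocatalytic.
#' Tier-1 cycles feed on the tier-0 food; higher cycles feed on species of
#' the tier below, so they can only be seeded after that tier is active.
#' All species carry integer pseudo-masses and every reaction is mass
#' balanced.
#'
#' @param params A [generator_params()].
#' @return A list: `net` (the `reaction_network`), `food` (tier-0 food ids)
#'   and `truth` — per tier: planted `seeds` (the cycle clique), `species`,
#'   `reactions`, `motif_size`, `waste`, `decoys`.
#' @export
generate_tiered_network <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$rng_seed)

  n_food <- max(2L, min(4L, params$species_per_tier))
  food <- sprintf("F%d", seq_len(n_food))
  rx <- list()
  species <- data.frame(id = food, mass = rep(2, n_food),
                        stringsAsFactors = FALSE)
  truth <- list()
  lower_pool <- food

  add_decoys <- function(tier, n, pool) {
    out <- list()
    for (d in seq_len(n)) {
      dn <- sprintf("T%d_D%d", tier, d)
      dp <- sprintf("T%d_Dp%d", tier, d)
      f <- sample(pool, 1L)
      out[[length(out) + 1L]] <- reaction(
        sprintf("T%d_RD%d", tier, d),
        stats::setNames(c(1, 1), c(dn, f)), stats::setNames(4, dp))
      species <<- rbind(species,
                        data.frame(id = c(dn, dp), mass = c(2, 1),
                                   stringsAsFactors = FALSE))
    }
    out
  }

  n_dec_tiers <- if (params$n_tiers == 0L) 1L else params$n_tiers
  for (t in seq_len(n_dec_tiers)) {
    cyc_rx <- list(); cyc_sp <- character(0); waste <- character(0)
    k <- 0L
    if (params$n_tiers > 0L) {
      ks <- seq.int(params$motif_size_range[1], params$motif_size_range[2])
      k <- ks[sample.int(length(ks), 1L)]
      if (k + 1L > params$species_per_tier)
        stop("motif size exceeds the species budget per tier", call. = FALSE)
      pool <- if (t == 1L) food else
        sample(lower_pool, min(params$cross_tier_food_edges,
                               length(lower_pool)))
      cyc_sp <- sprintf("T%d_C%d", t, seq_len(k))
      n_waste <- min(round(params$waste_fraction * k),
                     params$species_per_tier - k)
      waste_at <- if (n_waste > 0) sort(sample(seq_len(k), n_waste)) else integer(0)
      waste <- sprintf("T%d_W%d", t, seq_along(waste_at))
      for (i in seq_len(k)) {
        nxt <- cyc_sp[if (i == k) 1L else i + 1L]
        f <- pool[1L + (i - 1L) %% length(pool)]
        wi <- match(i, waste_at)
        if (!is.na(wi)) {
          # consume an extra food unit and emit the waste byproduct
          re <- stats::setNames(c(1, 2), c(cyc_sp[i], f))
          pr <- stats::setNames(c(2, 1), c(nxt, waste[wi]))
        } else {
          re <- stats::setNames(c(1, 1), c(cyc_sp[i], f))
          pr <- stats::setNames(2, nxt)
        }
        cyc_rx[[i]] <- reaction(sprintf("T%d_R%d", t, i), re, pr)
      }
      species <- rbind(species,
                       data.frame(id = c(cyc_sp, waste),
                                  mass = rep(2, length(cyc_sp) + length(waste)),
                                  stringsAsFactors = FALSE))
    }
    n_decoy <- max(0L, (params$species_per_tier - k - length(waste)) %/% 2L)
    dec_rx <- add_decoys(t, n_decoy, if (t == 1L) food else lower_pool)
    rx <- c(rx, cyc_rx, dec_rx)
    if (params$n_tiers > 0L) {
      truth[[t]] <- list(
        tier = t, seeds = cyc_sp, species = c(cyc_sp, waste),
        reactions = sprintf("T%d_R%d", t, seq_len(k)),
        motif_size = k, waste = waste,
        decoys = sprintf("T%d_D%d", t, seq_len(n_decoy)))
      lower_pool <- c(cyc_sp, waste)
    } else {
      truth <- list()
    }
  }
  net <- reaction_network(rx, species = species)
  list(net = net, food = food, truth = truth)
}
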