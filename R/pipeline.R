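#' Run the full SDAS analysis pipeline
#'
#' Orchestrates expansion, seed scanning, LP certification, motif
#' enumeration and interaction classification, writing tabular reports and
#' a machine-readable summary to a run directory. Re-running with the same
#' inputs reproduces identical tabular outputs.
#'
#' @param net A `reaction_network`, or a path readable by
#'   [read_reaction_db()].
#' @param food Ultimate food species ids.
#' @param out_dir Output directory (created if needed).
#' @param whitelist Always-available species merged into the food.
#' @param max_tier Maximum tier to scan.
#' @param pairs Optional list of composite-seed pairs to test at tier 1.
#' @param seed_list If non-`NULL`, skip the full scan and test only these
#'   species as seeds at tier 1.
#' @param motif_max_reactions Enumerate minimal motifs only for SDASs with
#'   at most this many internal reactions (integer-program cost grows
#'   quickly with size).
#' @param motif_cfg A [motif_config()].
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(net, food, out_dir, whitelist = character(),
                         max_tier = 3L, pairs = NULL, seed_list = NULL,
                         motif_max_reactions = 30L,
                         motif_cfg = motif_config()) {
  if (is.character(net)) net <- read_reaction_db(net)
  stopifnot(inherits(net, "reaction_network"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(food = food, whitelist = whitelist, max_tier = max_tier,
              seed_list = seed_list, motif_max_reactions = motif_max_reactions)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  if (!is.null(seed_list)) {
    t0 <- tier0(net, food, whitelist)
    scan <- scan_singleton_seeds(net, t0, intersect(seed_list,
                                                    setdiff(species_ids(net),
                                                            t0$species)))
    cliques <- group_cliques(scan)
    sdass <- lapply(seq_along(cliques), function(k) {
      sd <- cliques[[k]]$sdas; sd$id <- sprintf("sdas-t1-%d", k); sd
    })
    tiers <- structure(list(tier0 = t0,
                            tiers = if (length(sdass))
                              list(list(tier = 1L, scan = scan,
                                        cliques = cliques, sdass = sdass,
                                        food_closure = t0)) else list()),
                       class = "sdas_tiers")
  } else {
    tiers <- build_tiers(net, food, whitelist, max_tier = max_tier,
                         pairs = pairs)
  }
  t0 <- tiers$tier0
  utils::write.table(
    data.frame(kind = c(rep("species", length(t0$species)),
                        rep("reaction", length(t0$reactions))),
               id = c(sort(t0$species), sort(t0$reactions))),
    file.path(out_dir, "tier0.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  seed_rows <- list(); memb_rows <- list(); motif_rows <- list()
  all_sdass <- list(); motifs_by_sdas <- list()
  for (tr in tiers$tiers) {
    for (k in seq_along(tr$cliques)) {
      cl <- tr$cliques[[k]]; sd <- tr$sdass[[k]]
      all_sdass[[sd$id]] <- sd
      for (s in cl$seeds)
        seed_rows[[length(seed_rows) + 1L]] <- data.frame(
          tier = tr$tier, species = paste(s$members, collapse = "+"),
          kind = s$kind, status = s$support, clique = k, sdas = sd$id)
      memb_rows[[length(memb_rows) + 1L]] <- data.frame(
        sdas = sd$id, tier = sd$tier,
        kind = c(rep("species", length(sd$species)),
                 rep("reaction", length(sd$reactions))),
        id = c(sort(sd$species), sort(sd$reactions)))
      if (length(sd$reactions) <= motif_max_reactions) {
        M <- internal_partition(net, tr$food_closure, cl$members[1])
        mots <- enumerate_min_motifs(M, motif_cfg)
        motifs_by_sdas[[sd$id]] <- mots
        for (i in seq_along(mots)) {
          m <- mots[[i]]
          motif_rows[[length(motif_rows) + 1L]] <- data.frame(
            sdas = sd$id, motif = i, size = m$size,
            reactions = paste(m$reactions, collapse = ","),
            members = paste(m$members, collapse = ","),
            waste = paste(m$waste, collapse = ","))
        }
      }
    }
  }
  bind_write <- function(rows, file, empty_cols) {
    df <- if (length(rows)) do.call(rbind, rows) else empty_cols
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    df
  }
  bind_write(seed_rows, "seeds.tsv",
             data.frame(tier = integer(), species = character(),
                        kind = character(), status = character(),
                        clique = integer(), sdas = character()))
  bind_write(memb_rows, "sdas_membership.tsv",
             data.frame(sdas = character(), tier = integer(),
                        kind = character(), id = character()))
  bind_write(motif_rows, "motifs.tsv",
             data.frame(sdas = character(), motif = integer(),
                        size = integer(), reactions = character(),
                        members = character(), waste = character()))

  inter_rows <- list()
  ids <- names(all_sdass)
  for (a in ids) for (b in ids) {
    if (a == b) next
    sa <- all_sdass[[a]]; sb <- all_sdass[[b]]
    if (sa$tier > sb$tier) next
    rep_ab <- classify_interaction(sa, sb, net,
                                   low_motifs = motifs_by_sdas[[a]])
    if (length(rep_ab$labels))
      inter_rows[[length(inter_rows) + 1L]] <- data.frame(
        low = a, high = b, labels = paste(rep_ab$labels, collapse = ","))
  }
  bind_write(inter_rows, "interactions.tsv",
             data.frame(low = character(), high = character(),
                        labels = character()))

  summary <- list(
    n_species = nrow(net$species),
    n_reactions = length(net$reactions),
    tier0 = list(species = length(t0$species),
                 reactions = length(t0$reactions)),
    tiers = lapply(tiers$tiers, function(tr) list(
      tier = tr$tier,
      n_cliques = length(tr$cliques),
      sdas = lapply(tr$sdass, function(sd) list(
        id = sd$id, species = length(sd$species),
        reactions = length(sd$reactions))))),
    n_motifs = sum(lengths(motifs_by_sdas)),
    n_interactions = length(inter_rows))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
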