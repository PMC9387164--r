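# Seeded generator for a complete, internally consistent input bundle with a
# planted pathway signal.
#
# What it emulates: a GC-MS component table with a skewed composition (one
# dominant constituent around 30% of peak area), an n-alkane calibration
# ladder, a component-target bipartite map merged from prediction databases,
# a disease gene list, a thresholded differential-expression table, a
# pathway collection (GMT) and a STRING-style PPI edge list.
#
# Planted structure: a designated "key target" subset plays the role of the
# intersection of component targets, disease genes and DEGs. The planted
# pathway contains few key targets (so its overlap p-value is mediocre), but
# those targets are wired to the highest-A components with extra edges, so
# its weight coefficient C tops the collection. Decoy pathways each contain
# many low-weight key targets and therefore out-rank the planted pathway on
# p-value alone. Re-ranking by C is what the bundle is built to exercise.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator reproduces: 20 oil
#' components, 60 candidate targets, 25 pathways over a 500-gene universe,
#' 10% of the universe differentially expressed, and a 26-gene key-target
#' intersection of which 5 genes sit in the planted pathway.
#'
#' @param seed integer seed; the single source of randomness.
#' @param n_components number of oil components.
#' @param n_targets number of candidate target genes.
#' @param n_pathways number of pathway gene sets.
#' @param pathway_size_range (min, max) pathway sizes.
#' @param universe_size total genes in the background universe.
#' @param frac_de fraction of universe genes that are differentially
#'   expressed.
#' @param n_key_targets size of the planted key-target intersection.
#' @param n_planted_key key targets placed in the planted pathway.
#' @param n_decoy_pathways decoy pathways rich in low-weight key targets.
#' @param n_decoy_key key targets sampled into each decoy pathway.
#' @param planted_pathway_id id of the planted pathway.
#' @param planted_weight_boost multiplier (> 1 for a real boost) controlling
#'   how many of the top-A components are wired to each planted key target
#'   (`round(2 * boost)`); at 1 the planted pathway gets no special wiring
#'   beyond two extra edges and its C score is not guaranteed maximal.
#' @param planted_de_shift absolute log2 fold change given to
#'   differentially expressed genes.
#' @param content_concentration symmetric Dirichlet concentration for
#'   component contents; values < 1 give the skewed composition typical of
#'   essential oils.
#' @param ob_range (lo, hi) range for uniform oral-bioavailability draws.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_components = 20L,
                       n_targets = 60L,
                       n_pathways = 25L,
                       pathway_size_range = c(10L, 40L),
                       universe_size = 500L,
                       frac_de = 0.1,
                       n_key_targets = 26L,
                       n_planted_key = 5L,
                       n_decoy_pathways = 6L,
                       n_decoy_key = 9L,
                       planted_pathway_id = "PW01",
                       planted_weight_boost = 3,
                       planted_de_shift = 2.5,
                       content_concentration = 0.5,
                       ob_range = c(0.2, 0.9)) {
  cfg <- list(seed = as.integer(seed), n_components = as.integer(n_components),
              n_targets = as.integer(n_targets),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              universe_size = as.integer(universe_size),
              frac_de = as.numeric(frac_de),
              n_key_targets = as.integer(n_key_targets),
              n_planted_key = as.integer(n_planted_key),
              n_decoy_pathways = as.integer(n_decoy_pathways),
              n_decoy_key = as.integer(n_decoy_key),
              planted_pathway_id = as.character(planted_pathway_id),
              planted_weight_boost = as.numeric(planted_weight_boost),
              planted_de_shift = as.numeric(planted_de_shift),
              content_concentration = as.numeric(content_concentration),
              ob_range = as.numeric(ob_range))
  counts <- c(cfg$n_components, cfg$n_targets, cfg$n_pathways,
              cfg$universe_size, cfg$n_key_targets, cfg$n_planted_key,
              cfg$n_decoy_pathways, cfg$n_decoy_key)
  if (any(is.na(counts)) || any(counts <= 0))
    validation_error("all counts must be positive")
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    validation_error("frac_de must be in [0, 1]")
  if (length(cfg$pathway_size_range) != 2 ||
      cfg$pathway_size_range[1] < 1 ||
      diff(cfg$pathway_size_range) < 0)
    validation_error("pathway_size_range must be (min, max) with min <= max")
  if (length(cfg$ob_range) != 2 || cfg$ob_range[1] < 0 ||
      cfg$ob_range[2] > 1 || diff(cfg$ob_range) < 0)
    validation_error("ob_range must lie within [0, 1]")
  if (cfg$planted_weight_boost < 1)
    validation_error("planted_weight_boost must be >= 1")
  if (cfg$n_key_targets > cfg$n_targets)
    validation_error("n_key_targets cannot exceed n_targets")
  if (cfg$n_planted_key >= cfg$n_key_targets)
    validation_error("n_planted_key must be smaller than n_key_targets")
  if (cfg$n_decoy_key > cfg$n_key_targets - cfg$n_planted_key)
    validation_error("n_decoy_key exceeds the non-planted key targets")
  if (cfg$n_decoy_pathways + 1 > cfg$n_pathways)
    validation_error("too many decoy pathways for n_pathways")
  if (cfg$universe_size < cfg$n_targets)
    validation_error("universe must contain the targets")
  if (round(cfg$frac_de * cfg$universe_size) < cfg$n_key_targets)
    validation_error("frac_de too small to cover the key targets")
  pw_ids <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  if (!(cfg$planted_pathway_id %in% pw_ids))
    validation_error("planted_pathway_id must be one of ",
                     pw_ids[1], "..", pw_ids[length(pw_ids)])
  structure(cfg, class = "sim_config")
}

# In-memory realization of a config. Everything downstream (files, manifest,
# ground truth) derives from this one draw.
simulate_inputs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nc <- config$n_components
    # --- alkane ladder: C8 upwards, increasing retention times
    n_alk <- 15L
    ladder <- alkane_ladder(
      carbon_number = seq(8L, by = 1L, length.out = n_alk),
      retention_time = round(4 + cumsum(stats::runif(n_alk, 1.2, 2.4)), 4))

    # --- components: skewed Dirichlet contents summing to 100%
    g <- stats::rgamma(nc, shape = config$content_concentration, rate = 1)
    content <- 100 * g / sum(g)
    ob <- stats::runif(nc, config$ob_range[1], config$ob_range[2])
    rng <- range(ladder$retention_time)
    rt <- sort(round(stats::runif(nc, rng[1] + 0.05, rng[2] - 0.05), 4))
    cas <- sprintf("%06d-%02d-%d", sample.int(999999, nc),
                   sample.int(99, nc, replace = TRUE),
                   sample.int(9, nc, replace = TRUE))
    components <- component_table(data.frame(
      name = sprintf("component_%02d", seq_len(nc)),
      cas = cas,
      retention_time = rt,
      retention_index = NA_real_,
      area_pct = round(content, 6),
      ob = round(ob, 4),
      stringsAsFactors = FALSE))
    a <- component_a_scores(components)

    # --- genes
    targets <- sprintf("TGT%03d", seq_len(config$n_targets))
    fillers <- sprintf("GENE%04d", seq_len(config$universe_size - config$n_targets))
    universe <- c(targets, fillers)
    key <- sort(sample(targets, config$n_key_targets))
    hot <- sort(sample(key, config$n_planted_key))
    cold <- setdiff(key, hot)

    # --- component-target edges: 1-3 random components per target, plus the
    # top-A components wired to every hot target
    base <- do.call(rbind, lapply(targets, function(t) {
      comps <- sample(components$name, sample(1:3, 1))
      data.frame(component = comps, target = t, stringsAsFactors = FALSE)
    }))
    n_top <- min(nc, max(2L, as.integer(round(2 * config$planted_weight_boost))))
    top_comps <- components$name[order(-a)][seq_len(n_top)]
    boost <- expand.grid(component = top_comps, target = hot,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    edges <- target_map(rbind(base, boost))

    # --- pathways: planted holds the hot targets; decoys hold many cold key
    # targets; the rest sample filler genes with an occasional cold target.
    # Hot targets appear only in the planted pathway by construction.
    size <- sample(seq(config$pathway_size_range[1],
                       config$pathway_size_range[2]), config$n_pathways,
                   replace = TRUE)
    pw_ids <- sprintf("PW%02d", seq_len(config$n_pathways))
    others <- setdiff(pw_ids, config$planted_pathway_id)
    decoys <- others[seq_len(config$n_decoy_pathways)]
    sets <- stats::setNames(vector("list", config$n_pathways), pw_ids)
    for (i in seq_along(pw_ids)) {
      id <- pw_ids[i]
      sz <- max(size[i], config$n_decoy_key + 1L)
      genes <- if (id == config$planted_pathway_id) {
        c(hot, sample(fillers, max(sz - length(hot), 1L)))
      } else if (id %in% decoys) {
        c(sample(cold, config$n_decoy_key),
          sample(fillers, max(sz - config$n_decoy_key, 1L)))
      } else {
        n_cold <- sample(0:2, 1)
        c(if (n_cold > 0) sample(cold, n_cold),
          sample(fillers, max(sz - n_cold, 1L)))
      }
      sets[[id]] <- list(description = sprintf("synthetic pathway %s", id),
                         genes = sort(unique(genes)))
    }

    # --- differential expression: key targets always significant, padded
    # with random non-target genes up to frac_de of the universe
    n_sig <- max(config$n_key_targets,
                 as.integer(round(config$frac_de * config$universe_size)))
    extra <- sample(setdiff(universe, targets), n_sig - config$n_key_targets)
    sig <- c(key, extra)
    is_sig <- universe %in% sig
    sign_draw <- sample(c(-1, 1), length(universe), replace = TRUE)
    lfc <- ifelse(is_sig,
                  sign_draw * (config$planted_de_shift +
                                 stats::rnorm(length(universe), 0, 0.3)),
                  stats::rnorm(length(universe), 0, 0.3))
    fdr <- ifelse(is_sig,
                  stats::runif(length(universe), 0, 0.04),
                  stats::runif(length(universe), 0.05, 1))
    de <- de_table(data.frame(gene = universe, log2fc = round(lfc, 4),
                              fdr = round(fdr, 6), stringsAsFactors = FALSE))

    # --- disease genes: all key targets plus non-target noise, so that the
    # three-way intersection is exactly the key set
    disease <- gene_set("disease_genes",
                        c(key, sample(setdiff(universe, targets), 150)))

    # --- PPI: high-confidence clique among hot targets, random edges among
    # the rest of the key targets, 0-1000 integer scores
    hot_pairs <- if (length(hot) >= 2) t(utils::combn(hot, 2)) else
      matrix(character(0), ncol = 2)
    n_rand <- 4L * length(key)
    rnd <- cbind(sample(key, n_rand, replace = TRUE),
                 sample(key, n_rand, replace = TRUE))
    rnd <- rnd[rnd[, 1] != rnd[, 2], , drop = FALSE]
    ppi <- ppi_edge_list(data.frame(
      protein_a = c(hot_pairs[, 1], rnd[, 1]),
      protein_b = c(hot_pairs[, 2], rnd[, 2]),
      combined_score = c(sample(901:1000, nrow(hot_pairs), replace = TRUE),
                         sample(0:1000, nrow(rnd), replace = TRUE)),
      stringsAsFactors = FALSE))

    list(config = config, ladder = ladder, components = components,
         edges = edges, pathways = sets, de = de, disease = disease,
         ppi = ppi, universe = universe, key_targets = key,
         hot_targets = hot, deg_genes = sort(sig))
  })
}

# Independent straightforward recomputation of the weight cascade: a plain
# triple loop over (component row, edge, pathway member) incidences. Kept
# deliberately separate from the weighting module's code path so it can serve
# as its oracle.
oracle_weights <- function(components, edges, pathway_sets) {
  a <- numeric(nrow(components))
  for (i in seq_len(nrow(components)))
    a[i] <- components$ob[i] * components$area_pct[i]
  b <- list()
  for (j in seq_len(nrow(edges))) {
    t <- edges$target[j]
    total <- 0
    for (i in seq_len(nrow(components)))
      if (norm_key(components$name[i]) == norm_key(edges$component[j]))
        total <- total + a[i]
    b[[t]] <- (b[[t]] %||% 0) + total
  }
  b <- unlist(b)
  b <- if (is.null(b)) stats::setNames(numeric(0), character(0)) else b[order(names(b))]
  cs <- stats::setNames(numeric(length(pathway_sets)), names(pathway_sets))
  for (p in names(pathway_sets)) {
    genes <- if (is.list(pathway_sets[[p]]) && !is.null(pathway_sets[[p]]$genes))
      pathway_sets[[p]]$genes else pathway_sets[[p]]
    for (t in names(b))
      if (t %in% genes) cs[[p]] <- cs[[p]] + b[[t]]
  }
  list(a = stats::setNames(a, components$name), b = b, c = cs)
}

#' Ground-truth manifest for a simulation config
#'
#' Recomputes the planted quantities with a deliberately simple independent
#' implementation (a triple loop over component/edge/pathway incidences),
#' separate from the pipeline code path, so the pipeline can be checked
#' against it.
#'
#' @param config a [sim_config()].
#' @return list with the planted pathway id, key/hot target sets, DEG genes,
#'   expected DEG count, true `a`/`b`/`c` weight tables, and the C-score
#'   ordering.
#' @export
ground_truth <- function(config) {
  sim <- simulate_inputs(config)
  w <- oracle_weights(sim$components, sim$edges, sim$pathways)
  list(
    seed = config$seed,
    planted_pathway_id = config$planted_pathway_id,
    key_targets = sim$key_targets,
    hot_targets = sim$hot_targets,
    deg_genes = sim$deg_genes,
    n_deg_expected = length(sim$deg_genes),
    a_scores = as.list(w$a),
    b_scores = as.list(w$b),
    c_scores = as.list(w$c),
    c_ordering = names(sort(w$c, decreasing = TRUE)),
    planted_c_is_max = names(which.max(w$c)) == config$planted_pathway_id
  )
}

#' Generate a synthetic input bundle on disk
#'
#' Writes every file the pipeline consumes -- `components.csv`,
#' `alkane_ladder.csv`, `target_map.tsv`, `disease_genes.txt`,
#' `de_table.tsv`, `pathways.gmt`, `ppi_edges.tsv` -- plus `manifest.json`
#' recording the planted ground truth. Identical configs produce
#' byte-identical bundles.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the file `paths` and the `manifest`.
#' @export
generate_bundle <- function(config, out_dir) {
  sim <- simulate_inputs(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    components = file.path(out_dir, "components.csv"),
    ladder = file.path(out_dir, "alkane_ladder.csv"),
    target_map = file.path(out_dir, "target_map.tsv"),
    disease = file.path(out_dir, "disease_genes.txt"),
    de = file.path(out_dir, "de_table.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    ppi = file.path(out_dir, "ppi_edges.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_component_table(sim$components, paths$components)
  write_flat(as.data.frame(sim$ladder), paths$ladder, sep = ",")
  write_target_map(sim$edges, paths$target_map)
  write_gene_list(sim$disease, paths$disease)
  write_flat(as.data.frame(sim$de), paths$de)
  write_gmt(gene_set_collection(sim$pathways), paths$gmt)
  write_ppi_edges(sim$ppi, paths$ppi)
  manifest <- ground_truth(config)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}
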