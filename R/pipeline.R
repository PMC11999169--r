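#' Simulated pathway-analysis resources
#'
#' Small deterministic generators for the network and pathway inputs of
#' the pipeline: a synthetic protein-protein interaction edge list over
#' a kinase vocabulary, a synthetic gene-set library built around kinase
#' families, and synthetic term embeddings drawn from cluster
#' prototypes. These are statistical stand-ins for interaction-database
#' and ontology downloads, with known structure so the network and
#' clustering stages can be tested end to end.
#'
#' @param symbols Character vector of node symbols.
#' @param seed Integer seed.
#' @param extra_per_node Expected number of random extra edges per node
#'   beyond the high-confidence backbone.
#' @return `simulate_ppi_edges()`: data frame `protein_a`, `protein_b`,
#'   `confidence`.
#' @export
simulate_ppi_edges <- function(symbols, seed = 1L, extra_per_node = 2) {
  set.seed(seed)
  n <- length(symbols)
  stopifnot(n >= 2)
  # ring backbone keeps the graph connected
  backbone <- data.frame(protein_a = symbols,
                         protein_b = symbols[c(2:n, 1)],
                         confidence = stats::runif(n, 0.7, 0.99),
                         stringsAsFactors = FALSE)
  m <- round(extra_per_node * n / 2)
  ij <- cbind(sample.int(n, m, replace = TRUE),
              sample.int(n, m, replace = TRUE))
  ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
  extra <- data.frame(protein_a = symbols[ij[, 1]],
                      protein_b = symbols[ij[, 2]],
                      confidence = stats::runif(nrow(ij), 0.4, 0.95),
                      stringsAsFactors = FALSE)
  rbind(backbone, extra)
}

#' @rdname simulate_ppi_edges
#' @param aliases Alias/family table; one gene set is built per family
#'   (its member kinases plus random padding) plus `n_random` unrelated
#'   sets.
#' @param n_random Number of random decoy sets.
#' @export
simulate_gene_sets <- function(aliases = default_alias_map(), seed = 1L,
                               n_random = 6L) {
  set.seed(seed)
  symbols <- unique(aliases$symbol)
  sets <- list()
  for (fam in unique(aliases$family)) {
    members <- unique(aliases$symbol[aliases$family == fam])
    sets[[sprintf("%s_SIGNALING", fam)]] <- members
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(symbols, 6)
  }
  attr(sets, "level") <- "gene_set"
  attr(sets, "source_name") <- "synthetic_gene_sets"
  class(sets) <- "kinase_map"
  sets
}

#' @rdname simulate_ppi_edges
#' @param terms Term names to embed.
#' @param n_clusters Number of embedding prototype clusters.
#' @param dim Embedding dimension.
#' @param noise_sd SD of Gaussian jitter around each prototype.
#' @export
simulate_term_embeddings <- function(terms, n_clusters = 4L, dim = 16L,
                                     noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  protos <- matrix(stats::rnorm(n_clusters * dim), n_clusters, dim)
  assign <- rep_len(seq_len(n_clusters), length(terms))
  emb <- protos[assign, , drop = FALSE] +
    matrix(stats::rnorm(length(terms) * dim, 0, noise_sd), length(terms), dim)
  rownames(emb) <- terms
  colnames(emb) <- sprintf("v%d", seq_len(dim))
  emb
}

#' Write / read term-embedding tables
#'
#' TSV with a `term` column followed by the embedding dimensions.
#'
#' @param emb Numeric matrix with term rownames.
#' @param path File path.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(term = rownames(emb), emb, stringsAsFactors = FALSE,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"term" %in% names(df)) stop("format error: missing 'term' column")
  m <- as.matrix(df[setdiff(names(df), "term")])
  if (!is.numeric(m)) stop("format error: non-numeric embedding values")
  rownames(m) <- df$term
  m
}

#' Bundled demonstration configuration
#'
#' Writes the synthetic network/pathway inputs (interaction edges,
#' gene-set library, term embeddings, external ranker scores) into
#' `dir` and returns a full pipeline configuration: STK and PTK arrays
#' with a planted up-shift of the IKK family (+1 log2) on the STK chip
#' and of the EGFR family (+0.8 log2) on the PTK chip, alongside dead
#' and early-saturating peptides planted for quality control.
#'
#' @param dir Directory for the generated input files.
#' @param seed Master seed.
#' @return A pipeline configuration list (see [validate_config()]).
#' @export
demo_config <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aliases <- default_alias_map()
  symbols <- unique(aliases$symbol)

  edges <- simulate_ppi_edges(symbols, seed = seed + 11L)
  edges_path <- file.path(dir, "ppi_edges.tsv")
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gsets <- simulate_gene_sets(aliases, seed = seed + 12L)
  gmt_path <- file.path(dir, "gene_sets.gmt")
  write_gmt(gsets, gmt_path)

  emb <- simulate_term_embeddings(names(gsets), seed = seed + 13L)
  emb_path <- file.path(dir, "embeddings.tsv")
  write_embeddings(emb, emb_path)

  planted <- list(STK = c(IKK = 1.0), PTK = c(EGFR = 0.8))
  ranker_paths <- list()
  for (chip in c("STK", "PTK")) {
    for (rk in c("uka_like", "kea3_like")) {
      truth_stub <- list(chip_type = chip, planted_effects = planted[[chip]])
      sc <- simulate_ranker_scores(truth_stub, aliases, ranker_name = rk,
                                   seed = seed + 20L + nchar(rk) +
                                     (chip == "PTK") * 7L)
      p <- file.path(dir, sprintf("%s_%s.tsv", tolower(chip), rk))
      utils::write.table(sc, p, sep = "\t", quote = FALSE, row.names = FALSE)
      ranker_paths[[chip]][[rk]] <- p
    }
  }

  list(
    seed = as.integer(seed),
    groups = c(control = "sedentary", treatment = "exercise"),
    synthetic = list(
      STK = list(samples_per_group = 3L, n_chips = 3L, noise_sd = 1,
                 planted_effects = as.list(planted$STK),
                 dead_peptide_frac = 0.1, saturating_peptide_frac = 0.1),
      PTK = list(samples_per_group = 3L, n_chips = 3L, noise_sd = 1,
                 planted_effects = as.list(planted$PTK),
                 dead_peptide_frac = 0.1, saturating_peptide_frac = 0.1)),
    paths = list(edges = edges_path, gene_sets = gmt_path,
                 embeddings = emb_path, rankers = ranker_paths),
    thresholds = list(min_r2 = 0.9, min_signal = 5, logfc_flag = 0.2,
                      hit_fraction = 0.15, alpha = 0.05),
    krsa = list(n_iter = 1000L),
    pcsf = list(beta = 1, omega = 1, cost_mode = "one_minus"),
    clustering = list(k = "auto")
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a configuration list or the path of a YAML file. Returns the
#' list of violations found (empty when valid), with the parsed
#' configuration and a validity flag attached as attributes.
#'
#' @param config Configuration list or YAML file path.
#' @return Character vector of violations; attributes `valid` (logical)
#'   and `config` (the parsed list).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- character(0)
  th <- config$thresholds
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  chk(length(config$groups) == 2, "groups must name control and treatment")
  chk(is.numeric(th$alpha) && th$alpha > 0 && th$alpha < 1,
      "alpha must lie in (0, 1)")
  chk(is.numeric(th$min_r2) && th$min_r2 >= 0 && th$min_r2 <= 1,
      "min_r2 must lie in [0, 1]")
  chk(is.numeric(th$min_signal) && th$min_signal >= 0,
      "min_signal must be >= 0")
  chk(is.numeric(th$logfc_flag) && th$logfc_flag > 0,
      "logfc_flag must be > 0")
  chk(is.numeric(th$hit_fraction) && th$hit_fraction > 0 && th$hit_fraction < 1,
      "hit_fraction must lie in (0, 1)")
  chk(is.numeric(config$krsa$n_iter) && config$krsa$n_iter >= 1,
      "krsa n_iter must be >= 1")
  chk(is.numeric(config$pcsf$beta) && config$pcsf$beta > 0,
      "pcsf beta must be > 0")
  chk(is.numeric(config$pcsf$omega) && config$pcsf$omega > 0,
      "pcsf omega must be > 0")
  for (p in c("edges", "gene_sets", "embeddings")) {
    path <- config$paths[[p]]
    chk(is.character(path) && file.exists(path),
        sprintf("missing input file for '%s'", p))
  }
  for (chip in names(config$paths$rankers))
    for (rk in names(config$paths$rankers[[chip]]))
      chk(file.exists(config$paths$rankers[[chip]][[rk]]),
          sprintf("missing ranker file %s/%s", chip, rk))
  if (is.null(config$synthetic) && is.null(config$paths$reads))
    v <- c(v, "either synthetic settings or reads paths must be given")
  attr(v, "valid") <- length(v) == 0
  attr(v, "config") <- config
  v
}

write_stage_table <- function(df, path, stage, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# kinomepipe %s; stage=%s; seed=%d",
                     as.character(utils::packageVersion("kinomepipe")),
                     stage, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full kinome profiling pipeline
#'
#' Orchestrates every stage on one comparison (control vs treatment):
#' array simulation (or reading of supplied reads), kinetic fitting and
#' quality control, per-chip log2 fold changes with replicate averaging,
#' ternary kinase direction scores, resampling-based kinase-family
#' enrichment, harmonization with the external rankers, prize-collecting
#' Steiner forest integration over the interaction graph,
#' over-representation analysis of the forest nodes, meta-clustering of
#' significant terms, and the two-sample validation statistics. Every
#' intermediate table is written to `output_dir` as TSV with a
#' provenance header; a JSON manifest records parameters, seeds and
#' input digests. Re-running with an identical configuration reproduces
#' all outputs byte-identically (the manifest carries no timestamps).
#'
#' On a stage failure a `failed_<stage>` marker file is left next to the
#' partial outputs and the error names the stage.
#'
#' @param config Configuration list (see [demo_config()]) or YAML path.
#' @param output_dir Output directory (created if needed).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, output_dir) {
  report <- validate_config(config)
  if (!attr(report, "valid"))
    stop("invalid configuration:\n  ", paste(report, collapse = "\n  "))
  config <- attr(report, "config")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  th <- config$thresholds
  grp_a <- config$groups[["control"]]
  grp_b <- config$groups[["treatment"]]

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(output_dir, paste0("failed_", name)))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  manifest <- list(package = "kinomepipe",
                   version = as.character(utils::packageVersion("kinomepipe")),
                   seed = seed, parameters = config[c("thresholds", "krsa",
                                                      "pcsf", "clustering")],
                   groups = as.list(config$groups))

  harmonized <- list()
  signal_stats <- list()
  chips <- names(config$synthetic)
  for (chip in chips) {
    sc <- config$synthetic[[chip]]
    layout <- array_layout(chip)
    kmap <- demo_kinase_map(layout)
    cfg <- stage(paste0("simulate_", chip), simulation_config(
      layout = layout,
      groups = stats::setNames(rep(sc$samples_per_group, 2),
                               c(grp_a, grp_b)),
      n_chips = sc$n_chips, kinase_map = kmap,
      planted_effects = unlist(sc$planted_effects),
      dead_peptide_frac = sc$dead_peptide_frac,
      saturating_peptide_frac = sc$saturating_peptide_frac,
      noise_sd = sc$noise_sd, seed = seed + match(chip, chips)))
    sim <- stage(paste0("simulate_", chip), simulate_arrays(cfg))
    write_reads(sim$reads, file.path(output_dir,
                                     sprintf("reads_%s.tsv", chip)))
    write_ground_truth(sim$truth,
                       file.path(output_dir, sprintf("truth_%s.json", chip)))

    fits <- stage(paste0("qc_", chip), {
      f <- fit_kinetics(sim$reads)
      apply_qc(f, min_signal = th$min_signal, min_r2 = th$min_r2)
    })
    write_stage_table(fits, file.path(output_dir,
                                      sprintf("fits_%s.tsv", chip)),
                      paste0("qc_", chip), seed)
    mat <- stage(paste0("qc_", chip),
                 build_signal_matrix(fits, chip_type = chip))
    write_stage_table(data.frame(peptide_id = rownames(mat),
                                 as.data.frame(unclass(mat)),
                                 check.names = FALSE),
                      file.path(output_dir, sprintf("signal_%s.tsv", chip)),
                      paste0("signal_", chip), seed)

    fc <- stage(paste0("diff_", chip),
                log2_fold_change(mat, grp_a, grp_b,
                                 flag_threshold = th$logfc_flag,
                                 hit_fraction = th$hit_fraction))
    write_stage_table(fc, file.path(output_dir,
                                    sprintf("log2fc_%s.tsv", chip)),
                      paste0("diff_", chip), seed)
    tern <- ternary_score(fc, kmap, threshold = th$logfc_flag)
    write_stage_table(tern, file.path(output_dir,
                                      sprintf("ternary_%s.tsv", chip)),
                      paste0("diff_", chip), seed)
    hm <- stage(paste0("heatmap_", chip), heatmap_matrix(unclass(mat)))
    write_stage_table(data.frame(peptide_id = rownames(hm$matrix)[hm$row_order],
                                 as.data.frame(hm$matrix[hm$row_order,
                                                         hm$col_order]),
                                 check.names = FALSE),
                      file.path(output_dir, sprintf("heatmap_%s.tsv", chip)),
                      paste0("heatmap_", chip), seed)

    hits <- fc$peptide_id[fc$hit15]
    kr <- stage(paste0("krsa_", chip),
                krsa(hits, fc$peptide_id, kmap,
                     n_iter = config$krsa$n_iter, seed = seed + 100L))
    write_stage_table(kr, file.path(output_dir,
                                    sprintf("krsa_%s.tsv", chip)),
                      paste0("krsa_", chip), seed)

    krz <- kr[!is.na(kr$z), , drop = FALSE]
    rankers <- list(ranker_output("KRSA",
                                  stats::setNames(abs(krz$z), krz$family),
                                  "higher_better", level = "family"))
    for (rk in names(config$paths$rankers[[chip]])) {
      tab <- utils::read.delim(config$paths$rankers[[chip]][[rk]],
                               stringsAsFactors = FALSE)
      rankers[[length(rankers) + 1L]] <-
        ranker_output(rk, stats::setNames(tab$score, tab$kinase),
                      "higher_better", level = "kinase")
    }
    h <- stage(paste0("harmonize_", chip),
               suppressWarnings(harmonize(rankers)))
    write_stage_table(h, file.path(output_dir,
                                   sprintf("harmonized_%s.tsv", chip)),
                      paste0("harmonize_", chip), seed)
    write_stage_table(bubble_table(h),
                      file.path(output_dir, sprintf("bubble_%s.tsv", chip)),
                      paste0("harmonize_", chip), seed)
    harmonized[[chip]] <- h

    # per-sample mean signals feed the validation statistics stage
    info <- attr(mat, "col_info")
    sample_means <- tapply(colMeans(unclass(mat)), info$sample_id, mean)
    signal_stats[[chip]] <- list(
      means = sample_means,
      group = info$group[match(names(sample_means), info$sample_id)])
  }

  g <- stage("network", {
    gr <- read_interactions(config$paths$edges)
    assign_costs(gr, mode = config$pcsf$cost_mode)
  })
  prizes <- stage("network", do.call(prize_from_harmonized,
                                     unname(harmonized)))
  forest <- stage("network",
                  solve_pcsf(g, prizes, beta = config$pcsf$beta,
                             omega = config$pcsf$omega))
  write_stage_table(forest$edges, file.path(output_dir, "forest_edges.tsv"),
                    "network", seed)
  jsonlite::write_json(
    list(nodes = forest$nodes, terminals = forest$terminals,
         hidden_nodes = forest$hidden_nodes, objective = forest$objective,
         n_trees = forest$n_trees, parameters = forest$parameters),
    file.path(output_dir, "forest_nodes.json"), auto_unbox = TRUE,
    digits = NA)

  glib <- stage("enrich", read_gmt(config$paths$gene_sets))
  universe <- igraph::V(g)$name
  enr <- stage("enrich",
               ora(intersect(forest$nodes, universe), glib, universe,
                   alpha = th$alpha, seed = seed + 200L))
  write_stage_table(enr, file.path(output_dir, "ora.tsv"), "enrich", seed)

  sig_terms <- enr$term[enr$significant]
  clusters <- NULL
  if (length(sig_terms) >= 1L) {
    emb <- stage("cluster", read_embeddings(config$paths$embeddings))
    clusters <- stage("cluster",
                      cluster_terms(sig_terms, emb,
                                    k = config$clustering$k))
    write_stage_table(clusters, file.path(output_dir, "term_clusters.tsv"),
                      "cluster", seed)
    scores <- matrix(log(pmax(enr$combined_score[match(clusters$term,
                                                       enr$term)], 1e-12)),
                     ncol = 1, dimnames = list(clusters$term, "comparison"))
    ht <- cluster_heatmap_table(clusters, scores)
    write_stage_table(data.frame(term = rownames(ht$matrix),
                                 cluster = ht$row_clusters,
                                 score = ht$matrix[, 1]),
                      file.path(output_dir, "cluster_heatmap.tsv"),
                      "cluster", seed)
  }

  stats_out <- stage("stats", {
    sm <- signal_stats[[chips[1]]]
    a <- sm$means[sm$group == grp_a]
    b <- sm$means[sm$group == grp_b]
    tt <- pooled_t_from_raw(a, b)
    data.frame(statistic = c("t", "df", "p"),
               value = c(tt$t, tt$df, tt$p))
  })
  write_stage_table(stats_out, file.path(output_dir, "group_stats.tsv"),
                    "stats", seed)

  inputs <- c(config$paths$edges, config$paths$gene_sets,
              config$paths$embeddings,
              unlist(config$paths$rankers, use.names = FALSE))
  manifest$input_digests <- as.list(tools::md5sum(inputs))
  manifest$outputs <- sort(list.files(output_dir))
  manifest$forest <- list(n_nodes = length(forest$nodes),
                          n_hidden = length(forest$hidden_nodes),
                          objective = forest$objective)
  manifest$n_significant_terms <- length(sig_terms)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
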