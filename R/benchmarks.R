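#' Built-in validation experiments
#'
#' Self-contained experiments that probe the pipeline's statistical
#' machinery against independent oracles and planted ground truth:
#' convergence of the resampling null to the hypergeometric closed form,
#' agreement of the Steiner-forest heuristic with exhaustive
#' enumeration, recovery of a planted kinase-family activity shift
#' through the whole stack, quality-control recovery of planted
#' failures, agreement of the over-representation p-values with
#' brute-force enumeration, and byte-level reproducibility of the demo
#' pipeline. Each returns the measured quantities so callers can assert
#' or report them.
#'
#' @param n_iter Resampling iterations.
#' @param seed Integer seed.
#' @return `check_krsa_convergence()`: list with `mean_abs_error`,
#'   `sd_abs_error` (absolute deviations of the empirical permutation
#'   mean/SD from the hypergeometric closed form on a 20-peptide
#'   universe with a 10-substrate family and 6 hits) and `n_iter`.
#' @export
check_krsa_convergence <- function(n_iter = 10000L, seed = 1L) {
  u <- sprintf("pep%02d", 1:20)
  map <- structure(list(FAM = u[1:10]), class = "kinase_map")
  hits <- u[c(1:5, 15)]
  res <- krsa(hits, u, map, n_iter = n_iter, seed = seed)
  N <- 20; K <- 10; n <- 6
  mu <- n * K / N
  sdv <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
  list(mean_abs_error = abs(res$perm_mean - mu),
       sd_abs_error = abs(res$perm_sd - sdv),
       analytic_mean = mu, analytic_sd = sdv, n_iter = n_iter)
}

#' @rdname check_krsa_convergence
#' @param n_graphs Number of random instances.
#' @param n_nodes Nodes per instance (<= 12 for the exhaustive oracle).
#' @return `check_pcsf_oracle()`: list with `match_rate` (fraction of
#'   instances where the heuristic objective equals the exhaustive
#'   optimum), `never_better` (heuristic objective always >= optimum)
#'   and `n_graphs`.
#' @export
check_pcsf_oracle <- function(n_graphs = 50L, n_nodes = 10L, seed = 1L) {
  matches <- 0L
  never_better <- TRUE
  for (i in seq_len(n_graphs)) {
    set.seed(seed + i)
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    pairs <- t(utils::combn(n_nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.4
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) pairs <- matrix(c(1L, 2L), 1)
    g <- interaction_graph(data.frame(
      protein_a = nodes[pairs[, 1]], protein_b = nodes[pairs[, 2]],
      confidence = stats::runif(nrow(pairs), 0.05, 1),
      stringsAsFactors = FALSE))
    n_prized <- max(2L, stats::rpois(1, 4))
    prizes <- stats::setNames(stats::runif(n_prized, 0, 1.5),
                              sample(nodes, min(n_prized, n_nodes)))
    fh <- solve_pcsf(g, prizes, mode = "heuristic")
    fe <- solve_pcsf(g, prizes, mode = "exact")
    if (fh$objective < fe$objective - 1e-9) never_better <- FALSE
    if (abs(fh$objective - fe$objective) < 1e-9) matches <- matches + 1L
  }
  list(match_rate = matches / n_graphs, never_better = never_better,
       n_graphs = n_graphs)
}

#' @rdname check_krsa_convergence
#' @param n_seeds Number of independent simulated experiments.
#' @param effect Planted log2 activity shift of the IKK family.
#' @param noise_sd Intensity noise SD of the simulated arrays.
#' @return `check_planted_recovery()`: per-run success indicators and
#'   rates — `top_z_rate` (planted family attains the largest |Z|),
#'   `direction_up_rate` (ternary call is "up"), `quartile4_rate`
#'   (family mean harmonized percentile above 0.75) and `joint_rate`.
#' @export
check_planted_recovery <- function(n_seeds = 50L, effect = 1.0,
                                   noise_sd = 1, seed = 1L) {
  layout <- array_layout("STK")
  map <- demo_kinase_map(layout)
  aliases <- default_alias_map()
  top_z <- dir_up <- q4 <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(layout = layout,
                             groups = c(sedentary = 3L, exercise = 3L),
                             n_chips = 3L, kinase_map = map,
                             planted_effects = c(IKK = effect),
                             noise_sd = noise_sd, seed = seed + i)
    sim <- simulate_arrays(cfg)
    fits <- apply_qc(fit_kinetics(sim$reads))
    fc <- log2_fold_change(build_signal_matrix(fits),
                           "sedentary", "exercise")
    kr <- krsa(fc$peptide_id[fc$hit15], fc$peptide_id, map,
               n_iter = 500L, seed = seed + i)
    top_z[i] <- identical(kr$family[which.max(abs(kr$z))], "IKK")
    tern <- ternary_score(fc, map)
    dir_up[i] <- identical(tern$direction[tern$kinase == "IKK"], "up")
    krz <- kr[!is.na(kr$z), , drop = FALSE]
    e1 <- simulate_ranker_scores(sim$truth, aliases, seed = seed + i)
    e2 <- simulate_ranker_scores(sim$truth, aliases, seed = seed + i + 1000L)
    rankers <- list(
      ranker_output("KRSA", stats::setNames(abs(krz$z), krz$family),
                    level = "family"),
      ranker_output("ext1", stats::setNames(e1$score, e1$kinase)),
      ranker_output("ext2", stats::setNames(e2$score, e2$kinase)))
    h <- suppressWarnings(harmonize(rankers, aliases))
    fam_pct <- mean(h$mean_percentile[h$family %in% "IKK"])
    q4[i] <- is.finite(fam_pct) && fam_pct > 0.75
  }
  list(top_z_rate = mean(top_z), direction_up_rate = mean(dir_up),
       quartile4_rate = mean(q4),
       joint_rate = mean(top_z & dir_up & q4), n_seeds = n_seeds)
}

#' @rdname check_krsa_convergence
#' @param dead_frac,sat_frac Planted failure fractions.
#' @return `check_qc_recovery()`: `sensitivity` (planted failures
#'   removed) and `specificity` (noise-free linear peptides retained) of
#'   quality control against ground truth.
#' @export
check_qc_recovery <- function(dead_frac = 0.1, sat_frac = 0.1, seed = 1L) {
  cfg <- simulation_config(layout = array_layout("STK"),
                           dead_peptide_frac = dead_frac,
                           saturating_peptide_frac = sat_frac,
                           noise_sd = 0, seed = seed)
  sim <- simulate_arrays(cfg)
  fits <- apply_qc(fit_kinetics(sim$reads))
  truth <- sim$truth$peptide_class
  verdict <- tapply(fits$passed_qc, fits$peptide_id, all)[names(truth)]
  bad <- truth != "normal"
  list(sensitivity = mean(!verdict[bad]),
       specificity = mean(verdict[!bad]),
       n_planted = sum(bad), n_normal = sum(!bad))
}

#' @rdname check_krsa_convergence
#' @param n_cases Number of random small-universe instances.
#' @param max_universe Largest universe size enumerated.
#' @return `check_ora_enumeration()`: `max_abs_error` between the
#'   hypergeometric p-values and exhaustive pmf enumeration, and
#'   `bh_monotone` (step-up adjusted values non-decreasing in p).
#' @export
check_ora_enumeration <- function(n_cases = 100L, max_universe = 15L,
                                  seed = 1L) {
  set.seed(seed)
  max_err <- 0
  monotone <- TRUE
  for (i in seq_len(n_cases)) {
    N <- sample(5:max_universe, 1)
    u <- sprintf("g%02d", seq_len(N))
    n <- sample(2:(N - 1), 1)
    lib <- lapply(seq_len(3), function(j) sample(u, sample(1:N, 1)))
    names(lib) <- sprintf("t%d", seq_len(3))
    r <- ora(sample(u, n), lib, u, combined = "neglogp")
    for (j in seq_len(nrow(r))) {
      kk <- 0:r$set_size[j]
      pmf <- choose(r$set_size[j], kk) *
        choose(N - r$set_size[j], r$n_query[j] - kk) /
        choose(N, r$n_query[j])
      p_enum <- sum(pmf[kk >= r$overlap[j]], na.rm = TRUE)
      max_err <- max(max_err, abs(r$p_value[j] - p_enum))
    }
    o <- order(r$p_value)
    if (any(diff(r$fdr[o]) < -1e-12)) monotone <- FALSE
  }
  list(max_abs_error = max_err, bh_monotone = monotone, n_cases = n_cases)
}

#' @rdname check_krsa_convergence
#' @param work_dir Scratch directory for the two pipeline runs.
#' @return `check_pipeline_determinism()`: `identical` (all outputs
#'   byte-identical across two runs of the same configuration) and
#'   `n_files` compared.
#' @export
check_pipeline_determinism <- function(work_dir = tempfile(), seed = 1L) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- demo_config(file.path(work_dir, "inputs"), seed = seed)
  out1 <- file.path(work_dir, "run1")
  out2 <- file.path(work_dir, "run2")
  suppressWarnings(run_pipeline(cfg, out1))
  suppressWarnings(run_pipeline(cfg, out2))
  files <- list.files(out1)
  same <- vapply(files, function(f)
    identical(readLines(file.path(out1, f), warn = FALSE),
              readLines(file.path(out2, f), warn = FALSE)), logical(1))
  list(identical = all(same), n_files = length(files))
}
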