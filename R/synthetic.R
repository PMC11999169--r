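#' Configure a synthetic kinome-array simulation
#'
#' Bundles everything the generator needs: the chip layout, the two
#' experimental groups with their per-group sample counts, the number of
#' technical replicate chips, the exposure-time series of the kinetic
#' image capture, the kinase-substrate map, the planted per-family
#' activity shifts, the fractions of planted quality-control failures,
#' the noise level and the seed.
#'
#' Defaults emulate the study design the generator stands in for: two
#' groups (sedentary control vs voluntary wheel running), three samples
#' per group, triplicate chips, and exposures of 10, 20, 50, 100 and
#' 200 ms.
#'
#' @param layout An [array_layout()].
#' @param groups Named integer vector of length 2: samples per group. The
#'   second group is the treatment by convention.
#' @param n_chips Number of technical replicate chips.
#' @param exposures_ms Strictly increasing positive exposure times (ms).
#' @param kinase_map A `kinase_map` (named list of peptide-id sets);
#'   defaults to [demo_kinase_map()] for the layout.
#' @param planted_effects Named numeric: log2 activity shift per kinase
#'   family, applied multiplicatively (`2^effect`) to the treatment
#'   group's kinetic slope for the family's substrate peptides.
#' @param dead_peptide_frac,saturating_peptide_frac Fractions in `[0, 1)`
#'   of peptides planted as QC failures; counts are
#'   `floor(frac * n_peptides)`, selected by a seeded shuffle.
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise (intensity units).
#' @param seed Integer seed; identical configs produce identical tables.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(layout = array_layout("STK"),
                              groups = c(sedentary = 3L, exercise = 3L),
                              n_chips = 3L,
                              exposures_ms = c(10, 20, 50, 100, 200),
                              kinase_map = demo_kinase_map(layout),
                              planted_effects = numeric(0),
                              dead_peptide_frac = 0,
                              saturating_peptide_frac = 0,
                              noise_sd = 1,
                              seed = 1L) {
  cfg <- list(layout = layout, groups = groups, n_chips = as.integer(n_chips),
              exposures_ms = as.numeric(exposures_ms),
              kinase_map = kinase_map,
              planted_effects = planted_effects,
              dead_peptide_frac = dead_peptide_frac,
              saturating_peptide_frac = saturating_peptide_frac,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  validate_array_layout(cfg$layout)
  if (length(cfg$groups) != 2L || is.null(names(cfg$groups)) ||
      any(!nzchar(names(cfg$groups))) || anyDuplicated(names(cfg$groups)))
    stop("configuration error: groups must be two named sample counts")
  if (any(cfg$groups < 1L)) stop("configuration error: need >= 1 sample per group")
  if (cfg$n_chips < 1L) stop("configuration error: n_chips must be >= 1")
  if (length(cfg$exposures_ms) < 2L || any(cfg$exposures_ms <= 0) ||
      any(diff(cfg$exposures_ms) <= 0))
    stop("configuration error: exposures_ms must be strictly increasing and positive")
  if (cfg$dead_peptide_frac < 0 || cfg$saturating_peptide_frac < 0 ||
      cfg$dead_peptide_frac + cfg$saturating_peptide_frac >= 1)
    stop("configuration error: dead + saturating fractions must be in [0, 1)")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (length(cfg$planted_effects)) {
    missing <- setdiff(names(cfg$planted_effects), names(cfg$kinase_map))
    if (length(missing))
      stop("configuration error: planted family absent from kinase map: ",
           paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

#' Simulate kinome-array kinetic reads with known ground truth
#'
#' Generates per-peptide intensities across the exposure series for every
#' sample on every technical replicate chip. Normal peptides follow a
#' linear kinetic `intensity = slope * exposure + intercept` plus
#' Gaussian noise; substrates of a planted family have the treatment
#' group's slope multiplied by `2^effect`, so the planted effect equals
#' the expected log2 fold change of the slope-derived signal. Planted
#' dead peptides emit background-level values (`|N(0, noise_sd/10)|`) and
#' planted saturating peptides follow a concave early-saturating curve
#' (`amplitude * (1 - exp(-exposure / tau))` with small `tau`) that
#' violates the linearity required by quality control.
#'
#' @param config A [simulation_config()].
#' @return A list with `reads` (the kinetic read table: `chip_id`,
#'   `sample_id`, `group`, `peptide_id`, `exposure_ms`, `intensity`) and
#'   `truth` (per-peptide class, per-peptide baseline slope, planted
#'   family effects, seed and config echo).
#' @export
simulate_arrays <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  lay <- config$layout
  n_pep <- lay$n_peptides
  peptides <- lay$peptide_ids

  n_dead <- floor(config$dead_peptide_frac * n_pep)
  n_sat <- floor(config$saturating_peptide_frac * n_pep)
  shuffled <- sample(peptides)
  class_of <- stats::setNames(rep("normal", n_pep), peptides)
  if (n_dead > 0) class_of[shuffled[seq_len(n_dead)]] <- "dead"
  if (n_sat > 0) class_of[shuffled[n_dead + seq_len(n_sat)]] <- "saturating"

  base_slope <- stats::setNames(stats::runif(n_pep, 0.5, 3.0), peptides)
  intercept <- stats::setNames(stats::runif(n_pep, 0, 5), peptides)

  # per-peptide log2 slope shift in the treatment group (sum over planted
  # families covering the peptide)
  shift <- stats::setNames(numeric(n_pep), peptides)
  for (fam in names(config$planted_effects)) {
    subs <- intersect(config$kinase_map[[fam]], peptides)
    shift[subs] <- shift[subs] + config$planted_effects[[fam]]
  }

  grp_names <- names(config$groups)
  samples <- data.frame(
    sample_id = unlist(lapply(grp_names, function(g)
      sprintf("%s_%d", g, seq_len(config$groups[[g]])))),
    group = rep(grp_names, config$groups),
    stringsAsFactors = FALSE
  )
  chips <- sprintf("chip%d", seq_len(config$n_chips))
  expo <- config$exposures_ms
  tau_sat <- 5  # ms; saturates before the first exposure, clearly nonlinear

  grid <- expand.grid(exposure_ms = expo,
                      peptide_id = peptides,
                      sample_idx = seq_len(nrow(samples)),
                      chip_id = chips,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- samples$sample_id[grid$sample_idx]
  grid$group <- samples$group[grid$sample_idx]

  slope_eff <- base_slope[grid$peptide_id] *
    ifelse(grid$group == grp_names[2], 2^shift[grid$peptide_id], 1)
  mu <- slope_eff * grid$exposure_ms + intercept[grid$peptide_id]
  sat_amp <- base_slope[grid$peptide_id] * max(expo)
  cls <- class_of[grid$peptide_id]
  mu[cls == "saturating"] <-
    (sat_amp * (1 - exp(-grid$exposure_ms / tau_sat)))[cls == "saturating"]

  n_rec <- nrow(grid)
  noise <- stats::rnorm(n_rec, 0, config$noise_sd)
  intensity <- pmax(mu + noise, 0)
  dead_vals <- abs(stats::rnorm(n_rec, 0, config$noise_sd / 10))
  intensity[cls == "dead"] <- dead_vals[cls == "dead"]

  reads <- data.frame(chip_id = grid$chip_id, sample_id = grid$sample_id,
                      group = grid$group, peptide_id = grid$peptide_id,
                      exposure_ms = grid$exposure_ms, intensity = intensity,
                      stringsAsFactors = FALSE)
  ord <- order(reads$chip_id, reads$sample_id, reads$peptide_id,
               reads$exposure_ms)
  reads <- reads[ord, , drop = FALSE]
  rownames(reads) <- NULL

  truth <- list(peptide_class = class_of,
                base_slope = base_slope,
                planted_effects = config$planted_effects,
                seed = config$seed,
                chip_type = lay$chip_type,
                groups = config$groups,
                n_chips = config$n_chips,
                exposures_ms = config$exposures_ms)
  list(reads = reads, truth = truth)
}

read_columns <- c("chip_id", "sample_id", "group", "peptide_id",
                  "exposure_ms", "intensity")

#' Write / read kinetic read tables
#'
#' Long-format tab-separated text with header columns `chip_id`,
#' `sample_id`, `group`, `peptide_id`, `exposure_ms`, `intensity`.
#' Writing then reading reproduces the table exactly.
#'
#' @param reads A kinetic read table as returned by [simulate_arrays()].
#' @param path File path.
#' @return `read_reads()` returns the validated read table;
#'   `write_reads()` returns `path` invisibly.
#' @export
write_reads <- function(reads, path) {
  stopifnot(is.data.frame(reads))
  missing <- setdiff(read_columns, names(reads))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  out <- reads[read_columns]
  # full double precision so that write-then-read is exact
  out$exposure_ms <- sprintf("%.17g", out$exposure_ms)
  out$intensity <- sprintf("%.17g", out$intensity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chip_id = "character",
                                          sample_id = "character",
                                          group = "character",
                                          peptide_id = "character",
                                          exposure_ms = "numeric"))
  missing <- setdiff(read_columns, names(tab))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  tab <- tab[read_columns]
  bad <- which(!is.finite(tab$intensity))
  if (length(bad))
    stop("format error: non-numeric or missing intensity at data row ", bad[1])
  neg <- which(tab$intensity < 0)
  if (length(neg))
    stop("format error: negative intensity at data row ", neg[1])
  key <- paste(tab$chip_id, tab$sample_id, tab$peptide_id, tab$exposure_ms,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("format error: duplicate (chip, sample, peptide, exposure) at data row ",
         dup[1])
  tab
}

#' Write ground truth as JSON
#'
#' @param truth The `truth` element returned by [simulate_arrays()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(peptide_class = as.list(truth$peptide_class),
         planted_effects = as.list(truth$planted_effects),
         seed = truth$seed, chip_type = truth$chip_type,
         groups = as.list(truth$groups), n_chips = truth$n_chips,
         exposures_ms = truth$exposures_ms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate external upstream-kinase ranker score tables
#'
#' Stands in for the score files of external upstream-kinase tools
#' applied to the same samples. Member kinases of planted families
#' receive scores shifted by the absolute planted effect, so an informed
#' external ranker agrees with the internal resampling analysis up to
#' noise.
#'
#' @param truth Ground truth from [simulate_arrays()].
#' @param aliases Alias/family table ([default_alias_map()]).
#' @param ranker_name Label for the simulated tool.
#' @param score_sd Noise SD of the simulated scores.
#' @param seed Integer seed.
#' @return A data frame with columns `kinase`, `score`.
#' @export
simulate_ranker_scores <- function(truth, aliases = default_alias_map(),
                                   ranker_name = "external", score_sd = 0.25,
                                   seed = 1L) {
  set.seed(seed)
  fams <- switch(truth$chip_type, STK = stk_families(), PTK = ptk_families())
  tab <- unique(aliases[aliases$family %in% fams, c("symbol", "family")])
  eff <- truth$planted_effects
  bump <- ifelse(tab$family %in% names(eff), abs(eff[tab$family]), 0)
  score <- stats::rnorm(nrow(tab), 0, score_sd) + bump
  data.frame(kinase = tab$symbol, score = score, stringsAsFactors = FALSE)
}
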