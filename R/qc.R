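#' Fit per-peptide linear kinetics
#'
#' For every (chip, sample, peptide) series, fits ordinary least squares
#' of intensity on exposure time and reports the slope (intensity per
#' ms), intercept, coefficient of determination and maximum observed
#' intensity. The slope summarises the phosphorylation kinetics of the
#' reporter peptide across the multi-exposure capture; quality control
#' ([apply_qc()]) then screens on signal level and linearity.
#'
#' Series with fewer than three distinct exposures cannot support the
#' linearity check and are marked failed (`fail_reason = "nonlinear"`)
#' rather than raising an error. A series with zero intensity variance
#' has an undefined R^2, reported as `NA`.
#'
#' @param reads Kinetic read table (see [simulate_arrays()], [read_reads()]).
#' @return A data frame of per-series fits with columns `chip_id`,
#'   `sample_id`, `group`, `peptide_id`, `slope`, `intercept`,
#'   `r_squared`, `max_intensity`, `n_exposures`, `passed_qc`,
#'   `fail_reason`. `passed_qc`/`fail_reason` are placeholders (`NA` /
#'   `"none"`) until [apply_qc()] is applied, except for degenerate
#'   series which are failed immediately.
#' @export
fit_kinetics <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(read_columns %in% names(reads)))
  key <- paste(reads$chip_id, reads$sample_id, reads$peptide_id, sep = "\r")
  ukey <- unique(key)
  f <- factor(key, levels = ukey)
  x <- reads$exposure_ms
  y <- reads$intensity

  n <- as.vector(table(f))
  sx <- as.vector(rowsum(x, f))
  sy <- as.vector(rowsum(y, f))
  sxx <- as.vector(rowsum(x * x, f)) - sx^2 / n
  syy <- as.vector(rowsum(y * y, f)) - sy^2 / n
  sxy <- as.vector(rowsum(x * y, f)) - sx * sy / n

  slope <- sxy / sxx
  intercept <- sy / n - slope * sx / n
  r2 <- ifelse(syy > 0, pmin(pmax(sxy^2 / (sxx * syy), 0), 1), NA_real_)
  maxy <- as.vector(tapply(y, f, max))

  first <- !duplicated(key)
  out <- data.frame(chip_id = reads$chip_id[first],
                    sample_id = reads$sample_id[first],
                    group = reads$group[first],
                    peptide_id = reads$peptide_id[first],
                    slope = slope, intercept = intercept, r_squared = r2,
                    max_intensity = maxy, n_exposures = n,
                    passed_qc = NA, fail_reason = "none",
                    stringsAsFactors = FALSE)
  degenerate <- out$n_exposures < 3L
  out$slope[degenerate] <- NA_real_
  out$intercept[degenerate] <- NA_real_
  out$r_squared[degenerate] <- NA_real_
  out$passed_qc[degenerate] <- FALSE
  out$fail_reason[degenerate] <- "nonlinear"
  rownames(out) <- NULL
  out
}

#' Apply signal and linearity quality control
#'
#' Implements the two QC rules: peptides with zero or undetectable
#' signal (maximum intensity below `min_signal`, or a non-increasing
#' fitted slope) are flagged `undetectable`; peptides whose intensity
#' does not increase linearly over exposure time (R^2 below `min_r2`)
#' are flagged `nonlinear`. A flat series is undetectable, not
#' nonlinear: "linear increase" requires a strictly positive slope.
#'
#' @param fits Output of [fit_kinetics()].
#' @param min_signal Minimum max-exposure intensity counted as detected.
#' @param min_r2 Minimum R^2 for the linearity requirement, in `[0, 1]`.
#' @return `fits` with `passed_qc` and `fail_reason` filled in, and the
#'   thresholds attached as attribute `qc_thresholds`.
#' @export
apply_qc <- function(fits, min_signal = 5, min_r2 = 0.9) {
  stopifnot(min_r2 >= 0, min_r2 <= 1, min_signal >= 0)
  degenerate <- fits$n_exposures < 3L
  undetect <- !degenerate &
    (fits$max_intensity < min_signal | is.na(fits$slope) | fits$slope <= 0)
  nonlin <- !degenerate & !undetect &
    (is.na(fits$r_squared) | fits$r_squared < min_r2)
  fits$fail_reason <- "none"
  fits$fail_reason[undetect] <- "undetectable"
  fits$fail_reason[nonlin | degenerate] <- "nonlinear"
  fits$passed_qc <- fits$fail_reason == "none"
  attr(fits, "qc_thresholds") <- c(min_signal = min_signal, min_r2 = min_r2)
  fits
}

#' Build the per-peptide signal matrix
#'
#' Reduces each passing kinetic fit to one signal value, `slope *
#' reference_exposure_ms` — the model-predicted rise over the reference
#' exposure — and assembles the peptide x sample matrix used by all
#' downstream comparisons. A peptide is retained only if it passed QC in
#' every sample of every chip of the comparison; the single pass count
#' reported per comparison follows from this all-sample rule.
#'
#' @param fits QC-annotated fits from [apply_qc()].
#' @param reference_exposure_ms Reference exposure for the signal
#'   reduction (ms).
#' @param chip_type Optional chip label recorded in the metadata.
#' @return A numeric matrix (peptides x chip/sample columns) of class
#'   `peptide_signal_matrix` with attributes `col_info` (chip, sample
#'   and group per column), `reference_exposure_ms`, `qc_thresholds` and
#'   `chip_type`.
#' @export
build_signal_matrix <- function(fits, reference_exposure_ms = 100,
                                chip_type = NULL) {
  if (any(is.na(fits$passed_qc)))
    stop("fits must be QC-annotated; run apply_qc() first")
  pass_by_pep <- tapply(fits$passed_qc, fits$peptide_id, all)
  keep <- names(pass_by_pep)[pass_by_pep]
  if (!length(keep)) stop("no peptides passed QC")
  sub <- fits[fits$peptide_id %in% keep, , drop = FALSE]
  col_key <- paste(sub$chip_id, sub$sample_id, sep = ".")
  cols <- unique(col_key)
  mat <- matrix(NA_real_, nrow = length(keep), ncol = length(cols),
                dimnames = list(sort(keep), cols))
  mat[cbind(match(sub$peptide_id, rownames(mat)), match(col_key, cols))] <-
    sub$slope * reference_exposure_ms
  # a peptide absent from any sample of the comparison is excluded too
  complete <- rowSums(is.na(mat)) == 0
  if (!any(complete)) stop("no peptides passed QC")
  mat <- mat[complete, , drop = FALSE]
  first <- !duplicated(col_key)
  col_info <- data.frame(column = col_key[first], chip_id = sub$chip_id[first],
                         sample_id = sub$sample_id[first],
                         group = sub$group[first], stringsAsFactors = FALSE)
  col_info <- col_info[match(cols, col_info$column), , drop = FALSE]
  rownames(col_info) <- NULL
  structure(mat, col_info = col_info,
            reference_exposure_ms = reference_exposure_ms,
            qc_thresholds = attr(fits, "qc_thresholds"),
            chip_type = chip_type,
            class = c("peptide_signal_matrix", "matrix", "array"))
}
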