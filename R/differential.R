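#' Per-chip log2 fold change with replicate averaging
#'
#' Computes, within each technical replicate chip, the log2 ratio of the
#' treatment group's mean signal to the control group's mean signal for
#' every peptide, then averages the per-chip log2 fold changes across
#' chips. Two flags are derived from the averaged value: `flagged`
#' marks biologically meaningful changes at |log2FC| > 0.2, and `hit15`
#' marks peptides with at least a 15% change on the linear fold-change
#' scale (|2^log2FC - 1| >= 0.15), the input rule for upstream-kinase
#' identification. Both thresholds are applied independently; note the
#' slight asymmetry of the 15% rule on the log scale
#' (log2 1.15 = 0.2016 up, log2 0.85 = -0.2345 down).
#'
#' @param mat A [build_signal_matrix()] result.
#' @param group_a Control group label (denominator).
#' @param group_b Treatment group label (numerator).
#' @param flag_threshold Absolute log2FC above which a peptide is flagged.
#' @param hit_fraction Minimum fractional activity change for `hit15`.
#' @return A data frame (class `fold_change_table`) with one row per
#'   peptide: per-chip `log2fc_<chip>` columns, `mean_log2fc`, `flagged`
#'   and `hit15`.
#' @export
log2_fold_change <- function(mat, group_a, group_b, flag_threshold = 0.2,
                             hit_fraction = 0.15) {
  info <- attr(mat, "col_info")
  if (is.null(info)) stop("mat must be a peptide_signal_matrix")
  if (!all(c(group_a, group_b) %in% info$group))
    stop("both groups must be present in the matrix")
  chips <- unique(info$chip_id)
  per_chip <- list()
  for (ch in chips) {
    ca <- info$column[info$chip_id == ch & info$group == group_a]
    cb <- info$column[info$chip_id == ch & info$group == group_b]
    if (!length(ca) || !length(cb)) {
      warning(sprintf("chip %s lacks group %s; skipped", ch,
                      if (length(ca)) group_b else group_a))
      next
    }
    ma <- rowMeans(mat[, ca, drop = FALSE])
    mb <- rowMeans(mat[, cb, drop = FALSE])
    bad <- ma <= 0 | mb <= 0
    if (any(bad))
      warning(sprintf("chip %s: %d peptide(s) with non-positive group mean excluded",
                      ch, sum(bad)))
    lfc <- log2(mb / ma)
    lfc[bad] <- NA_real_
    per_chip[[ch]] <- lfc
  }
  if (!length(per_chip)) stop("no chip carried both groups")
  fc <- do.call(cbind, per_chip)
  colnames(fc) <- paste0("log2fc_", names(per_chip))
  mean_lfc <- rowMeans(fc, na.rm = FALSE)
  out <- data.frame(peptide_id = rownames(mat), fc,
                    mean_log2fc = mean_lfc,
                    flagged = !is.na(mean_lfc) & abs(mean_lfc) > flag_threshold,
                    hit15 = !is.na(mean_lfc) &
                      abs(2^mean_lfc - 1) >= hit_fraction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("fold_change_table", "data.frame")
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "flag_threshold") <- flag_threshold
  attr(out, "hit_fraction") <- hit_fraction
  out
}

#' Ternary direction-of-change score per kinase
#'
#' Assigns each mapped substrate peptide a value of +1 when its averaged
#' log2 fold change exceeds 0.2, -1 when below -0.2 and 0 otherwise
#' (boundary values score 0), averages the values over all substrates of
#' each kinase or family, and calls the direction from the sign of the
#' mean: up when positive, down when negative, no change at exactly
#' zero. Kinases with no mapped substrate surviving QC are reported with
#' direction `no_data`.
#'
#' @param fc A [log2_fold_change()] table.
#' @param map A `kinase_map` (named list of substrate peptide ids).
#' @param threshold Log2FC magnitude that a substrate must strictly
#'   exceed to count as changed.
#' @return Data frame with `kinase`, `n_substrates`, `mean_value` and
#'   `direction`.
#' @export
ternary_score <- function(fc, map, threshold = 0.2) {
  lfc <- stats::setNames(fc$mean_log2fc, fc$peptide_id)
  res <- lapply(names(map), function(kin) {
    subs <- intersect(map[[kin]], names(lfc))
    vals <- lfc[subs]
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      return(data.frame(kinase = kin, n_substrates = 0L,
                        mean_value = NA_real_, direction = "no_data",
                        stringsAsFactors = FALSE))
    tern <- ifelse(vals > threshold, 1, ifelse(vals < -threshold, -1, 0))
    m <- mean(tern)
    data.frame(kinase = kin, n_substrates = length(vals), mean_value = m,
               direction = if (m > 0) "up" else if (m < 0) "down" else "no_change",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Row-normalized matrix with hierarchical orderings
#'
#' Prepares the matrix behind a clustered heatmap: optional row
#' z-scoring ((x - row mean) / row SD; zero-variance rows become all
#' zeros with a warning) and agglomerative hierarchical clustering
#' (Euclidean distance, average linkage) of rows and columns. Returns
#' orderings and dendrograms, not images.
#'
#' @param mat Numeric matrix with at least 2 rows and 2 columns.
#' @param row_normalize Z-score rows before clustering?
#' @return List with `matrix` (normalized), `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust` and `metadata` (distance/linkage used).
#' @export
heatmap_matrix <- function(mat, row_normalize = TRUE) {
  mat <- unclass(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("heatmap requires at least 2 rows and 2 columns")
  if (row_normalize) {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance row(s) normalized to all zeros")
      sdv[zero] <- 1
    }
    mat <- (mat - mu) / sdv
  }
  rh <- stats::hclust(stats::dist(mat), method = "average")
  ch <- stats::hclust(stats::dist(t(mat)), method = "average")
  list(matrix = mat, row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch,
       metadata = list(distance = "euclidean", linkage = "average",
                       row_normalized = row_normalize))
}
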