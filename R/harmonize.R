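#' Construct a ranker output
#'
#' A ranker is any upstream-kinase tool that returns one score per
#' kinase (or per kinase family). Orientation declares whether larger
#' raw scores mean stronger implication; scores are negated internally
#' when `lower_better`, so after orientation higher is always more
#' implicated.
#'
#' @param name Ranker label.
#' @param scores Named numeric vector (kinase or family -> score).
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @param level `"kinase"` or `"family"`; family-level rankers are
#'   expanded to member kinases during harmonization.
#' @return List of class `ranker_output`.
#' @export
ranker_output <- function(name, scores,
                          orientation = c("higher_better", "lower_better"),
                          level = c("kinase", "family")) {
  orientation <- match.arg(orientation)
  level <- match.arg(level)
  if (!length(scores) || is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be a non-empty named numeric vector")
  if (any(!is.finite(scores))) stop("scores must be finite")
  structure(list(name = name, scores = scores, orientation = orientation,
                 level = level), class = "ranker_output")
}

#' Percentile rank normalization of a ranker's scores
#'
#' After orienting scores so that higher means more implicated, each
#' kinase receives percentile `rank / K` with average ranks on ties,
#' where `K` is the number of kinases the ranker scored. The best score
#' maps to exactly 1.
#'
#' @param r A [ranker_output()].
#' @return Named numeric vector of percentiles in `(0, 1]`.
#' @export
percentile_normalize <- function(r) {
  stopifnot(inherits(r, "ranker_output"))
  s <- r$scores
  if (r$orientation == "lower_better") s <- -s
  rank(s, ties.method = "average") / length(s)
}

#' Harmonize multiple upstream-kinase rankers
#'
#' Maps every ranker's kinase names to HGNC symbols through the alias
#' table, expands family-level rankers to their member kinases,
#' percentile-normalizes each ranker, and joins per kinase: the mean and
#' median percentile are computed over the rankers in which the kinase
#' is present (absence is recorded, not imputed, matching the
#' empty-circle convention of bubble plots; set `absent_as_zero = TRUE`
#' to count absence as zero evidence instead). Per-ranker quartiles are
#' `ceiling(4 * percentile)` clipped to 1..4.
#'
#' Unknown aliases are reported via a warning and kept under their
#' original name with an unknown family; two aliases collapsing to the
#' same symbol within one ranker is an error.
#'
#' @param rankers List of [ranker_output()] objects.
#' @param aliases Alias table ([default_alias_map()]): columns `alias`,
#'   `symbol`, `family`.
#' @param absent_as_zero Impute percentile 0 for absent rankers when
#'   averaging?
#' @return Data frame (class `harmonized_table`): `kinase`, `family`,
#'   one `pct_<ranker>` column per ranker, `mean_percentile`,
#'   `median_percentile`, one `q_<ranker>` quartile column per ranker
#'   (`NA` = absent).
#' @export
harmonize <- function(rankers, aliases = default_alias_map(),
                      absent_as_zero = FALSE) {
  if (!length(rankers)) stop("need at least one ranker")
  sym_of <- stats::setNames(aliases$symbol, aliases$alias)
  fam_of <- stats::setNames(aliases$family, aliases$symbol)

  pct_list <- list()
  for (r in rankers) {
    stopifnot(inherits(r, "ranker_output"))
    if (r$level == "family") {
      # every member kinase inherits its family's score
      expanded <- list()
      for (fam in names(r$scores)) {
        members <- unique(aliases$symbol[aliases$family == fam])
        for (m in members) expanded[[m]] <- r$scores[[fam]]
      }
      if (!length(expanded)) {
        warning(sprintf("ranker %s: no family maps to any kinase; skipped", r$name))
        next
      }
      r <- ranker_output(r$name, unlist(expanded), r$orientation, "kinase")
    }
    nm <- names(r$scores)
    mapped <- ifelse(nm %in% names(sym_of), sym_of[nm], nm)
    unknown <- nm[!(nm %in% names(sym_of))]
    if (length(unknown))
      warning(sprintf("ranker %s: unmapped alias(es) kept as-is: %s",
                      r$name, paste(unique(unknown), collapse = ", ")))
    if (anyDuplicated(mapped))
      stop(sprintf("ranker %s: ambiguous duplicate symbol after alias mapping: %s",
                   r$name,
                   paste(unique(mapped[duplicated(mapped)]), collapse = ", ")))
    names(r$scores) <- mapped
    pct_list[[r$name]] <- percentile_normalize(r)
  }
  if (!length(pct_list)) stop("no usable ranker")

  kinases <- sort(unique(unlist(lapply(pct_list, names))))
  pct <- sapply(pct_list, function(p) p[kinases])  # kinase x ranker, NA absent
  pct <- matrix(pct, nrow = length(kinases),
                dimnames = list(kinases, names(pct_list)))
  avg_src <- pct
  if (absent_as_zero) avg_src[is.na(avg_src)] <- 0
  mean_p <- rowMeans(avg_src, na.rm = TRUE)
  med_p <- apply(avg_src, 1, stats::median, na.rm = TRUE)
  quart <- pmin(pmax(ceiling(4 * pct), 1), 4)

  fam <- ifelse(kinases %in% names(fam_of), fam_of[kinases], NA_character_)
  out <- data.frame(kinase = kinases, family = fam, stringsAsFactors = FALSE)
  for (rn in colnames(pct)) out[[paste0("pct_", rn)]] <- pct[, rn]
  out$mean_percentile <- mean_p
  out$median_percentile <- med_p
  for (rn in colnames(quart)) out[[paste0("q_", rn)]] <- quart[, rn]
  rownames(out) <- NULL
  class(out) <- c("harmonized_table", "data.frame")
  attr(out, "rankers") <- colnames(pct)
  out
}

#' Long-format quartile table for bubble plots
#'
#' One row per (kinase, ranker): the quartile of the kinase within that
#' ranker, `NA` where the kinase is absent from the ranker's output.
#' Rows are grouped by family, then kinase.
#'
#' @param h A [harmonize()] table.
#' @return Data frame with `kinase`, `family`, `ranker`, `quartile`.
#' @export
bubble_table <- function(h) {
  stopifnot(inherits(h, "harmonized_table"), nrow(h) > 0)
  rankers <- attr(h, "rankers")
  out <- do.call(rbind, lapply(rankers, function(rn)
    data.frame(kinase = h$kinase, family = h$family, ranker = rn,
               quartile = h[[paste0("q_", rn)]], stringsAsFactors = FALSE)))
  out <- out[order(out$family, out$kinase, out$ranker), , drop = FALSE]
  rownames(out) <- NULL
  out
}
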