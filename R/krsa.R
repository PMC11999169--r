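#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' members. Used both for kinase-substrate maps and for gene-set
#' libraries. Duplicate members within a set are dropped; a set with no
#' members is a format error.
#'
#' @param path File path.
#' @param level Map level recorded on the result (`"family"` or
#'   `"kinase"` for substrate maps; ignored for plain libraries).
#' @return A named list of unique member character vectors (class
#'   `kinase_map`), with attributes `level` and `source_name`.
#' @export
read_gmt <- function(path, level = "family") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("malformed GMT line %d: empty member list", i))
    sets[[parts[1]]] <- members
  }
  attr(sets, "level") <- level
  attr(sets, "source_name") <- basename(path)
  class(sets) <- "kinase_map"
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Kinase-family enrichment by random resampling
#'
#' Scores each kinase family by comparing the number of differentially
#' phosphorylated ("hit") peptides among its substrates with the count
#' expected when the same number of peptides is drawn at random from the
#' QC-passing universe. Each iteration draws `|hits|` peptides uniformly
#' without replacement; the per-family permutation mean and SD yield a
#' Z score `(observed - mean) / sd`. Families with no substrate in the
#' universe are dropped with a warning; a zero permutation SD leaves Z
#' undefined (`NA`).
#'
#' As the iteration count grows, the permutation mean and SD converge to
#' the hypergeometric closed form `n K / N` and
#' `sqrt(n (K/N) (1 - K/N) (N - n) / (N - 1))`, which the test-suite
#' uses as an independent oracle.
#'
#' @param hits Character vector of hit peptide ids (subset of `universe`).
#' @param universe Character vector of QC-passing peptide ids.
#' @param map A `kinase_map`.
#' @param n_iter Number of resampling iterations.
#' @param seed Integer seed (recorded in the result).
#' @return Data frame with `family`, `observed`, `perm_mean`, `perm_sd`,
#'   `z`, `n_iterations`, `seed`.
#' @export
krsa <- function(hits, universe, map, n_iter = 2000L, seed = 1L) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  if (length(hits) > length(universe))
    stop("more hits than universe peptides")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  sets <- lapply(map, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping families with no universe substrate: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no family has substrates in the universe")

  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))          # universe x family
  observed <- as.vector(crossprod(member, universe %in% hits))

  m <- length(hits)
  set.seed(seed)
  perm <- matrix(0L, nrow = n_iter, ncol = ncol(member))
  for (b in seq_len(n_iter)) {
    draw <- sample.int(length(universe), m)
    perm[b, ] <- colSums(member[draw, , drop = FALSE])
  }
  pm <- colMeans(perm)
  psd <- apply(perm, 2, stats::sd)
  z <- ifelse(psd > 0, (observed - pm) / psd, NA_real_)
  data.frame(family = colnames(member), observed = observed,
             perm_mean = pm, perm_sd = psd, z = z,
             n_iterations = as.integer(n_iter), seed = as.integer(seed),
             stringsAsFactors = FALSE, row.names = NULL)
}
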