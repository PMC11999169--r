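#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric upper-tail test of each library set against
#' the query, relative to the universe, with Benjamini-Hochberg FDR over
#' the tested sets. The combined score follows the familiar
#' enrichment-app construction `-ln(p) * z`, where `z` standardizes the
#' deviation of the term's observed rank from its expected rank under
#' random queries of the same size (positive when the term ranks better
#' than expected); `combined = "neglogp"` uses `-ln(p)` alone.
#'
#' @param query Non-empty character vector, subset of `universe`.
#' @param library Named list of member vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @param alpha FDR significance level.
#' @param combined `"permutation"` or `"neglogp"`.
#' @param n_perm Permutations for the rank z term.
#' @param seed Seed for the permutations.
#' @return Data frame: `term`, `overlap`, `set_size`, `universe_size`,
#'   `n_query`, `p_value`, `fdr`, `combined_score`, `significant`.
#' @export
ora <- function(query, library, universe, alpha = 0.05,
                combined = c("permutation", "neglogp"), n_perm = 100L,
                seed = 1L) {
  combined <- match.arg(combined)
  universe <- unique(universe)
  query <- unique(query)
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  sets <- lapply(library, intersect, universe)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (!length(sets)) stop("no library set overlaps the universe")

  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")

  if (combined == "permutation" && length(sets) > 1L) {
    set.seed(seed)
    obs_rank <- rank(p, ties.method = "average")
    perm_ranks <- matrix(NA_real_, nrow = n_perm, ncol = length(sets))
    for (b in seq_len(n_perm)) {
      q <- sample(universe, n)
      kb <- vapply(sets, function(s) length(intersect(s, q)), integer(1))
      pb <- stats::phyper(kb - 1, K, N - K, n, lower.tail = FALSE)
      perm_ranks[b, ] <- rank(pb, ties.method = "average")
    }
    mu <- colMeans(perm_ranks)
    sd_r <- apply(perm_ranks, 2, stats::sd)
    z <- ifelse(sd_r > 0, (mu - obs_rank) / sd_r, 0)
  } else {
    z <- rep(1, length(sets))
  }
  score <- -log(pmax(p, .Machine$double.xmin)) * z

  data.frame(term = names(sets), overlap = k, set_size = K,
             universe_size = N, n_query = n, p_value = p, fdr = fdr,
             combined_score = score, significant = fdr < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

cosine_distance <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  xs <- x / nrm
  d <- 1 - tcrossprod(xs)
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Meta-cluster enriched terms and pick representative terms
#'
#' Hierarchically clusters term embedding vectors on cosine distance
#' (average linkage). The number of clusters is fixed by `k` or chosen
#' automatically as the largest average silhouette width over k in
#' `[2, min(10, n - 1)]`; geometrically degenerate inputs (fewer than
#' three terms, or all pairwise distances ~0) collapse to a single
#' cluster. Each cluster's most representative term (MRT) is the member
#' most cosine-similar to the cluster's average embedding, ties broken
#' lexicographically.
#'
#' 2-D scatter coordinates are presentation-only: supplied `coords` are
#' passed through, otherwise classical multidimensional scaling of the
#' cosine distances is used.
#'
#' @param terms Character vector of (significant) term ids.
#' @param embeddings Numeric matrix, rownames = term ids.
#' @param k Integer number of clusters, or `"auto"`.
#' @param coords Optional precomputed 2-column coordinate matrix.
#' @return Data frame: `term`, `cluster`, `sim_to_centroid`, `is_mrt`,
#'   `x`, `y`; cluster summary (id, representative term, size) attached
#'   as attribute `clusters`.
#' @export
cluster_terms <- function(terms, embeddings, k = "auto", coords = NULL) {
  miss <- setdiff(terms, rownames(embeddings))
  if (length(miss)) {
    warning("term(s) without embedding excluded: ", paste(miss, collapse = ", "))
    terms <- setdiff(terms, miss)
  }
  if (!length(terms)) stop("no term has an embedding")
  x <- embeddings[terms, , drop = FALSE]
  n <- length(terms)
  d <- cosine_distance(x)

  if (n == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(d, method = "average")
    if (identical(k, "auto")) {
      if (n < 3L || max(d) < 1e-10) {
        cl <- rep(1L, n)
      } else {
        ks <- 2:min(10L, n - 1L)
        sil <- vapply(ks, function(kk) {
          mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"])
        }, numeric(1))
        cl <- stats::cutree(hc, ks[which.max(sil)])
      }
    } else {
      stopifnot(k >= 1, k <= n)
      cl <- if (k == n) seq_len(n) else stats::cutree(hc, k)
    }
  }
  names(cl) <- terms

  nrm <- sqrt(rowSums(x^2)); nrm[nrm == 0] <- 1
  xs <- x / nrm
  sim <- numeric(n)
  mrt <- character(max(cl))
  for (cid in sort(unique(cl))) {
    idx <- which(cl == cid)
    centroid <- colMeans(x[idx, , drop = FALSE])
    cn <- sqrt(sum(centroid^2))
    s <- if (cn > 0) as.vector(xs[idx, , drop = FALSE] %*% (centroid / cn))
         else rep(0, length(idx))
    sim[idx] <- s
    cands <- terms[idx][s >= max(s) - 1e-12]
    mrt[cid] <- sort(cands)[1]
  }

  if (is.null(coords)) {
    coords <- if (n >= 3) suppressWarnings(stats::cmdscale(d, k = 2))
              else matrix(0, n, 2)
    # degenerate geometries can return < 2 usable axes; pad with zeros
    coords <- cbind(coords, matrix(0, n, 2))[, 1:2, drop = FALSE]
  } else {
    coords <- coords[terms, , drop = FALSE]
  }

  out <- data.frame(term = terms, cluster = as.integer(cl),
                    sim_to_centroid = sim,
                    is_mrt = terms == mrt[cl],
                    x = coords[, 1], y = coords[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "clusters") <- data.frame(
    cluster = sort(unique(cl)),
    representative_term = mrt[sort(unique(cl))],
    size = as.integer(table(cl)), stringsAsFactors = FALSE)
  out
}

#' Cluster-ordered enrichment heatmap table
#'
#' Arranges a term x comparison enrichment-score matrix for display:
#' rows are grouped by cluster, clusters ordered from most to least
#' enriched by their mean score (missing cells are masked and excluded
#' from the means), and terms within a cluster ordered by descending
#' mean score.
#'
#' @param assignments [cluster_terms()] output.
#' @param scores Numeric matrix term x comparison (NA = missing).
#' @return List: `matrix` (reordered, NA kept), `mask` (TRUE where
#'   missing), `row_clusters`, `cluster_order`.
#' @export
cluster_heatmap_table <- function(assignments, scores) {
  terms <- assignments$term
  scores <- scores[terms, , drop = FALSE]
  cl <- assignments$cluster
  term_mean <- rowMeans(scores, na.rm = TRUE)
  cl_mean <- tapply(as.vector(t(scores)), rep(cl, each = ncol(scores)),
                    mean, na.rm = TRUE)
  cl_order <- as.integer(names(sort(cl_mean, decreasing = TRUE)))
  ord <- order(match(cl, cl_order), -term_mean, terms)
  list(matrix = scores[ord, , drop = FALSE],
       mask = is.na(scores[ord, , drop = FALSE]),
       row_clusters = cl[ord],
       cluster_order = cl_order)
}
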