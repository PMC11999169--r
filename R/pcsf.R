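#' Read a protein-protein interaction edge list
#'
#' Tab-separated columns `protein_a`, `protein_b`, `confidence` with
#' confidences in (0, 1]. Self-loops are dropped with a warning and
#' duplicate edges are collapsed to their maximum confidence.
#'
#' @param path File path.
#' @return An undirected [igraph::graph] with edge attribute
#'   `confidence`.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "confidence")
  if (!all(need %in% names(tab)))
    stop("format error: expected columns protein_a, protein_b, confidence")
  interaction_graph(tab)
}

#' @rdname read_interactions
#' @param edges Data frame with columns `protein_a`, `protein_b`,
#'   `confidence`.
#' @export
interaction_graph <- function(edges) {
  if (any(!is.finite(edges$confidence)) || any(edges$confidence <= 0) ||
      any(edges$confidence > 1))
    stop("format error: confidence must lie in (0, 1]")
  self <- edges$protein_a == edges$protein_b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  key <- ifelse(edges$protein_a < edges$protein_b,
                paste(edges$protein_a, edges$protein_b, sep = "\r"),
                paste(edges$protein_b, edges$protein_a, sep = "\r"))
  conf <- tapply(edges$confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  el <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2),
                   confidence = as.vector(conf), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Edge costs from interaction confidence
#'
#' The default maps confidence `c` to cost `1 - c`, keeping costs in
#' `[0, 1)` and therefore on the same scale as percentile prizes; the
#' reciprocal `1 / c` is available as an alternative.
#'
#' @param g Interaction graph with edge attribute `confidence`.
#' @param mode `"one_minus"` (default) or `"inverse"`.
#' @return `g` with an added edge attribute `cost`.
#' @export
assign_costs <- function(g, mode = c("one_minus", "inverse")) {
  mode <- match.arg(mode)
  conf <- igraph::E(g)$confidence
  if (is.null(conf) || any(!is.finite(conf)) || any(conf <= 0) || any(conf > 1))
    stop("format error: edge confidences must lie in (0, 1]")
  igraph::E(g)$cost <- if (mode == "one_minus") 1 - conf else 1 / conf
  g
}

# Kruskal minimum spanning forest restricted to edges with cost < omega.
# `order_idx` pre-sorts edges by cost. Returns indices of chosen edges.
msf_reduced <- function(eu, ev, cost, order_idx, in_set, omega, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  chosen <- integer(0)
  for (i in order_idx) {
    if (cost[i] >= omega) break
    a <- eu[i]; b <- ev[i]
    if (!in_set[a] || !in_set[b]) next
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- c(chosen, i)
    }
  }
  chosen
}

# Objective for a fixed selected node set (logical vector): the optimal
# edge structure is the reduced-cost minimum spanning forest, so
#   obj = beta * excluded_prize + omega * |S| + sum(cost - omega over MSF).
pcsf_eval <- function(in_set, prize, beta, omega, eu, ev, cost, order_idx) {
  n <- length(in_set)
  chosen <- msf_reduced(eu, ev, cost, order_idx, in_set, omega, n)
  obj <- beta * sum(prize[!in_set]) + omega * sum(in_set) +
    sum(cost[chosen] - omega)
  list(objective = obj, edges = chosen,
       collected = sum(prize[in_set]))
}

#' Solve the prize-collecting Steiner forest
#'
#' Selects a forest (node-disjoint trees) in the interaction graph
#' minimizing
#' `beta * (sum of prizes of excluded nodes) + (sum of selected edge
#' costs) + omega * (number of trees)`,
#' i.e. it pays each uncollected prize as a penalty, pays edge costs for
#' connectivity, and pays `omega` per tree (without the per-tree charge
#' the trivial all-singletons solution would always win). Nodes selected
#' despite carrying no prize are the "hidden nodes" implicated purely by
#' connectivity.
#'
#' For a fixed node set the optimal edges are closed-form (the minimum
#' spanning forest over reduced costs `cost - omega`), so the search is
#' over node sets only: the default solver runs a deterministic
#' add/remove local search from two starts (all prized nodes; all
#' nodes); `mode = "exact"` enumerates all node subsets and is available
#' for graphs of up to 12 nodes. Ties in objective prefer the larger
#' collected prize, then fewer edges; the heuristic can therefore never
#' report a better objective than the exact optimum.
#'
#' @param g Interaction graph; edge attribute `cost` (see
#'   [assign_costs()]) or `confidence` (costs derived as `1 -
#'   confidence`).
#' @param prizes Named non-negative numeric; nodes absent from the
#'   vector get prize 0.
#' @param beta Prize scaling (> 0).
#' @param omega Per-tree charge (> 0).
#' @param mode `"heuristic"` or `"exact"`.
#' @return List of class `steiner_forest`: `nodes`, `edges` (data frame
#'   `from`, `to`, `cost`), `objective`, `terminals` (selected nodes
#'   with positive prize), `hidden_nodes` (selected nodes with zero
#'   prize), `n_trees`, `prizes`, `parameters`.
#' @export
solve_pcsf <- function(g, prizes, beta = 1, omega = 1,
                       mode = c("heuristic", "exact")) {
  mode <- match.arg(mode)
  stopifnot(beta > 0, omega > 0)
  if (is.null(igraph::E(g)$cost)) g <- assign_costs(g)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  pz <- stats::setNames(numeric(n), nodes)
  common <- intersect(names(prizes), nodes)
  pz[common] <- prizes[common]
  if (any(pz < 0)) stop("prizes must be non-negative")
  el <- igraph::as_data_frame(g, what = "edges")
  eu <- match(el$from, nodes); ev <- match(el$to, nodes)
  cost <- el$cost
  order_idx <- order(cost)
  params <- list(beta = beta, omega = omega, mode = mode)

  empty_forest <- function(warn) {
    if (warn) warning("all prizes are zero; returning the empty forest")
    structure(list(nodes = character(0),
                   edges = data.frame(from = character(0), to = character(0),
                                      cost = numeric(0)),
                   objective = 0, terminals = character(0),
                   hidden_nodes = character(0), n_trees = 0L,
                   prizes = pz, parameters = params),
              class = "steiner_forest")
  }
  if (all(pz == 0)) return(empty_forest(TRUE))

  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    if (cand$objective < best$objective - 1e-12) return(TRUE)
    if (cand$objective > best$objective + 1e-12) return(FALSE)
    if (cand$collected > best$collected + 1e-12) return(TRUE)
    if (cand$collected < best$collected - 1e-12) return(FALSE)
    length(cand$edges) < length(best$edges)
  }

  best <- NULL
  if (mode == "exact") {
    if (n > 12L) stop("exact mode enumerates node subsets; limited to 12 nodes")
    for (mask in 0:(2^n - 1)) {
      in_set <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L
      cand <- pcsf_eval(in_set, pz, beta, omega, eu, ev, cost, order_idx)
      cand$in_set <- in_set
      if (better(cand, best)) best <- cand
    }
  } else {
    # deterministic local search: single-node toggles plus edge-paired
    # add/remove moves (which can cross valleys that need a connector
    # and its partner to enter or leave together)
    moves <- c(lapply(seq_len(n), function(v) v),
               lapply(seq_len(length(eu)), function(i) c(eu[i], ev[i])))
    starts <- list(pz > 0, rep(TRUE, n), rep(FALSE, n))
    for (s in starts) {
      in_set <- s
      cur <- pcsf_eval(in_set, pz, beta, omega, eu, ev, cost, order_idx)
      repeat {
        improved <- FALSE
        for (mv in moves) {
          trial <- in_set
          if (length(mv) == 1L) {
            trial[mv] <- !trial[mv]
          } else if (all(in_set[mv])) {
            trial[mv] <- FALSE
          } else if (!any(in_set[mv])) {
            trial[mv] <- TRUE
          } else next
          cand <- pcsf_eval(trial, pz, beta, omega, eu, ev, cost, order_idx)
          # accept strictly better objective, or equal objective with
          # strictly more collected prize (keeps the search monotone)
          if (cand$objective < cur$objective - 1e-12 ||
              (cand$objective < cur$objective + 1e-12 &&
               cand$collected > cur$collected + 1e-12)) {
            in_set <- trial
            cur <- cand
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      cur$in_set <- in_set
      if (better(cur, best)) best <- cur
    }
  }

  sel <- nodes[best$in_set]
  edges <- data.frame(from = el$from[best$edges], to = el$to[best$edges],
                      cost = cost[best$edges], stringsAsFactors = FALSE)
  structure(list(nodes = sel, edges = edges, objective = best$objective,
                 terminals = sel[pz[sel] > 0],
                 hidden_nodes = sel[pz[sel] == 0],
                 n_trees = length(sel) - nrow(edges),
                 prizes = pz, parameters = params),
            class = "steiner_forest")
}

#' @export
print.steiner_forest <- function(x, ...) {
  cat(sprintf("<steiner_forest> %d node(s), %d edge(s), %d tree(s); objective %.4f\n",
              length(x$nodes), nrow(x$edges), x$n_trees, x$objective))
  cat(sprintf("  terminals: %d  hidden nodes: %d\n",
              length(x$terminals), length(x$hidden_nodes)))
  invisible(x)
}

#' Focal subnetwork of a solved forest
#'
#' Restricts the forest to the members of a gene set plus their direct
#' forest neighbors, annotating each node as `member` or `neighbor` and
#' flagging hidden (zero-prize) nodes.
#'
#' @param forest A [solve_pcsf()] result.
#' @param gene_set Non-empty character vector of gene symbols.
#' @return List of class `focal_subnetwork`: `nodes` (data frame `node`,
#'   `role`, `prize`, `hidden`) and `edges`.
#' @export
focal_subnetwork <- function(forest, gene_set) {
  stopifnot(inherits(forest, "steiner_forest"), length(gene_set) > 0)
  members <- intersect(gene_set, forest$nodes)
  if (!length(members)) {
    warning("no gene-set member present in the forest; empty subnetwork")
    nodes <- data.frame(node = character(0), role = character(0),
                        prize = numeric(0), hidden = logical(0))
    return(structure(list(nodes = nodes,
                          edges = forest$edges[0, , drop = FALSE]),
                     class = "focal_subnetwork"))
  }
  touch <- forest$edges$from %in% members | forest$edges$to %in% members
  nbrs <- setdiff(unique(c(forest$edges$from[touch], forest$edges$to[touch])),
                  members)
  keep <- c(members, nbrs)
  sub_edges <- forest$edges[forest$edges$from %in% keep &
                              forest$edges$to %in% keep, , drop = FALSE]
  nodes <- data.frame(node = keep,
                      role = c(rep("member", length(members)),
                               rep("neighbor", length(nbrs))),
                      prize = forest$prizes[keep],
                      hidden = forest$prizes[keep] == 0,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = sub_edges),
            class = "focal_subnetwork")
}

#' Hub nodes of a subnetwork
#'
#' Ranks nodes by their degree within the subnetwork; ties break by
#' prize (higher first), then lexicographically.
#'
#' @param sub A [focal_subnetwork()] (or any list with `nodes`/`edges`
#'   in the same shape).
#' @param k Number of top nodes to return.
#' @return Data frame `node`, `degree`, `prize`, ranked.
#' @export
hub_nodes <- function(sub, k = 5L) {
  stopifnot(nrow(sub$nodes) > 0)
  deg <- stats::setNames(integer(nrow(sub$nodes)), sub$nodes$node)
  for (col in c("from", "to")) {
    t <- table(sub$edges[[col]])
    deg[names(t)] <- deg[names(t)] + as.integer(t)
  }
  ord <- order(-deg, -sub$nodes$prize[match(names(deg), sub$nodes$node)],
               names(deg))
  out <- data.frame(node = names(deg)[ord], degree = as.integer(deg[ord]),
                    prize = sub$nodes$prize[match(names(deg)[ord],
                                                  sub$nodes$node)],
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::head(out, k)
}

#' Percentile-rank prizes from harmonized kinase tables
#'
#' Selects the kinomic hits — kinases whose harmonized mean percentile
#' exceeds `min_mean_percentile` (default 0.75, the top-quartile rule) —
#' and converts their mean percentiles into prizes by percentile-ranking
#' the hits among themselves (`rank / K`, average ties). All other graph
#' nodes receive prize 0 at solve time. Tables from both chip
#' chemistries are merged first, the larger mean percentile winning on
#' collision.
#'
#' @param ... One or more [harmonize()] tables.
#' @param min_mean_percentile Hit threshold on the harmonized mean
#'   percentile.
#' @return Named numeric vector of prizes in `(0, 1]`, one per hit.
#' @export
prize_from_harmonized <- function(..., min_mean_percentile = 0.75) {
  tabs <- list(...)
  stopifnot(length(tabs) > 0)
  merged <- stats::setNames(numeric(0), character(0))
  for (h in tabs) {
    v <- stats::setNames(h$mean_percentile, h$kinase)
    for (k in names(v))
      merged[k] <- if (k %in% names(merged)) max(merged[k], v[k]) else v[k]
  }
  hits <- merged[merged > min_mean_percentile]
  if (!length(hits)) {
    warning("no kinase exceeds the hit threshold; no prizes assigned")
    return(stats::setNames(numeric(0), character(0)))
  }
  rank(hits, ties.method = "average") / length(hits)
}
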