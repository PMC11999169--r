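graph_from_edges <- function(a, b, conf) {
  interaction_graph(data.frame(protein_a = a, protein_b = b,
                               confidence = conf, stringsAsFactors = FALSE))
}

random_instance <- function(seed, n = 10, p_edge = 0.4) {
  set.seed(seed)
  nodes <- LETTERS[1:n]
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) pairs <- matrix(c(1, 2), 1)
  g <- graph_from_edges(nodes[pairs[, 1]], nodes[pairs[, 2]],
                        runif(nrow(pairs), 0.05, 1))
  prized <- sample(n, max(2, rpois(1, 4)) , replace = FALSE)
  prizes <- setNames(runif(length(prized), 0, 1.5), nodes[prized])
  list(g = g, prizes = prizes)
}

test_that("edge costs are one minus confidence, validated", {
  g <- graph_from_edges(c("A", "B"), c("B", "C"), c(1, 0.4))
  g <- assign_costs(g)
  expect_equal(sort(igraph::E(g)$cost), c(0, 0.6))
  expect_error(
    interaction_graph(data.frame(protein_a = "A", protein_b = "B",
                                 confidence = 0)),
    "format error")
  g2 <- assign_costs(graph_from_edges("A", "B", 0.5), mode = "inverse")
  expect_equal(igraph::E(g2)$cost, 2)
})

test_that("duplicate edges collapse to max confidence; self-loops dropped", {
  expect_warning(
    g <- interaction_graph(data.frame(
      protein_a = c("A", "B", "C"), protein_b = c("B", "A", "C"),
      confidence = c(0.3, 0.9, 0.5))),
    "self-loop")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$confidence, 0.9)
})

test_that("obvious optima are found on two-node instances", {
  g <- assign_costs(graph_from_edges("A", "B", 0.9))  # cost 0.1
  f <- solve_pcsf(g, c(A = 1, B = 1), beta = 1, omega = 1, mode = "exact")
  expect_setequal(f$nodes, c("A", "B"))
  expect_equal(nrow(f$edges), 1L)
  expect_equal(f$objective, 2 * 1 - 0 + 0.1 - 1, tolerance = 1e-12)  # 1.1
  expect_equal(f$n_trees, 1L)

  # connection too expensive: two singleton trees win over paying cost 3
  g2 <- assign_costs(graph_from_edges("A", "B", 0.5))
  igraph::E(g2)$cost <- 3
  f2 <- solve_pcsf(g2, c(A = 1, B = 1), mode = "exact")
  expect_setequal(f2$nodes, c("A", "B"))
  expect_equal(nrow(f2$edges), 0L)
  expect_equal(f2$n_trees, 2L)
})

test_that("all-zero prizes give an empty forest with a warning", {
  g <- graph_from_edges("A", "B", 0.9)
  expect_warning(f <- solve_pcsf(g, c(A = 0)), "empty forest")
  expect_length(f$nodes, 0)
})

test_that("solutions are valid forests partitioned into terminals and hidden nodes", {
  for (s in 1:10) {
    inst <- random_instance(s)
    f <- solve_pcsf(inst$g, inst$prizes)
    if (!length(f$nodes)) next
    expect_true(all(c(f$edges$from, f$edges$to) %in% f$nodes))
    expect_setequal(c(f$terminals, f$hidden_nodes), f$nodes)
    # acyclic: edges <= nodes - trees
    expect_equal(nrow(f$edges), length(f$nodes) - f$n_trees)
    if (nrow(f$edges)) {
      sub <- igraph::graph_from_data_frame(f$edges, directed = FALSE)
      expect_equal(igraph::ecount(sub), igraph::vcount(sub) -
                     igraph::count_components(sub))
    }
  }
})

test_that("heuristic matches the exhaustive optimum on small instances and never beats it", {
  n_match <- 0L
  for (s in 1:12) {
    inst <- random_instance(s)
    fh <- solve_pcsf(inst$g, inst$prizes, mode = "heuristic")
    fe <- solve_pcsf(inst$g, inst$prizes, mode = "exact")
    expect_gte(fh$objective, fe$objective - 1e-9)
    if (abs(fh$objective - fe$objective) < 1e-9) n_match <- n_match + 1L
  }
  expect_gte(n_match, 10L)
})

test_that("in exact mode more prize weight never collects fewer terminals", {
  inst <- random_instance(99, n = 8)
  betas <- c(0.5, 1, 2, 4)
  n_term <- vapply(betas, function(b)
    length(solve_pcsf(inst$g, inst$prizes, beta = b, mode = "exact")$terminals),
    numeric(1))
  expect_true(all(diff(n_term) >= 0))
})

test_that("focal subnetworks take members plus forest neighbors", {
  # star forest: center C joined to L1..L4
  g <- assign_costs(graph_from_edges(rep("C", 4), paste0("L", 1:4),
                                     rep(0.95, 4)))
  pz <- setNames(c(0, rep(1, 4)), c("C", paste0("L", 1:4)))
  f <- solve_pcsf(g, pz, mode = "exact")
  expect_setequal(f$hidden_nodes, "C")   # center selected purely as connector

  sub_all <- focal_subnetwork(f, f$nodes)
  expect_setequal(sub_all$nodes$node, f$nodes)

  sub_c <- focal_subnetwork(f, "C")
  expect_setequal(sub_c$nodes$node, c("C", paste0("L", 1:4)))
  expect_equal(sub_c$nodes$role[sub_c$nodes$node == "C"], "member")
  expect_true(all(sub_c$nodes$role[sub_c$nodes$node != "C"] == "neighbor"))

  expect_warning(sub_0 <- focal_subnetwork(f, "ZZZ"), "no gene-set member")
  expect_equal(nrow(sub_0$nodes), 0L)

  hubs <- hub_nodes(sub_c, k = 3)
  expect_equal(hubs$node[1], "C")
  expect_equal(hubs$degree[1], 4L)
})

test_that("hub ranking breaks degree ties by prize then name", {
  sub <- list(nodes = data.frame(node = c("X", "Y", "Z"),
                                 role = "member",
                                 prize = c(0.1, 0.9, 0.9),
                                 hidden = FALSE, stringsAsFactors = FALSE),
              edges = data.frame(from = c("X", "Y"), to = c("Z", "Z"),
                                 cost = 0))
  h <- hub_nodes(sub, k = 3)
  expect_equal(h$node, c("Z", "Y", "X"))

  # path of 3: middle node is the hub
  sub2 <- list(nodes = data.frame(node = c("A", "B", "C"), role = "member",
                                  prize = 0, hidden = TRUE,
                                  stringsAsFactors = FALSE),
               edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                                  cost = 0))
  expect_equal(hub_nodes(sub2, 1)$node, "B")
})

test_that("hit-filtered prizes percentile-rank the merged harmonized tables", {
  h1 <- structure(data.frame(kinase = c("K1", "K2", "K3"),
                             mean_percentile = c(0.9, 0.8, 0.2)),
                  class = c("harmonized_table", "data.frame"))
  h2 <- structure(data.frame(kinase = c("K2", "K4"),
                             mean_percentile = c(0.95, 0.5)),
                  class = c("harmonized_table", "data.frame"))
  pz <- prize_from_harmonized(h1, h2)
  expect_setequal(names(pz), c("K1", "K2"))      # only > 0.75 survive
  expect_equal(unname(pz["K2"]), 1)              # merged max 0.95 wins
  expect_equal(unname(pz["K1"]), 0.5)
})
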