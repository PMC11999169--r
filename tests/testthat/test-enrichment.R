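# brute-force hypergeometric upper tail by enumeration of the pmf
enum_upper_tail <- function(k, K, N, n) {
  kk <- 0:min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

test_that("ORA p-values match closed forms and enumeration", {
  u <- paste0("g", 1:10)
  lib <- list(full = u[1:5], part = u[1:4])
  r <- ora(u[1:5], lib, u, combined = "neglogp")
  expect_equal(r$p_value[r$term == "full"], 1 / choose(10, 5),
               tolerance = 1e-12)
  # overlap 4 of set 4 within query 5: P[X >= 4]
  expect_equal(r$p_value[r$term == "part"], enum_upper_tail(4, 4, 10, 5),
               tolerance = 1e-12)

  # spec-style instance: query 5, set 4, universe 10, overlap 2
  lib2 <- list(t = u[c(1, 2, 6, 7)])
  r2 <- ora(u[1:5], lib2, u, combined = "neglogp")
  expect_equal(r2$p_value, 0.7380952, tolerance = 1e-6)
  expect_equal(r2$fdr, r2$p_value)   # single tested term: BH identity
  expect_equal(r2$combined_score, -log(r2$p_value))
})

test_that("ORA agrees with exhaustive enumeration on all small universes", {
  set.seed(4)
  for (rep in 1:20) {
    N <- sample(5:15, 1)
    u <- paste0("g", seq_len(N))
    n <- sample(2:(N - 1), 1)
    K <- sample(1:N, 1)
    q <- sample(u, n)
    lib <- list(s = sample(u, K))
    r <- ora(q, lib, u, combined = "neglogp")
    expect_equal(r$p_value, enum_upper_tail(r$overlap, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("BH correction is the step-up procedure and is monotone", {
  u <- paste0("g", 1:40)
  set.seed(9)
  lib <- lapply(1:8, function(i) sample(u, sample(4:10, 1)))
  names(lib) <- paste0("t", 1:8)
  r <- ora(u[1:12], lib, u, combined = "neglogp")
  expect_equal(r$fdr, p.adjust(r$p_value, "BH"))
  o <- order(r$p_value)
  expect_true(all(diff(r$fdr[o]) >= -1e-12))
  expect_true(all(r$fdr >= 0 & r$fdr <= 1))
  expect_identical(r$significant, r$fdr < 0.05)
})

test_that("ORA input contracts hold", {
  u <- paste0("g", 1:10)
  expect_error(ora(character(0), list(s = u[1:2]), u), "empty query")
  expect_error(ora("alien", list(s = u[1:2]), u), "subset")
  # a set with no universe overlap is skipped
  r <- ora(u[1:3], list(a = u[1:2], b = "other"), u, combined = "neglogp")
  expect_equal(r$term, "a")
})

test_that("permutation combined score is seeded and favors strong terms", {
  u <- paste0("g", 1:30)
  lib <- list(hit = u[1:6], decoy1 = u[11:16], decoy2 = u[21:26])
  q <- u[1:6]
  r1 <- ora(q, lib, u, n_perm = 50, seed = 5)
  r2 <- ora(q, lib, u, n_perm = 50, seed = 5)
  expect_identical(r1, r2)
  expect_gt(r1$combined_score[r1$term == "hit"],
            max(r1$combined_score[r1$term != "hit"]))
})

test_that("well-separated embedding bundles cluster perfectly with correct MRTs", {
  set.seed(2)
  proto <- rbind(c(10, 0, 0), c(0, 10, 0))
  terms <- c(paste0("a", 1:4), paste0("b", 1:4))
  emb <- proto[rep(1:2, each = 4), ] + matrix(rnorm(24, 0, 0.05), 8, 3)
  rownames(emb) <- terms
  cl <- cluster_terms(terms, emb, k = 2)
  expect_equal(length(unique(cl$cluster[1:4])), 1L)
  expect_equal(length(unique(cl$cluster[5:8])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[5])
  # each MRT is the bundle member most cosine-similar to its bundle mean
  for (cid in unique(cl$cluster)) {
    members <- cl[cl$cluster == cid, ]
    expect_equal(members$term[members$is_mrt],
                 members$term[which.max(members$sim_to_centroid)])
  }
})

test_that("degenerate embedding geometries collapse with lexicographic MRT", {
  terms <- c("zeta", "alpha", "mid")
  emb <- matrix(rep(c(1, 2, 3), each = 3), 3, 3,
                dimnames = list(terms, NULL))
  cl <- cluster_terms(terms, emb, k = "auto")
  expect_equal(unique(cl$cluster), 1L)
  expect_equal(cl$term[cl$is_mrt], "alpha")   # tie broken lexicographically

  # k == n: every term its own cluster and own MRT
  set.seed(3)
  emb2 <- matrix(rnorm(12), 4, 3,
                 dimnames = list(paste0("t", 1:4), NULL))
  cl2 <- cluster_terms(paste0("t", 1:4), emb2, k = 4)
  expect_equal(sort(unique(cl2$cluster)), 1:4)
  expect_true(all(cl2$is_mrt))
})

test_that("clustering is invariant to term input order", {
  set.seed(6)
  terms <- paste0("t", 1:9)
  emb <- rbind(matrix(rnorm(9, 5, 0.1), 3),
               matrix(rnorm(9, -5, 0.1), 3),
               matrix(rnorm(9, c(5, -5, 5), 0.1), 3, byrow = TRUE))
  emb <- matrix(rnorm(9 * 4), 9, 4)
  emb[1:4, 1] <- emb[1:4, 1] + 8
  emb[5:9, 2] <- emb[5:9, 2] + 8
  rownames(emb) <- terms
  c1 <- cluster_terms(terms, emb, k = 2)
  perm <- rev(terms)
  c2 <- cluster_terms(perm, emb, k = 2)
  part1 <- unname(lapply(split(c1$term, c1$cluster), sort))
  part2 <- unname(lapply(split(c2$term, c2$cluster), sort))
  expect_setequal(part1, part2)
  expect_setequal(c1$term[c1$is_mrt], c2$term[c2$is_mrt])
})

test_that("terms without embeddings are excluded with a warning", {
  emb <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_warning(cl <- cluster_terms(c("a", "b", "ghost"), emb, k = 1),
                 "ghost")
  expect_setequal(cl$term, c("a", "b"))
  expect_error(suppressWarnings(cluster_terms("ghost", emb)), "no term")
})

test_that("heatmap tables order clusters and terms by enrichment", {
  asg <- data.frame(term = c("t1", "t2", "t3", "t4"),
                    cluster = c(1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  sc <- matrix(c(3, 1, 5, 5, NA, 2, 6, 4), 4, 2,
               dimnames = list(asg$term, c("hpc", "str")))
  ht <- cluster_heatmap_table(asg, sc)
  # cluster means: c1 = mean(3,1,NA->excluded,2)=2, c2 = mean(5,5,6,4)=5
  expect_equal(ht$cluster_order, c(2L, 1L))
  expect_equal(rownames(ht$matrix), c("t3", "t4", "t1", "t2"))
  expect_true(ht$mask["t1", "str"])
  # single cluster, scores {t1:3, t2:1} -> t1 first
  ht2 <- cluster_heatmap_table(asg[1:2, ],
                               matrix(c(3, 1), 2, 1,
                                      dimnames = list(c("t1", "t2"), "c")))
  expect_equal(rownames(ht2$matrix), c("t1", "t2"))
})
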