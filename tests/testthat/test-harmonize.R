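test_that("percentile normalization follows rank/K with average ties", {
  r <- ranker_output("r", c(A = 3, B = 2, C = 1))
  expect_equal(percentile_normalize(r),
               c(A = 1, B = 2 / 3, C = 1 / 3))
  r_tied <- ranker_output("r", c(A = 5, B = 5, C = 5, D = 5))
  expect_equal(unname(percentile_normalize(r_tied)),
               rep((4 + 1) / (2 * 4), 4))
  expect_equal(unname(percentile_normalize(ranker_output("r", c(X = 9)))), 1)
  # lower_better orientation reverses the ordering
  r_lo <- ranker_output("r", c(A = 3, B = 2, C = 1), "lower_better")
  expect_equal(percentile_normalize(r_lo), c(A = 1 / 3, B = 2 / 3, C = 1))
})

test_that("percentiles are invariant under strictly monotone score transforms", {
  set.seed(1)
  s <- setNames(rnorm(15), paste0("K", 1:15))
  p1 <- percentile_normalize(ranker_output("r", s))
  p2 <- percentile_normalize(ranker_output("r", exp(3 * s + 1)))
  expect_equal(p1, p2)
})

test_that("harmonization averages over present rankers and records absence", {
  al <- data.frame(alias = c("K1", "K2", "K3"), symbol = c("K1", "K2", "K3"),
                   family = "FAM", stringsAsFactors = FALSE)
  # percentiles: r1 {K1:1, K2:.5}, r2 {K1:.9? ...}; build scores to control
  r1 <- ranker_output("r1", c(K1 = 10, K2 = 5))        # pct K1=1, K2=.5
  r2 <- ranker_output("r2", c(K1 = 1, K2 = 2, K3 = 3)) # pct 1/3, 2/3, 1
  h <- harmonize(list(r1, r2), al)
  k1 <- h[h$kinase == "K1", ]
  expect_equal(k1$mean_percentile, mean(c(1, 1 / 3)))
  expect_equal(k1$median_percentile, stats::median(c(1, 1 / 3)))
  k3 <- h[h$kinase == "K3", ]
  expect_true(is.na(k3$pct_r1))          # absent from r1, not imputed
  expect_equal(k3$mean_percentile, 1)
  # absent_as_zero imputes missing rankers as zero evidence
  h0 <- harmonize(list(r1, r2), al, absent_as_zero = TRUE)
  expect_equal(h0$mean_percentile[h0$kinase == "K3"], 0.5)
  # mean/median stay within the per-ranker percentile range
  rng <- cbind(h$pct_r1, h$pct_r2)
  expect_true(all(h$mean_percentile >= apply(rng, 1, min, na.rm = TRUE) - 1e-12))
  expect_true(all(h$mean_percentile <= apply(rng, 1, max, na.rm = TRUE) + 1e-12))
})

test_that("alias mapping flags duplicates and reports unknowns", {
  al <- default_alias_map()
  dup <- ranker_output("r", c(ERK1 = 2, MAPK3 = 3))  # both map to MAPK3
  expect_error(harmonize(list(dup), al), "ambiguous duplicate")
  unk <- ranker_output("r", c(NOT_A_KINASE = 1, CHUK = 2))
  expect_warning(h <- harmonize(list(unk), al), "NOT_A_KINASE")
  expect_true("NOT_A_KINASE" %in% h$kinase)  # kept, not dropped
})

test_that("family-level rankers expand to member kinases", {
  al <- default_alias_map()
  r <- ranker_output("krsa", c(IKK = 5, PKD = 1), level = "family")
  h <- suppressWarnings(harmonize(list(r), al))
  ikk <- h[h$family == "IKK", ]
  expect_true(all(c("CHUK", "IKBKB", "IKBKE", "TBK1") %in% ikk$kinase))
  expect_gt(min(ikk$pct_krsa), max(h$pct_krsa[h$family == "PKD"]))
})

test_that("harmonization is invariant to ranker order", {
  al <- default_alias_map()
  r1 <- ranker_output("r1", c(CHUK = 1, IKBKB = 3, TBK1 = 2))
  r2 <- ranker_output("r2", c(CHUK = 5, PRKD1 = 1))
  h12 <- harmonize(list(r1, r2), al)
  h21 <- harmonize(list(r2, r1), al)
  expect_equal(h12$mean_percentile, h21$mean_percentile)
  expect_equal(h12$kinase, h21$kinase)
})

test_that("bubble tables carry quartiles with the ceiling rule", {
  al <- data.frame(alias = c("K1", "K2", "K3", "K4"),
                   symbol = c("K1", "K2", "K3", "K4"),
                   family = c("F1", "F1", "F2", "F2"),
                   stringsAsFactors = FALSE)
  r1 <- ranker_output("r1", c(K1 = 4, K2 = 3, K3 = 2, K4 = 1))
  r2 <- ranker_output("r2", c(K1 = 1))
  h <- harmonize(list(r1, r2), al)
  # r1 percentiles 1, .75, .5, .25 -> quartiles 4, 3, 2, 1
  expect_equal(h$q_r1[match(c("K1", "K2", "K3", "K4"), h$kinase)],
               c(4, 3, 2, 1))
  bt <- bubble_table(h)
  expect_equal(nrow(bt), 8L)  # 4 kinases x 2 rankers
  expect_true(is.na(bt$quartile[bt$kinase == "K3" & bt$ranker == "r2"]))
  expect_equal(bt$quartile[bt$kinase == "K1" & bt$ranker == "r2"], 4)
  # grouped by family then kinase
  expect_equal(bt$family, sort(bt$family))
})
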