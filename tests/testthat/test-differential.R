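make_matrix <- function(values, groups, chips) {
  # values: named list peptide -> per-column signal
  cols <- sprintf("%s.%s", chips, names(groups))
  m <- do.call(rbind, values)
  dimnames(m) <- list(names(values), cols)
  structure(m,
            col_info = data.frame(column = cols, chip_id = chips,
                                  sample_id = names(groups),
                                  group = unname(groups),
                                  stringsAsFactors = FALSE),
            class = c("peptide_signal_matrix", "matrix", "array"))
}

two_chip_matrix <- function(a_vals, b_vals) {
  # one sample per group on each of two chips, same values per chip
  make_matrix(
    values = Map(function(a, b) c(a, b, a, b), a_vals, b_vals),
    groups = c(sA = "A", sB = "B", sA = "A", sB = "B"),
    chips = c("c1", "c1", "c2", "c2"))
}

test_that("log2 fold change follows the per-chip ratio and averaging rules", {
  mat <- two_chip_matrix(list(p1 = 100, p2 = 50), list(p1 = 200, p2 = 50))
  fc <- log2_fold_change(mat, "A", "B")
  expect_equal(fc$mean_log2fc[fc$peptide_id == "p1"], 1)
  expect_equal(fc$mean_log2fc[fc$peptide_id == "p2"], 0)
  expect_false(fc$flagged[fc$peptide_id == "p2"])
  expect_false(fc$hit15[fc$peptide_id == "p2"])
})

test_that("a mean log2FC of exactly 0.2 is not flagged (strict threshold)", {
  # per-chip values 0.3 and 0.1 average to 0.2
  mat <- make_matrix(values = list(p1 = c(100, 100 * 2^0.3, 100, 100 * 2^0.1)),
                     groups = c(sA = "A", sB = "B", sA = "A", sB = "B"),
                     chips = c("c1", "c1", "c2", "c2"))
  fc <- log2_fold_change(mat, "A", "B")
  expect_equal(fc$mean_log2fc, 0.2)
  expect_false(fc$flagged)
  # but 0.2 log2FC is a 14.9% linear change: just below the 15% hit rule
  expect_false(fc$hit15)
})

test_that("hit15 works on the linear fold-change scale, asymmetrically in log2", {
  lfc_up <- log2(1.151)    # just above +15%
  lfc_dn <- log2(0.849)    # just beyond -15%
  mat <- two_chip_matrix(
    list(up = 100, dn = 100, mid = 100),
    list(up = 100 * 2^lfc_up, dn = 100 * 2^lfc_dn, mid = 100 * 2^0.21))
  fc <- log2_fold_change(mat, "A", "B")
  expect_true(fc$hit15[fc$peptide_id == "up"])
  expect_true(fc$hit15[fc$peptide_id == "dn"])
  expect_true(fc$flagged[fc$peptide_id == "mid"])   # 0.21 > 0.2
  expect_true(fc$hit15[fc$peptide_id == "mid"])     # 2^0.21 - 1 = 15.7%
  # -0.21 log2FC is only a 13.5% linear drop: flagged but not a hit
  mat2 <- two_chip_matrix(list(p = 100), list(p = 100 * 2^-0.21))
  fc2 <- log2_fold_change(mat2, "A", "B")
  expect_true(fc2$flagged)
  expect_false(fc2$hit15)
})

test_that("swapping the groups negates fold changes and flips directions", {
  sim <- quick_sim(seed = 21, noise_sd = 1, planted = c(IKK = 0.8))
  mat <- build_signal_matrix(apply_qc(fit_kinetics(sim$reads)))
  ab <- log2_fold_change(mat, "sedentary", "exercise")
  ba <- log2_fold_change(mat, "exercise", "sedentary")
  expect_equal(ba$mean_log2fc, -ab$mean_log2fc)
  map <- demo_kinase_map(array_layout("STK"))
  t_ab <- ternary_score(ab, map)
  t_ba <- ternary_score(ba, map)
  ok <- t_ab$direction != "no_data"
  flip <- c(up = "down", down = "up", no_change = "no_change")
  expect_identical(t_ba$direction[ok], unname(flip[t_ab$direction[ok]]))
})

test_that("ternary scoring applies the +1/0/-1 rule with strict boundaries", {
  fc <- structure(data.frame(peptide_id = paste0("p", 1:6),
                             mean_log2fc = c(0.5, 0.3, -0.1, 0.25, -0.25, 0.2)),
                  class = c("fold_change_table", "data.frame"))
  map <- structure(list(K1 = c("p1", "p2", "p3"),
                        K2 = c("p4", "p5"),
                        K3 = "p6",
                        K4 = "absent_pep"),
                   class = "kinase_map")
  ts <- ternary_score(fc, map)
  expect_equal(ts$mean_value[ts$kinase == "K1"], 2 / 3, tolerance = 1e-12)
  expect_equal(ts$direction[ts$kinase == "K1"], "up")
  expect_equal(ts$mean_value[ts$kinase == "K2"], 0)
  expect_equal(ts$direction[ts$kinase == "K2"], "no_change")
  expect_equal(ts$mean_value[ts$kinase == "K3"], 0)  # exactly 0.2 scores 0
  expect_equal(ts$direction[ts$kinase == "K4"], "no_data")
  expect_true(all(abs(ts$mean_value) <= 1, na.rm = TRUE))
})

test_that("heatmap matrices are row-normalized with stable orderings", {
  m <- rbind(a = c(1, 2, 3), b = c(6, 4, 2), c = c(5, 5, 5))
  expect_warning(hm <- heatmap_matrix(m), "zero-variance")
  expect_equal(unname(hm$matrix["a", ]), c(-1, 0, 1))
  expect_equal(unname(hm$matrix["c", ]), c(0, 0, 0))
  expect_equal(hm$metadata$linkage, "average")
  hm2 <- suppressWarnings(heatmap_matrix(m))
  expect_identical(hm$row_order, hm2$row_order)
  expect_error(heatmap_matrix(m[1, , drop = FALSE]), "at least 2")
})
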