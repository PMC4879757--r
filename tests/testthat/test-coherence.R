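test_that("pair regression recovers exact linear relations and hand cases", {
  m <- toy_matrix(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
  r <- pair_regression(m, "a", "b")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  # hand evaluation: cov((0,1,2),(1,0,1)) = 0 exactly
  m0 <- toy_matrix(cbind(a = c(0, 1, 2), b = c(1, 0, 1)))
  expect_equal(pair_regression(m0, "a", "b")$r_squared, 0)
  # degenerate input names the offending gene
  mc <- toy_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_error(pair_regression(mc, "a", "b"), "'b' has zero variance")
})

test_that("r-squared is symmetric and invariant to positive affine rescaling", {
  m <- random_matrix(25, 4, seed = 41)
  r_ab <- pair_regression(m, "g1", "g2")$r_squared
  r_ba <- pair_regression(m, "g2", "g1")$r_squared
  expect_equal(r_ab, r_ba)
  scaled <- unclass(m)
  scaled[, "g1"] <- 3.7 * scaled[, "g1"] + 11
  ms <- toy_matrix(scaled, cells = cell_ids(m), genes = gene_ids(m))
  expect_equal(pair_regression(ms, "g1", "g2")$r_squared, r_ab, tolerance = 1e-12)
})

test_that("regression agrees with lm/cor on both scales", {
  m <- random_matrix(30, 2, seed = 42)
  a <- unclass(m)[, 1]; b <- unclass(m)[, 2]
  r <- pair_regression(m, "g1", "g2")
  fit <- stats::lm(b ~ a)
  expect_equal(r$slope, unname(stats::coef(fit)[2]))
  expect_equal(r$r_squared, stats::cor(a, b)^2)
  rl <- pair_regression(m, "g1", "g2", scale = "log10p")
  expect_equal(rl$r_squared, stats::cor(log10(a + 1), log10(b + 1))^2)
})

test_that("positivity split partitions cells into positive/negative/ambiguous", {
  m <- toy_matrix(matrix(c(0, 0.05, 0.5, 5), 4, 1), genes = "g",
                  cells = c("c1", "c2", "c3", "c4"))
  sp <- split_by_positivity(m, "g")
  expect_identical(sp$positive, "c4")
  expect_identical(sp$negative, c("c1", "c2"))
  expect_identical(sp$excluded, "c3")
  expect_setequal(c(sp$positive, sp$negative, sp$excluded), cell_ids(m))
  # all positive / all zero edge cases
  sp_hi <- split_by_positivity(toy_matrix(matrix(c(2, 3, 4), 3, 1), genes = "g"), "g")
  expect_length(sp_hi$negative, 0); expect_length(sp_hi$excluded, 0)
  sp_lo <- split_by_positivity(toy_matrix(matrix(0, 3, 1), genes = "g"), "g")
  expect_length(sp_lo$positive, 0)
})

test_that("predictability test compares response levels across the split", {
  # positive group responses {10, 20} vs negative {1, 2}: exact p = 1/3
  m <- toy_matrix(cbind(pred = c(5, 9, 0, 0.01),
                        resp = c(10, 20, 1, 2)),
                  cells = c("c1", "c2", "c3", "c4"))
  r <- predictability_test(m, "pred", "resp")
  expect_true(r$applicable)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$mean_response_positive, 15)
  expect_equal(r$mean_response_negative, 1.5)
  expect_equal(r$n_positive + r$n_negative + r$excluded_intermediate, n_cells(m))
  # identical response distributions -> p = 1
  m_same <- toy_matrix(cbind(pred = c(5, 9, 0, 0.01), resp = c(1, 2, 1, 2)))
  expect_equal(predictability_test(m_same, "pred", "resp")$p_value, 1)
  # predictor positive everywhere -> not applicable, no exception
  m_all <- toy_matrix(cbind(pred = c(5, 9, 8, 7), resp = c(1, 2, 3, 4)))
  r_na <- predictability_test(m_all, "pred", "resp")
  expect_false(r_na$applicable)
  expect_true(is.na(r_na$p_value))
})

test_that("coherence screen enumerates requested pair sets with class labels", {
  set.seed(43)
  vals <- matrix(stats::rlnorm(6 * 4, 1, 1), 6, 4)
  m <- toy_matrix(vals, genes = c("Arg1", "Mrc1", "Tnf", "Il1b"))
  panel <- toy_panel()
  all_rows <- coherence_screen(m, panel, "all")
  expect_equal(nrow(all_rows), choose(4, 2))
  within <- coherence_screen(m, panel, "within_class")
  expect_equal(nrow(within), 2)
  expect_true(all(within$class_a == within$class_b))
  across <- coherence_screen(m, panel, "across_class")
  expect_equal(nrow(across), 4)
  expect_true(all(across$class_a != across$class_b))
  # two same-class genes only: across-class screen yields zero rows
  m2 <- toy_matrix(vals[, 1:2], genes = c("Arg1", "Mrc1"))
  expect_equal(nrow(coherence_screen(m2, panel, "across_class")), 0)
  # degenerate gene skipped with a message, screen continues
  vals_deg <- vals; vals_deg[, 4] <- 2
  m_deg <- toy_matrix(vals_deg, genes = c("Arg1", "Mrc1", "Tnf", "Il1b"))
  expect_message(res <- coherence_screen(m_deg, panel, "all"), "skipping")
  expect_equal(nrow(res), choose(4, 2) - 3)
})

test_that("across-class pairs on admixture data are anti-correlated vs the null regime", {
  d <- simulate_dataset(sim_config("admixture", n_cells = 60, seed = 44))
  across <- coherence_screen(d$matrix, d$config$panel, "across_class",
                             scale = "log10p")
  expect_true(all(across$slope < 0))
  dn <- simulate_dataset(sim_config("null", n_cells = 60, seed = 44))
  null_across <- coherence_screen(dn$matrix, dn$config$panel, "across_class",
                                  scale = "log10p")
  expect_gt(min(across$r_squared), stats::median(null_across$r_squared))
})

test_that("across-class r-squared stays near zero on independent markers", {
  meds <- vapply(1:100, function(s) {
    m <- random_matrix(45, 6, seed = 500 + s)
    panel <- marker_panel(gene_ids(m),
                          rep(c("M(IL4)", "M(LPS,IFNg)"), each = 3))
    stats::median(coherence_screen(m, panel, "across_class")$r_squared)
  }, numeric(1))
  expect_lt(stats::median(meds), 0.1)
})
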