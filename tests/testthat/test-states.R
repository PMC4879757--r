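test_that("state calls record genes and classes above the tier", {
  m <- toy_matrix(cbind(Arg1 = c(150, 50), Tnf = c(120, 200), Il4ra = c(0, 0)),
                  cells = c("c1", "c2"))
  panel <- marker_panel(c("Arg1", "Tnf", "Il4ra"),
                        c("M(IL4)", "M(LPS,IFNg)", "M(IL10)"))
  st <- call_states(m, panel, 100)
  expect_setequal(st[[1]]$classes_hit, c("M(IL4)", "M(LPS,IFNg)"))
  expect_setequal(st[[2]]$classes_hit, "M(LPS,IFNg)")
  # tier comparison is strict: a value exactly at the tier is not called
  m_at <- toy_matrix(cbind(Arg1 = c(100, 101)), cells = c("c1", "c2"))
  st_at <- call_states(m_at, panel, 100)
  expect_length(st_at[[1]]$classes_hit, 0)
  expect_identical(st_at[[2]]$classes_hit, "M(IL4)")
  expect_error(call_states(toy_matrix(matrix(1, 2, 1), genes = "other"), panel, 100),
               "no panel genes")
})

test_that("multiclass counting matches brute force and handles empty profiles", {
  m <- toy_matrix(cbind(Arg1 = c(150, 150, 0), Tnf = c(120, 0, 0)),
                  cells = c("c1", "c2", "c3"))
  panel <- marker_panel(c("Arg1", "Tnf"), c("M(IL4)", "M(LPS,IFNg)"))
  st <- call_states(m, panel, 100)
  r <- count_multiclass_cells(st, 2)
  expect_equal(r$count, 1)
  expect_equal(r$fraction, 1 / 3)
  expect_equal(count_multiclass_cells(call_states(
    toy_matrix(matrix(0, 3, 2), genes = c("Arg1", "Tnf")), panel, 100), 2)$count, 0)
  expect_error(count_multiclass_cells(st, 1), "at least 2")
})

test_that("multiclass counts are non-increasing in min_classes and tier", {
  d <- simulate_dataset(sim_config("mixed", n_cells = 60, seed = 51))
  panel <- d$config$panel
  fr_by_k <- vapply(2:4, function(k) {
    count_multiclass_cells(call_states(d$matrix, panel, 100), k)$fraction
  }, numeric(1))
  expect_true(all(diff(fr_by_k) <= 0))
  fr_by_tier <- vapply(c(0.1, 1, 10, 100), function(t) {
    count_multiclass_cells(call_states(d$matrix, panel, t), 2)$fraction
  }, numeric(1))
  expect_true(all(diff(fr_by_tier) <= 0))
})

test_that("co-occurrence flags engineered mutual exclusivity", {
  # gene a above tier exactly when gene b is below it, 10/10 split
  a <- c(rep(200, 10), rep(0, 10))
  b <- c(rep(0, 10), rep(200, 10))
  m <- toy_matrix(cbind(Arg1 = a, Tnf = b))
  panel <- marker_panel(c("Arg1", "Tnf"), c("M(IL4)", "M(LPS,IFNg)"))
  r <- cooccurrence_permutation(m, panel, tier = 100, n_perm = 999, seed = 9)
  expect_equal(r$n11, 0)
  expect_lt(r$odds_ratio, 1)
  expect_lte(r$perm_p, 0.05)
})

test_that("degenerate all-zero genes give corrected OR and p = 1", {
  m <- toy_matrix(cbind(Arg1 = c(200, 0, 200, 0), Tnf = rep(0, 4)))
  panel <- marker_panel(c("Arg1", "Tnf"), c("M(IL4)", "M(LPS,IFNg)"))
  r <- cooccurrence_permutation(m, panel, tier = 100, n_perm = 99, seed = 9)
  expect_equal(r$perm_p, 1)
  expect_true(is.finite(r$log_or))
  expect_gt(r$odds_ratio, 0)
})

test_that("co-occurrence results are seed-deterministic and relabel-invariant", {
  d <- simulate_dataset(sim_config("mixed", n_cells = 40, seed = 52))
  panel <- d$config$panel
  r1 <- cooccurrence_permutation(d$matrix, panel, n_perm = 199, seed = 7)
  r2 <- cooccurrence_permutation(d$matrix, panel, n_perm = 199, seed = 7)
  expect_identical(r1, r2)
  # renaming cells leaves everything unchanged (values untouched)
  ren <- unclass(d$matrix)
  rownames(ren) <- sprintf("other_%02d", seq_len(nrow(ren)))
  r3 <- cooccurrence_permutation(expr_matrix(ren), panel, n_perm = 199, seed = 7)
  expect_equal(r3$perm_p, r1$perm_p)
  # reordering cells leaves the observed statistics unchanged
  set.seed(99)
  perm <- sample(seq_len(n_cells(d$matrix)))
  m_rel <- expr_matrix(unclass(d$matrix)[perm, , drop = FALSE])
  r4 <- cooccurrence_permutation(m_rel, panel, n_perm = 199, seed = 7)
  expect_equal(r4$n11, r1$n11)
  expect_equal(r4$log_or, r1$log_or)
})

test_that("contingency counts always sum to the number of cells", {
  d <- simulate_dataset(sim_config("mixed", n_cells = 35, seed = 53))
  r <- cooccurrence_permutation(d$matrix, d$config$panel, n_perm = 99, seed = 1)
  expect_true(all(r$n11 + r$n10 + r$n01 + r$n00 == 35))
  expect_true(all(r$perm_p > 0 & r$perm_p <= 1))
  expect_true(all(r$odds_ratio > 0))
})

test_that("verdict classifies the three regimes", {
  mk <- function(p, or) data.frame(perm_p = p, odds_ratio = or, log_or = log(or))
  expect_equal(admixture_vs_mixed_verdict(
    mk(rep(0.001, 10), rep(0.1, 10)))$verdict, "admixture-like")
  expect_equal(admixture_vs_mixed_verdict(
    mk(rep(0.8, 10), rep(1, 10)))$verdict, "mixed-state-like")
  expect_equal(admixture_vs_mixed_verdict(mk(0.2, 0.5))$verdict, "indeterminate")
  expect_error(admixture_vs_mixed_verdict(mk(numeric(0), numeric(0))), "no across-class")
})

test_that("mixed-scenario across-class odds ratios centre on 1 at large n", {
  d <- simulate_dataset(sim_config("mixed", n_cells = 1000, seed = 54))
  r <- cooccurrence_permutation(d$matrix, d$config$panel, n_perm = 99, seed = 2)
  med_or <- stats::median(r$odds_ratio)
  expect_gt(med_or, 0.8)
  expect_lt(med_or, 1.25)
})

test_that("type-I error approaches nominal on large independent populations", {
  rates <- vapply(1:10, function(s) {
    d <- simulate_dataset(sim_config("null", n_cells = 1000, seed = 9000 + s))
    r <- cooccurrence_permutation(d$matrix, d$config$panel, tier = 1,
                                  n_perm = 999, seed = s)
    mean(r$perm_p < 0.05)
  }, numeric(1))
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})
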