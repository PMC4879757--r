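test_that("noise-free admixture places markers exactly at the two regimes", {
  cfg <- sim_config("admixture", n_cells = 12, sigma = 0, dropout_prob = 0,
                    n_background_genes = 10, seed = 71)
  d <- simulate_dataset(cfg)
  panel <- cfg$panel
  for (i in seq_len(12)) {
    own <- panel$gene[panel$class == d$true_labels[i]]
    other <- setdiff(panel$gene, own)
    expect_equal(unname(unclass(d$matrix)[i, own]), rep(200, length(own)),
                 tolerance = 1e-12)
    expect_equal(unname(unclass(d$matrix)[i, other]), rep(0.5, length(other)),
                 tolerance = 1e-12)
  }
  # pure cells never co-express two classes above the very-high tier
  st <- call_states(d$matrix, panel, 100)
  expect_equal(count_multiclass_cells(st, 2)$count, 0)
})

test_that("largest-remainder class allocation is deterministic and exact", {
  alloc <- polcoherence:::allocate_classes(c(a = 0.5, b = 0.3, c = 0.2), 10)
  expect_identical(alloc, c(a = 5L, b = 3L, c = 2L))
  alloc2 <- polcoherence:::allocate_classes(c(a = 1 / 3, b = 1 / 3, c = 1 / 3), 10)
  expect_equal(sum(alloc2), 10)
  expect_identical(alloc2, c(a = 4L, b = 3L, c = 3L))  # ties broken by order
  d <- simulate_dataset(sim_config("admixture", n_cells = 45, seed = 72))
  expect_equal(as.integer(sort(table(d$true_labels))), c(11L, 11L, 11L, 12L))
})

test_that("mixed scenario activates classes independently at the stated rate", {
  cfg <- sim_config("mixed", n_cells = 10000, dropout_prob = 0,
                    n_background_genes = 0, seed = 73)
  d <- simulate_dataset(cfg)
  classes <- unique(cfg$panel$class)
  act <- vapply(d$active_classes,
                function(a) all(classes[1:2] %in% a), logical(1))
  # both of two given classes active: 0.25 +/- binomial error at n = 10000
  expect_equal(mean(act), 0.25, tolerance = 0.02 / 0.25)
})

test_that("generation is bit-deterministic in the seed and varies across seeds", {
  d1 <- simulate_dataset(sim_config("mixed", n_cells = 20, seed = 74))
  d2 <- simulate_dataset(sim_config("mixed", n_cells = 20, seed = 74))
  expect_identical(unclass(d1$matrix), unclass(d2$matrix))
  expect_identical(d1$qc, d2$qc)
  d3 <- simulate_dataset(sim_config("mixed", n_cells = 20, seed = 75))
  expect_false(identical(unclass(d1$matrix), unclass(d3$matrix)))
  # simulate_qc reproduces the QC table embedded in the dataset
  expect_identical(simulate_qc(d1$config), d1$qc)
})

test_that("dropout produces the configured fraction of exact zeros", {
  cfg <- sim_config("null", n_cells = 100, n_background_genes = 200,
                    dropout_prob = 0.2, seed = 76)
  d <- simulate_dataset(cfg)
  n <- length(d$matrix)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(unclass(d$matrix) == 0) - 0.2), 3 * se)
})

test_that("QC generation fails the configured number of cells, one criterion each", {
  cfg <- sim_config("null", n_cells = 63, qc_fail_fraction = 18 / 63, seed = 77)
  qc <- simulate_qc(cfg)
  kept <- filter_cells(qc)
  expect_length(kept, 45)
  failed <- qc[!qc$cell_id %in% kept, ]
  one_criterion <- (failed$aligned_reads < 1e6) != (failed$mapped_fraction < 0.5)
  expect_true(all(one_criterion))
  expect_length(filter_cells(simulate_qc(sim_config(n_cells = 20,
                                                    qc_fail_fraction = 0, seed = 1))), 20)
  expect_length(filter_cells(simulate_qc(sim_config(n_cells = 20,
                                                    qc_fail_fraction = 1, seed = 1))), 0)
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config("admixture",
                          class_proportions = c("M(IL4)" = 0.6, "M(LPS,IFNg)" = 0.6,
                                                "M(IL10)" = 0.4, "M(IC)" = 0.4)),
               "sum to 1")
  expect_error(sim_config("admixture", class_proportions = c(x = 1)), "classes")
  expect_error(sim_config("blended"), "arg")
  expect_error(sim_config(mu_high = log(0.1), mu_low = log(0.5)), "mu_high")
  expect_error(sim_config(dropout_prob = 1.5), "dropout")
})

test_that("fixture suite writes reproducible per-scenario datasets", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  man <- fixture_suite(td1, seed = 78, n_cells = 10)
  expect_setequal(names(man$scenarios), c("admixture", "mixed", "null"))
  for (s in names(man$scenarios)) {
    expect_true(file.exists(file.path(td1, s, "matrix.tsv")))
    m_tsv <- read_expression_matrix(file.path(td1, s, "matrix.tsv"), "tsv")
    m_mtx <- read_expression_matrix(file.path(td1, s, "matrix.mtx"), "mtx")
    expect_identical(unclass(m_tsv), unclass(m_mtx))
  }
  fixture_suite(td2, seed = 78, n_cells = 10)
  f1 <- file.path(td1, "mixed", "matrix.tsv")
  f2 <- file.path(td2, "mixed", "matrix.tsv")
  expect_identical(readLines(f1), readLines(f2))
  td3 <- withr::local_tempdir()
  fixture_suite(td3, seed = 79, n_cells = 10)
  expect_false(identical(readLines(f1),
                         readLines(file.path(td3, "mixed", "matrix.tsv"))))
})
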