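#' Simulation configuration
#'
#' Defines a synthetic single-cell TPM dataset under one of three population
#' scenarios formalising the competing explanations for mixed polarization
#' signatures:
#'
#' * `admixture` — each cell is purely polarized to a single class; its own
#'   class's markers are drawn from the active (high) lognormal, all other
#'   markers from the inactive (low) lognormal. Predicts mutual exclusivity
#'   of cross-class markers.
#' * `mixed` — each cell independently activates each class with
#'   `activation_prob`; markers of active classes are high, others low.
#'   Predicts cross-class co-expression at chance rates.
#' * `null` — no program is active anywhere; all markers low. Used for
#'   type-I-error calibration of the permutation tests.
#'
#' Marker magnitudes are lognormal so that expression spans the 4-5 orders of
#' magnitude seen in real single-cell TPM; the active mean ln(200) puts
#' active markers above the very-high tier (100) most of the time, the
#' inactive mean ln(0.5) leaves inactive markers around the detectability
#' boundary. Dropout zeroes each entry independently, emulating the exact
#' zeros of shallow single-cell libraries.
#'
#' @param scenario `"admixture"`, `"mixed"`, or `"null"`.
#' @param n_cells number of cells (default 45, the size of a typical
#'   QC-passing single-cell capture of this design).
#' @param panel a [marker_panel()]; default the shipped panel.
#' @param n_background_genes non-marker genes drawn from the inactive
#'   distribution in every scenario.
#' @param class_proportions admixture only: named proportions per class
#'   (default uniform over the panel's classes); must sum to 1.
#' @param activation_prob mixed only: per-class activation probability.
#' @param mu_high,mu_low log-scale means of active / inactive marker TPM.
#' @param sigma log-scale standard deviation.
#' @param dropout_prob probability an entry is set to exactly 0.
#' @param qc_fail_fraction fraction of cells generated to fail QC (default
#'   0.3, mirroring an 18-of-63 attrition).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset bit for bit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("admixture", "mixed", "null"),
                       n_cells = 45,
                       panel = default_marker_panel(),
                       n_background_genes = 500,
                       class_proportions = NULL,
                       activation_prob = 0.5,
                       mu_high = log(200),
                       mu_low = log(0.5),
                       sigma = 1.0,
                       dropout_prob = 0.2,
                       qc_fail_fraction = 0.3,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  classes <- unique(panel$class)
  if (is.null(class_proportions)) {
    class_proportions <- stats::setNames(rep(1 / length(classes), length(classes)), classes)
  }
  if (scenario == "admixture") {
    if (is.null(names(class_proportions)) ||
        !setequal(names(class_proportions), classes)) {
      stop("class_proportions must be named with exactly the panel's classes")
    }
    if (abs(sum(class_proportions) - 1) > 1e-9) {
      stop("class_proportions must sum to 1")
    }
  }
  if (activation_prob < 0 || activation_prob > 1) stop("activation_prob must be in [0, 1]")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1) stop("qc_fail_fraction must be in [0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  if (mu_high <= mu_low) stop("mu_high must exceed mu_low")
  if (n_cells < 1) stop("n_cells must be positive")
  structure(list(scenario = scenario, n_cells = n_cells, panel = panel,
                 n_background_genes = n_background_genes,
                 class_proportions = class_proportions,
                 activation_prob = activation_prob,
                 mu_high = mu_high, mu_low = mu_low, sigma = sigma,
                 dropout_prob = dropout_prob,
                 qc_fail_fraction = qc_fail_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic largest-remainder apportionment of n cells to class
# proportions; ties on the fractional remainder broken by class order.
allocate_classes <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Generate a synthetic dataset
#'
#' Draws an expression matrix, a matching QC table and the ground-truth cell
#' labels under the scenario described by `config`. See [sim_config()] for
#' the generative model. Identical configurations and seeds give
#' bit-identical datasets.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with `matrix` ([expr_matrix()]), `qc`
#'   ([cell_qc()]), `true_labels` (per-cell class, or per-cell active-class
#'   list for the mixed scenario), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(config$seed)

  panel <- config$panel
  classes <- unique(panel$class)
  n <- config$n_cells
  cells <- sprintf("cell_%03d", seq_len(n))
  bg <- if (config$n_background_genes > 0) {
    sprintf("bg_%04d", seq_len(config$n_background_genes))
  } else character(0)
  genes <- c(panel$gene, bg)

  # per-cell activation: which classes are "on"
  if (config$scenario == "admixture") {
    counts <- allocate_classes(config$class_proportions[classes], n)
    labels <- sample(rep(names(counts), counts))
    active <- lapply(labels, identity)
  } else if (config$scenario == "mixed") {
    active <- lapply(seq_len(n), function(i) {
      classes[stats::runif(length(classes)) < config$activation_prob]
    })
    labels <- vapply(active, function(a) paste(sort(a), collapse = "+"), character(1))
  } else {
    active <- rep(list(character(0)), n)
    labels <- rep("unpolarized", n)
  }

  mu <- matrix(config$mu_low, n, length(genes))
  for (i in seq_len(n)) {
    on_genes <- panel$gene[panel$class %in% active[[i]]]
    if (length(on_genes)) mu[i, match(on_genes, genes)] <- config$mu_high
  }
  vals <- matrix(stats::rlnorm(n * length(genes),
                               meanlog = as.vector(mu), sdlog = config$sigma),
                 n, length(genes))
  if (config$dropout_prob > 0) {
    vals[matrix(stats::runif(length(vals)) < config$dropout_prob,
                n, length(genes))] <- 0
  }
  m <- expr_matrix(vals, cell_ids = cells, gene_ids = genes)
  qc <- simulate_qc(config)  # own seeded stream: simulate_qc(config) reproduces it
  structure(list(matrix = m, qc = qc, true_labels = stats::setNames(labels, cells),
                 active_classes = stats::setNames(active, cells),
                 config = config),
            class = "sim_dataset")
}

#' Generate a QC table alone
#'
#' Draws per-cell QC metrics calibrated so that the standard filter removes
#' exactly `ceiling(qc_fail_fraction * n_cells)` cells: failing cells breach
#' exactly one criterion (alternating between too few aligned reads and too
#' low a mapped fraction), passing cells clear both with margin. Which cells
#' fail is a seeded random draw.
#'
#' @param config a [sim_config()].
#' @return a [cell_qc()] table with `n_cells` rows.
#' @export
simulate_qc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(config$seed + 1L)
  simulate_qc_impl(sprintf("cell_%03d", seq_len(config$n_cells)), config)
}

simulate_qc_impl <- function(cells, config) {
  n <- length(cells)
  n_fail <- min(n, ceiling(config$qc_fail_fraction * n))
  fail_idx <- sample.int(n, n_fail)
  reads <- stats::runif(n, 1.5e6, 5e6)
  mapped <- stats::runif(n, 0.6, 0.95)
  for (j in seq_along(fail_idx)) {
    i <- fail_idx[j]
    if (j %% 2 == 1) {
      reads[i] <- stats::runif(1, 1e5, 9.9e5)   # below the 1e6 floor
    } else {
      mapped[i] <- stats::runif(1, 0.1, 0.49)   # below the 0.5 floor
    }
  }
  cell_qc(cells, reads, mapped)
}

#' Write the standard fixture suite
#'
#' Writes one small dataset per scenario (default panel, 45 cells) under
#' `out_dir/<scenario>/`, each as a dense TSV and a MatrixMarket triple, plus
#' the QC table, the true labels, and a `manifest.json` describing the suite.
#' Byte-identical for identical seeds.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_cells cells per dataset.
#' @return invisibly, the manifest as a list.
#' @export
fixture_suite <- function(out_dir, seed = 1L, n_cells = 45) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  scenarios <- c("admixture", "mixed", "null")
  manifest <- list(seed = seed, n_cells = n_cells, scenarios = list())
  for (s in scenarios) {
    cfg <- sim_config(scenario = s, n_cells = n_cells, seed = seed)
    d <- simulate_dataset(cfg)
    sub <- file.path(out_dir, s)
    dir.create(sub, showWarnings = FALSE)
    write_expression_matrix(d$matrix, file.path(sub, "matrix.tsv"), "tsv")
    write_expression_matrix(d$matrix, file.path(sub, "matrix.mtx"), "mtx")
    write_qc_table(d$qc, file.path(sub, "qc.tsv"))
    utils::write.table(data.frame(cell_id = names(d$true_labels),
                                  label = unname(d$true_labels)),
                       file.path(sub, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$scenarios[[s]] <- list(
      dir = s, n_cells = n_cells, n_genes = n_genes(d$matrix),
      files = c("matrix.tsv", "matrix.mtx", "genes.tsv", "barcodes.tsv",
                "qc.tsv", "labels.tsv"))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
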