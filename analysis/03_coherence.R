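#!/usr/bin/env Rscript
# Pairwise coherence of polarization markers: linear-regression r-squared
# within and across classes, and positivity-split predictability tests.
# Contrasts the mixed-state population (expected: near-zero r-squared,
# insignificant splits) with the admixture population (expected: strong
# cross-class anti-association). Requires results/fixtures/.

library(polcoherence)

fx <- file.path("results", "fixtures")
stopifnot(dir.exists(fx))
out <- file.path("results", "coherence")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
panel <- default_marker_panel()

for (scen in c("mixed", "admixture")) {
  m <- read_expression_matrix(file.path(fx, scen, "matrix.tsv"), "tsv")
  scr <- coherence_screen(m, panel, "all")
  write.table(scr, file.path(out, paste0("pair_regressions_", scen, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  within <- scr$r_squared[scr$class_a == scr$class_b]
  across <- scr$r_squared[scr$class_a != scr$class_b]
  message(sprintf("%-9s: median r2 within-class %.3f (n=%d), across-class %.3f (n=%d)",
                  scen, median(within), length(within),
                  median(across), length(across)))
}

# can positivity for one program's marker predict the level of another's?
m <- read_expression_matrix(file.path(fx, "mixed", "matrix.tsv"), "tsv")
pairs <- expand.grid(predictor = c("Mrc1", "Socs2"),
                     response = c("Il1b", "Tnf", "Arg1", "Chi3l3"),
                     stringsAsFactors = FALSE)
pred <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  r <- predictability_test(m, pairs$predictor[i], pairs$response[i])
  as.data.frame(r[c("predictor", "response", "n_positive", "n_negative",
                    "excluded_intermediate", "mean_response_positive",
                    "mean_response_negative", "u_statistic", "p_value",
                    "applicable")])
}))
write.table(pred, file.path(out, "predictability_mixed.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
n_sig <- sum(pred$applicable & pred$p_value < 0.05)
message(sprintf(paste0("predictability (mixed population): %d of %d splits ",
                       "significant at 0.05 - positivity for one program does not ",
                       "predict another's level"),
                n_sig, sum(pred$applicable)))
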