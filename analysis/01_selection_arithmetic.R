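#!/usr/bin/env Rscript
# Reconstructs the published model-selection arithmetic from the printed
# per-model weights and best-fit counts: threshold-vs-drift ("B vs V")
# evidence ratios per data set, their means, and pooled best-fit
# percentages over the 87 participants.  Writes
# results/selection_reconstruction.tsv.

suppressPackageStartupMessages(library(cspclba))
dir.create("results", showWarnings = FALSE)

w <- reference_selection_weights()
rows <- list()
for (crit in c("AIC", "BIC")) {
  ratios <- sapply(c("I", "II", "III", "IV"), function(ds) {
    sub <- w[w$criterion == crit & w$dataset == ds, ]
    b_vs_v_ratio(setNames(sub$weight, sub$model))
  })
  for (ds in names(ratios)) {
    rows[[length(rows) + 1]] <- data.frame(criterion = crit,
      quantity = paste0("b_vs_v_", ds), value = ratios[[ds]])
  }
  rows[[length(rows) + 1]] <- data.frame(criterion = crit,
    quantity = "b_vs_v_mean", value = mean(ratios))
  for (m in c("V1", "V2", "B1", "B2")) {
    sub <- w[w$criterion == crit & w$model == m, ]
    rows[[length(rows) + 1]] <- data.frame(criterion = crit,
      quantity = paste0("pooled_best_pct_", m),
      value = pooled_best_fit_pct(sub$n_best, 87))
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/selection_reconstruction.tsv", sep = "\t",
  row.names = FALSE, quote = FALSE)

cat("Threshold-vs-drift evidence ratios (mean across data sets):\n")
print(tab[tab$quantity == "b_vs_v_mean", ], row.names = FALSE)
cat("\nA threshold-class model is ~1.9x (BIC) to ~4x (AIC) more likely\n")
cat("than a drift-class model; full table in results/selection_reconstruction.tsv\n")
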