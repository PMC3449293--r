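#!/usr/bin/env Rscript
# Recovery study: refits the generating model (B2) to each synthetic
# participant and scores per-parameter bias/RMSE and the sign-recovery
# rate of the context shift; then tallies the BIC best-model class from
# the 4-model fits as a model-recovery check.  Writes
# results/parameter_recovery.tsv and results/model_recovery.tsv.

suppressPackageStartupMessages(library(cspclba))
dir.create("results", showWarnings = FALSE)

truth <- read.delim("results/synthetic_trials.tsv.truth.tsv")
theta <- setNames(as.numeric(truth$value[-(1:2)]), truth$parameter[-(1:2)])
gen_model <- truth$value[truth$parameter == "model"]

fits <- read.delim("results/fits.tsv")
b2 <- fits[fits$model == gen_model, ]
fit_objs <- lapply(seq_len(nrow(b2)), function(i) {
  th <- unlist(b2[i, paste0("par_", names(theta))])
  names(th) <- names(theta)
  structure(list(model = gen_model, theta = th), class = "lba_fit")
})
rep_tab <- recovery_report(fit_objs, theta)
write.table(rep_tab, "results/parameter_recovery.tsv", sep = "\t",
  row.names = FALSE, quote = FALSE)
cat("Parameter recovery against the generating truth:\n")
print(rep_tab, row.names = FALSE, digits = 3)

rec <- selection_records(fits)
mr <- model_recovery_summary(rec, gen_model)
write.table(mr, "results/model_recovery.tsv", sep = "\t",
  row.names = FALSE, quote = FALSE)
cat("\nBest-model class tallies (threshold B vs drift V):\n")
print(mr, row.names = FALSE)
b_share <- with(mr[mr$criterion == "BIC", ], n[best_class == "B"] / sum(n))
cat(sprintf("\nBIC assigns %.0f%% of participants to the generating class.\n",
  100 * b_share))
cat("(At the published generating values the context shift db = 0.01 is\n")
cat(" small, so per-participant shift estimates carry real sign uncertainty\n")
cat(" even when the class is recovered; see parameter_recovery.tsv.)\n")
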