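#!/usr/bin/env Rscript
# Stage 3: model-qualification arithmetic.
#
# Recomputes every fold error of the bundled published observed/predicted
# table, the per-compound/metric GMFEs, and the twofold / 1.25-fold
# coverage; then evaluates this package's own engine predictions (from
# stage 2) against the published observed values. The printed-table
# arithmetic must match the published cells exactly at 2 d.p.; the
# engine's own fold errors characterise this implementation and are not
# expected to match the published predicted column.

suppressPackageStartupMessages(library(doxpbpk))

dir.create("results", showWarnings = FALSE)
ref <- reference_pk_values()

tab <- evaluation_table(ref)
stopifnot(identical(tab$fold_error_2dp, ref$fold_error_printed))
message("all ", nrow(tab), " published fold-error cells reproduced at 2 d.p.")

geno <- ref[ref$compound == "doxepin" & ref$metric == "AUC" &
              ref$cyp2d6 != "none", ]
message(sprintf("GMFE, genotyped doxepin AUC: %.2f",
                round_half_up(gmfe(geno$predicted, geno$observed), 2)))
fe_auc <- tab$fold_error[tab$metric == "AUC"]
message(sprintf("AUC fold errors within twofold: %.0f%%; within 1.25-fold: %.0f%%",
                100 * coverage_fraction(fe_auc, 2),
                100 * coverage_fraction(fe_auc, 1.25)))

writeLines(format_evaluation_table(tab), "results/evaluation_published.txt")
utils::write.table(tab, "results/evaluation_published.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

# engine predictions vs published observations
pred_file <- "results/predicted_pk_by_genotype.tsv"
if (file.exists(pred_file)) {
  preds <- utils::read.delim(pred_file)
  preds$cyp2d6[preds$cyp2d6 == "non_genotyped"] <- "none"
  obs <- ref[ref$metric %in% c("AUC", "Cmax"),
             c("compound", "cyp2d6", "metric", "observed")]
  own <- evaluate_predictions(
    preds[preds$metric %in% c("AUC", "Cmax"),
          c("compound", "cyp2d6", "metric", "predicted")], obs)
  utils::write.table(own, "results/evaluation_engine.tsv", sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message(sprintf(
    "engine fold errors: %d/%d within twofold (GMFE doxepin AUC %.2f)",
    sum(own$fold_error >= 0.5 & own$fold_error <= 2), nrow(own),
    attr(own, "gmfe")$gmfe[attr(own, "gmfe")$compound == "doxepin" &
                             attr(own, "gmfe")$metric == "AUC"]))
} else {
  message("run analysis/02_simulate_genotypes.R first for the engine ",
          "evaluation")
}
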