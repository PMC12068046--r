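#!/usr/bin/env Rscript
# Stage 3: classify shapes, filter normal cells, aggregate wells, Z-score
# against mock and call hits. The shape classifier is trained on
# ground-truth-labelled cells (standing in for manual exemplar
# annotation); the normal classifier derives its 1-SD PCA box from the
# pooled population.

suppressMessages(library(morphoscreen))
layout <- read_table_full("results/screen_layout.csv")
cells <- read_table_full("results/cell_table.csv")
reg <- feature_registry(c("dna", "tubulin", "actin", "yaptaz"))

lab <- cells[!is.na(cells$true_class), ]
model <- train_shape_classifier(lab[, reg], lab$true_class, seed = 11,
                                min_per_class = 10)
cat(sprintf("Shape classifier held-out accuracy: %.1f%%\n",
            100 * model$holdout_accuracy))
write_model(model, "results/shape_model.json")

cells$class <- classify_cells(model, cells[, reg])
nmodel <- derive_normal_classifier(
  cells[, reg],
  is_mock = cells$well_id %in% layout$well_id[layout$is_mock],
  seed = 12)
cells$is_normal <- filter_normal(cells[, reg], nmodel)$is_normal

summaries <- summarize_wells(cells, layout, min_cells = 10)
z <- zscore_vs_mock(normalize_per_plate(summaries))
qms <- assemble_qms(z)
hits <- call_hits(z, qms)
write_table_full(summaries, "results/well_summary.csv")
write_table_full(z, "results/well_zscores.csv")
write_table_full(qms, "results/qms.csv")
write_table_full(hits$conditions, "results/hits_conditions.csv")

cat("\nPer-condition QMS (ratio and normal-fraction Z):\n")
print(hits$conditions[, c("condition", "z_median_ratio",
                          "z_normal_fraction", "yap_low", "yap_high",
                          "shape_hit")], digits = 3)
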