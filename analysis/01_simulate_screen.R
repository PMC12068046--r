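#!/usr/bin/env Rscript
# Stage 1: simulate a small RNAi-style screen plate with known ground
# truth. Multi-channel fields (DNA, tubulin, actin, YAP/TAZ marker) go to
# scratch/screen_images as 16-bit TIFFs; the layout and per-cell ground
# truth go to results/ as CSV.

suppressMessages(library(morphoscreen))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/screen_images", showWarnings = FALSE, recursive = TRUE)

seed <- 2024L
mixtures <- list(
  siSPIN  = c(0.55, 0.05, 0.20, 0.10, 0.10),   # spindly-enriched
  siSPIN2 = c(0.50, 0.05, 0.25, 0.10, 0.10),   # near-duplicate signature
  siLARGE = c(0.05, 0.45, 0.25, 0.10, 0.15),   # large-round-enriched
  siFAN   = c(0.05, 0.05, 0.25, 0.50, 0.15),   # fan-enriched
  siLOW   = NULL,                              # ratio shift only
  siHIGH  = NULL)
mixtures <- Filter(Negate(is.null), mixtures)
layout <- screen_layout(
  c(names(mixtures), "siLOW", "siHIGH"), n_mock = 8, replicates = 2,
  mock_mixture = c(0.2, 0.15, 0.3, 0.15, 0.2),
  mixtures = mixtures,
  ratio_shifts = c(siLOW = -0.3, siHIGH = 0.3))
spec <- plate_spec(layout, cells_per_field = 42, fields_per_well = 1,
                   image_size = 320, margin = 30, seed = seed)
plate <- generate_plate(spec)
write_plate(plate, "scratch/screen_images")
write_table_full(layout, "results/screen_layout.csv")
write_table_full(plate$ground_truth, "results/screen_ground_truth.csv")

cat(sprintf("Simulated %d wells (%d mock), %d cells in %d fields.\n",
            nrow(layout), sum(layout$is_mock),
            nrow(plate$ground_truth), length(plate$fields)))
cat("Class totals:\n")
print(table(plate$ground_truth$class))
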