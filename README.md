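# morphoscreen

Single-cell morphological profiling and screen statistics for
high-content imaging of cell shape and YAP/TAZ nuclear translocation.

## The problem

In RNAi screens of Rho-family GEF/GAP regulators, each perturbation is
read out at the single-cell level: how the population redistributes over
a small set of reference cell shapes, and how far the transcriptional
co-activators YAP/TAZ move between cytoplasm and nucleus. Downstream of
the screen, the same studies quantify 3D collagen invasion, focal-adhesion
(FA) turnover kinetics, wound-heal front-rear polarity, and differential
protein abundance. `morphoscreen` implements that full analysis chain as
a tested R package for image-analysis and screening groups — and ships
synthetic-data generators with exact ground truth, so every stage can be
validated end to end without any microscopy or proteomics download.

## The statistics at its core

* **Translocation ratio** per cell:
  `log10( mean(marker | nucleus) / mean(marker | perinuclear ring) )`,
  background-subtracted.
* **Quantitative morphological signature (QMS)** per condition: the
  vector of mock-referenced Z-scores
  `Z = (x - mean_mock) / sd_mock`
  of the per-well shape-class percentages (five-class regularised linear
  classifier, "normal"-cell penetrance filter applied first), averaged
  over replicate wells. Hits: ratio `|Z| >= 1.5` (sign gives direction),
  shape hits at normal-fraction `Z <= -1`.
* **Phenoclusters**: agglomerative clustering of QMS vectors on
  `1 - r_u`, where `r_u = sum(x_i y_i) / sqrt(sum(x_i^2) sum(y_i^2))` is
  the uncentered Pearson correlation; clusters are maximal subtrees with
  root merge similarity `> 0.73`.
* **Invasion index**: `I = sum(counts at depth > 0) / sum(all counts)`
  over z-planes 30 µm apart, counting only blobs passing both nuclear
  and GFP intensity filters.
* **FA kinetics**: per track, `k_a` and `k_d` are the least-squares
  slopes of `ln I(t)` over the assembly (birth→peak) and disassembly
  (peak→death) phases; tracks with < 5 frames or mean axial ratio ≥ 3
  are discarded. Groups are compared with Hedges'
  `g = (m_b - m_a)/s_pooled * J`, `J = 1 - 3/(4(n_a+n_b)-9)`, a BCa
  bootstrap 95% CI and a two-sided Mann–Whitney test; |g| bins:
  0.2–0.5 S, 0.5–0.8 M, 0.8–1.2 L, 1.2+ VL.
* **Differential proteomics**: within-cell-line scaling on log2,
  s0-moderated Welch t with a label-permutation null and SAM-style
  q-values; calls at `|log2 ratio| > 0.5` and `FDR < 0.05`.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage
1 simulates a 20-well screen plate (8 mock wells, six siRNA-style
conditions in duplicate — three shape-mixture effects including a
near-duplicate pair, two translocation shifts) and writes TIFF fields;
stages 2–4 quantify, score and cluster it:

```sh
Rscript analysis/01_simulate_screen.R
Rscript analysis/02_quantify_cells.R
Rscript analysis/03_score_screen.R
Rscript analysis/04_phenoclusters.R
```

prints, among other things:

```
Quantified 835 cells (835 matched to ground truth).
Shape classifier held-out accuracy: 100.0%

  condition z_median_ratio z_normal_fraction yap_low yap_high shape_hit
2    siSPIN      -3.68e-01         -1.15e+00   FALSE    FALSE      TRUE
5     siFAN       6.54e-02         -1.18e+00   FALSE    FALSE      TRUE
6     siLOW      -2.84e+00          2.17e-01    TRUE    FALSE     FALSE
7    siHIGH       3.97e+00          8.40e-01   FALSE     TRUE     FALSE

Phenoclusters at PCC > 0.73: 1 multigene, 4 singleton(s).
1    siSPIN       1            2           0.9761234
2   siSPIN2       1            2           0.9761234
```

The condition simulated with a lowered nuclear:ring ratio (`siLOW`) is
the only `yap_low` hit; the mixture-shifted conditions deplete normal
cells (`shape_hit`); and the two near-identical spindly signatures — and
only they — group into one phenocluster at similarity 0.976.

Stage 5 tracks synthetic TIRF movies for a mock and a faster-turnover
condition and compares fitted rates with estimation statistics, counts a
rendered invasion stack, and scores a wound assay:

```
Assembly-rate effect (perturbed vs mock):
Hedges' g = 2.071 (VL), 95% CI [1.627, 2.491], n = 40/40
Invasion indices: mock 0.20, perturbed 0.02
Golgi 90-degree-bin percentage (mock vs perturbed): 66.5% vs 33.5%
Migration rates: 20.0 vs 9.0 um/h
```

Stage 6 runs the permutation-FDR differential test on a spiked protein
table (`Spiked-protein sensitivity 88.8%; observed FDR 5.3%`). All
tables land under `results/`.

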