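# chronocell

Tools for asking how a tissue of coupled circadian oscillators — the
suprachiasmatic nucleus (SCN) being the motivating case — organizes its
cell-to-cell signalling and its collective rhythm. The package covers two
complementary pipelines plus a synthetic-data module that makes both fully
testable without any external data.

## What it computes

**1. Ligand–receptor signalling topology from scRNA-seq.**
UMI count matrices are quality-controlled (≥ 200 and < 10,000 total UMIs,
< 10% mitochondrial, ≥ 100 genes/cell, genes in ≥ 3 cells, 3-MAD multiplet
removal), normalized to 10,000 UMIs/cell with `ln(1 + x)`, clustered on PCA
(k-means or graph-based), and tested for day/night differential expression
with a negative-binomial exact test (size factors = total/median total,
sSeq-style dispersion shrinkage, p-values conditioned on the per-gene total,
Benjamini–Hochberg correction). The inferred signalling strength from cluster
*i* to cluster *j* along an axis (ligand L, receptor R) is the outer product

    W[i, j] = mean count of L in cluster i × mean count of R in cluster j

scaled to [0, 1] per axis jointly across day and night, and summarized by the
connectivity σ = Σ W. Ligand-enriched source clusters, co-expression overlap
(Venn) summaries, and day/night network comparison (σ ratio, "disassembled"
flag) round out the topology module. Default axes: Prok2–ProkR2, Vip–Vipr2,
Avp–Avpr1a, Grp–Grpr.

**2. Bioluminescence rhythm analysis.**
Reporter traces are detrended (24-h moving-average baseline) and smoothed
(2.5-h moving average), then fitted with

    y(t) = c + A · exp(−λt) · cos(2π (t − φ) / τ)

by FFT-initialized nonlinear least squares. The relative amplitude error
(RAE = 95% CI half-width of A divided by Â) classifies fits as *initiated*
(rhythmic) when 23.5 ≤ τ ≤ 34.5 h and RAE < 0.3. ROI grids become phase maps
(relative phases, initiated fraction, Rayleigh vector length R = |Σe^{iθ}|/n
with corrected p-value); peak detection, treatment phase shifts (mean
deviation of the first three post-treatment peaks from the projected
schedule), waveform-change metrics (relative baseline/amplitude change,
period change) and 3-h-binned phase-response curves complete the module.

## Worked example

```r
library(chronocell)

# simulate a 4-cluster tissue where cluster 1 broadcasts a ligand to
# cluster 3 during the day only
cfg <- sc_sim_config(
  n_clusters = 4, cells_per_cluster = 150, n_genes = 200, base_mean = 1,
  axis_programs = list(list(ligand = "g0010", receptor = "g0011",
                            source_clusters = 1, target_clusters = 3,
                            fold_up = 10, conditions = "day")),
  condition_fractions = c(day = 0.5, night = 0.5), seed = 7)
sim <- simulate_sc_counts(cfg)
sim$matrix
#> chrono_counts: 200 genes x 600 cells (55.80% non-zero)
#> cell_meta columns: condition, run

qc <- compute_qc_metrics(sim$matrix)
fl <- filter_cells_and_genes(sim$matrix, qc,
        thresholds = list(min_total = 50, min_genes_per_cell = 20))
sum(fl$cell_report$kept)
#> 595 of 600 cells pass QC

# day vs night network of the planted axis, on the true clusters
ax  <- axis_spec("L10-R11", "g0010", "g0011")
day <- sim$matrix$cell_meta$condition == "day"
mk  <- function(l) structure(list(labels = as.integer(l), k = 4,
                                  method = "kmeans", seed = 1L),
                             class = "cluster_assignment")
net_day   <- axis_network(sim$matrix[, day],  mk(sim$truth$cluster[day]),  ax, "day")
net_night <- axis_network(sim$matrix[, !day], mk(sim$truth$cluster[!day]), ax, "night")
compare_networks(net_day, net_night)
#> sigma day = 1.60, night = 0.07, ratio = 0.043, disassembled = TRUE
```

The day network carries essentially all the axis's weight (σ_day = 1.60 vs
σ_night = 0.07 on the jointly scaled matrices): the night network is flagged
as disassembled, exactly the structure the generator planted.

```r
# fit a damped 25-h rhythm from a noisy trace
tr  <- simulate_biolum_trace(rhythm_config(period_h = 25, amplitude = 1,
                                           damping_per_h = 0.005,
                                           noise_sd = 0.1, duration_h = 144,
                                           seed = 7))
fit <- fit_rhythm(detrend_and_smooth(tr))
fit
#> rhythm_fit: tau = 24.79 h, phase = 0.50 h, A = 0.99, lambda = 0.0059 /h,
#>   RAE = 0.024, GOF = 0.985, initiated = TRUE
```

The fitted period (24.79 h), amplitude (0.99) and damping (0.0059/h) recover
the generating parameters; the low RAE classifies the trace as rhythmic.

A six-stage batch pipeline (`simulate → qc → cluster → de → topology →
rhythm`) is available through `pipeline_config()` / `run_pipeline()`, writing
versioned artifacts and a JSON run manifest per stage; a thin command-line
wrapper lives at `inst/cli/chronocell.R`.

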