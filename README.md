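# depthbias

Alpha-diversity estimates from amplicon sequencing are supposed to describe
communities, not sequencing runs — yet the way denoising pipelines (DADA2,
deblur) handle singletons ties richness to sequencing depth. In their
default *sample-wise* mode, a sequence seen once in a sample is discarded
as a presumptive error; deeper samples see rare sequences twice and keep
them, shallow samples see them once and lose them. The result is a spurious
correlation between sequencing depth and observed (or estimated) richness
that rarefying does not remove, plus richness estimators that degenerate:
with all singletons gone, Chao1 collapses to observed richness
(`Chao1 = Sobs + Sn1(Sn1−1)/(2(Sn2+1))` with `Sn1 = 0`), Good's coverage
`1 − Sn1/N` is exactly 1, and rarefaction curves plateau artificially.
*Pooled* processing — retaining a sequence wherever it has support in any
sample — breaks the link between individual depth and retention and
resolves the correlation.

`depthbias` is an R package for studying these mechanisms quantitatively.
It is aimed at microbiome researchers and methodologists who want to probe
how pipeline settings (sample-wise vs pooled vs prior-informed processing,
pre- vs post-ASV sub-sampling) shape richness and alpha-diversity
estimates, on synthetic communities where the truth is known. It provides:

* a lognormal community simulator with log-uniform depths and
  error-generated spurious singletons, built so that true richness carries
  **no** depth signal — any correlation observed downstream is caused by
  processing;
* the singleton-threshold abstraction of denoising filters
  (`filter_samplewise()`, `filter_pooled()`, prior lists,
  `extract_prior()`);
* read-level (pre-ASV) and count-level (post-ASV) sub-sampling without
  replacement, analytic Hurlbert rarefaction curves
  (`expected_richness()`, `rarefaction_curve()`, `terminal_slope()`);
* the standard index battery from per-sample components: Hill numbers,
  Shannon `H'` and `exp(H')`, inverse Simpson, Chao1, ACE, Good's
  coverage, Margalef, Menhinick (`diversity_profile()`);
* a 3 × 2 × 2 scenario grid engine (`run_grid()`) that runs all twelve
  processing scenarios from one read set and summarises each scenario's
  depth–richness correlation, mean richness and singleton load.

## Worked example

Simulate a 15-sample community and run the full scenario grid:

```r
library(depthbias)

model <- community_model(pool_size = 300, occupancy = 0.7, n_samples = 15,
                         depth_low = 3000, depth_high = 15000,
                         error_rate = 0.005, seed = 1)
ds   <- simulate_dataset(model)
cfg  <- analysis_config(seed = 1, min_full_depth = 3000, min_sub_depth = 500)
grid <- run_grid(ds$reads, cfg)
summary(grid)[, c("label", "rho_spearman", "mean_richness", "mean_singletons")]
```

```
                               label rho_spearman mean_richness mean_singletons
1               none.samplewise.none        0.856           183             0.0
2      none.samplewise.from_baseline        0.729           195            12.2
3                   none.pooled.none        0.705           196            12.9
4          none.pooled.from_baseline        0.705           196            12.9
5            pre_asv.samplewise.none        0.498           163             0.0
6   pre_asv.samplewise.from_baseline        0.171           184            20.5
7                pre_asv.pooled.none        0.121           184            20.6
8       pre_asv.pooled.from_baseline        0.113           184            20.8
9           post_asv.samplewise.none        0.614           177            13.0
10 post_asv.samplewise.from_baseline        0.315           183            20.3
11              post_asv.pooled.none        0.427           183            21.2
12     post_asv.pooled.from_baseline        0.427           183            21.2
```

Reading the table: sample-wise processing without sub-sampling shows the
strongest depth–richness correlation (ρ = 0.86) and exactly zero
singletons (the filter discards them all); pooling raises mean richness
(196 vs 183) by keeping cross-sample-supported singletons; pre-ASV
sub-sampling depresses richness (163) because it destroys
sub-sampling-induced singletons that the post-ASV path keeps (177); and
the pooled sub-sampled scenarios push the correlation down towards zero.
At the package's full default scale (60 samples, 2000-ASV pool, depths on
[10⁴, 10⁵]) the contrast is sharper still: ρ ≈ 0.97 sample-wise/none
versus |ρ| ≈ 0.07 pooled/post-ASV.

Per-sample index profiles come from the scenario tables directly:

```r
diversity_profile(grid$tables[["none.samplewise.none"]])[1:3,
    c("sample_id", "depth", "observed_richness", "singletons",
      "chao1", "goods_coverage")]
```

```
  sample_id depth observed_richness singletons chao1 goods_coverage
1      s001  6149               185          0   185              1
2      s002  4710               172          0   172              1
3      s004  8044               174          0   174              1
```

Chao1 equal to observed richness and coverage exactly 1 on every sample
are the degenerate-estimator identities described above.
`plot_depth_richness()`, `plot_index_distributions()` and
`plot_rarefaction()` visualise the grid; `write_grid_outputs()` writes
TSV summaries and a run manifest.

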