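# fcnflow

River networks are fragmented by dams and natural barriers into
*functionally connected networks* (FCNs) — patches of stream habitat a
fish can traverse without crossing a passage barrier. `fcnflow` implements
an analysis chain for asking whether the loss of network connectivity and
habitat diversity explains where freshwater fish communities changed
between a historical and a current period, at the HUC-12 subwatershed
scale. It is written for freshwater ecologists and conservation analysts
working with reach-based hydrography (NHDPlus-style), barrier inventories,
and two-period presence–absence fish data.

The chain has five stages, each exposed as package functions and driven by
the numbered scripts under `analysis/`:

1. **Delineation** — cut the dendritic reach graph at the active barriers
   of a scenario (waterfalls only = historical; waterfalls + dams =
   current) and enumerate FCNs.
2. **Habitat** — classify reaches into physical habitat classes, apply the
   1-km presence rule per FCN, and compute richness and rarity-weighted
   richness `RWR = sum_h 1/n_h` (z-scored within ecoregion).
3. **Linkage** — characterize each HUC-12 by its longest historical and
   current FCN; derive per-class percent-change and presence-change
   predictors, length-weighted condition, and outlet dam metrics.
4. **Temporal beta-diversity** — per site, the Sorensen dissimilarity
   `D = (b+c)/(2a+b+c)` decomposed into loss `B = b/(2a+b+c)` and gain
   `C = c/(2a+b+c)` components, with permutation p-values, a loss/gain
   dominance test, and per-species paired permutation tests (Holm
   corrected).
5. **Attribution** — correlation/VIF pruning (|r| ≤ 0.75, VIF ≤ 5), a
   random forest of TBI on the surviving predictors, Moran's I residual
   diagnostics across distance thresholds, Moran-eigenvector augmentation
   until residuals are spatially unstructured, 30 repeated fits, and
   partial dependence curves.

A seeded synthetic generator (`generate_dataset()`) emulates the whole
input bundle — dendritic network, barriers, HUC-12 partition, two-period
communities with a controllable fragmentation→loss effect — so the full
pipeline runs and is tested entirely offline. See
`vignettes/fcnflow-methods.Rmd` for the models, parameter defaults, and
what the synthetic system does and does not emulate.

## Worked example

The numbered scripts run the whole analysis on the synthetic study system
(seed 1) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_delineate.R
Rscript analysis/04_tbi.R
```

prints, among other lines:

```
Simulated 4000 reaches (9070 km of stream), 110 waterfalls, 66 dams,
460 HUC-12 sites and 40 species; seed 1.
Historical: 90 FCNs, mean length 80.9 km.
Current:    149 FCNs, mean length 48.9 km.
Dam construction raised the FCN count by +66% and changed mean length by -40%.
Mean TBI 0.138 over 451 sites (loss 0.138, gain 0.000).
Change is loss-dominated (p = 0.0001).
```

Reading: adding the 66 dams to the 110 natural barriers fragments the
system from 90 into 149 patches and shrinks the mean patch by 40%. The
mean per-site temporal beta-diversity of 0.138 says that, on average,
about 14% of the Sorensen denominator at a site is species turnover — and
its gain component is exactly zero, so all change is loss (sign-flip
p = 0.0001). The attribution stage
(`Rscript analysis/05_spatial_rf.R`) then reports

```
Median OOB R^2 = 0.36 (MAD 0.01) over 30 runs; 0 spatial predictor(s) added.
Top predictors: rwr_z_chg, total_km_pctchg, hwi.
The fragmentation measure (total_km_pctchg) ranks 2 of 12.
```

i.e. the planted drivers — fragmentation (percent change in network
length), habitat-rarity change, and condition (HWI) — are recovered as the
most important predictors of community change.

In code, the same run is one call:

```r
library(fcnflow)
ds  <- generate_dataset(synth_config(seed = 1))
res <- run_pipeline(ds$network, ds$barriers, ds$communities, ds$centroids,
                    out_dir = "results/pipeline", n_perm = 999, seed = 1)
res$dominance$direction   # "loss"
head(res$ranking, 3)      # rwr_z_chg, total_km_pctchg, hwi
```

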