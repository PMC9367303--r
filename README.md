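# porpoisetools

Line-transect distance sampling and ensemble habitat-suitability modelling
for coastal harbour porpoise (*Phocoena phocoena*) surveys — with a
synthetic survey generator so every estimator can be validated against a
known truth.

The package is aimed at marine-mammal monitoring analysts who need the two
standard engines of an aerial porpoise assessment in one tested, scriptable
place:

1. **Conventional distance sampling (CDS).** Perpendicular distances
   `y = altitude / tan(declination)` are modelled with a detection function
   `g(y)` (`g(0) = 1`), fitted by maximum conditional likelihood
   (`prod g(y_i) / mu`, `mu = integral of g over [0, W]` = the effective
   strip width) for the four conventional key/adjustment families
   (uniform + cosine, half-normal + cosine, half-normal + Hermite,
   hazard-rate + polynomial) and selected by AIC. Density and abundance
   follow

   ```
   D = n * E[s] / (2 * L * mu * g0),    N = D * A
   ```

   with the size-bias-corrected expected group size `E[s]` (regression of
   `log s` on `g(y)`, significance level 0.15), the availability correction
   `g0` (default 0.364, the published aerial value for this species in good
   conditions), and transect-level bootstrap CVs and percentile CIs.

2. **Ensembles of small models (ESM).** Every *bivariate* MaxEnt model over
   the eco-geographical variables (bathymetry, slope, SST, chlorophyll-a,
   ammonium) is fitted on repeated background replicates and 80/20 splits,
   scored with Somers' `D = 2*AUC - 1` on held-out data, and runs with
   `D >= 0.5` are averaged with weights `D_i / sum(D_j)` into a habitat
   suitability index (HSI) in [0, 1]. Validation uses the Continuous Boyce
   Index; variable contributions and multi-year mean/CV maps mirror the
   standard reporting tables.

Supporting modules cover environmental preprocessing (Horn slope and
distance-to-coast from bathymetry, inverse-distance-weighted interpolation,
Pearson |r| > 0.7 collinearity screening) and plain-text ASCII-grid raster
and CSV survey I/O.

## Worked example

A two-year synthetic survey, end to end (simulate → fit detection functions
→ stratified estimates with bootstrap → annual ESM):

```r
library(porpoisetools)
cfg <- pipeline_config(years = 2011:2012, seed = 7)
rep <- run_pipeline(cfg)
rep$estimate_table
#  stratum transects distance_km sightings individuals expected_group_size
#     2011        13       481.5        17          26                1.47
#     2012        13       481.5        13          18                1.47
#    Total        26       963.0        30          44                  NA
#  density  density_ci abundance abundance_ci cv_percent
#    0.579 0.177-1.162      5276   1619-10594      46.40
#    0.442 0.120-0.838      4035    1097-7641      43.94
#    0.510 0.198-0.907      4655    1803-8276      36.05
```

Each stratum row is one survey year: effort (13 transects, 481.5 km),
sighting and individual counts, the size-bias-corrected expected group
size, and density (ind/km²) and abundance with bootstrap 95% CIs and CVs
(g0 = 0.364 applied). The `Total` row pools years by effort weighting. The
AIC candidate table and the ESM outputs are in the same report:

```r
round(rep$contributions, 2)
#      bathymetry slope   sst  chla ammonium
# 2011      27.56 16.79 19.39 19.46    16.80
# 2012      15.60 14.09 24.67 24.09    21.55
round(rep$cbi, 3)
#  2011  2012
# 0.870 0.771
```

Contributions are percentages (rows sum to 100) of mean Somers' D per
variable; the CBI values near 1 say that held-in presences concentrate in
cells the ensemble ranks highly.

Because the generator knows the truth, the estimator can be audited
directly:

```r
recovery_experiment(n_replicates = 20)
#  n_replicates true_density mean_density mean_rel_bias coverage
#            20       0.0973       0.0963        -0.011       NA
#  mean_esw_rel_error mean_n_sightings
#              0.0913             56.1
```

— a 1% mean relative bias on the recovered density over 20 simulated
multi-pass surveys at the realistic density scale.

A thin CLI wrapper is installed at `inst/scripts/porpoise-pipeline.R`
(`run` and `recover` subcommands, YAML config).

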