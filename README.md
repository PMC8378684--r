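# winterdisp

Analysis of the **winter (non-breeding) dispersal of Magellanic penguins
(*Spheniscus magellanicus*)** tracked with light-level geolocators (GLS)
on the Patagonian Shelf: where the birds go, how strongly their
at-sea distribution overlaps bottom-trawl and shrimp fisheries, and what
their blood stable isotopes say about trophic niche — with every step
validated against a ground-truthed synthetic-data generator.

The package is aimed at movement ecologists and conservation analysts
working with archival light tags, vessel-monitoring effort grids and
bulk δ¹³C/δ¹⁵N measurements.

## What it implements

**Probabilistic geolocation.** A GLS tag yields daily sunrise/sunset
times; longitude follows from local solar midday, latitude from day
length via the hour-angle equation
`cos H = (sin a − sin φ sin δ)/(cos φ cos δ)`, which degenerates near the
equinoxes. `estimate_path()` builds per-day clouds of 2000 particles over
a range of twilight solar angles, weights them by travelling-speed
plausibility (gamma, capped at 8 km/h sustained), SST agreement (Gaussian
kernel, sd 1 °C) and land avoidance, runs repeated forward selection
passes, and returns the per-day **geographic median** path with
dispersion.

**Track metrics.** Latitudinal range (haversine between the
latitude-extreme points, R = 6378137 m), inclusive trip durations,
per-sex summaries, Welch-equivalent unequal-variance ("varIdent-style")
group tests, and a Gaussian mixed model
`depth ~ sex + (1 | individual)` with per-sex residual variances for
daily maximum dive depths.

**Fisheries overlap.** Daily fixes binned on a 2° grid, normalized to
the per sex × month maximum; 0.5° effort re-gridded by exact nesting and
binned to the 0–5 score (1: 0–60 h, 2: 60–200, 3: 200–800, 4: 800–6000,
5: > 6000); per-cell `overlap = 1{score > 0}` and
`interaction = density × score ∈ [0, 5]`; binomial and Gaussian GLM sex
tests per fishery.

**Isotopic niche & trophic position.** Standard ellipse areas
(`SEA = π√det Σ̂`, small-sample `SEA_C`, Bayesian `SEA_B` via a conjugate
normal–inverse-Wishart posterior), numeric ellipse overlap, and Bayesian
trophic position with one baseline (males) or two mixed baselines
(females): `E[δ¹⁵N] = α b₁ + (1−α) b₂ + Δᴺ(TP − 2)` (and the analogous
δ¹³C equation), TDFs 2.8 ± 0.2 / 0.9 ± 0.1 ‰, Suess correction
−0.022 ‰ yr⁻¹, custom MCMC with convergence diagnostics.

**Synthetic data.** `simulate_tracks()`, `simulate_tag_records()`,
`simulate_fishing_effort()` and `simulate_blood_isotopes()` generate
sex-structured tracks, tag records, clustered effort fields and isotope
cohorts with known truths; `run_pipeline()` chains everything with a
deterministic seed fan-out and a checksummed manifest.

## Worked example

```r
library(winterdisp)

# published deployment summary: per-sex latitudinal ranges
dep <- martillo_deployments()
summarize_by_sex(dep$latitudinal_range_km, dep$sex)
#>      sex n   mean       sd single_value
#> 1 female 5 1274.6 392.9138        FALSE
#> 2   male 4 1473.0 185.2356        FALSE

heteroscedastic_group_test(dep$latitudinal_range_km, dep$sex)
#> F = 0.9977 (t = 0.9988), df = 5.92, p = 0.3569
#>   means: female 1.27e+03 +/- 393 (n=5), male 1.47e+03 +/- 185 (n=4)

# two-baseline trophic position on a synthetic female cohort (truth:
# TP = 4.8, alpha = 0.5)
bl  <- default_baselines()
cfg <- simulation_config(rng_seed = 1)
fem <- subset(simulate_blood_isotopes(cfg), sex == "female")
tp_two_baseline(fem$d15N, fem$d13C,
                bl[bl$name == "southern_patagonia", ],
                bl[bl$name == "bahia_franklin", ], seed = 1)
#> TP posterior: 4.81 +/- 0.24 [4.38-5.31]
#> alpha: 0.48 +/- 0.24 [0.05-0.93]
```

The per-sex means/SDs are the sample statistics of the nine recovered
deployments; the F test is the unequal-variance comparison of the two
sexes (no significant difference). The trophic-position posterior
recovers the generator's truth within its credible interval, with α the
estimated contribution of the Southern Patagonia baseline.

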