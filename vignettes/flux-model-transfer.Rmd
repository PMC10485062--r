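---
title: "Transferring station-trained flux models by climate similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring station-trained flux models by climate similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtransfer)
```

## The problem

Eddy-covariance towers measure daily net ecosystem exchange (NEE, g C m⁻² d⁻¹)
and water flux (WF, mm d⁻¹) at a few hundred locations, while ordinary
meteorological stations number in the thousands. A machine-learning model
trained on the flux towers can in principle simulate fluxes at any
meteorological station that records the same covariates — but there is no
guarantee the model is applicable there. `fluxtransfer` implements a complete,
testable pipeline that (i) trains random-forest flux models under grouped
cross-validation, (ii) *predicts* how well each model will transfer to a new
station from the climatic similarity between the station and the model's
training set, and (iii) screens and applies only the models predicted to reach
a determination coefficient (R²) of at least 0.5.

## The procedure

**Categories.** Stations are partitioned nine ways: four landscape groups
(Wetland, Cropland, Grassland, Forest, mapped from IGBP land-cover classes),
two continents (Asia, Europe), two aridity classes (Arid iff aridity index
< 0.65), and the all-station pool (Overall). Each station belongs to exactly
four categories.

**Grouped cross-validation.** Within each category, whole stations are
shuffled into `k` folds, repeated over `p` independent splits
(`make_cv_plan()`). One forest is trained per (split, fold) on the stations
outside the fold and evaluated at each station inside it, giving `n × p`
per-station R² values per category. With nine categories and `p = k = 10`
the design enumerates 900 models per scenario–target pair and 3,600 in total
(`enumerate_training_plan()`). Two feature scenarios are carried through
everything: RS (all factors) and WRS (without the remote-sensing group).

**Forests.** `train_rfm()` fits `ranger` regressions of the daily flux on the
scenario's factors, choosing among randomly drawn hyperparameter
configurations (trees 100–500, depth 5–30 or unlimited, minimum node size
1–10, feature fraction 0.3–1.0; 20 draws by default) by out-of-bag R².
Out-of-bag scoring avoids a nested grouped CV; since fold-level models are
themselves validated at held-out stations, a station-blind inner criterion is
not required for the quantities this pipeline reports. Rows with any missing
feature or target are dropped, with counts logged.

**Distances.** For a factor `j`, the distance between two stations is the
Euclidean distance between their day-of-year climatologies over the DOYs both
observed,

$$ds(x, y) = \sqrt{\sum_{i=1}^{t} (x_i - y_i)^2}, \qquad t \le 365,$$

and the distance between a station and a model's training set is the mean of
its `ds` to each of the `n − m` training stations. One such distance per
factor yields the station's distance vector `d₁ … d_w`.

**The R²-simulation model (RSM).** Each per-station evaluation pairs its
realized R² with the distance vector between that station and that model's
training set ("Dataset 1", `n × p` samples per category). An ordinary
least-squares regression

$$R^2 = a_0 + a_1 d_1 + \cdots + a_w d_w$$

is fitted per (category, scenario, target) (`fit_rsm()`). Applied to a
meteorological station's distance vectors ("Dataset 2"), it predicts the R²
every candidate model would achieve there.

**Screening.** A met station's candidates are all models of its own four
categories. The model with the maximum predicted R² is chosen only if that
maximum is at least 0.5 (inclusive); otherwise the station is not
transferable for that scenario–target. Chosen models simulate daily fluxes on
every feature-complete day, written as one CSV per station
(`id,lon,lat,year,month,day,doy,NEE,WF`) plus a station-information table
whose quality classes are 1 (R² < 0.5), 2 (0.5 ≤ R² < 0.7) and
3 (R² ≥ 0.7).

## Numerical and design choices

* **VPD** uses the FAO-56 Magnus saturation curve
  `es(T) = 0.6108·exp(17.27T/(T+237.3))` kPa; a dew point above the air
  temperature is clamped to zero deficit with a warning. The LE→WF conversion
  multiplies the daily-mean flux density by 86 400 s and 0.408×10⁻⁶ mm per
  J m⁻² (the reciprocal latent heat of vaporisation).
* **QC filtering** is inclusive at the threshold (a flag of exactly 0.8
  passes at the default threshold 0.8).
* **Gap interpolation** linearly fills interior gaps of at most 7 consecutive
  missing days (the "< 8" rule); longer and edge gaps stay missing.
* **Leap days** are generated by the simulator (so downstream date handling is
  exercised) but dropped from climatologies, which live on DOY 1–365.
* **Static factors** (elevation, slope, soil fractions) enter distances as
  length-1 series — the absolute difference — since a time-invariant factor
  cannot be matched day by day.
* **Minimum overlap**: daily-factor distances require ≥ 30 common DOYs;
  pairs below that are excluded from the training-set mean rather than
  zero-filled, keeping distances comparable across pairs.
* **No standardization** is applied before the distance equations — they
  operate on raw units exactly as written; the MLR coefficients absorb scale.
* **Rank deficiency**: collinear distance columns are dropped (with a
  message) before refitting the RSM.
* **Negative R²** values are retained and flow into the RSM unmodified;
  predicted R² is reported unclamped and clamped to 1 only for quality-class
  binning.
* **Ties** in screening are broken by category order
  (Wetland … Overall) and then by model id, deterministically.
* **Folds** when `k` does not divide `n` differ in size by at most one;
  fold assignment is shuffled independently per category and per split with a
  logged seed.
* **RSM validation is in-sample**: classification accuracy is computed on the
  same Dataset 1 the RSM was fitted to, which is how the accuracy of this
  construction is conventionally assessed before transfer.
* **Candidate pool**: a met station is scored only against models of its own
  four categories; scoring against all nine would let, say, a
  Europe-category RSM judge an Asian station.

## The synthetic station network

Real flux archives cannot be redistributed, so the package ships a generator
(`generate_network()`) whose statistical structure exercises every stage:

* **Covariates** follow seasonal harmonics plus first-order autocorrelated
  daily noise: air temperature (amplitude ≈ 10 °C), dew point via a
  dew-point depression, downward shortwave radiation, fPAR, EVI and LSWI;
  seven reflectance bands are linear transforms of EVI/LSWI plus independent
  noise, carrying deliberately redundant signal. VPD is derived from the
  emitted temperatures by the package's own `compute_vpd()`.
* **A single climate gradient** `u` (station-level, sd 1) shifts the means of
  every covariate family together — temperature, dew-point depression,
  radiation and vegetation — so between-station climatic variation spans one
  dominant axis, as latitudinal gradients do. Category-level offsets
  (continent, aridity, landscape) sit on top.
* **Flux truth.** NEE is Q₁₀ respiration minus light-saturating,
  VPD-suppressed GPP:
  `NEE = −GPPmax · DSR/(DSR + k_I) · fPAR · e^(−k_V·VPD) + R₀·Q₁₀^((Ta−10)/10) + ε`,
  and `WF = max(0, c_R·DSR·fPAR + c_V·VPD + ε)`.
* **Response drift.** Station parameters drift along a response gradient
  `v = 0.85·u + 0.53·ε` — strongly coupled to the observable climate but with
  an unobservable share. The coupling is what makes climatic distance
  informative about transfer skill; the unobservable share is what prevents a
  sufficiently flexible model from simply absorbing the drift, which would
  otherwise leave nothing for the distance regression to explain. The WF
  drift is a *shape* contrast (c_R rises, c_V falls along `v`), keeping
  station flux amplitude roughly flat along the gradient: if amplitude grew
  with `u`, high-gradient stations would evaluate better purely because
  pooled least-squares training favours large-amplitude targets, and that
  artefact would invert the distance–skill relation the framework relies on.
* **Observation noise** scales with each station's flux variability
  (`noise_sd_nee` / `noise_sd_wf` are nominal at a reference station of
  sd 2 g C m⁻² d⁻¹ / 0.8 mm d⁻¹), as eddy-covariance random error roughly
  does.
* **Out-of-distribution stations**: a configurable fraction of met stations
  is displaced by `ood_shift` standard deviations along the climate gradient,
  in a random direction (warmer/wetter or colder/drier), with the response
  gradient inheriting its coupled share of the displacement.
* **Missingness** is injected into the remote-sensing factors as runs of at
  most `max_gap_days` consecutive days (optionally a fraction of longer
  runs), separated by at least one observed day, hitting the target rate
  exactly up to rounding — so the "< 8 days" interpolation rule is exercised
  both below and above its boundary.

What the generator does **not** emulate: MODIS retrieval artefacts, flux
footprint heterogeneity, energy-balance closure, sub-daily structure, rain
events, or realistic spatial autocorrelation between neighbouring stations.
Passing tests on this generator show the pipeline's logic and statistical
behaviour are sound; they do not certify skill numbers on real archives.

## Problem sizes used by the test-suite and acceptance script

All sizes are package choices for a single-CPU run. The miniature full-design
run trains all 3,600 models on a 48-station, one-year network with 3-tree
forests; skill-recovery checks use a 30-flux-station, 3-year network at low
noise (noise sd 0.05 g C m⁻² d⁻¹ / 0.02 mm d⁻¹) with forests of 40–80
trees; the screening study uses 24 flux and 20 met stations (half displaced
by 3 sd) over 3 years with `k = 3`, `p = 4`. The acceptance script runs the
full nine-category pipeline on a 40-flux / 16-met, one-year network with
`k = 5`, `p = 3` and 30-tree forests. At these scales each category's RSM is
fitted to 30–120 samples — far fewer than a continental archive would give —
so RSM fit statistics and transfer rates are noisier than the procedure would
be at scale, which is why the stochastic checks are framed as seed-majority
properties rather than point values.

## Known limitations

* The RSM is a linear description of a nonlinear decay of skill with
  dissimilarity; extrapolated predictions can exceed 1 or be strongly
  negative and are intentionally left unclamped for screening.
* With few stations per category the RSM is estimated on few effective
  samples (evaluations of the same station across splits are correlated), so
  per-category coefficient values should not be over-interpreted at small
  `n`.
* The factor registry is a reconstruction of a typical covariate set
  (4 meteorological, 10 remote-sensing, 4 static factors); it is fixed in
  ordering but not a reproduction of any particular archive's list.
* Grouped CV prevents within-station leakage but not spatial autocorrelation
  between distinct nearby stations; the generator draws stations
  independently, so this failure mode is not exercised.

## A worked mini-run

```{r, eval = FALSE}
cfg <- pipeline_config(
  network = network_config(n_flux_stations = 24, n_met_stations = 8,
                           years = 2018:2019, seed = 1),
  k = 4, p = 3, scenarios = "WRS", targets = "WF", categories = "Overall",
  hyper = hyper_config(n_draws = 2, trees = c(50, 100)), seed = 1
)
run <- run_flux_pipeline(cfg, out_dir = "fluxtransfer-out")
run                       # counts, skill summaries, accuracies, transfer rates
glance(run$rsms[[1]])     # RSM fit statistics
autoplot(run$rsms[[1]])   # predicted vs realized R2
plot_cv_r2(run$evaluations)
```
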