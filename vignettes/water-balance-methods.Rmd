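---
title: "Methods: the soilwb water balance, canopy model and pipeline design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the soilwb water balance, canopy model and pipeline design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilwb)
```

This vignette explains the science and the numerical choices behind
`soilwb`: what the model assumes, which parameters matter, what the
synthetic-trial generator does and does not emulate, and where design
decisions were genuinely open.

## The bucket model

The soil profile over the accounting depth (default 60 cm) is one store.
Its state is the soil moisture deficit `SMD` in mm, with `SMD = 0` meaning
the profile is at field capacity and larger values meaning drier soil. This
sign convention matches how irrigation schedulers read the quantity: the
deficit is the depth of water needed to refill the profile.

Each day, in one provisional-deficit formula (`wb_step()`):

* actual evapotranspiration `AET = PET × cover × stress`;
* provisional deficit `d = SMD_prev + AET − rain − irrigation`;
* `drainage = max(0, −d)` and `SMD = max(0, d)`.

At daily resolution the within-day order of evaporation, rainfall and
drainage is arbitrary; folding them into a single formula makes the
arithmetic auditable and gives the exact mass-balance identity
`ΔSMD = AET − rain − irrigation + drainage` on every non-reset day, which
the test suite asserts to 1e-9 over a 10-year, 8-plot synthetic trial.

Two corrections anchor the model to the field:

1. **Canopy-adjusted PET.** Before canopy closure a crop transpires less
   than the atmospheric demand, so PET is scaled by the cover fraction.
   With `cover = 0` (bare soil, fallow) the model moves no water at all;
   bare-soil evaporation is deliberately not modelled (see Limitations).
2. **Reset to observations.** On any day with a probe reading the model
   state is overridden by `SMD = max(0, FC − storage)` *after* the model
   step, so a prediction exists first and the signed residual
   (model − reset) quantifies drift between observations. A reading wetter
   than field capacity resets to 0 and is flagged supersaturated; no
   retroactive drainage is invented for the excess, since the model cannot
   know when it left.

The optional linear stress term `clamp((TAW − SMD)/(TAW − RAW), 0, 1)` is
off by default: the corrected model relies on canopy scaling and resets, and
the stress reduction is provided only for fidelity experiments. When it is
off no upper cap is placed on SMD; if a `taw_mm` is supplied anyway, a
deficit exceeding it logs a one-time warning rather than silently capping.

**Initialisation.** A run either starts from a supplied numeric deficit or,
by default, is anchored by the first storage observation. Forcing days
before the first observation are refused rather than guessed at — an
unanchored bucket can start arbitrarily far from the truth and there is no
principled default. The anchor day is recorded as a reset with zero fluxes
(no model step exists for it), which keeps the trajectory aligned with its
forcings one row per day.

## Canopy cover from NDVI

Cover is a linear function of standardised NDVI between two endpoints,
clamped to [0, 1]:

* `ndvi_closure = 0.75` — canopy closure, one threshold for all crops,
  consistent with field observations of well-watered vegetable crops;
* `ndvi_bare = 0.15` — the bare-soil baseline. Only the closure end is
  observationally fixed; bare soil does not measure NDVI 0, so a nonzero
  configurable baseline is used. This choice shifts early-season cover and
  hence AET, which is why it is surfaced prominently in `trial_config()`.

Canopy observations arrive fortnightly at best and from different
instruments. Standardisation is a per-instrument linear calibration
(`gain × raw + offset`); the cross-instrument mapping is a declared
assumption of this package — identity by default — because no physical
calibration between instruments is implied by the data format itself.

Interpolation to daily values assumes canopy development is linear in time
between observations (in cover space, after the NDVI-to-cover map):

* cover is 0 before emergence, on every fallow day, and after harvest;
* with no observation before emergence the ramp is anchored at
  `(emergence, 0)`;
* once cover reaches 1 it is held there until the next observation or
  harvest — closure is treated as an absorbing state within a crop; if a
  later observation is lower (senescence), the series follows it down, but
  no senescence model is invented;
* after the last observation the last value is carried to harvest;
* observations dated inside fallow or outside the crop interval are dropped
  with a warning rather than silently bent into the series.

## Profile storage and field capacity

Layered probe readings are aggregated as
`storage = Σ θ_i × thickness_i (mm)` over the layers intersected with the
accounting depth; a layer reaching below it contributes only its
intersection, and a coverage gap inside the profile is an error (a partial
profile would understate storage by an unknown amount). Layer boundaries
are cm below the surface, half-open `[top, bottom)`.

Field capacity is estimated per plot from winter-fallow storages: with no
crop and minimal winter evaporation, rainfall keeps the profile near its
drained upper limit, so fallow readings cluster at FC. The default rule is
the **maximum** winter-fallow storage ("the wettest fallow reading"); a
quantile rule (default q = 0.95 when selected) guards against a single
outlier reading. Estimation is per plot; a plot with no fallow reading is a
hard error because a defaulted FC would silently bias every SMD and
drainage value downstream. Note the max rule is an extreme-value statistic:
under observation noise its expectation exceeds the true FC by roughly
1.3–1.6 noise standard deviations depending on the number of fallow visits.
The tests therefore check recovery *on average* across seeded replicates
rather than demanding each replicate land within a fixed noise band — no
estimator of a maximum can promise that.

Fallow intervals are derived, not entered: the configured recurring fallow
months (default June–August, the southern-hemisphere winter) expanded over
the trial range, minus each plot's sowing-to-harvest interval. This keeps
the calendar CSV minimal and makes the "fallow never overlaps a crop"
invariant true by construction.

## Drainage events

Daily drainage is segmented into events: maximal runs of draining days,
merging runs separated by at most `event_merge_gap_days` dry days
(default 1) and discarding merged events totalling less than `event_min_mm`
(default 1 mm). The thresholds are artifact conventions — field dashboards
show discrete labelled events, but no segmentation rule is implied by the
data — so both are configuration, and filtering happens after merging so
that merging preserves mass and filtering only removes it. Lags are
measured from the *end* of an event to the next reference date, matching
the leachate-collection use: sampling happens after drainage completes. The
segmentation is verified against an exhaustive independent merge-to-fixpoint
oracle over every drainage series of length 12 on a {0, 1, 3} mm grid.

## The synthetic-trial generator

`generate_trial()` emulates a two-year irrigated vegetable trial at a
temperate southern-hemisphere site, with known ground truth for every
quantity the pipeline estimates:

* **Weather**: PET as a seasonal sinusoid peaking mid-January (June–August
  minimum), rain as Bernoulli occurrence × gamma amounts; defaults give
  ≈ 640 mm/yr rain and ≈ 1000 mm/yr PET. This is the simplest structure
  with realistic dry-day statistics, not a calibrated stochastic weather
  generator: no autocorrelation, no rain–PET coupling, no inter-annual
  variability beyond sampling noise.
* **Crop**: spring sowing (1 October), emergence after 10 days, a 42-day
  linear ramp to closure, harvest 31 March. The ramp matches the canopy
  module's linearity assumption deliberately, so that the NDVI-to-cover
  inversion is well-posed and zero-noise closure is an exact test of the
  plumbing rather than of model mismatch.
* **Truth**: per-plot FC drawn from U(170, 200) mm; the true SMD/drainage
  trajectory is produced by the forward model itself starting at FC on the
  winter start date, with rule-based irrigation (20 mm when the true
  deficit exceeds 25 mm on a November–March crop day).
* **Observations**: fortnightly NDVI (aligned with emergence and closure;
  two instruments with a known linear calibration between them, noise
  s.d. 0.03 added on the standardised scale) and four-weekly layered probe
  readings (noise s.d. 0.01 on θ per layer — per layer, not per profile, so
  aggregation averaging is genuinely exercised). Probe visits are sparser
  than canopy visits because neutron probing is labour-intensive.

What passing tests on these fixtures shows: the pipeline's algebra, wiring
and estimators are correct, and recovery degrades with observation noise in
the expected way. What it does not show: robustness to instrument drift,
spatially correlated noise, non-linear canopy growth, bare-soil
evaporation, or runoff — real-data features the generator does not emulate.

## Incremental execution

The stage runner re-executes a stage when, and only when, the content hash
of its declared inputs changes: input-file digests, upstream stage
fingerprints (chained, so change propagates along the DAG), the
configuration keys the stage reads, and a manually bumped code-version tag.
Content hashing rather than modification times survives file copies and
makes "nothing changed → nothing runs" exact. Reading the five CSVs is
folded into the consuming stages rather than being a stage of its own, so a
perturbation of one input file re-runs exactly the stages that consume that
file. The cache is one JSON manifest beside the outputs, written atomically
after each stage; an advisory lock file guards against concurrent runs in
the single-user lab setting this targets. Hashing live code objects is out
of scope — the version tag is the maintainer's contract.

## Problem sizes and numerical conventions

The test suite uses a 10-year × 8-plot trial for mass conservation, 20
seeded two-plot replicates for noisy FC recovery, 100 random 200-day
fixtures for balance-oracle equivalence, the full 531,441-series
enumeration for event segmentation, and one-plot one-year trials for the
six orchestrator perturbation checks — sizes chosen so each property is
exercised well past its edge cases while the whole suite stays quick to run
routinely. Tolerances: mass balance and closure at 1e-9 (the model is exact
arithmetic, so only accumulation error is tolerated); oracle equivalence is
exact (`identical`), since reference and implementation perform the same
floating-point operations in the same order. Dates are ISO-8601 and parsed
strictly; ambiguous formats are rejected rather than coerced, because
silent date coercion is precisely the class of data-entry accident a trial
pipeline must surface. Multiple irrigation records on one plot-day are
summed (physically additive); a missing PET value on any day is a hard
error since the balance cannot step without joint rain–PET forcing.

## Known limitations

* Single-store bucket: no layered soil physics, runoff, capillary rise or
  snow; nitrogen treatments are labels carried through, never modelled.
* No bare-soil evaporation: with cover 0 the store is inert, which
  overstates winter wetness slightly on real soils (harmless here, since FC
  estimation *assumes* winter wetness, but worth knowing).
* FC is per plot only; pooling across plots of one soil type is not
  implemented.
* The max-rule FC bias under noise, discussed above; use the quantile rule
  when probe visits are frequent.
* Event segmentation thresholds are conventions, not inferred from data.
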