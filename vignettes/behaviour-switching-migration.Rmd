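---
title: "Behaviour-switching analysis of juvenile southern bluefin tuna migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour-switching analysis of juvenile southern bluefin tuna migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbtmigrate)
```

## The problem

Juvenile southern bluefin tuna (*Thunnus maccoyii*, SBT) aggregate in the
Great Australian Bight (GAB) over the austral summer and disperse — mostly
westwards into the Indian Ocean, sometimes eastwards into the Tasman Sea —
over winter, returning the following summer. Daily-resolution geolocation
tracks from archival tags record these cycles, but raw positions do not say
*when* a fish is resident versus migrating. `sbtmigrate` classifies each
daily step into one of three behavioural states, segments tracks into
excursions ("trips"), summarises migration phenology on the annual circle,
and maps core residency areas.

## The model

All movement is referenced to a fixed point in the central GAB
(32°S, 130°E). For a track with daily positions, let $d_{GAB}(t)$ be the
great-circle distance (km, spherical Earth of radius 6371 km) from the
position on day $t$ to this reference, and let

$$ d_t = d_{GAB}(t) - d_{GAB}(t-1) $$

be the signed daily increment: positive when the fish moves away from the
GAB, negative when it closes in. This single 1-D observable carries the
behavioural signal of interest because SBT migrations are essentially
zonal excursions away from and back to one region.

A three-state hidden Markov model is placed on the $d_t$ series, with
latent states *resident* (1), *outward* (2) and *inward* (3) and transition
matrix

$$
\mathbf{P} = \begin{pmatrix}
\pi_{1,1} & \pi_{1,2} & \pi_{1,3} \\
\pi_{2,1} & \pi_{2,2} & 0 \\
\pi_{3,1} & 0 & \pi_{3,3}
\end{pmatrix}.
$$

The two zeros are *structural*: a fish cannot flip directly between
outward and inward migration, it must pass through residence (possibly for
a single day). Rows sum to one, so only four transition parameters are
free. Transition probabilities are constant over time. Conditional on the
state, the observation density is normal with state-specific mean and
standard deviation, $d_t \mid s_t = i \sim N(\mu_i, \sigma_i)$, with the
identifiability convention $\mu_{outward} > \mu_{resident} \approx 0 >
\mu_{inward}$ (the inward mean is negative internally; reporting prints
magnitudes). Fish whose tag ended before any return migration are fitted
with the two-state reduction (resident + one migratory state, the first
two rows/columns of $\mathbf{P}$), via `fit_two_state()`.

Note on the observable: we use the *signed displacement* convention for
$d_t$. An unsigned speed could not distinguish outward from inward with a
single observation stream, and unsigned per-direction observations would
require knowing the direction beforehand — the thing being inferred.

## Estimation and decoding

Parameters are estimated by pooled Baum–Welch EM (`fit_hmm()`): every
track contributes to one shared parameter set, matching the idea that the
population shares one behavioural repertoire, while decoding is per track.
Numerical choices:

* **Scaling.** The forward and backward recursions are normalised per
  step, and the emission log-densities are shifted by their per-step
  maximum before exponentiation, so series of $10^4$+ steps cannot
  underflow. The inner loops are in C++ (Rcpp), the standard approach for
  movement HMMs.
* **Structural zeros.** Expected transition counts are proportional to the
  current transition probability, so entries that start at exactly zero
  remain exactly zero through every EM iteration — verified bit-for-bit in
  the tests.
* **Initialisation.** State means start at the 50%, 90% and 10% quantiles
  of the pooled observations (resident, outward, inward), all standard
  deviations at the pooled SD, self-transitions at 0.9. Five restarts
  (jittered means) are run by default and the best likelihood kept.
* **Convergence.** Relative log-likelihood change below $10^{-8}$, cap of
  500 iterations (a warning and the best parameters on hitting the cap).
* **Variance floor.** $\sigma_i \ge 0.1$ km/day prevents a state from
  collapsing onto a point mass; disabling the floor turns a collapse
  ($\sigma < 10^{-3}$) into an error.
* **Label switching.** After convergence states are relabelled by the sign
  rule (most positive mean = outward, most negative = inward), attaching
  the ecological state meanings to the right components.
* **Initial distribution.** Defaults to the stationary law of
  $\mathbf{P}$; during EM it is estimated freely (constraining it to the
  stationary law of the updated matrix would break the monotone-likelihood
  guarantee that the tests rely on).

`decode_states()` returns both the Viterbi path (globally most probable
state sequence; ties break toward the lower state index) and
forward–backward posterior probabilities. Occupancy summaries use the
Viterbi path by default; posteriors are available for uncertainty-aware
summaries.

## Trips, phenology, residency

**Trips.** Tracks are segmented by a distance rule, not by the HMM: a
departure is the first day of a run of at least 120 consecutive daily
positions with $d_{GAB} \ge 500$ km, and the return is the first
subsequent day back inside 500 km. A position at exactly 500 km counts as
outside (the boundary convention; equality is otherwise undefined). A trip
still open when the track ends is censored — kept, with a missing return
date, because tags are recaptured by fisheries at sea. Return detection
uses the first threshold crossing; requiring a sustained re-entry run is
available via the same machinery but is not the default. Trip direction is
the sign of the net (shortest-way-around) longitude change over the first
30 days of the trip.

**Phenology.** Departure and return days-of-year are treated as angles
$\theta = 2\pi \cdot \mathrm{DOY}/365.25$ and smoothed with a von Mises
kernel density, so the Dec 31/Jan 1 boundary creates no artifact. The
kernel concentration defaults to a plug-in rule: the von Mises ML
concentration implied by the sample's mean resultant length, sharpened by
$n^{2/7}$ and capped at 500. The $n^{2/7}$ rate (bandwidth of order
$n^{-1/7}$) is the mode-estimation rate rather than the pointwise-density
rate $n^{-1/5}$: these densities are read off for their *peak days*, and
mode estimation calls for more smoothing. Peaks are the argmax on the
1-day grid; a flat density warns and returns day 1. Leap days map to
DOY 60; DOY runs 1–366, and a peak at the year boundary corresponds to the
printed "DOY 0" convention.

**Residency.** Positions whose decoded state is resident (each step's
state is attributed to the step's end day) feed a Gaussian product-kernel
density on a 0.5° lon/lat grid, expressed per km² with cos-latitude cell
areas and normalised to unit mass. Bandwidths default to Silverman's rule
per axis. Planar smoothing with cos-latitude weighting is adequate at the
latitudes SBT use (roughly 30–50°S); full spherical kernels are not
implemented. Core regions are 8-neighbour connected components of cells
above a density quantile (default 0.75 — a declared convention, since
published maps rarely state contour levels), ranked by contained mass.

## The synthetic-track simulator

No tag data are distributed, so the package carries a generative
counterpart of the analysis (`sim_config()`, `simulate_population()`).
Its defaults *are* the study conditions: 110 fish, two-year daily tracks,
state occupancy 0.57/0.25/0.18 with resident self-transition 0.93 (all
self-transitions then exceed 0.9), emission scales 0/14, 39.02/21.58 and
−31.08/22.65 km/day, 84% of excursions heading west, and 60% of fish
right-censored mid-excursion so the population contains one-way migrants.
The transition matrix is built in closed form from the target occupancy
(`transition_matrix_for_occupancy()`): with equal leave-probabilities for
the two migratory states, detailed balance on the star-shaped transition
graph gives exactly the requested stationary law.

Tracks are propagated in polar coordinates around the GAB reference:
radial increments are the state-conditional normal draws, resident wander
is isotropic (14 km/day per axis, so its radial component reproduces the
resident emission), and each excursion gets a bearing (west/east ± 10°)
that the fish turns onto at a bounded lateral speed. Because lateral
motion is applied *tangentially*, recomputing $d_{GAB}$ from the emitted
positions reproduces the internal radial draws to well under 0.5 km/day
RMS — the geometry and the generative model cannot drift apart. An
optional seasonal mode modulates the departure hazard around a peak
day-of-year for experiments that need phenology structure; it is off by
default because the core generative model is time-homogeneous.

What the simulator does *not* emulate: environmentally driven movement,
age-dependent drift, meridional structure, geolocation error. Passing
tests on synthetic data therefore demonstrates correctness of the
inference and segmentation machinery, not fidelity of any ecological
conclusion on real tracks.

**A boundary effect worth knowing about.** Distance to a point is bounded
below by zero, but the latent chain is position-independent: an inward
spell that reaches the reference point gets pinned at the distance floor
and emits near-zero displacements. Those steps are indistinguishable from
residence *in the observable*, so track-space simulations decode slightly
more residence than the stationary target — a property of the geometry,
not an estimator error. Estimator validation (parameter and occupancy
recovery) therefore uses `simulate_step_series()`, which samples directly
from the model's own observation space; the track-space simulator backs
everything genuinely geometric (telescoping, trip segmentation, mapping).
A characterisation test bounds the track-space residency excess.

## Validation design and problem sizes

The test-suite checks, at the sizes the package uses for routine
validation:

* forward likelihood, posteriors and Viterbi against brute-force path
  enumeration (200 random instances, ≤ 8 steps, ≤ 3 states, tolerance
  $10^{-10}$);
* EM parameter recovery on 100 series × 500 steps at the default
  emission/occupancy conditions (means and SDs recovered within
  1.5 km/day; decoded resident occupancy within 0.05 of target);
* the trip rule on constructed series (exact dates, 119-day negative
  control) and against simulator truth (≥ 90% of uncensored departures
  within ±2 days);
* circular peak recovery (95% of 200 replicates within ±7 days at
  $n = 100$, concentration 10);
* conservation laws: posterior rows, occupancy proportions and KDE mass
  sum to one; run-length mass equals per-state step counts; EM likelihood
  is monotone.

Track regularisation (one position per day; interior gaps of at most five
days bridged by great-circle interpolation along the shorter arc, longer
gaps splitting the track) is a declared convention of this package — daily
geolocation pipelines rarely publish their gap handling, and five days
keeps interpolated segments short relative to the 120-day trip rule.

## Known limitations

* The signed-displacement convention for $d_t$ is one of several possible
  operationalisations (unsigned speed, step length); results for strongly
  meridional movement would differ.
* One pooled parameter set is assumed for all fish; per-track fits are
  available but not the default, and no covariates enter the transition
  probabilities.
* Trip durations and maximum distances in simulated populations are
  emergent properties of the fitted chain, not calibrated targets; they
  come out in the observed range but longer on average than the field
  mean, because real departures and returns are seasonally forced while
  the default chain is time-homogeneous.
* The residency mapping is planar and does not mask land.
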