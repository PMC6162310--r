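# sbtmigrate

Behaviour-switching analysis of juvenile southern bluefin tuna (*Thunnus
maccoyii*, SBT) migration tracks.

Juvenile SBT spend the austral summer foraging in the Great Australian
Bight (GAB) and winter thousands of kilometres away in the Indian Ocean or
Tasman Sea. Archival tags yield daily position estimates over multiple
years, and the questions a movement ecologist or fishery scientist asks of
those tracks are behavioural: when is a fish resident, when is it
migrating out or back, when does it leave and return each year, and where
are its core residency areas? `sbtmigrate` answers these with a tested,
reusable pipeline: a constrained three-state hidden Markov model, rule-based
trip segmentation, circular phenology statistics, and kernel-density
residency mapping — plus a synthetic-track simulator with the same
generative structure, so the whole pipeline is verifiable without any
proprietary tag data.

## The model

Movement is summarised by the signed daily increment of great-circle
distance to a fixed GAB reference point (32°S, 130°E):
`d_t = d_GAB(t) − d_GAB(t−1)` (km/day). A hidden Markov model with states
*resident*, *outward* and *inward* is placed on `d_t`, with transition
matrix

```
         ⎛ π11  π12  π13 ⎞
    P  = ⎜ π21  π22   0  ⎟
         ⎝ π31   0   π33 ⎠
```

whose structural zeros forbid direct switches between the two migratory
states (a fish must pass through residence, if only for a day), and normal
state-conditional observation densities `d_t | s_t = i ~ N(μ_i, σ_i)`.
Estimation is pooled Baum–Welch EM with scaled forward–backward recursions
(C++ inner loops); decoding is per track by Viterbi plus posterior
smoothing. One-way migrants (tag recovered before any return) use the
two-state reduction. Trips are segmented by the distance rule — departure
= first day of ≥ 120 consecutive daily positions beyond 500 km, return =
first day back inside — and departure/return days-of-year are smoothed
with von Mises circular kernel densities.

## Worked example

Simulate a tagged population at the default study conditions, fit the
model, decode behaviour and segment trips:

```r
library(sbtmigrate)

sim   <- simulate_population(sim_config(n_fish = 30, n_steps = 730), seed = 7)
steps <- step_observations(sim$tracks)
fit   <- fit_hmm(steps)
fit
#> Behaviour-switching HMM fit (3 states, pooled over 30 tracks, 16939 steps)
#> log-likelihood: -74592.3 | iterations: 12 | converged: TRUE
#>
#> 3 state hidden Markov model (constrained: outward<->inward forbidden)
#> Transition matrix:
#>          resident outward inward
#> resident   0.9379  0.0377 0.0244
#> outward    0.0879  0.9121 0.0000
#> inward     0.1185  0.0000 0.8815
#> Emissions (km/day):
#> # A tibble: 3 × 3
#>   state        mean    sd
#>   <chr>       <dbl> <dbl>
#> 1 resident   0.0796  13.3
#> 2 outward   39.6     21.6
#> 3 inward   -30.3     22.4
```

The fitted self-transition probabilities all exceed 0.88 — behavioural
states are persistent from day to day — and the emission means say that
outward legs cover more ground per day (≈ 40 km) than inward legs
(≈ 30 km, printed as a magnitude; the observable is signed and inward
movement decreases `d_GAB`).

```r
dec <- decode_states(steps, fit)
occupancy_table(fit, dec)
#> # A tibble: 3 × 5
#>   state    proportion    iqr    mean    sd
#>   <chr>         <dbl>  <dbl>   <dbl> <dbl>
#> 1 resident      0.626 0.133   0.0796  13.3
#> 2 outward       0.257 0.139  39.6     21.6
#> 3 inward        0.117 0.0447 30.3     22.4
```

So these simulated fish spend roughly 60% of their time in resident mode,
a quarter migrating outward and the rest returning. Trip segmentation and
direction:

```r
trips <- detect_trips(add_gab_distance(sim$tracks))
trip_summaries(trips)
#> # A tibble: 1 × 11
#>   n_trips n_complete duration_mean duration_sd duration_min duration_max
#> 1      30          3          131.        8.74          124          141
#>   maxdist_mean maxdist_sd maxdist_max frac_westward frac_eastward
#> 1        4316.      2326.      10989.         0.933        0.0667
```

Thirty excursions beyond 500 km were detected, most heading west, reaching
on average ≈ 4300 km from the GAB; only three completed within these
two-year tracks (the rest were right-censored by tag recovery, as in real
deployments). Phenology comes from `circular_density()` /
`circular_peak()` on the departure and return dates, and residency maps
from `resident_points() |> kde2d_map() |> extract_regions()`. Each result
type has a plot helper (`plot_track_states()`, `plot_phenology()`,
`plot_state_doy()`, `plot_residency()`, `plot_run_lengths()`,
`autoplot()` on fits), and fitted models serialise with
`write_hmm_params()` / `read_hmm_params()`.

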