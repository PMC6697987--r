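# tremorprofile

Personalised tremor profiling from multichannel movement recordings.

Upper-limb tremor — in multiple sclerosis especially — shows large
test–retest variability: the same patient can measure very differently on
two occasions for reasons that have nothing to do with disease change. This
has kept wearable-sensor tremor metrics from beating simple clinical
observation at the one task that matters clinically: detecting *change* in
an individual's symptoms. `tremorprofile` implements a personalised answer:
treat each subject's multi-joint tremor amplitudes as a vector, learn the
subject's characteristic blend of joint involvement, and measure change
*along* that blend separately from change *away from* it, normalised by the
subject's own same-day variability.

## The model

For each execution of a standardised task (e.g. holding the finger at the
nose), the package extracts one tremor amplitude per movement parameter
(15 joint rotations plus hand displacement and rotation in their dominant
axes), giving a measurement vector
`a_i = [a_{i,1}, …, a_{i,N}]` of representative log-amplitudes, with
explicit nulls where no reliable tremor was detected. Amplitudes come from
the **ATA** estimator — the square-root power spectral density summed over a
±1 Hz band around the tremor peak `f_T` (the PSD maximum in 2–10 Hz, band
clamped to `[max(2, f_T−1), min(10, f_T+1)]`) — calibrated so a pure
sinusoid returns its peak-to-peak amplitude. Unreliable spectra are rejected
by heuristics that compare the tremor band against the fluctuation of the
rest of the 2–10 Hz band.

A subject's **characteristic vector** `a_c` is the per-parameter mean of
their valid measurements. The difference between two measurements `a_A`,
`a_B` is then decomposed against the unit profile `â_c`:

- scale change `d_S  = (a_B − a_A) · â_c` (signed: worse/better),
- scale2 change `d_S2 = (a_B − a_A) · â_c2`, where `a_c2` squares each
  element first, exaggerating the dominant joints,
- profile change `d_P = ‖(a_B − a_A) − d_S â_c‖` (≥ 0: the blend changed),
- mean difference `d_M = mean(a_B − a_A)` (the conventional comparator).

Between two visits (days `p`, `q`, two instances each) every metric is
normalised by intrinsic variability:

    d'_X = mean(d_X(a_p1, a_q1), d_X(a_p2, a_q2)) /
           mean(|d_X(a_p1, a_p2)|, |d_X(a_q1, a_q2)|)

Metric families are evaluated by squared Spearman correlation against
changes in Fahn–Tolosa–Marin Tremor Rating Scale references (task-based
part B, self-assessed part C), with Benjamini–Hochberg false-discovery-rate
control across the family of joint counts `N`. A synthetic cohort and raw
signal generator with known ground truth makes every stage testable.

## Worked example

```r
library(tremorprofile)

# a subject's profile from two measurements over three joints
cv <- characteristic_vector(matrix(c(0.8, 1.9, 0.2,
                                     0.7, 2.1, NA), nrow = 2, byrow = TRUE,
       dimnames = list(NULL, c("wrist", "forearm", "shoulder"))))
cv
#> <characteristic_vector> (plain) over 3 parameters
#>    wrist  forearm shoulder
#>     0.75     2.00     0.20

scale_change(c(0.8, 1.9, 0.2), c(1.3, 2.6, 0.4), cv)    #> 0.846
scale2_change(c(0.8, 1.9, 0.2), c(1.3, 2.6, 0.4), cv)   #> 0.765
profile_change(c(0.8, 1.9, 0.2), c(1.3, 2.6, 0.4), cv)  #> 0.253
```

The change from A to B is mostly a scaling-up of this subject's usual
tremor (`d_S = 0.85` log-units along the profile) with a smaller
re-blending component (`d_P = 0.25`).

End to end on a synthetic cohort (24 subjects, 15 joints, two visits):

```r
sim    <- simulate_cohort_vectors(seed = 42)
amp    <- dplyr::rename(sim$vectors, log_ata = value)
scores <- simulate_observer_scores(sim$truth, seed = 43)
ev     <- evaluate_metric_family(amp, scores, hand_params = character(0))
dplyr::filter(ev, metric_id == "joint_scale2", reference == "ftmtrs_c",
              n_joints == 15)
#>   metric_id    type   reference n_joints   rho  rho2       p  p_fdr n_points
#> 1 joint_scale2 change ftmtrs_c        15 0.574 0.329 0.00337 0.0118       24
```

Here the variability-adjusted scale2 change correlates with the change in
the self-assessed impact score (ρ² = 0.33) and survives FDR control
(pFDR = 0.012) — on a cohort where the simulated observer scores are a
noisy, discretised readout of the same latent severity that drives the
tremor amplitudes.

A command-line front end for file-based workflows is installed at
`system.file("exec", "tremorprofile", package = "tremorprofile")` with
subcommands `extract`, `profile`, `change`, `evaluate`, `simulate` and
`discretise`.

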