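# finepitch

Patient-specific quality assurance (PSQA) for stereotactic radiosurgery
(SRS) demands dose-distribution verification across very steep gradients:
a 1 cm cranial target planned to fall from ~100% to ~10% dose within a few
millimetres. General-purpose semiconductor diode arrays are reusable and
cheap but sample at a 10 mm pitch, far too coarse for such penumbrae, which
traditionally forces clinics onto radiochromic film or dedicated
high-resolution SRS arrays.

`finepitch` simulates and scores an alternative workflow: repeat the array
measurement under small, known translations of the treatment couch and merge
the shifted acquisitions onto a common grid, producing a *virtual* detector
spacing of 5, 4, 3, 2 or 1 mm from a native 10 mm array. The package
provides everything needed to study this method fully in silico, end to end:

* **Synthetic reference dose distributions** with error-function penumbrae —
  a single-field plan for a 1 cm target on a 1 mm grid, and a
  single-isocenter multiple-target (SIMT) geometry with two targets offset
  ±60 mm superior–inferior.
* **Detector models** — a rectangular diode array (10 mm pitch, 0.8 × 0.8 mm²
  active areas, optional 7 × 3 mm² diode-envelope averaging for
  partial-volume studies) and a fine-grid film stand-in, both with
  reproducible multiplicative reading noise.
* **Couch-shift planning and merging** — `plan_shifts()` derives the offset
  series that realises a requested virtual spacing; `merge_measurements()`
  assembles the shifted acquisitions onto the virtual grid.
* **Scoring** — central-axis profile RMSE and a 2D gamma (γ) index with
  configurable dose-difference/distance-to-agreement tolerances, low-dose
  threshold, and global or local normalization.
* **A one-command replication experiment** relating virtual spacing to
  profile RMSE and γ pass rate across seeded replicates.

## The quantities computed

Profile agreement is scored by the root-mean-square error between the
reference (planning-system) dose and the measured dose along the central
superior–inferior axis, both in percent of the reference maximum:

    RMSE(%) = sqrt( (1/n) * sum_i ( D_ref,i − D_meas,i )² )

where the sparse measured profile is first interpolated onto the reference
grid's positions along the line, so a coarse array is penalised for the
gradient it cannot see.

Dose-distribution agreement uses the γ index. For an evaluated point *i* at
position r_i with dose D_e(i), with dose criterion ΔD (e.g. 3% of the global
maximum) and distance criterion δ (e.g. 3 mm):

    γ(i) = min over r of sqrt( |r − r_i|²/δ² + (D_ref(r) − D_e(i))²/ΔD² )

and the point passes when γ ≤ 1. Points below a dose threshold (default 10%
of the reference maximum) are excluded.

## Worked example

Synthesise a 5 mm virtual spacing from two couch-shifted 10 mm acquisitions
of the single-field target, then score it:

```r
library(finepitch)

grid <- generate_single_field()       # 1 cm target, erf penumbra, 1 mm grid
sched <- plan_shifts(10, 5, "SI")
sched
#> <shift_schedule> SI axis: 10 mm pitch -> 5 mm virtual spacing
#>   2 acquisition(s), couch offsets (mm): 0, 5

layout <- detector_layout()           # 10 mm pitch, 0.8 x 0.8 mm active area
acqs <- lapply(seq_along(sched$offsets), function(k)
  sample_dose(grid, layout, shift = c(sched$offsets[k], 0),
              noise = noise_model(0.005, seed = k), quiet = TRUE))
virtual <- merge_measurements(acqs, sched)
virtual
#> <measurement> 171 points, mode array, merged SI spacing 5 mm
#>   SI range [-45, 45] mm, RL range [-40, 40] mm, dose range [0.99, 97.9]

compute_rmse(extract_profile(grid, virtual, axis = "SI", at = "grid"))
#> <rmse_result> RMSE = 5.0582% over 91 pairs

gamma_index(grid, virtual, gamma_params(3, 2, threshold = 10))
#> <gamma_result> 3%/2 mm (global, threshold 10%): 3/3 pass (100.0%)
```

The RMSE of ~5% reflects the penumbra still being undersampled at 5 mm; the
γ analysis at 3%/2 mm passes at every evaluated point because each sampled
dose agrees with the reference nearby. Running the full study shows the
spacing effect directly:

```r
ex <- run_experiment(experiment_config(scenario = "simt", seed = 1))
summary(ex)$rmse
#>   array 10 mm    4.72% +- 0.05%
#>   array 5 mm     4.65% +- 0.05%
#>   array 4 mm     2.49% +- 0.04%
#>   array 3 mm     1.51% +- 0.04%
#>   array 2 mm     0.79% +- 0.01%
#>   array 1 mm     0.27% +- 0.01%
#>   film (1 mm)    0.13% +- 0.02%
```

Refining the virtual spacing drives the profile error monotonically down
toward the film stand-in, the method's central qualitative claim.

A thin command-line front end over the same functions ships at
`system.file("cli", "finepitch.R", package = "finepitch")`, with subcommands
`simulate-dose`, `sample`, `plan-shifts`, `merge`, `rmse`, `gamma` and
`run-experiment`.

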