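# pillartrack

Contractility analysis of engineered heart tissues (EHTs) from brightfield
video, for labs running pillar-based EHT platforms. An EHT is a strip of
cardiomyocytes anchored between two elastic pillars; each beat bends the
pillar tips toward each other, and tip deflection × pillar stiffness is the
contractile force. The motions involved are routinely *smaller than one
pixel*, so the package's core is a sub-pixel tracker:

1. **Template matching.** Left/right pillar templates are cut from the
   first frame at the bounding boxes of the two largest connected
   components of the pillar class in a segmentation mask, then matched in
   restricted search regions with the normalized correlation coefficient

   *R(x,y) = Σ T′ I′ / √(Σ T′² · Σ I′²)*,

   mean-subtracted over the template support (1 = perfect match,
   invariant to affine intensity changes).
2. **Sub-pixel refinement.** A bicubic spline is fitted through the
   accumulator samples around the integer peak and maximized with
   Nelder–Mead (positional tolerance 0.0001 px), giving decimal pillar
   positions.
3. **Physiology.** The inter-pillar distance *T*<sub>pixel</sub> becomes
   displacement = *T*<sub>pixel</sub>·a − L₀ (pixel size *a*, resting
   distance L₀ = 3.2 mm by default); per beat the package reports force
   (F = k·contraction/2 per pillar), contraction/relaxation velocities and
   TC10/TC90/TR10/TR90 times.
4. **Verification.** A simulator renders videos with exact sub-pixel
   ground truth (sine-driven sprite motion, seeded additive noise) and
   scores the full pipeline with MAE/MSE across noise and frequency
   grids.

## Worked example

Simulate a standard verification video (2 Hz sine, 2 px per-side
amplitude, 100 fps, 10% added noise), track it, and score against ground
truth:

```r
library(pillartrack)

spec <- default_simulation_spec(n_frames = 300, noise_frac = 0.10, seed = 7)
sim  <- generate_video(spec)
traj <- track_simulation(sim, margin_px = 20)
head(traj[, c("frame", "time_s", "distance_px", "displacement_mm")], 3)
#> # A tibble: 3 × 4
#>   frame time_s distance_px displacement_mm
#>   <int>  <dbl>       <dbl>           <dbl>
#> 1     0   0           280.      0.00000135
#> 2     1   0.01        280.     -0.00495
#> 3     2   0.02        279.     -0.0112

score_tracker(traj, sim$truth)
#> <error_stats> MAE 0.0322 px, MSE 0.001535 px^2 over 300 frames
```

The tracker recovers the sub-pixel waveform to 0.03 px under 10% noise.
The same trajectory feeds the contractile analysis:

```r
cal <- calibration(stiffness_mN_per_mm = 2.8,
                   pixel_size_mm = spec$pixel_size_mm, fps = 100)
m <- contraction_metrics(traj, cal)
m
#> <eht_metrics> 6 beat(s) at 2 Hz, mode = per_pillar
#>   mean force 0.0664 mN, TC90 0.0898 s, TR90 0.122 s

glance(m)[, c("n_beats", "beat_rate_hz", "force_mN_mean", "tc90_mean")]
#> # A tibble: 1 × 4
#>   n_beats beat_rate_hz force_mN_mean tc90_mean
#>     <int>        <dbl>         <dbl>     <dbl>
#> 1       6            2        0.0664    0.0898
```

Six beats in 3 s of 2 Hz pacing; the 2-px peak-to-peak shortening at this
scene's pixel size (0.011 mm/px) and a 2.8 mN/mm pillar corresponds to
~0.07 mN per pillar. `tidy(m)` returns the per-beat table,
`autoplot(traj)` / `autoplot(m)` the displacement and force plots.

For real recordings the entry point is either the functions above
(`read_video()`, `read_label_mask()`, `extract_pillar_templates()`,
`track_video()`, `contraction_metrics()`, `write_results()`) or the batch
driver:

```r
analyze_videos("videos/", "masks/", "calibration.yaml", "results/")
```

which writes per-video trajectory and metrics CSVs, contraction plots, a
`summary.csv` over all videos and a run log. A thin command-line wrapper
with `analyze` / `verify` / `simulate` subcommands is installed at
`inst/cli/pillartrack.R`.

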