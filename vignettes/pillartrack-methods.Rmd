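---
title: "Sub-pixel pillar tracking and contractility analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-pixel pillar tracking and contractility analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillartrack)
```

## The measurement problem

Engineered heart tissues (EHTs) are strips of stem-cell-derived
cardiomyocytes anchored between two flexible pillars. Each beat pulls the
pillar tips toward each other; because a pillar behaves as a linear spring,
the tip deflection times the pillar bending stiffness is the contractile
force. Everything therefore hinges on measuring the inter-pillar distance
from brightfield video, precisely enough to resolve motions well below one
pixel: at typical magnifications a weak tissue moves the tips by only a few
micrometres.

pillartrack measures that distance by template matching. A template for
each pillar is cut from the first frame at the tight bounding box of the
two largest connected components of the pillar class in a user-supplied
segmentation mask (robust to small spurious blobs elsewhere in the mask).
Matching is restricted to a search region around each template — cardiac
tissue shortens by far less than the inter-pillar gap, so a generous margin
along the pillar-to-pillar axis plus a small transverse margin is enough,
and it keeps the per-frame cost low.

## Matching model

Each candidate placement is scored with the normalized correlation
coefficient

$$R(x,y) \;=\; \frac{\sum_{x',y'} T'(x',y')\, I'(x+x',y+y')}
{\sqrt{\sum T'^2 \;\sum I'^2}},$$

where $T'$ and $I'$ are the template and image window after subtracting
their means over the $w \times h$ template support. $R = 1$ is a perfect
match; the score is invariant to affine intensity changes, which makes it
robust to illumination drift. Windows with zero intensity variance are
scored 0 rather than left undefined, so flat background can never win the
argmax. The accumulator is computed either by direct window extraction or
by an FFT cross-correlation with integral-image window sums; both paths
agree to better than $10^{-10}$ and the direct path is kept as the
reference in the test suite.

## Sub-pixel refinement

The integer argmax of the accumulator quantizes the trajectory to whole
pixels. To refine it, a tensor-product natural cubic spline ("bicubic
spline") is fitted through the `window` x `window` accumulator samples
around the peak (default 7 x 7: at least four knots per axis with margin)
and maximized with a Nelder–Mead simplex started at the integer peak.

Two numerical choices matter here:

* **Stopping rule.** The optimizer terminates when the simplex diameter
  falls below `tol` = 0.0001 px, i.e. the tolerance is a *length in
  pixels*, the natural unit for a localization problem. This is why the
  package carries its own compact simplex implementation: the stock
  optimizers stop on objective-value changes, which have no fixed
  relationship to position.
* **Search domain.** The continuous peak always lies within half a pixel
  of the noise-free integer argmax, but under heavy noise the *observed*
  argmax can land one sample off. The refinement therefore first scans the
  interpolated surface on a coarse half-pixel grid (the integer peak is
  evaluated first, so exact symmetric peaks resolve to the integer) and
  then refines from the best coarse point, with the search confined to the
  inner part of the spline window. Clamping instead to ±1 px of the
  observed argmax would lock in half-pixel errors whenever noise displaces
  the argmax.

If the peak sits on the accumulator border the refinement is not defined;
the integer match is returned with a `border_peak` flag.

The anchor point reported per frame is the template-box centre. With a
rigid template any fixed anchor differs from the physical pillar centroid
by a constant, which cancels in the displacement trajectory. Templates are
fixed from frame 1 and never updated, which avoids adaptive-template
drift. Frames whose best score falls below `min_score` (default 0.3, far
below the ≥0.9 typical of valid matches) are flagged and imputed from the
previous frame.

## From trajectory to physiology

The per-frame distance $T_{\text{pixel}}$ between the left and right
anchors is converted with the pixel size $a$ (mm/px) and resting
inter-pillar distance $L_0$ (default 3.2 mm, configurable):

$$\text{displacement (mm)} = T_{\text{pixel}} \cdot a - L_0 .$$

Beats are local maxima of the contraction trace (negated displacement)
whose topographic prominence exceeds `prominence_frac` (default 0.3) of
the global range; boundaries lie at the surrounding crossings of the trace
median. Per beat, the diastolic baseline is the median displacement of the
preceding inter-beat interval — robust to slow drift. From the beat-local
contraction:

* **Force**: $F = k \cdot \text{contraction}/2$ per pillar (default),
  attributing half the inter-pillar shortening to each tip; a `total` mode
  reports $k \cdot \text{contraction}$. The factor-of-two convention is a
  genuine ambiguity of two-pillar systems; both readings are exposed.
* **TC10/TC90**: first times the contraction rises through 10%/90% of the
  beat amplitude, measured from beat start; **TR10/TR90**: first times it
  falls 10%/90% below the peak, measured from the peak. Crossings are
  located by linear interpolation between samples, so they are accurate to
  well under one frame period (0.01 s at 100 fps).
* **Velocities**: extrema of the 5-point-smoothed central-difference
  derivative of the contraction trace over the rising and falling phases,
  reported in mm/s. (Force-trace velocities differ only by the constant
  $k/2$, so the choice of trace affects units, not shape.)

Relative force across drug conditions is the ratio of each condition's
mean force to a designated baseline condition
(`dose_response_summary()`).

## The verification harness

Because no real video comes with sub-pixel ground truth, the tracker is
validated on synthetic videos: a static background, two half-tissue
sprites each carrying one pillar, translated horizontally by
$s(t) = A \sin(2\pi f t + \phi)$ (left sprite $+s$, right $-s$, so the
distance trace is $D_0 - 2s(t)$), composited by cubic-convolution (Keys)
resampling, plus additive noise. The defaults mirror the standard
verification condition: $A = 2$ px per side, $f = 2$ Hz, 100 fps, 10%
noise. "X% added noise" means amplitude-bounded uniform noise in
$\pm X\%$ of the clean video's intensity dynamic range, seeded and
reproducible; a Gaussian alternative ($\sigma = X\%/3$ of range) is a
switch. Noise levels are capped at 25% — beyond that the definition of
"dynamic range" itself becomes noise-dominated.

Deliberately, the simulator and the tracker use *different* interpolants
(Keys cubic convolution to generate, natural splines to refine), so the
harness cannot confirm the tracker through a shared resampling kernel.

The default scene is proportioned like a real brightfield EHT recording:
a 380 x 580 px frame, two hollow pillar tips (a dark annulus around a
bright core, as the tips appear in brightfield) about 280 px apart, a
darker tissue band, fine speckle on tissue and pillars, and a global
0.5-px Gaussian blur for the optical band limit. Two of these properties
are load-bearing for precision:

* **Template area.** The template cut from the first frame carries that
  frame's noise. Its interaction with per-frame noise perturbs
  accumulator entries by $O(\sigma_n^2/(\sigma_T\sigma_I\sqrt{N}))$ — a
  *quadratic* function of the noise level — so the ~130 x 250 px
  (N ≈ 30k) templates of a realistically proportioned scene are what make
  high noise fractions survivable.
* **Peak curvature.** Sub-pixel jitter is entry noise divided by the
  curvature of the correlation peak, which is set by the texture
  bandwidth. The hollow pillar tip and cellular speckle supply that
  curvature; a featureless dark blob does not.

What the simulation does *not* emulate: illumination drift, focus
changes, out-of-plane pillar motion, tissue deformation over the
template, and debris. Passing the harness therefore demonstrates the
precision of the *localization machinery* under noise, not robustness to
every artefact of live imaging.

Tracking error is scored per frame against the recorded ground truth
after de-meaning both traces (a constant anchor offset carries no
waveform information): MAE $= \frac1n \sum |y_i - x_i|$ and MSE
$= \frac1n \sum (y_i - x_i)^2$.

## Problem sizes and parameters used in the shipped checks

The packaged test suite runs the full sweep at 200 frames per video with
three noise seeds, noise levels 5–25% and 1 and 2 Hz waveforms; the
acceptance script uses 500-frame videos. The search-region margin for
simulated videos is set to 20 px — ten times the maximal 2-px excursion —
rather than the default quarter-gap rule, which is sized for unknown real
motions; the margin only bounds the searched area and does not affect the
estimates. Sweeps report per-level means over seeds.

Key defaults, with units: `window` = 7 accumulator samples per axis;
`tol` = 0.0001 px; `min_score` = 0.3; `margin_px` = 25% of the
inter-template gap (tracking real videos); `transverse_margin_px` = 8 px;
`prominence_frac` = 0.3 of the contraction range; `rest_distance_mm` =
3.2 mm; noise model `uniform`.

## Known limitations

* Rigid-template tracking: rotation or deformation of the pillar image is
  not modelled (flagged scores will reveal gross failures).
* The beat detector assumes a dominant diastolic baseline; continuous
  tachyarrhythmia-like traces without baseline returns will merge beats.
* The pixel size $a$ and stiffness $k$ are user inputs; the package
  cannot validate them beyond positivity.
* Integer-frame videos quantized to 8 bits lose some of the precision
  headroom; 16-bit input is preferred.
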