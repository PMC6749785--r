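---
title: "Simulating wiggle discrimination under disruptive camouflage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating wiggle discrimination under disruptive camouflage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wigglecamo)
```

## The problem

Disruptive colouration (DC) — contrasting pigment patches that create false
edges across a target's surface — is one of the best-studied camouflage
strategies, and in many animals it comes with *edge enhancement* (EE):
light patches carry lighter rims and dark patches darker rims, exaggerating
the contrast of the false edges. Beyond hiding a target, such colouration
may distort the perception of its *shape*. A clean psychophysical probe of
this idea is a curvature ("wiggle") discrimination task: show two
snake-like silhouettes side by side, let one be more sinuous than the
other, and measure the smallest wiggle difference an observer can detect.
If that threshold rises under EE DC relative to flat DC or uniform
colouring, edge-enhanced camouflage is degrading contour-shape perception
itself, not merely concealment.

`wigglecamo` implements this entire experimental chain as a reproducible
simulation: stimulus synthesis, an adaptive two-alternative forced-choice
(2AFC) experiment run against statistical observers, psychometric threshold
fitting, and Bayes-factor group inference. Simulated observers stand in for
humans, so the pipeline cannot reproduce any particular human dataset; what
it can do is verify, end to end, that the design recovers known ground
truth and detects a built-in ordering of condition effects.

## Viewing geometry

All sizes are specified in degrees of visual angle under a fixed geometry:
a 1,024-px stimulus subtending 29.86° at a 600-mm viewing distance. The
pixel pitch follows from the full-extent arctangent relation
$\theta(n) = 2\,\mathrm{atan}\!\left(n p / 2d\right)$
rather than small-angle scaling; the linear approximation cannot reconcile
a 29.86° full extent with the printed 82 px ≈ 2.44° snake width, while the
arctangent geometry reproduces both (82 px → 2.446°). The 82-px pair is
therefore treated as a checked consequence of the (1,024 px, 29.86°)
calibration, to within rounding of the printed value.

## Stimulus synthesis

**Texture.** Camouflage patterns start as white Gaussian noise filtered in
the Fourier domain by a radial Gaussian gain
$\exp\{-(d-\mu)^2 / 2 s^2\}$ with peak $\mu = 0.07$ cycles/pixel. The
bandwidth parameter is printed as a dimensionless multiplier
$\sigma = 120$; read with $s = \sigma\mu$ in cycles/pixel the gain would be
essentially flat over the whole representable band (|d| ≤ ~0.7), which
cannot produce a patterned texture. We therefore read $\sigma\mu$ in cycles
*per image*, i.e. $s = \sigma\mu/\text{size}$ cycles/pixel, which yields a
narrow band-pass peaked at a ~14-px period and a patch structure at the
scale of the snake body. Both $\mu$ and $\sigma$ are config-exposed, so
other readings are one line away. The filtered field is posterised at its
median — strictly-above pixels take the lighter colour, ties go to the dark
label (a measure-zero event on a continuous field, made deterministic) — so
each tone covers half the field by construction.

**Colours.** Patch colours are drawn from the leafy background's own pixel
population: the darker tone uniformly from pixels in the 35th–45th CIE L
percentile band, the lighter from the 55th–65th, so the pair straddles the
median lightness of the scene. The uniform control is a constant field at
the CIELAB midpoint of the two patch colours, matching the mean lightness
of the disruptive patterns. All colour arithmetic runs in CIELAB under the
D65 2° observer (via `farver`), with gamut clipping on the way back to
sRGB.

**Edge enhancement.** EE is parameterised by a total band width (0.63°,
both sides of a patch boundary combined) and a lightness offset (60 CIE L
units). Every pixel whose centre lies within half the band width of the
patch boundary has its L shifted by the full offset — up on light patches,
down on dark ones. Band membership is computed from a Euclidean distance
transform on the label map minus the half-pixel offset between a pixel's
centre and the boundary plane: the usual rasterisation convention, chosen
because the raw centre-to-centre distance would overcount the boundary gap
by half a pixel per side and leave a straight boundary's realised band a
full pixel narrower than the nominal 0.63°. The luminance profile across the band is a flat step by default;
a linear ramp is config-selectable, since the published profile sketch is
schematic. With a 60-unit offset most band pixels clip against the gamut
(L cannot exceed 100); the object therefore records the signed pre-clipping
shift (`$ee_dL`) so the nominal offset remains measurable. Note that at the
default texture scale the patch period (~14 px) is smaller than the band
width (~21 px), so effectively the whole pattern is enhanced; the band
geometry is still exactly verifiable on a straight synthetic boundary.

**Leafy background.** The background is 4,096 leaf shapes with mean height
0.68°. Leaf construction details are not specified by the design we
emulate, so the package's leaves are rotated ellipses: heights log-normal
around the mean (25% relative s.d., with the mean of the log-normal set to
the target mean), width 1.6× height, rotation jitter ~N(0°, 15°). The
rotated ellipse is rescaled so its vertical extent equals the drawn height,
which makes "realised height" exact and the realised mean an unbiased match
to the configured mean. Colours come from a naturalistic CIELCh population
(L ~ N(50, 12) truncated to [20, 80], hue ~ N(120°, 25°), chroma ~
N(30, 8)) — greens and browns with a broad lightness spread so the
percentile palette bands are never empty. Leaves land uniformly on a
torus-wrapped canvas in random order; 4,096 leaves of this size cover
roughly 93% of the canvas stochastically, so the canvas is first painted
with a base colour drawn from the same population — no pixel ever shows a
non-leaf colour, and the painted fraction is recorded. Each leaf casts a
"shadow": its own silhouette shifted 0.15° leftward (excluding the leaf
itself, identified per-pixel from the ownership map) multiplies CIE L by
0.70. Shadows are computed from geometry and applied to the unshadowed
image, so the pass is idempotent.

**Snake targets.** The original target was a clip-art snake silhouette that
is not redistributable, so the package generates one procedurally: a
constant-thickness (0.45°) tube following $x(t) = A \sin(2\pi k t)$ over a
9.73° vertical span with $k = 2.5$ periods and a rounded head, with $A$
bisected once per geometry so the amplitude-1.0 silhouette spans exactly
82 px between its leftmost and rightmost pixels. This preserves the
construct under test — horizontal rescaling modulates curvature amplitude —
and every printed dimension. Other amplitudes resample the base bitmap
row-wise with linear interpolation and a 0.5 re-binarisation, so width
tracks `round(a × 82)` exactly while height never changes. In a scene the
two snakes sit 15.9° apart centre-to-centre (±7.95° from fixation: a
per-snake eccentricity of 15.9° would fall outside the 29.86° stimulus, so
the printed figure is read as the separation, and it is config-overridable)
with independent vertical offsets uniform in ±1.49°, each sampling an
independently drawn texture instance — texture draws per trial are
independent per snake, the more conservative reading.

## The simulated experiment

**Observers.** A simulated observer responds to the folded amplitude
difference $\Delta = |a_\text{target} - a_\text{foil}|$ through
$p(\Delta) = \gamma + (1-\gamma-\lambda_\text{gen})\,
\mathrm{logistic}(\beta_\text{gen}(\Delta - \Delta^*))$
with guess rate $\gamma = 0.5$, a per-observer lapse rate (default 0.02),
slope, and per-condition true thresholds $\Delta^*$; at $\Delta = 0$ the
response is defined as a fair coin. The observer is deliberately
pedestal-invariant: the shared pedestal exists to block absolute-amplitude
strategies in humans, which a statistical observer has no analogue of (a
pedestal-sensitive variant is config-switchable). It is statistical, not
image-computable: sessions need not render a single pixel, which keeps a
full study cheap; trial records carry every scene parameter so any trial's
image can be rendered after the fact.

**Staircases.** Each colouration × background condition runs two
interleaved staircases starting at 1.2× and 0.8× baseline, 30 trials each,
with a shared pedestal drawn per trial from −0.2…+0.2 in 0.05 steps. The
adaptive rule is three-down-one-up on the unsigned difference |level − 1|:
this is the transformed up-down rule whose equilibrium satisfies
$p^3 = 1/2$, i.e. 79.37% correct — the printed convergence target, which is
how the rule was identified (the design we emulate names only the
convergence point). Steps start at 0.05, halve at each of the first two
reversals, and floor at 0.0125; the difference is also floored at one
minimum step so a staircase can never cross baseline and silently invert
its response mapping, and levels are clamped to [0.3, 2.5] (the range over
which the mask resampling is defined). The per-trial staircase choice,
pedestals, side assignments and observer responses each draw from their own
seed-derived substream, so any component can be replayed in isolation.

**Fitting.** Each condition's 60 trials are folded to $\Delta$, aggregated
to per-level proportions correct, and fit by weighted least squares (trial
counts as weights) with the logistic
$\psi(\Delta) = 0.5 + 0.5\,\mathrm{logistic}(\beta(\Delta - \alpha))$,
$\gamma = 0.5$ and $\lambda = 0$ held fixed — so $\psi(\alpha) = 0.75$
identically and the reported threshold is simply $1 + \alpha$. Folding both
staircases onto one increasing function is the only convention under which
a single logistic fit across the above- and below-baseline staircases is
well-defined. Least squares on binned proportions (not trial-level
likelihood) is used deliberately to match the analysis being emulated.
Optimisation is bounded L-BFGS-B (α ∈ [0.005, 0.6], β ∈ [1, 200]) from a
3×3 start grid plus a data-driven start at the level nearest 75% correct,
keeping the best of all starts; fits with α pinned to a box edge (e.g.
all-correct data) are flagged rather than silently reported.

**Group inference.** Condition comparisons use default-prior (JZS) Bayes
factors: a Cauchy(0, r = √2/2) prior on the standardised effect under H1
against a point null, computed by adaptive quadrature of the g-prior
integral to 1e-8 relative tolerance — the same default as the common
desktop Bayesian software, and config-exposed. The test suite cross-checks
it against an independent brute-force integration of the equivalent
noncentral-t ⊗ Cauchy formulation. Evidence labels follow the standard
bands (anecdotal ≤ 3 < moderate ≤ 10 < strong ≤ 30 < very strong ≤ 100 <
extreme, mirrored for H0). Group threshold summaries carry percentile
bootstrap 95% CIs over participants. Tests are two-sided by default; the
baseline comparisons support a one-sided option. No multiplicity
adjustment is applied, matching the practice being emulated. A Bayesian
ANOVA model comparison is deliberately out of scope; the pairwise and
one-sample tests carry the inferential surface.

## The synthetic cohort

The default cohort has 26 observers. Per-condition mean true thresholds
are `uniform.leafy` 0.10, `flat.leafy` 0.12, `ee.leafy` 0.20,
`uniform.grey` 0.09, `flat.grey` 0.10, `ee.grey` 0.15 (between-observer
s.d. 0.04, slopes ~N(20, 4) truncated above 2, lapses ~N(0.02, 0.01)
truncated to [0, 0.06]). These magnitudes are the package's own choices,
not measured values: they encode the qualitative ordering EE DC > flat DC >
uniform on both backgrounds, at effect sizes a 26-participant design has
adequate power to detect, which is exactly what the end-to-end check
asserts (the ordering and BF > 10 for EE-vs-flat recovered in ≥ 80% of 100
simulated studies). Because observers are pedestal-invariant,
threshold-only creatures, passing tests demonstrate that *the design and
analysis recover the generative structure* — they say nothing about how
image content drives human thresholds.

## Numerical choices and problem sizes

- Staircase equilibrium is verified with a free-running 100,000-trial
  staircase; the observer's true percent-correct at the mean post-burn-in
  level falls within 0.5 points of 79.37.
- Parameter recovery runs 200 sessions at each true threshold in
  {0.08, 0.15, 0.25} with slope 25; the median recovered threshold sits
  within 0.03 of truth, the mean within 0.02.
- Spectral and posterisation checks run at 256-px texture size (20 seeds);
  the band-pass peak is located to within one frequency bin (1/256
  cycles/pixel). Full-scale (1,024-px) textures behave identically; the
  reduced size keeps the default test run fast.
- The end-to-end power check simulates 100 full studies (26 observers ×
  360 trials). Thresholds for it are fit on the leaf-background conditions,
  where the ordered contrast lives.
- Exact-recovery fitting tests build trials whose per-level proportions lie
  exactly on a known logistic, so zero residual is attainable and the
  optimiser must return the generating (α, β).

## Known limitations

- Observers are not image-computable; nothing links pixel content to
  thresholds, by design.
- The uniform-grey background is recorded as mid-grey in sRGB; no display
  colorimetry is modelled beyond the config metadata (CRT resolution,
  refresh, and the 1,000-ms presentation / 2,000-ms ISI timing are carried
  as metadata only).
- The percentile bootstrap undercovers slightly at n = 26 (measured ~92%
  for a nominal 95% interval on Normal data); the CIs are descriptive, as
  bar-chart error bars, not inferential guarantees.
- Per-fit confidence intervals on individual thresholds are not provided;
  uncertainty is summarised at the group level.
- The leaf shapes, snake silhouette and colour population are principled
  stand-ins, synthetic by construction; analyses that depend on their exact
  forms should treat them as such.
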