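---
title: "Virtual-wave analysis of cold-stress thermograms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-wave analysis of cold-stress thermograms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermovasc)
```

## The problem

A cold-stress (dynamic) thermography exam cools the skin with forced air
until the surface reaches about 32.5 °C, then records a time-lapse of
calibrated temperature images — here 20 frames at 15 s intervals over
5 minutes, plus one pre-stimulus static frame.  Subcutaneous veins answer
the cooling in two physically distinct ways:

* **Passive thermal reflection.**  The cooling front diffuses inward and is
  reflected at boundaries with a thermal-impedance mismatch.  A high-flow
  vessel is effectively a constant-temperature boundary, i.e. a *total
  negative* reflector (reflection coefficient $R = -1$): its echo returns
  with polarity *opposite* to the stimulus, after a two-way (skin → vessel
  → skin) travel.
* **Active vasomodulation.**  Skin cooling triggers vasoconstriction — an
  almost immediate neurally mediated component and a delayed hormonal
  one — which reduces the heat the vessel releases.  That flux change
  diffuses *one way*, vessel → skin, and arrives with the *same* polarity
  as the stimulus.

Opposite polarities and a 2:1 arrival-time ratio are therefore the
signatures that let the two mechanisms be told apart, vessel depths be
estimated, and vessels that reflect but barely constrict — a
vasoconstriction deficit — be mapped.

## Forward model

All physics is one-dimensional per pixel (a layered-medium approximation;
lateral diffusion is neglected, consistent with reading depth from arrival
time).  In units with volumetric heat capacity 1 and conductivity equal to
the diffusivity $\alpha$ (default $7.58\times10^{-8}\,\mathrm{m^2 s^{-1}}$,
subcutaneous fat), the surface Green's function of a buried plane impulse
source at depth $z$ is

$$ g(t, z) = \frac{\exp(-z^2 / 4\alpha t)}{\sqrt{\pi \alpha t}}. $$

The cooling stimulus is modelled as a surface heat *flux*: a prescribed
surface temperature would make the measured surface trace identical to the
drive and carry no subsurface information, whereas a flux drive (fan-forced
convective cooling) leaves the surface temperature free to express the
returning echoes.  Excitation profiles are stored in °C (a step of
$-\Delta T$ over the cooling window) and converted to flux by a fixed scale
chosen so that the step depresses the vessel-free surface by exactly
$\Delta T$ at the end of cooling.

A reflector at depth $d$ adds image sources at $2kd$ with weights $R^k$
(series truncated at $10^{-6}$ of the direct term); vasomodulation is a
buried source whose flux follows the stimulus envelope scaled by the fast
and slow amplitudes, the slow part delayed by 60 s by default (the exact
neural and hormonal amplitudes and delays are not quantified in the
literature this model follows; they are configurable scene parameters, not
physiological claims).  `fdSolve1D()` solves the same problem by an
implicit finite-volume scheme — including partial reflectors realized as a
two-layer medium with effusivity ratio $(1-R)/(1+R)$ — and serves as the
independent oracle: method-of-images and finite-difference traces agree to
better than 1% of the trace range across $R \in \{0, \pm 1\}$ and depths
5–20 mm.

## The virtual wave transform

The measured trace of each pixel is related to a *virtual wave* signal
$m(t')$ by the Fredholm kernel

$$ K(t, t') = \frac{c}{\sqrt{\pi \alpha t}}
   \exp\!\left(-\frac{c^2 t'^2}{4 \alpha t}\right), $$

with virtual speed $c = 1\,\mathrm{m\,s^{-1}}$, so one-way arrival at $t'$
means depth $z = c\,t'$ numerically in metres.  The virtual time axis is
the logarithmic grid $t'_i = 0.025 \times 2^{(i-100)/20}$, $i = 1..100$.
For the non-impulse fan-cooling protocol, kernel rows are convolved with
the excitation normalized to unit area, which maps arrivals to the same
virtual times an impulse would; real observation times are counted from
stimulus onset (cooling duration + frame timestamp).

The inversion is ill-posed and solved per pixel as Tikhonov-regularized
least squares,

$$ \min_m \; \lVert T - W m \rVert^2
   + \lambda^2 \sigma_1(W)^2 \lVert L_2 m \rVert^2 , $$

with $\lambda = 0.003$ and $L_2$ the second-difference operator — the
order-2 smoothness penalty.  Numerical choices that matter:

* $\lambda$ is made dimensionless by scaling with the kernel's largest
  singular value $\sigma_1(W)$.
* $L_2$ acts on the grid extended by one zero sample at each end (zero
  Dirichlet padding).  Without this, ramps at the grid edge have zero
  second derivative and the inversion piles late echo energy onto the last
  virtual time; with it, a 9 mm two-way echo lands at $t' \approx 0.019$
  as it should.
* The augmented system is solved by SVD with a relative cutoff of
  $10^{-12}$, so results are deterministic; $\lambda = 0$ falls back to
  the minimum-norm pseudo-inverse with a warning.
* An alternative mode projects the solution on a Gauss–Hermite function
  basis truncated at the smoothness order (`mode = "hermite"`), provided
  for comparison with polynomial-order readings of the smoothness
  parameter.

**The static frame.**  The pre-stimulus frame has no post-stimulus
timestamp and cannot enter the kernel; its physical role is the per-pixel
baseline.  The pipeline therefore subtracts it from the dynamic columns
before inversion (`includeStaticInInversion = TRUE`).  This matters: after
the 21 °C room-background subtraction the data still carry a ~13.5 °C
offset, which otherwise dominates the inversion and contaminates every
unmixed image.

## Unmixing

The virtual matrix (pixels × 100) is factored by *uncentered* PCA —
the mean virtual trace is physical signal, and centering would push energy
into a discarded mean image — keeping 6 components ordered by singular
value.  ICA (fixed-point negentropy maximization, log-cosh contrast,
symmetric decorrelation) is then applied to the *time* matrix, and the
inverse transform to the image matrix, so the product — the data
reconstruction — is preserved to machine precision.

Two conventions resolve ICA's permutation/scale indeterminacy
deterministically: components are ordered by ascending dominant-peak
virtual time, and each trace's dominant peak is made positive (the
compensating flip goes into the image weights).  The fit is restarted from
five seeded initializations and the converged solution with the largest
negentropy kept, making the rotation reproducible given the seed.

The pipeline unmixes PCA components 2–5 by default
(`icaSkipBulk = TRUE`): component 1 is the bulk background recovery shared
by every pixel, and including it in the rotation leaks a uniform
background into all unmixed images, corrupting polarity reads.  Excluding
the bulk mirrors the practice of displaying six principal components but
unmixing four.

## Interpretation

A component's physical polarity is the sign of its trace peak times the
sign of its image weights (energy-weighted over the strongest decile of
pixels — a single-pixel rule is fragile at detector-noise levels).  Under
cooling, stimulus-polarity components are labelled *vasomodulation* and
opposite-polarity ones *reflection*; each vasomodulation at $t'$ is paired
with the nearest reflection at $\approx 2t'$ within ±25% (the ill-posed
inversion blurs virtual peaks, so exact doubling cannot be demanded).
Depths are $c\,t'$ for one-way (vasomodulation) and $c\,t'/2$ for two-way
(reflection) arrivals.  The deficit map is
$\max(|\hat{R}| - |\hat{V}|, 0)$ with each aggregate image normalized by
its maximum magnitude; high values mark vessels that reflect but barely
constrict.

## The phantom generator

`renderPhantom()` emulates the acquisition: per-pixel 1-D traces from the
background response plus per-vessel reflection echoes and vasomodulation
signatures, rasterized as hard (unantialiased) masks of whole-pixel width,
with i.i.d. Gaussian detector noise (default 0.2 °C, a typical NETD),
optional integer frame jitter, protocol timestamps and a static frame.
Vasomodulation amplitude can vary along the centerline (`vasoTaper`);
this models the along-vessel variability of vasomotor tone and is also
what makes the active and passive signatures of a single vessel spatially
distinguishable — with perfectly uniform tone the two share one spatial
pattern and no image/time factorization can separate them.  A steady warm
footprint (`baselineWarmth`) gives static frames the vessel structure that
real thermograms show.

What the phantom deliberately does **not** model: lateral (2-D/3-D)
diffusion, perfusion source terms of bioheat models, curved skin geometry,
emissivity variations, and non-rigid patient motion.  Passing tests
therefore validate the algorithmic chain under the stated 1-D physics, not
clinical performance on patient data.

The canonical scenes (`demoScene()`) fix the study conditions: 64 × 64
images, vessels at 9 mm and 13 mm with $R = -1$, fast/slow vasomodulation
amplitudes 0.5/0.2 (secondary vessel 0.3/0.15) in stimulus units, 60 s
hormonal delay, taper 0.2–1.8.  These sizes keep every validation run in
seconds while leaving the inversion genuinely ill-posed (condition number
of order $10^4$, surfaced in the pipeline log).

## Known limitations

* A 13 mm vessel's two-way echo arrives at $t' = 0.026$ — beyond the
  0.025 grid maximum and barely expressed within the 300 s recording
  (its thermal peak lies near 4500 s).  The reflection component of such
  deep vessels is edge-compressed and, in multi-vessel scenes, merges with
  shallower echoes; the one-way vasomodulation arrival (0.013, on-grid)
  remains accurate and is the preferred depth estimate for deep vessels.
* At the detector noise level (0.2 °C) the 20-frame protocol is marginal:
  the regularized inversion amplifies noise by orders of magnitude, and
  classification succeeds in most but not all noise realizations.  A
  high-rate protocol (900 frames over the same window) would gain a factor
  30 in signal-to-noise, as the averaging analysis in the validation suite
  confirms.
* Registration is translation-only phase correlation (patients sway, they
  do not rotate much over 5 minutes); sub-pixel refinement and non-rigid
  motion are out of scope.  Scenes without two-dimensional structure
  (perfectly straight vessels) cannot constrain the along-vessel shift
  component — the aperture problem — so realistic curved-vessel scenes are
  used to validate registration.
* The excitation extracted from masked data (`extractExcitation()`) is the
  post-stimulus footprint; the kernel uses the protocol's step profile.
  With measured per-exam cooling curves, `makeExcitation(kind =
  "measured")` plugs them in unchanged.
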