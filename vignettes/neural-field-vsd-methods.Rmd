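---
title: "Modeling mesoscopic VSD dynamics with a two-layer neural field: methods and design"
author: "neurofield package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mesoscopic VSD dynamics with a two-layer neural field: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofield)
```

## The model

Voltage-sensitive dye (VSD) imaging reports population membrane-potential
changes across millimeters of cortex as fractional fluorescence changes
(dF/F) at ~10 ms resolution. The signal mixes excitatory and inhibitory
contributions. This package implements a one-dimensional, two-layer neural
field along the posterior-anterior cortical axis: mean membrane potentials
$u_E(x,t)$ and $u_I(x,t)$ obey

$$
\tau_E \,\partial_t u_E = -u_E + h_E
  + g_{EE}\,(w_{EE} * f_E(u_E))
  - g_{IE}\, f_I(u_I) + S(x,t),
\qquad
\tau_I \,\partial_t u_I = -u_I + h_I + g_{EI}\,(w_{EI} * f_E(u_E)),
$$

with logistic transfer functions
$f(u) = 1/(1+e^{-\beta (u-\theta)})$ mapping depolarization to firing rate,
Gaussian coupling kernels $w(d)$ of widths $\sigma_{EE}, \sigma_{EI}$, a
strictly local inhibitory-to-excitatory coupling (interneurons project
locally) and the afferent drive $S$ entering the excitatory layer only. The
modeled dye signal is the affine mixture $s = a\,u_E + b\,u_I + c$ with
$a,b \ge 0$; the inhibitory share is $\kappa = b/(a+b)$.

The reference parameter set (`fieldParams()` defaults) is:
$\tau_E = 19.2$, $\tau_I = 28.8$ ms; $h_E = h_I = -60$ mV;
$g_{EE} = 125$, $g_{IE} = 50$, $g_{EI} = 125$;
$\sigma_{EE} = \sigma_{EI} = 1.27$ mm; $\beta_E = 0.15$, $\beta_I = 0.1$
mV$^{-1}$; $\theta_E = \theta_I = -40$ mV; feed-forward gain $g_{FF} = 70$
and smoothing width $\sigma_{FF} = 0.51$ mm. Because all communication runs
through $f(u-\theta)$, resting potentials and thresholds are jointly
redundant; `show()` on a `FieldParams` object therefore also reports the
invariant combinations $h - \theta$.

### Kernel normalization

The coupling kernels are normalized to unit area *before* gain
multiplication (`discreteGaussian()`), making the gains resolution
independent and the homogeneous steady state obey
$\bar u_E = h_E + g_{EE} f_E(\bar u_E) - g_{IE} f_I(\bar u_I)$ exactly. The
alternative convention (unit peak) scales the effective recurrent gains by
$\sigma\sqrt{2\pi}\approx 3.2$; with the reference gains that regime has no
quiescent state at all (the field relaxes to a saturated active state near
+290 mV), so unit area is the only convention consistent with the model's
published resting behavior, and we adopt it throughout.

### Bistability and the resting branch

At the reference gains the homogeneous equations are bistable: a quiescent
state near (-64.7, -57.0) mV coexists with a saturated active state near
(+15, +65) mV. The physically meaningful baseline is the quiescent branch.
`homogeneousFixedPoint()` finds it by continuation: the root is tracked from
the decoupled system (all gains zero, where it is exactly $(h_E, h_I)$)
while the gains ramp up. If the branch is annihilated on the way (saddle-node
fold under, e.g., strongly inflated $g_{EE}$), the model has no resting
state; `checkStability()` reports that structural failure as an unstable
verdict with an explanatory note. On the spatially discretized grid the
relaxation from $u \equiv 0$ selects the same quiescent branch - the
zero-padded boundary buffer nucleates the escape from the active plateau -
but needs about 1.3 s of model time; the default relaxation period is
therefore 2000 ms with a terminal-drift check (`driftTol = 1e-5` mV/ms).
Identification loops instead start at the algebraic fixed point with a
400 ms settle (`init = "fixedpoint"`), which agrees with the full relaxation
to better than $10^{-3}$ mV (tested).

## Discretization

Space: 150 positions at 0.14 mm/px (7 mm imaged extent over 50 mapped
pixels), the central 50 mapped to the camera, 50 buffer pixels on either
side against boundary effects. Time: explicit Euler with 10 substeps per
9.6 ms frame ($dt = 0.96$ ms), frames sampled on the imaging clock; the
analysis window is 26 frames (0-240 ms within the first 250 ms of each
condition). The integrator is first-order convergent; the post-stimulus
collapse of the saturated response makes raw frame values dt-stiff (errors
halve per dt halving but with a large constant), while the derived
quantities the package reports - layer correlations, wavefront speeds - move
by less than 0.015 and 0.1% respectively between 10 and 40 substeps
(tested). Convolutions are evaluated as dense Toeplitz matrix products built
from the discretely normalized kernel, which is identical to zero-padded
direct convolution; the C++ inner loop makes a full seven-condition
simulation run in well under a second.

## Stimuli

The experiments' exact visual stimulus sizes are not recoverable, so
cortical extents are reconstructions, fixed once against the constraints the
study states and then frozen (all are configurable in
`stimulusProtocol()`):

* **Square**: 1.5 mm of cortex, anchored at 2.25 mm so its center sits at
  the 3 mm input location named for the single-square traces. The width is
  calibrated so the peak afferent drive is about 60 mV at $g_{FF} = 70$ -
  the stated input amplitude. (With unit-area smoothing a much wider
  stimulus would plateau at exactly $g_{FF} = 70$ mV; the "about 60 mV"
  maximum is the finite-width square's peak.)
* **Bar**: 2.5 mm, sharing the square's lower cortical edge (the two stimuli
  are aligned on their upper visual-field edges, which map to the same
  posterior cortical edge) and extending 1 mm beyond it anteriorly.
* **Line-motion**: square 20-70 ms, 10 ms gap, bar 80-210 ms.
* **Moving squares**: 4, 8, 16 and 32 deg/s, mapped at 1.1 mm per visual
  degree. The motion is treated as ongoing at the window start: the square
  enters from below the simulated grid during a lead-in and its leading edge
  passes the flashed square's center at $t = 0$, so the analysis window
  captures steady translation. An in-window motion onset instead
  contaminates the high-amplitude wavefront contour with the onset
  transient and cannot reproduce the published cortical speeds at slow
  stimulus speeds.

**Magnification.** With steady translation the model's high-amplitude front
tracks the stimulus cortical speed essentially exactly, so the estimated
speeds are $m \cdot (4, 8, 16, 32)$ mm/s for magnification $m$. No single
$m$ reproduces all four published front speeds (their ratio spans a factor
10 over a factor-8 speed range); the minimax-relative-error calibration over
all four gives $m \approx 1.11$, and the package default is 1.1 mm/deg.

**Rasterization.** A position is covered when its pixel center lies inside
the half-open stimulus footprint; a frame interval is lit when the stimulus
is on at the interval midpoint. Midpoint sampling reproduces the stated
frame alignment: stimulus onset at 20 ms plus the fixed two-frame (19.2 ms)
retino-cortical delay makes the response rise from frame 5 of the window,
and the 50/130 ms stimulus durations rasterize to 5 and 14 frames.

## Observation model and identification

`fitMixture()` minimizes the squared error of $a u_E + b u_I + c$ against
the concatenated dye signal of all supplied conditions under
$a, b \ge 0$ (offset free), by exact active-set enumeration of the two
constraints after offset centering; ties on the boundary resolve toward the
smaller-norm solution. `restrictedFitTest()` compares the full fit to the
two single-layer restrictions via $n\,(RSS_r - RSS_f)/RSS_f$ against
$\chi^2_1$; space-time residuals are correlated and heteroscedastic, so the
p-values are indicative. `kappaSweep()` fixes the mixing ratio and refits
scale and offset only.

The grid search (`runGridSearch()`) scans per-parameter candidate lists
(the full design is $3^{10}$ over ten parameters with $h_I = h_E$ tied;
`defaultGridSpec()`) and applies four selection criteria: (1) linear
stability, (2) post-stimulus decay back to rest (terminal deviation below
1% of the peak on a window extended by 250 ms), (3) overall dye/model
correlation above 0.8, and (4) onset-slope similarity - the model/dye slope
ratio within [0.5, 2] at the stimulus-center pixel over 20-70 ms
(square-driven conditions) or 80-130 ms (bar). The slope band is our
operationalization of "similar rate of activity change"; the windows are the
study's.

Refinement (`refineCMAES()`) optimizes seven parameters (both resting
potentials, the three gains, the two transfer slopes) with a standard
$(\mu/\mu_w, \lambda)$ CMA-ES (population and adaptation constants at the
published defaults for the dimension, coordinates scaled by the start
vector, mandatory seed, bit-reproducible trace). The default objective is
$-\overline{r} + \lambda_\kappa (\kappa - \kappa^\ast)^2$ with the mixture
refitted per proposal ($\lambda_\kappa = 1$, $\kappa^\ast = 0.5$ by
default; both exposed). One identifiability caveat matters: with a refitted
mixture, $g_{EI}$ is almost perfectly absorbed by the fitted $b$ (the
inhibitory layer is linear in $g_{EI}$ up to the weak $f_I$ feedback), so
correlation-objective refinement cannot pin it down. Parameter-recovery
experiments therefore fix the known mixture and use the RSS metric
(`mixture =`, `metric = "rss"`), under which all seven parameters are
recoverable to fractions of a percent (tested).

## Stability analysis

Linearizing about the resting state and Fourier-transforming in space gives
a $2\times 2$ Jacobian per angular frequency $q$; asymptotic stability
requires, for all $q$,

$$
\frac{1 - g_{EE} f_E' \widehat w_{EE}(q)}{\tau_E} + \frac{1}{\tau_I} > 0
\quad\text{and}\quad
(1 - g_{EE} f_E' \widehat w_{EE}(q))
  + g_{IE}\, g_{EI}\, f_I' f_E'\, \widehat w_{EI}(q) > 0,
$$

the trace and determinant conditions, with
$\widehat w(q) = e^{-\sigma^2 q^2/2}$ and the transfer slopes evaluated at
the fixed point. `checkStability()` probes 512 frequencies on
$[0, 4/\sigma_{\min}]$ (Gaussian transforms are inert beyond) and refines
the worst margin locally; `dispersion()` exposes the underlying
eigenvalues, and `discretizedSpectrum()` cross-validates against the full
$2\times150$-dimensional discrete operator. Because the discrete operator is
zero-padded rather than circulant, near-marginal parameter sets can disagree
in sign with the infinite-domain criteria; the validation suite compares
verdicts away from marginality (|worst margin| > $10^{-3}$).

## Response analyses

* `superpositionCompare()` forms LM $-$ (square $+$ bar) on
  baseline-subtracted aggregated signals and tests pooled pixel values per
  interval (pre: frames 1-4; facilitatory: 5-12; suppressive: 13-20;
  1-based on the window clock) with a two-sided Mann-Whitney U (normal
  approximation with tie correction at the study's sample sizes, exact
  enumeration for small samples - `mannWhitneyExact()` is the validation
  oracle).
* `layerCorrelation()` is the Pearson correlation of the flattened mapped
  excitatory and inhibitory space-time blocks.
* `propagationSpeed()` thresholds a pattern at 80% of its *global* maximum
  (matching "80% of maximal activation"), takes the earliest upward
  crossing per position with sub-frame linear interpolation (positions
  already above threshold at frame 1 have no upward crossing and are
  excluded), and fits position versus crossing time by least squares;
  mm/ms equals m/s.
* For model-only analyses the aggregated signal uses the reference mixing
  ratio $\kappa = 0.54$ (`defaultMixture()`) and early-window baseline
  subtraction, mirroring the dye preprocessing.

At the reference parameters with the reconstructed overlapping square/bar
geometry, the early (facilitatory-interval) superposition difference is
dominated by the long-lived inhibitory residual of the square response and
is net suppressive in both layers; facilitation appears only when the bar
extends well beyond the square. This mirrors the original report that the
model's facilitation was much weaker than the data's and absent at the
pattern center, and it is the one reference signature the default
configuration does not reproduce with a positive net mass.

## Synthetic recordings

`generateRecording()` emulates the acquisition chain with known ground
truth: the aggregated 1-D signal (referenced to the resting state) is spread
along the 24-pixel medial-lateral axis by a Gaussian cross-section (center
pixel 12, sd 8, so mean $\pm$ 1 sd spans pixels 4-20), placed on a DC
fluorescence level, modulated by multiplicative heartbeat (~2.5 Hz, 1%) and
respiration (~0.4 Hz, 2%) artifacts, and pixel white noise is added; blank
trials carry artifacts and noise only. Artifact phases are shared between
stimulus and blank trials up to a 0.05 rad per-trial jitter, emulating
heartbeat/respiration-triggered acquisition - the mechanism that makes blank
division effective in practice; with independent phases the division removes
nothing and the residual artifact would rival the signal. The white-noise sd
(0.012 per pixel-frame) is set so the trial-averaged residual is roughly 6%
of the signal peak, inside the 5-10% regime suggested by the published
standard-error bands.

`preprocessRecording()` applies the chain in order: per-pixel DC
normalization against the ~200 ms pre-stimulus mean, division by the blank
average, trial averaging, averaging of x-pixels 4-20 (1-based, inclusive),
and subtraction of the no-stimulus reference level. The reference is the
pre-stimulus period ("activity when no stimulus was presented"); for flashed
stimuli this coincides with the first 20 ms of the window
(`baselineRef = "early"` reproduces that literal variant), but for
established-motion stimuli the window's first frames already carry the
traveling response and only the pre-stimulus period is signal-free.

What the generator does *not* emulate: photon/shot-noise statistics, dye
bleaching, eye movements, spatially correlated noise, or any real
retinotopic distortion. Passing recovery tests therefore demonstrate the
internal consistency of the pipeline (simulation, mixing, acquisition
emulation, unmixing), not robustness to every pathology of real recordings.

## Problem sizes and runtime choices

All tests and the acceptance script run at the study's native scale
(150 positions, 26 frames, 24 trials): a seven-condition simulation takes
well under a second, the 20-seed mixture-recovery experiment about a
minute, and the CMA-ES recovery experiment a few minutes at its
4000-evaluation budget. The full $3^{10}$ grid search is supported with
checkpoint-free deterministic iteration and a `budget` argument; the test
harness exercises miniature grids.

## Known limitations

* Stimulus geometry and magnification are reconstructions (see above); all
  are configurable, and the published model-only reference values constrain
  but do not uniquely determine them.
* The Euler integrator's stiff post-offset collapse limits frame-wise
  accuracy at the default step; derived quantities are insensitive, but
  applications needing frame-exact decay tails should raise `sub`.
* The Wald-type restricted-fit p-values ignore residual correlation.
* With a refitted mixture the correlation objective leaves $g_{EI}$ (and to
  a lesser degree $h_I$, $\beta_I$) ill-determined; treat refined values of
  those parameters as representative, not unique.
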