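---
title: "Models and methods for diatom gliding motility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for diatom gliding motility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diatomglide)
```

## The system and the model

Raphid pennate diatoms glide over surfaces by secreting adhesive mucilage
through the raphe, a slit running along the rigid silica cell wall. Tracked
at one frame per second, a gliding cell shows a small repertoire of
stereotyped behaviors: persistent **glides** along the body axis (forward
or backward — the cell is front–back symmetric), sudden **reversals** in
which the trailing end becomes the leading end, **pivots** about one cell
end, and **stops**. `diatomglide` implements the full quantitative chain
from tracking tables to long-time dispersal predictions built on this
four-state picture.

The within-state dynamics are a state-switching Langevin model for the
centroid $\mathbf r(t)$ and body orientation $\theta(t)$:

$$\mathrm d\mathbf r = f(\theta, s, \text{state})\,\mathrm dt
  + \mathbf u_\parallel\, v_\sigma\,\mathrm dW_{\mathrm{tra}},\qquad
  \mathrm d\theta = g(s, \text{state})\,\mathrm dt
  + \omega_\sigma\,\mathrm dW_{\mathrm{rot}},$$

with $\mathbf u_\parallel = [\cos\theta, \sin\theta]$ and the polarity
$s(t)\in\{-1,+1\}$ flipping at every reversal. In Glide,
$f = s\,\mathbf u_\parallel v_{\parallel\mu}^{G}$ and
$g = s\,\omega_\mu^{G}$ (a nonzero $\omega_\mu^{G}$ produces the looping
tracks of chiral species). In Pivot the centroid follows an end-anchored
rotation of radius $\bar L/2$; Stop and Reverse have zero drift.
Fluctuation magnitudes are shared across the stationary states
($v_\sigma^{S}$ for Stop/Pivot/Reverse translation, $\omega_\sigma^{S}$
for Stop/Reverse rotation), leaving **eight free parameters per species**:
$v_{\parallel\mu}^{G}, v_{\parallel\sigma}^{G}, \omega_\mu^{G},
\omega_\sigma^{G}, v_{\parallel\sigma}^{S}, \omega_\sigma^{S},
\omega_\mu^{P}, \omega_\sigma^{P}$. Translational and rotational
diffusivities are $D_{\mathrm{tra}} = v_\sigma^2/2$ and
$D_{\mathrm{rot}} = \omega_\sigma^2/2$.

State switching is a continuous-time Markov chain over
{Glide, Stop, Pivot, Reverse} with one structural constraint — Reverse can
only exit to Glide, because a reversal *is* the re-establishment of
directed motion — and one semi-Markov extension: species with
quasi-periodic reversals carry a lognormal Glide dwell instead of an
exponential one. Reversal itself is treated as instantaneous by default
(`reverse_mode = "dwell"` relaxes this). Simulation uses a hybrid
Gillespie–Langevin scheme: sojourn lengths and successor states come from
the dwell models and embedded chain; within a sojourn the SDE is
integrated by Euler–Maruyama at `dt = 0.1` s (configurable; partial steps
handle dwell boundaries), and the trajectory is emitted at the recording
interval of 1 s.

## Kinematics and geometry

Velocities are forward differences assigned to the interval's starting
frame; the velocity is decomposed onto the body frame as
$v_\parallel = \mathbf v\cdot\mathbf u_\parallel$ and
$v_\perp = \mathbf v\cdot\mathbf u_\perp$. Ellipse fitting reports the
orientation modulo $\pi$; `unwrap_orientation()` applies the
smallest-rotation rule ($\theta \Rightarrow (\theta+\pi)\bmod 2\pi$
whenever the frame-to-frame jump exceeds $\pi/2$), greedily frame by
frame. A two-branch dynamic program minimizing total rotation serves as
the test oracle; the greedy rule matches it whenever true frame-to-frame
rotations stay below $\pi/2$, which holds at 1 Hz for these speeds.

Track and raphe curvature both use arclength resampling followed by
moving-window three-point circle fits (first, middle, last point of each
window; $\kappa = 1/R$; triplets with triangle area below
$10^{-12}\,\mu\mathrm m^2$ count as straight). Resolution is tied to the
species' mean body length — resampling step $\bar L/10$, window 5 points —
so curvature is measured relative to cell size. Glides are segmented as
maximal sub-threshold curvature runs of at least 3 windows, and the
raphe-track comparison pools glide segments whose mean speed lies between
the 45th and 55th percentile (type-7, linear interpolation — segment
membership near the boundary depends on the convention, so it is fixed and
documented).

## Frame classification

The tangential channel is denoised with a 5-point running median followed
by a 5-point zero-phase moving average, giving $\tilde v_\parallel$.
Glide is $|\tilde v_\parallel| \ge v_{\mathrm{stop}}$; below that, Pivot
versus Stop is decided by $|\tilde\omega| \ge \omega_{\mathrm{pivot}}$
with a shorter 3/3 filter on the rotation channel (pivots are briefer than
glides; raw per-frame rotation noise would fragment them). Reversals are
sign flips of a *lightly* filtered velocity (3-point median — a reversal
is a large-amplitude event needing temporal sharpness, not smoothing)
between directed runs, with the sub-threshold gap labelled Reverse.

Thresholds are data-driven per dataset: the pooled magnitudes are modelled
as a half-normal (stationary fluctuations) plus a displaced normal (the
directed mode), fitted by EM, with the threshold at the posterior
crossover, capped at half the directed mode. The rotation pool excludes
frames within 3 frames of any glide (ramp frames carry glide-level
rotation noise and would form a spurious low mode).

## Calibration

Within-glide fluctuations are pooled after a velocity rescaling: each
glide is multiplied by (global mean glide speed)/(its own signed mean
speed), so every glide acquires the same positive mean while its
mean-to-SD ratio is preserved. That alignment is what makes pooling
legitimate: the pooled series is then *globally* permuted (destroying
temporal correlation) and averaged over a moving window of 5 frames.
Pooling before permutation matters — permuting within short segments pins
each segment's mean and deletes part of the variance (for a segment of
$n$ frames the window-mean variance is $\sigma^2(1/w - 1/n)$ instead of
$\sigma^2/w$), biasing fluctuation estimates low for short-glide species.

Distributions are fitted to symmetrized samples ($\pm x$ pooled), since
front and back are experimentally indistinguishable: a symmetric
equal-variance two-normal mixture $\tfrac12 N(\mu,\sigma) +
\tfrac12 N(-\mu,\sigma)$ for the glide speed (and for the glide rotation
of chiral species, and for pivot rotation), a zero-mean normal for the
stationary channels. The mixture is maximized directly with three
restarts; when the components are well separated the fit is refined with
the median/MAD of $|x|$, which is immune to the thin contamination of
boundary frames the classifier misassigns. Samples more than 6 robust SDs
from the median are dropped before coarse-graining for the same reason.

**De-scaling convention.** Averaging $w$ decorrelated samples shrinks the
spread by $\sqrt w$, so the fitted $\sigma$ is multiplied by $\sqrt 5$ to
recover the per-frame fluctuation magnitude (`cg_factor = "sqrt5"`, the
default). A divide-by-$w$ convention is sometimes written next to this
construction; both are implemented, and the glide-only round-trip test
(simulate with known parameters, calibrate, compare) shows only the
$\sqrt w$ choice returns the inputs — the other misses by a factor
$\sqrt 5$. This is the single most consequential convention choice in the
calibration and is pinned by a test.

**Static-error correction.** Localization and orientation noise inflate
every fitted fluctuation magnitude in quadrature (per-frame velocity noise
$2\sigma_{\mathrm{loc}}^2/\Delta t^2$; rotation noise
$2\sigma_{\mathrm{or}}^2/\Delta t^2$), and coarse-graining cannot remove
them — averaging shrinks signal and noise alike. Both are estimated from
the data by the standard intercept method of single-particle tracking:
during stops the true MSD grows linearly while iid localization noise adds
a constant $4\sigma_{\mathrm{loc}}^2$, and orientation-increment variances
add $2\sigma_{\mathrm{or}}^2$ (the orientation intercept uses a
tail-robust MAD$^2$ variance per lag, since hidden pivot frames inside
stops contaminate the means). The fitted magnitudes are then corrected in
quadrature. The glide rotation pool is additionally gated on instantaneous
$|v_\parallel|$ above half the mean glide speed: sojourns below the
classifier's resolution hide inside long glide runs and carry
stop/pivot-level rotation, and conditioning on speed does not bias
$\omega$ because the two fluctuations are independent in the model.

**Chirality** is decided on the raw per-frame glide rotation pool, before
any sign alignment: a symmetric mixture must beat the zero-mean normal by
AIC *and* be separated ($\mu > 2\sigma$). The rotation channel must be
assessed on its own because the $\pi$-ambiguity of ellipse orientations
randomizes each track's apparent front, making the sign coupling between
$v_\parallel$ and $\omega$ unobservable.

## Transition-model estimation at 1 Hz

Estimating switching rates through a frame classifier at
$\Delta t = 1$ s is the hardest inference in the pipeline: sojourns
shorter than the velocity filters are invisible, their neighbours fuse,
and boundary frames smear by one or two frames. The package ships three
estimators:

* **Naive counts** $\hat q_{ij} = n_{ij}/T_i$ — the continuous-observation
  MLE, reported always as a cross-check.
* **EM for interval-censored observation** — the discrete one-step counts
  are treated as a CTMC observed at $\Delta t$; expected jump counts and
  holding times are computed with Van Loan matrix-exponential integrals,
  and the Reverse constraint is imposed each M-step. A matrix-log-and-
  project estimate serves as fallback when EM cannot start.
* **Instantaneous-Reverse estimator** (`reverse_convention = "instant"`,
  used for recovery against simulator ground truth), which confronts the
  classifier's resolution limits explicitly:
  * Total exit rates come from *left-truncated* dwell fits on runs longer
    than 6 s: for exponential dwells the truncated mean
    $1/(\overline{d \mid d \ge c} - c)$ is unbiased regardless of what
    happens below the cutoff (memorylessness), and detection losses
    concentrate there. Observed run lengths are first shifted by the
    boundary offsets the filters impose (+2.5 frames for Glide, −1 for
    Stop/Pivot); the lognormal glide dwell needs this explicitly because
    it is not shift-invariant.
  * Exit destinations come from the chain of *long runs only*, with
    skipped short visits modelled by a three-phase visibility scheme
    (long / short-but-visible / invisible). Reversals appear as
    Glide→Glide junctions of this chain; same-state pairs whose
    intermediates are all invisible merge silently and leave no junction,
    which the forward model subtracts before inversion.
  * The classifier-resolution constants (3-frame run absorption, the
    boundary offsets, the visibility cutoffs) are tied to the widths of
    the velocity filters and were fixed once against synthetic ground
    truth; they are package constants — properties of the filters rather
    than of any dataset — and the recovery experiments exercise them
    end to end.

Despite these corrections, destination splits that hinge on
junction-adjacent statistics (especially Pivot-involved rates, the
lowest-occupancy state) retain systematic errors of order 15–30% at 1 Hz;
the eight Langevin parameters and most rates recover to within 10–15%.
The recovery experiments quantify exactly this, and we regard the residual
as the observability limit of frame-rate-censored switching rather than a
removable estimator defect.

Glide dwell families are compared by AIC between the exponential and
lognormal maximum-likelihood fits, with a Kolmogorov–Smirnov
goodness-of-fit p-value (computed at the fitted parameters, hence
approximate) attached. Oscillation periods are read from the averaged
autocorrelation of $v_\parallel$: the first significant local maximum
*after* the autocorrelation has dipped below zero, against a white-noise
band corrected for the number of lags scanned.

## The synthetic cohort

The generator wraps the simulator in a measurement model — additive
localization noise ($\sigma_{\mathrm{loc}} = 0.1\,\mu$m), orientation
noise, and the $\pi$-ambiguity (orientation reported mod $\pi$ with a
random branch per frame). Orientation noise defaults to
$\sigma_{\mathrm{or}} = 0.005$ rad: differenced orientation noise enters
$\omega$ with SD $\sqrt2\,\sigma_{\mathrm{or}}$, while keeping glide-only
motion ballistic to 600 s requires $\omega_\sigma^{G} \lesssim 0.03$
rad/s, so a coarser assumption (for example a few degrees) would bury the
glide rotational fluctuation under the measurement floor and make it
unidentifiable in principle. Sub-degree precision is realistic: the
orientation uncertainty of a fitted ellipse scales like the centroid
uncertainty over the half body length, $0.1/20$ rad for a 40 µm cell.

Five fixture profiles span the qualitative regimes seen across gliding
diatoms — a fast straight glider, a frequent reverser, a chiral looper
(loop period $2\pi/\omega_\mu^{G} \approx 41$ s), a periodic reverser with
lognormal glide dwells (median 11.5 s, so reversals recur about every
23 s), and a slow erratic mover. They are package choices, named
`species_like_*` to make clear they are not calibrated to any real
species. Dwell means sit in the 10–35 s range with Glide occupying
55–75% of time; reversals exit only from Glide in the fixtures, because a
reversal is kinematically detectable only between two glides. Measurement
aside, the generator reproduces none of the upstream imaging reality —
segmentation failures, track fragmentation, cell–cell contacts, drift —
so passing recovery demonstrates the identifiability of the model given
faithful tracking, not robustness to tracking pathology.

## Dispersal statistics

The MSD is time- and ensemble-averaged over all start times (overlapping
windows), with the 10–90 percentile band of squared displacements and a
track-level bootstrap for the diffusivity CI (frames within a track are
dependent; tracks are the exchangeable unit). The diffusivity convention
is $\mathrm{MSD} = 2\,d\,D\,\tau$ with $d$ the spatial dimension, and the
default fit window is the last decade of lags restricted to local
exponent in $[0.9, 1.1]$. Two convention pitfalls are worth stating
because they change answers by factors of two: run-and-reverse motion
along a line is one-dimensional ($\mathrm{MSD} = 2D\tau$, so the telegraph
closed form $D = v^2/2\lambda$ is checked with `dimension = 1`), and the
model's translational noise acts along the body axis only (one degree of
freedom), so the noise-only MSD slope is exactly
$\sigma^2 = 2D_{\mathrm{tra}}$ — not the $4D_{\mathrm{tra}}$ of isotropic
two-axis noise — independent of how fast the orientation decorrelates.

The local exponent is a smoothed finite-difference slope of the log-log
MSD; ballistic ($\approx 2$), diffusive ($\approx 1$) and sublinear
($<1$) regimes are labelled from it. Glide-only controls stay ballistic
through the 600 s experimental window for the non-chiral profiles (the
chiral looper is excluded: its glide-only track is a loop, which revisits
itself by construction); the lognormal reverser and the chiral looper dip
below exponent 1 at the oscillation scale before recovering diffusive
behaviour — the oscillator signature in the MSD.

## The 3D extension

In 3D the orientation is a moving orthonormal frame
$E = [E_{\mathrm{yaw}}, E_{\mathrm{pitch}}, E_{\mathrm{roll}}]$ with
self-propulsion along $E_{\mathrm{roll}}$. Glide applies the chiral drift
to yaw only (rotation about the cell's normal axis) with equal
fluctuation magnitude $\omega_\sigma^{G}$ on all three axes; Pivot is a
yaw-plus-pitch rotation about the trailing end (drift on yaw, equal noise
on both — the split is a documented choice, configurable); Stop and
Reverse are noise-only. The frame is re-orthonormalized by polar
decomposition (SVD) every step, the dominant numerical hazard being
rotation-matrix drift; the property suite composes $10^5$ random small
rotations and requires orthonormality within $10^{-9}$ per step and
$10^{-6}$ cumulatively. With pitch/roll noise off and a planar initial
frame the 3D dynamics reduce exactly to the 2D model, which is tested
statistically.

Obstacles in a granular 3D environment are represented statistically: the
Glide dwell is capped by an independent truncated-normal draw (mean 37 s,
SD 7.4 s, truncated at zero since a negative dwell is meaningless), so a
cell gliding at 2.7 µm/s covers roughly 100 µm — the free-space scale —
before an enforced interruption. When the bound, not the Markov clock,
ends a glide, the successor state is a normal transition draw (an
interpretation; the alternative of forcing a specific state is not
implemented). The bound moves the ballistic-to-diffusive crossover to
shorter lags, monotonically in the bound mean.

## Problem sizes and numerical choices

Recovery experiments run at the study scale of 300 tracks × 600 s per
profile and seed, with three seeds per profile; dispersal oracles use 500
tracks × $10^4$ s (telegraph, integrated at 1 s since the noise-free
drift is exact at any step), 1000 tracks × 600 s (active Brownian), and
200 tracks × 400 s (noise-only). Property tests use smaller ensembles
where the property is exact or concentrates quickly. Deterministic
geometry checks use `dt = 0.01` s so that Euler polygonization error
($(\omega\,\mathrm dt)^2/24$ in radius) sits below the $10^{-6}$
tolerances. All randomness is seeded; a dataset is reproducible
bit-exactly from its ground-truth description and seed, and pipeline runs
fan one seed out to per-stage derived seeds.

Known limitations, beyond those noted above: the classifier's Reverse
runs are a detection convention (the underlying event is modelled as
instantaneous), Stop→Reverse and Pivot→Reverse transitions are allowed by
the estimator but unobservable in principle at 1 Hz (a reversal without
flanking glides leaves no kinematic trace), and the curvature comparison
for strongly 3D raphes is expected to degrade since a 2D projection
underestimates torsion-dominated shape.
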