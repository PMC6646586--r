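---
title: "Active efficient coding: model, protocols and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active efficient coding: model, protocols and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model in one paragraph

A simulated agent watches a textured plane that drifts sideways, up/down and
in depth, through two pinhole cameras 0.068 m apart. Every 100 ms iteration
it whitens the camera images, cuts them into small patches at a coarse
(peripheral) and a fine (macular) scale, and encodes each patch as a sparse
combination of learned spatio-temporal binocular basis functions. The
quality of that encoding is the agent's only motivation: the negative
reconstruction error is fed as reward to a natural actor-critic that
controls pan/tilt accelerations and vergence steps of the cameras. Tracking
the stimulus and verging on its depth stabilise and align the two retinal
streams, which makes the sparse code more efficient -- so accurate pursuit
and vergence emerge without any explicit error signal, while the dictionary
simultaneously adapts to the input statistics the behaviour itself creates.

## World and camera geometry

Both cameras have a 90 degree horizontal field of view at 320 x 240 pixels.
Pan and tilt are version angles applied to both cameras; the vergence angle
is split symmetrically, each camera toed in by half. Fixating a point
straight ahead at distance $d_O$ requires

$$\xi^* = 2\arctan\!\left(\frac{d_E}{2 d_O}\right), \qquad d_E = 0.068\ \mathrm{m},$$

which is `vergenceTarget()`. The stimulus is a 1.5 m plane that stays
fronto-parallel while it translates; its direction is integrated in angular
coordinates (azimuth/elevation), so a nominal angular velocity of
7.5 deg/s accumulates to exactly 30 degrees over a 40-iteration interval --
the stated motion envelope. Pan/tilt commands are angular accelerations
integrated semi-implicitly (velocity before position) with dt = 0.1 s;
vergence commands are direct angle changes. Joint limits
(pan/tilt within 15 degrees, vergence in [0.2, 16.3] degrees) are
inclusive; violations zero the eye velocities and re-fixate at a random
distance in [0.3, 3] m.

The renderer is an analytic ray/plane homography with bilinear texture
lookup -- no lens distortion, lighting or occlusion. Its geometric accuracy
is tested against the closed-form pinhole projection of the plane centre:
measured central disparity agrees with the analytic value within half a
pixel across the training ranges of depth and vergence error.

## Synthetic stimuli

The original experiments textured the plane with photographs of man-made
scenes. This package generates stand-in textures emulating the two
statistics of such images that matter here: a roughly 1/f amplitude
spectrum (`pink_noise`) and oriented step edges with horizontal and
vertical orientations over-represented (`edges`, `blocks`). PGM files can
be substituted for real photographs. What the generators do *not* emulate:
higher-order structure (objects, shading, perspective), luminance
distributions of natural scenes, and the particular anisotropies of any
photographic database. A green behavioural test therefore establishes that
the mechanism works on natural-like second-order statistics, not that the
learned dictionaries match photograph-trained ones feature by feature;
orientation histograms, for instance, inherit whatever edge mix the
generators contain.

## Preprocessing

Each frame is convolved (in the frequency domain) with the retina-inspired
whitening/low-pass filter $R(f) = f\,e^{-(f/f_0)^n}$, $f_0 = 96$
cycles/image, $n = 4$. The cutoff is specified in "cycles per image" for a
non-square 320 x 240 image; this implementation measures radial frequency
in cycles per image *width* (320 px), the larger dimension, so that a
horizontal grating with 96 cycles across the image width sits exactly at
the cutoff. Whitening is applied once to the full camera frame, before any
sub-window extraction.

Two central sub-windows are taken: 128 px (36 degrees) reduced by two
levels of a binomial [1,4,6,4,1]/16 Gaussian pyramid to 32 px
(1.125 deg/px), and 64 px (18 degrees) kept at full resolution
(0.28125 deg/px). Each scale image is cut into 8 x 8 patches with stride 4
(49 and 225 patches), each patch normalized to zero mean and unit norm.
Patches that are uniform after mean subtraction (norm < 1e-8) are kept as
zeros rather than divided by numerical noise; they encode nothing and are
skipped consistently downstream. The four subfields per grid position
(left/right eye at t-1 and t) are assembled into one 16 x 16
spatio-temporal binocular patch, eyes in rows, times in columns. The
assembled patch is *not* re-normalized -- its squared norm is the number of
non-degenerate subfields (usually 4) -- and the reconstruction error's
denominator uses this assembled norm.

## Sparse coding

Each scale has a dictionary of (by default) 600 unit-energy 16 x 16 atoms.
Encoding is plain matching pursuit with a budget of 10 coefficients per
patch: repeatedly select the atom with the largest absolute inner product
with the residual, accumulate the coefficient, subtract the projection.
Numerical choices: re-selection of an atom is allowed (the budget counts
iterations, so a patch has *at most* 10 distinct non-zeros); exact ties go
to the lowest atom index; all patches of a scale are encoded simultaneously
so the inner loop is one BLAS product per pursuit iteration.

The reconstruction error of a scale is
$E_S = \sum_j \lVert p_j - \hat p_j\rVert^2 / \lVert p_j\rVert^2$ and the
reward is $r_t = -(E_c + E_f)$, unscaled. Dictionary learning is one
gradient step per iteration and scale,
$\Delta\phi_i = \frac{\eta}{|p_S|}\sum_j \kappa_{ij}(p_j - \hat p_j)$ with
$\eta = 0.5$, using the final accumulated coefficients, followed by
renormalization of every atom to unit energy (an atom nulled by a
pathological step keeps its previous value instead of dividing by zero).

At initialization the four subfields of each atom are independent random
Gabor functions: wavelength uniform in [8/3, 16] px, orientation in
[0, 180), phase in [0, 360), centre in [8/3, 8] px, envelope SD fixed at
2.5 px, aspect ratio wavelength/6.4. Each subfield is evaluated on pixel
centres 0..7 (the centre coordinates are offsets from the patch's top-left
pixel), unit-normalized *without* mean subtraction -- the initialization
distributions describe raw Gabor profiles, and subtracting the mean would
make the subfields unfittable by the pure Gabor family that the
receptive-field analysis uses (the measured initialization residual triples
otherwise). The white-noise variant draws standard-normal atoms instead.

The sensory state is the per-atom mean squared coefficient over patches
(coarse block then fine block, length 2 x 600 by default) -- a complex-cell
style pooling of squared simple-cell responses.

## Reinforcement learning

One linear critic $V(s) = \langle\theta^V, s\rangle$ and three independent
softmax actors (pan, tilt, vergence) share the state. The TD error is
implemented exactly as specified,

$$\delta_t = r_t - \hat J_t + \gamma V_t(s_t) - V_t(s_{t-2}),$$

with the average-reward estimate $\hat J_t$ low-pass filtered
($\xi = 0.01$) and $\gamma = 0.3$; the unusual combination of an
average-reward baseline, a discount, and a two-step-old comparison value is
kept as printed rather than "corrected" to a textbook TD(0) form. Because
an action needs two iterations to reach its full sensory effect, every
update consumes $(s_{t-2}, a_{t-2})$ together with $r_t$; the first two
iterations after any reset perform no updates. The critic uses
$\alpha = 0.4$; each actor updates advantage parameters
$w \leftarrow w + \beta(\delta\zeta - \zeta\,\zeta^\top w)$ with
$\beta = 0.16$ and takes the natural-gradient step
$\theta \leftarrow \theta + \eta w$ with $\eta = 0.4$, where $\zeta$ is the
softmax score of the taken action. All weights start at zero: uniform
initial policy, zero initial values. The shared TD error from the single
critic drives all three actors. The state vector enters the learner as-is
(no standardization).

`nacBandit()` is a desk-scale sanity check of this machinery: states are
one-hot error bins, the reward is the negative absolute post-action error,
and the greedy policy must learn to cancel the error. Its default learning
rates (critic 0.1, advantage 0.01, actor 0.001) are scaled to that task:
one-hot states are two orders of magnitude larger than the sparse-coding
state entries, and the full-model rates push the softmax into premature
saturation before the small-error states are resolved. A small actor step
keeps the sampling policy near-uniform -- every action is tried often in
every state -- while the accumulated natural gradient ranks the actions;
with this the greedy policy cancels the error in every state across seeds.

## Training and testing protocols

Training runs in 40-iteration intervals: place a random stimulus centred
in the field of view at a depth from [1, 2.5] m with episode-constant
velocities (up to 7.5 deg/s laterally, 0.375 m/s in depth), re-fixate, run
the perception-action loop. A stimulus closer than 5 cm aborts the
interval. Testing freezes all learning, switches the actors to greedy
(ties towards the lowest-magnitude action) and runs
stimuli x 6^3 velocity combinations (the multipliers
{-1, -0.5, -0.1, 0.1, 0.5, 1} of the maximum velocities) for 10 iterations
each -- 10800 trials at the full 50-stimulus grid. Errors are recorded at
the last iteration: pursuit errors as (stimulus speed - eye speed) x dt in
deg/iteration, vergence error as actual minus desired angle. Test depths
reuse the training distribution with a per-trial seed derived from the
trial index, so grids are reproducible. Each checkpoint is evaluated
independently; the 10 checkpoints are evenly spaced and include the final
iteration. In the random-action control (RNDCTL) only action generation is
randomized; the critic and actors stay frozen at zero rather than being
trained on uncontrollable actions.

The full-scale experiment (5e5 iterations, 600 atoms, 10 repetitions) is
out of desk reach; `deskProfile()` (5e4 iterations, 200 atoms, 5 test
stimuli) is the scaled profile, and `scripts/desk_experiment.R` runs the
trained-vs-random comparison at that scale (about 1-2 hours per seed). The
default test suite instead verifies the oracle-policy protocol, short-run
learning curves and bit-level reproducibility.

## Receptive-field analysis and the residual convention

`fitGabor()` fits the same Gabor family used at initialization, with an
analytically optimal amplitude, by multi-start bounded least squares: a
frequency/orientation start read off the zero-padded 2-D spectrum plus a
wavelength x orientation grid, each with its correlation-optimal phase
(a 2 x 2 generalized eigenproblem), the best six refined by L-BFGS-B in
generous supersets of the sampling ranges and polished by Nelder-Mead.
On 200 random initialization-range Gabors the fitter reaches a residual
fraction at or below 0.01 in at least 95% of cases.

The reported residual statistic follows the convention that reproduces the
published reference values: $r$ is the squared residual norm of a subfield
*at the scale it has inside the unit-energy atom*. A Gabor-initialized atom
has four equal-energy subfields, so each carries energy 1/4 and
$r = \mathrm{fraction}/4$; unit-energy white-noise atoms give
$r \approx 0.25 \times 0.75 \approx 0.19$ because a single Gabor explains
about a quarter of the energy of 8 x 8 Gaussian noise. Defining $r$ on
unit-normalized subfields instead (fraction alone) would give
initialization means near 0.004 and white-noise means near 0.75, far from
the reference values of 0.003 and 0.188 -- this normalization choice is the
single most consequential convention in the analysis module, which is why
`fitGabor()` reports the raw fraction and `residualStats()` applies the
atom-energy scaling explicitly.

Tuning preferences derive from fitted parameters: disparity
$\hat d = \lambda(\psi_\mathrm{left} - \psi_\mathrm{right}) /
(2\pi\cos\theta)$ and velocity
$\hat v = \lambda|\psi_t - \psi_{t-1}| / (2\pi)$, phase differences
wrapped to $(-\pi, \pi]$, pixel results converted with the scale's deg/px.
Two technicalities make phase *differences* well defined. First, the
fitted amplitude's sign is folded into the phase (a Gabor and its negation
differ by 180 degrees of phase), so every fit reports a canonical
positive-amplitude phase. Second, the fitted phase is referenced to the
fitted envelope centre, which differs between independent fits; the
preferences therefore use the origin-referenced phase
$\psi_0 = \psi - 2\pi(x_c\cos\theta + y_c\sin\theta)/\lambda$ (`psi0` in
the fit output), and when two paired fits land on opposite carrier
directions (orientations folded into $[0, 180)$ that differ by nearly
180 degrees) one is flipped before differencing. Without these steps the
phase-based preferences disagree with direct cross-correlation shift
measurements; with them they agree within half a pixel on clean Gabor
pairs.
Conventions adopted where the source is silent: the atom's orientation is
that of its time-t left subfield (0 degrees = vertical stripes); disparity
is flagged undefined when $|\cos\theta| < 0.1$ (near-horizontal stripes
carry no horizontal phase information); an atom is excluded from a
preference when its two fits disagree in wavelength by more than 10% or in
orientation by more than 10 degrees; atoms enter the tuning table only when
all four subfield fits have residual fraction at most 0.5 (trained atoms
average around 0.15).

## Known limitations

* The renderer supports a single fronto-parallel stimulus plane plus a
  background plane -- no slanted or curved objects.
* Textures are procedural stand-ins; dictionary-level statistics that
  depend on photographic content should be read qualitatively.
* Desk-scale runs shorten training a tenth and shrink dictionaries; they
  demonstrate the learning trends, not the converged error magnitudes.
* The two learning systems interact: frozen-dictionary or frozen-policy
  ablations beyond RNDCTL/NFS/CAS are not implemented.
* Configuration files are JSON (no YAML/TOML parser is assumed available).
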