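---
title: "Models and methods behind mocapfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mocapfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mocapfit turns two streams of laboratory measurements -- labeled optical
marker trajectories $\bar x_{1:T}$ and force-plate recordings -- into a
subject-specific rigid-body skeleton with dynamically consistent joint
kinematics and kinetics. This vignette describes the models, the
numerical choices, and what the synthetic validation does and does not
establish.

## The skeleton model

A skeleton is a tree of rigid segments connected by free (6-DOF), ball
(XYZ intrinsic Euler), universal (two axes) and revolute joints, rooted
at a pelvis-like segment on a free joint. All generalized coordinates are
concatenated into $q$; the per-axis segment scales into
$s \in \mathbb{R}^{3 n_\text{seg}}$, which multiply joint offsets, marker
offsets and segment centres of mass componentwise. Inertia tensors are
rescaled through the per-axis second moments implied by the unscaled
tensor ($p_x = (I_{yy}+I_{zz}-I_{xx})/2$ and permutations;
$I'_{xx} = s_y^2 p_y + s_z^2 p_z$, $I'_{xy} = s_x s_y I_{xy}$), the
mass-preserving rule consistent with stretching the underlying mass
distribution; mass itself is a separate parameter. This rescaling rule is
a package choice -- the per-axis scaling of inertia under anisotropic
segment scaling has no single canonical convention.

Forward kinematics, marker placement, analytic Jacobians (with respect to
$q$, $s$ and the local marker offsets $p$), the generalized mass matrix
and Newton--Euler inverse dynamics are implemented in compiled code and
cross-checked in the test suite against independent oracles: an explicit
homogeneous-transform chain, central finite differences, a
finite-difference Lagrangian, and an inverse-to-forward dynamics round
trip. The six root components of the inverse-dynamics solution are the
*residual wrench* -- the physically impossible load at the root that is
zero exactly when kinematics, mass properties and external forces are
mutually consistent. Because the root orientation uses Euler angles, the
rotational components are conjugate to Euler rates; `root_residual()`
maps them to a world-frame moment for reporting.

Rotational coordinates use intrinsic XYZ Euler angles throughout, with a
warning when a middle angle approaches gimbal lock (beyond 80 degrees).
Velocities and accelerations come from central finite differences
(one-sided at trial ends); the synthetic generator uses the same
convention, which is what makes its zero-residual construction exact at
every frame including the ends.

## Stage 1: functional joint geometry

Before any scaling is known, the rotation centre of each joint is
estimated from marker motion alone. Markers on the child segment are
expressed in a parent-attached frame (built per frame by Kabsch
registration of the parent markers), where the centre is a *constant*
point -- a deliberate restriction of the per-frame centre the objective
would otherwise allow, which stabilizes the fit and encodes the
rigid-body assumption. A linear least-squares centre-of-rotation estimate
initializes a nonlinear moving-sphere fit (residuals
$\lVert y_t^{(i)} - c\rVert - r_i$), followed by an axis fit that
decomposes each marker offset into components parallel and perpendicular
to a unit axis and requires both to be constant. The unit norm is
enforced by a spherical-angle parameterization, and the per-frame world
axis is the parent-frame axis mapped through the registration (sign
canonicalized) -- temporal smoothness of the axis is therefore built in
rather than regularized.

For near-planar (sagittal) motion the sphere fit is ill-posed along the
plane normal; the package detects this through the conditioning of the
centre block of the Gauss--Newton Hessian *after eliminating the radii*
(the raw block hides the ambiguity because sliding the centre along a
hinge axis is compensated by the radii). Classification follows the
"strictly more demanding" logic: a joint is `axis` when the axis-fit RMS
residual is below `max(1 mm, 1.5 x sphere residual)`, `sphere` when only
the sphere fit is well-posed, `none` otherwise. The 1 mm absolute floor
is deliberately strict: with a larger floor, low-noise ball joints with
small range of motion (the lumbar joint in gait) are misclassified as
hinges, and the resulting line constraint erases exactly the
pelvis-height information the scale initializer needs.

## Stage 2: scale initialization

Scales are initialized in two steps. First, closed-form estimates from a
pose-invariant: the distance between two functional joint loci attached
to the same segment equals the scaled model offset. Sphere centres give
point-to-point distances; axis fits give point-to-line or line-to-line
distances (the centre is only defined up to sliding along the axis), and
only offsets dominated by a single local axis and nearly perpendicular to
the involved axes are used. This pins the segment-length scales (thigh,
shank, pelvis width, torso length) without knowing any pose. Second, a
damped Gauss--Newton refinement of all scales and one slide parameter
$\alpha$ per axis joint, on a subsample of frames, minimizing marker
error plus the distance of each model joint centre to its estimated point
or line. Poses are kept as implicit variables and eliminated per frame by
a Schur complement, so the solver follows the coupled scale--pose valley
instead of zigzagging (plain alternation between scale steps and IK stalls
an order of magnitude short of the optimum). Data terms are weighted by a
1 cm marker SD so that a deliberately weak prior pull (5 % of the prior
precision) only matters in directions the data cannot see.

## Stage 3: the bilevel MAP fit

The joint posterior over $(s, p, q_{1:T})$ combines a Gaussian marker
likelihood (SD 1 cm per coordinate), the anthropometric scale prior, and
zero-mean Gaussian priors on the marker-offset adjustments -- 5 mm SD for
anatomical markers, 5 cm for tracking markers. The problem is bilevel:
each pose is itself the minimizer of the inner IK problem given
$(s, p)$. The package solves the single-level reformulation by
variable-projection Gauss--Newton: per-frame pose blocks are eliminated
by Schur complements and a final warm-started per-frame IK pass restores
exact inner stationarity, which the fit reports (`stationarity_norm`, the
maximum per-frame gradient norm of the data term). An interior-point
solver with explicit per-frame equality constraints, as a generic NLP
formulation would use, is not available in this stack; the
block-elimination route solves the same first-order conditions and the
stationarity requirement is verified rather than assumed. Objective
monotonicity is enforced (steps are accepted only on decrease), missing
marker-frames are dropped from the sum with equal weight on every present
marker-frame, and the anatomical/tracking variance ratio implements the
tie-break that resolves pelvis-tilt-type ambiguities in favour of
solutions that move anatomical markers least.

The shipped scaling prior is synthetic: a factor-structured Gaussian
(shared stature factor, per-segment factor shared across axes and
bilateral pairs, independent residual; 5 % marginal SD) with a joint
covariate block over (scales, height, weight) built from linearized
height and mass functionals, so conditioning on subject metadata is exact
partitioned-Gaussian conditioning. Parameters estimated from a real
anthropometric survey can be supplied through the same
`scaling_prior()` structure; the survey data itself cannot be
redistributed.

## Stage 4: linear dynamics fitting

With ground loads assigned to feet (threshold 10 N; a foot takes a
plate's wrench when its origin projects into the plate polygon below a
0.12 m contact height, with a nearest-to-COP fallback -- the originally
implemented nearest-to-plate-centre fallback misrouted loads in early
double stance when the landing foot hovered just above the contact
height), the COM trajectory implied by the forces is affine in
$\zeta = (z_1, \dot z_1, \mu)$ with $\mu$ the inverse total mass, under
semi-explicit Euler integration. The minimum-norm pseudo-inverse solution
(truncated SVD, relative cutoff $10^{-10}$) recovers $\zeta$ exactly on
self-consistent data and raises an explicit error when all forces vanish
(the inverse-mass column of the system is zero and mass is
unidentifiable). The root translation is then shifted per frame so the
model COM follows the fitted trajectory exactly.

The root-rotation stage extends the same idea: holding mass fixed, a
6T x 12 linear map from $(z_1, \dot z_1, \theta_1, \dot\theta_1)$ to the
stacked COM/rotation trajectory is built by freezing the mass matrix and
Coriolis terms at the current estimate and linearizing the coupling of
the ground-reaction moment to a rigid COM shift. One derivation note: for
a fixed world centre of pressure, shifting the body by $\delta z$ changes
the rotational generalized force by $E^\top (f \times \delta z)$ ($E$ the
root Euler axis matrix) -- the opposite sign of what a naive
"moment-changes-by-$\delta z \times f$" argument suggests. With the
virtual-work sign the rebuild-and-solve iteration converges in under ten
outer iterations on consistent data and the true trajectory is its fixed
point; with the opposite sign it diverges. The reference angular
acceleration per frame is the finite-difference acceleration corrected by
$-M_{\theta\theta}^{-1}$ times the rotational residual, so a
zero-residual trajectory is reproduced exactly (the semi-explicit
integrator reproduces central-difference trajectories exactly for the
right choice of initial rate). Force-plate position/orientation error
terms and long-trial drift terms are not modelled; the synthetic
validation regime has neither, and short laboratory trials are the
intended scope.

## Stage 5: the final residual-minimizing fit

The last stage minimizes marker error plus priors plus a Gaussian penalty
on the residual wrench (SD 1 N force, 1 N m torque per axis) over scales,
marker offsets, segment masses and the *root* coordinates per frame. Two
structural facts shape the implementation: the residual wrench lives
exactly in the six root degrees of freedom, so tuning the root trajectory
(with non-root angles kept marker-optimal) is sufficient to reach dynamic
consistency; and the residual is linear in the segment masses (each
body's contribution scales with its mass, inertia included), so masses
are re-solved in closed form with the total held near the linear-stage
estimate and the distribution regularized toward the standard segment
fractions. The remaining variables take damped Gauss--Newton steps on one
joint normal-equation system: analytic marker Jacobians, comb
finite differences for the residual's dependence on the root trajectory
(the residual at frame $t$ only sees frames $t\pm1$ through the
finite-difference accelerations, so perturbing every fourth frame at once
recovers the whole banded Jacobian from 24 trajectory evaluations), and
one-sided finite differences for the scales. The inner-IK stationarity
constraint is deliberately dropped at this stage: kinematics may deviate
slightly from marker-optimal to absorb the residual.

## The synthetic world

`make_trial()` generates the validation regime: a subject sampled from
the scaling prior (about 5 % scale SD), marker offsets perturbed with
1 cm SD (anatomical halved, truncated at 2 cm), noise-free markers at
100 Hz, and a smooth periodic gait-like motion (sinusoidal hips, a
raised-cosine swing knee bump, small ankle/lumbar/neck/pelvis
oscillations, 0.8 m/s progression, left/right half-period symmetric,
amplitudes jittered per seed). Ground reaction forces are *derived*, not
simulated: inverse dynamics of the prescribed motion gives the exact
total external wrench that zeroes the root residual, split between stance
feet by a smooth cosine schedule (60 % duty, 10 % double support) and
converted per foot into a ground-plane centre of pressure, force, and
free moment.

Two non-realisms are accepted deliberately. The prescribed kinematics are
not the solution of a contact simulation, so stance feet can glide
slightly; and the moment a real walker resolves through centre-of-pressure
placement and lateral sway is absorbed into a full 3-D free moment
whenever the exact line of action leaves a box around the stance foot
(real plates report only a vertical free moment). Both preserve the
generator's defining property -- the root residual of the generated trial
is zero to machine precision at every frame -- which is what the
downstream stages are validated against. Plate records default to the
marker rate so file round trips and synchronization leave the invariant
intact; the 1000--2000 Hz filter/resample path (4th-order zero-phase
Butterworth at 15 Hz, then linear resampling; COP resampled without
filtering because it is a quotient of filtered quantities) is validated
separately against analytic signals.

A green synthetic benchmark therefore establishes that the estimator
recovers a truth that *exists within the model family* -- same joint
structure, Gaussian perturbations matched to the priors, no soft-tissue
artifact, no marker noise in the headline regime. It does not establish
robustness to model mismatch, labeling errors, or real skin-motion
artifact.

## Numerical choices and limitations

* Marker SD 1 cm, anatomical offset SD 5 mm, tracking offset SD 5 cm,
  residual SDs 1 N / 1 N m: configuration defaults; the generative model
  of the synthetic world matches them where applicable.
* Damped (Levenberg-style) steps everywhere, accepted only on objective
  decrease; iteration caps of 30 (MAP), 100 (root fit), 10 (final map)
  with convergence tolerances 1e-9 relative, 1e-6 max-norm on the stacked
  trajectory, and 1e-6 relative respectively.
* Frame subsampling: scale initialization uses 30 evenly spaced frames;
  all other stages use every frame.
* Degenerate inputs: static marker groups raise a rank-deficiency error
  in the centre estimate; frames with fewer than three visible markers
  copy their neighbour's pose and are flagged; zero ground forces raise
  the mass-unidentifiability error; a zero peak GRF makes the residual
  normalization undefined and errors out.
* Joint limits, muscles, wrapping, closed loops and C3D parsing are out
  of scope; the OpenSim reader covers a restricted subset (Free, Ball,
  Universal, Pin joints, markers, mass properties) and rejects custom
  joints with a clear error.
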