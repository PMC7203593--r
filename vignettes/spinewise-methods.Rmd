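---
title: "Models and methods behind spinewise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinewise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinewise)
```

`spinewise` models a lumbar motion segment — two rigid vertebrae coupled by
an intervertebral disk, ligaments and facet joints — and calibrates the
nonlinear force laws of those couplings from stepwise-reduction
range-of-motion (ROM) data. This vignette explains the mechanical model and
its assumptions, the calibration algorithm (including the parts where the
design was genuinely open), the synthetic-data generator that stands in for
experimental inputs, and the numerical choices and known limitations.

## Coordinate and sign conventions

All global mechanics are SI (metres, newtons, radians internally; tables
carry degrees to match how ROM is conventionally reported). The global frame
is right-handed with x medio-lateral, y antero-posterior with +y pointing
dorsally, and z cranio-caudal pointing cranially. With these axes a positive
rotation about x tips the vertebra ventrally, i.e. is flexion; rotation
about y is lateral flexion and about z axial rotation. Facet-local surface
coordinates are in millimetres — that is the scale on which the published
regression-surface coefficients (e.g. an offset near 47 mm) live.

A `pose()` places a mobile vertebra by a rotation vector applied about its
centre of mass plus a translation of that centre. Body-frame point
coordinates coincide with world coordinates in the neutral configuration.

## Force elements

**Disk.** A six degree-of-freedom spring–damper bushing. Each rotation axis
follows the odd tanh-cubic law `T(φ) = p1·tanh(φ³/p2) + p3·φ` (rad → Nm);
flexion and extension have separate parameter rows because the segment is
asymmetric in the sagittal plane, while one odd curve serves both signs of
lateral and axial rotation. The default rows are the packaged calibrated
set (`default_characteristics()`). Axially the disk resists compression with
the quadratic polynomial `690 234 060 r² + 659 748 r` (N, r in m) and
transmits *no traction* — separation is force-free, a deliberate property
that also shapes the solver (below). Shear is linear; the published sources
give no shear numbers, so the default 260 000 N/m is an explicit
placeholder. Damping coefficients are carried for completeness but cannot
affect any result the package reports: everything is quasi-static, and a
dedicated test verifies that equilibria are damping-independent.

Two fine points about the flexion row deserve note. First, its linear
coefficient is negative (−1.685 Nm/rad), so the curve has a shallow
non-monotone toe below ~0.03 rad (dip magnitude < 0.02 Nm) and the upright
pose of a disk-only segment is weakly unstable between two stable equilibria
at ±0.031 rad. Second, the row saturates near 10.2 Nm, the top of the
protocol's torque range — loads beyond it have no equilibrium at all, which
the solver reports as a diagnostic error rather than hiding.

**Ligaments.** Point-to-point cables with the smooth softplus force–strain
law `F(ε) = a·ln(e^((ε+b)/d)+1) + c` (ε in percent, F in N), which
reproduces the toe zone and quasi-linear region of connective tissue with a
single differentiable expression. Negative `d` yields a concave, decreasing
curve (the packaged flaval-ligament row is of this kind). The supraspinous
row carries a separate negative-strain branch; construction asserts the two
branches agree at ε = 0 to within 0.1 N. Total tension is clamped
non-negative — a cable cannot push. Each ligament has a physiological
prestrain (8 % ALL, 10 % PLL/FL/ITL/CL, 4 % ISL, −6 % SSL); the rest length
is derived from the neutral-pose length via `L0 = L_neutral/(1+ε0/100)`, so
neutral-pose strain equals the declared prestrain by construction (the
sources state prestrains, never rest lengths). The intertransverse ligament
is carried geometrically with its prestrain but defaults to a zero-force
characteristic: the reduction protocol never isolates it, so no
characteristic can be derived for it.

**Facets.** Each articular surface is the convex cubic
`f(x,y) = p30·x³ + p03·y³ + p20·x² + p02·y² + p00` fitted by linear least
squares to nine landmarks per process; the joint surface is the
component-wise mean of the superior and inferior fits (coefficient
averaging, rather than refitting pooled points, is what yields a single
published-style coefficient set per facet). Contact is penalty-based on a
small set of probe points attached to the opposing process: the penetration
of a probe below the mean surface, projected on the local surface normal,
times the contact stiffness (≈ 12 000 N/m) gives a normal force at the
probe. Probe-point contact replaces surface–surface contact deliberately —
the model's design goal is to preserve individual surface curvature at
negligible computational cost.

**Muscles.** One-dimensional, length-independent cables: constant force
(40 N per cable, 80 N per pair) along a fixed global direction, applied at a
body-fixed attachment point. Only the application point moves with the
pose.

**Intradiscal pressure.** `IDP ≈ 1.68 · F/CSA`, with F the axial
compressive disk force and CSA the cross-sectional area; the 1.68 factor is
the established empirical ratio of nucleus pressure to mean axial stress.

## Equilibrium solver

The state vector stacks (translation, rotation vector) per mobile body; the
residual is the total wrench (applied pure moment plus all element wrenches)
about each mobile body's posed centre of mass, zero exactly at equilibrium.
Convergence requires every force component below 1e-6 N and every torque
component below 1e-8 Nm.

The core iteration is damped Newton with a central-difference Jacobian
(step 1e-7), a backtracking line search on a weighted residual norm (N and
Nm components are scaled to comparable magnitudes), a per-iteration trust
cap of 10 mm / 0.1 rad, and Broyden rank-one updates that let one Jacobian
serve several steps — the finite-difference Jacobian dominates the cost of
the 24-DOF chain model. Applied moments are ramped in at most five
increments with warm starts.

The model is only piecewise smooth: the disk axial law has a kink at
contact, ligaments switch between slack and taut, facet probes between
separated and contacting, and the sagittal disk row between its flexion and
extension branches. Three safeguards deal with this:

1. *Homotopy*: on stagnation the solver re-solves with a small artificial
   axial tension stiffness (1e4 N/m) and a smoothed ligament clamp
   (softplus smoothing, widths 1e-2 then 1e-4 N). This regularizes the
   force-free separation branch of the disk — which is otherwise a solution
   *manifold* along which Newton drifts — and removes the slack/taut
   derivative kink.
2. *Active set*: the smoothed solution seeds a stage that freezes every
   element on its current branch (making the residual smooth), solves, and
   re-checks branch consistency, flipping branches until consistent. A
   branch-consistent frozen solution that passes the exact tolerances is an
   exact equilibrium of the true piecewise model.
3. *Basin kicks and relaxation*: if branch assignment cycles (which happens
   when the iterate sits between the two stable sagittal basins created by
   the flexion row's negative toe slope), the sagittal rotations are kicked
   ±0.05 rad into each basin and the exact solve retried. The last resort is
   dynamic relaxation — explicit damped integration until the kinetic energy
   falls below 1e-9 J — followed by a Newton polish.

Regularized, smoothed or frozen force laws are used *only* to steer the
iteration; every reported equilibrium satisfies the exact piecewise model at
the stated tolerances.

## Backward stepwise-reduction calibration

The reduction protocol removes structures in the order SSL, ISL, FL, CL,
vertebral arches (taking facet contact and the ITL with them), PLL, ALL,
measuring ROM under pure moments of {0, 1, 2.5, 5, 7.5, 10} Nm in four
directions before each cut. Rolled backward, each stage adds exactly one
element on top of an already-calibrated partial model:

1. *Disk* ← disk-only stage: each record directly yields the point
   (φ = ROM in radians, T = applied torque); flexion and extension are kept
   separate, lateral/axial pooled by oddness, the origin appended, and the
   tanh-cubic law fitted per direction by Levenberg–Marquardt with a
   multi-start grid (p1 ∈ {1,5,20}, p2 ∈ {1e-3,1e-2}, p3 ∈ {−5,1,20}).
   On noiseless synthetic data this fit is exact to machine precision.
2. *ALL, PLL, facet stiffness, CL, FL, ISL, SSL* — one per subsequent
   stage. For each record the loading-axis rotation of the mobile vertebra
   is clamped at the recorded ROM, the free degrees of freedom are
   equilibrated with all known elements plus the current estimate of the
   new element, and the *deficit moment* — the torque about the disk centre
   that the known elements cannot supply — is attributed to the new
   element. Dividing by the element's moment arm about the disk centre
   yields a force sample at the strain of that pose; the softplus law is
   then refitted and the extract–fit cycle iterated to a fixed point.
   Because the translational DOFs are equilibrated in every record, the net
   force on the vertebra vanishes and the deficit torque is independent of
   the reference point, which makes the disk-centre convention consistent
   with the solver's centre-of-mass residual.

Facet stiffness uses the same machinery with a scalar unknown: engaging
records (extension, lateral, axial) yield per-record stiffness samples
(deficit torque over the facet moment per unit stiffness at that pose), and
the reported stiffness is the least-squares scalar over all samples,
iterated because the contact state feeds back on the free equilibria.

### The neutral-angle problem

ROM is recorded *relative to each stage's 0 Nm pose*, and that pose is not
itself observable from the table (the 0 Nm rows are the reference). The
absolute sagittal neutral angle of a stage therefore enters the calibration
as a hidden unknown, and it is almost degenerate with the fitted curve: a
shift of the neutral shifts every strain, and the softplus family can absorb
most of the shift into its `b` parameter. A naive extract–fit fixed point
can converge to self-consistent but wrong solutions. Two mechanisms resolve
the degeneracy:

* *Slack-side anchoring.* On the sagittal side where the new element goes
  slack (flexion for the anterior longitudinal ligament and the facets,
  extension for the posterior elements), the partial model alone must
  reproduce the recorded ROM. Each unconstrained equilibrium there yields an
  estimate of the absolute neutral angle; a torque-weighted mean (deepest
  slack first) anchors it.
* *One-dimensional refinement.* The anchor is then refined by minimising,
  over the neutral angle, the arm-weighted misfit of the extracted points to
  the softplus family plus a penalty on records that would require the cord
  to push. This also covers characteristics that never go slack — the
  concave flaval row keeps pulling at every strain the protocol reaches, so
  slack anchoring alone cannot pin its stage; the refinement resolves the
  trade-off through the known elements' nonlinearity.

Lateral and axial neutral angles are taken as zero, which is exact for the
sagittally symmetric synthetic geometry; asymmetric data with both load
signs would pin them the same way. Fit points are weighted by their moment
arm: a deficit torque divided by a millimetre-scale arm amplifies any pose
error a hundredfold, so cross-axis records of midline ligaments carry
little weight (records with arms below 1 mm, or requiring negative tension,
are dropped outright). Bilateral pairs split a sagittal deficit equally; in
lateral/axial loading the strained side receives it.

On noise-free synthetic data this pipeline recovers the generating model
essentially exactly: disk rows to the four significant digits they are
reported at, facet stiffness to a few tenths of a percent, ligament curves
to RMSEs of 0–1 N over their engaged strain ranges, and re-simulated ROM to
well under 0.1°.

## Synthetic data generator

The generator builds non-anatomical but scale-plausible geometry: a 40 mm
vertebral spacing with the disk centre midway, midline insertions for
ALL/PLL/FL/ISL/SSL at literature-like dorso-ventral offsets, exactly
mirror-symmetric bilateral CL/ITL pairs, and facet surfaces fitted to nine
landmarks sampled from a convex ellipsoid-like patch (±0.08 mm landmark
jitter, so the surface fit residual stays below 0.5 mm). Facet frames tilt
the local normal between lateral and cranial so that extension, lateral
bending and axial rotation all produce contact while flexion separates the
joint, as in the real articulation. Per-seed uniform jitter (±0.5 mm)
varies insertion points while preserving bilateral symmetry. The disk
cross-sectional area defaults to 1.8e-3 m².

Tables are shaped like the emulated experiments: the stepwise table carries
mean ROM (optionally with seeded Gaussian noise, default noise-free),
min/max ranges of half-width `max(0.1°, 15 % of the mean)`, and no ranges at
0 Nm; the pressure table carries mean ± SD with
`SD = max(0.02 MPa, 10 % of the mean)`. The lumbar chain stacks four such
segments (L2–S1, sacrum fixed) and attaches five mirror-symmetric cable
pairs. The experiment it emulates guides its wire cables along the spine, so
the 80 N pairs act like follower loads and cannot buckle the specimen; with
single-attachment constant-direction cables the equivalent safeguard is to
spread the attachments over the lumbar vertebrae near their caudal ends,
which keeps every disk's dead-load destabilising stiffness below its lateral
restoring stiffness while still loading the L4–L5 disk whose pressure is
reported. Cable directions are explicitly non-anatomical placeholders.

What passing the synthetic round trip does and does not show: it
demonstrates that the backward calibration is a consistent estimator of the
generating model under the protocol's information content — it does not
demonstrate anatomical fidelity, nor robustness to the systematic artifacts
of real reduction experiments (specimen settling after cuts, the
vertebral-arch-removal jump in lordotic angle that the original experiment
itself could not explain; the generator deliberately does not emulate that
artifact, and consequently the flaval stage here is well-behaved rather
than concave-artifactual).

A property worth flagging: removal monotonicity — deleting a resistive
element never decreases ROM — holds for every stage transition *except* the
flaval removal when the packaged concave FL row is the ground truth. A
ligament whose force decreases with strain shifts the stage neutral more
than it stiffens the end range, so per-stage-referenced ROM can drop
slightly when it is removed. The property tests therefore assert
monotonicity for all other transitions (with a 0.05° allowance for
neutral-reference effects) and exempt the FL step.

## Problem sizes and tolerances

The packaged study conditions are the full protocol grids: 8 stages × 4
directions × 6 torques (192 equilibria, 160 loaded) for the stepwise
experiment and 7 muscle configurations × 7 load cases (49 chain equilibria)
for the pressure experiment. A complete generate–calibrate–re-simulate loop
on a single CPU takes on the order of a minute or two; the chain protocol
about one more. The test suite runs the noise-free loop once and two noisy
replicates (noise SD 0.25°, range half-width 15 %), checking that the
re-simulated model stays inside the synthetic ranges in at least 90 % of
the 160 scenarios.

Numerical defaults: solver tolerances 1e-6 N / 1e-8 Nm, finite-difference
step 1e-7, torque ramp ≤ 5 increments, neutral-angle refinement tolerance
1e-4 rad, extract–fit convergence 0.02 N, curve fits run to
Levenberg–Marquardt machine tolerances with multi-start (ties within 1e-6 N
RMSE resolved toward the smaller |b|). Curve parameters are conventionally
reported at four significant digits.

## Robustness to measurement noise

The noise-free round trip closes essentially exactly, but three effects
limit robustness once ROM noise of the order of a quarter degree is
injected, and they are worth understanding before trusting a noisy
calibration:

* *Range tightness at low torque.* Synthetic ranges have half-width
  `max(0.1°, 15 % of the mean)`; at 1 Nm the mean ROM is itself around a
  degree, so the half-width is of the same order as the noise — even the
  generating model re-scores roughly 7–11 % of scenarios outside its own
  noisy ranges. Outlier counts at this noise level measure the range
  geometry as much as the calibration.
* *Facet stiffness identifiability.* Penalty contact depends on the stage
  neutral at the tenth-of-a-millimetre level. A neutral shift rescales all
  probe penetrations almost proportionally, so (neutral, stiffness) form a
  near-degenerate ridge: per-record stiffness samples can agree with each
  other to a few percent while sitting far from the generating value. The
  flexion records (open joint) pin the neutral independently of stiffness
  and are included in the refinement for exactly this reason, but their
  precision is noise-limited; stiffness estimates from noisy tables should
  be treated as order-of-magnitude.
* *Saturation knife edge.* The flexion disk row's maximum (~10.16 Nm) sits
  1.6 % above the protocol's top torque. Noise in the disk-only stage can
  push the fitted row's maximum below 10 Nm, and the re-simulated top
  flexion scenario of the sparsest stages then has no nearby equilibrium.
  This sensitivity is intrinsic to the printed parameters, not to the
  estimator.

The noisy property test therefore asserts graceful degradation (the
pipeline completes, re-simulation converges, disk rows are recovered at the
noise level, and the outlier rate stays below thirty percent of scenarios)
rather than noise-free tightness. Several estimator safeguards came out of
this analysis and are always active: the slack-side neutral anchor uses the
median across records (robust to the saturation record), failing
constrained records are skipped rather than fatal, the neutral refinement
refits with a full multi-start, and only points whose moment arm exceeds
8 mm enter a ligament fit (a ~0.1 Nm deficit uncertainty over a smaller arm
amplifies to tens of newtons; the 1 mm minimum remains the hard skip rule).

## Known limitations

* Geometry is rigid; vertebral surface deformation is out of scope.
* The disk transmits no traction, so scenarios dominated by cranial
  traction (the cranially pulling multifidus configuration) produce
  near-zero intradiscal pressure with only ligaments resisting — the same
  mechanism the source experiments identify as their hardest case.
* Shear disk characteristics are placeholders; calibration does not
  identify them (pure-moment protocols barely exercise shear).
* The intertransverse ligament cannot be calibrated from this protocol.
* Lateral/axial neutral angles are assumed zero during calibration, exact
  only for symmetric geometry or sign-symmetric protocols.
* The stepwise pipeline propagates each stage's fit residual into later
  stages; on noise-free data this stays at the ~1 N level by construction,
  but noisy data inflate it roughly with the noise level.
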