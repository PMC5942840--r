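---
title: "Probabilistic finite-element prediction of facial soft tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic finite-element prediction of facial soft tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surgical planning tools for Le Fort I maxillary advancement predict the
postoperative facial surface by simulating how the soft tissue follows the
repositioned bone. Deterministic simulators return a single surface, although
the inputs they depend on — soft-tissue stiffness, near-incompressibility,
viscoelastic relaxation, cartilage stiffness, and above all how precisely the
surgeon realises the planned advancement — are uncertain. `facefem` treats
those inputs as random variables and propagates them through a
finite-element model, so that every facial landmark receives a *prediction
envelope* (minimum, maximum, histogram, cumulative density) instead of one
number.

The landmarks are the standard cephalometric probe points: pronasale (N,
nose tip), labrale superius (UL), labrale inferius (LL), and a right and
left cheek point (RC, LC).

## The forward model

### Geometry: a layered midface phantom

Patient imaging is out of scope; the package generates a synthetic phantom
(`build_phantom()`) that preserves the mechanical structure the workflow
needs:

* a stiff posterior bone plate, split by an unmeshed osteotomy gap into a
  fixed skull base and a mobile maxillary segment (the two segments share no
  nodes, both are bonded to the soft tissue through shared interface nodes);
* an unmeshed window in the skull base above the osteotomy, emulating the
  piriform aperture and the thin-walled maxillary sinuses: there is no solid
  fixed bone directly behind the nose or the cheeks;
* a cartilage inclusion buried in the soft tissue, rooted on the mobile
  segment below the cut and bridging up behind the nose landmark, like the
  nasal cartilage riding on the maxilla;
* a near-incompressible soft-tissue layer covering the bone and filling the
  sub-maxillary (lip/chin) region, whose outer face is the skin.

Coordinates are x lateral, y anterior (the advancement direction), z
superior, lengths in mm. UL and LL sit over the mobile segment (rigid
followers of the advancement, correlation with it near 1), N sits over the
cartilage bridge (about two thirds of the advancement at mid-range
materials, strongly material-dependent), and RC/LC sit on the soft span over
the bone window (about a third of the advancement, material-dependent).
Earlier layouts with cheeks over solid fixed bone were rejected: their
responses were an order of magnitude smaller than clinically reported
landmark displacements, and their tiny-but-nonzero material leverage made the
downstream optimisation chase unreachable cheek targets into the bounds.

The mesher subdivides the block into hexahedral cells (target edge length
`edge`, default 5 mm) and each cell into six tetrahedra. A rectangular block
is a deliberate simplification: the contribution of the package is the
probabilistic workflow, not anatomical realism, and the block preserves the
fixed-bone / mobile-bone / cartilage / skin mechanics the workflow probes.

### Materials and viscoelasticity

Each region is linear elastic; the soft tissue additionally relaxes in shear
(no volumetric relaxation — the tissue is treated as nearly incompressible)
following a two-term Prony series

$$G(t) = 1 - s\sum_i g_i\,(1 - e^{-t/\tau_i}),
  \qquad g = (0.325,\, 0.3),\ \tau = (1,\, 6)\ \mathrm{s},$$

i.e. 62.5% long-time relaxation at unit scale. The scale factor $s \in
[0.488, 1.512]$ sweeps the relaxation between 30.5% and 94.4% and is one of
the uncertain inputs. The other uncertain inputs are the Young's moduli and
Poisson's ratios of bone, cartilage and soft tissue (literature ranges,
`material_bounds()`), and the advancement `x_adv` with a ±2 mm execution
window.

### Discretisation and time integration

Linear tetrahedra lock volumetrically as $\nu \to 0.5$; at $\nu_{soft} =
0.499$ the locking suppresses landmark motion by an order of magnitude. The
solver therefore applies an averaged-volumetric-strain (B-bar) treatment to
the soft tissue: the volumetric strain is replaced by its volume-weighted
average over the six tetrahedra of each parent hexahedral cell. Patch
averaging over the parent cell (rather than over nodal neighbourhoods)
keeps the stiffness stencil local — nodal averaging was measured to produce
a two-ring stencil whose factorisation cost made desk-scale designs of
experiments infeasible — while relaxing the incompressibility constraints
just as effectively (verified against the uniaxial closed form and by the
mesh-refinement study).

The viscoelastic stress follows the hereditary integral with the standard
internal-variable exponential recurrence: per time step of length
$\Delta t$, the effective soft-tissue shear factor is
$g_\infty + \sum_i s\,g_i\,\beta_i$ with
$\beta_i = (1 - e^{-\Delta t/\tau_i})\,\tau_i/\Delta t$, and the decayed
internal variables enter the right-hand side as a history force. The
prescribed translation ramps linearly over 1 s and is held to 60 s
(10 times the longest relaxation time, where the default series is within
$10^{-4}$ of its long-time plateau); the end-of-hold state is "the
prediction". The source material does not state a ramp shape, duration or
whether a component or magnitude is reported; these are this package's
declared conventions, with the signed anterior (y) component as the default
landmark output. The time grid uses linear steps across the ramp and
log-spaced steps through the hold (30 steps by default, 12 in the desk
preset); because the effective modulus of the final large steps approaches
the long-time value, the end state is insensitive to the step count (the
12-step end state agrees with a long-time elastic solve to about $10^{-4}$
relative).

Boundary conditions mirror the clinical fixation planes: soft tissue clamped
posteriorly, superiorly and inferiorly; skull base clamped posteriorly and
superiorly; the advancement prescribed on all surface nodes of the mobile
segment. The mandible is not modelled, which is why the lower lip is
excluded from optimisation downstream.

## The probabilistic workflow

### Variable screening

A space-filling design over all eight inputs (maximin Latin hypercube: 100
random Latin hypercubes are scored by their minimum pairwise distance and
the best kept) is solved, and Spearman rank correlations between every
input and every landmark decide inclusion: an input enters the later stages
if it is significant ($p < 0.05$) against at least one landmark; the rest
are frozen at their range midpoints. Confidence intervals use the Fisher
z-transform with the rank-correlation variance $1.06/(n-3)$. The screening
design defaults to $n = 100$ runs (60 in the desk preset), sized so the CI
half-widths match those a screening of this kind reports. On the phantom
the advancement dominates every landmark and the bone properties are never
selected; the soft-tissue/cartilage set that survives is geometry-specific
(at desk conditions: cartilage stiffness, soft-tissue stiffness and the
viscoelastic scale).

### Design of experiments I

Per subject, a maximin-LHS design over the screened inputs, sized by the
central-composite rule $2^{k-1} + 2k + 1$ for $k \ge 5$ (27 runs for five
variables) and $2^k + 2k + 1$ below, with the advancement range centred on
the subject's planned value. One forward solve per row gives per-landmark
min/max prediction ranges.

### Surrogates and goal-driven optimisation

Per landmark, two response-surface families are fitted on the DOE I results
over bounds-scaled inputs and the leave-one-out CV winner is kept: a full
quadratic polynomial with interactions, and a Gaussian process (RBF kernel,
bandwidth by the median heuristic; the kernel is isotropic after the
per-dimension bounds scaling). The loser remains available in an ensemble
slot with its CV error.

For each training subject the inputs are then optimised so the surrogate
predictions match the subject's observed landmark displacements at N, UL,
RC and LC (equally weighted; LL excluded because the mandible is not
modelled). The advancement is a *free* optimisation variable: the upper lip
follows the achieved advancement almost rigidly, so freeing `x_adv` lets the
optimiser infer the achieved advancement from the data, and only the
material columns enter the candidate matrix. Fixing `x_adv` at the planned
value was tried first and rejected: the UL target then encodes an execution
error the materials cannot reproduce, and that single unreachable objective
owns the tie-break along the weakly identified material directions, dragging
the whole candidate set onto a bound face of the box. Each
objective is the absolute mismatch $|s_j(x) - t_j|$, which seeks the exact
solution when the target is reachable and otherwise drives candidates to the
bound that minimises or maximises the landmark. The optimiser is an
NSGA-II-style evolution (simulated binary crossover, polynomial mutation,
non-dominated sorting with crowding) with two goal-driven ingredients that
this package adds deliberately: a 10% elite fraction selected by the equally
weighted sum of range-normalised objectives — with four near-degenerate
objectives almost the whole population becomes mutually non-dominated and
plain crowding actively pulls away from the goal — and a final bounded
quasi-Newton polish of the top-scoring candidate on the surrogates. With
these, a planted optimum is recovered to well under 1% of each input range;
without them the weakly identified inputs stall at 5–15%. Population 1000,
at most 10 iterations, early stop when every objective's best changes by
less than 2% between iterations and at least 70% of the population is
non-dominated (the desk preset halves the population). The best 100
candidates — ranked front by front, then by the equally weighted
normalised-objective sum — form the subject's candidate matrix. In the
pipeline the normalisation scale of each objective is the landmark's DOE
response range, a fixed physical scale; normalising by the achieved
objective range over the population was rejected because it inflates
landmarks the materials can barely move into full-weight objectives.

### Weibull fitting and design of experiments II

The five training candidate matrices are pooled row-wise (500 rows per
material) and a location-shifted (3-parameter) Weibull is fitted per
material by maximum likelihood, the location profiled on a grid below the
sample minimum and refined by a one-dimensional search. The shift matters
because parameters such as $\nu_{soft} \in [0.45, 0.499]$ live far from
zero, where a 2-parameter Weibull cannot go; the handling of bounded
parameters is this package's choice. Goodness of fit is summarised by the
Kolmogorov–Smirnov statistic.

DOE II on each validation subject reuses the DOE I probability design
(matched designs): the same Latin-hypercube uniforms are mapped through each
material's truncated inverse Weibull CDF, while the advancement column keeps
its uniform ±2 mm mapping. Matching the designs makes the DOE I vs DOE II
range comparison isolate what actually changed — the input distributions —
instead of Latin-hypercube realisation noise, which was observed to flip
range-refinement signs by ~0.01 mm. The advancement is *not* Weibull-fitted:
execution uncertainty is irreducible by material optimisation. DOE II
defaults to the DOE I run count; envelopes, Freedman–Diaconis histograms and
empirical CDFs are assembled per landmark, and truth containment plus range
refinement are reported per validation subject.

## The synthetic cohort

"Subjects" are phantom replicates sharing the mesh: each of the eight
subjects of the packaged cohort table receives hidden true material
properties (drawn around the range midpoints with a spread of 10% of each
range width — one population, moderate between-subject variability) and an
achieved advancement equal to the planned value plus a truncated-normal
execution error (sd 1 mm, truncated at ±2 mm, reading the ±2 mm figure as a
bound on execution error rather than a uniform spread). Observed landmark
displacements are the forward solve at the true inputs plus 0.2 mm Gaussian
landmark-identification noise. The split is five training / three validation
subjects, mirroring the cohort's P2, P3, P5, P7, P8 vs P1, P4, P6.

What the generator does *not* emulate: real anatomy (curved surfaces,
inhomogeneous skin/SMAS/fat layering), postoperative swelling, mandibular
surgery and autorotation, maxillary rotation, fixation hardware, and
segmentation error. Passing tests therefore demonstrate that the workflow is
implemented correctly and behaves as described on a system with the right
mechanical structure — not that its envelopes are clinically calibrated.

## Numerical choices and degenerate inputs

* Modulus-scale invariance: prescribed-displacement loading makes the
  solution invariant to a joint scaling of all Young's moduli; this is used
  as a solver check.
* Singular systems (insufficient constraints) abort with an error naming the
  likely cause; degenerate phantom dimensions and meshes under 100 nodes are
  rejected at construction.
* Constant screening columns give an undefined correlation: reported as not
  selected, with a warning rather than an error.
* Constant surrogate responses yield a constant predictor with zero CV
  error; a rank-deficient polynomial basis falls back to the GP family.
* Weibull fitting requires at least 30 non-constant samples (pool candidate
  sets); bounded sampling rejects and redraws, erroring when the bounds
  exclude more than 99.9% of the mass.
* FEM response tables are cached on disk keyed by a content hash of the
  inputs and solver protocol, so an unchanged stage rerun performs zero new
  solves; all randomness is seeded per stage from the base seed.

## Problem sizes

The desk preset runs the full pipeline — screening (60 runs), DOE I for
eight subjects, optimisation for five, DOE II for three — in roughly 350
forward solves at the default 5 mm mesh (about 1700 nodes) with 12 time
steps, a few minutes on one core. The full preset keeps the same geometry
with 30 time steps, a 100-run screen and the full MOGA population. The
mesh-refinement property (halving the edge length changes landmark
predictions by less than 5%) is part of the test suite.

## Known limitations

* The phantom is a block, not a face; absolute displacement magnitudes are
  geometry-specific even though the workflow behaviour (advancement
  dominance, N/UL bracketing of the truth) reproduces.
* **Material identifiability bounds the range refinement.** The quasi-static
  end state depends on `E_soft` and `G_scale` only through the long-time
  shear modulus `E_soft · (1 − 0.625·G_scale)` — an exact confound — and the
  four landmark observations span only about two independent material
  directions. Each subject's best-100 candidates therefore spread along a
  ridge that reaches the bounds of the box, the pooled Weibull fits span
  most of the literature ranges, and the DOE II envelopes land within about
  ±1.5% of the DOE I widths (narrower for many subject/landmark pairs,
  marginally wider for others) instead of being uniformly narrower. Truth
  containment, the headline behaviour, is unaffected. A sharper refinement
  would require landmarks that separate the confounded parameters (e.g.
  observations at more than one time point) or a joint (copula-aware)
  candidate distribution instead of four independent marginal fits.
* Small-strain kinematics and linear materials; advancements are ≤ 7 mm on
  ~100 mm geometry, but large advancements would demand nonlinear kinematics.
* The screened variable set at desk conditions can differ from the
  patient-derived set (e.g. $\nu_{soft}$ is marginal on the phantom);
  the pipeline fits whatever survives screening, and the screened set can be
  fixed via `pipeline_config(selected = ...)` when a canonical set is wanted.
* The goal-driven elitism and polish make the optimiser deliberately more
  exploitative than textbook NSGA-II; pure NSGA-II is available with
  `goal_frac = 0`.
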