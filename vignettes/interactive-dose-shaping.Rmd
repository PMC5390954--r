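---
title: "Interactive dose shaping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactive dose shaping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idsplan)
```

## The planning model

IMRT planning is conventionally posed as an inverse problem: minimize a
piece-wise quadratic penalty over non-negative bixel fluence weights,
inspect the resulting dose, adjust penalty weights, repeat. Interactive
dose shaping (IDS) inverts the interaction: the planner edits the dose
distribution itself, locally, and the system translates each edit into
a fluence change on the fly. `idsplan` implements this paradigm
end-to-end on synthetic data, with every step deterministic and
oracle-testable.

Everything rests on the linearity of dose in fluence. The
dose-influence operator $D$ maps bixel weights $w \ge 0$ to voxel doses
$d = Dw$; a local dose edit is a constraint $a \cdot P = \Delta d$ on a
fluence change $P$, where $a$ is the influence row of the selected
voxel. We use the minimum-norm solution

$$P = \Delta d \, \frac{a}{\lVert a \rVert^2},$$

clamped to keep $w + P \ge 0$ and re-solved over the unclamped bixels
(at most 10 passes). The minimum-norm choice is deliberate: it is the
unique closed-form patch enforcing the requested difference, it can be
verified against a brute-force constrained search on toys, and its
spread over all bixels that see the voxel mimics how a many-beam
geometry dilutes local edits.

### Modification and recovery

A patch perturbs dose outside the edited region. The recovery step
compares the current dose with the *pre-modification* reference,
collects voxels outside the modification region $V_M$ whose absolute
deviation exceeds a tolerance $\tau$, sorts them by decreasing
deviation (ties broken by ascending linear voxel index, for
determinism), truncates to the recovery budget $N_R$, and applies a
counter-patch per voxel restoring its reference dose. Design choices
worth making explicit:

* **Recovery is single-pass.** Recovery patches do not trigger further
  recovery; one DMR instance costs at most $1 + N_R$ patches, which
  bounds its runtime linearly in $N_R$.
* **Recovery targets the pre-modification dose.** "Original" is read as
  the dose immediately before the current instance, not the plan's
  initial state; this is what makes consecutive gestures composable.
* **Deviations are re-evaluated at application time.** The ranking is
  computed once against the post-modification field, but each
  counter-patch enforces the *current* deviation of its voxel, so that
  earlier recovery patches are taken into account. On toys with
  disjoint bixel support this restores recovery voxels exactly.
* **Protection of the modification.** Bixels that together carried at
  least 90% of the modification's enforced change are excluded from
  recovery-patch support. Without a guard, a recovery voxel adjacent to
  the edit can undo it immediately; full exclusion is the simplest rule
  that provably cannot reverse the edit, at the price of slightly
  larger recovery patches elsewhere. How the published interactive
  systems protect established dose features is not specified; this rule
  is our operationalization.
* $\tau$ defaults to 0.5% of the boost prescription (0.38 Gy at 76 Gy).
  Tying it to the prescription keeps the recovery set scale-invariant
  under dose rescaling. $N_R$ defaults to 15, the budget quoted for
  real-time operation on desktop hardware.

Internally, one instance updates the full dose grid twice (once for the
modification, once for the accumulated recovery delta); the doses of
individual recovery voxels are tracked exactly through sparse row dot
products. This is algebraically identical to updating after every patch
— dose is linear in fluence — but roughly an order of magnitude faster.

## The dose engine

Clinical IDS systems delegate the physics to a dedicated pencil-beam
engine; `idsplan` instead uses a transparent analytic kernel chosen so
that every property is testable:

* homogeneous water-equivalent body, unit density;
* exponential depth attenuation, $\mu = 0.005\,\mathrm{mm}^{-1}$
  (a 6 MV-like effective attenuation);
* lateral profile of a finite bixel: difference of error-function
  edges with penumbra $\sigma = 3$ mm;
* parallel rays (no divergence), bixels $5 \times 5$ mm so one bixel
  row maps onto one 5 mm MLC leaf pair;
* entries below $10^{-4}$ of a bixel's maximum are dropped, which
  bounds the sparse operator's memory while keeping linearity checks at
  the $10^{-9}$ Gy level.

Radiological depth is computed by ray marching (2 mm sampling). The
sample phase along the ray is $1/\pi$ of a step rather than $1/2$: with
half-step phases, gantry angles whose direction cosines are rational
(multiples of 60°) land samples exactly on voxel faces, where one-ulp
rounding differences flip the containment test and break the mirror
symmetry of opposed-beam geometries. None of these constants is
physical truth; all are exposed in `kernel_params()` and recorded in
the influence operator's JSON sidecar.

## The synthetic phantom

The generator emulates a male pelvis at planning resolution: a body
contour, a PTV with an interior simultaneous-integrated-boost volume at
a higher prescription (defaults 73 and 76 Gy, the top of the clinical
range), a rectum posterior of and abutting the PTV, and a bladder
anterior/superior. Organs are superellipsoids whose centers and radii
are jittered by a seeded uniform draw (±3 mm by default); the
containment chain boost ⊆ PTV ⊆ body and the OAR/PTV disjointness are
enforced by mask intersection after jitter, so they hold for every
seed. Margins between PTV and boost and the overlap conventions are
parameters of `phantom_spec()` rather than fixed values, since no
canonical figure exists for them.

What the phantom does *not* emulate: CT intensities and tissue
heterogeneity, concave target shapes wrapping around an OAR, air
cavities in the rectum, inter-fraction motion. Consequently, passing
tests show that the operators are correct and that the workflow can
reach its goals on smooth convex-ish anatomy; they do not show clinical
plan quality on real patients, where tighter overlaps make the
trade-offs considerably harder.

Two grid presets are built in: `test` (64 × 64 × 48 at 4 mm, the scale
used throughout the test-suite and the acceptance script) and
`clinical` (256 × 256 × 160 at 1.95 × 1.95 × 2.0 mm, matching planning
practice). All operators are resolution-independent; the coarse preset
exists purely to keep a full study in the tens of seconds.

## The scripted planning workflow

The clinical workflow being emulated was manual: open fields scaled so
that the PTV median dose equals the mean of the PTV and boost
prescriptions, then GUI shaping until each Quantec dose-volume
constraint held, then further sparing as a trade-off against coverage.
Reproducibility requires removing the human, so `goal_script_run()` is
an explicitly greedy automation:

1. per goal (rectum Quantec, bladder Quantec, then a target-coverage
   floor), find the most-violating constraint $V_x$;
2. place a sphere-decrease gesture (radius 3 voxels) at the hottest
   organ voxel above $x$ Gy, requesting a drop to 95% of $x$, capped at
   4 Gy per gesture;
3. accept the gesture only if a scalar objective — the summed Quantec
   excess plus 10 × the shortfall of the target `D98%` below 95% of
   prescription — strictly decreases *and* no previously satisfied
   constraint of the same or a higher-priority goal flips to violated;
   otherwise roll the plan back and blacklist the voxel;
4. stop at satisfaction or when the per-goal budget of DMR instances is
   spent (reported, not fatal).

Two aspects deserve justification. First, the planner's spheres carry a
`within` filter restricting the touched voxels to the organ being
spared. An unrestricted body-wide sphere centered on a rectum voxel at
the PTV interface also requests decreases *inside* the PTV, and because
those voxels belong to the modification region, recovery never restores
them — a single aggressive gesture was observed to push the PTV `D98%`
from 73.6 to 30.9 Gy. The filter is the scripted analogue of a planner
clicking the isodose surface *inside* the rectum, and it leaves the
plain gesture semantics (one request per in-sphere body voxel)
untouched for interactive use. Second, the 4 Gy per-gesture cap keeps
each gesture's collateral within what a 15-voxel recovery budget can
plausibly restore; large edits are reached by repeated accepted
gestures, mirroring how incremental interactive work proceeds.

The objective weights (1 per Quantec constraint, 10 on the coverage
floor) encode the hierarchy: target coverage is worth an order of
magnitude more than a percentage point of OAR volume. No plan
normalization is ever applied after shaping; the only global scaling
happens at initialization, where the open-field condition
$D_{50\%}(\mathrm{PTV}) = (Rx_\mathrm{PTV}+Rx_\mathrm{boost})/2$ is met
exactly by one closed-form rescaling (the median is linear in a global
factor).

## Metrics conventions

* `Dq%` is voxel-exact (no interpolation): the largest dose received by
  at least q% of the structure; `D50%` is therefore the sample median
  on odd-sized structures. `Vx` uses an inclusive ≥ at the threshold,
  matching the cumulative-DVH convention.
* The conformity index follows the two-factor definition
  $CI = CI_1 \cdot CI_2$ with the reference volume taken at a
  *threshold fraction* of the prescription (default 0.95). The
  threshold is a parameter because the index's prose definition uses
  the prescription itself while study practice applies the 95% level.
  If no voxel reaches the threshold all three factors are defined as 0.
* The homogeneity index is the population (divisor $n$) standard
  deviation of dose over the structure; at structure voxel counts the
  sample correction is negligible and no convention was specified.
* NTID is $\rho \cdot V \cdot \overline{D}$ over body-minus-PTV with
  $\rho = 1$, reported in litre·Gy.
* The bladder Quantec set is V65<50, V70<35, V75<25, V80<15 (%); the
  last bound is read as V80 for internal consistency with the V80
  reporting column of the study tables, which print the second V75
  twice. All nine inequalities are strict.
* PTV indicators are computed over the whole PTV including the boost
  region.

## Sequencing

"Seven equidistant fluence levels" is read per beam: the step is
`max(weight)/7` and each bixel rounds half-up to an integer level in
0–7, so the quantization error is at most half a step (an all-zero beam
has step 0 and produces no segments). Whether the clinical stratifier
rounds or floors, and whether levels are global or per beam, is not
derivable; per-beam rounding is the documented default. The
decomposition itself is the classic unidirectional sweep: per leaf-pair
row, cumulative positive and negative gradients of the integer profile
define the left and right leaf trajectories; rows are synchronized into
global unit-step segments; both leaves move monotonically and the
apertures sum back to the stratified map *exactly*, which is the
deliverability contract the rest of the package relies on. The
proprietary clinical sequencer is not reproduced, so segment counts are
comparable in spirit, not in value; no interdigitation or
tongue-and-groove constraints are imposed, which keeps the
decomposition exact.

## Numerical conventions and degenerate inputs

* Axis convention: x left–right, y anterior–posterior (+y posterior),
  z inferior–superior; column-major linear indices; voxel centers at
  `origin + (index − 0.5) · spacing`.
* Dose–fluence consistency is maintained to $10^{-8}$ Gy through every
  operation and asserted in tests; incremental updates agree with full
  recomputation to $10^{-9}$ Gy.
* Zero-dose-change requests produce zero patches; a voxel with an empty
  influence row raises an `ids_infeasible` condition and leaves the
  plan state untouched; the first infeasible instance of a gesture
  aborts the remainder while earlier instances persist.
* Plan states serialize to a directory container (JSON manifest,
  full-precision CSV fluence, raw little-endian dose block, NRRD
  masks); a save/load/save round trip is byte-identical.

## Problem sizes used by the test-suite

Unit tests run on 16³–32³ grids where the dense oracle comparisons are
cheap; the study-emulation checks run five seeded phantoms at the full
`test` preset (64 × 64 × 48). These sizes were chosen so the complete
suite, including the end-to-end checks, finishes in a couple of minutes
while still exercising the nine-beam geometry at a realistic aspect
ratio.

## Known limitations

* The analytic kernel has no scatter, heterogeneity or divergence; NTID
  and low-dose-bath behaviour are qualitative only.
* The greedy scripted planner has no global view: it can blacklist its
  way into a corner on geometries where single-voxel gestures cannot
  improve the objective, and its stopping rule for "further sparing as
  trade-off" is a budget, not an optimum.
* Recovery protection by full bixel exclusion is conservative; a
  directional clamp (allowing partial reuse of protected bixels) would
  likely reduce residuals.
* The baseline optimizer is a plain projected-gradient quadratic-penalty
  method, adequate as a deterministic reference, not competitive with a
  clinical TPS optimizer.
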