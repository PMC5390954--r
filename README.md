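# idsplan — interactive dose shaping for IMRT treatment planning

`idsplan` implements the *interactive dose shaping* (IDS) strategy for
intensity-modulated radiation therapy planning: instead of tuning the
weights of an inverse-planning cost function and waiting for a
re-optimization, the planner manipulates the 3D dose distribution
directly and locally, one voxel neighbourhood at a time. The package is
aimed at medical-physics researchers who want a transparent, fully
scriptable sandbox for this planning paradigm — every operator is exact,
testable, and runs on synthetic pelvic phantoms with no clinical data.

## The core operator: dose modification and recovery (DMR)

Dose is linear in the bixel (beamlet) fluence weights `w` through a
sparse dose-influence operator `D`:

    d = D w,        d_i = dose in voxel i,  D[i, b] = Gy per unit weight of bixel b.

A request to change the dose at voxel `v` by `Δd` is enforced by a
**fluence patch** applied to the influence row `a = D[v, ·]`:

    P = Δd · a / ‖a‖²     (minimum-norm solution of  a·P = Δd),

clamped so that `w + P ≥ 0`. The patch inevitably perturbs dose
elsewhere; the **recovery step** ranks all voxels outside the intended
modification region whose dose now deviates from the pre-modification
reference by more than a tolerance τ, and applies counter-patches to the
`N_R` worst of them (default `N_R = 15`), restoring their original dose.
Modification plus budgeted recovery is one *DMR instance*; interactive
gestures (single-voxel nudges, isodose-line drags, spherical
isodose-surface pushes) translate into sequences of DMR instances.

On top of DMR the package provides:

* a seeded synthetic **pelvic phantom** generator (body, PTV with
  simultaneous integrated boost, rectum, bladder) on a voxel grid;
* a finite **pencil-beam dose engine** (exponential depth attenuation,
  error-function lateral penumbra, nine co-planar beams, 5 mm bixels)
  with incremental dose updates;
* a **goal-driven shaping script** that emulates the clinical workflow:
  open-field initialization to `D50%(PTV) = (Rx_PTV + Rx_boost)/2`, then
  hierarchical Quantec-first sparing of rectum and bladder;
* **plan-quality mathematics**: DVH, `Dq%`/`Vx` indicators, the van't
  Riet conformity index `CI = CI1 · CI2` at a 95% dose threshold, the
  homogeneity index (dose standard deviation), the non-tumor integral
  dose `NTID = ρ · V · mean(dose)` in litre·Gy, and the Quantec
  constraint report (rectum V50<50, V60<35, V65<25, V70<20, V75<15;
  bladder V65<50, V70<35, V75<25, V80<15, in %);
* an MLC **sweep sequencer**: stratification to 7 equidistant fluence
  levels, unidirectional step-and-shoot decomposition with exact
  reconstruction, and a deliverability check that re-evaluates all
  metrics on the sequenced plan;
* a quadratic-penalty projected-gradient **baseline optimizer** standing
  in for a conventional inverse-planning reference plan.

## Worked example

```r
library(idsplan)

ph   <- generate_phantom(phantom_spec(seed = 2))          # 64 x 64 x 48, 4 mm
infl <- build_influence(ph$grid, ph$vois$body, beam_set()) # 9 beams, 5 mm bixels
plan <- init_plan(ph, infl)                                # open fields, D50% condition
plan
#> IDS plan: 17808 bixels, 1 history entries, D50%(PTV) = 74.50 Gy

quantec_check(plan$dose, ph$vois$rectum, ph$vois$bladder)
#>   structure  x limit     value  pass
#> 1    rectum 50    50 48.549811  TRUE
#> 2    rectum 60    35 32.912989  TRUE
#> 3    rectum 65    25 26.355612 FALSE
#> 4    rectum 70    20 19.798235  TRUE
#> 5    rectum 75    15  9.079445  TRUE
#> 6   bladder 65    50  9.360731  TRUE
#> ...
```

The open-field start violates the rectum V65 constraint. One scripted
shaping pass fixes it — a sphere-decrease gesture at the hottest rectum
voxel, executed as 71 DMR instances and accepted because the scalar
objective (summed Quantec violation plus target-coverage penalty)
improves:

```r
plan <- goal_script_run(plan)
attr(plan, "goal_log")
#>             goal  voxel dd instances accepted objective
#> 1 rectum_quantec 105056 -4        71     TRUE         0

rep <- metrics_report(plan$dose, plan$vois, plan$rx, plan$grid)
rep$indicators
#>       voi n_voxels  mean    d50       d98    d2      hi
#> 1    body    66434 15.85  9.506 0.000e+00 74.51 19.8299
#> 2     ptv     1816 74.70 74.599 7.255e+01 77.11  1.0126
#> 3   boost      451 73.90 74.011 7.236e+01 75.13  0.6626
#> 4  rectum      793 47.20 49.508 8.942e-04 77.28 21.4256
#> 5 bladder    1752 37.34 34.638 4.299e+00 73.73 16.3962
unlist(rep$conformity$boost)
#>       ci1       ci2        ci
#> 0.9933481 0.1659259 0.1648222
rep$ntid
#> [1] 58.71434   # litre Gy over body-minus-PTV
```

All nine Quantec constraints now pass with boost coverage
`CI1 = 0.993`. Finally the plan is made deliverable:

```r
del <- deliverability_delta(plan)   # stratify to 7 levels, sweep-sequence
del$counts$total                    # 88 segments over 9 beams
del$max_dose_delta                  # 1.82 Gy worst-voxel change after sequencing
```

`deliverability_delta` verifies that the segment apertures reconstruct
the stratified fluence exactly and that every per-voxel dose change is
within the half-level-step perturbation bound.

A YAML-configured pipeline (`run_study()`, or the `inst/cli/idsplan`
Rscript with stages `phantom|dij|init|shape|metrics|sequence|report|study`)
chains all of the above and writes NRRD masks, CSV fluence/DVH tables,
JSON segment and metrics reports, and a reproducibility manifest.

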