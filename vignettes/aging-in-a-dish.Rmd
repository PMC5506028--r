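---
title: "Interdependent cell failure in engineered tissues: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interdependent cell failure in engineered tissues: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Simple organisms die at a near-constant rate; complex organisms show a
mortality rate that rises with age. One mechanistic reading is that complex
systems are *interdependence networks*: components rely on one another, so a
local failure degrades the support of its neighbors and failures cascade.
`tissuefail` implements a complete in-silico version of the "aging in a
dish" programme that tests this picture in engineered tissues: primary
fibroblasts are fixed in a non-degradable hydrogel slab (5 µL, 100 µm thick)
at 1e3 ("1 K"), 1e4 ("10 K") or 1e5 ("100 K") cells per construct, so the
encapsulation density sets the cell-cell distance and hence how strongly
cells can exchange survival-promoting ("cooperative") secreted factors. Dead
cells are stained and counted daily until at least 98% of the population is
dead; the day this is reached is the construct's *lifetime*.

The null hypothesis is non-interacting cells: per-capita mortality
`m = -(Δn/n)(1/Δt)` constant, population `n(t) = n0 exp(-m t)`. Interacting
populations should deviate: as functional cells thin out, survivors lose
support and die faster, so `m` rises as `n` falls (a *decreasing* `m(n)` —
cooperativity), and the population collapses in a terminal cascade.

## The simulator

Each cell is an agent at a fixed uniform-random position in the slab. Cells
within the interaction radius `lambda_int` are graph neighbors. One step of
`step_day()` applies, in order:

1. **Intrinsic failure.** A functional cell dies with probability
   `1 - (1 - d*sigma)^(exp(-beta*s_i)*dt)`, where the support
   `s_i = c_i (f_i + w_global * G)` combines the functional fraction `f_i`
   of its neighbors and the shared-medium factor level `G`, both gated by
   the cell's reception competence `c_i`. With `beta = 0` this reduces
   exactly to a Bernoulli(d·sigma) death per day.
2. **Threshold cascade.** Synchronously and repeatedly until a fixed point:
   every functional cell with at least one neighbor whose
   functional-neighbor fraction is below `theta` fails. Synchronous sweeps
   make the fixed point independent of update order.
3. **Repair.** Failed cells revive with probability `r*dt`. The default is
   `r = 0`: the hydrogel is non-degradable, cells neither divide nor
   migrate, and death is permanent.
4. **Medium update.** `G <- G (1-delta)^dt + dt * sum(p_i)/n_ref` over
   functional cells, `p_i` the production competence. The influx is
   normalized by a *reference* cell number (`n_ref = 1e5`, the dense
   construct) rather than each construct's own count: the factor
   concentration a tissue builds in its (fixed-volume) media scales with
   how many cells secrete into it, which is precisely why density controls
   the degree of secreted-factor communication and why only dense-tissue
   conditioned media is potent. At `dt = 1` and `n_ref = n_cells` this
   reduces to the plain per-capita update.

Boundary effects are physical: cells near the slab faces simply have fewer
neighbors; there is no periodic wrapping. Every run derives all its random
streams (placement, senescence assignment, deaths, imaging noise) from one
integer seed at fixed offsets, so trajectories are bit-reproducible.

### Media handling in experiments

All lifetime experiments in the emulated protocol wash the constructs and
replace their media every 24 h. Scenario pipelines therefore reset `G` at
every daily boundary — to 0 for fresh media, or to the donor's harvested
level in conditioned-media arms. The bare simulator (`simulate_tissue()`
without `media_in`) keeps the closed-system dynamics for theory work.
Donors are conditioned for 2 days before the first transfer; that first
batch carries the decay-weighted accumulation of both conditioning days
(the donors are not washed during conditioning), later batches are the
donor's 24 h production.

### Aging and the two hypotheses

Pre-aging is encoded in the competences, not in new mechanisms. Two
hypotheses are switchable:

- **Reception loss** (default): aged cells still produce cooperative
  factors (`p = 1`) but cannot receive or process them (`c` small). Because
  `c` multiplies both the local and the medium term, reception-deficient
  cells are simultaneously blind to neighbors and to transferred media.
- **Production loss**: aged cells receive normally (`c = 1`) but produce
  little (`p` small).

A pre-aged population is drawn as a mixture with a senescent fraction of
0.7 (the staining-based estimate is "more than half") versus 0.005 for
young cells. By default both the senescent and the remaining pre-aged cells
carry the same deficit (0.02): senescence staining marks the extreme cells,
but DNA-damage and p21 measurements show the whole pre-aged population is
affected, so the deficit is modelled population-wide. The two knobs
(`severe`, `partial`) remain separate for exploration. Whether pre-aging
should additionally raise the intrinsic rate `d` is not decidable from the
data this emulates; the default `aged_d_factor = 1` attributes aging
entirely to competence loss, which is also what makes the young/pre-aged
lifetime difference vanish in sparse tissues, where competence has nothing
to act on.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `d` | 0.45 | /day | sets sparse-tissue lifetimes at ~6 days and keeps `d*sigma <= 1` under stress |
| `r` | 0 | /day | non-degradable gel, no recovery |
| `sigma` (stress) | 2 | – | oxidative stress (0.2 mM H2O2) as a hazard doubling |
| `lambda_int` | 35 | µm | ~paracrine range; mean degree ≈ 3.6 at 100 K, ≈ 0.04 at 1 K, so dense tissues percolate and sparse ones are essentially isolated |
| `theta` | 0.02 | – | cascades only finish off nearly-unsupported neighborhoods, giving the sharp terminal collapse without erasing the density ordering |
| `beta` | 2 | – | hazard reduction ≈ 7x for a fully supported cell; separates dense young (~15 d) from dense pre-aged (~6 d) |
| `w_global` | 2.5 | – | makes 100 K-conditioned media potent for competent recipients |
| `delta` | 0.1 | /day | long-lived secreted factor |
| `n_ref` | 1e5 | cells | medium normalization (above) |
| `dt` | 1 (1/12 for 1 K) | day | matches the staining cadence; 1 K tissues are stained sub-daily on day 1 |

These constants are not printed anywhere in the emulated study; they were
calibrated once, against the *orderings and trend labels* the study reports
(dense young outlive dense pre-aged; the difference vanishes when sparse;
m(n) cooperative when dense, near-constant when sparse; conditioned-media
rescue pattern), never against absolute day counts. Absolute lifetimes are
therefore model outputs, not targets: the defaults give ~15 days for young
100 K versus ~25 in the emulated study, with the orderings preserved. One
known cost of keeping the media predicates clean with a small uniform
deficit is that pre-aged 100 K tissues do not outlive young 1 K tissues
under the defaults, whereas the study reports dense tissues outliving
sparse ones regardless of age.

## The measurement emulator

The emulator reproduces the counting protocol, not pixels. Per staining
time it takes `n_stacks = 3` z-stacks at seeded random disjoint positions,
each covering `1/8` of the gel footprint and split into 10 equal optical
slices. Dense tissues are counted on the 3 central slices of each stack
(9 images per tissue); sparse 1 K tissues on the per-stack maximum
projections. Each newly dead cell in a field is detected with probability
`detection_gain` (default 1) with optional Poisson jitter. The emulator
reports *deaths since the previous staining*; whether re-stained dead cells
were double-counted in the real protocol is not stated, and the pipeline's
subtraction arithmetic is matched instead of resolving the biology.

A note on the field-of-view convention: the counting arithmetic multiplies
per-image averages by the number of slices and by 8, which is consistent
only if each stack covers 1/8 of the gel; the emulator adopts that reading
(3 stacks sample 3/8 in total).

## The counting pipeline

Per staining time: average the 9 middle-slice counts (or the 3
projections), normalize with an affine calibration curve (identity by
default; the real curve is unpublished), and scale by the slice count and
the inverse FOV fraction. Live bookkeeping starts at the theoretical seeded
number and subtracts each estimate cumulatively, clamped at zero (live
percentages cannot be negative). The lifetime is the first recorded time at
which at most 2% remain; series that never reach 2% are right-censored at
the last observed day. Because scenario simulations stop at the 2%
ground-truth rule, a censored measured lifetime sits at approximately the
true lifetime, making the convention nearly unbiased; censored values enter
group means at that day.

The middle-slice estimator assumes uniform dead density across slices —
a documented bias source near the slab faces, and the reason the sparse
protocol switches to projections.

## Mortality analysis

`mortality_rate()` is the discrete estimator `-(Δn/n)(1/Δt)`;
`fit_null()` fits `log n` on `t` by OLS; `probability_of_death()` is
`m·Δt`, identically `1 - n(t+Δ)/n(t)`; `normalize_time()` interpolates a
rate curve onto a fixed 21-point `t/T` grid. `classify_m_vs_n()` regresses
`m` on `n/n0` (normalizing by the seeded number so slopes are comparable
across densities) and labels the trend by a 1000-resample bootstrap CI of
the slope at `alpha = 0.05`: entirely negative = cooperative, entirely
positive = competitive, else non-interacting.

Pipelines classify on an *analysis window*: the measured series truncated
at the recorded lifetime (staining stops there in the protocol) and
intervals starting at >= 20% of the seeded population. The per-interval
dead estimates are unbiased, but their errors accumulate in the live-count
bookkeeping (about ±4% of the seeded number under the sparse 3×(1/8)
protocol) and are perfectly autocorrelated within a replicate: once the
measured count is within a couple of standard deviations of that error
scale, the per-capita rate `est/n_est` drifts systematically up or down
for the rest of the series. Restricting the rate regression to the first
80% of deaths keeps it on counts the bookkeeping can actually support,
while the dense-tissue acceleration — which develops well above the
floor — is untouched.

Group comparisons use the classical pooled two-sided Student's t-test with
significance at p < 0.05 and results reported as mean ± SD, matching the
emulated study's statistical conventions (n = 3 replicate constructs per
experiment, experiments repeated). Pairwise tests are reported raw, without
multiplicity correction, as in the study.

### The conditioned-media verdict

`evaluate_hypotheses()` applies four predicates to paired-seed media
experiments: pre-aged dense tissues are not rescued by young conditioned
media; pre-aged sparse tissues are not rescued; young sparse tissues are
rescued by young conditioned media; and by pre-aged conditioned media.
"Rescued" is defined as a paired lifetime increase that is both significant
(two-sided paired t-test, 0.05) and at least 10% in relative terms — an
effect-size guard so that a marginal but consistent shift does not count as
a rescue, mirroring population curves that "follow almost the same
profile". Under the defaults the reception-loss setting satisfies all four
predicates and the production-loss setting violates the first, second and
fourth, so the package reproduces the discrimination in favour of reception
loss.

## Distance analysis

`estimated_spacing()` is the cube root of the volume per cell, reported
both raw and rounded to the nearest 5 µm (ties up), the convention that
gives 170/80/35 µm for 1 K/10 K/100 K in 5 µL. `per_plane_nn()` measures
2-D nearest-neighbor distances within z-slices, as distances are measured
plane-by-plane in the imaging; `sample_imaging_points()` restricts the
measurement to a few seeded fields of view, which carries a small (a few
percent) upward edge bias because neighbors outside a field are invisible. The
measured per-plane means are treated as qualitative anchors only (their
ordering 1 K > 10 K > 100 K is asserted); the sparse-tissue measured mean
reported in the study is not reproducible from the stated geometry under
any plausible slice thickness, so no quantitative match is attempted.

## What the synthetic data does and does not show

The generator emulates: construct geometry and uniform placement, the
density series, competence-mixture aging, oxidative stress as a hazard
multiplier, daily media changes and conditioned-media transfer, the z-stack
counting protocol with its stereological scaling, and the n = 3 replicate
structure. It does not emulate: reaction–diffusion of factors, migration or
division, mechanics, optical artifacts, or pixel-level images. Passing
tests therefore show that the *pipeline and analysis* recover the designed
interdependence signatures from protocol-faithful synthetic measurements —
not that real tissues obey this particular hazard form.

Problem sizes in the test-suite: full 1e5-cell constructs for the density
and media experiments (20 repeated n = 3 experiments for the majority
votes; 8 paired replicates per media arm), 1e4 cells for estimator
calibration checks, and small same-density constructs (0.05 µL, 2000
cells) where only the interaction structure matters.

## Known limitations

- The cooperation functional form (support, hazard exponent, cascade
  threshold) is a reconstruction; the study constrains its qualitative
  behaviour, not its constants.
- Pre-aged dense tissues do not outlive young sparse ones under the
  defaults (see calibration note above).
- The repair pathway (`r > 0`) is provided for theory exploration but the
  cascade fixed-point guarantee is only asserted for `r = 0`.
- Measured per-plane distances are compared qualitatively only.
- With `aged_d_factor = 1`, sparse pre-aged tissues die at the same rate as
  sparse young ones; the study's sparse arms are themselves ambiguous on
  this point (one figure reports earlier sparse aged death, another reports
  no difference), and the no-difference reading is followed.
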