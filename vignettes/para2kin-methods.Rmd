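---
title: "Modelling the ParA2 ATPase cycle: kinetic scheme, synthetic assays and the tug-of-war cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ParA2 ATPase cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(para2kin)
```

## The system and the model

ParA2 is the Walker-type partition ATPase that positions and segregates
chromosome 2 of *Vibrio cholerae*. In live cells it forms an asymmetric
gradient on the nucleoid that oscillates pole to pole with periods of a few
minutes. The kinetic engine behind that behaviour is a nucleotide cycle:

1. ParA2 is a constitutive dimer (`D`). It binds two ATP in a single
   kinetic step to form a closed sandwich dimer (`DT`; constants `k1`,
   `k_minus1`).
2. The closed dimer remodels slowly to an open, DNA-binding-competent state
   `D*`-ATP (`DS`; constant `k2`). DNA catalyses this switch
   (`k2_dna_factor`). This step is rate-limiting for nucleoid rebinding.
3. The active dimer loads cooperatively onto nonspecific DNA
   (`k3`, `k_minus3`), building higher-order oligomers; cooperativity is a
   mean-field factor `coop_omega` on the loading rate.
4. ATP hydrolysis — stimulated by DNA, ParB2, or both
   (`stim_dna`, `stim_parb`, `stim_both`) — releases the ADP-bound dimer
   from DNA.
5. ADP dissociates (`k5`, `k_minus5`) and the dimer re-enters the cycle;
   loaded dimers can also swap nucleotide directly at slow effective
   exchange constants (`k6_*`), the secondary brake on DNA rebinding.

Every assay in the package is a window on some subset of these constants,
and every fitting operation is the analysis that is conventionally applied
to that assay. The package is organised as simulate-then-fit: the
generators produce synthetic data with a known ground truth, and the
inference layer must recover it by the standard procedures — which is both
a test harness for the analysis pipeline and an honest statement of what
each assay can and cannot identify.

## Concentration conventions

The model tracks **dimers**; all user-facing protein concentrations are
monomer-based (as they are conventionally printed, e.g. "1.25 uM ParA2")
and halved internally. Nucleotides load two-per-dimer in one kinetic step
(no half-loaded intermediate), first order in the free nucleotide but with
a stoichiometric coefficient of two, so free pools stay in nucleotide
units. Nonspecific DNA is a pool of independent 30 bp sites (one active
dimer footprint; `dna_sites_uM()` converts mg/ml to site concentration).
DNA-binding affinities are reported in nM, nucleotide affinities in uM.

## Default rate constants

The defaults in `rate_set()` are elementary constants calibrated once so
that the observed rate of each assay emerges at the concentration at which
that assay is performed (figure-level rates are observed, not elementary,
quantities — they depend on the stated concentrations):

| constant | default | emerges as |
|---|---|---|
| `k1`, `k_minus1` | 0.0035 /uM/s, 0.028 /s | MANT-ATP kobs 0.09–0.13 /s at 25 uM; KD 8 uM |
| `k2` (+`k_hyd`) | 0.016 /s (+0.0018 /s) | tryptophan-switch kobs 0.015–0.018 /s |
| `k2_dna_factor` | 3 | +DNA switch kobs 0.03–0.07 /s |
| `k3` | 0.1 /uM/s | carpet association 0.05 /s at 1 uM protein |
| `k4`, `k_minus3` | 0.04 /s, 0.02 /s | carpet wash 0.1 /s (ATP), 0.02 /s (ATPgS) |
| `k5`, `k_minus5` | as ATP | MANT-ADP KD 8 uM |
| `k6_adp_to_atp` etc. | 6.5e-4, 6.1e-4, 1.4e-3 /uM/s | exchange kobs slopes |
| `kcat` | 0.008 ATP/dimer/s | weak basal ATPase, 2/3/8-fold stimulated |

Two deliberate scale separations deserve emphasis, because the measured
data demand them:

**Bulk versus carpet release.** The flow-cell wash rate (0.1 /s) cannot be
the DNA-release rate of the bulk assays: with that release rate the
DNA-bound occupancy in a cuvette would cap near 35% and the
conformational-switch signal with DNA could never reach its quasi-stable
>2-fold plateau. The well-mixed scheme therefore releases DNA-bound dimers
at the bulk hydrolysis scale (`k_hyd` times the condition's stimulation
factor), while `k4` — the fast hydrolysis-stimulated release seen under
flow — drives the carpet wash model and the in-cell lattice. The 2/3/8-fold
stimulation structure is identical in both.

**Turnover coarse-graining for the ATPase assay.** Fold-stimulations of
hydrolysis are measured as ratios of percent ATP hydrolysed at equal time.
In a full cycle whose rate-limiting step is remodeling, stimulating the
hydrolysis step alone compresses those ratios toward ~2. The radiolabel
ATPase generator therefore works at the turnover level:
`d[ADP]/dt = kcat * stim * [dimer] * S/(KM + S)` with finite substrate
(KM = 20 uM, a declared assumption), which reproduces the printed ratios in
the linear regime and the saturation of the fixed-time titration by
substrate depletion.

One incompatibility is acknowledged rather than hidden: the slow phase of
the MANT-ATP chase (0.015–0.02 /s, attributed to hydrolysis-coupled
release) cannot coexist with the tryptophan-switch relaxation
(0.015–0.018 /s) in a single scheme — any exit from the remodeled state
fast enough to give the chase slow phase adds to the observed switch rate
(kobs ~ k2 + exit) and pushes it out of range. The defaults keep the
switch in range; the chase is then biphasic with a fast phase at
`k_minus1 + k2` and a much slower retained pool, and the tests assert that
actual structure.

## Synthetic assays: what is emulated, what is not

Each generator reproduces the *statistical shape* a real instrument would
yield — kinetic form, sampling grid, and iid Gaussian noise whose sigma
defaults to a fraction of the dynamic range (0.02 unless stated; real
instrument noise magnitudes are not published, so this is a declared
assumption). Fraction-type outputs are truncated to [0, 1] with the number
of clipped points counted on the trace. What is **not** emulated: gel
images (EMSA yields the quantified fraction-bound table), TIRF images
(time series only), photon statistics, instrument dead time, baseline
drifts other than the declared linear photobleach in the
tryptophan-control conditions (-0.02%/s), and any correlated noise.
Passing round-trip tests therefore show that the *analysis pipeline* is
unbiased on data generated by the stated model at instrument-like noise —
not that the model is the true data-generating process of the instruments.

Protocol details worth knowing:

* **Stopped-flow grids** are split-timebase: 10 ms steps to 30 s, then
  100 ms steps (binding traces default to the 30 s the real curves take to
  plateau).
* **The chase** (dissociation protocol) zeroes the effective exchange
  reactions: 1 mM unlabelled nucleotide makes label release irreversible by
  competition, and the effective second-order exchange constants are
  measured-range constructs that must not be extrapolated to millimolar
  concentrations.
* **The exchange protocol** starts from fully ADP-loaded dimers and uses
  only the effective swap reactions (release-then-rebind is folded into the
  effective constants, which is how the constants are defined), so the
  fitted kobs-vs-concentration slope is the exchange constant itself.
* **The carpet** is piecewise: association is supply-limited site filling
  at rate `k3 * [active dimer]` (released protein instantly rebinds inside
  a dense carpet while sample flows — which is also why the association
  rate can be slower than the wash rate, impossible for simple reversible
  binding); the wash decays biphasically (fast
  `k4*stim_dna + k_minus3`, slow protected fraction at `k_minus3`). The
  ATP-start condition feeds the carpet through the remodeling delay with a
  squared supply term (the 69 bp loading unit carries two dimers), which
  holds the signal below half its plateau for the first minute.
* **FRAP** and **EMSA** are generated directly from the double-exponential
  and Hill models — they are parameter-level assays whose published values
  are fit parameters, not cycle constants. The ADP-condition Hill
  coefficient (n = 2) and the ParB2-FRAP mobile fractions are synthetic
  defaults (not published values); the corresponding time constants and
  affinities are the published ones.

## Fitting: numerical choices

All nonlinear fits use Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with 5 log-spaced multi-starts on the rate
parameters, SSE tolerance 1e-12, ties broken by lowest SSE. Specifics:

* *Lag exclusion* (`exclude_lag`): the fit window starts where the
  smoothed derivative first exceeds 20% of its maximum; the window is
  always reported in the result.
* *Flat traces*: an amplitude below 3 sigma-hat (sigma-hat from first
  differences) is reported as non-converged with a "flat trace" flag
  rather than a spurious rate.
* *Model selection* single- vs two-phase decay: corrected AIC with a
  threshold of 2; a collapse to single-phase is flagged, never silent.
* *Hill fits*: the cooperativity coefficient is only identifiable when the
  titration reaches 80% of the plateau (otherwise n is fixed to 1 and
  flagged, which makes the fit exactly the hyperbolic one); a fitted
  plateau above the physical bound of 1 is fixed to the maximum observed
  fraction and flagged.
* *Pseudo-first-order lines*: a negative intercept reports koff = 0 with a
  KD-undefined flag.
* All fitters are equivariant under uniform y-scaling (rates and time
  constants unchanged, amplitudes scale).

`recover_cycle()` is the consolidation step: it runs exactly the staged
per-assay analysis above and then refines the two parameters that are only
observed through the full cycle (`k2`, `k2_dna_factor`) — and the binding
constants, whose raw pseudo-first-order line is biased by remodeling
sequestration — by matching forward-simulated observed rates to the fitted
ones (secant iteration on the generator). Parameters without a covering
assay are flagged unidentifiable and left at reference values, never
silently pinned. At zero noise the identifiable set comes back within
0.4%; at 2% noise the remodeling rate is recovered with under 10% median
bias across seeds.

## The tug-of-war cell

The spatial module realizes the proposed oscillation mechanism as a 1D
reaction–diffusion system on a lattice spanning the cell (reflecting
boundaries; the nucleoid occupies the whole length). Per site, the five
cycle states are present; the four cytoplasmic states diffuse
(`d_cyto` = 3 um^2/s, a declared assumption for cytoplasmic protein), the
bound state is immobile. The measured kinetic delays enter directly: ATP
binding at 1 mM cytoplasmic ATP, the 60 s remodeling delay (`k2`), slow
nucleotide exchange, and bulk-scale DNA release away from the partition
complex. The ParB2–parS2 focus is a window that multiplies the local
hydrolysis-release rate (`focus_stim`).

Nearest-neighbour cooperativity on the lattice is a *pair* recruitment
factor, `1 + (omega - 1) * f_nb^2`, with `f_nb` the occupancy of the three
local footprints: loading requires two-dimer units, so recruitment scales
with the probability that flanking footprints are occupied. The square
matters. A factor linear in occupancy has recruitment elasticity below 1
and provably cannot destabilize the uniform coating, no matter how large
omega; the pair form crosses elasticity 1 at moderate occupancy and
produces the winner-take-all polar gradients seen in cells.

Exploring this model produced three findings, each reproduced by the test
suite and `analysis/05_spatial_tugofwar.R`:

1. **A fixed midcell focus does not oscillate in mean field.** With the
   focus static, the deterministic system settles into a stable
   configuration — a symmetric double gradient with a midcell hole, or,
   when protein is scarce relative to nucleoid capacity, a static
   winner-take-all polar gradient. The measured in-vitro rates alone,
   with a stationary sink, are not sufficient for pole-to-pole
   oscillation.
2. **The tug itself is the missing ingredient.** Giving the focus the
   diffusion-ratchet response — drifting up the *locally sensed* bound-ParA2
   gradient (`focus_mode = "tracking"`, speed `focus_speed`, Gaussian
   sensing kernel of 0.15 cell lengths) — closes the loop: the focus
   chases the retreating wave edge to one pole, consumes it, the depleted
   zone behind it recovers only slowly (nucleation-limited cooperative
   rebinding), the opposite half wins the competition for recycled
   protein after the remodeling delay, and the focus turns. The shipped
   `preset("spatial", "tugofwar-demo")` configuration (2 um cell, 600
   dimers, focus stimulation 40, tracking at 0.01 um/s) oscillates with a
   period of ~370 s — inside the 4–6 min range observed in cells — with
   the asymmetry index alternating sign each half-period. Pole-to-pole
   transits of the simulated wave (~150 s) are slower than the 30–60 s
   seen in vivo; the model makes no claim to reproduce that number.
3. **Knockout behaves correctly.** Setting the focus stimulation to 1
   (no ParB2 effect) abolishes the oscillation, and the oscillation
   statistic is monotone non-decreasing along a stimulation scan.

The demo regime was located by a coarse scan of omega, copy number,
capacity and focus parameters and frozen; the scan grid is in the analysis
scripts. The stochastic engine (exact SSA, in C++) reproduces the same
physics with intrinsic noise and conserves copy number exactly; because
hop events at 3 um^2/s dominate its cost, long stochastic runs are
practical at reduced diffusion, and the mean-field engine is the default
for oscillation-scale spans. The PDE/SSA consistency check runs both
engines in a linear regime and compares ensemble means within 3 SE.

## Problem sizes

The shipped configurations are sized for a laptop-class single core: ODE
traces of 2,000–8,000 points, SSA ensembles of 200 runs at 1,000 copies,
a 50-site lattice over 1,800 s for the oscillation demonstration, and
multi-assay recoveries over 11 traces. All tolerances quoted above are
asserted by the test suite at exactly these sizes.

## Known limitations

* The cycle has no explicit filament state: cooperativity is mean-field
  (bulk) or nearest-neighbour-pair (lattice), with no length-dependent
  kinetics.
* The EMSA generator produces fraction-bound tables, not gel mobility
  physics; competitor-DNA chase experiments are not modelled beyond the
  qualitative release pathways.
* The tug is scripted (a gradient-following focus), not mechanically
  derived from ParA2–ParB2 bond forces; force generation is outside the
  model's scope.
* The spatial model is 1D with a full-length nucleoid; polar excluded
  volume, chromosome mechanics, replication, and coupling to the
  chromosome 1 cycle are not represented.
* Published values that were only available as figure-level observations
  were calibrated into elementary defaults once (table above) and are not
  refit anywhere.
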