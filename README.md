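# para2kin

Kinetic simulation and inference for the ATPase cycle of ParA2, the
Walker-type partition ATPase that segregates chromosome 2 of *Vibrio
cholerae*.

ParA2 dimers bind ATP (k1, k-1), remodel slowly to a DNA-binding-competent
open state D\*-ATP (k2, accelerated by DNA), load cooperatively onto
nonspecific nucleoid DNA (k3, k-3, cooperativity omega), and are released
by cofactor-stimulated ATP hydrolysis (k4; 2-fold by DNA, 3-fold by ParB2,
8-fold by both), after which slow ADP release and nucleotide exchange
(k5/k-5, k6) delay re-entry into the cycle. That remodeling-plus-exchange
delay is the timing element behind the pole-to-pole ParA2 oscillations that
position the chromosome 2 partition complex in cells.

The package provides, as one simulate-then-fit toolkit:

* **Cycle engines** — the mass-action reaction scheme for any assay
  condition (`assemble_scheme()`), a stiff ODE integrator
  (`integrate_scheme()`) and an exact Gillespie simulator (`sample_ssa()`),
  with conservation-checked trajectories and linear observables.
* **Synthetic assay generators** — stopped-flow MANT-nucleotide binding /
  dissociation / exchange, tryptophan conformational-switch kinetics, EMSA
  titrations, DNA-carpet TIRF time courses with a flow switch, FRAP
  recovery, radiolabel ATPase time courses, and CD thermal melts
  (`gen_*()`), each with configurable Gaussian noise and seeds, plus
  shipped presets for wild-type and the Walker-A K124 variants
  (`preset()`).
* **The matching fitting procedures** — single-exponential (with lag
  exclusion), two-phase decay with AICc collapse, pseudo-first-order
  kon/koff lines, cooperative Hill and hyperbolic binding isotherms,
  double-exponential FRAP, Boltzmann melts (`fit_*()`), and a staged global
  cycle recovery with identifiability flags (`recover_cycle()`).
* **A 1D tug-of-war cell** — a reaction-diffusion lattice model of ParA2
  cycling between cytoplasm and nucleoid with a ParB2-parS2 focus as a
  localized hydrolysis sink (`spatial_config()`, `simulate_cell()`), with
  exact-stochastic and mean-field engines and kymograph metrics
  (`measure_period()`, `measure_transit()`, `asymmetry_index()`). The
  shipped demo configuration oscillates pole-to-pole with a ~6 min period.

## Worked example

Generate a noisy EMSA titration from the wild-type + ATP DNA-binding
parameters (KD = 46 nM, Hill n = 4) and recover them with the cooperative
Hill fit:

```r
library(para2kin)
emsa <- gen_emsa(preset("emsa", "wt-atp"), noise_sigma = 0.02, seed = 7)
fit_hill(emsa)
#> para_fit [hill]
#>   kd             46.4156 +/- 1.27
#>   n              4.14665 +/- 0.411
#>   plateau        0.989179 +/- 0.0123
#>   RSS = 0.00286332, n = 8
```

The fitted `kd` is the dissociation constant in nM (46.4 vs the 46 used to
generate), `n` the Hill cooperativity (4.15 vs 4: two ParA2 dimers per
69 bp probe bind cooperatively), and `plateau` the saturating bound
fraction. At zero noise the recovery is exact.

A cycle-level example — stopped-flow MANT-ATP binding at 25 uM simulated
from the full scheme, fitted as in a pseudo-first-order analysis:

```r
tr <- gen_mant_kinetics(rate_set(), "binding", parA2_uM = 1.25, mant_uM = 25)
fit_single_exponential(tr, "rise")
#> para_fit [single_exponential]
#>   kobs           0.10532 +/- 7.14e-05
#>   ...
```

`kobs` = 0.105 /s sits where the pseudo-first-order relation
`k1*[MANT-ATP] + k_minus1` puts it for the default constants
(0.0035 x 25 + 0.028 = 0.116 /s, minus the small sequestration bias that
`recover_cycle()` corrects when estimating the constants themselves).

## Analysis workflow

The `analysis/` directory is a numbered narrative over the package:

| script | what it does |
|---|---|
| `01_simulate_cycle.R` | integrates the cycle under the main assay conditions; conservation and occupancy summary |
| `02_generate_assays.R` | writes the full 40-trace synthetic assay panel (CSV + JSON sidecars) |
| `03_fit_assays.R` | fits every trace with its matching procedure; fitted-vs-truth table |
| `04_recover_cycle.R` | staged global recovery of the rate set, noiseless and at 2% noise |
| `05_spatial_tugofwar.R` | runs the tug-of-war cell, measures period/transit/asymmetry, knockout control |

Each writes its tables under `results/`. Run them in order from the
repository root with `Rscript`.

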