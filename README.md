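# gaplearn

Active learning of sparse Gaussian-process interatomic potentials, with a
prospective stability metric.

## The problem

Machine-learned force fields promise reference-level accuracy at classical
cost, but condensed-phase models have typically needed thousands of
expensive reference ("ground truth") calculations, and a small held-out
error says little about whether the model survives molecular dynamics.
gaplearn implements a training strategy that needs only hundreds of
reference evaluations and a validation metric that measures exactly what
practitioners care about: how long model-driven MD stays faithful to the
reference surface.

Three ideas do the work:

* **Intra+inter decomposition (I+I).** Covalent and non-bonded
  interactions live on different energy and length scales. Each molecule
  type gets its own intramolecular model (fitted on a dense grid over the
  monomer's internal coordinates, or by elevated-temperature active
  learning), evaluated with all molecules rigidly separated in an expanded
  box; an intermolecular model is trained on subtraction labels
  `E_inter = E_total − E_intra` and the composite prediction is their sum.
* **Episode-scheduled active learning.** From a starting structure, the
  current model runs its own MD for `n³ + 2` fs; the final frame is
  accepted into the training set if its energy error `|E₀ − E_model|`
  exceeds a threshold (or, alternatively, if the GP's own predictive
  variance does), the model is refitted and `n` resets; otherwise `n`
  grows, so exploration lengthens cubically as the model stabilises.
* **The prospective metric τ_acc.** Along a model-driven trajectory the
  reference is evaluated every few fs as an observer; errors above a floor
  `E_l` accumulate, and τ_acc is the time at which the cumulative error
  exceeds `E_T` (default `10 E_l`). A single catastrophic frame fires the
  clock; a model that never fires is right-censored at the horizon.

The potentials are sparse GP regressions on many-body atomic-environment
descriptors — species-resolved two-body, symmetrised three-body, and a
SOAP-style power spectrum with a `ζ`-exponentiated normalised dot-product
kernel — fitted jointly to energies and forces. Everything runs against
cheap analytic surrogate ground truths shipped in the package (a separable
flexible water model and a two-state EVB reactive surface), so the entire
workflow is reproducible in minutes with no electronic-structure code.

## A worked example

Train a reactive potential on the EVB identity-exchange surface by
transition-state-initialised active learning, then compare its barrier with
the surrogate's:

```r
library(gaplearn)

truth <- evb_truth()                      # two-state EVB surrogate
res   <- train_evb_gap(truth, seed = 7)   # TS-initialised AL + NEB refinement
res$history
#> <al_history> strategy=diff, 147 episodes, 28 additions, 150 truth evals [unconverged]

ts    <- evb_ts_configuration(truth)
wells <- evb_well_configurations(truth)
predict_energy(res$model, ts) - predict_energy(res$model, wells$reactant)
#> [1] 0.2657
gt_evaluate(truth, ts)$energy - gt_evaluate(truth, wells$reactant)$energy
#> [1] 0.2688
```

From 150 reference evaluations the model reproduces the exchange barrier to
about 3 meV (<0.1 kcal/mol); climbing-image NEB against the surrogate itself
recovers the dense-scan barrier (0.2594 eV along the relaxed path) to
numerical precision. The same workflow for bulk water —
`train_water_composite()` — fits the monomer grid intra model, runs
intermolecular active learning on a periodic box, and returns a
`composite_potential` whose τ_acc can be measured with
`evaluate_tau_acc()`.

A declarative command-line interface wraps the same pipelines
(`inst/scripts/gaplearn-cli.R` with `train`, `tau-acc`, `md`, `rdf`, `neb`
subcommands driven by a YAML configuration).

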