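# hostfit

Force-field evaluation and force-matching refitting for macrocyclic host
molecules, in R.

Ring-shaped hosts (cucurbiturils, pillararenes, cyclodextrins, octa
acids) bind guest molecules in their central cavity, and the quality of
that modeling hinges on how well a transferable force field (a GAFF-style
parameter database) describes the *host's own* flexibility: whether the
cavity stays open, squashes shut, or interconverts between states. This
package provides the desk-scale machinery to study exactly that question:

* **MM engine** — AMBER-style intramolecular energies and analytic forces
  (harmonic bonds/angles, periodic torsions, 12-6 LJ + Coulomb with 1-4
  scaling, gas phase, no cutoffs), with term-by-term parameter-set
  diffing (`diff_parameter_sets`) in the altered / eliminated / newly
  defined taxonomy.
* **RESP charges** — Merz-Kollman-style ESP grids, restrained charge
  fitting with the hyperbolic penalty, and the ESP RRMSE quality metric.
* **Sampling** — Metropolis Monte Carlo gas-phase configurational
  sampling at a stated temperature (the stand-in for MD sampling in the
  refit protocol).
* **Force-matching refit** — the regularized least-squares refit of
  bonded parameters against a reference Hamiltonian,

  `L = w_E Σ (ΔE − offset)² + w_F Σ ‖ΔF‖²_F + λ‖(θ−θ0)/s‖²`,

  with adaptive data accumulation: 500 configurations per iteration at
  600 K, 18 iterations (9000 configurations), testing at 300 K under the
  final parameters.
* **Evaluation & dynamics** — offset-profiled energy RMSE/MAE, per-atom
  force-error heatmap matrices, per-repeating-unit error decomposition,
  Kabsch superposition, radius-of-gyration time series and open/squashed
  state classification.
* **Synthetic data** — toy n-unit macrocycles with a ground-truth
  parameter set acting as the reference oracle and calibrated
  "transferable-like" perturbed starting sets, so the entire workflow
  runs with no external data.

## Worked example

```r
library(hostfit)
ring  <- build_ring(ring_spec(n_units = 7, seed = 1))     # 42-atom toy host
truth <- ground_truth_params(ring$topology, seed = 3)     # reference Hamiltonian
conf0 <- minimize_energy(ring$topology, truth, ring$conf)$conf
start <- perturb_params(truth, perturb_spec(seed = 11))   # "transferable-like" start

diff_parameter_sets(truth, start)
#> bond     identical   0 | changed   6 | only in A   0 | only in B   0
#> angle    identical   0 | changed   9 | only in A   0 | only in B   0
#> torsion  identical   0 | changed  11 | only in A   1 | only in B   0
#> vdw      identical   6 | changed   0 | only in A   0 | only in B   0

fit <- adaptive_refit(ring$topology, start, mm_oracle(ring$topology, truth),
                      conf0, fit_config(n_iterations = 4, batch_size = 125,
                                        seed = 7))
fit
#> hf_fit_result: 4 iterations, final training set 500 configs
#>   test energy RMSE 2.1130 -> 0.0010 kcal/mol | force RMSE 8.1657 -> 0.0016 kcal/mol/A

per_unit_error(fit$test_errors$before[["rmse"]], 7)
#> [1] 0.3019

rg <- radius_of_gyration(metropolis_sample(ring$topology, fit$params_opt,
        conf0, sampler_config(300, 400, stride = 10, seed = 9)))
rg
#> hf_rg_series: 400 frames, Rg 3.611 +/- 0.019 A
```

Reading the output: the perturbed start — whose diff against the truth
shows jittered force constants, one eliminated torsion and altered
phases, the fingerprint of switching transferable force-field
generations — is ~2.1 kcal/mol off the reference on a 300 K test set.
The regularized force-matching refit drives that error to the
millikcal floor (the synthetic oracle shares the functional form, so no
representability gap remains), and the per-unit decomposition divides
the whole-ring error evenly over its 7 repeating units. The Rg series
of the refitted host shows a single tight cavity state; on flexible
multi-state fixtures `classify_states()` reports occupancies per state.

The methods vignette (`vignettes/hostfit-methods.Rmd`) documents the
model, conventions, defaults, and limitations. A thin CLI wrapper
(`inst/exec/hostfit`) exposes validate/diff/sample/refit/evaluate/
dynamics/espfit subcommands over files in the package's plain-text
parameter dialect.

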