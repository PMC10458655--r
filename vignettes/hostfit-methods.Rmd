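---
title: "Force-field evaluation and refitting for macrocyclic hosts: methods"
author: "hostfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field evaluation and refitting for macrocyclic hosts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostfit)
```

## Scope and model

hostfit studies how well a transferable, AMBER-style classical force field
describes a ring-shaped (macrocyclic) host molecule, and how much a
molecule-specific *force-matching* refit of its bonded terms against a
reference Hamiltonian improves it. The potential is the standard
intramolecular fixed-charge form

$$E = \sum_{\text{bonds}} k_b (r - r_0)^2
     + \sum_{\text{angles}} k_\theta (\theta - \theta_0)^2
     + \sum_{\text{torsions}} \sum_n \tfrac{V_n}{2}\,(1 + \cos(n\phi - \gamma_n))
     + \sum_{i<j} \left[ \varepsilon_{ij}\!\left(\Big(\tfrac{r^{min}_{ij}}{r_{ij}}\Big)^{12}
       - 2\Big(\tfrac{r^{min}_{ij}}{r_{ij}}\Big)^{6}\right)
       + \frac{C\, q_i q_j}{r_{ij}} \right]$$

with units fixed throughout as Angstrom, kcal/mol, amu, elementary
charges; angles are degrees in files and radians internally; the Coulomb
constant is $C = 332.0637$ kcal A mol$^{-1}$ e$^{-2}$. Lennard-Jones
parameters combine by Lorentz-Berthelot. 1-2 and 1-3 pairs are excluded;
1-4 pairs are divided by `scee = 1.2` (electrostatics) and `scnb = 2.0`
(vdW), the AMBER convention — the source force fields leave these
untouched without stating values, so the defaults are the conventional
ones. Everything is gas phase: all non-excluded pairs are summed exactly,
with no cutoff, periodicity, or solvent. Improper torsions are not
modeled; the synthetic systems avoid the sp$^2$ centers that would need
them (a documented limitation for importing real chemistries). Torsion
barriers follow the single convention $V_n \ge 0$; a negative printed
amplitude in a foreign file is equivalent to a $180^\circ$ phase shift,
and should be converted on import.

Forces are analytic negative gradients of this energy, implemented in
compiled code along with the per-parameter derivatives the refit needs.
Both are verified against central finite differences in the test suite
(tolerance $10^{-5}$ kcal mol$^{-1}$ A$^{-1}$ at step $10^{-5}$ A).

Atom indices are 1-based everywhere in the R interface, as is idiomatic;
only the compiled internals use 0-based arrays.

## ESP charges

The `esp_*`/`resp_fit` family implements restrained electrostatic-
potential fitting: minimize
$\sum_g (V_{\rm ref}(g) - V_q(g))^2 + a \sum_i (\sqrt{q_i^2 + b^2} - b)$
subject to $\sum_i q_i = Q$ and within-class charge equality, where
$V_q(g) = \sum_i q_i / |g - r_i|$ (potentials kept in e/A; multiply by
332.0637 for kcal/mol/e). The hyperbolic restraint is applied to
non-hydrogen atoms only, the standard convention. It is solved by
iterated reweighted linear KKT solves until $\max |\Delta q| < 10^{-6}$ e.
Defaults $a = 0.0005$ (stage 1), $b = 0.1$; an optional two-stage mode
(off by default) first fits all atoms independently and then refits only
multi-atom equivalence classes (methyl-like groups) at $a = 0.001$ with
the others frozen, mirroring standard two-stage practice for rotationally
equivalent hydrogens. With $a = 0$ the solver reduces to constrained
linear least squares and is checked against an independent
normal-equations oracle to $10^{-8}$ e.

Grids are Merz-Kollman-style: golden-spiral point layouts on shells at
1.4, 1.6, 1.8 and 2.0 times the Bondi radius (H = 1.2 A), about 1
point/A$^2$, points inside any other atom's same-scale surface removed.
The golden spiral plus a seeded per-shell rotation makes grids exactly
reproducible. Charge quality is reported as RRMSE,
$100 \sqrt{\sum (V_{\rm model}-V_{\rm ref})^2 / \sum V_{\rm ref}^2}$ (%).
Since no reference quantum-chemical grids ship with the package, absolute
RRMSE levels of real hosts are out of scope; the synthetic ESP cases
instead probe the machinery, including an off-center point-dipole term
("anisotropy") that an atom-centered model provably cannot absorb — the
lone-pair problem that makes hydroxyl-rich hosts hard to fit.

## Sampling

The refit needs Boltzmann-distributed configurations at a stated
temperature, not dynamics, so the sampler is Metropolis Monte Carlo with
single-atom Gaussian displacement trials: acceptance
$\min(1, e^{-\Delta E / k_B T})$, one sweep = $n_{\rm atoms}$ trials,
$k_B = 1.987204\times10^{-3}$ kcal/mol/K. This avoids integrators,
thermostats and mass-weighting while targeting the same ensemble; the
"sampling interval" of a molecular-dynamics protocol maps to a stride in
sweeps (default 10). Burn-in of $10 \times n_{\rm atoms}$ sweeps is
discarded, during which the trial step is tuned toward ~40% acceptance.
Moves that blow the energy up are simply rejected. The suite checks
equipartition on a harmonic dimer ($\langle E \rangle \to k_BT/2$ within
5% at 50k sweeps), the radial Boltzmann ratio, temperature monotonicity
of the mean energy, and bit-level determinism under a fixed seed.

## Force-matching refit

Only bonded terms move. The loss over a labelled dataset is

$$L(\theta) = w_E \sum_c \big(E_\theta(c) - E_{\rm ref}(c) - \Delta\big)^2
            + w_F \sum_c \lVert F_\theta(c) - F_{\rm ref}(c)\rVert_F^2
            + \lambda \lVert (\theta - \theta_0)/s \rVert^2 .$$

Reference and model energies have incommensurate zeros, so the offset
$\Delta$ is profiled out analytically as the mean energy residual at
every evaluation. Defaults make each block a per-datum mean square:
$w_E = 1/n_{\rm confs}$, $w_F = 1/(3 n_{\rm atoms} n_{\rm confs})$, with
$\lambda = 10^{-3}$ in scaled units. The per-parameter scales $s$ (bond
$k$: 100 kcal/mol/A$^2$; $r_0$: 0.1 A; angle $k$: 50 kcal/mol/rad$^2$;
$\theta_0$: 5 deg; torsion amplitudes: 1 kcal/mol) make $\lambda$
dimensionless across term classes. vdW, charges, 1-4 scalings and
periodicities stay frozen.

Optimization is bounded L-BFGS-B ($k \ge 0$, $V_n \ge 0$, $r_0$ and
$\theta_0$ boxed to physical windows) with analytic gradients. Torsions
are optimized in Fourier coordinates $a_n = (V_n/2)\cos\gamma_n$,
$b_n = (V_n/2)\sin\gamma_n$, in which the torsion energy is *linear*:
this convexifies the torsion block, removes the local minima a flipped
phase otherwise creates at the $V = 0$ boundary, keeps phases fully
continuous, and guarantees $V_n \ge 0$ on the way back. Explicit
zero-barrier components are nudged off the coordinate origin by
$10^{-6}$ kcal/mol so their gradient is defined. The L2 restraint is
applied in these same smooth scaled coordinates. A returned solution
never has higher loss than its starting point.

The adaptive loop accumulates data the way the protocol prescribes: per
iteration, sample 500 configurations at 600 K under the *current*
parameters (continuing from the previous iteration's last frame — the
protocol leaves fresh-vs-continued unstated, and continuing is cheaper
and keeps the chain equilibrated), label them with the reference oracle,
append, and re-optimize warm-started from the current parameters with the
restraint center fixed at the original start. 18 iterations give a
9000-configuration training set. The test set is 500 fresh
configurations at 300 K under the final parameters, probing the
room-temperature-accessible region. Error reports use the same
offset-profiled convention: RMSE and MAE for energies, and three force
conventions (component RMS — the default headline —, per-atom vector
RMS, mean deviation magnitude), because "per atom" force units are
genuinely ambiguous.

Identifiability caveats: recovery experiments compare per-type *energy
profiles*, not raw parameters, because $(V, \gamma)$ and
$(V, \gamma + 180^\circ)$ parameter pairs are sign-degenerate, and
because room-temperature data leaves stiff torsions underdetermined —
the recovery tests therefore sample at 1500 K to decorrelate dihedrals.

## Synthetic study systems

`build_ring()` closes `n` copies of a small repeating-unit template (4-8
atoms, two linker attachment points, generic C/N/O/H motifs) into a ring,
derives every bonded term from connectivity, and embeds the geometry on a
circle whose radius grows linearly with `n`. Templates are deliberately
abstract: the target is the *statistical* structure of macrocycles (ring
closure, unit repetition, shared per-type parameters, term-class mix, a
net-charge option), not any specific host chemistry. The default
benchmark is the 7-unit, 6-atom-template ring (42 atoms), small enough
that the full 18 x 500 protocol runs in minutes.

`ground_truth_params()` plays the reference Hamiltonian: bond
$k \in [250, 400]$ kcal/mol/A$^2$, $r_0 \in [1.0, 1.6]$ A, angle
$k \in [40, 80]$ kcal/mol/rad$^2$, $\theta_0 \in [105, 125]^\circ$, one
torsion component per term with $n \in \{1,2,3\}$, $V \in [0, 3]$
kcal/mol, phases 0/180$^\circ$, and a small per-element vdW table —
magnitudes a practitioner would call ordinary organic values.
`perturb_params()` then manufactures a "transferable-like" starting set:
30% fractional jitter on force constants and barriers, 0.02 A / 3 deg
jitter on equilibrium values, and per-torsion actions drawn as jitter
(70%), drop (15%, leaving an explicit zero-barrier component so the
parameter space keeps its dimension) or add (15%, a new component with an
unused periodicity) — the same taxonomy (altered / eliminated / newly
defined) seen when two generations of a transferable force field are
diffed. These defaults are the calibrated conditions under which the
refit halves (in practice: almost eliminates) the starting test error.

What the generator does *not* emulate: real electronic structure (the
oracle is itself an MM form, so the refit can in principle reach zero
error, unlike against a quantum reference, where a representability floor
of a few kcal/mol remains), solvent and counterion effects, improper
torsions, and multi-cavity collapse chemistry of very large rings. The
two-state radius-of-gyration fixture for state classification is
generated directly as a hidden-Markov series rather than by long
molecular sampling. Passing tests therefore demonstrate the machinery and
its statistical behavior, not chemical accuracy for any real host.

## Dynamics analyses

Radius of gyration is the mass-weighted RMS distance from the center of
mass, the order parameter separating opened from squashed cavities.
Structural overlays use Kabsch superposition (SVD with determinant sign
correction, optional weights; the default superposes all atoms, and
restricting to heavy atoms is left as a caller choice through the weight
vector). State classification runs 1-D k-means on the Rg series
(deterministic quantile initialization, clusters relabelled by descending
mean Rg so "opened" is state 1) followed by dwell smoothing: runs shorter
than `min_dwell` frames (default 10) merge into the neighboring state
with the closer mean. Occupancies always sum to 1.

## Numerical choices and problem sizes

Degenerate geometry (any pair closer than $10^{-6}$ A) is rejected with
an error; near-linear angles are guarded by a $\sin\theta$ floor of
$10^{-6}$. k-means initialization is quantile-based so classification is
deterministic. The parameter dialect prints with `%.17g`, so
write-read round trips are bit-stable. The test suite runs the protocol
at its stated scale (18 x 500 on the 42-atom ring) once per starting set;
unit tests use smaller chains (4-8 atoms) and shorter Monte Carlo runs
(a few hundred frames), sizes chosen so the whole suite completes in
about twenty minutes on a single core while still exercising every
code path at full numerical tolerance.
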