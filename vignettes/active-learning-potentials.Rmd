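---
title: "Active learning of sparse GP interatomic potentials: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning of sparse GP interatomic potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gaplearn trains reactive machine-learned force fields with as few reference
("ground truth") evaluations as possible, and validates them *prospectively*:
not by a held-out error table, but by asking how long a model-driven MD
trajectory stays faithful to the reference surface. This vignette explains
the models and algorithms, the tunable parameters that matter, what the
in-repo surrogate ground truths do and do not emulate, and the design
decisions taken where the design was genuinely open.

## The potential model

A potential is a sparse Gaussian-process regression from atomic environments
to local energies,

$$E(\text{config}) = \sum_i e_0[z_i] \;+\; \sum_d \sum_{i \in \text{centres}(d)}
  \sum_s w_{d,s}\, k_d(x_i, x_{d,s}),$$

summed over descriptors $d$, centre atoms $i$ and sparse (inducing)
environments $s$. Three descriptor families are implemented:

* **two_body** — the set of centre–neighbour distances $r$ within `r_c`,
  each weighted by the smooth cutoff $f_c(r) = (\cos(\pi r/r_c)+1)/2$;
  kernel: weighted squared exponential with length scale `sigma_atom`.
  Optional species filters (`neighbor_species`) and an `intermolecular`
  flag (neighbours restricted to other molecules of the configuration's
  partition) make species-pair-resolved inter-molecular pair bases.
* **three_body** — symmetrised triplet features $(r_1, r_2, \cos\theta)$
  with weight $f_c(r_1) f_c(r_2)$; squared-exponential kernel with radial
  scale `sigma_atom` and angular scale `theta_cos`.
* **soap** — a SOAP-style power spectrum of the Gaussian-smeared neighbour
  density (width `sigma_atom`) in a radial basis of `n_max` Gaussians times
  spherical harmonics truncated at `l_max`; the kernel is the
  $\zeta$-exponentiated dot product of L2-normalised vectors. The vector is
  computed through the Legendre addition theorem — pairwise over neighbour
  pairs with ordinary Legendre polynomials — which is algebraically
  identical to the species-resolved harmonic expansion but needs no
  explicit spherical harmonics and has pole-free analytic gradients.

Every descriptor carries a signal amplitude `delta` (eV): the GP prior
standard deviation of one local contribution. In the weight-space normal
equations it enters as $K_{mm}/\delta^2$, so larger `delta` means weaker
shrinkage. Fits solve a regularised weighted least-squares problem with one
energy row per configuration (noise `sigma_E` × atoms) and, where labels
exist, 3N force rows (noise `sigma_F`), in square-root (QR) form: the
normal equations of these systems are numerically unusable at the noise
levels used here (condition numbers above 1e14), the QR form is not.
Per-element baselines `e0` are least-squares offsets estimated before the
GP (or fixed at zero via `e0_mode = "zero"`, the right choice for residual
targets such as intermolecular labels, which vanish for separated
molecules).

Predictive uncertainty (`predict_atom_variance`) is the variance of an
atom's local energy conditional on the sparse environments,
$\delta^2\,(k(x,x) - k_{xm}(K_{mm}+\varepsilon I)^{-1}k_{mx})$: zero (up to
jitter) at a sparse environment, the prior $\delta^2 k(x,x)$ far from all of
them. The fully Bayesian alternative that also propagates the data noise
gives qualitatively the same ordering but does not vanish at inducing
points; the conditional form matches how the variance is used here — as a
novelty score for the `gp_var` acceptance rule.

Sparse environments are chosen from the pooled training environments. For
SOAP vectors the package uses deterministic CUR — top-`k` statistical
leverage scores from the leading singular directions, ties broken by row
index. Leverage selection degenerates in one- to three-dimensional feature
spaces (it picks only extremes), so two-body sparse points are evenly
spaced distance quantiles and three-body points are seeded k-means centres
mapped to the nearest actual features. This is a deliberate deviation from
using one selection rule everywhere: coverage, not leverage, is what a
low-dimensional kernel basis needs.

## Surrogate ground truths

Real reference surfaces (tight-binding, DFT, coupled cluster) are out of
scope; two cheap analytic surrogates stand in for them so every workflow
runs end-to-end in seconds.

**Toy water** — harmonic O–H bonds (`k_b` = 25 eV/Å², `r0` = 0.96 Å) and
H–O–H angle (`k_a` = 3 eV/rad², `theta0` = 1.824 rad) per molecule, plus
switched Lennard-Jones on oxygen pairs and switched Coulomb
(`q_O` = −0.82 e) between all intermolecular pairs. The switching function
is a C¹ cubic Hermite between `r_switch` and `r_cut` (5 and 6 Å for
gas-phase clusters; limited below half the box edge for periodic cells).
The total is *exactly* separable into intra- plus inter-molecular parts,
which is what makes it the right oracle for the decomposition machinery.
Two caveats matter. First, truncating bare SPC-magnitude charges at a
3 Å-scale cutoff (forced by the 7 Å study boxes) breaks the near-neutral
cancellation that real water enjoys, so intermolecular pair energies reach
±2–3 eV and the surface is much rougher than a tight-binding water surface;
consequences for the validation results are discussed under Limitations.
Second, there is no long-range electrostatics at all — deliberately, since
the package's descriptors are finite-ranged.

**Two-state EVB** — a triatomic A–B–C identity-exchange surface: the lower
eigenvalue of $\begin{pmatrix} V_1 & \Delta \\ \Delta & V_2 \end{pmatrix}$
with $V_1 = \mathrm{Morse}_{AB}(r_{AB}) + C\,e^{-r_{BC}/\rho}$ and the
mirrored $V_2$. The defaults (De = 2 eV, a = 1.2 Å⁻¹, re = 2 Å,
Δ = 0.25 eV) give two equivalent wells at $r \approx 2.0$ Å (−2.02 eV) and
a symmetric barrier of 0.27 eV (≈ 6 kcal/mol) at $r_{AB} = r_{BC} =
2.24$ Å — the scale of a facile solution substitution reaction. Because the
coupling is constant, the dissociated limit sits
$\Delta^2/(V_2 - V_1) \approx 0.02$ eV below the isolated Morse minimum;
tests account for this.

Both surrogates are implemented in compiled code with analytic forces,
verified against central finite differences to 1e-6 eV/Å.

## The intra+inter decomposition

Condensed-phase systems are partitioned into molecules by covalent
connectivity (bond when $r_{ij} < 1.2\,(R_{\mathrm{cov},i} +
R_{\mathrm{cov},j})$; an explicit `solute_atoms` list overrides
connectivity for reactive solutes). The partition is computed once per
configuration lineage and carried through MD — re-partitioning mid-run is
deliberately not done. Intramolecular models are evaluated with every
molecule rigidly translated apart (the periodic cell scaled by
`expansion_factor` = 10, each molecule's centroid scaled with it), so no
foreign atom sits within the intra cutoffs; since the translation is rigid,
internal gradients map back unchanged. Intermolecular training labels are
total labels minus the intra model's prediction, and the composite
prediction is their sum, so additivity and label bookkeeping are exact
identities, tested to 1e-12. Centroid (rather than reference-atom)
translation was chosen for the expansion; any rigid per-molecule
translation satisfies the contract.

## Dynamics

MD uses the BAOAB splitting of Langevin dynamics (friction default
0.02 fs⁻¹, timestep default 0.5 fs); zero friction reduces exactly to
velocity Verlet, which conserves the toy-water dimer's energy to <1e-3 eV
over 10 ps and reproduces a harmonic bond period to <1%. Minimisation is
steepest descent with Barzilai–Borwein steps and Armijo backtracking —
monotone by construction. NEB uses the improved-tangent projection with a
FIRE optimiser and optional climbing image. One subtlety found during
development and now exposed as a parameter: for symmetric exchange
reactions the straight-line interpolation between the two wells lies
exactly on a symmetry ridge of the surface (constant $r_{AB}+r_{BC}$),
where the perpendicular force vanishes identically and the band converges
to the ridge crossing instead of the reaction valley. `init_noise` applies
a small seeded perturbation to the interior starting images, which is
sufficient to drop the band into the valley; with a climbing image the
recovered barrier then matches a dense relaxed scan essentially exactly.

## The active-learning loop

Starting from truth-labelled initial configurations and a first fit, each
episode (i) runs model-driven MD from the designated start configuration at
the exploration temperature for $n^3 + 2$ fs, (ii) scores the final frame —
`diff`: $|E_0 - E_{\mathrm{model}}|$ with a fresh truth evaluation;
`gp_var`: the maximum per-atom predictive variance, consulting the truth
only on acceptance — and (iii) either adds the labelled frame and refits
(resetting $n$ to 1) or increments $n$. The loop stops when the schedule
reaches `target_time` without an addition, or when the truth budget runs
out. Two interpretive choices are deliberate: $n$ resets after every
accepted addition (exploration is short right after a model update and
grows cubically as the model stabilises), and every episode restarts from
the same start configuration rather than chaining. A `max_energy_rise`
filter discards labelled frames whose reference energy exceeds the lowest
training energy by more than a threshold: early models lack short-range
repulsion, their MD can collapse atom pairs, and a handful of such
+100 eV frames otherwise poisons the global fit.

Because the loop refits after every addition, the water pipeline uses an
incremental fitter: per-configuration design rows are cached, the weighted
QR factorisation is updated sequentially (with column pivoting undone so
the factor stays in a fixed basis), and the sparse set is re-selected only
when the environment pool has doubled. A refit after one addition costs
tens of milliseconds instead of seconds, with the same numerical behaviour
as the batch QR solve.

## The prospective metric

`tau_acc` is the earliest time at which the cumulative energy error of a
model-driven trajectory exceeds `E_T`, where only evaluation errors above
`E_l` contribute; if it never fires the result is right-censored at the
simulated horizon. The default accumulates the full error of a contributing
evaluation; an excess-over-threshold mode ships behind a flag because the
algebra admits both readings, and every result records which was used. The
clock fires on strict exceedance. Defaults: 10 fs evaluation interval,
`E_T = 10 E_l`. The truth is observer-only: it never steers the dynamics.

## Study systems, problem sizes and what passing shows

The bundled pipelines reproduce the method's study design at desk scale:

* **Water monomer grid** — the intra model trains on the evenly spaced
  8×8×8 grid over $(r_{OH1}, r_{OH2}, r_{HH})$ ∈ [0.8–1.5]² × [1.0–2.5] Å
  (512 points, 0.1 Å spacing; geometrically infeasible corners are
  enumerated but flagged and excluded from fitting), with 2+3-body
  descriptors on oxygen (`r_c` 3 Å, length scales 0.25, `delta` 3 eV,
  noise 1e-5 eV/atom). Held-out grid RMSE measures ≈1.2 meV (max ≈4 meV).
  An optional refinement stage adds two dozen monomer geometries sampled
  from elevated-temperature model MD, which sharpens the thermally
  relevant region roughly threefold.
* **Bulk-water boxes** — 10 molecules in a 7 Å cubic cell (and a 5-molecule
  variant), surrogate interaction range set to `r_switch` 2.5 / `r_cut`
  3.0 Å to match the 3.0 Å descriptor cutoffs within the minimum-image
  safe radius. The intermolecular model combines three species-resolved
  intermolecular pair bases (length scale 0.12 Å, `delta` 5 eV, 60 sparse
  points each) with an O-centred SOAP residual (`n_max` 4, `l_max` 3,
  ζ = 4, 250 sparse points), noise 3e-5 eV/atom and 0.1 eV/Å, zero `e0`.
  Active learning runs at 300 K with a 0.01 eV acceptance threshold and a
  1 ps schedule target against a budget of ~250 box evaluations.
* **EVB triatomic** — transition-state-initialised active learning
  (0.01 eV threshold, 300 K, 150-evaluation budget) followed by NEB
  refinement rounds: the band is relaxed on the current model, its images
  labelled, and images with errors above threshold added. Climbing-image
  NEB against the surrogate recovers the scanned barrier to numerical
  precision; the trained model reproduces the relaxed 1-d exchange profile
  to ≈9 meV RMSE (≈0.2 kcal/mol, about 3.5% of the well-to-barrier
  range).

Passing these pipelines demonstrates that the machinery — descriptors,
sparse fits, decomposition bookkeeping, the episode schedule, the metric —
behaves as designed on a separable, analytically known surface. It does
*not* demonstrate chemical accuracy on real electronic-structure surfaces:
the surrogate has no polarisation, no charge transfer, no long-range
electrostatics, and its truncated bare charges make its intermolecular
surface *harder* to regress than a tight-binding water surface in one
specific way discussed below.

## Numerical choices

Units are fixed package-wide: Å, eV, fs, K, amu (so 1 amu Å²/fs² =
103.6427 eV). Minimum-image displacements are exact only for orthorhombic
cells with cutoffs below half the shortest periodic edge; the code asserts
this rather than silently truncating, and triclinic cells are out of scope.
Coordinates are stored unwrapped. Gram matrices are inverted through
Cholesky with escalating jitter; fits go through pivoted QR of the
square-root system. Degenerate NEB inputs (identical endpoints) and flat
potentials return immediately. Extended-XYZ files are written with 16
significant digits so read∘write round-trips to 1e-10.

## Known limitations

* **Sustained sub-10-meV box accuracy is out of reach for the bundled
  water surrogate.** With SPC-magnitude charges truncated at ~3 Å, the
  10-molecule box's intermolecular surface has eV-scale pair roughness.
  Measured on ideally sampled data (frames spanning a full 5 ps
  trajectory), the composite's generalisation floor is ≈17–26 meV RMSE
  within a trajectory and ≈60 meV across independent trajectories — two
  5 ps runs at 300 K simply do not revisit the same region of the
  60-dimensional configuration space. A censored 5 ps cumulative-error run
  at `E_l` = 0.01 eV would require ≈0.3 meV/atom for 500 consecutive
  unseen frames, which no tested model size achieves (larger SOAP bases
  measure worse, not better). The qualitative result the design targets —
  the actively learned intra+inter composite survives an order of
  magnitude longer than a random-configuration baseline of equal budget —
  is robustly reproduced. With the thresholds the original study used for
  tight-binding water (`E_l` = 0.1 eV), the trained composites are
  censored at the full horizon.
* The composite partition is frozen along a trajectory: auto-ionisation
  and any process that changes molecular identity outside a declared
  solute is out of scope.
* The `gp_var` variance is the local-energy conditional variance, not a
  force variance; both appear in the literature.
* Episode exploration restarts from a fixed configuration; for systems
  whose relevant configuration space is not reachable within the schedule
  horizon, coverage — not model capacity — limits accuracy.
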