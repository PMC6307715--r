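---
title: "Side-chain free energies by belief propagation on an oriented-bead model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-chain free energies by belief propagation on an oriented-bead model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpack)
```

## The model

`scpack` treats a protein as its backbone trace — the N, CA and C atoms of
each residue — and replaces every side chain by a small set of discrete
*coarse rotamer states*, each represented by a single oriented bead (a
position plus a unit direction, roughly the side-chain center of mass and
the CB–CG bond direction). For a fixed backbone the side chains then form
a pairwise Markov random field: a 1-residue energy vector $v_i(\tilde\chi_i)$
per residue and a 2-residue energy matrix $v_{ij}(\tilde\chi_i,\tilde\chi_j)$
per spatially neighboring pair. The object of interest is the side-chain
free energy

$$G^{SC} = -\log \sum_{\tilde\chi_1,\dots,\tilde\chi_N} e^{-\bar v(\{\tilde\chi_i\})},$$

which acts as a smooth many-body potential for backbone dynamics: the side
chains are treated as instantaneously equilibrated, in the spirit of the
Born–Oppenheimer separation, so the backbone moves on a surface from which
side-chain steric rattling has been integrated out. All energies are in
natural units with $k_BT = 1$; all coordinates are in Ångström.

Exact evaluation of $G^{SC}$ is exponential in $N$, so the package
minimizes the *Bethe free energy* instead: the exact average energy plus
an entropy that keeps single-residue terms and pairwise mutual
informations only,

$$G^{SC} \approx \min_{\{p_i\},\{p_{ij}\}}\Big(\langle \bar v\rangle - S^{\text{approx}}\Big),
\qquad
S^{\text{approx}} = -\sum_i \sum_{\tilde\chi_i} p_i \log p_i
 - \sum_{ij} \sum p_{ij}\log\frac{p_{ij}}{p_i\,p_j}.$$

The minimizer is found by damped loopy belief propagation. The marginals
are constrained only by the obvious pairwise consistency conditions
(marginalization, normalization, symmetry); these are *necessary but not
sufficient* for the marginals to come from any joint distribution. The
package ships the classic three-residue counterexample — two perfectly
correlated pairs plus an independent one — as a test that the consistency
checker accepts it, documenting this known limitation. The approximation
also cannot represent fully correlated side-chain collectives, and in
bi- or multi-stable rotamer landscapes BP converges into one basin and
underestimates the side-chain entropy; no special handling is attempted.

## Coarse states from a fine rotamer library

A fine rotamer library tabulates, per residue type, fine states $f$ with
χ-bin labels, backbone-dihedral-dependent probabilities $p^f(\phi,\psi)$ on
a 10° grid, and atom positions $x^f$. Fine states are pooled into at most
six coarse states by the partition $c(f)$ minimizing the
Ramachandran-weighted positional variance

$$\sigma^2 = \int p^{\text{Rama}}(\phi,\psi)\,
  \sum_f \frac{p^f(\phi,\psi)}{N_{\text{atom}}}
  \sum_{\text{atoms}} \lVert x^f - y^{c(f)}\rVert^2 \, d\phi\, d\psi,$$

evaluated by the midpoint rule on the grid. The search enumerates every
admissible partition: $c(f)$ may depend only on the χ1/χ2 bins, a coarse
state may contain a single χ1 bin, and the χ2 bins pooled into one state
must be circularly contiguous. These constraints make the χ1 state of every
coarse state unambiguous — which is what makes χ1 accuracy well-defined —
and keep the enumeration tractable. The unit tests compare the optimizer
against an unconstrained set-partition oracle filtered for admissibility,
and verify that $\sigma^2$ is non-increasing in the state budget.

## The pair potential

Every interaction pair (side chain–side chain, side chain–carbonyl O,
side chain–amide H, side chain–backbone three-bead) carries four clamped
cubic splines and evaluates as

$$E = \kappa\Big(V_{\text{radial}}(r_{12}) +
\text{ang}_1(-n_1\!\cdot\!n_{12})\,\text{ang}_2(n_2\!\cdot\!n_{12})\,
V_{\text{angular}}(r_{12})\Big),$$

with $r_{12}$ the bead separation and $n_{12}$ the displacement unit
vector. Radial knots are spaced 0.5 Å apart on $[0, R_{\text{cutoff}}]$
(7 Å for side chain–side chain, 5 Å for side chain–backbone) with the last
knot pinned to zero; together with the zero-derivative clamp this makes
every curve — and hence the energy and its gradient — vanish smoothly at
the cutoff, so the dynamically rebuilt interaction graph never introduces
discontinuities. Angular knots are spaced 1/6 apart in $\cos\theta$ on
$[-1, 1]$. The angular factors are stored as log-coefficients
(positivity by exponential transform); the interpolating spline through
positive knot values may still undershoot slightly between knots, which we
accept as the standard reading of a positivity constraint *on the
coefficients*.

Side chain–backbone terms are gated by the hydrogen-bond state of the
backbone site: a confidence score $f \in [0,1]$ is the product of a smooth
distance window on the H···O separation (on above 1.4 Å, off at 2.5 Å,
0.3 Å transition width — the window endpoints are data, the smoothstep
interpolant a convention) and two angular switches whose half-heights sit
47° off co-linear for N–H–O and H–O–C. Side chain–O/H terms use
$\kappa = 1 - f$, so a backbone site already engaged in a backbone–backbone
hydrogen bond stops interacting with side chains — the mechanism by which
helix capping competes with helix propagation. The O and H sites carry
directions along their covalent bonds; the three N/CA/C beads are
parameter positions placed in the residue frame and are radial-only by
default (a configuration switch enables directional terms there too).

The 1-residue energy adds a rotamer prior $-\log q^c(\phi_i,\psi_i)$
(bilinear in the tabulated coarse probabilities; a Ramachandran-averaged,
φ/ψ-independent variant serves terminal residues and the corresponding
ablation preset).

## Frames, derived atoms and analytic forces

Each residue's bead is placed by the least-RMSD rigid superposition
(Kabsch) of an ideal N/CA/C triple onto the instantaneous backbone; the
carbonyl O and amide H are placed by in-plane external-bisector
constructions (C=O 1.229 Å, N–H 1.010 Å; values live in the parameter
file, not the code). The C-terminal O uses a virtual next N extrapolated
at ideal geometry. The first residue and prolines carry no H.

Because the BP marginals minimize the Bethe free energy, the backbone
gradient needs no derivative of the marginals:

$$\frac{dG^{SC}}{db_k} = \sum_i \sum_{\tilde\chi_i} p_i \frac{\partial v_i}{\partial b_k}
 + \sum_{ij} \sum p_{ij} \frac{\partial v_{ij}}{\partial b_k},$$

the entropy contributing nothing. Every term is pulled back onto N/CA/C
through analytic Jacobians: the Kabsch frame derivative (via the
polar-decomposition perturbation identity), the bisector and
internal-coordinate placements, the dihedral gradients of the rotamer
prior, and the gradient of the hydrogen-bond gating $\kappa$. The same
envelope identity applied to the spline coefficients gives the
maximum-likelihood gradient. Both derivative paths are validated against
central finite differences of the full pipeline (BP re-solved per
displacement) at relative error below $10^{-3}$; for those checks BP is
converged to $10^{-10}$ so that the envelope assumption (stationarity)
holds to the tested accuracy.

## Belief propagation: numerical choices

Messages follow the round-indexed synchronous schedule with damping
$\lambda = 0.4$ and the printed convergence rule (node-belief changes
below $10^{-3}$). Beliefs and messages are kept normalized (the fixed
point is scale-invariant) and message divisions are floored at $10^{-300}$
to survive strong sterics. Non-convergence within `max_iter` (default
1000) returns the best state with a flag rather than raising, because
dynamics needs a force every step; forces computed from non-converged
marginals carry a warning. Warm starts (from the previous dynamics frame,
or the previous optimizer step during training) are used whenever the
interaction graph is unchanged, and a test verifies they reach the same
marginals as cold starts.

## Training

The loss per example is the energy gap
$E_{\text{gap}} = \bar v(\tilde\chi_{\text{native}}) - G^{SC} = -\log p(\text{native})$,
minimized with Adam (defaults from the method: minibatch 256, α = 0.03,
β₁ = 0.90, β₂ = 0.96, ε = 10⁻⁶) plus three regularizers evaluated at the
knots: squared second differences of each isotropic radial curve, squared
directional coefficients, and $(c_0^{\text{unif}} - 5)^2$ anchoring a
strong steric core at contact. The directional-size penalty acts on the
angular envelope knots and on the angular factors' log-coefficients —
penalizing the raw positive coefficients toward zero would fight the
positivity transform, so the log-scale pull toward unit coefficients is
the recorded convention. Whether the gap is averaged per protein or per
residue is exposed (`per`), defaulting to per-protein.

For a fixed backbone the interaction geometry never changes, so training
caches the spline basis rows of every term once and each Adam step reduces
to small matrix products plus one BP solve per example.

## What the synthetic generators emulate

`gen_rotamer_library` builds fine states on a χ1 × χ2 grid with smoothly
(φ,ψ)-varying probabilities (softmax of low-order Fourier fields) and
atom geometry in which χ1 sets the CB-like direction and χ2 perturbs a
CG-like atom — enough structure for variance-minimizing partitions to be
non-trivial. `synthetic_rama_density` is a two-basin (helix/sheet)
mixture standing in for a coil-library Ramachandran table; the file format
accepts any table. `gen_toy_protein` grows chains at the ideal bond
lengths (N–CA 1.453, CA–C 1.526, C–N 1.300 Å) and angles (109.5°, 120°).
`gen_training_set` draws native states *exactly* from the planted
Boltzmann distribution by complete enumeration — no MCMC — so a failed
recovery implicates the trainer, never the sampler.

These generators do not emulate real PDB statistics: amino-acid
composition is uniform over a few types, side-chain geometry is schematic,
and chains are short. Passing the planted-recovery test therefore shows
that the estimator is consistent for a potential inside its model class
under clean sampling; it does not certify accuracy on real proteins, which
additionally depends on the external rotamer library and curated training
structures that are out of scope here.

## The planted-recovery study

`planted_recovery_experiment()` is the package's end-to-end validation:
a planted potential (one smooth attractive well per interaction block,
depth 0.5–2 kT centered at 3.5–5.5 Å, added to the default repulsive
cores) defines the truth; 600 nine-residue random-coil chains over
ALA/SER/VAL/LEU are generated (500 train, 100 held out) and natives
sampled exactly; training runs two phases — 240 minibatch-128 Adam steps
at α = 0.03, then a 60-step full-batch polish at α = 0.01 that removes
minibatch wander — with regularization weights (5·10⁻³, 10⁻³, 10⁻²)
chosen by held-out validation, the same criterion the regularizer exists
to improve. Gaps are reported per residue — the scale on which the
method's gap deltas are quoted, and the natural unit when chains differ
in length; on that scale the untrained (no-interaction-well) start sits
roughly 0.4–0.5 kT per residue above the planted model, in line with the
magnitude a no-interaction ablation costs. Success is a held-out mean
per-residue gap within 0.1 kT of the planted model's own and χ1 accuracy
clearly above the no-interaction prior baseline (typically ≈ 0.81 vs
≈ 0.36–0.43 here). The problem sizes (nine
residues, four types, isotropic blocks) keep every native draw exactly
enumerable and the whole study at desk scale.

## Dynamics

The backbone potential adds harmonic bonds and angles at the ideal values,
a soft-sphere repulsion $k(r_c - r)^2$ below $r_c = 3$ Å between atoms more
than three covalent bonds apart, a tabulated Ramachandran energy
($-\log$ density, bilinear), and a backbone hydrogen-bond energy
$E_{hb}\sum f$ with $E_{hb} = -1.8$ kT by default. Spring constants
(100 kT/Å², 50 kT/rad², steric 3 kT/Å²) are conventions recorded in the
parameter file; only the equilibrium geometry is prescribed by the model.

Integration is a BAOAB splitting of Langevin dynamics: Verlet drift plus
an exact Ornstein–Uhlenbeck velocity refresh with friction
$\gamma = 1/0.135$ (the thermalization time scale) and time step 0.009;
with friction off it reduces to velocity Verlet and conserves energy to
relative $10^{-3}$ over 10⁴ steps on a harmonic test. Replica exchange
uses the fourteen-temperature ladder 0.500–1.000 with Metropolis swaps
$\min(1, e^{\Delta\beta\,\Delta E})$ on alternating adjacent pairs and
velocity rescaling on acceptance. Masses are unit and time units are
arbitrary. Each integration step runs the six-stage cycle: place O/H,
place beads, solve BP, differentiate the free energy, pull forces back to
N/CA/C, advance.

Dynamics tests run on deliberately small systems (6–10 residues, tens of
steps) and on scalar harmonic models where equipartition and
distribution-preservation have closed forms; the trajectory-level tests
check determinism given a seed, frame bookkeeping, and warm-start/cold-start
equivalence rather than folding, which is out of scope.

## Known limitations

* The Bethe approximation has no general inequality against the exact
  free energy; only tree equality is asserted.
* Pairwise-consistent marginals need not be representable (see the
  counterexample test).
* Bead geometry is rigid within a coarse state; no continuous χ motion.
* The synthetic library is schematic; per-residue published state counts
  for the real library are not reproduced (they depend on external data).
* Dataset curation against sequence redundancy (an external culling
  service in the original workflow) is a dataset-preparation step, not
  implemented here; the non-globularity RANSAC filter is.
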