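---
title: "Native protein dynamics from O(N) restraints: the contact-number diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Native protein dynamics from O(N) restraints: the contact-number diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cndnma)
```

## The models

Normal mode analysis (NMA) expands a potential energy function to second
order about a minimum and decomposes the dynamics into independent harmonic
modes — the eigenpairs of the mass-weighted Hessian
$\tilde H_{ij} = H_{ij}/\sqrt{m_i m_j}$. The scientific question this package
serves is how much *specific* structural information such a potential needs
in order to reproduce native protein dynamics.

**Elastic network model (ENM).** Every atom pair is joined by a Hookean
spring at its native length:
$$U^{\mathrm{ENM}} = \frac{A^{\mathrm{ENM}}}{2}\sum_{i<j} c_{ij}\,
(d_{ij}-d^0_{ij})^2 ,$$
with spring constants from a sigmoidal distance rule
$c_{ij} = \rho(d^0_{ij})$ (below). This uses $O(N^2)$ pieces of native
pairwise-distance information.

**Contact-number diffusion model (CND).** Only sequence-*local* atom pairs
(residue separation at most $w$ within one chain; matrix $\theta$) carry
specific restraints. All non-local structure enters through one
semi-specific quantity per atom, the non-local contact number
$$n_i = \sum_{j\,:\,\theta_{ij}=0,\,j\neq i} \rho(d_{ij}), \qquad
\rho(d) = \frac{1}{1 + e^{(d-d_{\mathrm{cut}})/\sigma}} ,$$
a soft count of the atoms packed around atom $i$ — dual to burial and
hydrophobicity. The energy is
$$U = \underbrace{\tfrac12\sum_{i<j}\theta_{ij}\,d_{ij}^2\,
\bigl[A + B\,(n_i-n_j)^2\bigr]}_{\text{autonomous}}
\;-\;\underbrace{\sum_{i<j}\theta_{ij}\,\lambda^0_{ij}\,d_{ij}
\;-\;\sum_i \mu^0_i\, n_i}_{\text{native bias}} .$$
The $A$ term is a repulsion between local pairs that on its own would break
local structure; the $B$ term penalizes heterogeneity of contact numbers
between sequence neighbours — a local pair whose members are very unequally
buried repels strongly — which drives contact numbers to diffuse toward
uniformity along the chain (phase separation of buried and exposed atoms is
penalized, mimicking implicit protein–solvent interactions). The two
Lagrange terms bias this featureless "generic polypeptide" to the specific
native structure. Requiring the Jacobian to vanish at the native
coordinates gives closed-form multipliers, one per local pair and one per
atom:
$$\lambda^0_{ij} = d^0_{ij}\bigl[A + B\,(n^0_i-n^0_j)^2\bigr], \qquad
\mu^0_i = B\, D^0_i, \qquad
D_i = \sum_j \theta_{ij}\, d_{ij}^2\,(n_i - n_j),$$
where $D_i$ — the distance-weighted local Laplacian of the contact-number
profile — is the diffusion term: positive for an atom more buried than its
sequence neighbours. The total restraint count is $O(N)$: roughly
$(2w+1)\times$(atoms per residue) local multipliers per atom, plus one
$\mu_i$ per atom.

With the window spanning the whole chain every pair becomes local, all
$n_i$ vanish, $\lambda^0_{ij} \to A\,d^0_{ij}$, and the energy collapses to
$\tfrac{A}{2}\sum_{i<j}(d_{ij}-d^0_{ij})^2$ plus a constant — a
uniform-spring elastic network. ENM is thus the all-local limit of CND;
`cnd_to_enm_limit_check()` verifies the subspace identity numerically (mean
squared overlap of the ten lowest modes is 1 to machine precision, and
materially below 1 at the default window $w=1$).

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `A` | local-pair restraint weight | 10000 | dimensionless |
| `B` | contact-number diffusion weight | 1 | dimensionless |
| `w` | local sequence window | 1 (tri-peptide segments) | residues |
| `sigma` | sigmoid steepness | 2 | Å |
| `d_cut` | contact midpoint / ENM cutoff | 5 | Å |
| `amplitude` (ENM) | spring scale | 1 | dimensionless |

`A` and `B` are dimensionless weights; every reported observable
(scaled/normalized MSF, correlations, coverages, overlaps) is invariant to
the overall energy scale, so only the ratio `A/B` matters. `A` three orders
of magnitude above `B` keeps local covalent-scale geometry stiff; although
`A` dwarfs `B`, the `A` terms touch only the band-diagonal Hessian blocks,
while the far more numerous off-band couplings all come from the `B` term,
so the diffusion term always has a non-negligible effect. `run_parameter_sweep()`
exposes the `A`/`w`/`sigma` grid.

## Numerical design

**Hessian assembly.** Because the multipliers zero every first derivative of
the energy with respect to the interatomic distances and the contact numbers
at the native point, the native Hessian reduces *exactly* to the
Gauss–Newton form $H = G^{\mathsf T} K G$, where $G$ stacks the Jacobians of
the local distances and of the contact numbers with respect to the Cartesian
coordinates and $K$ is the small second-derivative matrix in those
intermediate variables (diagonal local stiffness $A + B(n_i-n_j)^2$, a
$2Bsd$ coupling row per local pair, and $B$ times the $d^2$-weighted local
graph Laplacian). No second derivatives of $\rho$ are needed, symmetry is
structural, and rigid-body invariance is inherited from the distance-only
dependence. $H$ is exactly linear in $(A, B)$, which the tests exploit.

**Oracles.** Every analytic derivative is checked against central finite
differences of the energy. The finite-difference comparisons run at
unit-scale weights ($A \sim 10$): second-difference round-off scales with
the absolute energy over the squared step, so at $A = 10^4$ it would swamp
the comparison, while the exact linearity of $H$ in $(A, B)$ — itself
asserted numerically — carries the unit-scale verification to the default
scale. The oracle step is $10^{-4}$ Å on the smallest fixtures and
$10^{-3}$ Å on larger ones for the same reason.

**Diagonalization.** Base `eigen()` (LAPACK) on the dense symmetric
mass-weighted Hessian. Modes with $|\omega^2|$ below $10^{-8}$ times the
largest eigenvalue are flagged rigid; a connected non-collinear structure
has exactly six, leaving $3N-6$ vibrational modes. The Lagrange construction
guarantees stationarity of the native structure, not minimality, so any
negative vibrational eigenvalue is reported as a diagnostic
(`n_negative`) rather than silently assumed away; at the default parameters
all fixtures tested are positive semidefinite.

**Conformational-change fitting.** The change vector superposes the holo
structure onto the apo structure (all-atom, unweighted — matching the
convention of all-atom RMSD tables; mass-weighted superposition is a flag)
so that displacement and modes share one frame, mass-weights and normalizes.
For a *finite* change, optimal superposition leaves second-order
rigid-rotation content in the difference vector, which no vibrational basis
can represent; the residual rigid component is projected out against the
apo structure's mass-weighted rigid-body subspace (`remove_rigid = TRUE`,
fraction reported), making "complete basis $\Rightarrow$ zero residual"
exact. Coefficients are orthogonal projections $c_i = v_i \cdot \hat Y$
(identical to least squares in the orthonormal mode basis), the relative
RMSD after $N_m$ modes is $\sqrt{1-\sum_{i\le N_m} c_i^2} \in [0,1]$,
coverage is $100(1-\mathrm{relRMSD})$ (the $100(1-\mathrm{relRMSD}^2)$
variant is a switch), and the AUC is the sum of the relative RMSD over the
curve. Degenerate zero displacement raises a typed error.

**Surface analysis.** Shrake–Rupley ASA with a deterministic golden-spiral
point set (960 points, probe 1.4 Å, Bondi-type radii; all configurable).
Buried means zero ASA (tolerance $10^{-6}$ Å$^2$). Total ASA is rigid-motion
invariant to well under 0.5%; individual boundary atoms carry the larger
share of the discretization noise, which is why the burial rule is a
zero/nonzero criterion rather than a fine threshold.

**Trajectory PCA.** Frames are superposed onto the mean structure (two
passes), mass-weighted, and the frame covariance is eigendecomposed via SVD.
Principal modes are unit vectors in the same mass-weighted space as the
normal modes, so `cumulative_fit()` applies to them directly.

## The synthetic fixtures, and what passing tests do not show

Crystal-structure batteries (matched apo–holo pairs, experimental
B-factors, MD trajectories) require downloads, so the test suite runs
entirely on generated fixtures:

* `make_helix_fixture()` — an idealised $\alpha$-helix (radius 2.3 Å, rise
  1.5 Å, 100°/residue) of pseudo-residues with up to 8 heavy atoms each,
  optional Gaussian coordinate jitter under a caller-supplied seed, and
  synthetic B-factors $b = 5 + 25\,(r/r_{\max})^2$ — a smooth, monotone
  function of distance from the helix axis, encoding "exposed atoms
  fluctuate more".
* `make_hinge_pair()` — an apo–holo test double: the same atoms with every
  residue beyond a hinge rotated rigidly about a stated radial axis, so the
  conformational change is a known large-scale domain motion and atom
  counts match exactly. Fixture RMSDs grow monotonically with the hinge
  angle.
* the planted-covariance trajectory — frames displaced along two known
  orthonormal mass-weighted directions with 4:1 variances, the ground truth
  for PCA recovery (5000 frames recover the variances within 5%).

These fixtures exercise every contract — stationarity, spectra,
fitting identities, exposure contrasts — but they are regular, single-chain,
and thin: they have no deep hydrophobic core, no side-chain packing
heterogeneity, no crystal contacts, and their "B-factors" are by
construction a clean function of burial. Passing them demonstrates the
correctness of the machinery, not the biological performance of either
model on real proteins; quantities such as B-factor correlations on
fixtures are internally consistent numbers, not reproductions of values
measured on crystal structures. Problem sizes in the tests (30–104 atoms,
5000-frame trajectories) were chosen so the full suite and the acceptance
script each run in about a minute on one CPU.

## A worked run

```{r hinge}
pair <- make_hinge_pair(26, 4, hinge_residue = 13, angle = 30,
                        noise = 0.05, seed = 3)
run_table2(pair$apo, pair$holo, n_modes = c(5, 100))
```

The coverage at 100 modes always dominates the coverage at 5 (nested least
squares), and both models fit the hinge motion well from the apo side. The
collectivity contrast between the models shows in the cumulative variance:

```{r cumvar}
md_cnd <- run_modes(pair$apo, "cnd")
md_enm <- run_modes(pair$apo, "enm")
dplyr::bind_rows(
  CND = cumulative_variance(md_cnd)[50, ],
  ENM = cumulative_variance(md_enm)[50, ],
  .id = "model")
```

The 50 lowest CND modes carry nearly the whole variance while the ENM
spectrum is much flatter — the contact-number model concentrates the
dynamics into few collective low-frequency modes, the behaviour that makes
it attractive for studying functional motions.

## Known limitations

* The CND Hessian is not proven positive semidefinite; negative vibrational
  eigenvalues are reported, not repaired.
* Dense Hessian storage: $3N \lesssim 12{,}000$ (a ~4000-atom protein) is
  the practical ceiling.
* PDB handling is deliberately plain: first-listed altloc, 0-based residue
  ordinals (insertion codes ordered by file position), no symmetry
  expansion, no hydrogen placement; mmCIF is out of scope.
* Exposure classification depends on the radii set and sampling density at
  the margins; only the zero-ASA criterion is robust across ASA
  implementations.
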