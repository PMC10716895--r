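---
title: "Staged virtual screening: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged virtual screening: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligscreen)
```

`ligscreen` implements a three-stage structure-based virtual-screening
workflow on desk-scale systems: a fast empirical docking score ranks every
candidate ligand; the best move on to an MM/GBSA binding free energy estimate
from toy trajectories; the best of those are refined with alchemical free
energy perturbation (FEP) over a restrained thermodynamic cycle. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions that were genuinely open.

## Units and constants

All quantities use a single unit system: length in Å, energy in kcal/mol,
mass in amu, time in ps, charge in units of the elementary charge.
Avogadro's number, the vacuum permittivity, the elementary charge and
Planck's constant are absorbed into four conversion constants
(`ls_constants()`): the Boltzmann constant
$k_B = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹, the Coulomb conversion
$k_e = 332.0636$ kcal Å mol⁻¹ e⁻², the reduced Planck constant
$\hbar = 1.5179\times10^{-2}$ kcal ps mol⁻¹ and the mechanical conversion
1 kcal/mol = 418.4 amu Å² ps⁻². Writing every formula in this one system
makes each operation testable against a closed-form oracle.

## Stage 1 — empirical docking

The docking score is a weighted sum of pairwise terms over all
ligand–receptor atom pairs, each a function of the *surface distance*
$d = r - R_i - R_j$ (the gap between van der Waals surfaces):

$$C = \sum_{i<j} \Big[ w_1 e^{-(d/0.5)^2} + w_2 e^{-((d-3)/2)^2}
  + w_r\, d^2\,[d<0] + w_h\, h(d) + w_b\, b(d) \Big],$$

where $h(d)$ is a hydrophobic contact ramp (1 below 0.5 Å, 0 above 1.5 Å,
linear between; applied only between two hydrophobic carbons) and $b(d)$ a
hydrogen-bond ramp (1 below −0.7 Å, 0 above 0 Å; applied only between a
donor and an acceptor). Default weights are
(−0.0356, −0.00516, 0.840, −0.0351, −0.587) with an 8 Å surface-distance
cutoff; all are configurable through `dock_weights()`. Atom types come from
`assign_dock_types()`: a closed five-way typing (hydrophobic carbon, polar
donor, polar acceptor, donor–acceptor, other) driven by the bond graph.

The ligand is treated as *rigid*: the pose optimizer explores only the six
rigid-body degrees of freedom, so intraligand distances never change and the
score runs over intermolecular pairs only. Torsional flexibility and the
rotatable-bond penalty are deliberately omitted to keep the optimizer
desk-scale; the pairwise scoring function is exercised in full.

`optimize_pose()` is an iterated local search: a derivative-free
Nelder–Mead simplex minimization over (translation, rotation vector),
followed by `n_restarts` rounds of random rigid perturbation within the
search box plus re-minimization, accepting only improvements. A quadratic
penalty keeps the ligand centroid inside the `search_box()`. The simplex
was chosen over a quasi-Newton method because the contract is only "reach a
local minimum", which is verified against a brute-force translation grid in
the test suite; ties between equal scores go to the first pose found. The
default of 8 restarts is the package's own choice and is exposed as
configuration.

## Stage 2 — MM/GBSA

The binding free energy is estimated from three separate trajectories
(complex C, receptor R, ligand L; for $N$ ligands the stage plans $2N+1$
jobs, see `plan_md_batch()`):

$$\Delta G^0 = G_C - G_L - G_R, \qquad
  G = \langle E_{\mathrm{MM}}\rangle + \langle G_{\mathrm{polar}}\rangle +
      \langle G_{\mathrm{nonpolar}}\rangle - T\,S .$$

`mm_energy()` evaluates harmonic bonds $k(r-r_0)^2$ and angles, cosine
dihedrals, 12-6 Lennard-Jones with Lorentz–Berthelot combining
(`lj_radius` is the $R_{\min}/2$ convention) and Coulomb $k_e q_i q_j/r$
with interior dielectric 1, excluding 1-2 and 1-3 pairs.

The polar solvation term is a generalized-Born model with Debye ionic
screening:

$$G_{\mathrm{polar}} = -\frac{k_e}{2}\sum_{i,j}
   \Big(1 - \frac{e^{-\kappa g_{ij}}}{\varepsilon_s}\Big)
   \frac{q_i q_j}{g_{ij}}, \qquad
  g_{ij} = \sqrt{r_{ij}^2 + \alpha_i\alpha_j
           e^{-r_{ij}^2/4\alpha_i\alpha_j}},$$

with the double sum including the self terms $i=j$ ($g_{ii}=\alpha_i$), so a
single unit charge reduces exactly to the Born ion
$-(k_e/2)(1-1/\varepsilon_s)/\alpha$. The screening constant
$\kappa = \sqrt{8\pi k_e n / (\varepsilon_s k_B T)}$ uses the salt number
density $n$ converted from mol/L; 0.1 M at 300 K gives a Debye length of
about 9.6 Å. We use the unscaled $\kappa$; some implementations apply an
additional 0.73 prefactor, which we do not.

Effective Born radii come from Hawkins–Cramer–Truhlar pairwise descreening
integrals with the Onufriev–Bashford–Case tanh rescaling (coefficients 1.0,
0.8, 4.85). One package-specific convention: the per-atom `gb_radius` is
used *directly* as the intrinsic radius, so an isolated atom's effective
radius equals its intrinsic radius exactly and burial can only increase it.
(The common alternative subtracts a fixed 0.09 Å offset first; users who
want that convention can simply store offset radii in `gb_radius`.)

The nonpolar term is $\gamma A_{SA}$ with surface tension
$\gamma = 0.005$ kcal mol⁻¹ Å⁻² by default (configurable; the literature
spans roughly 0.005–0.0072) and $A_{SA}$ a Shrake–Rupley solvent-accessible
surface area with a deterministic Fibonacci sphere quadrature (default 960
points/atom, probe 1.4 Å); doubling the quadrature moves small-cluster areas
by well under 0.5 %.

### Quasiharmonic entropy

The entropy is estimated from the mass-weighted covariance of the Cartesian
coordinates. Rigid-body motion is removed first by Kabsch superposition of
every frame onto the first, fitted on the receptor α-carbons for
receptor-containing systems (ligand-alone trajectories align on all
non-hydrogen atoms — the natural analogue, since they have no α-carbons).
The eigenvalues $\lambda_k$ of $M^{1/2}\sigma M^{1/2}$ define mode
frequencies $\omega_k = \sqrt{k_B T \cdot 418.4 / \lambda_k}$, and each
retained mode contributes a quantum-harmonic-oscillator entropy

$$S = k_B \sum_k \Big[ \frac{u_k}{e^{u_k}-1} - \ln(1 - e^{-u_k}) \Big],
 \qquad u_k = \hbar\omega_k / k_B T .$$

Eigenvalues below $10^{-8}$ amu Å² are numerically null modes left by the
alignment (at most six for a connected molecule) and are discarded and
counted rather than propagated. The binding entropy
$\Delta S = S_C - S_R - S_L$ therefore captures the ligand's total entropy
and the receptor's vibrational entropy, while the receptor's overall
translation and rotation — constant during binding for a heavy receptor —
drop out with the alignment. For the complex we include *all* atoms in the
covariance after aligning on the receptor selection; whether the ligand
atoms belong in the complex covariance is an interpretation, and including
them is the choice consistent with "total ligand entropy".

Averages discard the first 10 % of frames as equilibration by default
(`equil_fraction`), a package convention.

## Stage 3 — alchemical FEP

The FEP engine couples the ligand–environment interaction to a parameter
$\lambda \in [0,1]$: electrostatics scale as $(1-\lambda)$ on a softened
distance, and Lennard-Jones uses a β-soft-core form with $\alpha_{sc}=0.5$,

$$U_{LJ}(\lambda) = (1-\lambda)\,\varepsilon
  \Big[ \big(\alpha_{sc}\lambda + x^6\big)^{-2}
      - 2\big(\alpha_{sc}\lambda + x^6\big)^{-1} \Big],
  \quad x = r/R_{\min},$$

which reduces exactly to the physical potential at $\lambda = 0$ and stays
finite for overlapping atoms at every $\lambda > 0$; at $\lambda = 1$ the
ligand is fully decoupled (annihilated). Harmonic restraints — a distance
restraint anchoring the ligand centroid to non-hydrogen receptor atoms and a
best-fit-RMSD restraint that penalizes deformation but not rigid motion —
are coupled by their own parameter so their free-energy cost is measured,
not ignored.

Ensembles at each λ-window come from a Metropolis Monte Carlo sampler
(`metropolis_sample()`), which plays the role of the MD engine at desk
scale; it is exact for the Boltzmann distribution of the coupled potential
and deterministic per seed. Each window's free-energy increment is the
Zwanzig exponential average

$$\Delta G_i = -k_B T \ln \big\langle e^{-\Delta U_i / k_B T}
  \big\rangle_i,$$

computed with log-sum-exp stabilization, where $\Delta U_i$ is evaluated on
the window-$i$ ensemble toward window $i+1$ (forward) or $i-1$ (backward).
This is the standard single-direction convention; stratified double-wide
sampling would also be defensible but is not what "a direct average over
frames" describes. Every leg is run in both directions; the leg estimate is
the mean of (forward, −backward), with the hysteresis $|f + b|$ reported as
a convergence diagnostic. Bennett-style acceptance-ratio estimators are
deliberately not used — the workflow is defined by forward/backward
exponential averaging — and per-window standard errors come from batch
means over eight blocks, which is robust to the chain's autocorrelation.

The binding free energy closes a four-leg thermodynamic cycle: restrain the
bound ligand, decouple it in the bound state, transfer the non-interacting
ligand at zero cost ($\Delta G_3 = 0$, since a decoupled ligand has the same
free energy anywhere), then undo decoupling and restraint in the unbound
state:

$$\Delta G_{\mathrm{bind}} = -\big(\Delta G_{\mathrm{restrain}}^{bound}
 + \Delta G_{\mathrm{decouple}}^{bound}
 - \Delta G_{\mathrm{decouple}}^{unbound}
 - \Delta G_{\mathrm{restrain}}^{unbound}\big),$$

signed so stronger binding is more negative. Defaults: 20 equally spaced
λ states, 20 % of each window's steps as extra equilibration, restraint
force constant 10 kcal mol⁻¹ Å⁻² — all exposed as configuration, all the
package's own choices. **Known omission:** no standard-state volume
correction is applied to the restraint release, so absolute binding free
energies are comparable only within a common confinement volume; rankings
(the pipeline's purpose) are unaffected. The test suite validates the cycle
against direct numerical quadrature of a one-dimensional dimer's
configuration integrals, where the confinement volume is explicit and
cancels exactly.

## The pipeline

`run_screen()` wires the stages together: dock every ligand → rank
(ascending score, more negative is better) → promote the top `n_to_md` →
MM/GBSA ($2N+1$ toy trajectories) → rank → promote the top `n_to_fep` →
FEP → final ranking. Two rules matter:

* **Failures are ranked worst, never raised.** Any exception while
  processing one ligand (unparseable structure, non-finite score, unstable
  evaluation) becomes a `failed_*` status; the ligand sorts after every
  scored record (ties broken lexicographically by id) and is never
  promoted. A screening campaign must survive individual bad inputs.
* **Stages never mix scores.** Each stage re-ranks purely on its own score;
  an earlier stage's ordering only decides who enters.

Between docking and the MD stage the pose is relaxed rigid-body against the
MM potential (`relax_pose()`): the empirical score and the force field put
their contact minima at slightly different separations, and trajectories
must fluctuate about the force field's minimum, not the docking score's.

## What the synthetic fixtures emulate — and what they do not

`make_pocket_receptor()` builds a concave cage of ~20 carbon atoms
(radius 5 Å, opening along +z) with a 3 Å half-length search box.
`make_ligand_set()` builds compact carbon-cluster ligands: actives are
larger (6–8 atoms) with pocket well depths calibrated to −8 kcal/mol,
decoys smaller (3–5 atoms) calibrated to −2 kcal/mol. Calibration is exact:
the intermolecular LJ energy scales linearly in
$\sqrt{\varepsilon_{\mathrm{lig}}}$, so scaling all ligand epsilons by
$(\text{target}/\text{scan minimum})^2$ pins the 1-D pocket-scan minimum to
the requested depth. Toy ligands are bonded as a complete graph of harmonic
bonds — an elastically rigid body with no intra-ligand nonbonded pairs — so
the calibrated epsilons act purely intermolecularly. `harmonic_trajectory()`
draws frames from the exact Boltzmann distribution of independent harmonic
modes (variance $k_B T/k$ per coordinate), giving ensembles whose covariance
and quasiharmonic spectrum are known analytically.

These fixtures make every downstream check an analytic or constructive
oracle, which is their purpose — and their limit. They do not emulate real
chemistry: no valence or protonation, no decoy property-matching, no
conformational flexibility, no explicit solvent, and trajectory frames are
uncorrelated rather than dynamical. A passing suite demonstrates that the
estimators are implemented correctly and that the pipeline separates
strong from weak binders *when the energy models are the truth*; it says
nothing about force-field accuracy on real proteins.

In both the active/decoy design and the trajectory generator, the actives
are better binders at every stage by construction; the interesting
quantities are whether each stage's estimator recovers that ordering from
its own samples, and the test suite's study conditions (3 actives among 17
decoys, 10 promoted to MD, 5 to FEP; 80-frame trajectories with mode
stiffness 200 kcal mol⁻¹ Å⁻²; 16 λ states × 4000 steps for the dimer
oracle) were sized so each estimator's sampling error is comfortably below
the signal it must resolve on one CPU.

## Numerical choices and degenerate inputs

* Pose and alignment rotations use unit quaternions / SVD with a
  determinant correction; alignment selections with fewer than three atoms
  fall back to translation-only with a warning.
* Eigenvalue floor $10^{-8}$ amu Å² for quasiharmonic modes; covariance of
  a single frame is an error, not a zero.
* `zwanzig_increment()` uses log-sum-exp; a constant $\Delta U$ returns that
  constant exactly and Jensen's bound $\Delta G \le \langle \Delta U\rangle$
  holds for any sample.
* Multi-MODEL PDB files read as their first model with a warning; first
  altloc kept with a warning; file serials are 1-based, internal indices
  are R's native 1-based.
* Missing per-atom parameters default from a bundled Bondi-like element
  table and are flagged per atom (`param_defaulted`) rather than failing:
  toy fixtures must run without a force-field generator.
* Enrichment axes are fractions in [0, 1] on both axes, so
  difference integrals of a perfect ranking against the diagonal have the
  closed form $(1-a)/2$ for active fraction $a$. Per-stage curves are
  computed within the set entering that stage.

## Known limitations

Rigid ligands in docking; implicit solvent only; no standard-state
correction in FEP; toy trajectory generator instead of molecular dynamics;
no per-residue decomposition; fingerprints are plain bitsets (Tanimoto
only). Each is a scope decision, not an accident: the package's purpose is
a faithful, fully testable implementation of the staged estimators
themselves.
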