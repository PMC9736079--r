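---
title: "Electrostatics-driven rescoring of ligand poses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatics-driven rescoring of ligand poses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elscreen)
```

## The problem and the model

Structure-based virtual screening ranks a library of candidate small
molecules against a protein target. Docking scores and end-point free-energy
methods (MM-GB/PBSA) approximate the binding free energy of each complex;
`elscreen` takes a different, knowledge-based route. Given a protein with a
co-crystallized reference ("cognate") ligand and a library of query poses
already placed in the binding site, it asks a relative question: *what does
it cost to replace the cognate by the query?*

The electrostatic half of that question uses the field of the **ligand-free
protein**. The linearized Poisson–Boltzmann equation

$$\nabla\!\cdot\!\big(\varepsilon(\mathbf r)\,\nabla\phi(\mathbf r)\big)
  \;-\; \bar\kappa^2(\mathbf r)\,\phi(\mathbf r)
  \;=\; -4\pi k_c \rho_{\text{protein}}(\mathbf r)$$

is solved once per target on a cubic grid ($\varepsilon_{in}=2$ inside the
van der Waals envelope, $\varepsilon_{out}=80$ outside, 0.145 M 1:1
electrolyte with a 2.0 Å ion-exclusion layer, 0.6 Å spacing, protein
occupying 70% of the box edge). The interaction energy of a pose is then
the energy of assembling its partial charges in that fixed field,

$$E_{\text{elec}} \;=\; \sum_j \phi(\mathbf r_j)\, q_j ,$$

with $\phi$ interpolated trilinearly at the ligand atom sites and $q_j$
Gasteiger (PEOE) charges. Because the field is ligand-free, it is shared by
every pose: one solve serves the entire library, which is what makes the
method cheap enough for large screens.

Nonpolar contributions are two single-point terms: a 12-6 Lennard-Jones
protein–ligand sum (element-level parameters, arithmetic/geometric
combination, 12 Å cutoff) and a buried-surface hydrophobic term
$\gamma\,[\mathrm{SASA}(PL) - \mathrm{SASA}(P) - \mathrm{SASA}(L)]$ with
$\gamma = 0.0226$ kJ/mol/Å². Each channel $c \in \{\text{elec}, \text{hyd},
\text{vdw}\}$ enters as a **replacement energy**
$\Delta E_c = E_c(\text{query}) - E_c(\text{cognate})$; negative values
favour the query.

Replacement energies, two shape similarities, eight physicochemical
descriptor similarities, and an atom-pair fingerprint similarity are
normalized onto $[0,1]$ and combined into the ranking score

$$Z \;=\; \omega_E N(\Delta E_{\text{elec}})
      + \omega_H N(\Delta E_{\text{hyd}})
      + \omega_{vdw} N(\Delta E_{\text{vdw}})
      + \omega_m f_m + \omega_{m'} f_{m'}
      + \sum_{n=1}^{8} X_n + \omega_A \cdot AP$$

with default weights $\omega_E{=}2$, $\omega_H{=}\omega_{vdw}{=}1$,
$\omega_m{=}1$ (pocket shape), $\omega_{m'}{=}2$ (reference shape), unit
descriptor weights, and $\omega_A{=}4$; the maximum attainable score is 19.
The electrostatic channel is deliberately over-weighted: charge
complementarity is the signal the method is built to exploit.

### Normalization

Raw terms mix units (kcal/mol, kJ/mol, unitless distances). Each term is
mapped to the unit interval by

$$N_\alpha(x) \;=\; \begin{cases} 1 & x \le 0 \\ 1 - \tanh(\alpha x) & x > 0,
\end{cases}$$

continuous at zero: any energetically favourable replacement scores 1, and
penalties decay smoothly. Shape distances $d \ge 0$ use the same
$1-\tanh(\alpha d)$ map so identical shapes score 1. The steepness absorbs
the unit scale: $\alpha = 0.25$ for the kcal/mol electrostatic channel and
for shape distances, $\alpha = 0.05$ for the larger-magnitude kJ/mol
nonpolar channels. A sigmoid written as $1-|1-\tanh(\alpha x)|$ reduces to
$\tanh(\alpha x)$ for positive $x$, which would *reward* worse replacement
costs; the decaying form used here is the one consistent with the
favourability rule above, and we treat that as the defining convention.

## Numerical choices

**LPBE solver.** Red-black Gauss-Seidel SOR ($\omega = 1.6$, relative
tolerance $10^{-6}$, at most 10 000 sweeps) on the 7-point stencil with
edge-midpoint dielectric classification, trilinear charge spreading, and
Dirichlet boundaries from the analytic screened-Coulomb sum. Point sources
on a lattice carry a well-known near-field discretization error (about 5%
three spacings from the charge). The default source treatment therefore
*regularizes the singularity*: the potential is split into the analytic
Coulomb field of the charges in their reference dielectric plus a smooth
correction solved numerically, with the screening and dielectric-interface
terms moved to the right-hand side. Against the Debye–Hückel closed form
(single +1 e charge, uniform ε = 80, I = 0.145 M) the solved potential is
accurate to ~0.01% at 0.6 Å spacing for all radii ≥ 1.8 Å, with
monotone improvement under refinement (0.9 → 0.6 → 0.45 Å); the test suite
and the acceptance script recompute exactly this. The split requires
sources to sit in a homogeneous reference dielectric (true for protein
atoms, which are inside their own vdW spheres); charges violating it
trigger a fallback to direct spreading with a warning.

**Charges.** Ligands: classical PEOE — electronegativity
$\chi(q)=a+bq+cq^2$ per element/hybridization, per-bond transfer damped by
$2^{-k}$, 12 iterations, seeded from formal charges. Charge is conserved
exactly and topologically equivalent atoms receive equal charges. The
implementation reproduces an independent PEOE implementation atom-by-atom
within 5×10⁻³ e on an 11-molecule panel shipped with the package. Proteins:
a per-atom (residue, atom name) charge table — a minimal amber-style TSV is
packaged, and real targets should supply a complete table; metals take
configured integer charges.

**Shape.** Shapes are compared through rotation-invariant per-degree
energies $c_\ell = \sqrt{\sum_m a_{\ell m}^2}$ of a real spherical-harmonics
expansion ($\ell_{max}=6$) of the star-shaped radial surface function
around the centroid (largest ray–sphere intersection per direction). The
radial function is sampled on a Gauss–Legendre × uniform-azimuth product
grid (16 × 32 = 512 directions) and the expansion is a weighted
least-squares fit, i.e. a discrete projection. Projection onto each degree
commutes with rotation, so with exact quadrature $c_\ell$ is
rotation-invariant to machine precision for smooth surfaces; an equal-weight
spiral sampling was measured to alias the truncation error
orientation-dependently and was rejected. The pocket is represented by a
protomol — carbon probes (r = 1.7 Å) on a 0.8 Å lattice within 10 Å of the
reference centroid, clash-free against the protein and within 5 Å surface
reach of pocket-lining atoms; hydrogen probes are omitted (single probe
type). Descriptor distances are Euclidean on the $c_\ell$ vectors; smaller
is more similar.

**Descriptors and fingerprints.** The eight ligand-centric descriptors are
H-bond acceptor/donor counts (element rules: donors = H on N/O, acceptors =
N/O excluding quaternary N), dipole moment from partial charges about the
centroid (Debye), electron affinity and ionization potential (element-table
proxies — classically uncomputable, flagged `proxy`, and their weights can
be zeroed), globularity (equal-volume-sphere area / SASA, clamped to 1),
SASA (Å²), and vdW volume by lattice occupancy (Å³). Scalar similarities
use min/max with sign-mismatch → 0 and 0/0 → 1, landing on the unit range
with the right endpoints. Atom pairs are Carhart-style typed pairs
(element, heavy-neighbour count, π flag) at topological shortest-path
distances, counted by default, compared by count-Tanimoto
$\sum\min/\sum\max$.

**Hill fits.** Competition-binding dose–response series are fitted as
$R = B + (S-B)/(1+(k_d/D)^{s})$ with the slope fixed (default −1) by
Levenberg–Marquardt least squares on $\log k_d$ (initialized at the
geometric mean dose), co-fitting $B$ and $S$ unless supplied. Noiseless
11-point 3-fold dilution data at $k_d = 100$ nM is recovered to 0.1%;
median recovery under 2% assay noise stays within 10% over 50 replicates.

**Evaluation.** AUC is the rank-based Mann–Whitney form with half-credit
ties. The relative enrichment factor is
$EF_{rel} = n_a / \min(N_{x\%}, n) \times 100$ with top-set size
$\lfloor N x/100 \rfloor$ (minimum 1) — a per-cent of the maximum
achievable early recovery, insensitive to the active/decoy ratio.

## What the synthetic systems emulate — and what they do not

`make_toy_system()` builds the whole statistical situation the method
exploits, without any external data: a cavity lined by two stacked rings of
charged pseudo-atoms (16 atoms, ring radius 6 Å, alternating ±0.4 e), and a
cognate whose balanced ±0.35 e charges are placed *against the solved
ligand-free pocket field* (negative charges at the most positive potential
sites) — electrostatic complementarity by construction, the toy analogue of
a co-crystallized ligand. A neutral central atom keeps the surface
star-shaped for the shape module. Decoy classes reproduce the
charge-decoy idea: `inverted` (identical geometry, negated charges — the
hardest case, indistinguishable by shape or composition), `perturbed`
(jittered geometry, same charges), `scrambled` (jittered geometry,
spatially permuted charges). Actives are small-jitter (σ = 0.1 Å) copies of
the cognate. All randomness flows from one seed; identical seeds give
byte-identical files.

On these systems the electrostatic channel is the only thing separating
inverted decoys from actives, and the package's end-to-end check shows
exactly that: with default weights ≥ 4 of 5 actives rank in the top 10% of
a 50-ligand screen across seeds, and setting $\omega_E = 0$ collapses the
enrichment.

What the toys do **not** emulate: real chemistry (pseudo-atoms are bare
carbons), protein flexibility, desolvation of deeply buried polar groups,
pose-placement error, and decoys property-matched the way curated
benchmarks build them. Passing the fixture checks demonstrates the
machinery and the mechanism, not screening performance on real targets;
absolute energies are not comparable to any reference implementation
(different surface construction, nonpolar model, and charge sets), and
ranking behaviour is the contract.

## Problem sizes and determinism

Defaults keep every stage deterministic: fixed SOR schedule, fixed sphere
point sets and quadrature grids, seeded generators. The test suite solves
the closed-form benchmark on boxes up to 37³ nodes and screens 7–50-ligand
libraries; the acceptance script runs five 50-ligand systems plus the
solver-refinement study, all on one CPU in a few minutes. Larger real
systems scale as one LPBE solve (O(nodes × sweeps)) plus per-ligand
O(protein atoms × ligand atoms) terms.

## Known limitations

* The solute boundary is the vdW surface, not a molecular (SES) surface;
  solvent-probe reentrant volume is honoured only in SASA.
* Protein charges require a user table for real targets; the packaged one
  is minimal.
* EA/IP descriptor proxies are crude element means; zero their weights if
  this matters for a target class.
* The pocket protomol depends on a reach cutoff (5 Å) to exclude bulk
  solvent; very open pockets make the pocket-shape term weakly
  discriminating (it is constant-shifted within one screen either way).
* Scores are ranking devices; no calibration to binding affinity is
  attempted or implied.
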