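---
title: "Delta-learning energy corrections from local density-matrix eigen-descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-learning energy corrections from local density-matrix eigen-descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

High-level correlated wavefunction methods such as CCSD(T) deliver
chemically accurate reaction energetics but scale too steeply to apply
routinely; mean-field baselines (Hartree–Fock, density functionals) are
cheap but miss correlation. `deltaqc` learns the *difference*:

$$ E_H - E_L \;=\; E_\delta \;\approx\; \sum_I F_{\mathrm{NN}}\!\left(d^I \,\middle|\, \omega\right), $$

where $E_L$ is the baseline total energy, $E_H$ the high-level one, and the
correction is a sum of atom-wise neural-network contributions. The per-atom
input $d^I$ is built from the baseline's occupied orbitals
$\{\varphi_i\}$: an identical set of auxiliary Gaussian shells
$\alpha^I_{nlm}$ is centred on every atom $I$, the local density matrix

$$ (D^I_{nl})_{mm'} = \sum_i f_i \,\langle \alpha^I_{nlm} | \varphi_i \rangle \langle \varphi_i | \alpha^I_{nlm'} \rangle $$

is assembled per shell $(n,l)$ with occupation weights $f_i$ (2 for a
closed shell), and its eigenvalues — concatenated over shells in a fixed
order — form $d^I$. Because a rotation of the molecule acts on the magnetic
components $m$ as an orthogonal mixing, the eigenvalues are exactly
invariant under rotations and translations; permutation of atoms permutes
the per-atom rows; and the atom-wise sum makes $E_\delta$ size-consistent
by construction. These three symmetries are the design content of the
descriptor and are verified as properties in the test suite.

When the baseline is Hartree–Fock, $E_\delta$ is the correlation energy and
is strictly negative for closed-shell ground states — a sign property the
fixture labels must, and do, satisfy.

## The engine

No electronic-structure engine is available in this R environment, so the
package carries a self-contained desk-scale one:

* **Integrals** over generalized contracted Cartesian Gaussians via the
  McMurchie–Davidson Hermite expansion (overlap, kinetic, nuclear
  attraction, two-electron repulsion), implemented in C++ through Rcpp.
  The Boys function uses a top-order series with downward recursion below
  $x = 35$ and an erf-based upward recursion above.
* **Baseline**: restricted closed-shell Hartree–Fock with DIIS. Only the
  `hf` baseline is implemented; density-functional baselines would require
  exchange–correlation quadrature machinery that is out of proportion for a
  desk-scale engine, and every acceptance property here is defined against
  the HF baseline. The method name remains a required, validated argument.
* **Reference**: spin-orbital CCSD with perturbative triples, CCSD(T),
  in the same AO basis. CCSD is exact for two-electron systems, which the
  tests exploit by comparing against an independent determinant-enumeration
  FCI oracle (H2 in two bases, He); for water the full-CI oracle bounds the
  CCSD(T) error at a few $10^{-5}$ Hartree.

Shipped AO bases are STO-3G and 6-31G for H, He, C, N, O (the standard
published exponents and contraction coefficients). The default for tests
and fixtures is STO-3G: a correlation-consistent basis with d shells would
make CCSD(T) labelling one to two orders of magnitude slower while changing
nothing about the learning problem's structure; the basis is always an
explicit configuration field, so users with more patience can switch to
6-31G (or extend the table). Coordinates are Angstrom at the interface and
bohr internally (0.52917721092 Å/bohr); energies are Hartree internally and
kcal/mol in reports (627.509474 kcal/mol per Hartree).

## The projection basis

The auxiliary shells are even-tempered: exponents $\zeta_k = b\,r^{k-1}$
(bohr$^{-2}$) for $k = 1..n_l$ at each angular momentum $l$. Defaults:
4 s-shells, 3 p-shells, 2 d-shells with $b = 0.25$, $r = 2.5$, spanning
diffuse ($0.25$) to tight ($3.9$ bohr$^{-2}$) length scales of valence
densities; the per-atom descriptor length is then
$4 + 3\cdot 3 + 2\cdot 5 = 23$. The same shells sit on every atom
regardless of element, giving fixed-length, element-transferable
descriptors. Angular parts are real solid harmonics, so each shell block
is exactly $(2l+1)\times(2l+1)$; every projection function is
L2-normalized numerically before overlaps are taken, making descriptor
magnitudes independent of the exponent scale. Eigenvalues are sorted
descending within each shell block; no eigenvector tie-breaking is needed
because only the values are consumed. Occupation weighting is on by
default (`weighted = FALSE` recovers the bare orbital sum); only orbitals
with occupation above $10^{-6}$ enter.

## The network and training protocol

Per element (H, C, N, O by default; a shared-network flag exists), a fully
connected network with 3 hidden layers of 108 units, GELU activations, and
a linear output whose weights and bias start at zero — an untrained model
therefore reduces exactly to the linear head. Before network training a
ridge-regularized linear head is fitted in closed form on the summed
standardized descriptors; the network learns the residual. The head's
intercept is *per atom* ($b \cdot n_{\mathrm{atoms}}$), not per molecule: a
molecule-level constant would break the strict additivity
$E_\delta(A \cup B) = E_\delta(A) + E_\delta(B)$ that the atom-wise sum
otherwise guarantees, and size consistency is a property we refuse to
trade. Feature standardization statistics (per-feature mean and standard
deviation over all training atoms; zero-variance features get sd 1) are
stored in the checkpoint.

Optimization is Adam with batch size 16, initial learning rate
$3\times10^{-4}$, stepwise exponential decay by a factor 0.96 every 500
epochs (a literal step schedule, not a continuous one), and 15,000 epochs
by default. The checkpoint with the best validation MAE is returned
alongside the final-epoch parameters and a full history (epoch, learning
rate, train loss, validation MAE). Training is deterministic under a fixed
seed. Datasets are split 8:1:1 at *reaction* level — all structures of a
reaction stay together — because structure-level splitting would leak
near-duplicate conformers of the same reaction across splits.

## The synthetic fixture generator

Real benchmark reaction sets (with coupled-cluster reference labels
computed by commercial F12 software) are out of reach of a self-contained
package, so the generator emulates their *structure*: small neutral
closed-shell molecules of H, C, N, O (templates: H2, H2O, NH3, CH4, CO,
N2, HCN, H2CO at standard experimental equilibrium geometries), Gaussian
coordinate perturbations of amplitude $\sigma = 0.05$ Å standing in for
reactant and product geometries, and pseudo-paths of 8 structures that
linearly interpolate the endpoints with a sinusoidal midpoint bulge, the
mid-path structure playing the transition state. A minimum interatomic
distance guard of 0.6 Å rejects collapsed geometries (perturbations are
resampled; path bulges are damped). Labels, when requested, are genuine
engine outputs: $E_L$ from HF and $E_H$ from CCSD(T) per structure.

What these fixtures do **not** emulate: real bond rearrangements (the
"paths" are geometric interpolations, not minimum-energy paths), barrier
heights of chemical magnitude, basis-set completeness, or the diversity of
a 40,000-structure training corpus. Passing tests therefore demonstrate
the correctness and internal consistency of the machinery — symmetries,
oracle equivalence, label signs, learning capacity, and that delta
learning at toy scale recovers most of the HF-to-CCSD(T) gap — not
chemical accuracy on real benchmark sets.

## Numerical choices

* SCF: convergence $10^{-10}$ Hartree on the energy with a DIIS residual
  criterion; symmetric orthogonalization with a $10^{-8}$ overlap
  eigenvalue floor.
* CCSD: amplitude DIIS over stacked $t_1, t_2$, energy convergence
  $10^{-9}$ Hartree; perturbative triples via full $o^3v^3$ arrays
  (adequate at desk scale, 8 GiB covers the largest fixtures comfortably).
* Local density matrices are symmetrized and checked against a $10^{-8}$
  asymmetry tolerance; eigenvalues may dip to $-10^{-10}$ from roundoff
  and are accepted there.
* Ridge strength default $10^{-5}$ on standardized features.
* Degenerate descriptor eigenvalues need no special handling (values only).

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full pipeline on
24–28-reaction fixture sets (72–84 CCSD(T)-labelled structures over H2O,
NH3, CH4, H2CO), train for 1,500–2,500 epochs, and use 200/50 splits for
the function-recovery experiment. These sizes were chosen so the whole
suite exercises every pipeline stage, including training dynamics across
multiple learning-rate plateaus, at desk scale.

## Known limitations

* HF is the only baseline; charged and open-shell species are rejected.
* The engine's AO bases stop at p shells (STO-3G, 6-31G); the projection
  side supports up to d shells.
* No nuclear gradients: descriptors and energies only, so no geometry
  optimization or force training.
* The fixture "transition states" are path maxima of synthetic
  interpolations; forward/reverse barrier conventions follow them.
* Multi-fragment reactants/products are handled by summing fragment
  energies (well-defined because the model is size-consistent), but the
  shipped fixture records always use single structures per role.
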