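---
title: "Methods: anisotropic deformability maps from elastic stiffness tensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anisotropic deformability maps from elastic stiffness tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastmap)
```

## Scope and model

`elastmap` analyses the *linear elastic* response of a molecular crystal,
represented by its 6x6 stiffness matrix **C** in Voigt notation. The model
assumes:

* **Hooke's law** holds: stress is linear in strain,
  $\sigma_{ij} = C_{ijkl}\,\varepsilon_{kl}$. All deformability maps are
  properties of the tensor alone; finite-strain, plastic, or thermal effects
  are out of scope.
* **Voigt convention** with pair order
  $1\!\to\!11,\ 2\!\to\!22,\ 3\!\to\!33,\ 4\!\to\!23,\ 5\!\to\!13,\ 6\!\to\!12$
  and *engineering* shear strain, so the compliance matrix **S** maps to the
  full tensor $S_{ijkl}$ with the usual factors 1, 1/2, 1/4 depending on how
  many of the two Voigt indices refer to shear pairs. Stiffness carries no
  factors.
* Units are whatever the input matrix is in; the package reports GPa in
  labels because that is the conventional unit for molecular crystals.

The input matrix is validated (`validate_stiffness()`): it must be symmetric
to a relative tolerance (default `1e-3`, generous enough for matrices
truncated to a few significant digits, tight enough to catch transposed or
corrupted input) and is then symmetrized exactly as $(C + C^\top)/2$.
Mechanical (Born) stability is the positive definiteness of **C**, checked by
eigendecomposition; Voigt averages $K_V$, $G_V$, $E_V$ follow the standard
closed forms over the matrix elements.

## Directional moduli

The directional Young's modulus and shear modulus are full contractions of
the compliance tensor:

$$\frac{1}{E(\mathbf{u})} = u_i u_j u_k u_l\, S_{ijkl}, \qquad
  \frac{1}{G(\mathbf{u},\mathbf{v})} = 4\, u_i v_j u_k v_l\, S_{ijkl},
  \quad \mathbf{v}\perp\mathbf{u}.$$

Internally both are evaluated as quadratic forms of a 9x9 reshape of
$S_{ijkl}$ ($1/E = \mathbf{w}^\top M \mathbf{w}$ with
$\mathbf{w} = \mathrm{vec}(\mathbf{u}\mathbf{u}^\top)$), which vectorizes
over thousands of directions at once in plain R. Correctness is pinned by an
independent oracle in the test suite: rotating the full tensor with
$T'_{ijkl} = R_{ia}R_{jb}R_{kc}R_{ld}T_{abcd}$ so that **u** becomes the new
x-axis must reproduce $1/E(\mathbf{u}) = S'_{1111}$ and
$1/G(\mathbf{u},\mathbf{v}) = 1/(4S'_{1212})$, and does so to below
$10^{-9}$ GPa over hundreds of random stable tensors.

### Global extrema

`global_extrema()` finds $E_{\min}, E_{\max}$ (and for shear the extrema
over both **u** and the transverse direction **v**):

1. **Seeding**: directions are taken from an icosphere subdivision
   (12, 42, 162, 642, 2562 vertices). Unlike latitude-longitude grids, the
   icosphere samples the sphere nearly uniformly with no polar clustering,
   and it is fully deterministic. The default `n_seed = 2562` resolves
   modulus surfaces of low-symmetry (triclinic) tensors; 162 suffices for
   high-symmetry cases.
2. **Transverse scan** (shear only): for each **u**, $G$ is scanned over the
   transverse angle $\chi$ on `n_chi = 72` points (5 degree spacing; the
   $\chi$-dependence is a smooth trigonometric polynomial of low order, so
   72 points cannot miss a lobe) and each grid optimum is refined with
   Brent's method (`stats::optimize`, tolerance `1e-7`).
3. **Refinement**: up to 6 seed candidates, kept at least 0.15 rad apart so
   they represent distinct basins, are polished with Nelder-Mead over
   spherical angles (relative tolerance `1e-14`). Shear refines jointly over
   $(\theta, \phi, \chi)$.

The anisotropy index is the ratio $A_X = X_{\max}/X_{\min}$; an isotropic
tensor gives exactly 1 and any deviation from 1 is a direct, dimensionless
measure of directionality.

`sphere_map()` exports the full surface on a $\theta \times 2\theta$ grid
for plotting; `plane_slice()` evaluates a property on a crystallographic
plane (*ab*, *ac*, *bc*, or a general (hkl)) in the Cartesian frame of the
cell, which is where packing motifs such as hydrogen-bonded tapes or sheets
live.

## Crystal frames and contacts

`crystal_cell()`/`cell_to_cartesian()` use the standard crystallographic
convention **a** along x, **b** in the xy-plane (positive y), **c**
completing a right-handed set; rows of the resulting matrix are the lattice
vectors and `cart = frac %*% A`. `read_cif()` is a minimal reader for
small-molecule CIF files (cell tags, atom-site loop, symmetry operations
applied and deduplicated); it does not attempt the full CIF grammar.

`detect_contacts()` finds D-H...A hydrogen bonds under periodic boundary
conditions with the conventional geometric criteria: donor elements
{N, O, C}, acceptor elements {N, O}, covalent D-H within 1.25 A,
H...A $\le$ 2.7 A and D-H...A angle $\ge$ 120 degrees. The number of
periodic images searched in each direction is derived from the perpendicular
cell heights so skewed cells are handled correctly. `alignment_report()`
then folds contact directions to a hemisphere, takes the principal axis of
their second-moment matrix per contact class, and reports the angle (0-90
degrees) between that axis and the stiffest direction $E_{\max}$ — the
quantitative version of "the crystal is stiffest along the hydrogen-bonded
chains".

## Elastic-constant extraction from stress-strain series

`fit_constants()` recovers **C** column-by-column from uniaxial strain
patterns. A pattern with Voigt component $k$ and amplitude $a$ means the
physical strain tensor has $\varepsilon_{kk} = a$ (normal) or
$2\varepsilon_{ij} = a$ (shear, engineering convention), so the OLS slope of
each stress component $\sigma_i$ against $a$ is $C_{ik}$ directly.

Defaults and their rationale:

* **Amplitudes**: `n_points = 12` symmetric values
  $\pm\{1,3,\dots,11\}/11 \times a_{\max}$ with `max_amplitude = 0.003`.
  The symmetric design cancels even-order anharmonic contamination in the
  slope; 0.3% strain is small enough that cubic terms are negligible for
  typical molecular-crystal stiffnesses yet large enough that realistic
  stress noise does not dominate. `apply_strain()` refuses strains beyond
  20%, far outside the linear regime.
* **Standard errors**: the synthetic oracle adds i.i.d. noise of a single
  standard deviation to every stress component, so the residual variance is
  pooled across the six per-series regressions (66 degrees of freedom for
  the default design instead of 11 per component). Under the homoscedastic
  contract this is the statistically correct estimator; with only 11 dof the
  per-component variance estimate is noisy enough to visibly degrade
  3-sigma coverage.
* **Laue classes**: `class_tie_labels()` encodes the independent-constant
  pattern for triclinic (21), monoclinic 2/m unique-b (13), orthorhombic
  (9), tetragonal (6), cubic (3) and isotropic (2, with
  $C_{44} = (C_{11}-C_{12})/2$ enforced). Higher-symmetry classes need
  fewer strain patterns ({1,3,4,6} for tetragonal, {1,4} for cubic, {1} for
  isotropic); entries never probed are completed from their symmetry
  tie-mates, and measured entries are reported as measured so that symmetry
  violations in the data remain visible (`max_asymmetry`).

### The synthetic oracle

`synthetic_oracle()` stands in for an ab initio stress calculation:
$\sigma = C\!:\!\varepsilon + \gamma \lVert\varepsilon\rVert \varepsilon +
\mathcal{N}(0, \text{noise\_sd}^2)$. The $\gamma$ term mimics leading
anharmonicity (odd in strain, so it biases slopes and shrinks with
amplitude, which the tests verify). The oracle keeps a private RNG stream:
replaying the same evaluation sequence is bit-identical and the global
`.Random.seed` is never touched. It does **not** emulate relaxation of
internal coordinates, k-point/basis convergence noise (which is not i.i.d.),
or symmetry breaking of the reference cell.

`random_stable_stiffness()` draws class-constrained matrices uniformly with
a diagonal bias and rejects until Born-stable; it is a test-bed generator,
not a sampler of physically representative crystals. `urea_like_structure()`
is a hand-built two-molecule tape motif in a tetragonal cell whose two
N-H...O contacts (H...A = 1.90 A, angle = 165 degrees, one crossing the cell
boundary along **c**) are known analytically and shipped as
`contacts_truth` — a fixture for the contact detector, not a real crystal
structure.

## Problem sizes and cost

All numerics are pure R. Representative timings on one CPU: a full
`analyze_stiffness()` report with 2562-direction Young and shear extrema,
three plane slices and contact detection runs in a few seconds; the complete
test suite (about 900 assertions, including 60-replicate coverage studies)
runs in ~15 s.

## Limitations

* Linear elasticity only; no third-order constants, no temperature or
  pressure dependence.
* The CIF reader handles routine small-molecule files, not the full
  standard (no ADPs, no disorder assemblies, no multi-block files).
* Contact detection is geometric; it does not distinguish hydrogen bonds
  from close contacts energetically.
* `fit_constants()` assumes the strain patterns are the package's own
  uniaxial designs; arbitrary mixed-strain designs are not supported.
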