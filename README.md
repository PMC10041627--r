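# elastmap

Anisotropic deformability maps from elastic stiffness tensors of molecular
crystals.

Molecular crystals — pharmaceutical solids above all — deform very unevenly:
a crystal held together by hydrogen-bonded tapes is stiff along the tapes
and soft across them, and that directionality controls tabletability,
cleavage and polymorph behaviour. All of it is encoded in the 6x6 elastic
stiffness matrix **C** (Voigt notation, GPa). `elastmap` turns such a matrix
into quantitative deformability maps and connects them back to the packing
motifs of the structure.

## What it computes

Given a stiffness matrix **C** and its compliance **S** = **C**⁻¹:

* **Tensor algebra** — validation and symmetrization, stiffness/compliance
  inversion with condition-number guard, Voigt ↔ full rank-4 tensor
  conversion (engineering-strain factors 1, 1/2, 1/4 on compliance), exact
  tensor rotation, Born (mechanical) stability, Voigt-average moduli

  K_V = (C₁₁+C₂₂+C₃₃+2(C₁₂+C₁₃+C₂₃))/9,  G_V, and E_V = 9K_V G_V/(3K_V+G_V).

* **Directional moduli** — Young's modulus along a direction **u** and shear
  modulus for a plane/direction pair (**u**, **v**), **v** ⊥ **u**:

      1/E(u)   = u_i u_j u_k u_l S_ijkl
      1/G(u,v) = 4 u_i v_j u_k v_l S_ijkl

  with global extrema over the sphere (icosphere seeding + Nelder–Mead /
  Brent refinement), anisotropy indices A_E = E_max/E_min and
  A_G = G_max/G_min, full sphere maps, and slices through crystallographic
  planes (*ab*, *ac*, *bc*, general (hkl)).

* **Elastic-constant extraction** — uniaxial strain patterns per Laue class
  (triclinic 21 constants … cubic 3, isotropic 2), a synthetic stress oracle
  (Hooke + optional anharmonic bias + seeded noise) standing in for an
  ab initio code, and OLS recovery of **C** with pooled standard errors and
  a symmetry-violation diagnostic.

* **Crystal frames and contacts** — cell → Cartesian conversion (**a**
  along x convention), a minimal CIF reader/writer, periodic D–H...A
  hydrogen-bond detection (H...A ≤ 2.7 Å, angle ≥ 120°), and alignment
  reports measuring the angle between contact-network axes and the stiffest
  direction of the crystal.

* **Reporting and CLI** — one-call `analyze_stiffness()` reports, JSON/CSV
  export, and a thin command-line front end in `inst/cli/elastmap.R`.

## Worked example

A tape-like tetragonal crystal, stiff along **c**, together with the
built-in toy hydrogen-bonded structure:

```r
library(elastmap)

C <- matrix(0, 6, 6)
C[1,1] <- C[2,2] <- 10; C[3,3] <- 30
C[1,2] <- C[2,1] <- 5
C[1,3] <- C[3,1] <- C[2,3] <- C[3,2] <- 5
diag(C)[4:5] <- 4; C[6,6] <- 3
C <- validate_stiffness(C, source_label = "tape-like tetragonal")

born_stability(C)
#> Born stability: stable
#> eigenvalues (GPa): 3, 4, 4, 5, 12.192, 32.808

voigt_averages(C)
#> Voigt averages: K_V = 8.889  G_V = 4.533  E_V = 11.62 GPa

S <- invert_to_compliance(C)
young_modulus(S, c(0, 0, 1))        # stiff along the tape axis
#> [1] 26.66667

ext <- global_extrema(S, "young")
ext
#> young modulus extrema: min 7.273 GPa at (6.123e-17, 1, 6.123e-17), max 26.67 GPa at (0, 0, 1)
anisotropy_index(ext)
#> [1] 3.666667
```

The toy structure carries two N–H...O contacts running (on average) along
**c**; the full report ties the elastic map to them:

```r
toy <- urea_like_structure()
rep <- analyze_stiffness(C, cell = toy$cell, sites = toy$sites)
print(rep)
#> Deformability report - tape-like tetragonal
#>   G_V = 4.533 GPa  E_V = 11.62 GPa  (K_V = 8.889 GPa)
#>   E: 7.273 .. 26.67 GPa  A_E = 3.667
#>   G: 2.5 .. 5.455 GPa  A_G = 2.182

rep$alignment$classes
#>     class n mean_axis_x mean_axis_y mean_axis_z angle_to_Emax_deg min_angle_deg
#> 1 N-H...O 2           0 2.57528e-17           1                 0      20.12336
```

The principal axis of the hydrogen-bond network coincides with the
E-maximum direction (0° misalignment): the crystal is stiffest along its
tapes. `write_report_json()` exports the report plus per-plane slice CSVs,
and `fit_and_analyze()` runs the whole chain starting from a stress oracle
instead of a known matrix.

See the methods vignette
(`vignettes/anisotropic-deformability.Rmd`) for model assumptions,
parameter defaults and numerical choices.

## License

MIT (see `LICENSE`).
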