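# Directional moduli, extrema, anisotropy indices, surface sampling.

test_that("Young's modulus reproduces isotropic and cubic closed forms", {
  Si <- invert_to_compliance(iso_example())
  expect_equal(young_modulus(Si, c(1, 0, 0)), 10, tolerance = 1e-12)
  expect_equal(young_modulus(Si, random_unit(3)), 10, tolerance = 1e-12)

  S <- invert_to_compliance(cubic_example())
  expect_equal(young_modulus(S, c(1, 0, 0)), 10, tolerance = 1e-9)
  # 1/E<111> = S11 - 2 (S11 - S12 - S44/2) / 3
  expect_equal(young_modulus(S, c(1, 1, 1) / sqrt(3)),
               1 / (0.1 - 2 * (0.1 - (-0.025) - (1 / 3) / 2) / 3),
               tolerance = 1e-12)
  expect_equal(young_modulus(S, c(1, 1, 1) / sqrt(3)), 7.826087,
               tolerance = 1e-6)

  expect_error(young_modulus(S, c(1, 1, 0)), "unit")
})

test_that("shear modulus reproduces closed forms and is u/v symmetric", {
  Si <- invert_to_compliance(iso_example())
  u <- random_unit(4)
  B <- elastmap:::perp_basis(u)
  expect_equal(shear_modulus(Si, u, B[, 1]), 4, tolerance = 1e-12)

  S <- invert_to_compliance(cubic_example())
  expect_equal(shear_modulus(S, c(0, 0, 1), c(1, 0, 0)), 3, tolerance = 1e-12)
  h <- 1 / sqrt(2)
  expect_equal(shear_modulus(S, c(h, h, 0), c(-h, h, 0)), 4,
               tolerance = 1e-12)

  for (seed in 1:10) {
    C <- random_stable_stiffness("triclinic", seed = seed)
    Sx <- invert_to_compliance(C)
    u <- random_unit(seed + 30)
    B <- elastmap:::perp_basis(u)
    v <- B[, 1]
    expect_equal(shear_modulus(Sx, u, v), shear_modulus(Sx, v, u),
                 tolerance = 1e-12)
  }
  expect_error(shear_modulus(S, c(1, 0, 0), c(1, 0, 0)), "orthogonal")
})

test_that("contraction agrees with the rotate-and-read oracle", {
  for (seed in 1:10) {
    C <- random_stable_stiffness("triclinic", seed = seed)
    S <- invert_to_compliance(C)
    Sf <- voigt_to_full(S)
    for (k in 1:3) {
      u <- random_unit(100 * seed + k)
      B <- elastmap:::perp_basis(u)
      R <- rbind(u, B[, 1], B[, 2])   # maps x -> u, y -> v
      if (det(R) < 0) R[3, ] <- -R[3, ]
      Sr <- rotate_full(Sf, R)
      expect_equal(young_modulus(S, u), 1 / Sr[1, 1, 1, 1],
                   tolerance = 1e-9)
      expect_equal(shear_modulus(S, u, B[, 1]), 1 / (4 * Sr[1, 2, 1, 2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("shear extrema over v: isotropic flat, cubic constant at u=001", {
  Si <- invert_to_compliance(iso_example())
  se <- shear_extrema_over_v(Si, random_unit(9))
  expect_equal(se$G_min, 4, tolerance = 1e-9)
  expect_equal(se$G_max, 4, tolerance = 1e-9)
  expect_equal(se$G_avg, 4, tolerance = 1e-9)

  # cubic, u along a crystal axis: 1/G = v1^2 S55 + v2^2 S44 = S44 for all v,
  # so the modulus is constant at 1/S44 = 3 GPa over the whole v circle
  S <- invert_to_compliance(cubic_example())
  se <- shear_extrema_over_v(S, c(0, 0, 1))
  expect_equal(se$G_min, 3, tolerance = 1e-9)
  expect_equal(se$G_max, 3, tolerance = 1e-9)

  # the 4 GPa extreme lives at u = [110]: G ranges over [3, 4] there
  h <- 1 / sqrt(2)
  se2 <- shear_extrema_over_v(S, c(h, h, 0))
  expect_equal(se2$G_min, 3, tolerance = 1e-6)
  expect_equal(se2$G_max, 4, tolerance = 1e-6)
})

test_that("chi refinement matches a dense 1e5-point scan", {
  for (seed in c(2, 12)) {
    C <- random_stable_stiffness("triclinic", seed = seed)
    S <- invert_to_compliance(C)
    M <- elastmap:::compliance_quad(S)
    u <- random_unit(seed + 60)
    B <- elastmap:::perp_basis(u)
    chi_dense <- seq(0, pi, length.out = 1e5)
    g <- elastmap:::shear_values_chi(M, u, B, chi_dense)
    se <- shear_extrema_over_v(S, u)
    expect_equal(se$G_min, min(g), tolerance = 1e-6)
    expect_equal(se$G_max, max(g), tolerance = 1e-6)
  }
})

test_that("global extrema find the cubic <100>/<111> directions", {
  S <- invert_to_compliance(cubic_example())
  ext <- global_extrema(S, "young")
  expect_equal(ext$max_value, 10, tolerance = 1e-6)
  expect_equal(ext$min_value, 7.826087, tolerance = 1e-5)
  # max along a <100> axis, min along a <111> diagonal
  expect_lt(min(acos(pmin(1, abs(ext$max_direction))) * 180 / pi), 0.1)
  expect_equal(sort(abs(ext$min_direction)), rep(1 / sqrt(3), 3),
               tolerance = 1e-4)

  extG <- global_extrema(S, "shear", n_seed = 642)
  expect_equal(extG$min_value, 3, tolerance = 1e-6)
  expect_equal(extG$max_value, 4, tolerance = 1e-6)

  iso <- global_extrema(invert_to_compliance(iso_example()), "young",
                        n_seed = 162)
  expect_equal(iso$min_value, 10, tolerance = 1e-9)
  expect_equal(iso$max_value, 10, tolerance = 1e-9)
})

test_that("global extrema are frame-independent", {
  C <- random_stable_stiffness("monoclinic", seed = 21)
  S <- invert_to_compliance(C)
  ext <- global_extrema(S, "young")
  R <- random_rotation(99)
  Crot <- validate_stiffness(
    full_to_voigt(rotate_full(voigt_to_full(C), R), "stiffness"),
    tolerance = 1e-6)
  ext_rot <- global_extrema(invert_to_compliance(Crot), "young")
  expect_equal(ext_rot$min_value, ext$min_value, tolerance = 1e-6)
  expect_equal(ext_rot$max_value, ext$max_value, tolerance = 1e-6)
})

test_that("anisotropy index is max/min, 1 for isotropic, always >= 1", {
  iso_ext <- global_extrema(invert_to_compliance(iso_example()), "young",
                            n_seed = 162)
  expect_equal(anisotropy_index(iso_ext), 1, tolerance = 1e-9)
  iso_sh <- global_extrema(invert_to_compliance(iso_example()), "shear",
                           n_seed = 162)
  expect_equal(anisotropy_index(iso_sh), 1, tolerance = 1e-9)

  cub <- global_extrema(invert_to_compliance(cubic_example()), "young")
  expect_equal(anisotropy_index(cub), 10 / 7.826087, tolerance = 1e-5)

  for (seed in 1:5) {
    ext <- global_extrema(
      invert_to_compliance(random_stable_stiffness("triclinic", seed = seed)),
      "young", n_seed = 162)
    expect_gte(anisotropy_index(ext), 1)
  }
  expect_error(anisotropy_index(list(min_value = -1, max_value = 2)),
               "marginally stable")
})

test_that("sphere map is antipodally symmetric and bounded by the extrema", {
  Si <- invert_to_compliance(iso_example())
  sm <- sphere_map(Si, "young", resolution = 16)
  expect_equal(range(sm$value), c(10, 10), tolerance = 1e-9)

  C <- random_stable_stiffness("triclinic", seed = 14)
  S <- invert_to_compliance(C)
  M <- elastmap:::compliance_quad(S)
  for (seed in 41:45) {
    u <- random_unit(seed)
    expect_equal(1 / sum(as.vector(outer(u, u)) *
                           (M %*% as.vector(outer(u, u)))),
                 young_modulus(S, -u), tolerance = 1e-12)
  }

  sm <- sphere_map(S, "young", resolution = 24)
  ext <- global_extrema(S, "young")
  expect_lte(max(sm$value), ext$max_value + 1e-9)
  expect_gte(min(sm$value), ext$min_value - 1e-9)
  # the grid approaches the optimizer extrema as resolution grows
  sm2 <- sphere_map(S, "young", resolution = 64)
  expect_lt(ext$max_value - max(sm2$value), ext$max_value - max(sm$value) + 1e-9)
  expect_gt(all(sm$value > 0), 0)
})

test_that("E is azimuthally invariant for transversely isotropic tensors", {
  S <- invert_to_compliance(hexagonal_example())
  for (theta in c(0.3, 0.9, 1.4)) {
    vals <- vapply(seq(0, 2 * pi, length.out = 17), function(phi)
      young_modulus(S, c(sin(theta) * cos(phi), sin(theta) * sin(phi),
                         cos(theta))), numeric(1))
    expect_lt(diff(range(vals)), 1e-9)
  }
})
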