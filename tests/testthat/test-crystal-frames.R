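# Lattice frames, plane slices, contact detection, alignment.

test_that("cell_to_cartesian follows the a||x, b-in-xy convention", {
  A <- cell_to_cartesian(crystal_cell(10, 10, 10))
  expect_equal(A, diag(3) * 10)

  A <- cell_to_cartesian(crystal_cell(10, 10, 10, beta = 95))
  expect_equal(A[3, ], c(10 * cos(95 * pi / 180), 0, 10 * sin(95 * pi / 180)))
  expect_equal(A[2, ], c(0, 10, 0))

  cell <- crystal_cell(6.2, 7.1, 9.3, alpha = 80, beta = 100, gamma = 95)
  A <- cell_to_cartesian(cell)
  cosd <- function(x) cos(x * pi / 180)
  vol <- 6.2 * 7.1 * 9.3 * sqrt(1 - cosd(80)^2 - cosd(100)^2 - cosd(95)^2 +
                                  2 * cosd(80) * cosd(100) * cosd(95))
  expect_equal(det(A), vol, tolerance = 1e-10)
  expect_gt(A[2, 2], 0)
  expect_error(crystal_cell(10, 10, 10, alpha = 1, beta = 1, gamma = 178),
               "degenerate|positive definite")
})

test_that("plane slices: isotropic circle, tetragonal 4-fold cross", {
  cell <- crystal_cell(5, 5, 5)
  Si <- invert_to_compliance(iso_example())
  sl <- plane_slice(Si, cell, "ab", "young", n_angles = 72)
  expect_equal(range(sl$value), c(10, 10), tolerance = 1e-9)

  # tetragonal tensor, ab plane: value(theta) = value(theta + pi/2)
  St <- invert_to_compliance(fibrous_example())
  sl <- plane_slice(St, crystal_cell(6, 6, 4.8), "ab", "young",
                    n_angles = 360)
  v <- sl$value
  expect_lt(max(abs(v - v[((seq_along(v) - 1 + 90) %% 360) + 1])), 1e-9)
  # pi periodicity (antipodal symmetry in the plane)
  expect_lt(max(abs(v - v[((seq_along(v) - 1 + 180) %% 360) + 1])), 1e-9)
  # but genuinely phi-dependent: the cross shape has lobes
  expect_gt(diff(range(v)), 0.1)

  expect_error(plane_slice(Si, crystal_cell(5, 5, 5, gamma = 179.99999),
                           "ab"), "parallel|degenerate")
})

test_that("orthorhombic in-plane frames equal the normalized lattice vectors", {
  cell <- crystal_cell(4, 6, 8)
  S <- invert_to_compliance(random_stable_stiffness("orthorhombic", seed = 2))
  fr <- attr(plane_slice(S, cell, "bc", "young", n_angles = 36), "frame")
  expect_equal(fr["e1", ], c(0, 1, 0))
  expect_equal(fr["e2", ], c(0, 0, 1))
})

test_that("slice values are invariant under plane axis relabeling", {
  cell <- crystal_cell(6.2, 7.1, 9.3, alpha = 80, beta = 100, gamma = 95)
  S <- invert_to_compliance(random_stable_stiffness("triclinic", seed = 8))
  sl <- plane_slice(S, cell, "ac", "young", n_angles = 360)
  # ca frame: e1' = c/|c|, lies in the same plane; the value set must match
  A <- cell_to_cartesian(cell)
  e1 <- A[3, ] / sqrt(sum(A[3, ]^2))
  raw2 <- A[1, ]; e2 <- raw2 - sum(raw2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  M <- elastmap:::compliance_quad(S)
  theta <- sl$theta
  U <- outer(e1, cos(theta)) + outer(e2, sin(theta))
  v2 <- elastmap:::young_values_quad(M, U)
  expect_equal(sort(round(v2, 9)), sort(round(sl$value, 9)), tolerance = 1e-7)
})

test_that("contact detection applies the distance and angle rules", {
  cell <- crystal_cell(20, 20, 20)   # big box: no periodic interference
  mk <- function(h_z, o_z) data.frame(
    element = c("N", "H", "O"),
    x = c(0.5, 0.5, 0.5), y = c(0.5, 0.5, 0.5),
    z = c(0.40, h_z, o_z),
    site_label = c("N1", "H1", "O1"), stringsAsFactors = FALSE)
  # N-H...O at d_HA = 1.9 A, angle 180 deg
  sites <- mk(0.45, 0.45 + 1.9 / 20)
  ct <- detect_contacts(sites, cell)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$d_HA, 1.9, tolerance = 1e-9)
  expect_equal(ct$angle_DHA, 180, tolerance = 1e-9)

  # same distance but angle 90 deg: H equidistant sideways
  sites <- data.frame(
    element = c("N", "H", "O"),
    x = c(0.5, 0.5, 0.5 + 1.9 / 20),
    y = c(0.5, 0.5, 0.5),
    z = c(0.45, 0.5, 0.5),
    site_label = c("N1", "H1", "O1"), stringsAsFactors = FALSE)
  ct <- detect_contacts(sites, cell)
  expect_equal(nrow(ct), 0)

  expect_error(detect_contacts(sites[sites$element != "H", ], cell),
               "hydrogen")
})

test_that("the toy tape structure reproduces its shipped ground truth", {
  toy <- urea_like_structure()
  ct <- detect_contacts(toy$sites, toy$cell)
  truth <- toy$contacts_truth
  expect_equal(nrow(ct), nrow(truth))
  ct <- ct[order(ct$donor_label), ]
  truth <- truth[order(truth$donor_label), ]
  expect_equal(ct$donor_label, truth$donor_label)
  expect_equal(ct$acceptor_label, truth$acceptor_label)
  expect_equal(ct$d_HA, truth$d_HA, tolerance = 1e-9)
  expect_equal(ct$angle_DHA, truth$angle_DHA, tolerance = 1e-9)
  expect_equal(ct[, c("shift_a", "shift_b", "shift_c")],
               truth[, c("shift_a", "shift_b", "shift_c")],
               ignore_attr = TRUE)
  # every N-H...O direction within 30 degrees of the c axis
  dirs <- as.matrix(ct[, c("dir_x", "dir_y", "dir_z")])
  ang_c <- acos(abs(dirs[, 3])) * 180 / pi
  expect_true(all(ang_c < 30))
})

test_that("contact detection is invariant under lattice translation", {
  toy <- urea_like_structure()
  ct0 <- detect_contacts(toy$sites, toy$cell)
  shifted <- toy$sites
  shifted$x <- (shifted$x + 0.37) %% 1
  shifted$y <- (shifted$y + 0.81) %% 1
  shifted$z <- (shifted$z + 1.00) %% 1
  ct1 <- detect_contacts(shifted, toy$cell)
  key <- function(ct) sort(paste(round(ct$d_HA, 9), round(ct$angle_DHA, 9)))
  expect_equal(key(ct1), key(ct0))
})

test_that("alignment angles fold into [0, 90] and hit the constructed values", {
  contacts_along <- function(dir) data.frame(
    donor_label = "N1", hydrogen_label = "H1", acceptor_label = "O1",
    donor_element = "N", acceptor_element = "O",
    d_HA = 1.9, d_DA = 2.9, angle_DHA = 170,
    shift_a = 0L, shift_b = 0L, shift_c = 0L,
    dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
    stringsAsFactors = FALSE)
  ext_z <- list(max_direction = c(0, 0, 1), min_direction = c(1, 0, 0),
                max_value = 30, min_value = 10, property = "young")
  rep <- alignment_report(ext_z, contacts_along(c(0, 0, 1)))
  expect_equal(rep$classes$angle_to_Emax_deg, 0, tolerance = 1e-9)

  rep <- alignment_report(ext_z, contacts_along(c(1, 0, 0)))
  expect_equal(rep$classes$angle_to_Emax_deg, 90, tolerance = 1e-9)

  # antipodal folding: -z counts as z
  rep <- alignment_report(ext_z, contacts_along(c(0, 0, -1)))
  expect_equal(rep$classes$angle_to_Emax_deg, 0, tolerance = 1e-9)

  expect_error(alignment_report(ext_z, data.frame()), "empty")
})

test_that("fibrous tensor + tape contacts align within 10 degrees", {
  toy <- urea_like_structure()
  ct <- detect_contacts(toy$sites, toy$cell)
  S <- invert_to_compliance(fibrous_example())
  ext <- global_extrema(S, "young", n_seed = 642)
  rep <- alignment_report(ext, ct)
  expect_lte(rep$classes$angle_to_Emax_deg, 10)
  expect_true(all(rep$classes$angle_to_Emax_deg >= 0 &
                    rep$classes$angle_to_Emax_deg <= 90))
})
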