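# Synthetic stiffness tensors and toy crystal structures with known
# contact geometry: the test bed standing in for ab initio outputs.

#' Isotropic stiffness tensor from engineering constants
#'
#' Builds the Voigt stiffness of an isotropic medium from Young's modulus and
#' Poisson's ratio via the Lame constants: C11 = lambda + 2 mu, C12 = lambda,
#' C44 = mu with lambda = E nu / ((1 + nu)(1 - 2 nu)), mu = E / (2 (1 + nu)).
#'
#' @param E Young's modulus in GPa, positive.
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return a \code{voigt_stiffness}.
#' @examples
#' isotropic_stiffness(10, 0.25)  # C11 = 12, C12 = 4, C44 = 4
#' @export
isotropic_stiffness <- function(E, nu) {
  stopifnot(E > 0)
  if (nu <= -1 || nu >= 0.5)
    stop("Poisson's ratio must lie in (-1, 0.5)")
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lambda
  diag(C)[1:3] <- lambda + 2 * mu
  diag(C)[4:6] <- mu
  validate_stiffness(C, source_label = sprintf("isotropic E=%g nu=%g", E, nu))
}

#' Symmetry class specification for stiffness generation
#'
#' Returns the independent-coefficient positions and equality ties of a Laue
#' class, in the conventional crystallographic setting (tetragonal unique axis
#' c, monoclinic unique axis b).
#'
#' @param laue_class class name as in \code{\link{generate_patterns}}.
#' @return list of class \code{symmetry_class_spec}: \code{laue_class},
#'   \code{labels} (6x6 integer tie matrix, 0 = structural zero),
#'   \code{independent} (data.frame of representative (i, j) positions).
#' @export
symmetry_class_spec <- function(laue_class) {
  laue_class <- match.arg(laue_class, .laue_classes)
  L <- class_tie_labels(laue_class)
  reps <- do.call(rbind, lapply(sort(unique(L[L > 0])), function(lab) {
    ij <- which(L == lab & upper.tri(L, diag = TRUE), arr.ind = TRUE)
    data.frame(label = lab, i = ij[1, 1], j = ij[1, 2])
  }))
  structure(list(laue_class = laue_class, labels = L, independent = reps),
            class = "symmetry_class_spec")
}

#' Random Born-stable stiffness tensor of a given symmetry class
#'
#' Draws each independent coefficient from a seeded uniform distribution at
#' the given scale, adds a diagonal bias of one scale unit to make stability
#' rejection rare, and redraws until the matrix is Born-stable. The generated
#' tensor satisfies its class's equality pattern exactly and is bit-identical
#' under the same seed.
#'
#' @param spec a \code{symmetry_class_spec} or a class name.
#' @param scale coefficient scale in GPa. Default 10.
#' @param seed integer seed.
#' @param max_tries rejection limit. Default 1000.
#' @return a Born-stable \code{voigt_stiffness}.
#' @export
random_stable_stiffness <- function(spec, scale = 10, seed = 1L,
                                    max_tries = 1000) {
  if (is.character(spec)) spec <- symmetry_class_spec(spec)
  stopifnot(inherits(spec, "symmetry_class_spec"), scale > 0)
  L <- spec$labels
  with_preserved_rng({
    set.seed(seed)
    for (try in seq_len(max_tries)) {
      C <- matrix(0, 6, 6)
      for (r in seq_len(nrow(spec$independent))) {
        lab <- spec$independent$label[r]
        i <- spec$independent$i[r]; j <- spec$independent$j[r]
        v <- stats::runif(1, -scale / 2, scale / 2)
        if (i == j) v <- v + scale   # diagonal bias favours stability
        C[L == lab] <- v
      }
      if (spec$laue_class == "isotropic")
        diag(C)[4:6] <- (C[1, 1] - C[1, 2]) / 2
      if (born_stability(C)$stable)
        return(validate_stiffness(
          C, source_label = sprintf("random %s seed=%d", spec$laue_class,
                                    seed)))
    }
    stop("no stable tensor after ", max_tries,
         " draws; increase the diagonal bias or scale")
  })
}

#' Toy hydrogen-bonded tape structure
#'
#' A tetragonal toy cell holding two planar four-atom "molecules" (C, O, N, H)
#' stacked head-to-tail in columns along c, so that every N-H...O hydrogen
#' bond runs within a few degrees of the c axis (d_HA about 1.9 Angstrom,
#' D-H...A angle about 172 degrees). One of the two contacts crosses the cell
#' boundary, exercising periodic-image handling. This mimics the
#' head-to-tail tape motif of hydrogen-bonded molecular crystals such as urea;
#' it is a synthetic fixture, not a real structure.
#'
#' @return list with \code{cell} (a \code{crystal_cell}), \code{sites}
#'   (data.frame: element, x, y, z fractional, site_label), and
#'   \code{contacts_truth} (data.frame of the ground-truth N-H...O contacts:
#'   donor/hydrogen/acceptor labels, d_HA, d_DA, angle_DHA, image shift,
#'   Cartesian donor-to-acceptor direction).
#' @export
urea_like_structure <- function() {
  a <- 6.0; c_len <- 4.8
  cell <- crystal_cell(a, a, c_len, 90, 90, 90)
  # Cartesian site positions (orthogonal cell, so frac = cart / lengths).
  # Each acceptor O sits 1.9 A from the H of the molecule below, placed by
  # rotating the N-H direction by 15 deg in the xz plane, so d_HA = 1.9 and
  # the D-H...A angle is exactly 165 deg; the N->O directions end up about
  # 20 deg off the c axis.
  n1 <- c(1.50, 1.50, 0.53); h1 <- c(1.68, 1.50, 1.52)
  n2 <- c(4.50, 4.50, 3.30); h2 <- c(4.32, 4.50, 4.29)
  place_acceptor <- function(n, h, tilt_deg) {
    w <- h - n
    aw <- atan2(w[1], w[3]) + tilt_deg * pi / 180
    h + 1.9 * c(sin(aw), 0, cos(aw))
  }
  o1 <- place_acceptor(n1, h1, 15)
  o2 <- place_acceptor(n2, h2, -15)
  o2[3] <- o2[3] - c_len          # wrap into the cell; contact image (0,0,1)
  cart <- rbind(
    C1 = c(1.50, 2.90, 0.50),
    N1 = n1, H1 = h1, O1 = o1,
    C2 = c(4.50, 3.10, 3.30),
    N2 = n2, H2 = h2, O2 = o2)
  frac <- sweep(cart, 2, c(a, a, c_len), "/")
  sites <- data.frame(
    element = c("C", "N", "H", "O", "C", "N", "H", "O"),
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    site_label = rownames(cart), stringsAsFactors = FALSE)
  geom <- function(D, H, A) {
    d_HA <- sqrt(sum((A - H)^2)); d_DA <- sqrt(sum((A - D)^2))
    hd <- D - H; ha <- A - H
    ang <- acos(sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))) * 180 / pi
    dir <- (A - D) / d_DA
    c(d_HA = d_HA, d_DA = d_DA, angle_DHA = ang, dir)
  }
  g1 <- geom(cart["N1", ], cart["H1", ], cart["O1", ])
  g2 <- geom(cart["N2", ], cart["H2", ], cart["O2", ] + c(0, 0, c_len))
  contacts_truth <- data.frame(
    donor_label = c("N1", "N2"), hydrogen_label = c("H1", "H2"),
    acceptor_label = c("O1", "O2"),
    d_HA = c(g1["d_HA"], g2["d_HA"]),
    d_DA = c(g1["d_DA"], g2["d_DA"]),
    angle_DHA = c(g1["angle_DHA"], g2["angle_DHA"]),
    shift_a = c(0L, 0L), shift_b = c(0L, 0L), shift_c = c(0L, 1L),
    dir_x = c(g1[4], g2[4]), dir_y = c(g1[5], g2[5]),
    dir_z = c(g1[6], g2[6]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(cell = cell, sites = sites, contacts_truth = contacts_truth)
}
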