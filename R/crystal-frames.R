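# Lattice-frame conventions, crystallographic-plane modulus slices,
# periodic close-contact detection, and modulus-vs-contact alignment.

#' Crystal cell from lattice parameters
#'
#' @param a,b,c lattice lengths in Angstrom, positive.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return list of class \code{crystal_cell}.
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  for (ang in c(alpha, beta, gamma))
    if (ang <= 0 || ang >= 180) stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                         gamma = gamma), class = "crystal_cell")
  # positive-definite metric check via the cell volume argument
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) stop("degenerate cell: metric tensor is not positive definite")
  cell
}

#' @export
print.crystal_cell <- function(x, ...) {
  cat(sprintf("cell: a=%.4g b=%.4g c=%.4g A  alpha=%.4g beta=%.4g gamma=%.4g deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Cartesian lattice basis of a crystal cell
#'
#' Frame convention: a along x; b in the xy plane with positive y component;
#' c completing a right-handed set. Rows of the returned matrix are the
#' lattice vectors, so Cartesian coordinates of a fractional point f are
#' \code{f \%*\% basis}.
#'
#' @param cell a \code{crystal_cell}.
#' @return 3x3 matrix of lattice vectors (rows), Angstrom.
#' @export
cell_to_cartesian <- function(cell) {
  stopifnot(inherits(cell, "crystal_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0 || abs(sg) < 1e-12)
    stop("degenerate cell: cannot build a Cartesian basis")
  v <- sqrt(arg)
  rbind(
    c(cell$a, 0, 0),
    c(cell$b * cg, cell$b * sg, 0),
    c(cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg))
}

plane_axes <- function(plane) {
  switch(plane,
         ab = c(1L, 2L), ac = c(1L, 3L), bc = c(2L, 3L),
         stop("plane must be one of 'ab', 'ac', 'bc'"))
}

#' Modulus slice in a crystallographic plane
#'
#' Builds an in-plane orthonormal frame (e1 = first axis normalized; e2 =
#' second axis Gram-Schmidt orthogonalized against e1), sweeps
#' \eqn{u(\theta) = \cos\theta\, e_1 + \sin\theta\, e_2} over
#' \eqn{\theta \in [0, 2\pi)}, and evaluates the chosen directional modulus.
#' This is the quantitative form of the familiar 2-D polar "deformability"
#' plots.
#'
#' @inheritParams young_modulus
#' @param cell a \code{crystal_cell}.
#' @param plane \code{"ab"}, \code{"ac"} or \code{"bc"}.
#' @param property \code{"young"} or \code{"shear_min"}.
#' @param n_angles number of theta samples, at least 36. Default 360.
#' @param n_chi chi-scan resolution for \code{"shear_min"}.
#' @return data.frame of class \code{plane_slice} with columns \code{theta}
#'   (rad from the first in-plane axis) and \code{value} (GPa); attributes
#'   \code{plane}, \code{property}, \code{frame} (2x3: e1, e2 rows).
#' @export
plane_slice <- function(S, cell, plane = c("ab", "ac", "bc"),
                        property = c("young", "shear_min"),
                        n_angles = 360, n_chi = 72) {
  plane <- match.arg(plane)
  property <- match.arg(property)
  stopifnot(n_angles >= 36)
  S <- as_compliance(S)
  A <- cell_to_cartesian(cell)
  ax <- plane_axes(plane)
  e1 <- A[ax[1], ] / sqrt(sum(A[ax[1], ]^2))
  raw2 <- A[ax[2], ]
  e2 <- raw2 - sum(raw2 * e1) * e1
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-6 * sqrt(sum(raw2^2)))
    stop("the two plane axes are parallel; no plane is defined")
  e2 <- e2 / n2
  theta <- seq(0, 2 * pi, length.out = n_angles + 1)[seq_len(n_angles)]
  U <- outer(e1, cos(theta)) + outer(e2, sin(theta))   # 3 x n
  M <- compliance_quad(S)
  value <- if (property == "young") {
    young_values_quad(M, U)
  } else {
    vapply(seq_len(ncol(U)), function(k)
      shear_extrema_quad(M, U[, k], n_chi)$G_min, numeric(1))
  }
  structure(data.frame(theta = theta, value = value),
            class = c("plane_slice", "data.frame"),
            plane = plane, property = property,
            frame = rbind(e1 = e1, e2 = e2))
}

#' Write a plane slice to CSV with a JSON header sidecar
#'
#' The CSV has columns \code{theta_rad}, \code{value_gpa}; the JSON sidecar
#' (same path with extension \code{.json}) names the plane, property and
#' in-plane frame.
#'
#' @param slice a \code{plane_slice}.
#' @param path output CSV path.
#' @export
write_slice_csv <- function(slice, path) {
  utils::write.csv(data.frame(theta_rad = slice$theta,
                              value_gpa = slice$value),
                   path, row.names = FALSE)
  hdr <- list(plane = attr(slice, "plane"),
              property = attr(slice, "property"),
              frame = attr(slice, "frame"))
  jsonlite::write_json(hdr, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Detect periodic hydrogen bonds / close contacts
#'
#' Covalent D-H pairs are assigned by a minimum-image D-H distance at most
#' \code{d_DH_max}; each hydrogen is then tested against acceptor atoms over
#' all neighbour images within the H...A cutoff. A contact passes when
#' d_HA <= \code{d_HA_max} and the D-H...A angle is at least
#' \code{angle_min}. Each contact is reported once per (donor, acceptor,
#' image) triple, with the Cartesian donor-to-acceptor unit direction.
#'
#' @param sites data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (fractional) and \code{site_label}.
#' @param cell a \code{crystal_cell}.
#' @param donors donor element symbols. Default \code{c("N", "O", "C")}.
#' @param acceptors acceptor element symbols. Default \code{c("N", "O")}.
#' @param d_HA_max H...A distance cutoff in Angstrom. Default 2.7.
#' @param angle_min D-H...A angle cutoff in degrees. Default 120.
#' @param d_DH_max covalent D-H assignment cutoff in Angstrom. Default 1.25.
#' @return data.frame of contacts: donor/hydrogen/acceptor labels and
#'   elements, \code{d_HA}, \code{d_DA}, \code{angle_DHA}, image shift
#'   integers \code{shift_a/b/c}, and direction components
#'   \code{dir_x/y/z}. Attribute \code{criteria} records the rules used.
#' @export
detect_contacts <- function(sites, cell, donors = c("N", "O", "C"),
                            acceptors = c("N", "O"), d_HA_max = 2.7,
                            angle_min = 120, d_DH_max = 1.25) {
  stopifnot(is.data.frame(sites),
            all(c("element", "x", "y", "z", "site_label") %in% names(sites)))
  if (!any(sites$element == "H"))
    stop("no hydrogen atoms in the structure; contact detection needs ",
         "explicit hydrogens (add them or use a structure that includes them)")
  A <- cell_to_cartesian(cell)
  frac <- as.matrix(sites[, c("x", "y", "z")]) %% 1
  cart <- frac %*% A

  # image shifts large enough to cover the cutoff for thin cells
  perp_heights <- abs(det(A)) / c(
    sqrt(sum(pracma_cross(A[2, ], A[3, ])^2)),
    sqrt(sum(pracma_cross(A[1, ], A[3, ])^2)),
    sqrt(sum(pracma_cross(A[1, ], A[2, ])^2)))
  nimg <- pmax(1L, ceiling((d_HA_max + 0.1) / perp_heights))
  shifts <- as.matrix(expand.grid(a = -nimg[1]:nimg[1], b = -nimg[2]:nimg[2],
                                  c = -nimg[3]:nimg[3]))
  shift_cart <- shifts %*% A

  hyd <- which(sites$element == "H")
  don <- which(sites$element %in% donors)
  acc <- which(sites$element %in% acceptors)

  # covalent donor of each hydrogen: nearest donor-element atom (min image)
  h_donor <- sapply(hyd, function(h) {
    best <- NA_integer_; bestd <- Inf
    for (d in don) {
      dd <- min(sqrt(rowSums(sweep(shift_cart, 2,
                                   cart[h, ] - cart[d, ], "+")^2)))
      if (dd < bestd) { bestd <- dd; best <- d }
    }
    if (bestd <= d_DH_max) best else NA_integer_
  })

  out <- list()
  for (hi in seq_along(hyd)) {
    h <- hyd[hi]; d <- h_donor[hi]
    if (is.na(d)) next
    # donor image placed at minimum distance to its hydrogen
    ddists <- sqrt(rowSums(sweep(shift_cart, 2, cart[d, ] - cart[h, ], "+")^2))
    dpos <- cart[d, ] + shift_cart[which.min(ddists), ]
    for (a in acc) {
      for (s in seq_len(nrow(shifts))) {
        apos <- cart[a, ] + shift_cart[s, ]
        # skip the donor atom itself (same site, same position)
        if (a == d && sqrt(sum((apos - dpos)^2)) < 1e-6) next
        dHA <- sqrt(sum((apos - cart[h, ])^2))
        if (dHA > d_HA_max) next
        hd <- dpos - cart[h, ]; ha <- apos - cart[h, ]
        ang <- acos(max(-1, min(1, sum(hd * ha) /
                                  sqrt(sum(hd^2) * sum(ha^2))))) * 180 / pi
        if (ang < angle_min) next
        dDA <- sqrt(sum((apos - dpos)^2))
        dir <- (apos - dpos) / dDA
        out[[length(out) + 1]] <- data.frame(
          donor_label = sites$site_label[d],
          hydrogen_label = sites$site_label[h],
          acceptor_label = sites$site_label[a],
          donor_element = sites$element[d],
          acceptor_element = sites$element[a],
          d_HA = dHA, d_DA = dDA, angle_DHA = ang,
          shift_a = shifts[s, 1], shift_b = shifts[s, 2],
          shift_c = shifts[s, 3],
          dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) == 0) {
    data.frame(donor_label = character(0), hydrogen_label = character(0),
               acceptor_label = character(0), donor_element = character(0),
               acceptor_element = character(0), d_HA = numeric(0),
               d_DA = numeric(0), angle_DHA = numeric(0),
               shift_a = integer(0), shift_b = integer(0),
               shift_c = integer(0), dir_x = numeric(0), dir_y = numeric(0),
               dir_z = numeric(0), stringsAsFactors = FALSE)
  } else {
    r <- do.call(rbind, out)
    r[!duplicated(r[, c("donor_label", "acceptor_label", "shift_a",
                        "shift_b", "shift_c")]), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "criteria") <- list(donors = donors, acceptors = acceptors,
                                d_HA_max = d_HA_max, angle_min = angle_min,
                                d_DH_max = d_DH_max)
  res
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

fold_hemisphere <- function(v) if (v[3] < 0 ||
                                   (v[3] == 0 && (v[2] < 0 ||
                                                  (v[2] == 0 && v[1] < 0))))
  -v else v

angle_between_deg <- function(u, v) {
  # fold by antipodal symmetry: directions are axes, angles in [0, 90]
  cu <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cu))) * 180 / pi
}

#' Alignment of modulus maxima with contact networks
#'
#' Quantifies the overlay of stiffness maps on contact networks. Contact
#' directions are folded into a hemisphere and grouped into classes by
#' donor-element...acceptor-element type (e.g. \code{"N-H...O"}). For each
#' class the principal axis of the direction second-moment matrix (the mean
#' axis of the contact bundle) is compared with the 3-D Young's-modulus
#' maximum direction. When plane slices are supplied, the angle between each
#' slice maximum and the in-plane projection of the nearest contact direction
#' is also reported. All angles are folded to [0, 90] degrees; large angles
#' are legitimate output (stiffness is not always contact-driven), not an
#' error.
#'
#' @param extrema an \code{extremum_result} for Young's modulus (3-D), or
#'   \code{NULL} to skip the 3-D comparison.
#' @param contacts nonempty contact data.frame from
#'   \code{\link{detect_contacts}}.
#' @param slices optional named list of \code{plane_slice} objects.
#' @return list of class \code{alignment_report}: \code{classes} (data.frame:
#'   class, n, mean_axis_x/y/z, angle_to_Emax_deg, min_angle_deg) and,
#'   when slices are given, \code{planes} (data.frame: plane, theta_max_rad,
#'   angle_to_nearest_contact_deg).
#' @export
alignment_report <- function(extrema, contacts, slices = NULL) {
  if (is.null(contacts) || nrow(contacts) == 0)
    stop("contact list is empty; run detect_contacts first")
  dirs <- as.matrix(contacts[, c("dir_x", "dir_y", "dir_z")])
  dirs <- t(apply(dirs, 1, fold_hemisphere))
  cls <- paste0(contacts$donor_element, "-H...", contacts$acceptor_element)

  emax <- if (!is.null(extrema)) extrema$max_direction else NULL
  classes <- do.call(rbind, lapply(split(seq_len(nrow(dirs)), cls),
                                   function(idx) {
    D <- dirs[idx, , drop = FALSE]
    Mmt <- crossprod(D) / nrow(D)
    ax <- eigen(Mmt, symmetric = TRUE)$vectors[, 1]
    ax <- fold_hemisphere(ax)
    ang <- if (is.null(emax)) NA_real_ else angle_between_deg(ax, emax)
    mn <- if (is.null(emax)) NA_real_ else
      min(apply(D, 1, angle_between_deg, v = emax))
    data.frame(class = cls[idx[1]], n = nrow(D),
               mean_axis_x = ax[1], mean_axis_y = ax[2], mean_axis_z = ax[3],
               angle_to_Emax_deg = ang, min_angle_deg = mn,
               stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  rep <- list(classes = classes)

  if (!is.null(slices)) {
    rows <- lapply(slices, function(sl) {
      fr <- attr(sl, "frame")
      th <- sl$theta[which.max(sl$value)]
      umax <- cos(th) * fr["e1", ] + sin(th) * fr["e2", ]
      # in-plane projections of contact directions
      proj <- t(apply(dirs, 1, function(d) {
        p <- sum(d * fr["e1", ]) * fr["e1", ] + sum(d * fr["e2", ]) * fr["e2", ]
        p
      }))
      lens <- sqrt(rowSums(proj^2))
      keep <- lens > 1e-8
      ang <- if (!any(keep)) NA_real_ else
        min(apply(proj[keep, , drop = FALSE], 1, angle_between_deg, v = umax))
      data.frame(plane = attr(sl, "plane"), theta_max_rad = th,
                 angle_to_nearest_contact_deg = ang, stringsAsFactors = FALSE)
    })
    rep$planes <- do.call(rbind, rows)
    rownames(rep$planes) <- NULL
  }
  structure(rep, class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("Contact / modulus-maximum alignment\n")
  print(x$classes)
  if (!is.null(x$planes)) print(x$planes)
  invisible(x)
}
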