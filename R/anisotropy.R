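# Directional moduli from the compliance tensor.
#
# All quadratic-form evaluations go through a 9x9 reshape of the full
# compliance tensor: with w = vec(u v^T), u_i v_j u_k v_l S_ijkl = w' M w.
# This keeps the inner loops in vectorized matrix algebra.

compliance_quad <- function(S) {
  Sf <- voigt_to_full(S, flavor = "compliance")
  dim(Sf) <- c(9, 9)
  Sf
}

as_compliance <- function(S) {
  if (inherits(S, "voigt_compliance")) return(S)
  if (inherits(S, "voigt_stiffness")) return(invert_to_compliance(S))
  stop("expected a voigt_compliance (or voigt_stiffness) object")
}

unit_vector <- function(u, tol = 1e-12, what = "direction") {
  u <- as.numeric(u)
  if (length(u) != 3 || any(!is.finite(u)))
    stop(what, " must be a finite 3-vector")
  n <- sqrt(sum(u^2))
  if (abs(n - 1) > tol)
    stop(what, " must be a unit vector (|norm - 1| <= ", tol, ")")
  u
}

sph_to_cart <- function(theta, phi) {
  theta <- unname(theta); phi <- unname(phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

cart_to_sph <- function(u) {
  c(theta = acos(max(-1, min(1, u[3]))), phi = atan2(u[2], u[1]))
}

# right-handed orthonormal pair spanning the plane perpendicular to u
perp_basis <- function(u) {
  a <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) c(1, 0, 0)
       else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2)
}

# vectorized 1/E over columns of U (3 x N)
young_values_quad <- function(M, U) {
  W <- apply(U, 2, function(u) as.vector(outer(u, u)))
  1 / colSums(W * (M %*% W))
}

#' Directional Young's modulus E(u)
#'
#' Resistance to uniaxial deformation along the unit direction \code{u}:
#' \eqn{1/E(u) = u_i u_j u_k u_l S_{ijkl}}.
#'
#' @param S compliance (\code{voigt_compliance}); a \code{voigt_stiffness} is
#'   inverted on the fly.
#' @param u unit 3-vector (tolerance 1e-12 on the norm).
#' @return Young's modulus in GPa.
#' @examples
#' C <- isotropic_stiffness(10, 0.25)
#' young_modulus(invert_to_compliance(C), c(0, 0, 1))  # 10 GPa
#' @export
young_modulus <- function(S, u) {
  S <- as_compliance(S)
  u <- unit_vector(u, what = "u")
  M <- compliance_quad(S)
  w <- as.vector(outer(u, u))
  1 / sum(w * (M %*% w))
}

#' Directional shear modulus G(u, v)
#'
#' Resistance to shear along \code{u} in the plane normal to \code{v}, with
#' \code{u} perpendicular to \code{v}:
#' \eqn{1/G(u,v) = 4\, u_i v_j u_k v_l S_{ijkl}}. Symmetric under swapping
#' \code{u} and \code{v}.
#'
#' @inheritParams young_modulus
#' @param v unit 3-vector perpendicular to \code{u} (dot product below
#'   \code{ortho_tol}).
#' @param ortho_tol orthogonality tolerance, default 1e-8.
#' @return shear modulus in GPa.
#' @export
shear_modulus <- function(S, u, v, ortho_tol = 1e-8) {
  S <- as_compliance(S)
  u <- unit_vector(u, what = "u")
  v <- unit_vector(v, what = "v")
  if (abs(sum(u * v)) > ortho_tol)
    stop("u and v must be orthogonal (|u.v| <= ", ortho_tol, ")")
  M <- compliance_quad(S)
  w <- as.vector(outer(u, v))
  1 / (4 * sum(w * (M %*% w)))
}

# vectorized G over chi grid for fixed u; B = perp basis, M = 9x9 compliance
shear_values_chi <- function(M, u, B, chi) {
  V <- B[, 1] %o% cos(chi) + B[, 2] %o% sin(chi)   # 3 x n
  W <- matrix(0, 9, length(chi))
  for (i in 1:3) W[(0:2) * 3 + i, ] <- u[i] * V    # vec(u v^T), column-major
  1 / (4 * colSums(W * (M %*% W)))
}

#' Shear modulus extrema over the second direction
#'
#' For fixed \code{u}, the admissible \code{v} directions form a circle
#' \eqn{v(\chi)} in the plane perpendicular to \code{u}. The modulus is scanned
#' at \code{n_chi} equally spaced \eqn{\chi \in [0, \pi)} (it is
#' \eqn{\pi}-periodic) and the best brackets are refined by bounded
#' one-dimensional minimization to 1e-6 rad. The average is the periodic
#' trapezoid mean over the scan.
#'
#' @inheritParams young_modulus
#' @param n_chi number of scan points, at least 8. Default 72.
#' @return list with \code{G_min}, \code{G_max}, \code{G_avg} (GPa),
#'   \code{chi_min} (rad in [0, pi)), and \code{v_min}, \code{v_max} (unit
#'   3-vectors).
#' @export
shear_extrema_over_v <- function(S, u, n_chi = 72) {
  S <- as_compliance(S)
  u <- unit_vector(u, what = "u")
  stopifnot(n_chi >= 8)
  M <- compliance_quad(S)
  shear_extrema_quad(M, u, n_chi)
}

shear_extrema_quad <- function(M, u, n_chi = 72) {
  B <- perp_basis(u)
  chi <- seq(0, pi, length.out = n_chi + 1)[seq_len(n_chi)]
  g <- shear_values_chi(M, u, B, chi)
  h <- pi / n_chi
  f <- function(x) shear_values_chi(M, u, B, x)
  refine <- function(i0, maximize) {
    lo <- chi[i0] - h; hi <- chi[i0] + h
    opt <- stats::optimize(f, c(lo, hi), maximum = maximize, tol = 1e-7)
    if (maximize) c(opt$maximum, opt$objective) else c(opt$minimum, opt$objective)
  }
  rmin <- refine(which.min(g), FALSE)
  rmax <- refine(which.max(g), TRUE)
  chi_min <- rmin[1] %% pi
  v_at <- function(x) B[, 1] * cos(x) + B[, 2] * sin(x)
  list(G_min = rmin[2], G_max = rmax[2], G_avg = mean(g),
       chi_min = chi_min,
       v_min = v_at(rmin[1]), v_max = v_at(rmax[1]))
}

#' Global extrema of a directional modulus over the sphere
#'
#' Seeds with a deterministic icosphere grid of at least \code{n_seed}
#' directions, then refines the best candidates with Nelder-Mead over
#' \eqn{(\theta, \phi)} (Young's) or \eqn{(\theta, \phi, \chi)} (shear).
#' Deterministic given \code{n_seed}.
#'
#' @inheritParams young_modulus
#' @param property \code{"young"} or \code{"shear"}.
#' @param n_seed minimum number of seed directions. Default 2562.
#' @param n_chi chi-scan resolution used at the seeding stage for shear.
#' @return list of class \code{extremum_result}: \code{min_value},
#'   \code{max_value} (GPa), \code{min_direction}, \code{max_direction} (unit
#'   3-vectors), and for shear \code{min_secondary}, \code{max_secondary}
#'   (the v vectors).
#' @export
global_extrema <- function(S, property = c("young", "shear"),
                           n_seed = 2562, n_chi = 72) {
  property <- match.arg(property)
  S <- as_compliance(S)
  M <- compliance_quad(S)
  U <- t(icosphere_directions(n_seed))      # 3 x N

  if (property == "young") {
    vals <- young_values_quad(M, U)
    fE <- function(p) {
      w <- as.vector(outer(sph_to_cart(p[1], p[2]), sph_to_cart(p[1], p[2])))
      1 / sum(w * (M %*% w))
    }
    ref_min <- refine_candidates(U, vals, fE, minimize = TRUE)
    ref_max <- refine_candidates(U, vals, fE, minimize = FALSE)
    res <- list(min_value = ref_min$value, max_value = ref_max$value,
                min_direction = ref_min$direction,
                max_direction = ref_max$direction)
  } else {
    N <- ncol(U)
    gmin <- numeric(N); gmax <- numeric(N)
    cmin <- numeric(N); cmax <- numeric(N)
    for (k in seq_len(N)) {
      B <- perp_basis(U[, k])
      chi <- seq(0, pi, length.out = n_chi + 1)[seq_len(n_chi)]
      g <- shear_values_chi(M, U[, k], B, chi)
      gmin[k] <- min(g); gmax[k] <- max(g)
      cmin[k] <- chi[which.min(g)]; cmax[k] <- chi[which.max(g)]
    }
    fG <- function(p) {
      u <- sph_to_cart(p[1], p[2])
      B <- perp_basis(u)
      shear_values_chi(M, u, B, p[3])
    }
    ref_min <- refine_candidates(U, gmin, fG, minimize = TRUE, chi = cmin)
    ref_max <- refine_candidates(U, gmax, fG, minimize = FALSE, chi = cmax)
    v_of <- function(p) {
      B <- perp_basis(sph_to_cart(p[1], p[2]))
      B[, 1] * cos(p[3]) + B[, 2] * sin(p[3])
    }
    res <- list(min_value = ref_min$value, max_value = ref_max$value,
                min_direction = ref_min$direction,
                max_direction = ref_max$direction,
                min_secondary = v_of(ref_min$par),
                max_secondary = v_of(ref_max$par))
  }
  res$property <- property
  structure(res, class = "extremum_result")
}

# Nelder-Mead refinement of the n_cand best seeds (kept apart by >= 0.15 rad)
refine_candidates <- function(U, vals, fn, minimize, chi = NULL, n_cand = 6) {
  ord <- if (minimize) order(vals) else order(-vals)
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) >= n_cand) break
    if (all(vapply(picked, function(j)
      acos(min(1, abs(sum(U[, i] * U[, j])))) > 0.15, TRUE)))
      picked <- c(picked, i)
  }
  sign <- if (minimize) 1 else -1
  best <- NULL
  for (i in picked) {
    p0 <- cart_to_sph(U[, i])
    if (!is.null(chi)) p0 <- c(p0, chi[i])
    opt <- stats::optim(p0, function(p) sign * fn(p), method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 4000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(value = sign * best$value,
       direction = sph_to_cart(best$par[1], best$par[2]),
       par = best$par)
}

#' @export
print.extremum_result <- function(x, ...) {
  cat(sprintf("%s modulus extrema: min %.4g GPa at (%s), max %.4g GPa at (%s)\n",
              x$property, x$min_value,
              paste(signif(x$min_direction, 4), collapse = ", "),
              x$max_value,
              paste(signif(x$max_direction, 4), collapse = ", ")))
  invisible(x)
}

#' Anisotropy index of a modulus
#'
#' The ratio of the global maximum to the global minimum of a directional
#' modulus, \eqn{A_X = X_{max} / X_{min}}; 1 for an isotropic medium.
#'
#' @param ext an \code{extremum_result} from \code{\link{global_extrema}}.
#' @return dimensionless anisotropy index, >= 1.
#' @export
anisotropy_index <- function(ext) {
  if (!is.list(ext) || is.null(ext$min_value) || is.null(ext$max_value))
    stop("expected an extremum_result")
  if (ext$min_value <= 0)
    stop("minimum modulus is non-positive; tensor is marginally stable")
  ext$max_value / ext$min_value
}

#' Sample a modulus surface on a regular spherical grid
#'
#' Evaluates a directional modulus on a regular \eqn{(\theta, \phi)} grid,
#' \eqn{\theta \in [0, \pi]}, \eqn{\phi \in [0, 2\pi)}; the sampled radius
#' gives the familiar 3-D "deformability map" surface.
#'
#' @inheritParams young_modulus
#' @param property one of \code{"young"}, \code{"shear_min"},
#'   \code{"shear_max"}, \code{"shear_avg"}.
#' @param resolution samples per ring, at least 16. The grid has
#'   \code{resolution} polar and \code{2 * resolution} azimuthal samples.
#' @param n_chi chi-scan resolution for the shear properties.
#' @return data.frame of class \code{modulus_surface} with columns
#'   \code{theta}, \code{phi} (rad) and \code{value} (GPa); attributes
#'   \code{property} and \code{resolution}.
#' @export
sphere_map <- function(S, property = c("young", "shear_min", "shear_max",
                                       "shear_avg"),
                       resolution = 32, n_chi = 72) {
  property <- match.arg(property)
  stopifnot(resolution >= 16)
  S <- as_compliance(S)
  M <- compliance_quad(S)
  theta <- seq(0, pi, length.out = resolution)
  phi <- seq(0, 2 * pi, length.out = 2 * resolution + 1)[seq_len(2 * resolution)]
  grid <- expand.grid(theta = theta, phi = phi, KEEP.OUT.ATTRS = FALSE)
  U <- rbind(sin(grid$theta) * cos(grid$phi),
             sin(grid$theta) * sin(grid$phi),
             cos(grid$theta))
  if (property == "young") {
    grid$value <- young_values_quad(M, U)
  } else {
    field <- c(shear_min = "G_min", shear_max = "G_max",
               shear_avg = "G_avg")[[property]]
    grid$value <- vapply(seq_len(ncol(U)), function(k)
      shear_extrema_quad(M, U[, k], n_chi)[[field]], numeric(1))
  }
  structure(grid, class = c("modulus_surface", "data.frame"),
            property = property, resolution = resolution)
}

#' Write a sampled modulus surface to CSV
#'
#' Columns \code{theta_rad}, \code{phi_rad}, \code{value_gpa}.
#'
#' @param surface a \code{modulus_surface}.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(
    data.frame(theta_rad = surface$theta, phi_rad = surface$phi,
               value_gpa = surface$value),
    path, row.names = FALSE)
  invisible(path)
}

#' JSON summary of a modulus over the sphere
#'
#' @param S compliance or stiffness object.
#' @param property \code{"young"} or \code{"shear"}.
#' @param path optional output path for the JSON.
#' @param ... passed to \code{\link{global_extrema}}.
#' @return list: \code{property}, \code{min}, \code{max}, \code{min_dir},
#'   \code{max_dir}, \code{anisotropy}.
#' @export
surface_summary <- function(S, property = c("young", "shear"), path = NULL,
                            ...) {
  property <- match.arg(property)
  ext <- global_extrema(S, property, ...)
  out <- list(property = property, min = ext$min_value, max = ext$max_value,
              min_dir = ext$min_direction, max_dir = ext$max_direction,
              anisotropy = anisotropy_index(ext))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  out
}
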