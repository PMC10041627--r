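# Voigt pair table: alpha -> (i, j), 1..6 = 11, 22, 33, 23, 13, 12
.voigt_pairs <- matrix(c(1L, 1L,
                         2L, 2L,
                         3L, 3L,
                         2L, 3L,
                         1L, 3L,
                         1L, 2L), ncol = 2L, byrow = TRUE)

# (i, j) -> alpha lookup, symmetric
.voigt_index <- matrix(c(1L, 6L, 5L,
                         6L, 2L, 4L,
                         4L, 4L, 3L), nrow = 3L, byrow = TRUE)
.voigt_index[2, 3] <- 4L; .voigt_index[3, 2] <- 4L
.voigt_index[1, 3] <- 5L; .voigt_index[3, 1] <- 5L
.voigt_index[1, 2] <- 6L; .voigt_index[2, 1] <- 6L

#' Validate and symmetrize a 6x6 Voigt stiffness matrix
#'
#' Elastic constants in Voigt notation form a symmetric 6x6 matrix
#' \eqn{C_{\alpha\beta}} (GPa). File round-tripping and fitting can leave tiny
#' asymmetries, so the matrix is symmetrized as \eqn{(C + C^T)/2} provided the
#' worst asymmetry does not exceed \code{tolerance}.
#'
#' @param raw 6x6 numeric matrix of elastic constants in GPa.
#' @param tolerance maximum permitted absolute asymmetry
#'   \eqn{|C_{\alpha\beta} - C_{\beta\alpha}|} in GPa. Default 1e-3.
#' @param source_label free-text provenance (system + method).
#' @return An object of class \code{voigt_stiffness}: the symmetrized matrix
#'   with a \code{source_label} attribute.
#' @examples
#' C <- validate_stiffness(diag(6), source_label = "identity")
#' @export
validate_stiffness <- function(raw, tolerance = 1e-3, source_label = "") {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || !identical(dim(raw), c(6L, 6L)))
    stop("stiffness must be a numeric 6x6 matrix")
  if (any(!is.finite(raw)))
    stop("stiffness contains non-finite entries")
  asym <- abs(raw - t(raw))
  if (max(asym) > tolerance) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    ij <- sort(ij)
    stop(sprintf(
      "asymmetry %.6g GPa at (%d,%d) exceeds tolerance %.3g GPa",
      max(asym), ij[1], ij[2], tolerance))
  }
  C <- (raw + t(raw)) / 2
  dimnames(C) <- NULL
  structure(C, class = "voigt_stiffness", source_label = source_label)
}

#' @export
print.voigt_stiffness <- function(x, ...) {
  lbl <- attr(x, "source_label")
  cat("Voigt stiffness matrix (GPa)",
      if (nzchar(lbl)) paste0(" - ", lbl), "\n", sep = "")
  print(round(unclass_matrix(x), 4))
  invisible(x)
}

# strip attributes so numeric code sees a plain matrix
unclass_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "source_label") <- NULL
  y
}

#' Invert a stiffness matrix to the compliance matrix
#'
#' The compliance matrix \eqn{S_{\alpha\beta}} (GPa^-1) is the matrix inverse
#' of the Voigt stiffness matrix; all directional moduli are computed from it.
#' Near-singular matrices (condition number above \code{max_condition}) are
#' rejected, since they signal an unstable or degenerate tensor.
#'
#' @param C a \code{voigt_stiffness} object (or a plain symmetric 6x6 matrix).
#' @param max_condition 2-norm condition number cutoff. Default 1e12.
#' @return An object of class \code{voigt_compliance}.
#' @export
invert_to_compliance <- function(C, max_condition = 1e12) {
  Cm <- as_stiffness_matrix(C)
  sv <- svd(Cm, nu = 0, nv = 0)$d
  if (min(sv) <= 0 || max(sv) / min(sv) > max_condition)
    stop(sprintf(
      "stiffness matrix is singular or ill-conditioned (condition number %.3g)",
      if (min(sv) > 0) max(sv) / min(sv) else Inf))
  S <- solve(Cm)
  S <- (S + t(S)) / 2
  structure(S, class = "voigt_compliance",
            source_label = attr(C, "source_label") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_stiffness_matrix <- function(C) {
  if (inherits(C, "voigt_stiffness") || inherits(C, "voigt_compliance"))
    return(unclass_matrix(C))
  C <- as.matrix(C)
  stopifnot(identical(dim(C), c(6L, 6L)))
  C
}

#' Expand a Voigt matrix to the full fourth-order tensor
#'
#' Stiffness maps with unit factors: \eqn{C_{ijkl} = C_{\alpha\beta}}.
#' Compliance carries the Voigt weights 1 / 2 / 4 (both, one, or neither of
#' \eqn{\alpha,\beta \le 3}) so that \eqn{\sigma_{ij} = C_{ijkl}\epsilon_{kl}}
#' and \eqn{1/E(u) = u_i u_j u_k u_l S_{ijkl}} are mutually consistent.
#'
#' @param M a \code{voigt_stiffness} or \code{voigt_compliance} object, or a
#'   plain 6x6 matrix with \code{flavor} given.
#' @param flavor \code{"stiffness"} or \code{"compliance"}; inferred from the
#'   class of \code{M} when possible.
#' @return 3x3x3x3 numeric array with attribute \code{flavor}.
#' @export
voigt_to_full <- function(M, flavor = NULL) {
  if (is.null(flavor)) {
    flavor <- if (inherits(M, "voigt_compliance")) "compliance"
              else if (inherits(M, "voigt_stiffness")) "stiffness"
              else stop("flavor must be given for a plain matrix")
  }
  flavor <- match.arg(flavor, c("stiffness", "compliance"))
  Mm <- as_stiffness_matrix(M)
  Tf <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) {
    for (b in 1:6) {
      f <- if (flavor == "stiffness") 1 else
        (if (a <= 3) 1 else 2) * (if (b <= 3) 1 else 2)
      v <- Mm[a, b] / f
      i <- .voigt_pairs[a, 1]; j <- .voigt_pairs[a, 2]
      k <- .voigt_pairs[b, 1]; l <- .voigt_pairs[b, 2]
      Tf[i, j, k, l] <- v; Tf[j, i, k, l] <- v
      Tf[i, j, l, k] <- v; Tf[j, i, l, k] <- v
    }
  }
  attr(Tf, "flavor") <- flavor
  Tf
}

#' Contract a full fourth-order tensor back to Voigt notation
#'
#' Exact inverse of \code{\link{voigt_to_full}} for tensors with the minor and
#' major symmetries.
#'
#' @param Tf 3x3x3x3 array with attribute \code{flavor} (or pass \code{flavor}).
#' @param flavor \code{"stiffness"} or \code{"compliance"}.
#' @return plain 6x6 matrix.
#' @export
full_to_voigt <- function(Tf, flavor = attr(Tf, "flavor")) {
  flavor <- match.arg(flavor, c("stiffness", "compliance"))
  M <- matrix(0, 6, 6)
  for (a in 1:6) {
    for (b in 1:6) {
      f <- if (flavor == "stiffness") 1 else
        (if (a <= 3) 1 else 2) * (if (b <= 3) 1 else 2)
      M[a, b] <- Tf[.voigt_pairs[a, 1], .voigt_pairs[a, 2],
                    .voigt_pairs[b, 1], .voigt_pairs[b, 2]] * f
    }
  }
  M
}

#' Rotate a full fourth-order tensor
#'
#' Applies \eqn{T'_{ijkl} = R_{ia} R_{jb} R_{kc} R_{ld} T_{abcd}} for a proper
#' rotation \code{R}. Used as the brute-force oracle for directional moduli:
#' with the first row of \code{R} equal to \code{u}, component (1,1,1,1) of the
#' rotated compliance is \eqn{1/E(u)}.
#'
#' @param Tf 3x3x3x3 array.
#' @param R 3x3 rotation matrix, orthogonal with det +1 within \code{tol}.
#' @param tol orthogonality tolerance. Default 1e-10.
#' @return rotated 3x3x3x3 array (flavor attribute preserved).
#' @export
rotate_full <- function(Tf, R, tol = 1e-10) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("R is not a proper rotation (orthogonal, det +1)")
  flavor <- attr(Tf, "flavor")
  Tn <- Tf
  # contract one index at a time: T <- R %*% T along each mode
  for (mode in 1:4) {
    Tm <- aperm(Tn, c(mode, setdiff(1:4, mode)))
    dim(Tm) <- c(3, 27)
    Tm <- R %*% Tm
    dim(Tm) <- c(3, 3, 3, 3)
    Tn <- aperm(Tm, order(c(mode, setdiff(1:4, mode))))
  }
  attr(Tn, "flavor") <- flavor
  Tn
}

#' Born mechanical stability of a stiffness matrix
#'
#' An unstressed crystal is mechanically stable if and only if its Voigt
#' stiffness matrix is positive definite. This single spectral test is
#' necessary and sufficient for every crystal system, so no per-class
#' inequality sets are needed.
#'
#' @param C a \code{voigt_stiffness} object or 6x6 matrix.
#' @return list of class \code{stability_report} with \code{stable} (logical)
#'   and \code{eigenvalues} (six reals, GPa, ascending).
#' @export
born_stability <- function(C) {
  Cm <- as_stiffness_matrix(C)
  ev <- sort(eigen(Cm, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(stable = ev[1] > 0, eigenvalues = ev),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Born stability: %s\n", if (x$stable) "stable" else "UNSTABLE"))
  cat("eigenvalues (GPa):", paste(signif(x$eigenvalues, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Voigt (uniform-strain) polycrystalline averages
#'
#' Orientation averages of the stiffness matrix under the uniform-strain
#' assumption:
#' \deqn{K_V = (C_{11}+C_{22}+C_{33}+2(C_{12}+C_{13}+C_{23}))/9}
#' \deqn{G_V = ((C_{11}+C_{22}+C_{33})-(C_{12}+C_{13}+C_{23}))/15 +
#'             (C_{44}+C_{55}+C_{66})/5}
#' \deqn{E_V = 9 K_V G_V / (3 K_V + G_V)}
#'
#' @param C a Born-stable \code{voigt_stiffness}.
#' @return list of class \code{voigt_averages} with \code{K_V}, \code{G_V},
#'   \code{E_V} in GPa.
#' @export
voigt_averages <- function(C) {
  Cm <- as_stiffness_matrix(C)
  st <- born_stability(Cm)
  if (!st$stable) {
    e <- simpleError("stiffness matrix is not Born-stable; averages undefined")
    e$stability <- st
    stop(e)
  }
  dia <- Cm[1, 1] + Cm[2, 2] + Cm[3, 3]
  off <- Cm[1, 2] + Cm[1, 3] + Cm[2, 3]
  she <- Cm[4, 4] + Cm[5, 5] + Cm[6, 6]
  K_V <- (dia + 2 * off) / 9
  G_V <- (dia - off) / 15 + she / 5
  structure(list(K_V = K_V, G_V = G_V,
                 E_V = 9 * K_V * G_V / (3 * K_V + G_V)),
            class = "voigt_averages")
}

#' @export
print.voigt_averages <- function(x, ...) {
  cat(sprintf("Voigt averages: K_V = %.4g  G_V = %.4g  E_V = %.4g GPa\n",
              x$K_V, x$G_V, x$E_V))
  invisible(x)
}
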