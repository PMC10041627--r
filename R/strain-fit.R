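# Elastic-constant extraction from stress-strain series.
#
# Strains use engineering (Voigt) components: amplitude a on component k means
# eps_kk = a for k <= 3 and 2*eps_ij = a for the shear components 4..6, so the
# OLS slope of sigma_i against a is directly C_ik.

.laue_classes <- c("triclinic", "monoclinic", "orthorhombic", "tetragonal",
                   "cubic", "isotropic")

# components strained by the canonical minimal pattern set of each class
.pattern_components <- list(
  triclinic    = 1:6,
  monoclinic   = 1:6,
  orthorhombic = 1:6,
  tetragonal   = c(1L, 3L, 4L, 6L),
  cubic        = c(1L, 4L),
  isotropic    = 1L)

# equality-tie labels: entries sharing a positive label are equal by symmetry,
# label 0 entries are structurally zero (upper triangle; symmetric completion)
class_tie_labels <- function(laue_class) {
  L <- matrix(0L, 6, 6)
  set <- function(pairs, lab) {
    for (p in pairs) { L[p[1], p[2]] <<- lab; L[p[2], p[1]] <<- lab }
  }
  nextlab <- 0L
  own <- function(pairs) {
    nextlab <<- nextlab + 1L
    set(pairs, nextlab)
  }
  switch(laue_class,
    triclinic = {
      for (i in 1:6) for (j in i:6) own(list(c(i, j)))
    },
    monoclinic = {   # unique axis b (Laue 2/m): extra C15, C25, C35, C46
      for (p in list(c(1,1), c(2,2), c(3,3), c(4,4), c(5,5), c(6,6),
                     c(1,2), c(1,3), c(2,3), c(1,5), c(2,5), c(3,5), c(4,6)))
        own(list(p))
    },
    orthorhombic = {
      for (p in list(c(1,1), c(2,2), c(3,3), c(1,2), c(1,3), c(2,3),
                     c(4,4), c(5,5), c(6,6)))
        own(list(p))
    },
    tetragonal = {   # 4/mmm-type pattern (also holds for -42m, e.g. urea)
      own(list(c(1,1), c(2,2)))
      own(list(c(3,3)))
      own(list(c(1,2)))
      own(list(c(1,3), c(2,3)))
      own(list(c(4,4), c(5,5)))
      own(list(c(6,6)))
    },
    cubic = {
      own(list(c(1,1), c(2,2), c(3,3)))
      own(list(c(1,2), c(1,3), c(2,3)))
      own(list(c(4,4), c(5,5), c(6,6)))
    },
    isotropic = {    # shear diagonal additionally tied to (C11 - C12)/2
      own(list(c(1,1), c(2,2), c(3,3)))
      own(list(c(1,2), c(1,3), c(2,3)))
      own(list(c(4,4), c(5,5), c(6,6)))
    },
    stop("unknown Laue class: ", laue_class))
  L
}

#' Canonical strain pattern set for a Laue class
#'
#' Single-component strain patterns sufficient to determine every independent
#' elastic coefficient of the class: all six components for triclinic,
#' monoclinic and orthorhombic; components \{1, 3, 4, 6\} for tetragonal;
#' \{1, 4\} for cubic; \{1\} for isotropic (one axial strain determines C11 and
#' C12, and the shear modulus follows as (C11 - C12)/2).
#'
#' @param laue_class one of \code{"triclinic"}, \code{"monoclinic"},
#'   \code{"orthorhombic"}, \code{"tetragonal"}, \code{"cubic"},
#'   \code{"isotropic"}.
#' @return list of \code{strain_pattern} objects (fields \code{component},
#'   \code{weight}, \code{label}).
#' @export
generate_patterns <- function(laue_class) {
  laue_class <- match.arg(laue_class, .laue_classes)
  lapply(.pattern_components[[laue_class]], function(k)
    structure(list(component = k, weight = 1,
                   label = paste0("e", k)),
              class = "strain_pattern"))
}

# symmetric 3x3 strain tensor for amplitude a on Voigt component k
strain_tensor <- function(component, amplitude, weight = 1) {
  e <- matrix(0, 3, 3)
  a <- amplitude * weight
  i <- .voigt_pairs[component, 1]; j <- .voigt_pairs[component, 2]
  if (i == j) e[i, j] <- a else { e[i, j] <- a / 2; e[j, i] <- a / 2 }
  e
}

# symmetric 3x3 -> Voigt stress vector (no shear doubling for stress)
stress_to_voigt <- function(sig) {
  c(sig[1, 1], sig[2, 2], sig[3, 3], sig[2, 3], sig[1, 3], sig[1, 2])
}

#' Apply a homogeneous strain to a lattice basis
#'
#' Lattice vectors (rows of \code{cell_basis}) are mapped by \eqn{(I +
#' \epsilon)}. Strains beyond 0.2 in any component are rejected as far outside
#' the linear elastic regime.
#'
#' @param cell_basis 3x3 matrix, rows = lattice vectors in Angstrom.
#' @param strain symmetric 3x3 dimensionless strain tensor.
#' @return deformed 3x3 lattice matrix.
#' @export
apply_strain <- function(cell_basis, strain) {
  cell_basis <- as.matrix(cell_basis)
  strain <- as.matrix(strain)
  stopifnot(identical(dim(cell_basis), c(3L, 3L)),
            identical(dim(strain), c(3L, 3L)))
  if (abs(det(cell_basis)) < 1e-12) stop("cell basis is singular")
  if (max(abs(strain - t(strain))) > 1e-12) stop("strain must be symmetric")
  if (max(abs(strain)) > 0.2)
    stop("strain component exceeds 0.2; outside the linear elastic regime")
  cell_basis %*% (diag(3) + strain)
}

#' Synthetic stress engine for a known stiffness tensor
#'
#' Stands in for an ab initio stress calculator: returns
#' \eqn{\sigma = C{:}\epsilon + \gamma \lVert\epsilon\rVert \epsilon +}
#' Gaussian noise (sd \code{noise_sd} per independent stress component). The
#' noise stream is seeded and private to the returned calculator, so replaying
#' with the same seed reproduces the stress sequence bit-for-bit and the
#' global RNG state is left untouched.
#'
#' @param C_true Born-stable \code{voigt_stiffness} in GPa.
#' @param noise_sd Gaussian stress noise sd in GPa. Default 0.
#' @param anharmonic_gamma quadratic anharmonicity coefficient in GPa
#'   (multiplies the Frobenius norm of the strain times the strain). Default 0.
#' @param seed integer seed for the private noise stream.
#' @return object of class \code{stress_calculator} with an \code{evaluate}
#'   function mapping a symmetric 3x3 strain to a symmetric 3x3 stress (GPa).
#' @export
synthetic_oracle <- function(C_true, noise_sd = 0, anharmonic_gamma = 0,
                             seed = 1L) {
  Cm <- as_stiffness_matrix(C_true)
  stopifnot(noise_sd >= 0)
  if (!born_stability(Cm)$stable)
    stop("C_true must be Born-stable")
  rng_state <- with_preserved_rng({
    set.seed(seed)
    get(".Random.seed", envir = globalenv())
  })
  evaluate <- function(strain) {
    strain <- as.matrix(strain)
    stopifnot(identical(dim(strain), c(3L, 3L)))
    if (max(abs(strain - t(strain))) > 1e-12) stop("strain must be symmetric")
    eps_v <- c(strain[1, 1], strain[2, 2], strain[3, 3],
               2 * strain[2, 3], 2 * strain[1, 3], 2 * strain[1, 2])
    sig_v <- as.numeric(Cm %*% eps_v)
    sig <- matrix(c(sig_v[1], sig_v[6], sig_v[5],
                    sig_v[6], sig_v[2], sig_v[4],
                    sig_v[5], sig_v[4], sig_v[3]), 3, 3)
    if (anharmonic_gamma != 0)
      sig <- sig + anharmonic_gamma * sqrt(sum(strain^2)) * strain
    if (noise_sd > 0) {
      n <- with_preserved_rng({
        assign(".Random.seed", rng_state, envir = globalenv())
        x <- stats::rnorm(6, 0, noise_sd)
        rng_state <<- get(".Random.seed", envir = globalenv())
        x
      })
      sig <- sig + matrix(c(n[1], n[6], n[5],
                            n[6], n[2], n[4],
                            n[5], n[4], n[3]), 3, 3)
    }
    sig
  }
  structure(list(evaluate = evaluate, noise_sd = noise_sd,
                 anharmonic_gamma = anharmonic_gamma, seed = seed),
            class = "stress_calculator")
}

# run expr, then restore whatever global RNG state existed before
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Collect a stress-strain deformation series
#'
#' Amplitudes are evenly spaced over \eqn{[-a_{max}, +a_{max}]} excluding 0
#' (for \code{n_points = 12}: \eqn{\pm\{1,3,5,7,9,11\}/11 \cdot a_{max}}); the
#' symmetric spacing cancels even-order anharmonicity in the fitted slope, and
#' zero strain is skipped because it carries no slope information.
#'
#' @param oracle a \code{stress_calculator}.
#' @param pattern a \code{strain_pattern}.
#' @param max_amplitude maximum dimensionless strain amplitude. Default 0.003.
#' @param n_points number of amplitudes, even, at least 4. Default 12.
#' @return object of class \code{deformation_series}: \code{pattern},
#'   \code{amplitudes}, \code{stresses} (list of symmetric 3x3 GPa).
#' @export
collect_series <- function(oracle, pattern, max_amplitude = 0.003,
                           n_points = 12) {
  stopifnot(inherits(oracle, "stress_calculator"),
            inherits(pattern, "strain_pattern"),
            max_amplitude > 0, n_points >= 4, n_points %% 2 == 0)
  amps <- seq(-(n_points - 1), n_points - 1, by = 2) / (n_points - 1) *
    max_amplitude
  stresses <- lapply(amps, function(a) {
    s <- tryCatch(oracle$evaluate(strain_tensor(pattern$component, a,
                                                pattern$weight)),
                  error = function(e)
                    stop(sprintf("stress evaluation failed at amplitude %g: %s",
                                 a, conditionMessage(e))))
    s
  })
  structure(list(pattern = pattern, amplitudes = amps, stresses = stresses),
            class = "deformation_series")
}

# per-series OLS: slope of each stress component vs amplitude. The oracle
# contract makes the stress noise homoscedastic across components, so the
# residual variance is pooled over the six regressions of the series, which
# sharpens the per-coefficient stderr (6 (n - p) dof instead of n - p).
series_slopes <- function(series, intercept = FALSE) {
  a <- series$amplitudes
  Yv <- vapply(series$stresses, stress_to_voigt, numeric(6))  # 6 x n
  n <- length(a)
  p <- if (intercept) 2L else 1L
  slopes <- numeric(6); rss <- 0
  sxx <- if (intercept) sum((a - mean(a))^2) else sum(a^2)
  for (i in 1:6) {
    y <- Yv[i, ]
    if (intercept) {
      fit <- stats::lm.fit(cbind(1, a), y)
      b <- fit$coefficients[2]
      r <- fit$residuals
    } else {
      b <- sum(a * y) / sum(a^2)
      r <- y - b * a
    }
    slopes[i] <- b; rss <- rss + sum(r^2)
  }
  dof <- 6 * (n - p)
  s2 <- rss / dof
  list(slopes = slopes, se = rep(sqrt(s2 / sxx), 6), rss = rss, dof = dof)
}

#' Fit elastic constants from deformation series
#'
#' Each series contributes one column of the stiffness matrix: the
#' ordinary-least-squares slope of each Voigt stress component against the
#' strain amplitude. Columns not strained by the class's canonical pattern set
#' are completed from the class's symmetry ties (equal coefficients,
#' structural zeros; for isotropic media the shear diagonal is (C11 - C12)/2).
#' The assembled matrix is symmetrized as \eqn{(C + C^T)/2}, with the
#' pre-symmetrization asymmetry reported as a fit diagnostic.
#'
#' @param series_set list of \code{deformation_series}.
#' @param laue_class symmetry class used for completion; default
#'   \code{"triclinic"} (requires all six components covered).
#' @param intercept fit an intercept per regression (detects residual stress);
#'   default \code{FALSE}, since the oracle contract fixes evaluate(0) = 0.
#' @return object of class \code{fit_result}: \code{stiffness}
#'   (\code{voigt_stiffness}), \code{per_coefficient_stderr} (6x6 GPa),
#'   \code{residual_rms} (GPa), \code{max_asymmetry} (GPa),
#'   \code{laue_class}.
#' @export
fit_constants <- function(series_set, laue_class = "triclinic",
                          intercept = FALSE) {
  laue_class <- match.arg(laue_class, .laue_classes)
  if (inherits(series_set, "deformation_series"))
    series_set <- list(series_set)
  comps <- vapply(series_set, function(s) s$pattern$component, integer(1))
  need <- .pattern_components[[laue_class]]
  missing <- setdiff(need, comps)
  if (length(missing) > 0)
    stop("underdetermined: no series strains Voigt component(s) ",
         paste(missing, collapse = ", "), " required for class ", laue_class)

  P <- matrix(NA_real_, 6, 6)      # measured coefficients, column = pattern
  SE <- matrix(NA_real_, 6, 6)
  rss <- 0; dof <- 0
  for (s in series_set) {
    sl <- series_slopes(s, intercept = intercept)
    k <- s$pattern$component
    P[, k] <- sl$slopes / s$pattern$weight
    SE[, k] <- sl$se / abs(s$pattern$weight)
    rss <- rss + sl$rss; dof <- dof + sl$dof
  }

  L <- class_tie_labels(laue_class)
  Cfit <- matrix(0, 6, 6); SEfit <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (!is.na(P[i, j])) { Cfit[i, j] <- P[i, j]; SEfit[i, j] <- SE[i, j] }
    else if (!is.na(P[j, i])) { Cfit[i, j] <- P[j, i]; SEfit[i, j] <- SE[j, i] }
    else if (L[i, j] > 0) {
      mates <- which(L == L[i, j] & (!is.na(P) | !is.na(t(P))), arr.ind = TRUE)
      vals <- c(P[mates], t(P)[mates])
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        if (laue_class == "isotropic" && i == j && i >= 4) {
          # isotropy constrains the shear modulus to (C11 - C12)/2
          Cfit[i, j] <- (P[1, 1] - mean(c(P[2, 1], P[3, 1]))) / 2
          SEfit[i, j] <- sqrt(SE[1, 1]^2 + SE[2, 1]^2) / 2
        } else {
          stop("underdetermined: coefficient (", i, ",", j,
               ") not measured and not tied to a measured one")
        }
      } else {
        Cfit[i, j] <- mean(vals)
        SEfit[i, j] <- mean(c(SE[mates], t(SE)[mates]), na.rm = TRUE)
      }
    }
    # label 0: structural zero, stays 0
  }
  asym <- max(abs(Cfit - t(Cfit)))
  Csym <- (Cfit + t(Cfit)) / 2
  SEsym <- (SEfit + t(SEfit)) / 2
  structure(list(
    stiffness = validate_stiffness(Csym, tolerance = Inf,
                                   source_label = paste0("fit:", laue_class)),
    per_coefficient_stderr = SEsym,
    residual_rms = sqrt(rss / max(dof, 1)),
    max_asymmetry = asym,
    laue_class = laue_class), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Elastic-constant fit (%s): residual rms %.4g GPa, max asymmetry %.4g GPa\n",
    x$laue_class, x$residual_rms, x$max_asymmetry))
  print(round(unclass_matrix(x$stiffness), 4))
  invisible(x)
}

#' Write deformation series to a CSV archive
#'
#' Columns \code{pattern_label}, \code{amplitude}, \code{s11}, \code{s22},
#' \code{s33}, \code{s23}, \code{s13}, \code{s12} (GPa), written at 12
#' significant digits so a read/write round trip is exact at that precision.
#'
#' @param series_set list of \code{deformation_series} (or a single one).
#' @param path output CSV path.
#' @export
write_series_csv <- function(series_set, path) {
  if (inherits(series_set, "deformation_series"))
    series_set <- list(series_set)
  rows <- do.call(rbind, lapply(series_set, function(s) {
    Yv <- t(vapply(s$stresses, stress_to_voigt, numeric(6)))
    data.frame(pattern_label = s$pattern$label,
               amplitude = s$amplitudes,
               s11 = Yv[, 1], s22 = Yv[, 2], s33 = Yv[, 3],
               s23 = Yv[, 4], s13 = Yv[, 5], s12 = Yv[, 6])
  }))
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(x) formatC(x, format = "g",
                                                     digits = 12))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deformation-series CSV archive
#'
#' @param path CSV written by \code{\link{write_series_csv}}.
#' @return list of \code{deformation_series}, one per pattern label.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pattern_label", "amplitude", "s11", "s22", "s33", "s23", "s13",
            "s12")
  if (!all(need %in% names(df)))
    stop("series archive must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$pattern_label), function(d) {
    d <- d[order(d$amplitude), ]
    comp <- as.integer(sub("^e", "", d$pattern_label[1]))
    if (is.na(comp) || comp < 1 || comp > 6)
      stop("cannot infer strained component from label: ", d$pattern_label[1])
    stresses <- lapply(seq_len(nrow(d)), function(r)
      matrix(c(d$s11[r], d$s12[r], d$s13[r],
               d$s12[r], d$s22[r], d$s23[r],
               d$s13[r], d$s23[r], d$s33[r]), 3, 3))
    structure(list(
      pattern = structure(list(component = comp, weight = 1,
                               label = d$pattern_label[1]),
                          class = "strain_pattern"),
      amplitudes = d$amplitude, stresses = stresses),
      class = "deformation_series")
  })
}
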