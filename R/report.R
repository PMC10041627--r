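# End-to-end deformability report: validate -> stability -> Voigt averages ->
# directional extrema -> anisotropy -> plane slices (-> contacts -> alignment
# when a structure is given). JSON is the canonical report; CSV sidecars hold
# the sampled slices and surfaces.

#' Full deformability analysis of one stiffness tensor
#'
#' Runs the whole pipeline on a stiffness matrix: Born stability, Voigt
#' averages, global Young's and shear extrema with anisotropy indices, plane
#' slices in the requested crystallographic planes, and, when a structure is
#' supplied, contact detection and the modulus/contact alignment report.
#' When the tensor is unstable the directional sections are omitted and
#' \code{stable} is \code{FALSE}; everything reported is re-derivable from the
#' inputs and the recorded configuration.
#'
#' @param C a \code{voigt_stiffness} (or path to a stiffness matrix file).
#' @param cell optional \code{crystal_cell} for plane slices and contacts.
#' @param sites optional site data.frame (see \code{\link{detect_contacts}}).
#' @param planes planes to slice. Default \code{c("ab", "ac", "bc")}.
#' @param properties slice properties. Default \code{c("young", "shear_min")}.
#' @param n_seed,n_chi,n_angles sampling controls (see
#'   \code{\link{global_extrema}}, \code{\link{plane_slice}}).
#' @param contact_criteria named list overriding \code{\link{detect_contacts}}
#'   defaults.
#' @param round_digits decimals used for the rounded convenience fields
#'   (moduli and indices as conventionally printed). Default 1.
#' @return list of class \code{deformability_report}.
#' @export
analyze_stiffness <- function(C, cell = NULL, sites = NULL,
                              planes = c("ab", "ac", "bc"),
                              properties = c("young", "shear_min"),
                              n_seed = 2562, n_chi = 72, n_angles = 360,
                              contact_criteria = list(),
                              round_digits = 1) {
  if (is.character(C)) C <- read_stiffness(C)
  stopifnot(inherits(C, "voigt_stiffness"))
  config <- list(planes = planes, properties = properties, n_seed = n_seed,
                 n_chi = n_chi, n_angles = n_angles,
                 contact_criteria = contact_criteria,
                 round_digits = round_digits)
  st <- born_stability(C)
  rep <- list(source_label = attr(C, "source_label") %||% "",
              stiffness = unclass_matrix(C),
              stable = st$stable, eigenvalues = st$eigenvalues,
              config = config)
  if (!st$stable) {
    class(rep) <- "deformability_report"
    return(rep)
  }
  av <- voigt_averages(C)
  S <- invert_to_compliance(C)
  extE <- global_extrema(S, "young", n_seed = n_seed, n_chi = n_chi)
  extG <- global_extrema(S, "shear", n_seed = n_seed, n_chi = n_chi)
  rep$K_V <- av$K_V; rep$G_V <- av$G_V; rep$E_V <- av$E_V
  rep$E_min <- extE$min_value; rep$E_max <- extE$max_value
  rep$E_min_direction <- extE$min_direction
  rep$E_max_direction <- extE$max_direction
  rep$G_min <- extG$min_value; rep$G_max <- extG$max_value
  rep$G_min_direction <- extG$min_direction
  rep$G_max_direction <- extG$max_direction
  rep$A_E <- anisotropy_index(extE)
  rep$A_G <- anisotropy_index(extG)
  rep$rounded <- lapply(list(G_V = av$G_V, E_V = av$E_V, A_G = rep$A_G,
                             A_E = rep$A_E), round, digits = round_digits)
  rep$extrema <- list(young = extE, shear = extG)

  if (!is.null(cell)) {
    rep$slices <- list()
    for (pl in planes) for (pr in properties) {
      rep$slices[[paste(pl, pr, sep = "_")]] <-
        plane_slice(S, cell, pl, pr, n_angles = n_angles, n_chi = n_chi)
    }
    if (!is.null(sites)) {
      contacts <- do.call(detect_contacts,
                          c(list(sites = sites, cell = cell),
                            contact_criteria))
      rep$contacts <- contacts
      if (nrow(contacts) > 0) {
        young_slices <- rep$slices[grepl("_young$", names(rep$slices))]
        rep$alignment <- alignment_report(extE, contacts,
                                          slices = young_slices)
      }
    }
  }
  class(rep) <- "deformability_report"
  rep
}

#' @export
print.deformability_report <- function(x, ...) {
  cat("Deformability report", if (nzchar(x$source_label))
    paste0(" - ", x$source_label), "\n", sep = "")
  if (!x$stable) {
    cat("tensor is NOT Born-stable; directional analysis omitted\n")
    return(invisible(x))
  }
  cat(sprintf("  G_V = %.4g GPa  E_V = %.4g GPa  (K_V = %.4g GPa)\n",
              x$G_V, x$E_V, x$K_V))
  cat(sprintf("  E: %.4g .. %.4g GPa  A_E = %.4g\n", x$E_min, x$E_max, x$A_E))
  cat(sprintf("  G: %.4g .. %.4g GPa  A_G = %.4g\n", x$G_min, x$G_max, x$A_G))
  invisible(x)
}

#' Write a deformability report to JSON (+ CSV sidecars)
#'
#' The JSON body is deterministic for identical inputs; slices and surfaces
#' are written as CSV sidecars next to it.
#'
#' @param report a \code{deformability_report}.
#' @param path output JSON path.
#' @return invisibly, the paths written.
#' @export
write_report_json <- function(report, path) {
  body <- report[setdiff(names(report), c("slices", "extrema", "contacts",
                                          "alignment"))]
  body$stiffness <- apply(body$stiffness, 1, identity, simplify = FALSE)
  if (!is.null(report$alignment)) {
    body$alignment <- list(classes = report$alignment$classes,
                           planes = report$alignment$planes)
  }
  if (!is.null(report$contacts))
    body$n_contacts <- nrow(report$contacts)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  written <- path
  if (!is.null(report$slices)) {
    for (nm in names(report$slices)) {
      p <- file.path(dirname(path),
                     paste0(sub("\\.json$", "", basename(path)), "_slice_",
                            nm, ".csv"))
      write_slice_csv(report$slices[[nm]], p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Fit elastic constants from an oracle, then analyze the result
#'
#' Generates the canonical deformation series for the Laue class from a
#' stress calculator, fits the stiffness matrix, and chains into
#' \code{\link{analyze_stiffness}}. When the generating tensor is known the
#' recovery error is reported.
#'
#' @param oracle a \code{stress_calculator} (see
#'   \code{\link{synthetic_oracle}}).
#' @param laue_class symmetry class driving the pattern set.
#' @param max_amplitude,n_points series controls
#'   (see \code{\link{collect_series}}).
#' @param C_truth optional generating \code{voigt_stiffness} for the recovery
#'   diagnostic.
#' @param ... passed to \code{\link{analyze_stiffness}}.
#' @return list with \code{fit} (a \code{fit_result}), \code{report}
#'   (a \code{deformability_report}), and optionally
#'   \code{max_abs_error} (GPa) against \code{C_truth}.
#' @export
fit_and_analyze <- function(oracle, laue_class, max_amplitude = 0.003,
                            n_points = 12, C_truth = NULL, ...) {
  patterns <- generate_patterns(laue_class)
  series <- lapply(patterns, function(p)
    collect_series(oracle, p, max_amplitude = max_amplitude,
                   n_points = n_points))
  fit <- fit_constants(series, laue_class = laue_class)
  out <- list(fit = fit,
              report = analyze_stiffness(fit$stiffness, ...))
  if (!is.null(C_truth))
    out$max_abs_error <- max(abs(as_stiffness_matrix(fit$stiffness) -
                                   as_stiffness_matrix(C_truth)))
  out
}
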