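#' Read a 6x6 stiffness matrix from a plain-text file
#'
#' The accepted dialect is six lines of six whitespace-separated reals in GPa,
#' optionally preceded by comment lines starting with \code{#} (the format the
#' ELATE web tool accepts).
#'
#' @param path file path.
#' @param tolerance symmetrization tolerance passed to
#'   \code{\link{validate_stiffness}}.
#' @param source_label provenance label; defaults to the file name.
#' @return a \code{voigt_stiffness} object.
#' @export
read_stiffness <- function(path, tolerance = 1e-3,
                           source_label = basename(path)) {
  if (!file.exists(path)) stop("cannot read stiffness file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != 6)
    stop(sprintf("expected 6 matrix rows in %s, found %d", path, length(lines)))
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:],]+")[[1]]))
    v <- v[!is.na(v)]
    if (length(v) != 6)
      stop("each row must contain 6 numbers: ", l)
    v
  })
  validate_stiffness(do.call(rbind, rows), tolerance = tolerance,
                     source_label = source_label)
}

#' Write a stiffness matrix to a plain-text file
#'
#' Emits six rows of six values at 6 significant digits, with an optional
#' comment header.
#'
#' @param C \code{voigt_stiffness} or 6x6 matrix.
#' @param path output file path.
#' @param header optional character vector of comment lines (written with
#'   a leading \code{#}).
#' @export
write_stiffness <- function(C, path, header = NULL) {
  Cm <- as_stiffness_matrix(C)
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  body <- apply(Cm, 1, function(r)
    paste(formatC(signif(r, 6), format = "g", digits = 6), collapse = " "))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Stability-and-averages JSON report for one stiffness matrix
#'
#' @param C \code{voigt_stiffness}.
#' @param path optional path; when given the JSON is written there.
#' @return the report as a list: \code{source_label}, \code{stable},
#'   \code{eigenvalues} (6, GPa), and when stable \code{K_V}, \code{G_V},
#'   \code{E_V}.
#' @export
stiffness_report <- function(C, path = NULL) {
  st <- born_stability(C)
  rep <- list(source_label = attr(C, "source_label") %||% "",
              stable = st$stable,
              eigenvalues = st$eigenvalues)
  if (st$stable) {
    av <- voigt_averages(C)
    rep$K_V <- av$K_V; rep$G_V <- av$G_V; rep$E_V <- av$E_V
  }
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  rep
}
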