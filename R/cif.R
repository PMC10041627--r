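# Minimal CIF 1.1 reader: cell parameters, atom-site loop, symmetry
# operators given as x,y,z strings. Covers P1 and symmetry-listed
# small-molecule files; disorder is not modelled (every listed site is kept,
# with a warning when occupancies below 1 are seen).

strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

tokenize_cif_line <- function(line) {
  # whitespace split honouring single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Read a crystal structure from a CIF file
#'
#' Parses cell parameters, the atom-site loop (label, type symbol, fractional
#' coordinates) and, when present, symmetry operators
#' (\code{_symmetry_equiv_pos_as_xyz} or
#' \code{_space_group_symop_operation_xyz}), which are applied to expand the
#' asymmetric unit to P1. Fractional coordinates are wrapped into [0, 1) and
#' symmetry-duplicate positions are merged.
#'
#' @param path CIF file path.
#' @param dedup_tol fractional-coordinate tolerance for merging
#'   symmetry-equivalent sites. Default 1e-3.
#' @return list with \code{cell} (a \code{crystal_cell}) and \code{sites}
#'   (data.frame: element, x, y, z, site_label).
#' @export
read_cif <- function(path, dedup_tol = 1e-3) {
  if (!file.exists(path)) stop("cannot read CIF file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  cellval <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) stop("CIF is missing ", tag)
    strip_su(tokenize_cif_line(hit[1])[2])
  }
  cell <- crystal_cell(cellval("_cell_length_a"), cellval("_cell_length_b"),
                       cellval("_cell_length_c"), cellval("_cell_angle_alpha"),
                       cellval("_cell_angle_beta"), cellval("_cell_angle_gamma"))

  # collect loops: header tags then data rows
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      tags <- character(0)
      i <- i + 1
      while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, tokenize_cif_line(lines[i])[1])
        i <- i + 1
      }
      rows <- list()
      while (i <= length(lines)) {
        l <- trimws(lines[i])
        if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
            startsWith(l, "data_")) break
        rows[[length(rows) + 1]] <- tokenize_cif_line(lines[i])
        i <- i + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
    } else i <- i + 1
  }

  find_loop <- function(need_any) {
    for (lp in loops) if (any(need_any %in% lp$tags)) return(lp)
    NULL
  }

  atoms <- find_loop(c("_atom_site_fract_x"))
  if (is.null(atoms)) stop("CIF has no _atom_site loop")
  col <- function(lp, tag) match(tag, lp$tags)
  ix <- col(atoms, "_atom_site_fract_x")
  iy <- col(atoms, "_atom_site_fract_y")
  iz <- col(atoms, "_atom_site_fract_z")
  il <- col(atoms, "_atom_site_label")
  it <- col(atoms, "_atom_site_type_symbol")
  io <- col(atoms, "_atom_site_occupancy")
  rows <- atoms$rows[vapply(atoms$rows, length, 1L) >= length(atoms$tags)]
  lab <- vapply(rows, function(r) if (!is.na(il)) r[il] else r[it],
                character(1))
  elem <- if (!is.na(it)) vapply(rows, `[`, character(1), it) else
    sub("[0-9'].*$", "", lab)
  elem <- sub("[+-].*$", "", elem)
  occ <- if (!is.na(io)) vapply(rows, function(r) strip_su(r[io]), numeric(1))
         else rep(1, length(rows))
  if (any(occ < 1 - 1e-6))
    warning("partial occupancies found; disorder is not modelled and all ",
            "listed sites are kept")
  frac <- cbind(vapply(rows, function(r) strip_su(r[ix]), numeric(1)),
                vapply(rows, function(r) strip_su(r[iy]), numeric(1)),
                vapply(rows, function(r) strip_su(r[iz]), numeric(1)))

  symloop <- find_loop(c("_symmetry_equiv_pos_as_xyz",
                         "_space_group_symop_operation_xyz"))
  ops <- if (is.null(symloop)) list("x, y, z") else {
    tag <- intersect(c("_symmetry_equiv_pos_as_xyz",
                       "_space_group_symop_operation_xyz"), symloop$tags)[1]
    k <- col(symloop, tag)
    lapply(symloop$rows, function(r) r[length(r) - length(symloop$tags) + k])
  }

  apply_op <- function(op, p) {
    parts <- strsplit(gsub("['\"]", "", op), ",")[[1]]
    if (length(parts) != 3) stop("malformed symmetry operator: ", op)
    vapply(parts, function(expr) {
      expr <- gsub("\\s", "", tolower(expr))
      if (grepl("[^xyz0-9+/*.-]", expr))
        stop("unsupported symmetry operator: ", op)
      eval(parse(text = expr),
           envir = list(x = p[1], y = p[2], z = p[3]))
    }, numeric(1), USE.NAMES = FALSE)
  }

  out_lab <- character(0); out_elem <- character(0)
  out_frac <- matrix(numeric(0), ncol = 3)
  seen <- character(0)
  for (s in seq_len(nrow(frac))) {
    for (op in ops) {
      p <- apply_op(op, frac[s, ]) %% 1
      p[p > 1 - dedup_tol / 2] <- 0   # wrap near-1 back to 0 before keying
      key <- paste(elem[s], paste(round(p / dedup_tol), collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      out_lab <- c(out_lab, lab[s]); out_elem <- c(out_elem, elem[s])
      out_frac <- rbind(out_frac, p)
    }
  }
  sites <- data.frame(element = out_elem, x = out_frac[, 1],
                      y = out_frac[, 2], z = out_frac[, 3],
                      site_label = make.unique(out_lab, sep = "_"),
                      stringsAsFactors = FALSE)
  list(cell = cell, sites = sites)
}

#' Write a structure to a minimal P1 CIF file
#'
#' @param cell a \code{crystal_cell}.
#' @param sites data.frame with element, fractional x/y/z, site_label.
#' @param path output path.
#' @param data_name CIF data block name.
#' @export
write_cif <- function(cell, sites, path, data_name = "structure") {
  lines <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s %s %.6f %.6f %.6f", sites$site_label, sites$element,
            sites$x %% 1, sites$y %% 1, sites$z %% 1))
  writeLines(lines, path)
  invisible(path)
}
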