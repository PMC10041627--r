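# Deterministic quasi-uniform sphere sampling by icosahedron subdivision.
# Vertex counts by level: 12, 42, 162, 642, 2562, ...

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- function(a, b) paste(min(a, b), max(a, b))
  midpoints <- new.env(parent = emptyenv())
  get_mid <- function(a, b) {
    k <- key(a, b)
    idx <- midpoints[[k]]
    if (!is.null(idx)) return(idx)
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    v <<- rbind(v, m)
    idx <- nrow(v)
    midpoints[[k]] <- idx
    idx
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    nf[4 * t - 3, ] <- c(a, ab, ca)
    nf[4 * t - 2, ] <- c(b, bc, ab)
    nf[4 * t - 1, ] <- c(c, ca, bc)
    nf[4 * t, ]     <- c(ab, bc, ca)
  }
  list(vertices = v, faces = nf)
}

#' Quasi-uniform unit directions on the sphere
#'
#' Vertices of a subdivided icosahedron projected to the unit sphere: a
#' deterministic quasi-uniform direction set with no seed dependence. The
#' smallest subdivision level with at least \code{n_min} vertices is used
#' (levels give 12, 42, 162, 642, 2562, ... vertices).
#'
#' @param n_min minimum number of directions.
#' @return N x 3 matrix of unit row vectors, N >= n_min.
#' @export
icosphere_directions <- function(n_min = 2562) {
  stopifnot(n_min >= 1)
  mesh <- icosahedron()
  while (nrow(mesh$vertices) < n_min) mesh <- subdivide_once(mesh)
  mesh$vertices
}
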