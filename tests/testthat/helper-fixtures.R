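# Shared fixtures, built in code.

# cubic reference tensor: C11 = 12, C12 = 4, C44 = 3 GPa.
# closed forms: S11 = 0.1, S12 = -0.025, S44 = 1/3;
# E<100> = 10, E<111> = 7.826087; G(001 plane) = 3; G(110,-110) = 4.
cubic_example <- function() {
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 4
  diag(m)[1:3] <- 12
  diag(m)[4:6] <- 3
  validate_stiffness(m, source_label = "cubic example")
}

# isotropic with E = 10, nu = 0.25: C11 = 12, C12 = 4, C44 = mu = 4
iso_example <- function() isotropic_stiffness(10, 0.25)

# transversely isotropic (hexagonal-limit): E depends on polar angle only
hexagonal_example <- function() {
  m <- matrix(0, 6, 6)
  m[1, 1] <- m[2, 2] <- 14; m[3, 3] <- 30
  m[1, 2] <- m[2, 1] <- 6
  m[1, 3] <- m[3, 1] <- m[2, 3] <- m[3, 2] <- 5
  diag(m)[4:5] <- 7
  m[6, 6] <- (m[1, 1] - m[1, 2]) / 2
  validate_stiffness(m, source_label = "transversely isotropic")
}

# tetragonal tensor stiffest along c (a fibrous, tape-like crystal)
fibrous_example <- function() {
  m <- matrix(0, 6, 6)
  m[1, 1] <- m[2, 2] <- 10; m[3, 3] <- 30
  m[1, 2] <- m[2, 1] <- 5
  m[1, 3] <- m[3, 1] <- m[2, 3] <- m[3, 2] <- 5
  diag(m)[4:5] <- 4
  m[6, 6] <- 3
  validate_stiffness(m, source_label = "fibrous tetragonal")
}

# deterministic random proper rotation
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# deterministic random unit vector
random_unit <- function(seed) {
  set.seed(seed)
  u <- rnorm(3)
  u / sqrt(sum(u^2))
}

# plain numeric matrix, class and label attributes dropped
strip_attrs <- function(C) {
  m <- unclass(C)
  attr(m, "source_label") <- NULL
  m
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
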