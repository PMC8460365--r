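# Independent brute-force implementations of the geometric primitives,
# kept deliberately different from the package's formulas so the two can
# cross-check each other.

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

norm3 <- function(v) sqrt(sum(v^2))

# projection via the explicit outer-product projector matrix
oracle_project <- function(v, n) {
  nh <- n / norm3(n)
  P <- diag(3) - nh %o% nh
  as.numeric(P %*% v)
}

# angle via clamped arccos of the normalized dot product
oracle_angle <- function(u, v) {
  d <- sum(u * v) / (norm3(u) * norm3(v))
  acos(max(-1, min(1, d))) * 180 / pi
}

# betweenness via 2D sign tests in an in-plane orthonormal basis
oracle_between <- function(v, a, b) {
  e1 <- a / norm3(a)
  n <- cross3(a, b)
  if (norm3(n) < 1e-12 * norm3(a) * norm3(b)) {
    # a, b (anti)parallel: v between iff aligned with a (or any, if b = -a
    # spans the half-turn: fall back to the angle-sum definition)
    return(abs(oracle_angle(a, v) + oracle_angle(v, b) -
                 oracle_angle(a, b)) <= 1e-6)
  }
  e2 <- cross3(n / norm3(n), e1)
  p <- function(x) c(sum(x * e1), sum(x * e2))
  a2 <- p(a); b2 <- p(b); v2 <- p(v)
  cr <- function(x, y) x[1] * y[2] - x[2] * y[1]
  s <- sign(cr(a2, b2))
  cr(a2, v2) * s >= -1e-12 && cr(v2, b2) * s >= -1e-12
}
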