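# Shared oracles and geometry helpers.  All expected values here are
# computed by routes independent of the writhe-table recursion: adaptive
# 2D quadrature of the Gauss integrand for single segment pairs, and
# direct double sums over the R-side pairwise matrix for sub-chains.

# (1/4pi) * int_0^1 int_0^1 ((u x v) . (g1(s) - g2(t))) / |g1 - g2|^3
# by adaptive quadrature
quad_pair_writhe <- function(p0, p1, q0, q1, reltol = 1e-10) {
  u <- p1 - p0; v <- q1 - q0
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  f <- function(s, t) {
    d1 <- (p0[1] + s * u[1]) - (q0[1] + t * v[1])
    d2 <- (p0[2] + s * u[2]) - (q0[2] + t * v[2])
    d3 <- (p0[3] + s * u[3]) - (q0[3] + t * v[3])
    (cr[1] * d1 + cr[2] * d2 + cr[3] * d3) / (d1^2 + d2^2 + d3^2)^1.5
  }
  pracma::integral2(f, 0, 1, 0, 1, reltol = reltol)$Q / (4 * pi)
}

# brute-force sub-chain writhe W(a, b) for all a <= b from the pairwise
# matrix: sum over the upper triangle of the (a..b) block
brute_force_table <- function(wm) {
  S <- nrow(wm)
  W <- matrix(0, S, S)
  for (a in seq_len(S))
    for (b in a:S)
      W[a, b] <- sum(wm[a:b, a:b]) / 2  # symmetric, zero diagonal
  W
}

# seeded random rotation (uniform via QR with positive determinant) and
# translation
random_rigid_motion <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = rnorm(3, sd = 25))
}

as_iv <- function(v) interval(v[1], v[2])

# exhaustive stepped window-pair enumeration, independent of the table
# look-ups: direct cross sums from the pairwise matrix
stepped_pairs_brute <- function(trace, window, step) {
  wm <- pairwise_writhe_matrix(trace)
  S <- nrow(wm)
  starts <- seq.int(0L, S - window, by = step)
  out <- expand.grid(a = starts, b = starts)
  out <- out[out$b >= out$a + window, , drop = FALSE]
  out$mw <- mapply(function(a, b)
    sum(wm[(a:(a + window - 1L)) + 1L, (b:(b + window - 1L)) + 1L]),
    out$a, out$b)
  out
}
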