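#' Writhe contribution of one segment pair
#'
#' Evaluates the closed form of the Gauss integral for two straight line
#' segments: the signed solid angle swept by the connecting direction —
#' the area of the spherical quadrilateral spanned by the four unit
#' vectors between the segments' endpoints — divided by `4 * pi`.  The
#' quadrilateral is split into two spherical triangles, each evaluated
#' with the atan2-of-scalar-triple-product (van Oosterom-Strackee)
#' formula, which stays fully accurate near coplanarity where
#' arcsine-based forms lose half the working precision.  The sign
#' follows the right-hand-rule crossing convention, so that summing
#' `w(i, j)` over all segment pairs `i < j` of a polygon gives that
#' polygon's writhe in the one-count-per-pair normalisation used
#' throughout this package, and summing over all cross pairs of two
#' disjoint closed polygons gives their integer linking number.
#'
#' Coplanar endpoint configurations give 0 to machine precision.
#' Segments sharing an endpoint (e.g. consecutive trace segments) give
#' exactly 0, the solid angle vanishing; connecting directions shorter
#' than 1e-12 are treated as degenerate and contribute 0.
#'
#' @param p0,p1 endpoints of the first segment (numeric length 3).
#' @param q0,q1 endpoints of the second segment.
#' @return A single real, dimensionless.
#' @export
#' @examples
#' segment_pair_writhe(c(0, 0, 0), c(1, 0, 0),
#'                     c(0.5, -0.5, 0.5), c(0.5, 0.5, 0.5))
segment_pair_writhe <- function(p0, p1, q0, q1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  q0 <- as.numeric(q0); q1 <- as.numeric(q1)
  stopifnot(length(p0) == 3L, length(p1) == 3L,
            length(q0) == 3L, length(q1) == 3L)
  if (all(p0 == p1) || all(q0 == q1))
    stop("degenerate (zero-length) segment")
  if (all(p0 == q0) || all(p0 == q1) || all(p1 == q0) || all(p1 == q1))
    return(0)

  # unit vectors from each endpoint of segment p to each endpoint of q,
  # in cyclic order around the Gauss-map quadrilateral
  va <- q0 - p0; vb <- q1 - p0; vc <- q1 - p1; vd <- q0 - p1
  l <- sqrt(c(sum(va^2), sum(vb^2), sum(vc^2), sum(vd^2)))
  if (any(l < 1e-12)) return(0)
  a <- va / l[1L]; b <- vb / l[2L]; c <- vc / l[3L]; d <- vd / l[4L]

  tri <- function(x, y, z) {
    num <- x[1L] * (y[2L] * z[3L] - y[3L] * z[2L]) -
      x[2L] * (y[1L] * z[3L] - y[3L] * z[1L]) +
      x[3L] * (y[1L] * z[2L] - y[2L] * z[1L])
    2 * atan2(num, 1 + sum(x * y) + sum(y * z) + sum(z * x))
  }
  -(tri(a, b, c) + tri(a, c, d)) / (4 * pi)
}

#' All pairwise segment writhe contributions of a trace
#'
#' Vectorised evaluation of [segment_pair_writhe()] for every segment pair
#' of a trace, returned as a symmetric `S x S` matrix with zero diagonal
#' (and zero for consecutive segments, which share an endpoint).  This is
#' the reference engine behind [gauss_integral_oracle()]; it is computed
#' entirely in R, independently of the compiled recursion in
#' [build_writhe_table()].
#'
#' @param trace a [ca_trace()] or a numeric matrix of xyz rows.
#' @return Symmetric numeric matrix, `W[i, j]` = contribution of segments
#'   `i - 1` and `j - 1` (0-based).
#' @export
pairwise_writhe_matrix <- function(trace) {
  pts <- if (inherits(trace, "ca_trace")) trace$points else as.matrix(trace)
  S <- nrow(pts) - 1L
  if (S < 1L) stop("need at least 2 points")
  out <- matrix(0, S, S)
  if (S < 3L) return(out)
  ij <- which(upper.tri(out), arr.ind = TRUE)
  ij <- ij[ij[, 2L] - ij[, 1L] >= 2L, , drop = FALSE]  # adjacent pairs are 0
  i <- ij[, 1L]; j <- ij[, 2L]

  P0 <- pts[i, , drop = FALSE]; P1 <- pts[i + 1L, , drop = FALSE]
  Q0 <- pts[j, , drop = FALSE]; Q1 <- pts[j + 1L, , drop = FALSE]

  rdot <- function(a, b) rowSums(a * b)
  rtriple <- function(x, y, z)
    x[, 1L] * (y[, 2L] * z[, 3L] - y[, 3L] * z[, 2L]) -
    x[, 2L] * (y[, 1L] * z[, 3L] - y[, 3L] * z[, 1L]) +
    x[, 3L] * (y[, 1L] * z[, 2L] - y[, 2L] * z[, 1L])

  a <- Q0 - P0; b <- Q1 - P0; c <- Q1 - P1; d <- Q0 - P1
  la <- sqrt(rdot(a, a)); lb <- sqrt(rdot(b, b))
  lc <- sqrt(rdot(c, c)); ld <- sqrt(rdot(d, d))
  ok <- la >= 1e-12 & lb >= 1e-12 & lc >= 1e-12 & ld >= 1e-12
  a <- a / la; b <- b / lb; c <- c / lc; d <- d / ld

  om1 <- 2 * atan2(rtriple(a, b, c),
                   1 + rdot(a, b) + rdot(b, c) + rdot(c, a))
  om2 <- 2 * atan2(rtriple(a, c, d),
                   1 + rdot(a, c) + rdot(c, d) + rdot(d, a))
  w <- ifelse(ok, -(om1 + om2) / (4 * pi), 0)

  out[cbind(i, j)] <- w
  out[cbind(j, i)] <- w
  out
}

#' Build the all-sub-chain writhe table
#'
#' Fills the triangular table `W(a, b)` = writhe of the sub-chain spanning
#' segments `a..b` (0-based, inclusive) for all `a <= b`, using the
#' inclusion-exclusion recursion
#' `W(a, b) = W(a, b - 1) + W(a + 1, b) - W(a + 1, b - 1) + w(a, b)`,
#' where `w(a, b)` is [segment_pair_writhe()] of segments `a` and `b`.
#' The cost is exactly `S * (S - 1) / 2` segment-pair evaluations for `S`
#' segments; the recursion runs in compiled code.
#'
#' @param trace a [ca_trace()] (or numeric matrix of points) with at least
#'   2 segments.
#' @return An object of class `writhe_table`: list with `W` (dense `S x S`
#'   matrix, upper triangle filled, `W[a+1, b+1]` holding `W(a, b)`), `S`,
#'   `trace_id`, and `n_pair_evals` (instrumented evaluation count).
#' @export
build_writhe_table <- function(trace) {
  if (inherits(trace, "ca_trace")) {
    pts <- trace$points
    id <- paste(trace$structure_id, trace$chain_id, trace$model_no,
                trace$fragment_no, sep = "/")
  } else {
    pts <- as.matrix(trace)
    id <- "points"
  }
  if (nrow(pts) < 3L)
    stop("need at least 3 points (2 segments) to build a writhe table")
  res <- .writhe_table_cpp(pts)
  structure(list(W = res$W, S = nrow(res$W), trace_id = id,
                 n_pair_evals = res$n_pair_evals),
            class = "writhe_table")
}

#' @export
print.writhe_table <- function(x, ...) {
  cat(sprintf("<writhe_table> %s: %d segments, whole-chain writhe %.6f\n",
              x$trace_id, x$S, x$W[1L, x$S]))
  invisible(x)
}

# table lookup with the empty-sub-chain convention: W(a, b) = 0 for a > b
# (also covers the single-segment diagonal).  Vectorised over a, b.
wt_lookup <- function(table, a, b) {
  out <- numeric(length(a))
  ok <- a <= b
  if (any(ok))
    out[ok] <- table$W[cbind(a[ok] + 1L, b[ok] + 1L)]
  out
}

#' Writhe of one sub-chain (table lookup)
#'
#' @param table a [build_writhe_table()] result.
#' @param iv an [interval()] (first/last segment index, 0-based inclusive).
#' @return The stored writhe `W(first, last)`.
#' @export
subchain_writhe <- function(table, iv) {
  stopifnot(inherits(table, "writhe_table"))
  iv <- check_interval(iv, table$S)
  table$W[iv[1L] + 1L, iv[2L] + 1L]
}

#' Mutual writhe of two disjoint sub-chains
#'
#' The cross term of the writhe between sub-chains `A` and `B` — the sum
#' of segment-pair contributions with one segment in each — obtained in
#' constant time from four look-ups in the writhe table:
#' `M(A, B) = W(A1, B2) - W(A1, B1 - 1) - W(A2 + 1, B2) + W(A2 + 1, B1 - 1)`
#' with `A = (A1, A2)`, `B = (B1, B2)` and the convention that look-ups
#' with first > last (empty sub-chains, arising when the intervals are
#' adjacent or touch the trace ends) are 0.  For two (almost) closed
#' loops the mutual writhe approximates their linking number.
#'
#' The intervals may be given in either order; they must not share a
#' segment (sharing the boundary vertex is fine).
#'
#' @inheritParams subchain_writhe
#' @param A,B disjoint [interval()]s.
#' @return The mutual writhe, a real number.
#' @export
mutual_writhe <- function(table, A, B) {
  stopifnot(inherits(table, "writhe_table"))
  A <- check_interval(A, table$S)
  B <- check_interval(B, table$S)
  if (A[1L] > B[1L]) { tmp <- A; A <- B; B <- tmp }
  if (A[2L] >= B[1L])
    stop(sprintf("intervals (%d,%d) and (%d,%d) overlap",
                 A[1L], A[2L], B[1L], B[2L]))
  wt_lookup(table, A[1L], B[2L]) -
    wt_lookup(table, A[1L], B[1L] - 1L) -
    wt_lookup(table, A[2L] + 1L, B[2L]) +
    wt_lookup(table, A[2L] + 1L, B[1L] - 1L)
}

# vectorised four-look-up mutual writhe for parallel interval arrays
# (a1 <= a2 < b1 <= b2 assumed valid)
mutual_writhe_vec <- function(table, a1, a2, b1, b2) {
  wt_lookup(table, a1, b2) - wt_lookup(table, a1, b1 - 1L) -
    wt_lookup(table, a2 + 1L, b2) + wt_lookup(table, a2 + 1L, b1 - 1L)
}

#' Brute-force Gauss integral of an interval pair
#'
#' Independent reference for [mutual_writhe()] and [subchain_writhe()]:
#' the direct `O(|A| * |B|)` double sum of segment-pair contributions,
#' evaluated in R from [pairwise_writhe_matrix()] without touching the
#' writhe-table recursion.  With `A == B` (or `B` missing) it returns the
#' sub-chain writhe, the double sum over `i < j` within the interval.
#'
#' @param trace a [ca_trace()] or point matrix.
#' @param A,B [interval()]s; disjoint unless identical.
#' @param wm optionally a precomputed [pairwise_writhe_matrix()] of the
#'   trace, to amortise sweeps over many intervals.
#' @return The writhe value, a real number.
#' @export
gauss_integral_oracle <- function(trace, A, B = A, wm = NULL) {
  if (is.null(wm)) wm <- pairwise_writhe_matrix(trace)
  S <- nrow(wm)
  A <- check_interval(A, S)
  B <- check_interval(B, S)
  if (identical(A, B)) {
    sub <- wm[(A[1L]:A[2L]) + 1L, (A[1L]:A[2L]) + 1L, drop = FALSE]
    return(sum(sub) / 2)  # symmetric, zero diagonal: half of full sum
  }
  if (A[1L] > B[1L]) { tmp <- A; A <- B; B <- tmp }
  if (A[2L] >= B[1L]) stop("intervals overlap")
  sum(wm[(A[1L]:A[2L]) + 1L, (B[1L]:B[2L]) + 1L])
}

#' Dump a writhe table as TSV
#'
#' @param table a [build_writhe_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_writhe_table <- function(table, path) {
  stopifnot(inherits(table, "writhe_table"))
  idx <- which(upper.tri(table$W, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(a = idx[, 1L] - 1L, b = idx[, 2L] - 1L,
                   writhe = sprintf("%.6f", table$W[idx]))
  writeLines(paste0("# ", jsonlite::toJSON(
    list(trace_id = table$trace_id, S = table$S, format = "writhe_table/1"),
    auto_unbox = TRUE)), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}
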