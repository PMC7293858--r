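#' Construct a C-alpha trace
#'
#' A `ca_trace` is the polygonal curve all computations in this package run
#' on: the ordered 3D coordinates of the alpha carbons of one (fragment of
#' a) protein chain, traversed N-to-C.  A trace of `N` points has `N - 1`
#' line segments; segment `i` (0-based) connects point `i` to point `i + 1`.
#' All segment/interval indices used downstream are 0-based positions along
#' the trace, not PDB residue numbers.
#'
#' @param points numeric matrix with one row per point and columns x, y, z
#'   (Angstrom).  At least 2 rows; all coordinates finite; consecutive
#'   points distinct.
#' @param structure_id,chain_id character scalars identifying the structure
#'   and chain.
#' @param model_no integer model number (1 for single-model files).
#' @param residue_labels optional character vector of PDB residue labels
#'   (residue number + insertion code), one per point; defaults to the
#'   point index.
#' @param fragment_no integer fragment counter, > 1 when a chain was split
#'   at a chain break.
#'
#' @return An object of class `ca_trace`: a list with elements `points`,
#'   `structure_id`, `chain_id`, `model_no`, `residue_labels`,
#'   `fragment_no`.
#' @export
#' @examples
#' tr <- ca_trace(cbind(0:3 * 3.8, 0, 0), structure_id = "toy")
#' n_segments(tr)
ca_trace <- function(points, structure_id = "trace", chain_id = "A",
                     model_no = 1L, residue_labels = NULL,
                     fragment_no = 1L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("'points' must have 3 columns (x, y, z)")
  if (nrow(points) < 2L)
    stop("a ca_trace needs at least 2 points (1 segment)")
  if (!all(is.finite(points)))
    stop("all coordinates must be finite")
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(d == 0))
    stop("consecutive points must be distinct")
  if (is.null(residue_labels))
    residue_labels <- as.character(seq_len(nrow(points)))
  if (length(residue_labels) != nrow(points))
    stop("'residue_labels' must have one entry per point")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(
    list(points = points,
         structure_id = as.character(structure_id),
         chain_id = as.character(chain_id),
         model_no = as.integer(model_no),
         residue_labels = as.character(residue_labels),
         fragment_no = as.integer(fragment_no)),
    class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s/%s model %d fragment %d: %d points (%d segments)\n",
              x$structure_id, x$chain_id, x$model_no, x$fragment_no,
              nrow(x$points), n_segments(x)))
  invisible(x)
}

#' Number of points / segments of a trace
#'
#' @param trace a [ca_trace()].
#' @return Integer count.
#' @export
n_segments <- function(trace) nrow(trace$points) - 1L

#' @rdname n_segments
#' @export
n_points <- function(trace) nrow(trace$points)

#' Sub-chain interval
#'
#' An interval designates a contiguous sub-chain by its first and last
#' segment index (0-based, inclusive).  An interval `(a, b)` spans points
#' `a` to `b + 1` of the owning trace.
#'
#' @param first,last segment indices, `0 <= first <= last`.
#' @return Integer vector of length 2 with class `ws_interval`.
#' @export
interval <- function(first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (length(first) != 1L || length(last) != 1L || is.na(first) || is.na(last))
    stop("'first' and 'last' must be single integers")
  if (first < 0L || first > last)
    stop("need 0 <= first <= last")
  structure(c(first = first, last = last), class = "ws_interval")
}

check_interval <- function(iv, S) {
  iv <- as.integer(iv)
  if (length(iv) != 2L || anyNA(iv))
    stop("an interval is two segment indices (first, last)")
  if (iv[1L] < 0L || iv[1L] > iv[2L] || iv[2L] > S - 1L)
    stop(sprintf("interval (%d, %d) out of range for %d segments",
                 iv[1L], iv[2L], S))
  iv
}

#' Apply a rigid motion to a trace
#'
#' Rotates (about the origin) and translates the coordinates of a trace.
#' All writhe quantities are invariant under such motions.
#'
#' @param trace a [ca_trace()].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return The transformed [ca_trace()].
#' @export
transform_trace <- function(trace, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(trace, "ca_trace"))
  pts <- trace$points %*% t(rotation)
  pts <- sweep(pts, 2L, as.numeric(translation), "+")
  out <- trace
  out$points <- pts
  dimnames(out$points) <- list(NULL, c("x", "y", "z"))
  out
}
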