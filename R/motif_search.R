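# Restricted search (almost-closed loops -> 1-link and poke candidates)
# and unrestricted search (extreme mutual writhe over all disjoint
# fixed-length window pairs).

pair_record <- function(structure_id, chain_id, kind, a1, a2, b1, b2, mw) {
  data.frame(structure_id = structure_id, chain_id = chain_id, kind = kind,
             A_first = as.integer(a1), A_last = as.integer(a2),
             B_first = as.integer(b1), B_last = as.integer(b2),
             mutual_writhe = as.numeric(mw), stringsAsFactors = FALSE)
}

empty_pair_records <- function() {
  pair_record(character(0), character(0), character(0),
              integer(0), integer(0), integer(0), integer(0), numeric(0))
}

trace_ids <- function(trace) {
  if (inherits(trace, "ca_trace"))
    list(structure_id = trace$structure_id, chain_id = trace$chain_id)
  else list(structure_id = "points", chain_id = "A")
}

#' Find almost-closed loops in a trace
#'
#' Enumerates every sub-chain of `min_segments` to `max_segments` segments
#' whose terminal C-alpha atoms are at most `closure_max` Angstrom apart —
#' the operational definition of a closed loop used by the restricted
#' search.  Loops may overlap each other; only disjoint pairs enter the
#' link/poke searches.
#'
#' @param trace a [ca_trace()].
#' @param min_segments,max_segments loop length bounds in segments.
#' @param closure_max maximum terminus-terminus distance (Angstrom).
#' @return A data.frame with columns `first`, `last` (0-based segment
#'   interval), `n_segments`, `closure_distance`, in lexicographic
#'   (first, last) order.  Zero rows when nothing qualifies.
#' @export
find_closed_loops <- function(trace, min_segments = 6L, max_segments = 30L,
                              closure_max = 7.0) {
  stopifnot(inherits(trace, "ca_trace"))
  pts <- trace$points
  S <- n_segments(trace)
  first <- integer(0); last <- integer(0)
  for (len in seq.int(min_segments, min(max_segments, S))) {
    a <- seq_len(S - len + 1L) - 1L  # 0-based first segment
    first <- c(first, a)
    last <- c(last, a + len - 1L)
  }
  if (!length(first))
    return(data.frame(first = integer(0), last = integer(0),
                      n_segments = integer(0), closure_distance = numeric(0)))
  # interval (a, b) spans points a .. b+1 (0-based) = rows a+1 .. b+2
  d <- sqrt(rowSums((pts[first + 1L, , drop = FALSE] -
                       pts[last + 2L, , drop = FALSE])^2))
  keep <- d <= closure_max
  out <- data.frame(first = first[keep], last = last[keep],
                    n_segments = last[keep] - first[keep] + 1L,
                    closure_distance = d[keep])
  out <- out[order(out$first, out$last), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search for 1-links among closed loops
#'
#' For every pair of disjoint loops (no shared segment; sharing the
#' boundary vertex is allowed) computes the mutual writhe by four table
#' look-ups.  Pairs with mutual writhe near +-1 are 1-link (co-poke)
#' candidates: two almost closed loops interlinking once.
#'
#' @param table a [build_writhe_table()] result.
#' @param loops a [find_closed_loops()] data.frame from the same trace.
#' @param trace optionally the owning [ca_trace()], for output labels.
#' @return A [data.frame] of pair records (columns structure_id,
#'   chain_id, kind = "link", A_first, A_last, B_first, B_last,
#'   mutual_writhe), sorted by mutual writhe.
#' @export
link_search <- function(table, loops, trace = NULL) {
  stopifnot(inherits(table, "writhe_table"))
  ids <- trace_ids(trace)
  n <- nrow(loops)
  if (n < 2L) return(empty_pair_records())
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  # orient A as the N-terminal loop, keep only disjoint pairs
  swap <- loops$first[j] < loops$first[i]
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  ok <- loops$last[a] < loops$first[b]
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(empty_pair_records())
  mw <- mutual_writhe_vec(table, loops$first[a], loops$last[a],
                          loops$first[b], loops$last[b])
  out <- pair_record(ids$structure_id, ids$chain_id, "link",
                     loops$first[a], loops$last[a],
                     loops$first[b], loops$last[b], mw)
  out <- out[order(out$mutual_writhe, out$A_first, out$B_first), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search for pokes (short sub-chain through a closed loop)
#'
#' Pairs every loop with every sub-chain of exactly `poke_segments`
#' segments disjoint from it and computes the mutual writhe.  Large
#' |mutual writhe| flags a rod threading the loop.  The output is
#' truncated to the `keep` most negative and `keep` most positive records
#' per chain.
#'
#' @inheritParams link_search
#' @param trace the owning [ca_trace()].
#' @param poke_segments length of the poking sub-chain in segments.
#' @param keep records kept per sign.
#' @return A pair-record data.frame (kind = "poke"), sorted by mutual
#'   writhe.
#' @export
poke_search <- function(table, loops, trace, poke_segments = 10L,
                        keep = 10L) {
  stopifnot(inherits(table, "writhe_table"))
  ids <- trace_ids(trace)
  S <- table$S
  if (nrow(loops) < 1L || S < poke_segments)
    return(empty_pair_records())
  rod_first <- seq_len(S - poke_segments + 1L) - 1L
  rod_last <- rod_first + poke_segments - 1L
  li <- rep(seq_len(nrow(loops)), each = length(rod_first))
  rf <- rep(rod_first, times = nrow(loops))
  rl <- rep(rod_last, times = nrow(loops))
  lf <- loops$first[li]; ll <- loops$last[li]
  before <- rl < lf   # rod N-terminal of loop
  after <- ll < rf    # rod C-terminal of loop
  ok <- before | after
  if (!any(ok)) return(empty_pair_records())
  a1 <- ifelse(before, rf, lf)[ok]; a2 <- ifelse(before, rl, ll)[ok]
  b1 <- ifelse(before, lf, rf)[ok]; b2 <- ifelse(before, ll, rl)[ok]
  mw <- mutual_writhe_vec(table, a1, a2, b1, b2)
  out <- pair_record(ids$structure_id, ids$chain_id, "poke",
                     a1, a2, b1, b2, mw)
  out <- out[order(out$mutual_writhe, out$A_first, out$B_first), ,
             drop = FALSE]
  n <- nrow(out)
  if (n > 2L * keep)
    out <- out[c(seq_len(keep), seq.int(n - keep + 1L, n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unrestricted search: extreme-writhe window pairs
#'
#' Enumerates all disjoint ordered pairs of sub-chains of exactly
#' `window_segments` segments (stride 1; windows may abut, sharing one
#' vertex but no segment) and keeps the `keep` lowest and `keep` highest
#' mutual-writhe pairs.  Extreme positive values flag knot-like winding,
#' extreme negative values the mirror sense; both arise without any
#' prior constraint on the geometry.
#'
#' @inheritParams link_search
#' @param window_segments window length in segments.
#' @param keep records kept per extreme.
#' @return A list with elements `min_records` (ascending mutual writhe)
#'   and `max_records` (descending), each a pair-record data.frame with
#'   kind = "window_pair"; both empty when the trace is too short for a
#'   disjoint pair.  Ties broken lexicographically on (A_first, B_first).
#' @export
unrestricted_search <- function(table, window_segments = 30L, keep = 10L,
                                trace = NULL) {
  stopifnot(inherits(table, "writhe_table"))
  ids <- trace_ids(trace)
  pr <- window_pair_writhes(table, window_segments, step = 1L)
  if (!nrow(pr))
    return(list(min_records = empty_pair_records(),
                max_records = empty_pair_records()))
  rec <- pair_record(ids$structure_id, ids$chain_id, "window_pair",
                     pr$a, pr$a + window_segments - 1L,
                     pr$b, pr$b + window_segments - 1L, pr$mw)
  lo <- rec[order(rec$mutual_writhe, rec$A_first, rec$B_first), ,
            drop = FALSE]
  hi <- rec[order(-rec$mutual_writhe, rec$A_first, rec$B_first), ,
            drop = FALSE]
  lo <- head(lo, keep); hi <- head(hi, keep)
  rownames(lo) <- NULL; rownames(hi) <- NULL
  list(min_records = lo, max_records = hi)
}

# mutual writhe of all disjoint ordered pairs of length-w windows whose
# start positions lie on the stepped grid 0, step, 2*step, ...
window_pair_writhes <- function(table, window_segments, step = 1L) {
  S <- table$S
  w <- as.integer(window_segments)
  if (w > S)
    return(data.frame(a = integer(0), b = integer(0), mw = numeric(0)))
  starts <- seq.int(0L, S - w, by = as.integer(step))
  if (length(starts) < 2L)
    return(data.frame(a = integer(0), b = integer(0), mw = numeric(0)))
  g <- expand.grid(a = starts, b = starts)
  g <- g[g$b >= g$a + w, , drop = FALSE]  # disjoint segments; abutting ok
  if (!nrow(g))
    return(data.frame(a = integer(0), b = integer(0), mw = numeric(0)))
  g$mw <- mutual_writhe_vec(table, g$a, g$a + w - 1L, g$b, g$b + w - 1L)
  rownames(g) <- NULL
  g
}

#' Write pair records as TSV
#'
#' One row per record: structure_id, chain_id, kind, A_first, A_last,
#' B_first, B_last, mutual_writhe (6 decimals), sorted by mutual writhe;
#' LF line endings.
#'
#' @param records a pair-record data.frame.
#' @param path output path.
#' @param header optional named list echoed as a JSON comment line.
#' @return `path`, invisibly.
#' @export
write_pair_records <- function(records, path, header = NULL) {
  records <- records[order(records$mutual_writhe), , drop = FALSE]
  records$mutual_writhe <- sprintf("%.6f", records$mutual_writhe)
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE)),
               con, sep = "\n")
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
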