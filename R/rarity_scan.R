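# rar0 rarity scan: per-structure extreme mutual writhe over stepped
# window pairs, ranked against a background by one-sided empirical
# exceedance probabilities.

#' Extreme mutual writhe of one structure
#'
#' Slides windows of `window_segments` segments along the trace at the
#' given step (starts 0, step, 2*step, ...) and, over all disjoint window
#' pairs, returns the single pair with maximum and the single pair with
#' minimum mutual writhe (ties broken lexicographically on the start
#' positions).
#'
#' @param table a [build_writhe_table()] result.
#' @param window_segments window length in segments.
#' @param step window start stride.
#' @param trace optionally the owning [ca_trace()], for output labels.
#' @return List with `best_pos` and `best_neg` (1-row pair-record
#'   data.frames, kind = "window_pair") and `ok = TRUE`; or
#'   `list(ok = FALSE)` when the trace admits no disjoint window pair.
#' @export
structure_extremes <- function(table, window_segments = 30L, step = 2L,
                               trace = NULL) {
  stopifnot(inherits(table, "writhe_table"))
  ids <- trace_ids(trace)
  pr <- window_pair_writhes(table, window_segments, step)
  if (!nrow(pr)) return(list(ok = FALSE))
  rec <- function(row)
    pair_record(ids$structure_id, ids$chain_id, "window_pair",
                row$a, row$a + window_segments - 1L,
                row$b, row$b + window_segments - 1L, row$mw)
  i_max <- order(-pr$mw, pr$a, pr$b)[1L]
  i_min <- order(pr$mw, pr$a, pr$b)[1L]
  list(best_pos = rec(pr[i_max, ]), best_neg = rec(pr[i_min, ]), ok = TRUE)
}

#' Writhe content of one structure above a threshold
#'
#' Alternative rar0 score: the summed mutual writhe of all stepped window
#' pairs whose value exceeds the threshold, per sign — `pos` is the sum
#' over pairs with mutual writhe >= `threshold`, `neg` the (negative) sum
#' over pairs <= `-threshold`.
#'
#' @inheritParams structure_extremes
#' @param threshold absolute mutual-writhe threshold.
#' @return List with numbers `pos` (>= 0), `neg` (<= 0) and `ok`.
#' @export
structure_content <- function(table, window_segments = 30L, step = 2L,
                              threshold = 1.0) {
  stopifnot(inherits(table, "writhe_table"))
  pr <- window_pair_writhes(table, window_segments, step)
  if (!nrow(pr)) return(list(ok = FALSE))
  list(pos = sum(pr$mw[pr$mw >= threshold]),
       neg = sum(pr$mw[pr$mw <= -threshold]), ok = TRUE)
}

bg_entry <- function(trace, window_segments, step, score, threshold) {
  table <- build_writhe_table(trace)
  base <- data.frame(structure_id = trace$structure_id,
                     chain_id = trace$chain_id,
                     model_no = trace$model_no,
                     stringsAsFactors = FALSE)
  if (score == "extreme") {
    ex <- structure_extremes(table, window_segments, step, trace = trace)
    if (!ex$ok) return(NULL)
    cbind(base,
          data.frame(pos_A_first = ex$best_pos$A_first,
                     pos_A_last = ex$best_pos$A_last,
                     pos_B_first = ex$best_pos$B_first,
                     pos_B_last = ex$best_pos$B_last,
                     pos_score = ex$best_pos$mutual_writhe,
                     neg_A_first = ex$best_neg$A_first,
                     neg_A_last = ex$best_neg$A_last,
                     neg_B_first = ex$best_neg$B_first,
                     neg_B_last = ex$best_neg$B_last,
                     neg_score = ex$best_neg$mutual_writhe))
  } else {
    ct <- structure_content(table, window_segments, step, threshold)
    if (!ct$ok) return(NULL)
    cbind(base,
          data.frame(pos_A_first = NA_integer_, pos_A_last = NA_integer_,
                     pos_B_first = NA_integer_, pos_B_last = NA_integer_,
                     pos_score = ct$pos,
                     neg_A_first = NA_integer_, neg_A_last = NA_integer_,
                     neg_B_first = NA_integer_, neg_B_last = NA_integer_,
                     neg_score = ct$neg))
  }
}

#' Build a scan background
#'
#' Runs the per-structure scoring over a set of traces and collects one
#' entry per (structure, chain, model): the two extreme mutual writhe
#' values (or threshold-content scores) with their window pairs.  Traces
#' too short for a disjoint window pair are skipped with a warning.  The
#' result is sorted by (structure_id, chain_id, model_no), so it does not
#' depend on input order.
#'
#' @param traces list of [ca_trace()] objects.
#' @param window_segments,step scan parameters.
#' @param score `"extreme"` (per-structure extreme pair, the table
#'   semantics of the published scans) or `"content"` (summed writhe
#'   above `threshold`).
#' @param threshold threshold for `score = "content"`.
#' @return Object of class `writhe_background`: list with `params` and
#'   `entries` (data.frame).
#' @export
build_background <- function(traces, window_segments = 30L, step = 2L,
                             score = c("extreme", "content"),
                             threshold = 1.0) {
  score <- match.arg(score)
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  rows <- list()
  for (tr in traces) {
    e <- bg_entry(tr, window_segments, step, score, threshold)
    if (is.null(e)) {
      warning(sprintf("%s/%s too short for window pairs at length %d; skipped",
                      tr$structure_id, tr$chain_id, window_segments))
      next
    }
    rows[[length(rows) + 1L]] <- e
  }
  if (!length(rows))
    stop("no usable structure in the background set")
  entries <- do.call(rbind, rows)
  entries <- entries[order(entries$structure_id, entries$chain_id,
                           entries$model_no), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(params = list(window_segments = as.integer(window_segments),
                               step = as.integer(step), score = score,
                               threshold = threshold),
                 entries = entries),
            class = "writhe_background")
}

#' @export
print.writhe_background <- function(x, ...) {
  cat(sprintf(
    "<writhe_background> %d entries; window %d, step %d, score '%s'\n",
    nrow(x$entries), x$params$window_segments, x$params$step,
    x$params$score))
  invisible(x)
}

#' Serialize / reload a background
#'
#' Gzipped TSV with a JSON header line carrying the scan parameters; the
#' round trip reproduces the background exactly.
#'
#' @param background a [build_background()] result.
#' @param path file path (conventionally `.tsv.gz`).
#' @return `write_background`: `path`, invisibly.  `read_background`: the
#'   `writhe_background`.
#' @export
write_background <- function(background, path) {
  stopifnot(inherits(background, "writhe_background"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(
    c(background$params, list(format = "writhe_background/1")),
    auto_unbox = TRUE)), con)
  entries <- background$entries
  entries$pos_score <- sprintf("%.17g", entries$pos_score)
  entries$neg_score <- sprintf("%.17g", entries$neg_score)
  write.table(entries, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  if (!startsWith(hdr, "# "))
    stop("not a background file (missing JSON header): ", path)
  params <- jsonlite::fromJSON(sub("^# ", "", hdr))
  entries <- read.table(con, sep = "\t", header = TRUE,
                        colClasses = c(structure_id = "character",
                                       chain_id = "character"))
  structure(list(params = list(window_segments = as.integer(params$window_segments),
                               step = as.integer(params$step),
                               score = params$score,
                               threshold = as.numeric(params$threshold)),
                 entries = entries),
            class = "writhe_background")
}

#' rar0 rarity scan of query structures against a background
#'
#' Scores each query trace with the background's scan parameters and
#' attaches one-sided empirical exceedance probabilities: `prob_pos` is
#' the frequency of background structures whose positive score is >= the
#' query's, `prob_neg` the frequency whose negative score is <= the
#' query's.  Plain frequencies are used (no smoothing), so 0 is a legal
#' probability for a query more extreme than the whole background.
#' Queries are ranked independently on each tail; the output is sorted by
#' decreasing positive score (`rank_by = "pos"`, default) or increasing
#' negative score (`rank_by = "neg"`), rank 1 first.
#'
#' @param queries list of [ca_trace()] objects.
#' @param background a [build_background()] (or [read_background()])
#'   result; its parameters drive the scoring.
#' @param rank_by which tail orders the report.
#' @return Data.frame with one row per scored query: identifiers, the
#'   extreme pairs (or NA for content scores), `pos_score`, `neg_score`,
#'   `prob_pos`, `prob_neg`, `rank_pos`, `rank_neg`.  Queries too short
#'   to score are skipped with a warning.
#' @export
rar0_scan <- function(queries, background, rank_by = c("pos", "neg")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(background, "writhe_background"))
  p <- background$params
  if (inherits(queries, "ca_trace")) queries <- list(queries)
  rows <- list()
  for (tr in queries) {
    e <- bg_entry(tr, p$window_segments, p$step, p$score, p$threshold)
    if (is.null(e)) {
      warning(sprintf("query %s/%s too short for window pairs; skipped",
                      tr$structure_id, tr$chain_id))
      next
    }
    rows[[length(rows) + 1L]] <- e
  }
  if (!length(rows)) stop("no scorable query")
  out <- do.call(rbind, rows)
  bg <- background$entries
  n_bg <- nrow(bg)
  out$prob_pos <- vapply(out$pos_score,
                         function(s) sum(bg$pos_score >= s) / n_bg, 0)
  out$prob_neg <- vapply(out$neg_score,
                         function(s) sum(bg$neg_score <= s) / n_bg, 0)
  out$rank_pos <- rank(-out$pos_score, ties.method = "min")
  out$rank_neg <- rank(out$neg_score, ties.method = "min")
  ord <- if (rank_by == "pos") order(out$rank_pos, out$structure_id)
         else order(out$rank_neg, out$structure_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a scan report as TSV
#'
#' Columns mirror the published scan tables: structure/chain, the extreme
#' window pair per tail, its mutual writhe (6 decimals), probability and
#' rank.
#'
#' @param scores a [rar0_scan()] result.
#' @param path output path.
#' @param header optional named list echoed as a JSON comment line.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(scores, path, header = NULL) {
  fmt_pair <- function(f, l)
    ifelse(is.na(f), "NA", sprintf("(%d,%d)", f, l + 1L))
  df <- data.frame(
    structure_chain = paste(scores$structure_id, scores$chain_id, sep = "/"),
    pos_pair = paste0(fmt_pair(scores$pos_A_first, scores$pos_A_last), ";",
                      fmt_pair(scores$pos_B_first, scores$pos_B_last)),
    pos_score = sprintf("%.6f", scores$pos_score),
    prob_pos = signif(scores$prob_pos, 6),
    rank_pos = scores$rank_pos,
    neg_pair = paste0(fmt_pair(scores$neg_A_first, scores$neg_A_last), ";",
                      fmt_pair(scores$neg_B_first, scores$neg_B_last)),
    neg_score = sprintf("%.6f", scores$neg_score),
    prob_neg = signif(scores$prob_neg, 6),
    rank_neg = scores$rank_neg)
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE)),
               con, sep = "\n")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
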