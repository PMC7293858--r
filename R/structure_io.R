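#' Read C-alpha traces from a PDB file
#'
#' Parses a PDB file (wwPDB v3.3 fixed-column ATOM records, via
#' [bio3d::read.pdb()]) and returns one clean [ca_trace()] per chain
#' fragment.  Only alpha-carbon ATOM records are used; HETATM records,
#' waters and alternate locations other than `' '`/`'A'` are discarded.
#' Each chain is split at chain breaks, i.e. wherever the consecutive
#' Ca-Ca distance exceeds `break_threshold` (default 4.5 Angstrom, wide
#' enough for trans ~3.8 A and cis ~3.0 A peptide bonds while flagging
#' genuine gaps).  Residues keep their file order; no renumbering.
#'
#' @param path path to a readable PDB file.
#' @param model_policy `"first"` (default) uses the first model only;
#'   `"all"` returns every model as its own set of traces with `model_no`
#'   set.
#' @param break_threshold chain-break distance threshold in Angstrom.
#' @return A list of [ca_trace()] objects in file order (chains in order of
#'   first appearance, fragments N-to-C).  A file without any alpha
#'   carbons yields an empty list with a warning.
#' @seealso [split_on_breaks()], [write_trace_pdb()]
#' @export
parse_pdb <- function(path, model_policy = c("first", "all"),
                      break_threshold = 4.5) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path))
    stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = (model_policy == "all"),
                         rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  alt_ok <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  keep <- at$type == "ATOM" & at$elety == "CA" & alt_ok
  if (!any(keep)) {
    warning("no C-alpha atoms found in ", path)
    return(list())
  }
  structure_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                      ignore.case = TRUE)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- if (model_policy == "all") nrow(xyz) else 1L

  idx <- which(keep)
  chains <- at$chain[idx]
  chains[is.na(chains)] <- " "
  icode <- at$insert[idx]
  icode[is.na(icode)] <- ""
  labels <- paste0(at$resno[idx], icode)

  out <- list()
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    for (ch in unique(chains)) {
      sel <- chains == ch
      pts <- coords[idx[sel], , drop = FALSE]
      labs <- labels[sel]
      # collapse exact duplicate consecutive positions (e.g. stray altlocs)
      if (nrow(pts) > 1L) {
        d <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
        if (any(d == 0)) {
          warning(sprintf("%s/%s: dropping %d duplicate consecutive point(s)",
                          structure_id, ch, sum(d == 0)))
          dup <- c(FALSE, d == 0)
          pts <- pts[!dup, , drop = FALSE]
          labs <- labs[!dup]
        }
      }
      frags <- split_points_on_breaks(pts, break_threshold)
      for (k in seq_along(frags)) {
        rows <- frags[[k]]
        out[[length(out) + 1L]] <- ca_trace(
          pts[rows, , drop = FALSE],
          structure_id = structure_id, chain_id = ch, model_no = m,
          residue_labels = labs[rows], fragment_no = k)
      }
    }
  }
  out
}

# indices of maximal runs with consecutive distance <= threshold;
# runs shorter than 2 points are dropped
split_points_on_breaks <- function(points, threshold) {
  n <- nrow(points)
  if (n < 2L) return(list())
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  grp <- cumsum(c(0L, d > threshold))
  runs <- split(seq_len(n), grp)
  Filter(function(r) length(r) >= 2L, unname(runs))
}

#' Split a point series at chain breaks
#'
#' Cuts an ordered series of C-alpha positions wherever two consecutive
#' points are further apart than `threshold`.  The concatenation of the
#' returned fragments reproduces the input order; fragments of fewer than
#' 2 points are dropped.
#'
#' @param points a [ca_trace()] or a numeric matrix of xyz rows.
#' @param threshold maximum intra-fragment consecutive distance (Angstrom).
#' @inheritParams ca_trace
#' @return List of [ca_trace()] fragments (possibly empty).
#' @export
split_on_breaks <- function(points, threshold = 4.5, structure_id = "trace",
                            chain_id = "A", model_no = 1L,
                            residue_labels = NULL) {
  stopifnot(threshold > 0)
  if (inherits(points, "ca_trace")) {
    tr <- points
    points <- tr$points
    structure_id <- tr$structure_id
    chain_id <- tr$chain_id
    model_no <- tr$model_no
    residue_labels <- tr$residue_labels
  }
  points <- as.matrix(points)
  if (is.null(residue_labels))
    residue_labels <- as.character(seq_len(nrow(points)))
  runs <- split_points_on_breaks(points, threshold)
  lapply(seq_along(runs), function(k) {
    rows <- runs[[k]]
    ca_trace(points[rows, , drop = FALSE], structure_id = structure_id,
             chain_id = chain_id, model_no = model_no,
             residue_labels = residue_labels[rows], fragment_no = k)
  })
}

#' Write traces as a minimal PDB file
#'
#' Emits one CA ATOM record per trace point in wwPDB v3.3 fixed columns
#' (coordinates to 3 decimals), with a TER record after each trace.
#' Residue numbers are taken from the numeric part of `residue_labels`
#' when available, else sequential.  Useful for round-trip tests and for
#' feeding synthetic curves to the command-line tool.
#'
#' @param traces a [ca_trace()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_pdb <- function(traces, path) {
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (tr in traces) {
    resno <- suppressWarnings(as.integer(sub("([0-9]+).*", "\\1",
                                             tr$residue_labels)))
    if (anyNA(resno)) resno <- seq_len(n_points(tr))
    ch <- substr(tr$chain_id, 1L, 1L)
    if (!nzchar(ch)) ch <- " "
    for (i in seq_len(n_points(tr))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial %% 100000L, ch, resno[i] %% 10000L,
        tr$points[i, 1L], tr$points[i, 2L], tr$points[i, 3L], 1, 0), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      ALA %1s%4d",
                       serial %% 100000L, ch,
                       resno[n_points(tr)] %% 10000L), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Tabular view of a trace
#'
#' @param trace a [ca_trace()].
#' @return A data.frame with columns structure_id, chain_id, position
#'   (0-based), residue_label, x, y, z.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  data.frame(structure_id = trace$structure_id,
             chain_id = trace$chain_id,
             position = seq_len(n_points(trace)) - 1L,
             residue_label = trace$residue_labels,
             x = trace$points[, 1L], y = trace$points[, 2L],
             z = trace$points[, 3L])
}
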