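# Anchor-column classification and Protein Variable Region delineation.
#
# A PVR is a stretch between two anchor columns (alignment positions whose
# cross-structure CA spread is below an RMSD cut-off, present in every
# structure) whose per-structure length range exceeds a residue threshold.
# Terminal regions are bounded by a single anchor.

#' Cross-structure positional spread per alignment column
#'
#' For each fully occupied column, the RMSD of the member CA atoms about the
#' column centroid, measured after each structure's single global transform
#' into the reference frame. Partially occupied columns get `Inf` (a position
#' absent from any structure is not structurally aligned across all).
#'
#' @param msa A `pvr_msa`.
#' @param method `"centroid"` (default) or `"to_reference"` (root mean square
#'   distance of the non-reference members to the reference CA).
#' @return Data frame with `column`, `occupancy`, `rmsd`.
#' @export
column_profile <- function(msa, method = c("centroid", "to_reference")) {
  method <- match.arg(method)
  ids <- msa$structure_ids
  n <- length(ids)
  if (any(vapply(msa$transforms, is.null, logical(1))))
    stop("missing transform into the reference frame")
  # transform every trace once
  txyz <- lapply(ids, function(id)
    apply_transform(trace_coords(msa$traces[[id]]), msa$transforms[[id]]))
  names(txyz) <- ids
  occ <- column_occupancy(msa)
  n_col <- ncol(msa$cells)
  rmsd <- rep(Inf, n_col)
  full <- which(occ == n)
  if (length(full)) {
    per_struct <- lapply(ids, function(id)
      txyz[[id]][msa$cells[id, full], , drop = FALSE])
    arr <- simplify2array(per_struct) # n_full x 3 x n
    ctr <- apply(arr, c(1, 2), mean)
    if (method == "centroid") {
      dev2 <- sweep(arr, c(1, 2), ctr)^2
      rmsd[full] <- sqrt(apply(dev2, 1, sum) / n)
    } else {
      ref_xyz <- per_struct[[which(ids == msa$reference_id)]]
      dev2 <- sweep(arr, c(1, 2), ref_xyz)^2
      rmsd[full] <- sqrt(apply(dev2, 1, sum) / (n - 1))
    }
  }
  structure(data.frame(column = seq_len(n_col), occupancy = as.integer(occ),
                       rmsd = rmsd),
            class = c("pvr_profile", "data.frame"), n_structures = n)
}

#' Call anchor columns
#'
#' Anchors are fully occupied columns with spread strictly below `rmsd_cut`,
#' thinned to runs of at least `min_run` consecutive qualifying columns.
#'
#' @param profile Output of [column_profile()].
#' @param rmsd_cut Positional RMSD cut-off in Angstrom (default 2.0,
#'   exclusive). Raise it for families with a less rigid core.
#' @param min_run Minimum run length of consecutive qualifying columns
#'   (default 1).
#' @return Sorted integer vector of anchor columns, with the thresholds kept
#'   as attributes.
#' @export
call_anchors <- function(profile, rmsd_cut = 2.0, min_run = 1L) {
  if (rmsd_cut <= 0) stop("rmsd_cut must be positive")
  n <- attr(profile, "n_structures")
  ok <- profile$occupancy == n & profile$rmsd < rmsd_cut
  if (min_run > 1L && any(ok)) {
    r <- rle(ok)
    r$values[r$values & r$lengths < min_run] <- FALSE
    ok <- inverse.rle(r)
  }
  structure(profile$column[ok], rmsd_cut = rmsd_cut, min_run = as.integer(min_run))
}

seq2 <- function(a, b) if (b < a) integer() else seq.int(a, b)

# Residues of one structure inside a region given by its columns and
# inter-column spaces. Returns indices into that structure's CA trace.
region_residues <- function(msa, id, cols, spaces) {
  in_cols <- msa$cells[id, cols]
  in_cols <- in_cols[!is.na(in_cols)]
  ins <- msa$insertions[[id]]
  c(in_cols, ins$idx[ins$after_col %in% spaces])
}

#' Delineate Protein Variable Regions
#'
#' Candidate regions are the maximal stretches between consecutive anchors
#' (residues strictly between the bounding anchor columns, plus insertion
#' runs attached there) and the two terminal regions bounded by a single
#' anchor. Per-structure lengths are counted in each structure's own
#' residues; regions whose length range (max - min) strictly exceeds
#' `range_cut` are reported as PVRs, numbered from N to C. The bounding
#' anchor residues themselves are not counted.
#'
#' @param msa A `pvr_msa`.
#' @param anchors Anchor columns from [call_anchors()].
#' @param range_cut Length-range threshold in residues (default 10,
#'   exclusive).
#' @param reference_id Structure whose lengths anchor `sigma_abs`; defaults
#'   to the alignment reference.
#' @return A `pvr_table`: `pvrs` (one row per PVR with kind, bounding
#'   anchors, length range), `lengths` (structures x PVRs), `segments` (long
#'   table with first/last residue numbers), `sigma_abs` (per structure, sum
#'   over PVRs of |length - reference length|), and the thresholds used.
#' @export
delineate_pvrs <- function(msa, anchors, range_cut = 10,
                           reference_id = msa$reference_id) {
  if (!length(anchors)) stop("no conserved core: no anchor columns")
  anchors <- sort(anchors)
  ids <- msa$structure_ids
  n_col <- ncol(msa$cells)
  first_a <- anchors[1]; last_a <- anchors[length(anchors)]
  regions <- list()
  if (first_a > 1 || any_insertions(msa, seq2(0L, first_a - 1L)))
    regions[[length(regions) + 1L]] <-
      list(kind = "N_terminal", start_anchor = NA_integer_,
           end_anchor = first_a, cols = seq2(1L, first_a - 1L),
           spaces = seq2(0L, first_a - 1L))
  if (length(anchors) > 1) {
    for (k in seq_len(length(anchors) - 1L)) {
      p <- anchors[k]; q <- anchors[k + 1L]
      cols <- seq2(p + 1L, q - 1L)
      spaces <- seq2(p, q - 1L)
      if (length(cols) || any_insertions(msa, spaces))
        regions[[length(regions) + 1L]] <-
          list(kind = "internal", start_anchor = p, end_anchor = q,
               cols = cols, spaces = spaces)
    }
  }
  if (last_a < n_col || any_insertions(msa, seq2(last_a, n_col)))
    regions[[length(regions) + 1L]] <-
      list(kind = "C_terminal", start_anchor = last_a,
           end_anchor = NA_integer_, cols = seq2(last_a + 1L, n_col),
           spaces = seq2(last_a, n_col))
  keep <- list(); lengths <- list(); seg_rows <- list()
  for (rg in regions) {
    res <- lapply(setNames(ids, ids), function(id)
      region_residues(msa, id, rg$cols, rg$spaces))
    len <- vapply(res, length, integer(1))
    rng <- max(len) - min(len)
    if (rng > range_cut) {
      keep[[length(keep) + 1L]] <- c(rg, list(length_range = rng))
      lengths[[length(lengths) + 1L]] <- len
      seg_rows[[length(seg_rows) + 1L]] <- lapply(ids, function(id) {
        tr <- msa$traces[[id]]
        ri <- res[[id]]
        if (length(ri))
          data.frame(structure_id = id, chain = tr$chain[1],
                     first_resno = tr$resno[min(ri)],
                     last_resno = tr$resno[max(ri)],
                     length = length(ri), stringsAsFactors = FALSE)
        else
          data.frame(structure_id = id, chain = tr$chain[1],
                     first_resno = NA_integer_, last_resno = NA_integer_,
                     length = 0L, stringsAsFactors = FALSE)
      })
    }
  }
  n_pvr <- length(keep)
  pvrs <- if (n_pvr) data.frame(
    pvr_id = seq_len(n_pvr),
    kind = vapply(keep, `[[`, character(1), "kind"),
    start_anchor = vapply(keep, `[[`, integer(1), "start_anchor"),
    end_anchor = vapply(keep, `[[`, integer(1), "end_anchor"),
    length_range = vapply(keep, `[[`, integer(1), "length_range"),
    stringsAsFactors = FALSE)
  else data.frame(pvr_id = integer(), kind = character(),
                  start_anchor = integer(), end_anchor = integer(),
                  length_range = integer())
  len_mat <- if (n_pvr) do.call(cbind, lengths)
             else matrix(integer(), nrow = length(ids),
                         dimnames = list(ids, NULL))
  if (n_pvr) dimnames(len_mat) <- list(ids, paste0("PVR", seq_len(n_pvr)))
  segments <- if (n_pvr) {
    do.call(rbind, lapply(seq_len(n_pvr), function(k)
      cbind(pvr_id = k, do.call(rbind, seg_rows[[k]]))))
  } else data.frame(pvr_id = integer(), structure_id = character(),
                    chain = character(), first_resno = integer(),
                    last_resno = integer(), length = integer())
  sigma_abs <- if (n_pvr)
    rowSums(abs(len_mat - matrix(len_mat[reference_id, ], nrow = length(ids),
                                 ncol = n_pvr, byrow = TRUE)))
  else setNames(rep(0, length(ids)), ids)
  structure(list(pvrs = pvrs, lengths = len_mat, segments = segments,
                 sigma_abs = sigma_abs, reference_id = reference_id,
                 thresholds = list(rmsd_cut = attr(anchors, "rmsd_cut"),
                                   range_cut = range_cut,
                                   min_run = attr(anchors, "min_run"))),
            class = "pvr_table")
}

any_insertions <- function(msa, spaces) {
  any(vapply(msa$insertions, function(ins)
    any(ins$after_col %in% spaces), logical(1)))
}

#' @export
print.pvr_table <- function(x, ...) {
  cat("pvr_table:", nrow(x$pvrs), "PVR(s), reference",
      sQuote(x$reference_id), "\n")
  if (nrow(x$pvrs)) {
    print(x$pvrs, row.names = FALSE)
    cat("sigma_abs:\n")
    print(x$sigma_abs)
  }
  invisible(x)
}

#' Per-structure PVR report
#'
#' Flattens a `pvr_table` into a per-structure segment table plus
#' visualization selection strings (PyMOL syntax) naming the residue range of
#' each PVR in each structure.
#'
#' @param table A `pvr_table`.
#' @param msa The `pvr_msa` it was derived from.
#' @return List with `segments` (TSV-ready data frame), `sigma_abs`, and
#'   `selections` (named character vector, one entry per structure/PVR; empty
#'   string for zero-length segments).
#' @export
pvr_report <- function(table, msa) {
  seg <- table$segments
  sel <- character(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    sel[k] <- if (is.na(seg$first_resno[k])) "" else
      sprintf("chain %s and resi %d-%d", seg$chain[k],
              seg$first_resno[k], seg$last_resno[k])
  }
  names(sel) <- sprintf("%s_PVR%d", seg$structure_id, seg$pvr_id)
  list(segments = seg, sigma_abs = table$sigma_abs, selections = sel)
}
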