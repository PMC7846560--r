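# Reference-anchored multiple structural alignment (star topology).

#' Build a reference-anchored multiple structural alignment
#'
#' Aligns every structure pairwise to the reference and merges on reference
#' residues: columns are the reference CA residues in order, each target
#' residue sits in the column of its reference partner, and target residues
#' with no reference partner are stored as insertion runs attached between
#' the flanking columns (`after_col` 0 marks the space before the first
#' column). The reference is never gapped out.
#'
#' @param structures List of `pvr_structure` (or CA traces) including the
#'   reference.
#' @param reference_id Label of the reference structure.
#' @param chains Optional named character vector mapping structure id to the
#'   chain to use.
#' @param alignments Optional precomputed list of `pvr_alignment` against the
#'   reference (keyed or in `structures` order, reference omitted); computed
#'   when absent.
#' @param ... Passed to [align_pair()].
#' @return A `pvr_msa` with the column table (`cells`), insertion runs,
#'   per-structure transforms into the reference frame, and the pairwise
#'   alignments used.
#' @export
star_align <- function(structures, reference_id, chains = NULL,
                       alignments = NULL, ...) {
  ids <- vapply(structures, function(s)
    if (inherits(s, "pvr_structure")) s$id else s$structure_id[1], character(1))
  names(structures) <- ids
  if (!reference_id %in% ids)
    stop("reference ", sQuote(reference_id), " not among inputs")
  get_trace <- function(id) {
    s <- structures[[id]]
    if (inherits(s, "pvr_structure")) ca_trace(s, chains[id]) else s
  }
  traces <- lapply(setNames(ids, ids), get_trace)
  ref <- traces[[reference_id]]
  n_col <- nrow(ref)
  others <- setdiff(ids, reference_id)
  ordered_ids <- c(reference_id, others)
  cells <- matrix(NA_integer_, nrow = length(ids), ncol = n_col,
                  dimnames = list(ordered_ids, NULL))
  cells[reference_id, ] <- seq_len(n_col)
  insertions <- setNames(vector("list", length(ids)), ordered_ids)
  insertions[[reference_id]] <-
    data.frame(after_col = integer(), idx = integer())
  transforms <- setNames(vector("list", length(ids)), ordered_ids)
  transforms[[reference_id]] <- list(rotation = diag(3), translation = numeric(3))
  pairwise <- list()
  for (id in others) {
    al <- alignments[[id]]
    if (is.null(al)) {
      al <- tryCatch(align_pair(ref, traces[[id]], ...),
                     error = function(e)
                       stop("pairwise alignment ", reference_id, " vs ", id,
                            " failed: ", conditionMessage(e), call. = FALSE))
    }
    pairwise[[id]] <- al
    cells[id, al$pairs$ai] <- al$pairs$bi
    transforms[[id]] <- al$transform
    m <- nrow(traces[[id]])
    unal <- setdiff(seq_len(m), al$pairs$bi)
    if (length(unal)) {
      # attach each unaligned residue after the column of the nearest
      # preceding aligned residue (0 = before the first column)
      left_col <- vapply(unal, function(k) {
        prior <- al$pairs$ai[al$pairs$bi < k]
        if (length(prior)) max(prior) else 0L
      }, integer(1))
      insertions[[id]] <- data.frame(after_col = as.integer(left_col),
                                     idx = as.integer(unal))
    } else {
      insertions[[id]] <- data.frame(after_col = integer(), idx = integer())
    }
    stopifnot(sum(!is.na(cells[id, ])) + nrow(insertions[[id]]) == m)
  }
  structure(list(reference_id = reference_id, structure_ids = ordered_ids,
                 traces = traces[ordered_ids], cells = cells,
                 insertions = insertions, transforms = transforms,
                 pairwise = pairwise),
            class = "pvr_msa")
}

#' @export
print.pvr_msa <- function(x, ...) {
  cat("pvr_msa:", length(x$structure_ids), "structures,",
      ncol(x$cells), "columns (reference", sQuote(x$reference_id), ")\n")
  occ <- column_occupancy(x)
  cat("  fully occupied columns:", sum(occ == length(x$structure_ids)), "\n")
  n_ins <- sum(vapply(x$insertions, nrow, integer(1)))
  cat("  insertion residues:", n_ins, "\n")
  invisible(x)
}

#' Column occupancy of a multiple alignment
#' @param msa A `pvr_msa`.
#' @return Integer vector, number of non-gap cells per column.
#' @export
column_occupancy <- function(msa) as.integer(colSums(!is.na(msa$cells)))

# CA coordinates of every structure at one column, in the reference frame.
column_coords <- function(msa, col) {
  out <- matrix(NA_real_, nrow = length(msa$structure_ids), ncol = 3,
                dimnames = list(msa$structure_ids, c("x", "y", "z")))
  for (id in msa$structure_ids) {
    k <- msa$cells[id, col]
    if (!is.na(k)) {
      xyz <- trace_coords(msa$traces[[id]])[k, , drop = FALSE]
      out[id, ] <- apply_transform(xyz, msa$transforms[[id]])
    }
  }
  out
}

one_letter <- function(resid) {
  aa <- bio3d::aa321(resid)
  aa[is.na(aa) | aa == ""] <- "X"
  aa
}

#' Export a multiple alignment as gapped FASTA
#'
#' Insertion runs are expanded into columns where every other structure is
#' gapped, so the export round-trips through [import_alignment()].
#'
#' @param msa A `pvr_msa`.
#' @param path Optional output file; when `NULL` the gapped sequences are
#'   returned as a named character vector.
#' @return Named character vector of gapped sequences (invisibly when written).
#' @export
msa_to_fasta <- function(msa, path = NULL) {
  ids <- msa$structure_ids
  n_col <- ncol(msa$cells)
  seqs <- setNames(rep("", length(ids)), ids)
  letters_of <- lapply(msa$traces, function(tr) one_letter(tr$resid))
  append_block <- function(seqs, col) { # one reference column
    for (id in ids) {
      k <- msa$cells[id, col]
      seqs[id] <- paste0(seqs[id],
                         if (is.na(k)) "-" else letters_of[[id]][k])
    }
    seqs
  }
  append_insertions <- function(seqs, space) {
    for (id in ids) {
      ins <- msa$insertions[[id]]
      idx <- ins$idx[ins$after_col == space]
      if (length(idx)) {
        block <- paste(letters_of[[id]][idx], collapse = "")
        for (other in ids)
          seqs[other] <- paste0(seqs[other],
                                if (other == id) block
                                else strrep("-", length(idx)))
      }
    }
    seqs
  }
  seqs <- append_insertions(seqs, 0L)
  for (col in seq_len(n_col)) {
    seqs <- append_block(seqs, col)
    seqs <- append_insertions(seqs, col)
  }
  if (!is.null(path)) {
    seqinr::write.fasta(as.list(seqs), names = ids, file.out = path,
                        as.string = TRUE, nbchar = 60)
    return(invisible(seqs))
  }
  seqs
}

#' Import a gapped FASTA alignment onto structures
#'
#' Builds the column table directly from FASTA columns; the first record (or
#' `reference_id`) anchors the columns. Each record's ungapped sequence must
#' match the corresponding chain's residue sequence exactly. Transforms into
#' the reference frame are recomputed by Kabsch on fully occupied columns.
#'
#' @param fasta Path to a FASTA file, or a named character vector of gapped
#'   sequences.
#' @param structures List of `pvr_structure` or CA traces, ids matching the
#'   FASTA record names.
#' @param reference_id Reference label; default the first FASTA record.
#' @param chains Optional named chain selector as in [star_align()].
#' @return A `pvr_msa`.
#' @export
import_alignment <- function(fasta, structures, reference_id = NULL,
                             chains = NULL) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    recs <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE)
    seqs <- toupper(vapply(recs, as.character, character(1)))
    names(seqs) <- names(recs)
  } else seqs <- toupper(fasta)
  if (is.null(reference_id)) reference_id <- names(seqs)[1]
  if (!reference_id %in% names(seqs)) stop("reference not among FASTA records")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) stop("gapped sequences differ in width")
  ids <- vapply(structures, function(s)
    if (inherits(s, "pvr_structure")) s$id else s$structure_id[1], character(1))
  names(structures) <- ids
  missing_ids <- setdiff(names(seqs), ids)
  if (length(missing_ids))
    stop("no structure for FASTA record(s): ", paste(missing_ids, collapse = ", "))
  traces <- lapply(setNames(names(seqs), names(seqs)), function(id) {
    s <- structures[[id]]
    if (inherits(s, "pvr_structure")) ca_trace(s, chains[id]) else s
  })
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  # validate ungapped sequences against the structures
  for (id in names(seqs)) {
    got <- chars[[id]][chars[[id]] != "-"]
    want <- one_letter(traces[[id]]$resid)
    if (length(got) != length(want) || any(got != want)) {
      at <- if (length(got) != length(want)) min(length(got), length(want)) + 1
            else which(got != want)[1]
      stop("sequence mismatch for ", id, " at ungapped position ", at,
           ": alignment has ", if (at <= length(got)) got[at] else "<end>",
           ", structure has ", if (at <= length(want)) want[at] else "<end>")
    }
  }
  ref_chars <- chars[[reference_id]]
  ref_cols <- which(ref_chars != "-")
  n_col <- length(ref_cols)
  ordered_ids <- c(reference_id, setdiff(names(seqs), reference_id))
  cells <- matrix(NA_integer_, nrow = length(ordered_ids), ncol = n_col,
                  dimnames = list(ordered_ids, NULL))
  insertions <- setNames(vector("list", length(ordered_ids)), ordered_ids)
  col_of <- integer(length(ref_chars)) # fasta column -> reference column (0 between)
  col_of[ref_cols] <- seq_len(n_col)
  for (id in ordered_ids) {
    cc <- chars[[id]]
    res_i <- 0L; ref_seen <- 0L
    ins <- list()
    for (c0 in seq_along(cc)) {
      is_ref <- col_of[c0] > 0L
      if (is_ref) ref_seen <- col_of[c0]
      if (cc[c0] != "-") {
        res_i <- res_i + 1L
        if (is_ref) cells[id, col_of[c0]] <- res_i
        else ins[[length(ins) + 1L]] <- c(ref_seen, res_i)
      }
    }
    insertions[[id]] <- if (length(ins)) {
      m <- do.call(rbind, ins)
      data.frame(after_col = as.integer(m[, 1]), idx = as.integer(m[, 2]))
    } else data.frame(after_col = integer(), idx = integer())
  }
  transforms <- setNames(vector("list", length(ordered_ids)), ordered_ids)
  transforms[[reference_id]] <- list(rotation = diag(3), translation = numeric(3))
  full <- which(colSums(!is.na(cells)) == length(ordered_ids))
  ref_xyz <- trace_coords(traces[[reference_id]])
  for (id in setdiff(ordered_ids, reference_id)) {
    if (length(full) < 3)
      stop("fewer than 3 fully occupied columns; cannot derive transforms")
    P <- ref_xyz[cells[reference_id, full], , drop = FALSE]
    Q <- trace_coords(traces[[id]])[cells[id, full], , drop = FALSE]
    transforms[[id]] <- kabsch(P, Q)[c("rotation", "translation")]
  }
  structure(list(reference_id = reference_id, structure_ids = ordered_ids,
                 traces = traces[ordered_ids], cells = cells,
                 insertions = insertions, transforms = transforms,
                 pairwise = list()),
            class = "pvr_msa")
}
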