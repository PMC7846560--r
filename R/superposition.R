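# Rigid-body superposition, TM-score, and iterative pairwise structural
# alignment of CA traces.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of point set
#' `Q` onto `P` (SVD solution; a reflection, if optimal for the covariance,
#' is corrected to a proper rotation).
#'
#' @param P,Q Numeric n x 3 matrices of matched points (n >= 3).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3) so
#'   that `Q %*% t(rotation) + translation` best matches `P`, and `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in length")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2)
    stop("degenerate (collinear) point set")
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cp - as.numeric(R %*% cq)
  moved <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - moved)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param tr List with `rotation` and `translation` (as from [kabsch()]).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tr)
  sweep(as.matrix(xyz) %*% t(tr$rotation), 2, tr$translation, "+")

#' Invert a rigid transform
#' @param tr List with `rotation`, `translation`.
#' @return The inverse transform.
#' @export
invert_transform <- function(tr)
  list(rotation = t(tr$rotation),
       translation = as.numeric(-t(tr$rotation) %*% tr$translation))

compose_transform <- function(a, b) # apply b first, then a
  list(rotation = a$rotation %*% b$rotation,
       translation = as.numeric(a$rotation %*% b$translation) + a$translation)

#' TM-score distance scale d0
#' @param L_norm Normalisation length (> 15 for the formula's domain).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_norm) {
  if (L_norm <= 15) stop("TM-score d0 undefined for L_norm <= 15")
  1.24 * (L_norm - 15)^(1 / 3) - 1.8
}

#' TM-score from aligned-pair distances
#'
#' `score = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L_norm - 15)^(1/3) - 1.8`.
#'
#' @param d Distances (Angstrom) of aligned residue pairs after superposition.
#' @param L_norm Normalisation length.
#' @return Score in (0, 1].
#' @export
tm_score <- function(d, L_norm) {
  if (!length(d)) stop("empty distance vector")
  if (any(d < 0)) stop("negative distance")
  d0 <- tm_d0(L_norm)
  sum(1 / (1 + (d / d0)^2)) / L_norm
}

#' Structure-based sequence identity
#' @param al A `pvr_alignment` from [align_pair()].
#' @return Percent of aligned pairs with identical residue names.
#' @export
seq_identity <- function(al) {
  if (!inherits(al, "pvr_alignment")) stop("expected a pvr_alignment")
  if (al$n_aligned == 0) stop("empty alignment")
  100 * mean(al$pairs$resid_a == al$pairs$resid_b)
}

# Ungapped sliding-window superposition seed: best-RMSD window pair.
seed_alignment <- function(A, B, window = 40L, stride = 8L) {
  n <- nrow(A); m <- nrow(B)
  w <- min(window, n, m)
  sa <- unique(c(seq(1L, n - w + 1L, by = stride), n - w + 1L))
  sb <- unique(c(seq(1L, m - w + 1L, by = stride), m - w + 1L))
  best <- NULL; best_rmsd <- Inf
  for (i in sa) for (j in sb) {
    k <- kabsch(A[i:(i + w - 1L), , drop = FALSE],
                B[j:(j + w - 1L), , drop = FALSE])
    if (k$rmsd < best_rmsd) { best_rmsd <- k$rmsd; best <- k }
  }
  best
}

#' Iterative pairwise structural alignment
#'
#' Alternates (i) semi-global dynamic programming over the TM-score per-pair
#' similarity `1/(1 + (d_ij/d0)^2)` under the current superposition and (ii) a
#' Kabsch refit on the aligned subset, until the aligned pair set is stable or
#' `max_iter` iterations. Seeded by the best ungapped sliding-window
#' superposition. End gaps are free, so divergent termini remain unaligned.
#'
#' @param a,b `pvr_structure` objects, or CA-trace data frames from
#'   [ca_trace()].
#' @param chain_a,chain_b Chains to use when structures are given.
#' @param norm TM-score normalisation length: `"reference"` (length of `a`,
#'   default) or `"shorter"`.
#' @param gap Gap penalty for the dynamic program (default -0.6).
#' @param max_iter Iteration cap (default 30).
#' @param window,stride Seed-search window length and stride.
#' @return A `pvr_alignment`: `pairs` (aligned residue table), `transform`
#'   mapping `b` onto `a`, `rmsd`, `tm_score`, `seq_identity`, `n_aligned`,
#'   `converged`.
#' @export
align_pair <- function(a, b, chain_a = NULL, chain_b = NULL,
                       norm = c("reference", "shorter"),
                       gap = -0.6, max_iter = 30L,
                       window = 40L, stride = 8L) {
  norm <- match.arg(norm)
  ta <- if (inherits(a, "pvr_structure")) ca_trace(a, chain_a) else a
  tb <- if (inherits(b, "pvr_structure")) ca_trace(b, chain_b) else b
  A <- trace_coords(ta); B <- trace_coords(tb)
  n <- nrow(A); m <- nrow(B)
  if (n < 20 || m < 20) stop("CA traces must have at least 20 residues")
  L_norm <- if (norm == "reference") n else min(n, m)
  d0 <- tm_d0(L_norm)
  tr <- seed_alignment(A, B, window, stride)
  prev_key <- ""
  converged <- FALSE
  pairs <- NULL
  for (it in seq_len(max_iter)) {
    Bt <- apply_transform(B, tr)
    d2 <- outer(rowSums(A^2), rowSums(Bt^2), "+") - 2 * (A %*% t(Bt))
    S <- 1 / (1 + pmax(d2, 0) / d0^2)
    pairs <- nw_align(S, gap)
    key <- paste(pairs[, 1], pairs[, 2], collapse = ";")
    if (identical(key, prev_key)) { converged <- TRUE; break }
    prev_key <- key
    if (nrow(pairs) >= 3)
      tr <- kabsch(A[pairs[, 1], , drop = FALSE], B[pairs[, 2], , drop = FALSE])
  }
  if (!converged)
    warning("pairwise alignment did not converge within ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  ai <- pairs[, 1]; bi <- pairs[, 2]
  fit <- kabsch(A[ai, , drop = FALSE], B[bi, , drop = FALSE])
  dists <- sqrt(rowSums((A[ai, , drop = FALSE] -
                           apply_transform(B[bi, , drop = FALSE], fit))^2))
  out <- structure(list(
    a_id = ta$structure_id[1], b_id = tb$structure_id[1],
    pairs = data.frame(ai = ai, bi = bi,
                       resid_a = ta$resid[ai], resid_b = tb$resid[bi],
                       resno_a = ta$resno[ai], resno_b = tb$resno[bi],
                       dist = dists, stringsAsFactors = FALSE),
    transform = fit[c("rotation", "translation")],
    rmsd = fit$rmsd,
    tm_score = tm_score(dists, L_norm),
    n_aligned = length(ai),
    norm = norm, L_norm = L_norm,
    trace_a = ta, trace_b = tb,
    converged = converged), class = "pvr_alignment")
  out$seq_identity <- seq_identity(out)
  out
}

#' @export
print.pvr_alignment <- function(x, ...) {
  cat(sprintf("pvr_alignment %s vs %s: %d pairs, RMSD %.3f A, TM %.4f, id %.1f%%\n",
              x$a_id, x$b_id, x$n_aligned, x$rmsd, x$tm_score, x$seq_identity))
  invisible(x)
}

#' Filter alignments by the core-comparability rule
#'
#' Keeps alignments against a common reference with strictly more than
#' `min_aligned` aligned residues or an RMSD strictly below `max_rmsd`.
#'
#' @param alignments List of `pvr_alignment` sharing structure `a`.
#' @param min_aligned Aligned-residue threshold (default 220, exclusive).
#' @param max_rmsd RMSD threshold in Angstrom (default 3.0, exclusive).
#' @return The filtered list.
#' @export
select_subset <- function(alignments, min_aligned = 220, max_rmsd = 3.0) {
  keep <- vapply(alignments, function(al)
    al$n_aligned > min_aligned || al$rmsd < max_rmsd, logical(1))
  alignments[keep]
}
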