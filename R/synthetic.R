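# Seeded generator of CA-resolved structure ensembles with a rigid shared
# core and planted length-variable regions, plus the ground-truth alignment
# and PVR table. This is the test bed for the whole pipeline: it emulates the
# statistical structure the PVR analysis assumes (conserved core with
# positional noise well below the anchor threshold, insertions whose length
# range exceeds the reporting threshold).

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Specify a synthetic structure ensemble
#'
#' The defaults describe the standard validation conditions used throughout
#' the package: 5 structures sharing a 250-residue core in four blocks, three
#' planted internal regions with length ranges 15, 25 and 40 residues,
#' core positional noise of 0.3 Angstrom per axis, and a random rigid motion
#' per structure.
#'
#' @param n_structures Number of structures.
#' @param core_blocks Lengths (residues) of the conserved core blocks.
#' @param planted_regions List of planted regions; each is
#'   `list(position =, lengths =)` where `position` p inserts between core
#'   blocks p and p+1 (0 = N-terminal extension, `length(core_blocks)` =
#'   C-terminal), and `lengths` gives one loop length per structure.
#' @param noise_sigma Isotropic Gaussian noise, Angstrom per axis, applied to
#'   core CA atoms of each structure.
#' @param transforms `"random"`, `"identity"`, or a list of rigid transforms
#'   (one per structure).
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#' @param range_cut Length-range threshold used to decide which planted
#'   regions enter the ground-truth PVR table (default 10, strict).
#' @param metal Optional `list(element =, residues =, )`: place one hetero
#'   metal per structure at the centroid of the named core residue indices.
#' @param n_copies Emit assembly instructions for this many symmetric copies
#'   (default 1 = monomer only).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_structures = 5,
                           core_blocks = c(70, 60, 60, 60),
                           planted_regions = list(
                             list(position = 1, lengths = c(5, 8, 12, 16, 20)),
                             list(position = 2, lengths = c(4, 10, 16, 22, 29)),
                             list(position = 3, lengths = c(6, 16, 26, 36, 46))),
                           noise_sigma = 0.3, transforms = "random",
                           seed = 1L, range_cut = 10, metal = NULL,
                           n_copies = 1L) {
  spec <- list(n_structures = as.integer(n_structures),
               core_blocks = as.integer(core_blocks),
               planted_regions = planted_regions,
               noise_sigma = noise_sigma, transforms = transforms,
               seed = as.integer(seed), range_cut = range_cut,
               metal = metal, n_copies = as.integer(n_copies))
  validate_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_spec <- function(spec) {
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(spec$core_blocks < 1)) stop("core blocks must be positive")
  K <- length(spec$core_blocks)
  for (rg in spec$planted_regions) {
    if (length(rg$lengths) != spec$n_structures)
      stop("planted region lengths must have one entry per structure")
    if (any(rg$lengths < 0)) stop("planted lengths must be >= 0")
    if (rg$position < 0 || rg$position > K)
      stop("planted region position must be in 0..", K)
  }
  if (is.list(spec$transforms) && length(spec$transforms) != spec$n_structures)
    stop("need one transform per structure")
  invisible(spec)
}

#' Derive a modified copy of a synthetic spec
#'
#' @param spec A `synthetic_spec`.
#' @param ... Named fields to override (unknown names are an error).
#' @return The modified `synthetic_spec`.
#' @export
perturb_case <- function(spec, ...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(unclass(spec)))
  if (length(unknown))
    stop("unknown spec field(s): ", paste(unknown, collapse = ", "))
  out <- unclass(spec)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out$n_structures <- as.integer(out$n_structures)
  out$seed <- as.integer(out$seed)
  validate_spec(out)
  class(out) <- "synthetic_spec"
  out
}

unit <- function(v) v / sqrt(sum(v^2))

# Smooth self-avoiding CA curve, 3.8 A consecutive spacing.
gen_core_curve <- function(n, step = 3.8, min_sep = 4.0, wobble = 0.25,
                           max_restart = 20) {
  for (attempt in seq_len(max_restart)) {
    xyz <- matrix(0, n, 3)
    dir <- unit(rnorm(3))
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      for (try in 1:50) {
        nd <- unit(dir + rnorm(3, sd = wobble))
        cand <- xyz[k - 1, ] + step * nd
        if (k <= 3 ||
            min(sqrt(rowSums(sweep(xyz[1:(k - 3), , drop = FALSE], 2,
                                   cand)^2))) >= min_sep) {
          xyz[k, ] <- cand; dir <- nd; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("failed to generate self-avoiding core curve")
}

# L loop residues on a circular arc joining anchors A and B with exact `step`
# spacing, in a random plane, clashing with no `avoid` point by < min_clear.
arc_loop <- function(A, B, L, avoid, step = 3.8, min_clear = 2.5,
                     max_try = 80) {
  cvec <- B - A
  cl <- sqrt(sum(cvec^2))
  half <- step / 2
  f <- function(r) (L + 1) * 2 * asin(pmin(1, half / r)) +
    2 * asin(pmin(1, cl / (2 * r))) - 2 * pi
  r_lo <- max(half, cl / 2) + 1e-9
  if (f(r_lo) < 0) stop("impossible loop closure: ", L, " residues over ",
                        round(cl, 2), " A")
  r <- uniroot(f, c(r_lo, 1e4), tol = 1e-10)$root
  M <- (A + B) / 2
  h <- sqrt(max(r^2 - (cl / 2)^2, 0))
  u <- unit(cvec)
  for (try in seq_len(max_try)) {
    w <- rnorm(3)
    v <- w - sum(w * u) * u
    if (sqrt(sum(v^2)) < 1e-6) next
    v <- unit(v)
    O <- M + h * v
    e1 <- unit(A - O)
    bo <- B - O
    e2v <- bo - sum(bo * e1) * e1
    e2 <- unit(e2v)
    theta_b <- atan2(sum(bo * e2), sum(bo * e1))
    if (theta_b <= 0) theta_b <- theta_b + 2 * pi
    sweep_ang <- theta_b - 2 * pi      # go the long way round
    ks <- seq_len(L) / (L + 1)
    ang <- sweep_ang * ks
    pts <- t(vapply(ang, function(a)
      O + r * (cos(a) * e1 + sin(a) * e2), numeric(3)))
    if (nrow(avoid) == 0) return(pts)
    dmin <- min(vapply(seq_len(nrow(pts)), function(i)
      min(sqrt(rowSums(sweep(avoid, 2, pts[i, ])^2))), numeric(1)))
    if (dmin >= min_clear) return(pts)
  }
  stop("impossible loop closure: no clash-free arc for ", L,
       " residues after ", max_try, " attempts")
}

# Terminal extension: smooth outward walk from an anchor.
terminal_walk <- function(anchor, away, L, avoid, step = 3.8,
                          min_clear = 2.5, wobble = 0.3) {
  if (L == 0) return(matrix(numeric(), 0, 3))
  pts <- matrix(0, L, 3)
  dir <- unit(away)
  prev <- anchor
  for (k in seq_len(L)) {
    placed <- FALSE
    for (try in 1:60) {
      nd <- unit(dir + rnorm(3, sd = wobble))
      cand <- prev + step * nd
      clear <- if (nrow(avoid)) min(sqrt(rowSums(sweep(avoid, 2, cand)^2)))
               else Inf
      if (clear >= min_clear) {
        pts[k, ] <- cand; dir <- nd; prev <- cand; placed <- TRUE; break
      }
    }
    if (!placed) stop("impossible terminal extension of length ", L)
  }
  pts
}

random_rotation <- function() {
  # uniform rotation via normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

#' Generate a synthetic structure ensemble with ground truth
#'
#' Builds the shared core as a smooth self-avoiding CA curve (3.8 Angstrom
#' spacing), perturbs each structure's core CA atoms with isotropic Gaussian
#' noise, plants the variable regions as clash-checked circular-arc loops
#' (internal) or outward walks (terminal) of the specified per-structure
#' lengths, synthesizes minimal N/C backbone stubs so the PDB output is
#' valid, and applies one rigid motion per structure. The same seed yields a
#' bit-identical ensemble.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `structures` (list of `pvr_structure`, ids `S1..Sn`),
#'   `truth` (planted-region table: `lengths` matrix, `length_range`,
#'   `sigma_abs` versus the first structure, filtered at the spec's
#'   `range_cut`), `msa` (ground-truth `pvr_msa`), and `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_structures
  K <- length(spec$core_blocks)
  n_core <- sum(spec$core_blocks)
  core <- gen_core_curve(n_core)
  block_end <- cumsum(spec$core_blocks)
  block_start <- c(1L, head(block_end, -1) + 1L)
  core_seq <- sample(AA3, n_core, replace = TRUE)
  centroid <- colMeans(core)

  regions <- spec$planted_regions
  positions <- vapply(regions, `[[`, numeric(1), "position")
  # loop coordinates per region per structure (in core frame)
  loops <- lapply(seq_along(regions), function(ri) {
    rg <- regions[[ri]]
    lapply(seq_len(n), function(s) {
      L <- rg$lengths[s]
      if (L == 0) return(matrix(numeric(), 0, 3))
      # the clash check spares the 2 residues flanking each anchor: real
      # loops pack against their anchor's neighbours too
      if (rg$position == 0) {
        anch <- core[1, ]
        pts <- terminal_walk(anch, anch - core[2, ], L,
                             avoid = core[-(1:3), , drop = FALSE])
        pts[rev(seq_len(L)), , drop = FALSE]   # N->C toward the anchor
      } else if (rg$position == K) {
        anch <- core[n_core, ]
        terminal_walk(anch, anch - core[n_core - 1, ], L,
                      avoid = core[-((n_core - 2):n_core), , drop = FALSE])
      } else {
        iA <- block_end[rg$position]
        iB <- block_start[rg$position + 1]
        excl <- intersect(c((iA - 2):(iA + 2), (iB - 2):(iB + 2)),
                          seq_len(n_core))
        arc_loop(core[iA, ], core[iB, ], L,
                 avoid = core[-excl, , drop = FALSE])
      }
    })
  })
  loop_seqs <- lapply(seq_along(regions), function(ri)
    lapply(seq_len(n), function(s)
      sample(AA3, regions[[ri]]$lengths[s], replace = TRUE)))

  region_at <- function(pos) which(positions == pos)
  ids <- paste0("S", seq_len(n))
  structures <- vector("list", n)
  res_kind <- vector("list", n)   # per structure: "core" index or 0 (loop)
  tr_list <- vector("list", n)
  for (s in seq_len(n)) {
    core_s <- core + matrix(rnorm(3 * n_core, sd = spec$noise_sigma),
                            n_core, 3)
    coords <- list(); seqs <- list(); kinds <- list()
    add_region <- function(pos) {
      for (ri in region_at(pos)) {
        pts <- loops[[ri]][[s]]
        if (nrow(pts)) {
          coords[[length(coords) + 1L]] <<- pts
          seqs[[length(seqs) + 1L]] <<- loop_seqs[[ri]][[s]]
          kinds[[length(kinds) + 1L]] <<- rep(0L, nrow(pts))
        }
      }
    }
    add_region(0)
    for (b in seq_len(K)) {
      idx <- block_start[b]:block_end[b]
      coords[[length(coords) + 1L]] <- core_s[idx, , drop = FALSE]
      seqs[[length(seqs) + 1L]] <- core_seq[idx]
      kinds[[length(kinds) + 1L]] <- idx
      if (b < K) add_region(b)
    }
    add_region(K)
    xyz <- do.call(rbind, coords)
    resid <- unlist(seqs)
    kind <- unlist(kinds)
    tr <- if (identical(spec$transforms, "identity"))
      list(rotation = diag(3), translation = numeric(3))
    else if (is.list(spec$transforms)) spec$transforms[[s]]
    else list(rotation = random_rotation(), translation = runif(3, -30, 30))
    if (spec$n_copies > 1)   # keep copies off the symmetry axis
      tr$translation <- tr$translation + c(40, 0, 0)
    xyz_t <- apply_transform(xyz, tr)
    structures[[s]] <- build_ca_structure(ids[s], xyz_t, resid, spec, core_s,
                                          kind, tr)
    res_kind[[s]] <- kind
    tr_list[[s]] <- tr
  }

  msa <- truth_msa(ids, structures, res_kind, tr_list, n_core)
  truth <- truth_table(spec, ids)
  list(structures = structures, truth = truth, msa = msa, spec = spec)
}

# CA plus minimal N/C stubs; optional metal HETATM; assembly ops for
# n_copies symmetric copies about the z axis.
build_ca_structure <- function(id, xyz, resid, spec, core_s, kind, tr) {
  nres <- nrow(xyz)
  stub <- function(i, toward) {
    ref <- if (toward >= 1 && toward <= nres) xyz[toward, ] else
      xyz[i, ] + c(1, 0, 0)
    d <- ref - xyz[i, ]
    l <- sqrt(sum(d^2))
    if (l < 1e-6) d <- c(1, 0, 0) else d <- d / l
    xyz[i, ] + 0.7 * d
  }
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    npos <- stub(i, i - 1)
    cpos <- stub(i, i + 1)
    rows[[i]] <- data.frame(
      type = "ATOM", elety = c("N", "CA", "C"), resid = resid[i],
      chain = "A", resno = i,
      x = c(npos[1], xyz[i, 1], cpos[1]),
      y = c(npos[2], xyz[i, 2], cpos[2]),
      z = c(npos[3], xyz[i, 3], cpos[3]),
      elesy = c("N", "C", "C"), stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(spec$metal)) {
    m <- spec$metal
    core_rows <- which(kind > 0)
    sel <- core_rows[match(m$residues, kind[core_rows])]
    pos <- colMeans(xyz[sel, , drop = FALSE])
    atoms <- rbind(atoms, data.frame(
      type = "HETATM", elety = toupper(m$element), resid = toupper(m$element),
      chain = "A", resno = nres + 1L,
      x = pos[1], y = pos[2], z = pos[3],
      elesy = toupper(m$element), stringsAsFactors = FALSE))
  }
  asm <- list()
  if (spec$n_copies > 1) {
    ops <- lapply(seq_len(spec$n_copies) - 1L, function(k)
      list(R = rot_z(2 * pi * k / spec$n_copies), t = numeric(3)))
    asm <- list("1" = list(id = "1", chains = "A", ops = ops))
  }
  pvr_structure(atoms, id, assemblies = asm)
}

# Ground-truth star alignment: columns are the reference's residues; core
# residues correspond across structures; non-reference loop residues are
# insertions attached after the column of the last preceding reference
# residue that is core (0 when none).
truth_msa <- function(ids, structures, res_kind, tr_list, n_core) {
  n <- length(ids)
  traces <- lapply(structures, function(s) ca_trace(s, "A"))
  names(traces) <- ids
  ref_kind <- res_kind[[1]]
  n_col <- length(ref_kind)
  # reference column of each core index
  col_of_core <- match(seq_len(n_core), ref_kind)
  cells <- matrix(NA_integer_, n, n_col, dimnames = list(ids, NULL))
  cells[1, ] <- seq_len(n_col)
  insertions <- setNames(vector("list", n), ids)
  insertions[[1]] <- data.frame(after_col = integer(), idx = integer())
  transforms <- setNames(vector("list", n), ids)
  transforms[[1]] <- list(rotation = diag(3), translation = numeric(3))
  ref_tr <- tr_list[[1]]
  for (s in seq.int(2, length.out = n - 1)) {
    kind <- res_kind[[s]]
    core_rows <- which(kind > 0)
    cells[s, col_of_core[kind[core_rows]]] <- core_rows
    loop_rows <- which(kind == 0)
    if (length(loop_rows)) {
      after <- vapply(loop_rows, function(k) {
        prior_core <- kind[seq_len(k - 1)]
        prior_core <- prior_core[prior_core > 0]
        if (length(prior_core)) col_of_core[max(prior_core)] else 0L
      }, integer(1))
      insertions[[s]] <- data.frame(after_col = after,
                                    idx = as.integer(loop_rows))
    } else {
      insertions[[s]] <- data.frame(after_col = integer(), idx = integer())
    }
    transforms[[s]] <- compose_transform(ref_tr, invert_transform(tr_list[[s]]))
  }
  structure(list(reference_id = ids[1], structure_ids = ids,
                 traces = traces, cells = cells, insertions = insertions,
                 transforms = transforms, pairwise = list()),
            class = "pvr_msa")
}

truth_table <- function(spec, ids) {
  lens <- do.call(cbind, lapply(spec$planted_regions, `[[`, "lengths"))
  if (is.null(lens)) lens <- matrix(numeric(), nrow = length(ids), ncol = 0)
  rng <- if (ncol(lens)) apply(lens, 2, function(x) max(x) - min(x))
         else numeric()
  keep <- rng > spec$range_cut
  lens <- lens[, keep, drop = FALSE]
  positions <- vapply(spec$planted_regions, `[[`, numeric(1),
                      "position")[keep]
  dimnames(lens) <- list(ids,
                         if (ncol(lens)) paste0("PVR", seq_len(ncol(lens))))
  sigma_abs <- rowSums(abs(lens - matrix(lens[1, ], nrow = nrow(lens),
                                         ncol = ncol(lens), byrow = TRUE)))
  list(n_pvrs = ncol(lens), positions = positions, lengths = lens,
       length_range = rng[keep], sigma_abs = sigma_abs,
       range_cut = spec$range_cut)
}

#' Write an ensemble to PDB files
#' @param ens Result of [generate_ensemble()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(ens$structures, function(s) {
    p <- file.path(dir, paste0(s$id, ".pdb"))
    write_structure(s, p)
    p
  }, character(1))
}
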