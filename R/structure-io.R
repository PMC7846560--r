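#' @useDynLib pvrscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames uniroot
#' @importFrom utils head modifyList tail write.table
NULL

# Elements treated as bound metal cofactors when seen as hetero atoms.
METAL_ELEMENTS <- c("ZN", "NI", "FE", "MN", "CU", "CO", "MG", "CA")

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Loads model 1 of a PDB or mmCIF file into a `pvr_structure`: polymer atoms
#' with alternate locations resolved (highest occupancy kept, first record on
#' tie), hetero metal atoms of a configurable element set, and any biological
#' assembly instructions present in the file (PDB `REMARK 350` or the mmCIF
#' `pdbx_struct_assembly_gen` / `pdbx_struct_oper_list` categories).
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format Optional override, `"pdb"` or `"mmcif"`; by default inferred
#'   from the file extension (`.cif`/`.mmcif` vs anything else).
#' @param id Structure label; defaults to the file base name without extension.
#' @param metal_elements Upper-case element symbols recognised as metals.
#' @return A `pvr_structure` with components `id`, `source_format`, `atoms`
#'   (a data frame in bio3d column layout), and `assemblies` (named list of
#'   assembly instructions).
#' @export
read_structure <- function(path, format = NULL,
                           id = sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                                    basename(path), ignore.case = TRUE),
                           metal_elements = METAL_ELEMENTS) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "mmcif"))
  pdb <- tryCatch(
    withCallingHandlers(
      if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                           verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
      warning = function(w) { # bio3d advisory notices, not data problems
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("empty model in ", path)
  # Model 1 only: bio3d returns model 1 in $atom for multi-model files.
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$elesy <- toupper(trimws(ifelse(is.na(atoms$elesy), "", atoms$elesy)))
  atoms$o[is.na(atoms$o)] <- 1
  miss <- atoms$elesy == ""
  if (any(miss))  # infer element from atom-name first letter when absent
    atoms$elesy[miss] <- substr(gsub("[^A-Za-z].*$", "",
                                     trimws(atoms$elety[miss])), 1, 1)
  atoms <- resolve_altlocs(atoms)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  asm <- if (format == "pdb") parse_remark350(pdb) else parse_cif_assemblies(path)
  structure(
    list(id = id, source_format = format, atoms = atoms,
         metal_elements = toupper(metal_elements), assemblies = asm),
    class = "pvr_structure")
}

# Highest occupancy wins within each (chain, resno, insert, elety) group;
# first record wins ties. Residue count is never changed by this step.
resolve_altlocs <- function(atoms) {
  has_alt <- atoms$alt != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$type, atoms$chain, atoms$resno, atoms$insert,
               atoms$resid, atoms$elety, sep = "\r")
  keep <- !logical(nrow(atoms))
  for (idx in split(seq_len(nrow(atoms)), key)) {
    if (length(idx) > 1L) {
      best <- idx[which.max(atoms$o[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pvr_structure <- function(x, ...) {
  cat("pvr_structure", sQuote(x$id), sprintf("[%s]\n", x$source_format))
  poly <- polymer_atoms(x)
  cat("  chains:", paste(unique(poly$chain), collapse = ", "), "\n")
  cat("  polymer residues:", n_residues(x),
      " atoms:", nrow(x$atoms),
      " metals:", nrow(metal_atoms(x)), "\n")
  if (length(x$assemblies))
    cat("  assemblies:", paste(names(x$assemblies), collapse = ", "), "\n")
  invisible(x)
}

polymer_atoms <- function(s) s$atoms[s$atoms$type == "ATOM", , drop = FALSE]

#' Hetero metal atoms of a structure
#' @param s A `pvr_structure`.
#' @return Data frame of hetero atoms whose element is in the structure's
#'   configured metal set.
#' @export
metal_atoms <- function(s) {
  a <- s$atoms
  a[a$type == "HETATM" & a$elesy %in% s$metal_elements &
      !(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
}

#' @export
chain_ids <- function(s) unique(polymer_atoms(s)$chain)

residue_keys <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")

n_residues <- function(s, chain = NULL) {
  a <- polymer_atoms(s)
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  length(unique(residue_keys(a)))
}

#' Alpha-carbon trace of a chain
#'
#' One row per polymer residue possessing a CA atom (element C), in file
#' order. Residues lacking a CA are skipped with a warning so the omission is
#' auditable; downstream alignment treats them as gaps.
#'
#' @param s A `pvr_structure`.
#' @param chain_id Chain identifier; defaults to the first polymer chain.
#' @return Data frame with columns `structure_id`, `chain`, `resno`, `insert`,
#'   `resid`, `x`, `y`, `z`.
#' @export
ca_trace <- function(s, chain_id = NULL) {
  poly <- polymer_atoms(s)
  if (nrow(poly) == 0) stop("structure ", s$id, " has no polymer atoms")
  if (is.null(chain_id)) chain_id <- poly$chain[1]
  a <- poly[poly$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0)
    stop("unknown chain ", sQuote(chain_id), " in structure ", s$id,
         "; available: ", paste(unique(poly$chain), collapse = ", "))
  keys <- residue_keys(a)
  is_ca <- a$elety == "CA" & a$elesy == "C"
  ca_rows <- a[is_ca, , drop = FALSE]
  ca_rows <- ca_rows[!duplicated(residue_keys(ca_rows)), , drop = FALSE]
  n_skip <- length(unique(keys)) - nrow(ca_rows)
  if (n_skip > 0)
    warning(n_skip, " residue(s) without CA skipped in ", s$id, " chain ",
            chain_id, call. = FALSE)
  data.frame(structure_id = s$id, chain = chain_id, resno = ca_rows$resno,
             insert = ca_rows$insert, resid = ca_rows$resid,
             x = ca_rows$x, y = ca_rows$y, z = ca_rows$z,
             stringsAsFactors = FALSE)
}

trace_coords <- function(tr) as.matrix(tr[, c("x", "y", "z")])

#' Write a structure to a PDB file
#'
#' @param s A `pvr_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", "", a$insert),
                   o = a$o, b = ifelse(is.na(a$b), 0, a$b), elesy = a$elesy)
  invisible(path)
}

# ---- biological assemblies ---------------------------------------------

# REMARK 350 instructions as parsed by bio3d into $remark$biomat.
parse_remark350 <- function(pdb) {
  bm <- pdb$remark$biomat
  if (is.null(bm)) return(list())
  out <- list()
  for (i in seq_len(bm$num)) {
    mats <- bm$mat[[i]]
    ops <- lapply(mats, function(m)
      list(R = m[, 1:3, drop = FALSE], t = as.numeric(m[, 4])))
    out[[as.character(i)]] <- list(id = as.character(i),
                                   chains = bm$chain[[i]], ops = unname(ops))
  }
  out
}

# Minimal reader for the two mmCIF categories that define assemblies. Handles
# the common loop_ and key-value layouts; oper expressions "1", "1,2", "(1-3)".
parse_cif_assemblies <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gen <- read_cif_category(lines, "_pdbx_struct_assembly_gen")
  oper <- read_cif_category(lines, "_pdbx_struct_oper_list")
  if (is.null(gen) || is.null(oper)) return(list())
  ops_by_id <- list()
  for (k in seq_len(nrow(oper))) {
    g <- function(nm) suppressWarnings(as.numeric(oper[[nm]][k]))
    R <- matrix(c(g("matrix[1][1]"), g("matrix[1][2]"), g("matrix[1][3]"),
                  g("matrix[2][1]"), g("matrix[2][2]"), g("matrix[2][3]"),
                  g("matrix[3][1]"), g("matrix[3][2]"), g("matrix[3][3]")),
                3, 3, byrow = TRUE)
    tv <- c(g("vector[1]"), g("vector[2]"), g("vector[3]"))
    if (any(!is.finite(R)) || any(!is.finite(tv)))
      stop("missing operator matrix in ", path)
    ops_by_id[[oper$id[k]]] <- list(R = R, t = tv)
  }
  out <- list()
  for (k in seq_len(nrow(gen))) {
    aid <- gen$assembly_id[k]
    ids <- expand_oper_expression(gen$oper_expression[k])
    missing_ops <- setdiff(ids, names(ops_by_id))
    if (length(missing_ops))
      stop("assembly ", aid, " references undefined operator(s): ",
           paste(missing_ops, collapse = ", "))
    entry <- list(id = aid,
                  chains = trimws(strsplit(gen$asym_id_list[k], ",")[[1]]),
                  ops = unname(ops_by_id[ids]))
    if (aid %in% names(out)) { # multiple gen rows for one assembly
      out[[aid]]$chains <- union(out[[aid]]$chains, entry$chains)
      out[[aid]]$ops <- c(out[[aid]]$ops, entry$ops)
    } else out[[aid]] <- entry
  }
  out
}

expand_oper_expression <- function(expr) {
  expr <- gsub("[()']", "", expr)
  parts <- trimws(strsplit(expr, ",")[[1]])
  unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      rng <- as.integer(strsplit(p, "-")[[1]])
      as.character(seq(rng[1], rng[2]))
    } else p
  }))
}

read_cif_category <- function(lines, cat) {
  pref <- paste0(cat, ".")
  hit <- grep(pref, lines, fixed = TRUE)
  if (!length(hit)) return(NULL)
  start <- hit[1]
  in_loop <- any(trimws(lines[max(1, start - 3):start]) == "loop_")
  if (in_loop) {
    keys <- character(); i <- start
    while (i <= length(lines) && startsWith(trimws(lines[i]), pref)) {
      keys <- c(keys, sub(pref, "", trimws(lines[i]), fixed = TRUE))
      i <- i + 1
    }
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || ln == "#" || startsWith(ln, "loop_") ||
          startsWith(ln, "data_")) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = "", quiet = TRUE)
      i <- i + 1
    }
    vals <- do.call(rbind, rows)
    if (is.null(vals) || ncol(vals) != length(keys)) return(NULL)
    df <- as.data.frame(vals, stringsAsFactors = FALSE)
    names(df) <- keys
    df
  } else {
    # key-value layout: one row
    kv <- list(); i <- start
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (startsWith(ln, pref)) {
        tok <- scan(text = ln, what = "", quiet = TRUE)
        kv[[sub(pref, "", tok[1], fixed = TRUE)]] <-
          paste(tok[-1], collapse = " ")
      } else if (length(kv) && (ln == "#" || startsWith(ln, "_") == FALSE &&
                                ln != "")) break
      i <- i + 1
    }
    as.data.frame(kv, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Build a biological assembly
#'
#' Applies the deposited symmetry operators of one assembly to the included
#' chains, producing a new structure with one chain copy per (chain,
#' operator). Copies get fresh single-character chain identifiers drawn from
#' `A-Z a-z 0-9`; the mapping back to the source chain and operator is kept in
#' `attr(, "chain_map")`. Waters are excluded by default; hetero metals are
#' carried along with their chain.
#'
#' @param s A `pvr_structure` with assembly instructions.
#' @param assembly_id Assembly identifier (e.g. `"1"`).
#' @param include_waters Keep water molecules? Default `FALSE`.
#' @return A new `pvr_structure`; the input is not modified.
#' @export
build_assembly <- function(s, assembly_id = "1", include_waters = FALSE) {
  if (!length(s$assemblies))
    stop("structure ", s$id, " carries no assembly instructions")
  aid <- as.character(assembly_id)
  if (!aid %in% names(s$assemblies))
    stop("unknown assembly id ", sQuote(aid), "; available: ",
         paste(names(s$assemblies), collapse = ", "))
  asm <- s$assemblies[[aid]]
  if (!length(asm$ops)) stop("assembly ", aid, " has no operator matrices")
  a <- s$atoms
  if (!include_waters)
    a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  keep_chains <- intersect(asm$chains, unique(a$chain))
  if (!length(keep_chains)) keep_chains <- unique(a$chain)
  pool <- c(LETTERS, letters, as.character(0:9))
  pieces <- list(); map <- list(); ci <- 0L
  for (k in seq_along(asm$ops)) {
    op <- asm$ops[[k]]
    for (ch in keep_chains) {
      ci <- ci + 1L
      if (ci > length(pool)) stop("assembly produces more chains than ids available")
      blk <- a[a$chain == ch, , drop = FALSE]
      xyz <- as.matrix(blk[, c("x", "y", "z")]) %*% t(op$R)
      blk$x <- xyz[, 1] + op$t[1]
      blk$y <- xyz[, 2] + op$t[2]
      blk$z <- xyz[, 3] + op$t[3]
      blk$chain <- pool[ci]
      pieces[[ci]] <- blk
      map[[ci]] <- data.frame(chain = pool[ci], source_chain = ch,
                              operator = k, stringsAsFactors = FALSE)
    }
  }
  out <- s
  out$atoms <- do.call(rbind, pieces)
  rownames(out$atoms) <- NULL
  out$id <- paste0(s$id, "-assembly", aid)
  out$assemblies <- list()
  attr(out, "chain_map") <- do.call(rbind, map)
  out
}
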