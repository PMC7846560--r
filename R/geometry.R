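# Metal coordination spheres, buried interface area, and inter-chain
# hydrogen-bond inventories.

# Bondi-style van der Waals radii (Angstrom), pinned for reproducibility.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               ZN = 1.39, NI = 1.63, FE = 1.61, MN = 1.61, CU = 1.40,
               CO = 1.61, MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75)
DEFAULT_RADIUS <- 1.80

#' Construct a structure from an atom table
#'
#' Low-level constructor used by the synthetic generator and by tests to
#' assemble a `pvr_structure` without a file. The atom table uses the bio3d
#' column layout; missing bookkeeping columns are filled with defaults.
#'
#' @param atoms Data frame with at least `type`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`, `elesy`.
#' @param id Structure label.
#' @param assemblies Optional assembly instruction list.
#' @param metal_elements Metal element set (see [read_structure()]).
#' @return A `pvr_structure`.
#' @export
pvr_structure <- function(atoms, id, assemblies = list(),
                          metal_elements = METAL_ELEMENTS) {
  defaults <- list(insert = "", alt = "", o = 1, b = 0)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  atoms$elesy <- toupper(atoms$elesy)
  structure(list(id = id, source_format = "constructed", atoms = atoms,
                 metal_elements = toupper(metal_elements),
                 assemblies = assemblies),
            class = "pvr_structure")
}

#' Find metal coordination sites
#'
#' For every hetero metal atom, collects the polymer N/O/S atoms within
#' `cutoff` (inclusive), grouped by residue. The default 3.0 Angstrom
#' tolerates refinement error around typical 1.9-2.3 Angstrom Zn-N/O bonds.
#'
#' @param s A `pvr_structure`.
#' @param cutoff Ligand distance cutoff in Angstrom (default 3.0, inclusive).
#' @return List of sites, each with `metal` (element, chain, resno, xyz) and
#'   `ligands` (data frame with residue, atom name, distance). Empty list
#'   when the structure has no metals.
#' @export
find_metal_sites <- function(s, cutoff = 3.0) {
  metals <- metal_atoms(s)
  if (nrow(metals) == 0) return(list())
  poly <- polymer_atoms(s)
  lig_pool <- poly[poly$elesy %in% c("N", "O", "S"), , drop = FALSE]
  lxyz <- as.matrix(lig_pool[, c("x", "y", "z")])
  sites <- vector("list", nrow(metals))
  for (k in seq_len(nrow(metals))) {
    m <- metals[k, ]
    d <- sqrt(colSums((t(lxyz) - c(m$x, m$y, m$z))^2))
    hit <- which(d <= cutoff)
    lig <- lig_pool[hit, c("chain", "resno", "insert", "resid", "elety",
                           "elesy"), drop = FALSE]
    lig$dist <- d[hit]
    lig <- lig[order(lig$dist), , drop = FALSE]
    rownames(lig) <- NULL
    sites[[k]] <- list(
      metal = list(element = m$elesy, chain = m$chain, resno = m$resno,
                   resid = m$resid, xyz = c(m$x, m$y, m$z)),
      ligands = lig)
  }
  sites
}

# Deterministic near-uniform unit-sphere points (golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements, radii = VDW_RADII,
                       default_radius = DEFAULT_RADIUS) {
  r <- radii[toupper(elements)]
  r[is.na(r)] <- default_radius
  as.numeric(r)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling with a fixed deterministic point set per atom.
#'
#' @param xyz n x 3 coordinate matrix of heavy atoms.
#' @param elements Element symbols, length n.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sample points per atom (default 960).
#' @param radii Named van der Waals radii table; unknown elements get
#'   `default_radius`.
#' @param default_radius Fallback radius.
#' @return Per-atom accessible area in square Angstrom.
#' @export
sasa <- function(xyz, elements, probe = 1.4, n_points = 960,
                 radii = VDW_RADII, default_radius = DEFAULT_RADIUS) {
  r <- atom_radii(elements, radii, default_radius) + probe
  sasa_atoms(as.matrix(xyz), r, sphere_points(n_points))
}

sasa_selection <- function(atoms, ...) {
  sum(sasa(as.matrix(atoms[, c("x", "y", "z")]), atoms$elesy, ...))
}

chain_atoms_for_surface <- function(s, chain) {
  a <- s$atoms
  a <- a[a$chain == chain & a$elesy != "H" &
           !(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(a) == 0) stop("unknown or empty chain ", sQuote(chain),
                         " in ", s$id)
  a
}

#' Buried interface area between two chains
#'
#' `buried = SASA(A) + SASA(B) - SASA(A+B)`, reported as `buried / 2` (the
#' PISA convention: the area of one face of the interface).
#'
#' @param assembly A `pvr_structure` containing both chains.
#' @param chains Length-2 character vector of chain ids.
#' @inheritParams sasa
#' @return Interface area in square Angstrom.
#' @export
interface_area <- function(assembly, chains, probe = 1.4, n_points = 960,
                           radii = VDW_RADII,
                           default_radius = DEFAULT_RADIUS) {
  stopifnot(length(chains) == 2)
  a <- chain_atoms_for_surface(assembly, chains[1])
  b <- chain_atoms_for_surface(assembly, chains[2])
  args <- list(probe = probe, n_points = n_points, radii = radii,
               default_radius = default_radius)
  sa <- do.call(sasa_selection, c(list(a), args))
  sb <- do.call(sasa_selection, c(list(b), args))
  sab <- do.call(sasa_selection, c(list(rbind(a, b)), args))
  (sa + sb - sab) / 2
}

# Donor/acceptor-capable heavy atoms, by residue and atom name. Backbone N is
# a donor and backbone O (and OXT) an acceptor for every residue.
HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH")
HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH")

hb_capable <- function(atoms, role) {
  if (nrow(atoms) == 0) return(atoms)
  dict <- if (role == "donor") HB_DONORS else HB_ACCEPTORS
  bb <- if (role == "donor") atoms$elety == "N"
        else atoms$elety %in% c("O", "OXT")
  side <- mapply(function(res, ety) ety %in% (dict[[res]] %||% character()),
                 atoms$resid, atoms$elety)
  atoms[(bb | side) & atoms$elesy %in% c("N", "O"), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inter-chain hydrogen-bond inventory
#'
#' Counts donor/acceptor heavy-atom pairs (N or O) across a chain interface
#' with distance at most `d_max`. The deposited models carry no hydrogens, so
#' no angle criterion is applied; pairs where both atoms sit in a metal
#' coordination sphere are excluded as metal-mediated. Each atom pair is
#' counted once even when it qualifies in both donor/acceptor directions.
#'
#' @param assembly A `pvr_structure` containing both chains.
#' @param chains Length-2 character vector of chain ids.
#' @param d_max Heavy-atom distance cutoff in Angstrom (default 3.5,
#'   inclusive).
#' @param metal_cutoff Distance to a metal below which a polar atom counts as
#'   metal-coordinated (default 3.0).
#' @return List with `chains`, `hbonds` (one row per bond) and `hbond_count`.
#' @export
count_interface_hbonds <- function(assembly, chains, d_max = 3.5,
                                   metal_cutoff = 3.0) {
  stopifnot(length(chains) == 2)
  poly <- polymer_atoms(assembly)
  A <- poly[poly$chain == chains[1], , drop = FALSE]
  B <- poly[poly$chain == chains[2], , drop = FALSE]
  if (nrow(A) == 0) stop("unknown chain ", sQuote(chains[1]))
  if (nrow(B) == 0) stop("unknown chain ", sQuote(chains[2]))
  metals <- metal_atoms(assembly)
  near_metal <- function(atoms) {
    if (nrow(metals) == 0 || nrow(atoms) == 0)
      return(logical(nrow(atoms)))
    mx <- as.matrix(metals[, c("x", "y", "z")])
    ax <- as.matrix(atoms[, c("x", "y", "z")])
    apply(ax, 1, function(p)
      any(sqrt(colSums((t(mx) - p)^2)) <= metal_cutoff))
  }
  pair_up <- function(don, acc) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    dxyz <- as.matrix(don[, c("x", "y", "z")])
    axyz <- as.matrix(acc[, c("x", "y", "z")])
    d2 <- outer(rowSums(dxyz^2), rowSums(axyz^2), "+") - 2 * dxyz %*% t(axyz)
    hit <- which(d2 <= d_max^2 + 1e-9, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    dm <- near_metal(don); am <- near_metal(acc)
    keep <- !(dm[hit[, 1]] & am[hit[, 2]])
    hit <- hit[keep, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(
      donor_chain = don$chain[hit[, 1]], donor_resno = don$resno[hit[, 1]],
      donor_resid = don$resid[hit[, 1]], donor_atom = don$elety[hit[, 1]],
      acceptor_chain = acc$chain[hit[, 2]],
      acceptor_resno = acc$resno[hit[, 2]],
      acceptor_resid = acc$resid[hit[, 2]],
      acceptor_atom = acc$elety[hit[, 2]],
      dist = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
  }
  bonds <- rbind(pair_up(hb_capable(A, "donor"), hb_capable(B, "acceptor")),
                 pair_up(hb_capable(B, "donor"), hb_capable(A, "acceptor")))
  if (is.null(bonds)) {
    bonds <- data.frame(donor_chain = character(), donor_resno = integer(),
                        donor_resid = character(), donor_atom = character(),
                        acceptor_chain = character(),
                        acceptor_resno = integer(),
                        acceptor_resid = character(),
                        acceptor_atom = character(), dist = numeric())
  } else {
    # one count per unordered atom pair
    key <- apply(bonds, 1, function(r) {
      x <- paste(r["donor_chain"], r["donor_resno"], r["donor_atom"])
      y <- paste(r["acceptor_chain"], r["acceptor_resno"], r["acceptor_atom"])
      paste(sort(c(x, y)), collapse = "|")
    })
    bonds <- bonds[!duplicated(key), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  list(chains = chains, hbonds = bonds, hbond_count = nrow(bonds))
}
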