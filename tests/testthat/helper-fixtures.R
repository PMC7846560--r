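# Fixtures are built in code at test time; no binary data.

# Hand-written 3-residue, 1-chain PDB with backbone + CA atoms.
toy_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
  "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
  "ATOM      6  CA  GLY A   2       4.000   2.800   0.100  1.00 10.00           C",
  "ATOM      7  C   GLY A   2       5.300   2.900   0.800  1.00 10.00           C",
  "ATOM      8  N   SER A   3       6.100   3.900   0.500  1.00 10.00           N",
  "ATOM      9  CA  SER A   3       7.400   4.200   1.100  1.00 10.00           C",
  "ATOM     10  OG  SER A   3       8.100   5.300   0.500  1.00 10.00           O",
  "END")

write_toy_pdb <- function(path = tempfile(fileext = ".pdb"),
                          lines = toy_pdb_lines()) {
  writeLines(lines, path)
  path
}

# Minimal atom table row for constructed structures.
atom_row <- function(elety, resid, chain, resno, x, y, z, elesy,
                     type = "ATOM") {
  data.frame(type = type, elety = elety, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, elesy = elesy,
             stringsAsFactors = FALSE)
}

# CA trace along a line, for hand-built alignments.
line_trace <- function(id, n = 30, resid = "ALA") {
  data.frame(structure_id = id, chain = "A", resno = seq_len(n), insert = "",
             resid = resid, x = 3.8 * seq_len(n), y = 0, z = 0,
             stringsAsFactors = FALSE)
}

identity_tr <- function() list(rotation = diag(3), translation = numeric(3))

# Hand-built two-structure MSA over identical line traces (no gaps).
two_struct_msa <- function(tr_a, tr_b) {
  n <- nrow(tr_a)
  structure(list(
    reference_id = tr_a$structure_id[1],
    structure_ids = c(tr_a$structure_id[1], tr_b$structure_id[1]),
    traces = setNames(list(tr_a, tr_b),
                      c(tr_a$structure_id[1], tr_b$structure_id[1])),
    cells = matrix(rep(seq_len(n), 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c(tr_a$structure_id[1],
                                     tr_b$structure_id[1]), NULL)),
    insertions = setNames(
      list(data.frame(after_col = integer(), idx = integer()),
           data.frame(after_col = integer(), idx = integer())),
      c(tr_a$structure_id[1], tr_b$structure_id[1])),
    transforms = setNames(list(identity_tr(), identity_tr()),
                          c(tr_a$structure_id[1], tr_b$structure_id[1])),
    pairwise = list()), class = "pvr_msa")
}

# Small, fast ensemble spec used by most alignment tests.
small_spec <- function(seed, ...) {
  args <- list(n_structures = 3, core_blocks = c(40, 40),
               planted_regions = list(list(position = 1,
                                           lengths = c(0, 6, 15))),
               noise_sigma = 0.3, seed = seed)
  dots <- list(...)
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]
  do.call(synthetic_spec, args)
}

# Random rotation matrix for property tests.
rand_rot <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_move <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

# Apply one rigid motion to every atom of a structure.
move_structure <- function(s, R, t) {
  xyz <- rigid_move(as.matrix(s$atoms[, c("x", "y", "z")]), R, t)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# Rotation-space brute force oracle for minimal RMSD: coarse Euler grid plus
# Nelder-Mead polish. Independent of the SVD route.
grid_min_rmsd <- function(P, Q, n_alpha = 18, n_beta = 10) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rmsd_at <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    R <- Rz1 %*% Ry %*% Rz2
    sqrt(mean(rowSums((Pc - Qc %*% t(R))^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = n_alpha + 1)[-1],
                      b = seq(0, pi, length.out = n_beta),
                      g = seq(0, 2 * pi, length.out = n_alpha + 1)[-1])
  vals <- apply(grid, 1, rmsd_at)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, rmsd_at, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
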