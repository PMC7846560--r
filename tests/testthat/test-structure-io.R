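test_that("a hand-written PDB parses into chains, residues and traces", {
  path <- write_toy_pdb()
  s <- read_structure(path)
  expect_s3_class(s, "pvr_structure")
  expect_identical(chain_ids(s), "A")
  expect_identical(pvrscan:::n_residues(s), 3L)
  expect_identical(nrow(metal_atoms(s)), 0L)
  tr <- ca_trace(s, "A")
  expect_identical(tr$resno, 1:3)
  expect_identical(tr$resid, c("ALA", "GLY", "SER"))
  expect_error(ca_trace(s, "Z"), "unknown chain")
})

test_that("altloc resolution keeps the highest-occupancy copy and residue count", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 10.00           C",
    "ATOM      4  CA AGLY A   3       7.600   0.000   0.000  0.50 10.00           C",
    "ATOM      5  CA BGLY A   3       8.600   0.000   0.000  0.50 10.00           C",
    "END")
  s <- read_structure(write_toy_pdb(lines = lines))
  expect_identical(pvrscan:::n_residues(s), 3L)
  tr <- ca_trace(s, "A")
  expect_equal(tr$x[1], 1.0)  # occupancy 0.6 beats 0.4
  expect_equal(tr$x[3], 7.6)  # tie: first record wins
})

test_that("residues without CA are skipped from the trace with a warning", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  N   GLY A   2       3.800   0.000   0.000  1.00 10.00           N",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00 10.00           C",
    "END")
  s <- read_structure(write_toy_pdb(lines = lines))
  expect_warning(tr <- ca_trace(s, "A"), "without CA")
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$resno, c(1L, 3L))
})

test_that("write/read round trip preserves residue refs and coordinates", {
  s <- read_structure(write_toy_pdb())
  out <- tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_identical(s2$atoms$resno, s$atoms$resno)
  expect_identical(s2$atoms$elety, s$atoms$elety)
  expect_identical(s2$atoms$chain, s$atoms$chain)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("hetero metals are captured and waters are not metals", {
  lines <- c(toy_pdb_lines()[1:10],
    "HETATM   11 ZN    ZN A 101       2.000   2.000   2.000  1.00 10.00          ZN",
    "HETATM   12  O   HOH A 201       8.000   8.000   8.000  1.00 10.00           O",
    "END")
  s <- read_structure(write_toy_pdb(lines = lines))
  m <- metal_atoms(s)
  expect_identical(nrow(m), 1L)
  expect_identical(m$elesy, "ZN")
  expect_identical(pvrscan:::n_residues(s), 3L)  # polymer only
})

test_that("REMARK 350 assemblies expand chains and reject unknown ids", {
  lines <- c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    toy_pdb_lines())
  s <- read_structure(write_toy_pdb(lines = lines))
  asm <- build_assembly(s, "1")
  # identity-only assembly: atom-identical copy
  expect_identical(nrow(asm$atoms), nrow(s$atoms))
  expect_equal(as.matrix(asm$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), ignore_attr = TRUE)
  expect_error(build_assembly(s, "9"), "unknown assembly id")

  lines2 <- c(lines[1:5],
    "REMARK 350   BIOMT1   2 -0.500000 -0.866025  0.000000       10.00000",
    "REMARK 350   BIOMT2   2  0.866025 -0.500000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000",
    toy_pdb_lines())
  s2 <- read_structure(write_toy_pdb(lines = lines2))
  asm2 <- build_assembly(s2, "1")
  # atom count = atoms x operators; fresh chain ids per copy
  expect_identical(nrow(asm2$atoms), 2L * nrow(s2$atoms))
  expect_identical(length(unique(asm2$atoms$chain)), 2L)
  # second copy is rotated: first CA of copy 2
  ca2 <- asm2$atoms[asm2$atoms$chain == "B" & asm2$atoms$elety == "CA", ][1, ]
  expect_equal(ca2$x, -0.5 * 1.458 + 10, tolerance = 1e-4)
})

test_that("mmCIF files parse with assembly operators", {
  cif <- c(
    "data_TOY",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.800 0.000 0.000 1.00 10.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . SER A 1 3 ? 8.600 0.000 0.000 1.00 10.00 ? 3 SER A CA 1",
    "#",
    "loop_",
    "_pdbx_struct_assembly_gen.assembly_id",
    "_pdbx_struct_assembly_gen.oper_expression",
    "_pdbx_struct_assembly_gen.asym_id_list",
    "1 1,2 A",
    "#",
    "loop_",
    "_pdbx_struct_oper_list.id",
    "_pdbx_struct_oper_list.type",
    "_pdbx_struct_oper_list.matrix[1][1]",
    "_pdbx_struct_oper_list.matrix[1][2]",
    "_pdbx_struct_oper_list.matrix[1][3]",
    "_pdbx_struct_oper_list.vector[1]",
    "_pdbx_struct_oper_list.matrix[2][1]",
    "_pdbx_struct_oper_list.matrix[2][2]",
    "_pdbx_struct_oper_list.matrix[2][3]",
    "_pdbx_struct_oper_list.vector[2]",
    "_pdbx_struct_oper_list.matrix[3][1]",
    "_pdbx_struct_oper_list.matrix[3][2]",
    "_pdbx_struct_oper_list.matrix[3][3]",
    "_pdbx_struct_oper_list.vector[3]",
    "1 identity 1 0 0 0 0 1 0 0 0 0 1 0",
    "2 crystal -1 0 0 5 0 -1 0 0 0 0 1 0",
    "#")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_identical(s$source_format, "mmcif")
  expect_identical(pvrscan:::n_residues(s), 3L)
  expect_identical(names(s$assemblies), "1")
  asm <- build_assembly(s, "1")
  expect_identical(nrow(asm$atoms), 6L)
  ca_b <- asm$atoms[asm$atoms$chain == "B", ][1, ]
  expect_equal(ca_b$x, -1 + 5, tolerance = 1e-6)
})

test_that("garbled and empty files raise parse errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure", bad)
  expect_error(read_structure(bad))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})
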