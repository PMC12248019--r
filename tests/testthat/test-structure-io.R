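# Parsing, validation, correspondence and chain mapping.

pdb_lines <- c(
  "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00  0.00           P",
  "ATOM      2  C4'   G A   1       2.000   3.000   4.000  1.00  0.00           C",
  "ATOM      3  C1'   G A   1       3.000   3.500   4.200  1.00  0.00           C",
  "ATOM      4  P     C A   2       5.000   6.000   7.000  1.00  0.00           P",
  "ATOM      5  C4'   C A   2       6.000   7.000   8.000  1.00  0.00           C",
  "ATOM      6  P     U A   3       9.000  10.000  11.000  1.00  0.00           P",
  "ATOM      7  C4'   U A   3      10.000  11.000  12.000  1.00  0.00           C",
  "END")

cif_lines <- c(
  "data_test",
  "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
  "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
  "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 P P . A A 1 1 ? 1.0 2.0 3.0 1.00 0.00 1 A A P 1",
  "ATOM 2 C \"C4'\" . A A 1 1 ? 2.0 3.0 4.0 1.00 0.00 1 A A \"C4'\" 1",
  "ATOM 3 C CA . ALA B 2 1 ? 9.0 9.0 9.0 1.00 0.00 1 ALA B CA 1")

test_that("a minimal RNA PDB parses into one typed chain", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  s <- read_structure(f)
  ch <- structure_chains(s)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$polymer_type, "RNA")
  expect_equal(ch$n_residues, 3L)
  expect_true(all(residue_table(s)$resolved))
})

test_that("mmCIF with RNA and protein chains gets both polymer types", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif_lines, f)
  s <- read_structure(f)
  ch <- structure_chains(s)
  expect_setequal(ch$polymer_type, c("RNA", "protein"))
  expect_equal(s$source_format, "mmcif")
})

test_that("residues without finite coordinates are unresolved", {
  a <- data.frame(chain = "A", resno = c(1, 1, 2), insert = "",
                  resname = "A", elety = c("C4'", "N1", "C4'"),
                  element = c("C", "N", "C"),
                  x = c(1, 2, NA), y = c(0, 0, NA), z = c(0, 0, NA))
  s <- new_structure("u", a)
  rt <- residue_table(s)
  expect_equal(rt$resolved, c(TRUE, FALSE))
})

test_that("unparsable and missing files raise errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("garbage with no atoms", f)
  expect_error(read_structure(f))
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("parse-write-parse round trip preserves the structure", {
  s <- make_hairpin(seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(structure_chains(s2)), nrow(structure_chains(s)))
  expect_equal(nrow(residue_table(s2)), nrow(residue_table(s)))
  fin <- is.finite(s$atoms$x)
  expect_lt(max(abs(s2$atoms$x - s$atoms$x[fin])), 1e-3)
  expect_lt(max(abs(s2$atoms$z - s$atoms$z[fin])), 1e-3)
})

test_that("altloc conformers collapse to the highest occupancy", {
  alt <- c(
    "ATOM      1  C4'AG A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  C4'BG A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  C4'   G A   2       5.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, f)
  s <- read_structure(f)
  a1 <- s$atoms[s$atoms$resno == 1 & s$atoms$elety == "C4'", ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$x, 9)
})

test_that("sequence correspondence matches shared resolved residues", {
  ref <- make_hairpin(seed = 5)
  corr <- residue_correspondence(ref, ref)
  expect_equal(nrow(corr), nrow(residue_table(ref)))
  # model missing residue 5
  a <- ref$atoms[!(ref$atoms$resno == 5), , drop = FALSE]
  m <- new_structure("m", a)
  corr2 <- residue_correspondence(m, ref)
  expect_false("A|5|" %in% corr2$model_key)
  expect_equal(nrow(corr2), nrow(corr) - 1)
  # reference residue 7 unresolved
  a2 <- ref$atoms
  a2[a2$resno == 7, c("x", "y", "z")] <- NA
  ref2 <- new_structure("r2", a2)
  corr3 <- residue_correspondence(ref, ref2)
  expect_false("A|7|" %in% corr3$ref_key)
  # disjoint numbering -> error
  a3 <- ref$atoms; a3$resno <- a3$resno + 100
  expect_error(residue_correspondence(new_structure("x", a3), ref),
               "no correspondence")
})

test_that("chain mapping recovers swapped labels of identical chains", {
  mono <- make_hairpin(seed = 2)
  dimer <- build_assembly(mono, "C", 2, seed = 5)
  a <- dimer$atoms
  a$chain <- ifelse(a$chain == "A", "B", "A")
  swapped <- new_structure("sw", a)
  map <- chain_mapping_search(swapped, dimer)
  expect_equal(unname(map[c("A", "B")]), c("B", "A"))
  expect_equal(tm_score(swapped, dimer, chain_map = map), 1)
})

test_that("heterodimers with distinct sequences force the identity map", {
  rna <- make_hairpin(seed = 2)
  other <- build_structure(
    secstruct_spec("AAAAGGCCAAAA", "............", id = "o"), seed = 9)
  oa <- other$atoms; oa$chain <- "B"
  het <- new_structure("het", rbind(rna$atoms, oa))
  map <- chain_mapping_search(het, het)
  expect_equal(unname(map[c("A", "B")]), c("A", "B"))
})

test_that("rotated ring labels map back with the self objective", {
  mono <- make_hairpin(seed = 2)
  ring <- build_assembly(mono, "C", 4, seed = 5)
  self_obj <- attr(chain_mapping_search(ring, ring), "objective")
  a <- ring$atoms
  a$chain <- c(A = "B", B = "C", C = "D", D = "A")[a$chain]
  rot <- new_structure("rot", a)
  map <- chain_mapping_search(rot, ring)
  expect_equal(attr(map, "objective"), self_obj, tolerance = 1e-9)
  # the rotation permutation undoes the relabeling
  expect_equal(unname(map[c("B", "C", "D", "A")]), c("A", "B", "C", "D"))
})

test_that("incompatible stoichiometry is rejected", {
  mono <- make_hairpin(seed = 2)
  dimer <- build_assembly(mono, "C", 2, seed = 5)
  expect_error(chain_mapping_search(mono, dimer), "stoichiometry")
})
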