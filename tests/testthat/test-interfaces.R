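# Contact extraction, interface scores, ligand metrics, degeneracy.

make_duplex <- function(seed = 3) {
  build_structure(secstruct_spec("GGGGGGAAACCCCCCAAA", "((((((...))))))...",
                                 chain_ends = 9, id = "dup"), seed = seed)
}

test_that("contact extraction follows the distance rule", {
  dup <- make_duplex()
  cs <- extract_contacts(dup)
  expect_gt(length(cs$contacts), 0)
  # every paired nucleotide is an interface residue
  canon <- annotate_pairs(dup)
  canon <- canon[canon$klass == "canonical" & canon$intermolecular, ]
  expect_true(all(c(canon$key_i, canon$key_j) %in% cs$residues))
  # far-apart chains -> empty
  a <- dup$atoms
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 500
  far <- new_structure("far", a)
  expect_length(extract_contacts(far)$contacts, 0)
  # zero threshold -> empty (strict inequality)
  expect_length(extract_contacts(dup, threshold = 0)$contacts, 0)
  expect_warning(extract_contacts(subset_chains(dup, "A")), "single chain")
})

test_that("ICS and IPS follow their set formulas", {
  ref <- c("A|1|--B|1|", "A|2|--B|2|")
  expect_equal(ics(ref, ref)$f1, 1)
  got <- ics("A|1|--B|1|", ref)
  expect_equal(got$f1, 2 / 3)
  expect_equal(ics(character(0), ref)$f1, 0)
  expect_true(ics(character(0), character(0))$null_score)
  expect_equal(ips(ref, ref), 1)
  expect_equal(ips("A|1|--B|1|", ref), 0.5)
  expect_equal(ips("A|3|--B|3|", ref), 0)
  expect_true(is.na(ips(character(0), character(0))))
})

test_that("interface lDDT isolates the interface", {
  dup <- make_duplex()
  expect_equal(interface_lddt(dup, dup), 1)
  # wrongly placed second chain: monomer quality intact, interface broken
  m <- perturb_model(dup, perturbation_spec(10, "chain", seed = 4))
  expect_lt(interface_lddt(m, dup), lddt(m, dup))
  # chains separated to infinity -> 0
  a <- dup$atoms
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 1e5
  expect_equal(interface_lddt(new_structure("inf", a), dup), 0)
})

test_that("NA-interface aggregation weights by residue count", {
  rec <- data.frame(type = c("NA-NA", "NA-protein"),
                    residue_count = c(10, 30), score = c(0.8, 0.4))
  expect_equal(aggregate_na_interfaces(rec), 0.5)
  one <- data.frame(type = "NA-NA", residue_count = 7, score = 0.63)
  expect_equal(aggregate_na_interfaces(one), 0.63)
  mixed <- data.frame(type = c("NA-NA", "protein-protein"),
                      residue_count = c(10, 100), score = c(0.8, 0.1))
  expect_equal(aggregate_na_interfaces(mixed), 0.8)
  pp <- data.frame(type = "protein-protein", residue_count = 5, score = 1)
  expect_true(is.na(aggregate_na_interfaces(pp)))
  # convex combination property
  expect_true(aggregate_na_interfaces(rec) >= min(rec$score) &&
              aggregate_na_interfaces(rec) <= max(rec$score))
})

make_ligand_target <- function() {
  mono <- make_hairpin(seed = 2)
  a <- mono$atoms
  sel <- a$resno == 6
  n_xyz <- unlist(a[sel & a$elety %in% c("N1", "N3"), c("x", "y", "z")])
  c1_xyz <- unlist(a[sel & a$elety == "C1'", c("x", "y", "z")])
  v <- (n_xyz - c1_xyz) / sqrt(sum((n_xyz - c1_xyz)^2))  # away from the chain
  p0 <- n_xyz + 3 * v
  lig <- data.frame(chain = "L", resno = 1, insert = "", resname = "LIG",
                    elety = c("C1", "C2", "N1"), element = c("C", "C", "N"),
                    x = p0[1] + c(0, 1.4 * v[1], 0.7 * v[1]),
                    y = p0[2] + c(0, 1.4 * v[2], 0.7 * v[2] + 1.2),
                    z = p0[3] + c(0, 1.4 * v[3], 0.7 * v[3]), occ = 1)
  new_structure("ligt", rbind(a, lig))
}

test_that("ligand metrics decouple pocket and pose accuracy", {
  ref <- make_ligand_target()
  pocket <- define_ligand_pocket(ref, "L|1|", radius = 12)
  expect_gt(length(pocket$pocket_residues), 0)
  perfect <- ligand_metrics(ref, ref, pocket)
  expect_equal(perfect$i_lddt, 1)
  expect_equal(perfect$lddt_pocket, 1)
  expect_equal(perfect$pocket_rmsd, 0, tolerance = 1e-9)
  # ligand translated 20 A: pocket stays perfect, interface collapses
  a <- ref$atoms
  a$x[a$chain == "L"] <- a$x[a$chain == "L"] + 40
  shifted <- ligand_metrics(new_structure("s", a), ref, pocket)
  expect_equal(shifted$lddt_pocket, 1)
  expect_lt(shifted$i_lddt, 0.05)
  # ligand absent -> all null with flag
  noflig <- new_structure("n", ref$atoms[ref$atoms$chain != "L", ])
  missing <- ligand_metrics(noflig, ref, pocket)
  expect_true(missing$ligand_missing)
  expect_true(is.na(missing$i_lddt))
})

test_that("pocket RMSD matches the quaternion oracle", {
  ref <- make_ligand_target()
  pocket <- define_ligand_pocket(ref, "L|1|", radius = 12)
  m <- perturb_model(ref, perturbation_spec(1, "gaussian", seed = 8))
  lm <- ligand_metrics(m, ref, pocket)
  ma <- nascore:::matched_atoms(m, ref, residue_correspondence(m, ref))
  sel <- ma$ref_reskey %in% pocket$pocket_residues &
    stats::complete.cases(ma$mod_xyz)
  expect_equal(lm$pocket_rmsd,
               quaternion_rmsd(ma$mod_xyz[sel, ], ma$ref_xyz[sel, ]),
               tolerance = 1e-6)
})

test_that("half-pocket normalisation picks the better half and caps at 1", {
  expect_equal(normalize_half_pocket(0.3, 0.6, 0.5), 0.5)
  expect_equal(normalize_half_pocket(0, 0.6, 0.5), 0)
  expect_equal(normalize_half_pocket(0.6, 0.6, 0.5), 1)
  expect_equal(normalize_half_pocket(0.9, 0.6, 0.5), 1)  # capped
  expect_true(is.na(normalize_half_pocket(0.3, 0, 0)))
  # idempotent on an already-perfect half prediction
  expect_equal(normalize_half_pocket(normalize_half_pocket(0.6, 0.6, 0.5),
                                     1, 1), 1)
})

test_that("degenerate multimer models are detected", {
  dup <- make_duplex()
  expect_false(detect_no_interaction(dup))
  a <- dup$atoms
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 500
  expect_true(detect_no_interaction(new_structure("sep", a)))
  # superposed duplicate chains
  b <- dup$atoms[dup$atoms$chain == "A", ]
  b2 <- b; b2$chain <- "B"
  expect_true(detect_no_interaction(new_structure("ovl", rbind(b, b2))))
})

test_that("ICS and IPS are invariant to chain relabeling after mapping", {
  dup <- make_duplex()
  ref_cs <- extract_contacts(dup)
  a <- dup$atoms
  a$chain <- ifelse(a$chain == "A", "B", "A")
  sw <- new_structure("sw", a)
  map <- chain_mapping_search(sw, dup)
  corr <- residue_correspondence(sw, dup, chain_map = map)
  lookup <- stats::setNames(corr$ref_key, corr$model_key)
  mapped <- vapply(strsplit(extract_contacts(sw)$contacts, "--", fixed = TRUE),
                   function(p) pair_id(lookup[p[1]], lookup[p[2]]),
                   character(1))
  expect_equal(ics(mapped, ref_cs)$f1, 1)
  mres <- unique(unlist(strsplit(mapped, "--", fixed = TRUE)))
  expect_equal(length(intersect(mres, ref_cs$residues)) /
                 length(union(mres, ref_cs$residues)), 1)
})
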