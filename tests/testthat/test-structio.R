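test_that("PDB write/read round trip preserves models, inventory and coordinates", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  ens <- generate_complex_ensemble(fixture_preset("cage-demo"),
                                   n_models = 20, jitter_sd = 0.2, seed = 11,
                                   path = pdb)
  back <- read_structure_ensemble(pdb, receptor_chains = "A",
                                  ligand_chains = "B")
  expect_equal(n_models(back), 20L)

  key <- function(e) paste(e$model, e$chain, e$seq_num, e$icode, e$res_name,
                           e$atom)
  expect_setequal(key(back), key(ens))
  ord1 <- order(key(ens))
  ord2 <- order(key(back))
  expect_lt(max(abs(ens$x[ord1] - back$x[ord2])), 1e-3 + 1e-12)
  expect_lt(max(abs(ens$y[ord1] - back$y[ord2])), 1e-3 + 1e-12)
  expect_lt(max(abs(ens$z[ord1] - back$z[ord2])), 1e-3 + 1e-12)

  # second round trip is exact: coordinates are already on the PDB grid
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, pdb2)
  back2 <- read_structure_ensemble(pdb2, receptor_chains = "A",
                                   ligand_chains = "B")
  expect_equal(back2$x, back$x)
})

test_that("files without MODEL records give M = 1", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_complex_ensemble(fixture_preset("charge-hbond-np"),
                            n_models = 1, seed = 1, path = pdb)
  expect_false(any(grepl("^MODEL", readLines(pdb))))
  ens <- read_structure_ensemble(pdb, receptor_chains = "A",
                                 ligand_chains = "B")
  expect_equal(n_models(ens), 1L)
})

test_that("reader drops hydrogens, heteroatoms and resolves altlocs by occupancy", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "ATOM      6  HB1 ALA A   1       9.000   0.000   0.000  1.00  0.00           H",
    "HETATM    7  O   HOH A 100       5.000   0.000   0.000  1.00  0.00           O",
    "ATOM      8  N   GLY B   1       0.000   4.000   0.000  1.00  0.00           N",
    "END"
  )
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, pdb)
  ens <- read_structure_ensemble(pdb, receptor_chains = "A",
                                 ligand_chains = "B")
  expect_setequal(ens$atom[ens$chain == "A"], c("N", "CA", "CB"))
  # CA: highest occupancy wins; CB: tie broken by file order
  expect_equal(ens$x[ens$atom == "CA"], 2.0)
  expect_equal(ens$x[ens$atom == "CB"], 3.0)
})

test_that("mmCIF reader agrees with the PDB reader", {
  specs <- fixture_preset("charge-hbond-np")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  ens <- generate_complex_ensemble(specs, n_models = 2, jitter_sd = 0.1,
                                   seed = 5, path = pdb)
  cif <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_fixture", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "auth_comp_id", "auth_asym_id",
                    "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                    "Cartn_z", "occupancy", "pdbx_PDB_model_num")))
  body <- sprintf("ATOM %d %s %s . %s %s %d ? %.3f %.3f %.3f 1.00 %d",
                  seq_len(nrow(ens)), ens$element, ens$atom, ens$res_name,
                  ens$chain, ens$seq_num, ens$x, ens$y, ens$z, ens$model)
  writeLines(c(hdr, body, "#"), cif)
  from_cif <- read_structure_ensemble(cif, receptor_chains = "A",
                                      ligand_chains = "B")
  from_pdb <- read_structure_ensemble(pdb, receptor_chains = "A",
                                      ligand_chains = "B")
  expect_equal(n_models(from_cif), 2L)
  key <- function(e) paste(e$model, e$chain, e$seq_num, e$atom)
  expect_setequal(key(from_cif), key(from_pdb))
  m <- match(key(from_pdb), key(from_cif))
  expect_lt(max(abs(from_pdb$x - from_cif$x[m])), 1e-3 + 1e-12)
})

test_that("reader errors name the offending chain or inventory mismatch", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_complex_ensemble(fixture_preset("charge-hbond-np"),
                            n_models = 2, seed = 1, path = pdb)
  expect_error(
    read_structure_ensemble(pdb, receptor_chains = "A", ligand_chains = "C"),
    "chain 'C'"
  )
  # drop one atom from model 2 only -> inventory mismatch
  lines <- readLines(pdb)
  drop <- which(grepl("^ATOM", lines) & grepl(" NZ ", lines))[2]
  writeLines(lines[-drop], pdb)
  expect_error(
    read_structure_ensemble(pdb, receptor_chains = "A", ligand_chains = "B"),
    "inventory differs"
  )
})

test_that("atom classes follow the lookup table and are idempotent", {
  df <- tibble::tibble(
    chain = c(rep("A", 5), "B"),
    seq_num = c(1L, 1L, 2L, 3L, 4L, 1L),
    res_name = c("ARG", "ARG", "ASP", "LEU", "CYS", "XYZ"),
    atom = c("NH1", "N", "OD1", "CD1", "SG", "O1"),
    x = c(0, 1, 2, 3, 4, 5), y = 0, z = 20
  )
  df$element <- c("N", "N", "O", "C", "S", "O")
  ens <- toy_ensemble(df)

  cls <- function(a, res) {
    row <- ens[ens$atom == a & ens$res_name == res, ]
    c(nonpolar = row$nonpolar, donor = row$donor, acceptor = row$acceptor,
      positive = row$positive, negative = row$negative)
  }
  expect_equal(cls("NH1", "ARG"),
               c(nonpolar = FALSE, donor = TRUE, acceptor = FALSE,
                 positive = TRUE, negative = FALSE))
  expect_equal(cls("OD1", "ASP"),
               c(nonpolar = FALSE, donor = FALSE, acceptor = TRUE,
                 positive = FALSE, negative = TRUE))
  expect_equal(cls("CD1", "LEU"),
               c(nonpolar = TRUE, donor = FALSE, acceptor = FALSE,
                 positive = FALSE, negative = FALSE))
  # backbone N is a donor; CYS SG is donor + nonpolar
  expect_true(ens$donor[ens$atom == "N"])
  expect_equal(cls("SG", "CYS")[c("nonpolar", "donor")],
               c(nonpolar = TRUE, donor = TRUE))
  # nonstandard residue: element fallback (O -> acceptor only)
  expect_equal(cls("O1", "XYZ"),
               c(nonpolar = FALSE, donor = FALSE, acceptor = TRUE,
                 positive = FALSE, negative = FALSE))

  expect_identical(assign_atom_classes(ens), ens)
})

test_that("disjoint/empty partner chain sets and empty structures are rejected", {
  df <- tibble::tibble(chain = c("A", "B"), seq_num = 1L,
                       res_name = "GLY", atom = "CA", x = 0, y = 0,
                       z = c(0, 5))
  expect_error(toy_ensemble(df, receptor = "A", ligand = "A"), "disjoint")
  expect_error(toy_ensemble(df, receptor = character(), ligand = "B"),
               "non-empty")
  expect_error(toy_ensemble(df[0, ]), "zero protein atoms")
})
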