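test_that("pair energies match hand evaluation of the ramp terms", {
  p <- energy_params()
  e_at <- function(d, r_res, r_atom, l_res, l_atom) {
    ens <- two_atom_ensemble(d, r_res, r_atom, l_res, l_atom)
    pair_energy(ens[ens$role == "receptor", ], ens[ens$role == "ligand", ], p)
  }
  # nonpolar-nonpolar at the ramp onset: full well depth
  expect_equal(e_at(3.4, "LEU", "CD1", "LEU", "CD1"), -0.4)
  # donor-acceptor at 3.0: ramp (3.6-3.0)/1.0 = 0.6
  expect_equal(e_at(3.0, "SER", "OG", "ASN", "OD1"), -4.0 * 0.6)
  # clash + nonpolar at 2.0: +25*0.5/2.5 - 0.4
  expect_equal(e_at(2.0, "LEU", "CD1", "LEU", "CD1"), 25 * 0.5 / 2.5 - 0.4)
  # salt bridge carries H-bond and charge terms: -2.4 - 8*(2/2.2)
  expect_equal(e_at(3.0, "LYS", "NZ", "ASP", "OD1"),
               -4.0 * 0.6 - 8.0 * (2 / 2.2))
  # like charges repel
  expect_equal(e_at(3.0, "LYS", "NZ", "ARG", "NH1"), +8.0 * (2 / 2.2))
  # at/beyond the global cutoff the energy vanishes
  expect_equal(e_at(8.0, "LYS", "NZ", "ASP", "OD1"), 0)
})

test_that("binding free energy is the sum over cross-partner pairs", {
  p <- energy_params()
  # three independent designed contacts: -0.4, -2.4, and a pure
  # opposite-charge pair at 3.0 (Lys NZ vs C-terminal OXT: charge only)
  df <- tibble::tibble(
    chain = rep(c("A", "B"), 3),
    seq_num = rep(1:3, each = 2),
    res_name = c("LEU", "LEU", "SER", "ASN", "LYS", "XCT"),
    atom = c("CD1", "CD1", "OG", "OD1", "NZ", "OXT"),
    element = c("C", "C", "O", "O", "N", "O"),
    x = rep(c(0, 30, 60), each = 2), y = 0,
    z = c(0, 3.4, 0, 3.0, 0, 3.0)
  )
  ens <- toy_ensemble(df)
  # OXT on a nonstandard residue gets acceptor via element fallback only;
  # force the designed "pure charge" classes by hand
  ens$acceptor[ens$atom == "OXT"] <- FALSE
  ens$negative[ens$atom == "OXT"] <- TRUE
  ens$donor[ens$atom == "NZ"] <- FALSE
  expect_equal(binding_free_energy(ens, p)$dg,
               -0.4 - 2.4 - 8.0 * (2 / 2.2))

  # partners far apart: zero with a warning
  far <- two_atom_ensemble(100)
  expect_warning(dg <- binding_free_energy(far, p), "no cross-partner")
  expect_equal(dg$dg, 0)
})

test_that("single-model scan reproduces hand-computed truncation effects", {
  ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
                                   n_models = 1, seed = 1)
  scan <- alanine_scan_model(ens, side = "receptor")
  ddg <- setNames(scan$ddg, scan$res_name)
  # Lys loses its NZ salt bridge: +2.4 + 8*(2/2.2) = +9.67
  expect_equal(unname(ddg["LYS"]), 4.0 * 0.6 + 8.0 * (2 / 2.2))
  expect_equal(unname(ddg["SER"]), 2.4)
  expect_equal(unname(ddg["LEU"]), 0.4)
})

test_that("scan equals the literal-truncation oracle on jittered ensembles", {
  ens <- generate_complex_ensemble(fixture_preset("cage-demo"),
                                   n_models = 4, jitter_sd = 0.25, seed = 42)
  for (m in 1:4) {
    for (side in c("receptor", "ligand", "both")) {
      fast <- alanine_scan_model(ens, model = m, side = side)
      slow <- oracle_scan_model(ens, model = m, side = side)
      key <- function(d) capscan:::residue_key(d$chain, d$seq_num, d$icode)
      expect_setequal(key(fast), key(slow))
      expect_equal(fast$ddg[order(key(fast))], slow$ddg[order(key(slow))],
                   tolerance = 1e-9)
    }
  }
})

test_that("residues without cross-partner side-chain contacts score zero; Gly/Ala are not scanned", {
  df <- tibble::tibble(
    chain = c("A", "A", "A", "A", "A", "B"),
    seq_num = c(1L, 1L, 2L, 3L, 3L, 1L),
    res_name = c("SER", "SER", "GLY", "ALA", "ALA", "ASN"),
    atom = c("OG", "CB", "CA", "CA", "CB", "OD1"),
    x = 0, y = 0, z = c(0, -1.4, -20, -30, -31, 3.0)
  )
  scan <- alanine_scan_model(toy_ensemble(df), side = "receptor")
  expect_setequal(scan$res_name, "SER") # GLY/ALA absent from the map
  # CB stays on truncation, so a CB-only contact residue scores 0
  df2 <- df
  df2$z[df2$atom == "CB" & df2$res_name == "SER"] <- 20
  df2$z[df2$atom == "OG"] <- 20 # side chain away; no scannable contact
  scan2 <- alanine_scan_model(toy_ensemble(df2), side = "receptor")
  expect_equal(scan2$ddg, 0)
})

test_that("ensemble aggregation is linear and SD degenerates correctly", {
  ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
                                   n_models = 6, jitter_sd = 0.3, seed = 9)
  scan <- alanine_scan(ens, side = "both")
  per_model <- lapply(1:6, function(m) {
    alanine_scan_model(ens, model = m, side = "both")
  })
  for (i in seq_len(nrow(scan))) {
    if (scan$res_name[i] %in% c("GLY", "ALA")) next
    vals <- vapply(per_model, function(pm) {
      pm$ddg[pm$chain == scan$chain[i] & pm$seq_num == scan$seq_num[i]]
    }, numeric(1))
    expect_equal(scan$ddg_mean[i], mean(vals), tolerance = 1e-12)
    expect_equal(scan$ddg_sd[i], sd(vals), tolerance = 1e-12)
    expect_equal(scan$ddg_per_model[[i]], vals, tolerance = 1e-12)
  }
  # M = 1: sample SD defined as 0
  one <- alanine_scan(generate_complex_ensemble(
    fixture_preset("charge-hbond-np"), n_models = 1, seed = 2), "receptor")
  expect_true(all(one$ddg_sd == 0))
  # jitter-free ensembles have identical models, hence SD 0
  flat <- alanine_scan(generate_complex_ensemble(
    fixture_preset("charge-hbond-np"), n_models = 20, jitter_sd = 0,
    seed = 2), "receptor")
  expect_true(all(flat$ddg_sd == 0))
})

test_that("polar down-weighting rescales DERKH residues and reranks", {
  ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
                                   n_models = 1, seed = 1)
  plain <- alanine_scan(ens, side = "receptor")
  down <- alanine_scan(ens, side = "receptor",
                       params = energy_params(w_polar = 0.5))
  lys_plain <- plain[plain$res_name == "LYS", ]
  lys_down <- down[down$res_name == "LYS", ]
  expect_equal(lys_down$ddg_mean, lys_plain$ddg_mean) # mean untouched
  expect_equal(lys_down$ddg_weighted, 0.5 * lys_plain$ddg_weighted)
  ser <- down[down$res_name == "SER", ]
  expect_equal(ser$ddg_weighted, ser$ddg_mean) # non-DERKH untouched
  expect_equal(lys_down$rank, 1L) # 4.84 still tops 2.4
})

test_that("energies are invariant under rigid translation", {
  ens <- generate_complex_ensemble(fixture_preset("cage-demo"),
                                   n_models = 2, jitter_sd = 0.2, seed = 6)
  shifted <- ens
  shifted$x <- shifted$x + 123.4
  shifted$y <- shifted$y - 77.7
  shifted$z <- shifted$z + 0.5
  expect_equal(binding_free_energy(shifted)$dg, binding_free_energy(ens)$dg,
               tolerance = 1e-9)
  a <- alanine_scan(ens, "receptor")
  b <- alanine_scan(shifted, "receptor")
  expect_equal(b$ddg_mean, a$ddg_mean, tolerance = 1e-9)
})

test_that("truncations of residues with disjoint contacts are additive", {
  ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
                                   n_models = 1, seed = 1)
  wt <- binding_free_energy(ens)$dg
  truncate <- function(e, seqs) {
    keep <- !(e$role == "receptor" & e$seq_num %in% seqs &
                !(e$atom %in% c("N", "CA", "C", "O", "OXT", "CB")))
    capscan:::rewrap_ensemble(e[keep, ], e)
  }
  d1 <- binding_free_energy(truncate(ens, 1))$dg - wt
  d2 <- binding_free_energy(truncate(ens, 2))$dg - wt
  d12 <- binding_free_energy(truncate(ens, c(1, 2)))$dg - wt
  expect_equal(d12, d1 + d2, tolerance = 1e-9)
})
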