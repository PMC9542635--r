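# build a small ensemble from a compact atom table; fills defaults
toy_ensemble <- function(df, receptor = "A", ligand = "B", classify = TRUE) {
  df <- tibble::as_tibble(df)
  if (!"model" %in% names(df)) df$model <- 1L
  if (!"icode" %in% names(df)) df$icode <- ""
  if (!"element" %in% names(df)) {
    df$element <- substr(sub("^[0-9]+", "", df$atom), 1, 1)
  }
  ens <- complex_ensemble(df, receptor_chains = receptor,
                          ligand_chains = ligand)
  if (classify) assign_atom_classes(ens) else ens
}

# two single-atom residues facing each other across the interface at
# distance d; class behaviour comes from the (res_name, atom) pair
two_atom_ensemble <- function(d, r_res = "LEU", r_atom = "CD1",
                              l_res = "LEU", l_atom = "CD1", model = 1L) {
  n_mod <- length(model)
  toy_ensemble(tibble::tibble(
    model = rep(model, each = 2),
    chain = rep(c("A", "B"), n_mod),
    seq_num = 1L,
    res_name = rep(c(r_res, l_res), n_mod),
    atom = rep(c(r_atom, l_atom), n_mod),
    x = 0, y = 0, z = rep(c(0, d), n_mod)
  ))
}

# hexagonal aromatic ring (radius 1.39) centred at `centre`, normal +z,
# plus backbone-ish stubs far away so the residue parses
ring_atoms <- function(res_name, centre = c(0, 0, 0), seq_num = 1L,
                       chain = "A") {
  stopifnot(res_name %in% c("TYR", "PHE"))
  ang <- seq(0, 300, by = 60) * pi / 180
  tibble::tibble(
    chain = chain, seq_num = as.integer(seq_num),
    res_name = res_name,
    atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    x = centre[1] + 1.39 * cos(ang),
    y = centre[2] + 1.39 * sin(ang),
    z = centre[3]
  )
}

# guanidinium group (CZ centre, NE/NH1/NH2 at 120 deg, radius 1.33) whose
# plane normal is tilted by `tilt_deg` about the x axis from +z
guanidinium_atoms <- function(centre = c(0, 0, 0), tilt_deg = 0,
                              seq_num = 1L, chain = "B") {
  ang <- c(90, 210, 330) * pi / 180
  pts <- cbind(1.33 * cos(ang), 1.33 * sin(ang), 0)
  pts <- rbind(c(0, 0, 0), pts) # CZ first
  t <- tilt_deg * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
                byrow = TRUE)
  pts <- pts %*% t(rot)
  tibble::tibble(
    chain = chain, seq_num = as.integer(seq_num), res_name = "ARG",
    atom = c("CZ", "NE", "NH1", "NH2"),
    x = centre[1] + pts[, 1], y = centre[2] + pts[, 2],
    z = centre[3] + pts[, 3]
  )
}

# independent brute-force scan oracle: literally truncate each residue
# beyond CB and recompute the full binding free energy
oracle_scan_model <- function(ensemble, model, side,
                              params = energy_params()) {
  ensemble <- assign_atom_classes(ensemble)
  sub <- ensemble[ensemble$model == model, , drop = FALSE]
  wt <- sum(capscan:::cross_pair_table(sub, params)$energy)
  res <- dplyr::distinct(sub[, c("role", "chain", "seq_num", "icode",
                                 "res_name")])
  res <- res[res$role %in% (if (side == "both") c("receptor", "ligand")
                            else side) &
               !(res$res_name %in% c("GLY", "ALA")), , drop = FALSE]
  res$ddg <- vapply(seq_len(nrow(res)), function(i) {
    r <- res[i, ]
    keep <- !(sub$chain == r$chain & sub$seq_num == r$seq_num &
                sub$icode == r$icode &
                !(sub$atom %in% c("N", "CA", "C", "O", "OXT", "CB")))
    mut <- sum(capscan:::cross_pair_table(sub[keep, , drop = FALSE],
                                          params)$energy)
    mut - wt
  }, numeric(1))
  res
}
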