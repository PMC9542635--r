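#' Surrogate pair-potential parameters
#'
#' Fully specified empirical energy function used for ensemble alanine
#' scanning. Each class term is a linear distance ramp
#' `ramp(d; on, off) = 1` for `d <= on`, `(off - d)/(off - on)` for
#' `on < d < off`, else 0. A pair of atoms contributes:
#' a steric penalty `+k_clash * (d_clash - d)/d_clash` for `d < d_clash`;
#' `-k_np * ramp` when both atoms are nonpolar; `-k_hb * ramp` for a
#' donor/acceptor pair; `-k_q * ramp` for opposite formal charges and
#' `+k_q * ramp` for like charges. Pairs at or beyond `global_cutoff`
#' contribute nothing. Magnitudes are ordered charge > hydrogen bond >
#' dispersion. `w_polar` optionally down-weights the scan ΔΔG of
#' charged/polar residues (Asp, Glu, Arg, Lys, His); 1 disables the
#' correction, 0.5 mirrors the published down-weighting that has been
#' suggested to be too severe.
#'
#' @param d_clash,k_clash Clash onset (Angstrom) and penalty scale (kJ/mol).
#' @param k_np,np_on,np_off Nonpolar term: well depth and ramp window.
#' @param k_hb,hb_on,hb_off Donor-acceptor term.
#' @param k_q,q_on,q_off Formal-charge term.
#' @param global_cutoff Distance beyond which pairs are ignored (Angstrom).
#' @param w_polar DERKH down-weight in (0, 1].
#' @return An object of class `energy_params`.
#' @examples
#' energy_params()
#' energy_params(w_polar = 0.5)
#' @export
energy_params <- function(d_clash = 2.5, k_clash = 25,
                          k_np = 0.4, np_on = 3.4, np_off = 6.0,
                          k_hb = 4.0, hb_on = 2.6, hb_off = 3.6,
                          k_q = 8.0, q_on = 2.8, q_off = 5.0,
                          global_cutoff = 8.0, w_polar = 1.0) {
  p <- list(d_clash = d_clash, k_clash = k_clash,
            k_np = k_np, np_on = np_on, np_off = np_off,
            k_hb = k_hb, hb_on = hb_on, hb_off = hb_off,
            k_q = k_q, q_on = q_on, q_off = q_off,
            global_cutoff = global_cutoff, w_polar = w_polar)
  with(p, {
    stopifnot(k_clash >= 0, k_np >= 0, k_hb >= 0, k_q >= 0,
              np_on < np_off, hb_on < hb_off, q_on < q_off,
              d_clash < global_cutoff, w_polar > 0, w_polar <= 1)
  })
  structure(p, class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("surrogate pair potential (kJ/mol, Angstrom):\n")
  cat(sprintf("  clash   : +%g*(%g-d)/%g for d < %g\n",
              x$k_clash, x$d_clash, x$d_clash, x$d_clash))
  cat(sprintf("  nonpolar: -%g * ramp(d; %g, %g)\n", x$k_np, x$np_on, x$np_off))
  cat(sprintf("  H-bond  : -%g * ramp(d; %g, %g)\n", x$k_hb, x$hb_on, x$hb_off))
  cat(sprintf("  charge  : -/+%g * ramp(d; %g, %g)\n", x$k_q, x$q_on, x$q_off))
  cat(sprintf("  cutoff  : %g; DERKH weight %g\n", x$global_cutoff, x$w_polar))
  invisible(x)
}

ramp <- function(d, on, off) pmin(1, pmax(0, (off - d) / (off - on)))

# vectorised core: all inputs are parallel vectors describing atom pairs
pair_energy_vec <- function(d, np_i, np_j, don_i, don_j, acc_i, acc_j,
                            q_i, q_j, params) {
  e <- ifelse(d < params$d_clash,
              params$k_clash * (params$d_clash - d) / params$d_clash, 0)
  e <- e - params$k_np * (np_i & np_j) * ramp(d, params$np_on, params$np_off)
  hb <- (don_i & acc_j) | (acc_i & don_j)
  e <- e - params$k_hb * hb * ramp(d, params$hb_on, params$hb_off)
  e <- e + params$k_q * (q_i * q_j) * ramp(d, params$q_on, params$q_off)
  ifelse(d >= params$global_cutoff, 0, e)
}

#' Energy of a single cross-partner atom pair
#'
#' @param atom_i,atom_j One-row data frames (e.g. rows of a classified
#'   [complex_ensemble()]) with coordinate and class columns; the two atoms
#'   must lie on opposite partners.
#' @param params An [energy_params()] object.
#' @return Pair energy in kJ/mol (negative favours binding).
#' @examples
#' ens <- assign_atom_classes(generate_complex_ensemble(
#'   fixture_preset("charge-hbond-np"), n_models = 1, seed = 1))
#' nz <- ens[ens$atom == "NZ", ]
#' od1 <- ens[ens$atom == "OD1" & ens$res_name == "ASP", ]
#' pair_energy(nz, od1)
#' @export
pair_energy <- function(atom_i, atom_j, params = energy_params()) {
  stopifnot(nrow(atom_i) == 1L, nrow(atom_j) == 1L)
  d <- sqrt((atom_i$x - atom_j$x)^2 + (atom_i$y - atom_j$y)^2 +
              (atom_i$z - atom_j$z)^2)
  if (d <= 0) abort("atom pair distance must be positive")
  pair_energy_vec(
    d,
    atom_i$nonpolar, atom_j$nonpolar,
    atom_i$donor, atom_j$donor,
    atom_i$acceptor, atom_j$acceptor,
    as.integer(atom_i$positive) - as.integer(atom_i$negative),
    as.integer(atom_j$positive) - as.integer(atom_j$negative),
    params
  )
}

# all cross-partner pairs within global_cutoff for one model, with energies
cross_pair_table <- function(model_atoms, params) {
  rec <- model_atoms[model_atoms$role == "receptor", , drop = FALSE]
  lig <- model_atoms[model_atoms$role == "ligand", , drop = FALSE]
  if (nrow(rec) == 0L || nrow(lig) == 0L) {
    abort("model lacks receptor or ligand atoms")
  }
  dx <- outer(rec$x, lig$x, "-")
  dy <- outer(rec$y, lig$y, "-")
  dz <- outer(rec$z, lig$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  idx <- which(d < params$global_cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(
      r_chain = character(), r_seq = integer(), r_icode = character(),
      r_res = character(), r_atom = character(),
      l_chain = character(), l_seq = integer(), l_icode = character(),
      l_res = character(), l_atom = character(),
      d = double(), energy = double()
    ))
  }
  ri <- idx[, 1]
  li <- idx[, 2]
  dd <- d[idx]
  qr <- as.integer(rec$positive) - as.integer(rec$negative)
  ql <- as.integer(lig$positive) - as.integer(lig$negative)
  tibble::tibble(
    r_chain = rec$chain[ri], r_seq = rec$seq_num[ri],
    r_icode = rec$icode[ri], r_res = rec$res_name[ri],
    r_atom = rec$atom[ri],
    l_chain = lig$chain[li], l_seq = lig$seq_num[li],
    l_icode = lig$icode[li], l_res = lig$res_name[li],
    l_atom = lig$atom[li],
    d = dd,
    energy = pair_energy_vec(
      dd,
      rec$nonpolar[ri], lig$nonpolar[li],
      rec$donor[ri], lig$donor[li],
      rec$acceptor[ri], lig$acceptor[li],
      qr[ri], ql[li], params
    )
  )
}

#' Empirical binding free energy of each pose
#'
#' Sums the surrogate pair potential over all cross-partner heavy-atom
#' pairs within the global cutoff, per model. More negative means stronger
#' predicted binding.
#'
#' @param ensemble A [complex_ensemble()] (classified automatically).
#' @param params An [energy_params()] object.
#' @return A tibble with columns `model` and `dg` (kJ/mol).
#' @examples
#' ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
#'                                  n_models = 1, seed = 1)
#' binding_free_energy(ens)
#' @export
binding_free_energy <- function(ensemble, params = energy_params()) {
  stopifnot(inherits(ensemble, "complex_ensemble"))
  ensemble <- require_classified(ensemble)
  models <- sort(unique(ensemble$model))
  dg <- vapply(models, function(m) {
    pairs <- cross_pair_table(ensemble[ensemble$model == m, , drop = FALSE],
                              params)
    if (nrow(pairs) == 0L) {
      warn(paste0("model ", m, ": no cross-partner pair within cutoff; dG = 0"))
      return(0)
    }
    sum(pairs$energy)
  }, numeric(1))
  tibble::tibble(model = models, dg = dg)
}
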