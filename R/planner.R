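#' Specify a photocage site
#'
#' A cage site is a tyrosine in the binding interface whose side chain is
#' replaced by a photocaged tyrosine. The energetic effect of the cage is
#' supplied as an in-vitro Kd fold-change rather than modelled
#' structurally: published values are ~10,000-fold for ortho-nitrobenzyl
#' tyrosine (ONBY) and ~420-fold for nitropiperonyl tyrosine (NPY), the
#' default. Non-tyrosine positions are accepted with a warning (they can
#' be planned but not chemically caged with these reagents).
#'
#' @param chain,seq_num,icode Residue identifier (author numbering).
#' @param fold_caged Kd fold-change of the caged vs uncaged binder (> 1).
#' @return An object of class `cage_spec`.
#' @examples
#' cage_spec("A", 37, fold_caged = 420)    # NPY-style cage
#' cage_spec("A", 37, fold_caged = 10000)  # ONBY-style cage
#' @export
cage_spec <- function(chain, seq_num, fold_caged = 420, icode = "") {
  stopifnot(fold_caged > 1)
  structure(list(chain = as.character(chain), seq_num = as.integer(seq_num),
                 icode = as.character(icode), fold_caged = fold_caged),
            class = "cage_spec")
}

#' @export
print.cage_spec <- function(x, ...) {
  cat(sprintf("cage site %s (fold-change %g)\n",
              residue_key(x$chain, x$seq_num, x$icode), x$fold_caged))
  invisible(x)
}

scan_side_roles <- function(scan) {
  side <- attr(scan, "side") %||% "receptor"
  if (side == "both") c("receptor", "ligand") else side
}

# residue keys of interface residues on the scanned side
interface_keys_for_scan <- function(scan, ensemble, cutoff = 5.0) {
  contacts <- find_interface_residues(ensemble, cutoff = cutoff)
  keys <- character()
  roles <- scan_side_roles(scan)
  if ("receptor" %in% roles) {
    keys <- c(keys, residue_key(contacts$chain_a, contacts$seq_a,
                                contacts$icode_a))
  }
  if ("ligand" %in% roles) {
    keys <- c(keys, residue_key(contacts$chain_b, contacts$seq_b,
                                contacts$icode_b))
  }
  unique(keys)
}

#' Rank candidate photocage sites
#'
#' Returns the tyrosines of the scanned side that sit in the
#' partner interface, ordered by descending weighted ensemble ΔΔG — the
#' logic by which an alanine scan that flags a tyrosine as a hot-spot also
#' flags it as a caging candidate.
#'
#' @param scan An [alanine_scan()] result.
#' @param ensemble The [complex_ensemble()] the scan was computed from.
#' @param cutoff Interface distance cutoff in Angstrom (default 5.0).
#' @return Tibble of candidate sites (subset of scan rows), best first;
#'   empty if the side has no interface tyrosine.
#' @export
propose_cage_sites <- function(scan, ensemble, cutoff = 5.0) {
  stopifnot(inherits(scan, "alanine_scan"), nrow(scan) > 0)
  iface <- interface_keys_for_scan(scan, ensemble, cutoff)
  key <- residue_key(scan$chain, scan$seq_num, scan$icode)
  out <- scan[scan$res_name == "TYR" & key %in% iface & !is.na(scan$rank), ,
              drop = FALSE]
  out <- dplyr::arrange(out, dplyr::desc(.data$ddg_weighted), .data$chain,
                        .data$seq_num, .data$icode)
  tibble::as_tibble(out)
}

#' Predict a variant Kd from additive ΔΔG contributions
#'
#' `Kd_variant = Kd_wt * exp(sum(ddgs) / RT)`: each mutation multiplies the
#' wild-type Kd by its own fold-change, the additivity assumption used for
#' combination variants.
#'
#' @param kd_wt Wild-type Kd (any concentration unit; output has the same).
#' @param ddgs Numeric vector of per-mutation ΔΔG values in kJ/mol
#'   (empty = wild type).
#' @param temperature Temperature in kelvin.
#' @return Predicted variant Kd.
#' @examples
#' predict_variant_affinity(0.76, fold_change_ddg(726.4, "fold_to_ddg"))
#' @export
predict_variant_affinity <- function(kd_wt, ddgs = numeric(),
                                     temperature = 298.15) {
  stopifnot(kd_wt > 0)
  kd_wt * exp(sum(ddgs) / rt_kj(temperature))
}

#' Plan caged-OFF / uncaged-ON switch variants
#'
#' Exhaustively combines a photocage site with 0 to `k_max` secondary
#' alanine mutations drawn from the scannable interface residues of the
#' scanned side. For each plan the uncaged Kd applies the secondary ΔΔGs
#' only (`kd_on`), the caged Kd additionally multiplies by the cage
#' fold-change (`kd_off`), and antigen occupancy plus predicted N/C ratio
#' are evaluated under the supplied cell scenario. A plan passes when the
#' caged occupancy is at most `theta_off` and the uncaged occupancy at
#' least `theta_on`; `fail_on` flags variants over-weakened beyond rescue
#' by uncaging (the fate of an interface doubly mutated on top of a cage),
#' `fail_off` variants whose caged form still binds.
#'
#' @param scan An [alanine_scan()] result containing the cage site.
#' @param ensemble The [complex_ensemble()] the scan came from (used to
#'   restrict candidates to interface residues and to flag shared
#'   contacts).
#' @param kd_wt Wild-type Kd in nanomolar.
#' @param cage A [cage_spec()].
#' @param cell A [cell_model()] (concentrations in micromolar).
#' @param k_max Maximal number of secondary mutations (default 2).
#' @param theta_off,theta_on Occupancy thresholds (defaults 0.05 and 0.5).
#' @param cutoff Interface cutoff in Angstrom for candidate selection.
#' @param temperature Temperature in kelvin.
#' @return Tibble of class `switch_plans`, one row per plan: `cage`,
#'   `secondary` (list of residue keys) and its flat `secondary_label`,
#'   `ddg_secondary`, `kd_on_nM`,
#'   `kd_off_nM`, `occ_on`, `occ_off`, `nc_on`, `nc_off`,
#'   `shared_contacts`, `verdict`; sorted pass-first then by `occ_on`
#'   descending (deterministic tie-breaks).
#' @examples
#' ens <- generate_complex_ensemble(fixture_preset("cage-demo"), seed = 1)
#' scan <- alanine_scan(ens, side = "receptor")
#' plan_switch(scan, ens, kd_wt = 0.76, cage = cage_spec("A", 4),
#'             cell = cell_model(1, 5, 0.15))
#' @export
plan_switch <- function(scan, ensemble, kd_wt, cage, cell, k_max = 2,
                        theta_off = 0.05, theta_on = 0.5, cutoff = 5.0,
                        temperature = 298.15) {
  stopifnot(inherits(scan, "alanine_scan"), inherits(cage, "cage_spec"),
            inherits(cell, "cell_model"), kd_wt > 0, k_max >= 0)
  key <- residue_key(scan$chain, scan$seq_num, scan$icode)
  cage_key <- residue_key(cage$chain, cage$seq_num, cage$icode)
  cage_row <- which(key == cage_key)
  if (length(cage_row) != 1L || is.na(scan$rank[cage_row])) {
    abort(paste0("cage site ", cage_key, " is not a scannable scan entry"))
  }
  if (scan$res_name[cage_row] != "TYR") {
    warn(paste0("cage site ", cage_key, " is ", scan$res_name[cage_row],
                ", not TYR; planning anyway"))
  }

  iface <- interface_keys_for_scan(scan, ensemble, cutoff)
  cand <- scan[key %in% setdiff(iface, cage_key) & !is.na(scan$rank), ,
               drop = FALSE]
  cand <- dplyr::arrange(cand, .data$chain, .data$seq_num, .data$icode)
  cand_key <- residue_key(cand$chain, cand$seq_num, cand$icode)

  contact_sets <- candidate_contact_atoms(ensemble, scan_side_roles(scan))

  subsets <- list(integer(0))
  for (k in seq_len(min(k_max, nrow(cand)))) {
    subsets <- c(subsets, utils::combn(nrow(cand), k, simplify = FALSE))
  }

  plans <- purrr::map(subsets, function(ix) {
    ddgs <- cand$ddg_weighted[ix]
    kd_on <- predict_variant_affinity(kd_wt, ddgs, temperature)
    kd_off <- kd_on * cage$fold_caged
    on <- predict_nc_ratio(cell, kd_on * 1e-3)   # nM -> uM
    off <- predict_nc_ratio(cell, kd_off * 1e-3)
    verdict <- if (on$occupancy < theta_on) "fail_on"
      else if (off$occupancy > theta_off) "fail_off"
      else "pass"
    sets <- contact_sets[cand_key[ix]]
    shared <- length(ix) > 1 &&
      any(duplicated(unlist(sets, use.names = FALSE)))
    tibble::tibble(
      cage = cage_key,
      secondary = list(cand_key[ix]),
      n_secondary = length(ix),
      ddg_secondary = sum(ddgs),
      kd_on_nM = kd_on,
      kd_off_nM = kd_off,
      occ_on = on$occupancy,
      occ_off = off$occupancy,
      nc_on = on$nc_ratio,
      nc_off = off$nc_ratio,
      shared_contacts = shared,
      verdict = verdict
    )
  }) |> dplyr::bind_rows()

  plans$secondary_label <- vapply(plans$secondary, paste, "", collapse = "+")
  plans <- plans |>
    dplyr::arrange(.data$verdict != "pass", dplyr::desc(.data$occ_on),
                   .data$n_secondary, .data$secondary_label)
  structure(plans, class = c("switch_plans", class(tibble::tibble())),
            thresholds = c(theta_off = theta_off, theta_on = theta_on),
            fold_caged = cage$fold_caged)
}

# ligand-side (or cross-side) atom keys contacted by each scannable residue's
# removable atoms, pooled over models; used to flag non-additive combinations
candidate_contact_atoms <- function(ensemble, roles,
                                    params = energy_params()) {
  ensemble <- require_classified(ensemble)
  pairs <- dplyr::bind_rows(lapply(sort(unique(ensemble$model)), function(m) {
    cross_pair_table(ensemble[ensemble$model == m, , drop = FALSE], params)
  }))
  sets <- list()
  if ("receptor" %in% roles) {
    sub <- pairs[removable_atom(pairs$r_atom) & pairs$energy != 0, ,
                 drop = FALSE]
    sp <- split(paste(sub$l_chain, sub$l_seq, sub$l_icode, sub$l_atom),
                residue_key(sub$r_chain, sub$r_seq, sub$r_icode))
    sets <- c(sets, lapply(sp, unique))
  }
  if ("ligand" %in% roles) {
    sub <- pairs[removable_atom(pairs$l_atom) & pairs$energy != 0, ,
                 drop = FALSE]
    sp <- split(paste(sub$r_chain, sub$r_seq, sub$r_icode, sub$r_atom),
                residue_key(sub$l_chain, sub$l_seq, sub$l_icode))
    sets <- c(sets, lapply(sp, unique))
  }
  sets
}

#' OFF/ON design-window plot for switch plans
#'
#' @param plans A [plan_switch()] result.
#' @return A ggplot object of caged vs uncaged occupancy, coloured by
#'   verdict, with the threshold window marked.
#' @export
plot_switch_plans <- function(plans) {
  stopifnot(inherits(plans, "switch_plans"))
  th <- attr(plans, "thresholds")
  ggplot2::ggplot(plans, ggplot2::aes(x = .data$occ_off, y = .data$occ_on,
                                      colour = .data$verdict)) +
    ggplot2::geom_vline(xintercept = th["theta_off"], linetype = 2) +
    ggplot2::geom_hline(yintercept = th["theta_on"], linetype = 2) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_continuous("caged (OFF) antigen occupancy",
                                limits = c(0, 1)) +
    ggplot2::scale_y_continuous("uncaged (ON) antigen occupancy",
                                limits = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.switch_plans <- function(object, ...) plot_switch_plans(object, ...)
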