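# aggregate per-model contact records into persistence + mean distance
aggregate_contacts <- function(long, n_mod, extra_cols = character()) {
  if (nrow(long) == 0L) {
    cols <- c("kind", "chain_a", "seq_a", "icode_a", "res_a",
              "chain_b", "seq_b", "icode_b", "res_b", extra_cols,
              "mean_distance", "persistence", "n_models")
    out <- tibble::as_tibble(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("kind", "chain_a", "seq_a", "icode_a", "res_a",
        "chain_b", "seq_b", "icode_b", "res_b", extra_cols)
    ))) |>
    dplyr::summarise(
      mean_distance = mean(.data$distance),
      mean_angle = if ("angle" %in% names(long)) mean(.data$angle) else NA_real_,
      persistence = dplyr::n_distinct(.data$model) / n_mod,
      .groups = "drop"
    ) |>
    dplyr::mutate(n_models = n_mod) |>
    dplyr::arrange(.data$chain_a, .data$seq_a, .data$icode_a,
                   .data$chain_b, .data$seq_b, .data$icode_b)
}

#' Interface residues by heavy-atom distance
#'
#' A receptor/ligand residue pair is an interface contact in a model iff
#' any cross-partner heavy-atom distance is at most `cutoff`. Persistence
#' is the fraction of models in which the contact is present.
#'
#' @param ensemble A [complex_ensemble()].
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @return Tibble with one row per residue pair: residue identifiers on
#'   both sides (`_a` = receptor, `_b` = ligand), `mean_distance` (mean
#'   over contact-bearing models of the minimal atom distance),
#'   `persistence` and `n_models`; sorted by receptor then ligand residue.
#' @examples
#' ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
#'                                  n_models = 3, seed = 1)
#' find_interface_residues(ens)
#' @export
find_interface_residues <- function(ensemble, cutoff = 5.0) {
  stopifnot(inherits(ensemble, "complex_ensemble"), cutoff > 0)
  ensemble <- require_classified(ensemble)
  rows <- lapply(sort(unique(ensemble$model)), function(m) {
    sub <- ensemble[ensemble$model == m, , drop = FALSE]
    rec <- sub[sub$role == "receptor", , drop = FALSE]
    lig <- sub[sub$role == "ligand", , drop = FALSE]
    if (nrow(rec) == 0L || nrow(lig) == 0L) abort("empty receptor or ligand")
    d <- sqrt(outer(rec$x, lig$x, "-")^2 + outer(rec$y, lig$y, "-")^2 +
                outer(rec$z, lig$z, "-")^2)
    idx <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(
      kind = "interface", model = m,
      chain_a = rec$chain[idx[, 1]], seq_a = rec$seq_num[idx[, 1]],
      icode_a = rec$icode[idx[, 1]], res_a = rec$res_name[idx[, 1]],
      chain_b = lig$chain[idx[, 2]], seq_b = lig$seq_num[idx[, 2]],
      icode_b = lig$icode[idx[, 2]], res_b = lig$res_name[idx[, 2]],
      distance = d[idx]
    ) |>
      dplyr::group_by(dplyr::across(-dplyr::all_of("distance"))) |>
      dplyr::summarise(distance = min(.data$distance), .groups = "drop")
  })
  out <- aggregate_contacts(dplyr::bind_rows(rows), length(unique(ensemble$model)))
  out$mean_angle <- NULL
  out
}

#' Polar cross-partner contacts (hydrogen-bond proxy)
#'
#' Reports cross-partner donor/acceptor heavy-atom pairs at distance
#' `<= dmax`. No angle criterion is applied (hydrogens are stripped on
#' read); the role assignment is symmetric, i.e. a donor on either side
#' paired with an acceptor on the other counts.
#'
#' @param ensemble A [complex_ensemble()].
#' @param dmax Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @return Tibble of atom-level contacts with `atom_a`/`atom_b`,
#'   `mean_distance`, `persistence`.
#' @export
detect_polar_contacts <- function(ensemble, dmax = 3.5) {
  stopifnot(inherits(ensemble, "complex_ensemble"), dmax > 0)
  ensemble <- require_classified(ensemble)
  rows <- lapply(sort(unique(ensemble$model)), function(m) {
    sub <- ensemble[ensemble$model == m, , drop = FALSE]
    rec <- sub[sub$role == "receptor", , drop = FALSE]
    lig <- sub[sub$role == "ligand", , drop = FALSE]
    d <- sqrt(outer(rec$x, lig$x, "-")^2 + outer(rec$y, lig$y, "-")^2 +
                outer(rec$z, lig$z, "-")^2)
    polar <- outer(rec$donor, lig$acceptor, "&") |
      outer(rec$acceptor, lig$donor, "&")
    idx <- which(d <= dmax & polar, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(
      kind = "hbond", model = m,
      chain_a = rec$chain[idx[, 1]], seq_a = rec$seq_num[idx[, 1]],
      icode_a = rec$icode[idx[, 1]], res_a = rec$res_name[idx[, 1]],
      atom_a = rec$atom[idx[, 1]],
      chain_b = lig$chain[idx[, 2]], seq_b = lig$seq_num[idx[, 2]],
      icode_b = lig$icode[idx[, 2]], res_b = lig$res_name[idx[, 2]],
      atom_b = lig$atom[idx[, 2]],
      distance = d[idx]
    )
  })
  out <- aggregate_contacts(dplyr::bind_rows(rows),
                            length(unique(ensemble$model)),
                            extra_cols = c("atom_a", "atom_b"))
  out$mean_angle <- NULL
  out
}

RING_ATOMS <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD1", "NE2", "CE2")
)
GUANIDINIUM_ATOMS <- c("NE", "NH1", "NH2", "CZ")

plane_fit <- function(xyz) {
  centroid <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

# extract ring/cation groups (centroid + normal or point) for one model side
pi_groups <- function(atoms, what = c("ring", "cation")) {
  what <- match.arg(what)
  res <- dplyr::distinct(atoms, .data$chain, .data$seq_num, .data$icode,
                         .data$res_name)
  out <- list()
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    sub <- atoms[atoms$chain == r$chain & atoms$seq_num == r$seq_num &
                   atoms$icode == r$icode, , drop = FALSE]
    if (what == "ring" && r$res_name %in% names(RING_ATOMS)) {
      want <- RING_ATOMS[[r$res_name]]
      got <- sub[match(want, sub$atom), , drop = FALSE]
      if (anyNA(got$x)) {
        warn(paste0("ring atoms missing for ", r$res_name, " ",
                    residue_key(r$chain, r$seq_num, r$icode), "; skipped"))
        next
      }
      pf <- plane_fit(as.matrix(got[, c("x", "y", "z")]))
      out[[length(out) + 1L]] <- c(r, list(group = "ring",
                                           centroid = list(pf$centroid),
                                           normal = list(pf$normal)))
    } else if (what == "cation" && r$res_name == "ARG") {
      got <- sub[match(GUANIDINIUM_ATOMS, sub$atom), , drop = FALSE]
      if (anyNA(got$x)) {
        warn(paste0("guanidinium atoms missing for ARG ",
                    residue_key(r$chain, r$seq_num, r$icode), "; skipped"))
        next
      }
      pf <- plane_fit(as.matrix(got[, c("x", "y", "z")]))
      out[[length(out) + 1L]] <- c(r, list(group = "guanidinium",
                                           centroid = list(pf$centroid),
                                           normal = list(pf$normal)))
    } else if (what == "cation" && r$res_name == "LYS") {
      got <- sub[sub$atom == "NZ", , drop = FALSE]
      if (nrow(got) != 1L) next
      out[[length(out) + 1L]] <- c(r, list(group = "NZ",
                                           centroid = list(c(got$x, got$y, got$z)),
                                           normal = list(NULL)))
    }
  }
  out
}

#' Cross-partner cation-pi contacts
#'
#' Pairs each aromatic ring (Tyr/Phe six-ring, Trp six-ring, His
#' five-ring) with a cross-partner cationic group — the Arg guanidinium
#' plane (NE, NH1, NH2, CZ) or the Lys NZ atom. A pair is reported when
#' the ring-centroid to cation-centroid distance is at most `dmax` and,
#' for the planar guanidinium, the interplanar angle (ring normal vs
#' guanidinium normal) is at most `max_angle`; for Lys NZ only the
#' distance criterion applies. This geometry captures the parallel,
#' tightly packed arrangement photocaging groups can adopt against an
#' interface arginine.
#'
#' @param ensemble A [complex_ensemble()].
#' @param dmax Centroid-centroid cutoff in Angstrom (default 6.0).
#' @param max_angle Maximal interplanar angle in degrees (default 30).
#' @return Tibble of contacts with `mean_distance`, `mean_angle` (NA for
#'   Lys), `persistence`.
#' @export
detect_cation_pi <- function(ensemble, dmax = 6.0, max_angle = 30) {
  stopifnot(inherits(ensemble, "complex_ensemble"), dmax > 0, max_angle > 0)
  ensemble <- require_classified(ensemble)
  rows <- lapply(sort(unique(ensemble$model)), function(m) {
    sub <- ensemble[ensemble$model == m, , drop = FALSE]
    rec <- sub[sub$role == "receptor", , drop = FALSE]
    lig <- sub[sub$role == "ligand", , drop = FALSE]
    hits <- list()
    for (dir in 1:2) {
      rings <- pi_groups(if (dir == 1) rec else lig, "ring")
      cations <- pi_groups(if (dir == 1) lig else rec, "cation")
      for (ring in rings) {
        for (cat_ in cations) {
          dd <- sqrt(sum((ring$centroid[[1]] - cat_$centroid[[1]])^2))
          if (dd > dmax) next
          ang <- NA_real_
          if (!is.null(cat_$normal[[1]])) {
            cosang <- abs(sum(ring$normal[[1]] * cat_$normal[[1]]))
            ang <- acos(pmin(1, cosang)) * 180 / pi
            if (ang > max_angle) next
          }
          # _a is always the receptor residue
          a <- if (dir == 1) ring else cat_
          b <- if (dir == 1) cat_ else ring
          hits[[length(hits) + 1L]] <- tibble::tibble(
            kind = "cation_pi", model = m,
            chain_a = a$chain, seq_a = a$seq_num, icode_a = a$icode,
            res_a = a$res_name,
            chain_b = b$chain, seq_b = b$seq_num, icode_b = b$icode,
            res_b = b$res_name,
            distance = dd, angle = ang
          )
        }
      }
    }
    dplyr::bind_rows(hits)
  })
  aggregate_contacts(dplyr::bind_rows(rows), length(unique(ensemble$model)))
}
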