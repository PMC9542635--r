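# heavy-atom inventories used by the fixture generator
FIXTURE_ATOMS <- list(
  GLY = c("N", "CA", "C", "O"),
  ALA = c("N", "CA", "C", "O", "CB"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

fixture_element <- function(atom) substr(sub("^[0-9]+", "", atom), 1, 1)

#' Specify one designed cross-chain contact
#'
#' One receptor residue and one ligand residue whose named atoms are
#' placed at an exact distance in the jitter-free base pose. All other
#' atoms of both residues are laid out on a tail more than the global
#' energy cutoff away from the partner chain, so the designed atom pair is
#' the only energetic cross-chain interaction and scan energies can be
#' computed by hand.
#'
#' @param r_res,r_atom Receptor residue type (3-letter code from the
#'   supported set) and contact atom name.
#' @param l_res,l_atom Ligand residue type and contact atom name.
#' @param distance Designed heavy-atom distance in Angstrom (> 0).
#' @return One-row tibble; bind rows of these into a spec table.
#' @examples
#' contact_spec("LYS", "NZ", "ASP", "OD1", 3.0)
#' @export
contact_spec <- function(r_res, r_atom, l_res, l_atom, distance) {
  if (distance <= 0) abort("designed distance must be positive")
  for (rn in c(r_res, l_res)) {
    if (!rn %in% names(FIXTURE_ATOMS)) {
      abort(paste0("unsupported fixture residue: ", rn))
    }
  }
  if (!r_atom %in% FIXTURE_ATOMS[[r_res]]) {
    abort(paste0("atom '", r_atom, "' is not part of ", r_res))
  }
  if (!l_atom %in% FIXTURE_ATOMS[[l_res]]) {
    abort(paste0("atom '", l_atom, "' is not part of ", l_res))
  }
  tibble::tibble(r_res = r_res, r_atom = r_atom,
                 l_res = l_res, l_atom = l_atom, distance = distance)
}

#' Built-in contact spec tables
#'
#' `"charge-hbond-np"`: a salt bridge (Lys NZ / Asp OD1 at 3.0, carrying
#' both a hydrogen-bond and a charge term), a hydrogen bond (Ser OG / Asn
#' OD1 at 3.0) and a single nonpolar contact (Leu CD1 / Leu CD1 at 3.4) —
#' designed hot-spot ordering charge > H-bond > nonpolar.
#' `"cage-demo"` adds an interface tyrosine (Tyr OH / Arg NH1 at 2.9) as
#' receptor residue 4, giving the planner a cage site plus three
#' secondary-mutation candidates.
#'
#' @param name Preset name.
#' @return A contact spec tibble for [generate_complex_ensemble()].
#' @export
fixture_preset <- function(name = c("charge-hbond-np", "cage-demo")) {
  name <- match.arg(name)
  base <- dplyr::bind_rows(
    contact_spec("LYS", "NZ", "ASP", "OD1", 3.0),
    contact_spec("SER", "OG", "ASN", "OD1", 3.0),
    contact_spec("LEU", "CD1", "LEU", "CD1", 3.4)
  )
  if (name == "cage-demo") {
    base <- dplyr::bind_rows(base, contact_spec("TYR", "OH", "ARG", "NH1", 2.9))
  }
  base
}

# place a residue: contact atom at `origin`, remaining atoms on a helical
# tail starting `tail_gap` along `direction` (+1 or -1 z) and receding
place_residue <- function(res_name, contact_atom, origin, direction,
                          tail_gap = 8.6, step = 1.45) {
  atoms <- FIXTURE_ATOMS[[res_name]]
  others <- setdiff(atoms, contact_atom)
  k <- seq_along(others)
  coords <- rbind(
    c(0, 0, 0),
    cbind(0.8 * sin(k), 0.8 * cos(k), direction * (tail_gap + step * k))
  )
  tibble::tibble(
    atom = c(contact_atom, others),
    element = fixture_element(c(contact_atom, others)),
    x = origin[1] + coords[, 1],
    y = origin[2] + coords[, 2],
    z = origin[3] + coords[, 3]
  )
}

#' Generate a synthetic multi-model complex with designed contacts
#'
#' Builds a two-chain complex (receptor chain A, ligand chain B) in which
#' each [contact_spec()] row becomes one receptor/ligand residue pair
#' whose designed atom distance holds exactly in the jitter-free base
#' pose. Contact sites are spaced 30 Angstrom apart and non-contact atoms
#' are kept beyond the global energy cutoff of the partner chain by
#' construction (deliberately non-physical stretched side chains), so
#' every cross-chain energy is a single hand-computable pair term. Each
#' model adds isotropic Gaussian jitter of `jitter_sd` to all coordinates;
#' generation is seeded and reproducible.
#'
#' @param specs Contact spec tibble ([contact_spec()] rows or a
#'   [fixture_preset()]).
#' @param n_models Number of models M (>= 1).
#' @param jitter_sd Per-coordinate Gaussian jitter in Angstrom.
#' @param seed Integer seed.
#' @param path Optional path; when given, the ensemble is also written as
#'   a multi-model PDB file.
#' @param spacing Distance between successive contact sites (Angstrom).
#' @return A [complex_ensemble()] (classified).
#' @examples
#' ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
#'                                  n_models = 20, jitter_sd = 0.2, seed = 7)
#' n_models(ens)
#' @export
generate_complex_ensemble <- function(specs, n_models = 1, jitter_sd = 0,
                                      seed = 1, path = NULL, spacing = 30) {
  specs <- tibble::as_tibble(specs)
  stopifnot(n_models >= 1, jitter_sd >= 0, spacing > 0)
  if (any(specs$distance <= 0)) abort("designed distances must be positive")
  pair_id <- paste(specs$r_res, specs$r_atom, specs$l_res, specs$l_atom)
  if (any(duplicated(pair_id)) &&
      any(tapply(specs$distance, pair_id, function(d) length(unique(d))) > 1)) {
    abort("conflicting distance constraints on the same atom pair")
  }

  base <- purrr::imap_dfr(split(specs, seq_len(nrow(specs))), function(sp, i) {
    i <- as.integer(i)
    sx <- spacing * (i - 1)
    rec <- place_residue(sp$r_res, sp$r_atom, c(sx, 0, 0), direction = -1)
    rec$chain <- "A"
    lig <- place_residue(sp$l_res, sp$l_atom, c(sx, 0, sp$distance),
                         direction = +1)
    lig$chain <- "B"
    rec$res_name <- sp$r_res
    lig$res_name <- sp$l_res
    rec$seq_num <- i
    lig$seq_num <- i
    dplyr::bind_rows(rec, lig)
  })
  base$icode <- ""
  base$occupancy <- 1

  set.seed(seed)
  models <- purrr::map_dfr(seq_len(n_models), function(m) {
    out <- base
    if (jitter_sd > 0) {
      out$x <- out$x + rnorm(nrow(out), 0, jitter_sd)
      out$y <- out$y + rnorm(nrow(out), 0, jitter_sd)
      out$z <- out$z + rnorm(nrow(out), 0, jitter_sd)
    }
    out$model <- m
    out
  })

  ens <- complex_ensemble(models, receptor_chains = "A", ligand_chains = "B",
                          source = sprintf("synthetic fixture (seed %d)", seed))
  ens <- assign_atom_classes(ens)
  if (!is.null(path)) {
    write_pdb(ens, path)
    attr(ens, "source") <- paste0(path, " [pdb, synthetic]")
  }
  ens
}

#' Generate a synthetic one-site binding dataset
#'
#' Responses follow `y = bmax * x / (kd + x)` plus Gaussian noise, floored
#' at 0 — an in-silico stand-in for an ELISA titration with replicate
#' wells.
#'
#' @param kd True dissociation constant in nanomolar (> 0).
#' @param bmax Plateau response.
#' @param concentrations Concentrations in nanomolar; default 8 log-spaced
#'   points spanning `0.01 * kd` to `100 * kd`.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param replicates Replicate wells per concentration (>= 1).
#' @param seed Integer seed.
#' @return Tibble with columns `concentration_nM`, `response`,
#'   `replicate`, ready for [fit_one_site()].
#' @export
generate_elisa_dataset <- function(kd, bmax = 1, concentrations = NULL,
                                   noise_sd = 0.05, replicates = 3,
                                   seed = 1) {
  stopifnot(kd > 0, replicates >= 1, noise_sd >= 0)
  if (is.null(concentrations)) {
    concentrations <- exp(seq(log(0.01 * kd), log(100 * kd), length.out = 8))
  }
  set.seed(seed)
  grid <- tidyr::expand_grid(concentration_nM = concentrations,
                             replicate = seq_len(replicates))
  mu <- bmax * grid$concentration_nM / (kd + grid$concentration_nM)
  grid$response <- pmax(mu + rnorm(nrow(grid), 0, noise_sd), 0)
  grid[, c("concentration_nM", "response", "replicate")]
}
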