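#' Build a complex ensemble from an atom table
#'
#' A complex ensemble is a tidy atom table (one row per heavy atom per
#' model) describing M poses of a two-partner complex, e.g. the twenty
#' end-of-trajectory snapshots a molecular-dynamics run of a nanobody/antigen
#' complex provides. Every model must carry an identical
#' (chain, seq_num, icode, res_name, atom) inventory, and the receptor and
#' ligand chain sets must be disjoint and non-empty.
#'
#' @param atoms Data frame with columns `model` (integer), `chain`,
#'   `seq_num`, `icode`, `res_name`, `atom`, `element`, `x`, `y`, `z` and
#'   optionally `occupancy`.
#' @param receptor_chains,ligand_chains Character vectors of chain
#'   identifiers assigning each chain to one binding partner.
#' @param source Optional provenance string (file path and format).
#' @return A tibble of class `complex_ensemble` with a `role` column
#'   (`"receptor"`/`"ligand"`) and attributes `receptor_chains`,
#'   `ligand_chains`, `n_models` and `source`.
#' @seealso [read_structure_ensemble()], [assign_atom_classes()]
#' @export
complex_ensemble <- function(atoms, receptor_chains, ligand_chains,
                             source = "in-memory") {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("model", "chain", "seq_num", "icode", "res_name", "atom",
              "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    abort(paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  atoms$model <- as.integer(atoms$model)
  atoms$seq_num <- as.integer(atoms$seq_num)
  atoms$icode <- ifelse(is.na(atoms$icode), "", as.character(atoms$icode))
  if (nrow(atoms) == 0L) abort("zero protein atoms in structure")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }

  receptor_chains <- as.character(receptor_chains)
  ligand_chains <- as.character(ligand_chains)
  if (length(receptor_chains) == 0L || length(ligand_chains) == 0L) {
    abort("receptor and ligand chain sets must be non-empty")
  }
  if (length(intersect(receptor_chains, ligand_chains))) {
    abort("receptor and ligand chain sets must be disjoint")
  }
  present <- unique(atoms$chain)
  for (ch in c(receptor_chains, ligand_chains)) {
    models_with <- unique(atoms$model[atoms$chain == ch])
    if (!ch %in% present || length(models_with) < length(unique(atoms$model))) {
      abort(paste0("chain '", ch, "' absent from structure (or from some models)"))
    }
  }
  atoms <- atoms[atoms$chain %in% c(receptor_chains, ligand_chains), , drop = FALSE]
  atoms$role <- ifelse(atoms$chain %in% receptor_chains, "receptor", "ligand")

  # identical atom inventory across models
  key <- paste(atoms$chain, atoms$seq_num, atoms$icode, atoms$res_name,
               atoms$atom, sep = "|")
  models <- sort(unique(atoms$model))
  ref <- sort(key[atoms$model == models[1]])
  for (m in models[-1]) {
    cur <- sort(key[atoms$model == m])
    if (length(cur) != length(ref) || any(cur != ref)) {
      bad <- c(setdiff(ref, cur), setdiff(cur, ref))[1]
      abort(paste0("atom inventory differs between models (model ", m,
                   " vs model ", models[1], "): first mismatch '", bad, "'"))
    }
  }
  atoms <- dplyr::arrange(atoms, .data$model, .data$chain, .data$seq_num,
                          .data$icode, .data$atom)
  structure(
    atoms,
    receptor_chains = receptor_chains,
    ligand_chains = ligand_chains,
    n_models = length(models),
    source = source,
    class = c("complex_ensemble", class(tibble::tibble()))
  )
}

# re-attach ensemble attributes after dplyr manipulation
rewrap_ensemble <- function(atoms, template) {
  structure(
    tibble::as_tibble(atoms),
    receptor_chains = attr(template, "receptor_chains"),
    ligand_chains = attr(template, "ligand_chains"),
    n_models = length(unique(atoms$model)),
    source = attr(template, "source"),
    class = c("complex_ensemble", class(tibble::tibble()))
  )
}

#' Number of models in an ensemble
#' @param ensemble A [complex_ensemble()].
#' @return Integer model count M.
#' @export
n_models <- function(ensemble) {
  stopifnot(inherits(ensemble, "complex_ensemble"))
  attr(ensemble, "n_models")
}

#' Chain identifiers of each binding partner
#' @param ensemble A [complex_ensemble()].
#' @return Character vector of chain ids.
#' @export
receptor_chains <- function(ensemble) attr(ensemble, "receptor_chains")

#' @rdname receptor_chains
#' @export
ligand_chains <- function(ensemble) attr(ensemble, "ligand_chains")

#' @export
print.complex_ensemble <- function(x, ...) {
  cat("# complex_ensemble: ", attr(x, "n_models"), " model(s), receptor {",
      paste(attr(x, "receptor_chains"), collapse = ","), "}, ligand {",
      paste(attr(x, "ligand_chains"), collapse = ","), "}\n", sep = "")
  cat("# source: ", attr(x, "source"), "\n", sep = "")
  NextMethod()
}

is_classified <- function(ensemble) {
  all(c("nonpolar", "donor", "acceptor", "positive", "negative") %in%
        names(ensemble))
}

require_classified <- function(ensemble) {
  if (!is_classified(ensemble)) assign_atom_classes(ensemble) else ensemble
}
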