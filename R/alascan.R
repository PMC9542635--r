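removable_atom <- function(atom) !(atom %in% c(BACKBONE_ATOMS, "CB"))

# residue inventory for one side of the ensemble (model 1 suffices:
# inventories are identical across models)
side_residues <- function(ensemble, side) {
  first <- ensemble[ensemble$model == min(ensemble$model), , drop = FALSE]
  res <- dplyr::distinct(first, .data$role, .data$chain, .data$seq_num,
                         .data$icode, .data$res_name)
  if (side != "both") res <- res[res$role == side, , drop = FALSE]
  dplyr::arrange(res, .data$role, .data$chain, .data$seq_num, .data$icode)
}

# per-model ddg for every scannable residue on one side, via the pair table:
# truncating a residue deletes exactly the cross pairs that involve its
# removable atoms, so ddg = -sum(energy over those pairs)
scan_one_model <- function(pairs, residues, side) {
  ddg_for <- function(role) {
    if (role == "receptor") {
      rem <- pairs[removable_atom(pairs$r_atom), , drop = FALSE]
      key <- residue_key(rem$r_chain, rem$r_seq, rem$r_icode)
    } else {
      rem <- pairs[removable_atom(pairs$l_atom), , drop = FALSE]
      key <- residue_key(rem$l_chain, rem$l_seq, rem$l_icode)
    }
    sums <- tapply(rem$energy, key, sum)
    res <- residues[residues$role == role, , drop = FALSE]
    rkey <- residue_key(res$chain, res$seq_num, res$icode)
    ddg <- -as.vector(sums[rkey])
    ddg[is.na(ddg)] <- 0
    res$ddg <- ddg
    res
  }
  roles <- if (side == "both") c("receptor", "ligand") else side
  out <- dplyr::bind_rows(lapply(roles, ddg_for))
  out[!(out$res_name %in% c("GLY", "ALA")), , drop = FALSE]
}

#' Alanine scan of a single pose
#'
#' For each scannable residue (anything but Gly/Ala) on the chosen side,
#' computes ΔΔG = ΔG(side chain truncated beyond CB) − ΔG(wild type) for
#' one model of the ensemble. Backbone atoms (N, CA, C, O, OXT) and CB are
#' never removed; proline is truncated like any other residue. Positive
#' ΔΔG means the residue stabilises binding.
#'
#' @param ensemble A [complex_ensemble()].
#' @param model Model index to scan (default the first).
#' @param side `"receptor"`, `"ligand"` or `"both"`.
#' @param params An [energy_params()] object.
#' @return Tibble with columns `role`, `chain`, `seq_num`, `icode`,
#'   `res_name`, `ddg` (kJ/mol); Gly/Ala are absent.
#' @export
alanine_scan_model <- function(ensemble, model = NULL,
                               side = c("receptor", "ligand", "both"),
                               params = energy_params()) {
  stopifnot(inherits(ensemble, "complex_ensemble"))
  side <- match.arg(side)
  ensemble <- require_classified(ensemble)
  if (is.null(model)) model <- min(ensemble$model)
  if (!model %in% ensemble$model) abort(paste0("no model ", model))
  pairs <- cross_pair_table(ensemble[ensemble$model == model, , drop = FALSE],
                            params)
  residues <- side_residues(ensemble, side)
  scan_one_model(pairs, residues, side)
}

#' Ensemble-averaged alanine scan
#'
#' Runs [alanine_scan_model()] on every pose and aggregates per residue:
#' `ddg_mean` is the arithmetic mean over models (the ensemble ΔΔG),
#' `ddg_sd` the sample standard deviation (0 when M = 1), and
#' `ddg_weighted` applies the DERKH polar down-weight `w_polar` from
#' `params` to Asp/Glu/Arg/Lys/His. Residues are ranked 1..n by descending
#' `ddg_weighted`, ties broken by (chain, seq_num, icode); Gly/Ala entries
#' are reported with ΔΔG 0 and `rank = NA`.
#'
#' @inheritParams alanine_scan_model
#' @return Tibble of class `alanine_scan` with columns `role`, `chain`,
#'   `seq_num`, `icode`, `res_name`, `ddg_per_model` (list column),
#'   `ddg_mean`, `ddg_sd`, `ddg_weighted`, `rank`, `n_models`.
#' @examples
#' ens <- generate_complex_ensemble(fixture_preset("charge-hbond-np"),
#'                                  n_models = 5, jitter_sd = 0.1, seed = 7)
#' alanine_scan(ens, side = "receptor")
#' @export
alanine_scan <- function(ensemble, side = c("receptor", "ligand", "both"),
                         params = energy_params()) {
  stopifnot(inherits(ensemble, "complex_ensemble"))
  side <- match.arg(side)
  ensemble <- require_classified(ensemble)
  models <- sort(unique(ensemble$model))
  residues <- side_residues(ensemble, side)

  per_model <- lapply(models, function(m) {
    pairs <- cross_pair_table(ensemble[ensemble$model == m, , drop = FALSE],
                              params)
    out <- scan_one_model(pairs, residues, side)
    out$model <- m
    out
  })
  long <- dplyr::bind_rows(per_model)

  scanned <- long |>
    dplyr::group_by(.data$role, .data$chain, .data$seq_num, .data$icode,
                    .data$res_name) |>
    dplyr::summarise(
      ddg_per_model = list(.data$ddg[order(.data$model)]),
      ddg_mean = mean(.data$ddg),
      ddg_sd = if (dplyr::n() > 1) sd(.data$ddg) else 0,
      .groups = "drop"
    )
  polar <- c("ASP", "GLU", "ARG", "LYS", "HIS")
  scanned$ddg_weighted <- scanned$ddg_mean *
    ifelse(scanned$res_name %in% polar, params$w_polar, 1)
  scanned <- scanned |>
    dplyr::arrange(dplyr::desc(.data$ddg_weighted), .data$chain,
                   .data$seq_num, .data$icode)
  scanned$rank <- seq_len(nrow(scanned))

  glyala <- residues[residues$res_name %in% c("GLY", "ALA"), , drop = FALSE]
  if (nrow(glyala)) {
    glyala$ddg_per_model <- rep(list(rep(0, length(models))), nrow(glyala))
    glyala$ddg_mean <- 0
    glyala$ddg_sd <- 0
    glyala$ddg_weighted <- 0
    glyala$rank <- NA_integer_
    scanned <- dplyr::bind_rows(scanned, glyala)
  }
  scanned$n_models <- length(models)
  structure(scanned, class = c("alanine_scan", class(tibble::tibble())),
            params = params, side = side)
}

#' Lollipop plot of ensemble alanine-scan ΔΔG values
#'
#' @param scan Result of [alanine_scan()].
#' @param top_n Show only the `top_n` ranked residues (default all ranked).
#' @return A ggplot object: residues on the x axis, weighted ensemble ΔΔG
#'   with ±1 SD error bars on the y axis.
#' @export
plot_alanine_scan <- function(scan, top_n = Inf) {
  stopifnot(inherits(scan, "alanine_scan"))
  df <- scan[!is.na(scan$rank) & scan$rank <= top_n, , drop = FALSE]
  df$label <- paste0(df$chain, ":", substr(df$res_name, 1, 3), df$seq_num,
                     df$icode)
  df$label <- factor(df$label, levels = df$label[order(df$rank)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$ddg_weighted)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$label, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ddg_weighted - .data$ddg_sd,
                   ymax = .data$ddg_weighted + .data$ddg_sd),
      width = 0.2, colour = "grey40"
    ) +
    ggplot2::labs(x = NULL, y = "weighted ensemble ΔΔG (kJ/mol)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.alanine_scan <- function(object, ...) plot_alanine_scan(object, ...)
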