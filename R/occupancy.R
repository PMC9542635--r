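#' Convert between affinity fold-change and ΔΔG
#'
#' The thermodynamic bridge `ΔΔG = RT ln(fold)` linking a Kd fold-change
#' relative to wild type (e.g. the 420-fold weakening of a caged tyrosine,
#' or a mutant/wild-type Kd ratio) to a binding free-energy difference in
#' kJ/mol, and its inverse. The round trip is an identity to 1e-12
#' relative.
#'
#' @param x Fold-change(s) (> 0) or ΔΔG value(s) in kJ/mol, per `direction`.
#' @param direction `"fold_to_ddg"` or `"ddg_to_fold"`.
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Numeric vector: ΔΔG in kJ/mol, or a dimensionless fold-change.
#' @examples
#' fold_change_ddg(420, "fold_to_ddg") # ~14.97 kJ/mol
#' fold_change_ddg(fold_change_ddg(726.4, "fold_to_ddg"), "ddg_to_fold")
#' @export
fold_change_ddg <- function(x, direction = c("fold_to_ddg", "ddg_to_fold"),
                            temperature = 298.15) {
  direction <- match.arg(direction)
  if (!is.numeric(x) || anyNA(x)) abort("input must be numeric and non-missing")
  rt <- rt_kj(temperature)
  if (direction == "fold_to_ddg") {
    if (any(x <= 0)) abort("fold-change must be positive")
    rt * log(x)
  } else {
    exp(x / rt)
  }
}

#' Equilibrium complex concentration of two species
#'
#' Single-compartment mass-action equilibrium `A + B <-> C` with
#' dissociation constant Kd: the exact root
#' `C = ((A + B + Kd) - sqrt((A + B + Kd)^2 - 4AB)) / 2`,
#' computed in the numerically stable form `2AB / (s + sqrt(s^2 - 4AB))`.
#' `kd = 0` is allowed as the stoichiometric limit `C = min(A, B)`.
#'
#' @param a_total,b_total Total species concentrations (same unit as `kd`).
#' @param kd Dissociation constant.
#' @return Complex concentration, `0 <= C <= min(A, B)`, vectorised.
#' @examples
#' complex_concentration(1, 1, 1) # (3 - sqrt(5))/2
#' @export
complex_concentration <- function(a_total, b_total, kd) {
  if (any(a_total < 0) || any(b_total < 0) || any(kd < 0)) {
    abort("concentrations and kd must be non-negative")
  }
  s <- a_total + b_total + kd
  disc <- pmax(0, s^2 - 4 * a_total * b_total)
  denom <- s + sqrt(disc)
  ifelse(denom == 0, 0, 2 * a_total * b_total / denom)
}

#' Describe the intracellular scenario for the localisation read-out
#'
#' Parameters of the single-cell equilibrium model behind the
#' nuclear/cytoplasmic (N/C) ratio prediction: a freely diffusing binder
#' (e.g. a nanobody::mCherry fusion, small enough to cross the nuclear
#' membrane) and an antigen anchored in the nucleus (e.g. GFP::NLS).
#'
#' @param nb_total Total binder concentration averaged over the whole cell
#'   (micromolar).
#' @param antigen_nuclear Antigen concentration within the nucleus
#'   (micromolar).
#' @param phi_nuc Nuclear volume fraction of the cell, in (0, 1).
#' @param background Non-negative signal offset added to both compartments
#'   before forming the ratio (caps the predicted N/C; default 0).
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(nb_total, antigen_nuclear, phi_nuc,
                       background = 0) {
  stopifnot(nb_total >= 0, antigen_nuclear >= 0, background >= 0,
            phi_nuc > 0, phi_nuc < 1)
  structure(list(nb_total = nb_total, antigen_nuclear = antigen_nuclear,
                 phi_nuc = phi_nuc, background = background),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(paste0("cell model: binder %g uM (whole cell), antigen %g uM",
                     " (nuclear), phi_nuc %g, background %g\n"),
              x$nb_total, x$antigen_nuclear, x$phi_nuc, x$background))
  invisible(x)
}

#' Predict the nuclear/cytoplasmic ratio of a freely diffusing binder
#'
#' Solves the equilibrium in which free binder equilibrates across the
#' nuclear membrane while the antigen is immobilised in the nucleus:
#' `nb_total = x + phi_nuc * antigen_nuclear * x / (kd + x)` for the free
#' binder concentration `x >= 0` (closed-form quadratic with a bisection
#' fallback, relative tolerance 1e-10). Nuclear signal is free plus bound
#' binder, cytoplasmic signal free binder only, so with background `b`:
#' `N/C = (x + complex + b) / (x + b)`. Strong binders give high N/C;
#' as Kd grows or antigen vanishes the ratio tends to 1, the free-diffusion
#' signature of a non-binder.
#'
#' @param cell A [cell_model()].
#' @param kd Dissociation constant in micromolar (> 0), vectorised.
#' @return Tibble with columns `kd`, `nb_free`, `complex_nuclear`,
#'   `occupancy` (bound antigen fraction) and `nc_ratio`.
#' @examples
#' predict_nc_ratio(cell_model(1, 10, 0.2), kd = 0.5)
#' @export
predict_nc_ratio <- function(cell, kd) {
  stopifnot(inherits(cell, "cell_model"))
  if (any(kd <= 0)) abort("kd must be positive")
  if (cell$nb_total == 0) abort("nb_total = 0: N/C ratio undefined")
  nb <- cell$nb_total
  ag <- cell$antigen_nuclear
  phi <- cell$phi_nuc

  # x^2 + (kd + phi*ag - nb) x - kd*nb = 0, positive root (stable form)
  b <- kd + phi * ag - nb
  x <- (-b + sqrt(b^2 + 4 * kd * nb)) / 2
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    x[bad] <- vapply(kd[bad], function(k) {
      f <- function(v) v + phi * ag * v / (k + v) - nb
      lo <- 0
      hi <- nb
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) hi <- mid else lo <- mid
        if ((hi - lo) <= 1e-10 * max(nb, 1)) break
      }
      (lo + hi) / 2
    }, numeric(1))
  }
  cmplx <- ag * x / (kd + x)
  tibble::tibble(
    kd = kd,
    nb_free = x,
    complex_nuclear = cmplx,
    occupancy = if (ag > 0) cmplx / ag else 0,
    nc_ratio = (x + cmplx + cell$background) / (x + cell$background)
  )
}
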