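#' Thermal energy RT in kJ/mol
#'
#' @param temperature Temperature in kelvin (default 298.15 K).
#' @return RT in kJ/mol (R = 0.008314 kJ/mol/K).
#' @examples
#' rt_kj() # ~2.479
#' @export
rt_kj <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  GAS_CONSTANT_KJ * temperature
}

#' Parse a concentration string with a unit suffix
#'
#' Accepts numbers suffixed with `nM`, `uM`/`µM`/`μM` or `mM` (case
#' insensitive); bare numbers are taken as micromolar. All values are
#' normalised to micromolar, the working unit of the occupancy model.
#'
#' @param x Character vector such as `"0.76nM"`, `"1uM"`, `"2 mM"`.
#' @return Numeric vector of concentrations in micromolar.
#' @examples
#' parse_concentration(c("0.76nM", "1uM", "2mM"))
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) {
    return(as.double(x))
  }
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*([a-zA-Zµμ]*)$", x))
  out <- vapply(seq_along(x), function(i) {
    parts <- m[[i]]
    if (length(parts) != 3L || parts[1] == "") {
      abort(paste0("cannot parse concentration: '", x[i], "'"))
    }
    val <- as.double(parts[2])
    unit <- tolower(chartr("µμ", "uu", parts[3]))
    if (unit == "") unit <- "um"
    scale <- switch(unit,
      "nm" = 1e-3,
      "um" = 1,
      "mm" = 1e3,
      abort(paste0("unknown concentration unit: '", parts[3], "'"))
    )
    val * scale
  }, numeric(1))
  out
}

# residue identifier string "chain:seq" or "chain:seq:icode"
residue_key <- function(chain, seq_num, icode = "") {
  if (length(chain) == 0L) return(character(0))
  icode <- ifelse(is.na(icode) | icode == "", "", icode)
  paste0(chain, ":", seq_num, ifelse(icode == "", "", paste0(":", icode)))
}

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
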