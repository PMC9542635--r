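#' Nuclear/cytoplasmic intensity ratios from an image and label masks
#'
#' Implements the localisation read-out of the intracellular binding
#' assay: for each cell, the background-subtracted mean intensity over its
#' nucleus divided by that over its cytoplasm (cell minus nucleus). A
#' freely diffusing non-binder gives N/C near 1; binding to a
#' nuclear-anchored antigen raises it.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param nucleus_mask,cell_mask Integer label matrices of the same shape;
#'   0 is background. Every nucleus label must lie within exactly one cell
#'   label.
#' @param background Either a numeric value, `"outside-cells-median"`
#'   (median intensity outside all cells, the default) or `"mode"` (most
#'   frequent rounded intensity). Subtracted and floored at 0 before
#'   averaging.
#' @return Tibble with one row per cell: `cell`, `nuc_mean`, `cyto_mean`,
#'   `nc_ratio`, `n_pixels_nuc`, `n_pixels_cyto`.
#' @examples
#' syn <- generate_synthetic_cell(true_nc = 2.59, seed = 1)
#' compute_nc_ratio(syn$image, syn$nucleus_mask, syn$cell_mask)
#' @export
compute_nc_ratio <- function(image, nucleus_mask, cell_mask,
                             background = "outside-cells-median") {
  stopifnot(is.matrix(image), is.matrix(nucleus_mask), is.matrix(cell_mask))
  if (!all(dim(image) == dim(nucleus_mask)) ||
      !all(dim(image) == dim(cell_mask))) {
    abort("image and masks must share the same shape")
  }
  cells <- sort(unique(cell_mask[cell_mask > 0]))
  if (length(cells) == 0L) abort("cell mask contains no labels")

  # every nucleus label must sit inside exactly one cell
  for (nl in sort(unique(nucleus_mask[nucleus_mask > 0]))) {
    under <- unique(cell_mask[nucleus_mask == nl])
    if (length(under) != 1L || under == 0) {
      abort(paste0("nucleus label ", nl,
                   " does not lie within exactly one cell"))
    }
  }

  bg <- if (is.numeric(background)) {
    background
  } else if (identical(background, "outside-cells-median")) {
    outside <- image[cell_mask == 0]
    if (length(outside) == 0L) abort("no pixels outside cells for background")
    median(outside)
  } else if (identical(background, "mode")) {
    tab <- table(round(as.vector(image)))
    as.double(names(tab)[which.max(tab)])
  } else {
    abort("background must be a number, 'outside-cells-median' or 'mode'")
  }
  corrected <- pmax(image - bg, 0)

  purrr::map_dfr(cells, function(cl) {
    in_cell <- cell_mask == cl
    in_nuc <- in_cell & nucleus_mask > 0
    in_cyto <- in_cell & nucleus_mask == 0
    if (!any(in_nuc)) abort(paste0("cell ", cl, " has no nucleus pixels"))
    if (!any(in_cyto)) abort(paste0("cell ", cl, ": empty cytoplasm"))
    nuc_mean <- mean(corrected[in_nuc])
    cyto_mean <- mean(corrected[in_cyto])
    tibble::tibble(
      cell = cl, nuc_mean = nuc_mean, cyto_mean = cyto_mean,
      nc_ratio = nuc_mean / cyto_mean,
      n_pixels_nuc = sum(in_nuc), n_pixels_cyto = sum(in_cyto)
    )
  })
}

#' Generate a synthetic cell image with a known N/C ratio
#'
#' Builds a concentric-disc cell: cytoplasm at `base_intensity`, nucleus
#' at `base_intensity * true_nc`, plus a constant background and optional
#' noise. The closed loop with [compute_nc_ratio()] recovers `true_nc`
#' exactly at zero noise.
#'
#' @param true_nc True nuclear/cytoplasmic ratio (>= 1).
#' @param nuc_radius,cell_radius Disc radii in pixels
#'   (`nuc_radius < cell_radius`).
#' @param base_intensity Cytoplasmic intensity above background.
#' @param background Constant offset added everywhere.
#' @param noise `"none"`, `"gaussian"` (sd `noise_sd`) or `"poisson"`
#'   (each pixel Poisson with its noiseless value as mean).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional integer for reproducibility.
#' @return List with `image`, `nucleus_mask`, `cell_mask` (matrices).
#' @export
generate_synthetic_cell <- function(true_nc, nuc_radius = 12,
                                    cell_radius = 25, base_intensity = 100,
                                    background = 10,
                                    noise = c("none", "gaussian", "poisson"),
                                    noise_sd = 5, seed = NULL) {
  noise <- match.arg(noise)
  if (nuc_radius >= cell_radius) abort("nuc_radius must be < cell_radius")
  if (true_nc < 1) abort("true_nc must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  n <- 2L * ceiling(cell_radius) + 5L
  ctr <- (n + 1) / 2
  dist <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  cell_mask <- matrix(0L, n, n)
  cell_mask[dist <= cell_radius] <- 1L
  nucleus_mask <- matrix(0L, n, n)
  nucleus_mask[dist <= nuc_radius] <- 1L

  image <- matrix(background, n, n)
  image[cell_mask == 1L] <- background + base_intensity
  image[nucleus_mask == 1L] <- background + base_intensity * true_nc
  image <- switch(noise,
    none = image,
    gaussian = image + matrix(rnorm(n * n, 0, noise_sd), n, n),
    poisson = matrix(as.double(rpois(n * n, lambda = pmax(image, 0))), n, n)
  )
  image <- pmax(image, 0)
  list(image = image, nucleus_mask = nucleus_mask, cell_mask = cell_mask)
}
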