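#' Fit a one-site specific binding curve
#'
#' Least-squares fit of the saturation model `y = Bmax * x / (Kd + x)` to
#' concentration/response data (the standard "one site - specific binding"
#' analysis applied to ELISA titrations). Replicates are fitted jointly
#' with equal weights. Starting values are `Bmax0 = max(y)` and `Kd0` the
#' concentration at half-maximal mean response (linear interpolation);
#' optimisation uses `stats::nls` (port algorithm, parameter tolerance
#' 1e-10, up to 1e4 iterations, both parameters bounded below by 0).
#'
#' @param data Data frame with one row per well.
#' @param concentration,response Column names (default `concentration_nM`
#'   and `response`).
#' @return An object of class `one_site_fit` with elements `kd`, `bmax`,
#'   `se_kd`, `se_bmax`, `r_squared`, `n`, the `nls` fit and the data.
#'   Use [tidy()], [glance()], [augment()] and [autoplot()] on it.
#' @examples
#' dat <- generate_elisa_dataset(kd = 106.1, noise_sd = 0, seed = 1)
#' glance(fit_one_site(dat))
#' @export
fit_one_site <- function(data, concentration = "concentration_nM",
                         response = "response") {
  stopifnot(is.data.frame(data))
  if (!all(c(concentration, response) %in% names(data))) {
    abort("data must contain the concentration and response columns")
  }
  x <- as.double(data[[concentration]])
  y <- as.double(data[[response]])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (any(x < 0)) abort("concentrations must be non-negative")
  if (length(unique(x)) < 4) abort("need at least 4 distinct concentrations")
  if (!any(y > 0)) abort("Kd unidentifiable: no positive response")
  if (diff(range(y)) == 0) abort("Kd unidentifiable: all responses equal")

  means <- tapply(y, x, mean)
  xs <- as.double(names(means))
  ord <- order(xs)
  xs <- xs[ord]
  means <- as.double(means)[ord]
  bmax0 <- max(y)
  half <- max(means) / 2
  above <- which(means >= half)
  kd0 <- if (length(above) == 0 || above[1] == 1) {
    max(xs[1], median(xs))
  } else {
    i <- above[1]
    xs[i - 1] + (half - means[i - 1]) / (means[i] - means[i - 1]) *
      (xs[i] - xs[i - 1])
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(xs[xs > 0])

  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    nls(y ~ bmax * x / (kd + x), data = df,
        start = list(bmax = bmax0, kd = kd0),
        algorithm = "port", lower = c(bmax = 0, kd = 1e-12),
        control = stats::nls.control(maxiter = 1e4, tol = 1e-10,
                                     warnOnly = FALSE)),
    error = function(e) {
      abort(paste0("one-site fit did not converge (start bmax=",
                   signif(bmax0, 4), ", kd=", signif(kd0, 4), "): ",
                   conditionMessage(e)))
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bmax = NA_real_, kd = NA_real_))
  ss_res <- sum(residuals_nls(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(kd = unname(est["kd"]), bmax = unname(est["bmax"]),
         se_kd = unname(se["kd"]), se_bmax = unname(se["bmax"]),
         r_squared = 1 - ss_res / ss_tot, n = length(y),
         fit = fit, data = tibble::tibble(concentration = x, response = y)),
    class = "one_site_fit"
  )
}

residuals_nls <- function(fit) as.double(stats::residuals(fit))

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("one-site specific binding: Kd = %.4g +/- %.2g, Bmax = %.4g, R^2 = %.4f (n = %d)\n",
              x$kd, x$se_kd, x$bmax, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_one_site
#' @param x,object A `one_site_fit`.
#' @param ... Unused.
#' @export
tidy.one_site_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bmax", "kd"),
    estimate = c(x$bmax, x$kd),
    std.error = c(x$se_bmax, x$se_kd)
  )
}

#' @rdname fit_one_site
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, bmax = x$bmax, se_kd = x$se_kd,
                 r.squared = x$r_squared, nobs = x$n)
}

#' @rdname fit_one_site
#' @export
augment.one_site_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- x$bmax * out$concentration / (x$kd + out$concentration)
  out$.resid <- out$response - out$.fitted
  out
}

#' @rdname fit_one_site
#' @export
autoplot.one_site_fit <- function(object, ...) {
  dat <- object$data
  pos <- dat$concentration[dat$concentration > 0]
  grid <- tibble::tibble(
    concentration = exp(seq(log(min(pos)), log(max(pos)), length.out = 200))
  )
  grid$response <- object$bmax * grid$concentration /
    (object$kd + grid$concentration)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration,
                                    y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$kd, linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_x_log10("concentration (nM)") +
    ggplot2::labs(y = "response",
                  subtitle = sprintf("Kd = %.4g nM, Bmax = %.3g, R2 = %.4f",
                                     object$kd, object$bmax,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}
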