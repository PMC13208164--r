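# Quantitation: cross-sections and molar attenuation coefficients from
# absorbances, additive combination of single-species spectra, and
# Beer-Lambert calibration regressions with uncertainty transfer.

LN10 <- log(10)

#' Convert between molar attenuation coefficient and cross-section
#'
#' `sigma = ln(10) * epsilon / N_A` (dm^2 per molecule) and its inverse
#' `epsilon = N_A * sigma / ln(10)` (dm^2 mol^-1).
#'
#' @param epsilon Molar attenuation coefficient, dm^2 mol^-1.
#' @param sigma Attenuation cross-section, dm^2.
#' @return The converted quantity.
#' @export
sigma_from_epsilon <- function(epsilon) LN10 * epsilon / AVOGADRO

#' @rdname sigma_from_epsilon
#' @export
epsilon_from_sigma <- function(sigma) AVOGADRO * sigma / LN10

#' Cross-section from a single-species relative absorbance
#'
#' `sigma = -log(1 - r) / (beta * N_A * c)`. Bins with `r >= 1` are
#' saturated (the optical depth diverges) and reported missing, as are
#' bins with `r < 0` (noise overshoot below zero absorbance).
#'
#' @param r Relative absorbance, dimensionless.
#' @param conc Species concentration, mol dm^-3 (> 0).
#' @param beta Path length, dm.
#' @return Cross-section(s), dm^2; `NA` where undefined.
#' @export
#' @examples
#' # the 500 nm nitroprusside coefficient, round-tripped through r
#' r <- 1 - 10^(-0.621)
#' epsilon_from_sigma(cross_section_from_absorbance(r, conc = 0.1, beta = 0.1))
cross_section_from_absorbance <- function(r, conc, beta = 0.1) {
  if (any(conc <= 0)) abort("`conc` must be > 0.")
  if (beta <= 0) abort("`beta` must be > 0.")
  ok <- is.finite(r) & r >= 0 & r < 1
  out <- rep(NA_real_, length(r))
  out[ok] <- -log(1 - r[ok]) / (beta * AVOGADRO * conc)
  out
}

#' @rdname cross_section_from_absorbance
#' @export
epsilon_from_absorbance <- function(r, conc, beta = 0.1) {
  epsilon_from_sigma(cross_section_from_absorbance(r, conc, beta))
}

#' Predict the spectrum of a mixture from single-species curves
#'
#' Optical depths add: `tau(lambda) = sum_i sigma_i(lambda) n_i beta`
#' (equivalently `ln(10) * sum_i eps_i c_i beta`), and the combined
#' relative absorbance is `r = 1 - exp(-tau)`. If the curves carry
#' `epsilon_err`, the combined error is propagated on the premise that the
#' total cross-section is the linear sum of the constituent cross-sections.
#'
#' @param curves Long tibble of attenuation curves (`wavelength`,
#'   `epsilon`, optional `epsilon_err`, `species`) on a common grid.
#' @param concentrations Named numeric vector, mol dm^-3, one entry per
#'   species to include.
#' @param path_length Path length, dm.
#' @return A tibble with columns `wavelength`, `tau`, `r` and, when errors
#'   are available, `r_err`.
#' @export
#' @examples
#' curves <- default_lake_curves(grid = 300:600)
#' combine_spectra(curves, c(ferrocyanide = 0.1, nitroprusside = 0.01))
combine_spectra <- function(curves, concentrations, path_length = 0.1) {
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  if (path_length <= 0) abort("`path_length` must be > 0.")
  species <- names(concentrations)
  grid <- NULL
  tau <- NULL
  tau_err <- NULL
  for (sp in species) {
    cur <- curves[curves$species == sp, , drop = FALSE]
    if (nrow(cur) == 0) abort(sprintf("No attenuation curve for species '%s'.", sp))
    if (is.null(grid)) {
      grid <- cur$wavelength
      tau <- rep(0, length(grid))
      tau_err <- rep(0, length(grid))
    } else if (length(cur$wavelength) != length(grid) ||
               any(abs(cur$wavelength - grid) > 1e-9)) {
      abort("Curves are not on a common grid.")
    }
    tau <- tau + LN10 * cur$epsilon * concentrations[[sp]] * path_length
    if ("epsilon_err" %in% names(cur)) {
      tau_err <- tau_err + LN10 * abs(cur$epsilon_err) *
        concentrations[[sp]] * path_length
    }
  }
  out <- tibble(wavelength = grid, tau = tau, r = 1 - exp(-tau))
  if (any(tau_err > 0)) out$r_err <- exp(-tau) * tau_err
  out
}

#' Beer-Lambert calibration fit at one wavelength
#'
#' Ordinary least squares of `log(1 - r)` against concentration. The
#' gradient `m` relates to the cross-section via `m = -beta * N_A * sigma`,
#' so the molar attenuation coefficient is `epsilon = -m / (beta * ln 10)`
#' with fractional error transfer
#' `d(epsilon) = epsilon * d(m) / m`. Points with `r >= 1` or `r < 0` are
#' unusable in the log domain and dropped before fitting. A free intercept
#' is included by default (baseline offsets are real even though the law
#' predicts none); set `intercept = FALSE` to force the line through the
#' origin.
#'
#' @param points A tibble with columns `conc` (mol dm^-3) and `r`.
#' @param beta Path length, dm.
#' @param intercept Include a free intercept?
#' @return An object of class `beer_fit`; see [tidy.beer_fit()] and
#'   [glance.beer_fit()].
#' @export
#' @examples
#' conc <- c(0.02, 0.05, 0.1)
#' r <- 1 - 10^(-62.1 * conc * 0.1)
#' glance(fit_epsilon_at_wavelength(tibble::tibble(conc = conc, r = r)))
fit_epsilon_at_wavelength <- function(points, beta = 0.1, intercept = TRUE) {
  if (beta <= 0) abort("`beta` must be > 0.")
  usable <- is.finite(points$r) & points$r >= 0 & points$r < 1 &
    is.finite(points$conc)
  pts <- points[usable, , drop = FALSE]
  if (length(unique(pts$conc)) < 3) {
    abort(sprintf(
      "Need >= 3 usable points with distinct concentrations; have %d.",
      length(unique(pts$conc))
    ))
  }
  pts$y <- log(1 - pts$r)
  fit <- if (intercept) lm(y ~ conc, data = pts) else lm(y ~ conc - 1, data = pts)
  sm <- summary(fit)
  m <- coef(fit)[["conc"]]
  dm <- sm$coefficients["conc", "Std. Error"]
  epsilon <- -m / (beta * LN10)
  structure(
    list(
      fit = fit,
      slope = m,
      slope_err = dm,
      epsilon = epsilon,
      epsilon_err = if (m != 0) abs(epsilon * dm / m) else NA_real_,
      r_squared = sm$r.squared,
      n_points = nrow(pts),
      beta = beta,
      intercept = intercept,
      # A positive gradient means absorbance falling with concentration:
      # non-physical for a Beer-Lambert system, so the fit is flagged.
      flagged = m > 0
    ),
    class = "beer_fit"
  )
}

#' @export
print.beer_fit <- function(x, ...) {
  cat(sprintf(
    "Beer-Lambert fit: epsilon = %.4g +/- %.2g dm^2 mol^-1 (R^2 = %.4f, n = %d)%s\n",
    x$epsilon, x$epsilon_err, x$r_squared, x$n_points,
    if (x$flagged) " [flagged: positive gradient]" else ""
  ))
  invisible(x)
}

#' Tidiers for Beer-Lambert calibration fits
#'
#' `tidy()` returns the regression coefficients; `glance()` returns a
#' one-row summary with the derived molar attenuation coefficient and its
#' uncertainty.
#'
#' @param x A `beer_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy beer_fit
#' @export
tidy.beer_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.beer_fit
#' @method glance beer_fit
#' @export
glance.beer_fit <- function(x, ...) {
  tibble(
    epsilon = x$epsilon,
    epsilon_err = x$epsilon_err,
    slope = x$slope,
    slope_err = x$slope_err,
    r.squared = x$r_squared,
    n = x$n_points,
    flagged = x$flagged
  )
}

#' Per-wavelength calibration curve from a ladder of standards
#'
#' Applies the Beer-Lambert regression of [fit_epsilon_at_wavelength()]
#' independently at every wavelength bin of a set of standards measured at
#' known concentrations. Only bins retained in a standard contribute to
#' that standard's points; bins with fewer than three usable points are
#' left undefined.
#'
#' @param standards Long tibble with columns `wavelength`, `r`, `conc` and
#'   optionally `retained`; one block per standard concentration.
#' @param beta Path length, dm.
#' @param intercept Include a free intercept in each per-bin fit?
#' @return A tibble with columns `wavelength`, `epsilon`, `epsilon_err`,
#'   `r_squared`, `n`; `NA` rows where a bin had too few usable points.
#' @export
epsilon_curve_from_standards <- function(standards, beta = 0.1,
                                         intercept = TRUE) {
  if (beta <= 0) abort("`beta` must be > 0.")
  if (!"retained" %in% names(standards)) standards$retained <- TRUE
  if (length(unique(standards$conc)) < 3) {
    abort("Need standards at >= 3 distinct concentrations.")
  }
  wide <- tidyr::pivot_wider(
    standards[c("wavelength", "conc", "r", "retained")],
    names_from = "conc", values_from = c("r", "retained")
  )
  concs <- sort(unique(standards$conc))
  rmat <- as.matrix(wide[paste0("r_", concs)])
  kmat <- as.matrix(wide[paste0("retained_", concs)])
  kmat[is.na(kmat)] <- FALSE
  valid <- kmat & is.finite(rmat) & rmat >= 0 & rmat < 1
  y <- log(1 - rmat)
  y[!valid] <- 0
  cmat <- matrix(concs, nrow = nrow(rmat), ncol = length(concs), byrow = TRUE)
  cmat[!valid] <- 0
  n <- rowSums(valid)
  sx <- rowSums(cmat)
  sy <- rowSums(y)
  sxx <- rowSums(cmat^2)
  sxy <- rowSums(cmat * y)
  syy <- rowSums(y^2)
  if (intercept) {
    den <- n * sxx - sx^2
    slope <- (n * sxy - sx * sy) / den
    icept <- (sy - slope * sx) / n
    rss <- syy - icept * sy - slope * sxy
    tss <- syy - sy^2 / n
    dof <- n - 2
    se <- sqrt(pmax(rss, 0) / pmax(dof, 1) * n / pmax(den, .Machine$double.eps))
  } else {
    slope <- sxy / sxx
    rss <- syy - slope * sxy
    tss <- syy
    dof <- n - 1
    se <- sqrt(pmax(rss, 0) / pmax(dof, 1) / sxx)
  }
  min_pts <- if (intercept) 3 else 3
  bad <- n < min_pts | dof < 1
  slope[bad] <- NA_real_
  se[bad] <- NA_real_
  epsilon <- -slope / (beta * LN10)
  epsilon_err <- abs(epsilon * se / slope)
  r_squared <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  r_squared[bad] <- NA_real_
  tibble(
    wavelength = wide$wavelength,
    epsilon = epsilon,
    epsilon_err = epsilon_err,
    r_squared = r_squared,
    n = as.integer(n)
  ) |> dplyr::arrange(.data$wavelength)
}

#' Report fitted coefficients at selected peak wavelengths
#'
#' @param curve A fitted curve from [epsilon_curve_from_standards()].
#' @param wavelengths Peak positions to report, nm.
#' @return The matching rows of `curve`.
#' @export
peak_epsilon <- function(curve, wavelengths = c(340, 400, 500)) {
  dplyr::filter(curve, .data$wavelength %in% wavelengths)
}

#' Write / read a fitted attenuation curve
#'
#' Tab-delimited wavelength, epsilon, epsilon_err (plus fit diagnostics).
#'
#' @param curve Curve tibble.
#' @param path File path.
#' @export
write_epsilon_curve <- function(curve, path) {
  readr::write_tsv(curve, path)
  invisible(path)
}
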