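# ggplot2 views of the main result types.

#' Plot an absorbance spectrum
#'
#' Retained bins as a line, with a shaded ribbon where replicate errors
#' are available; masked bins are omitted.
#'
#' @param absorbance An absorbance tibble (`wavelength`, `r`, optionally
#'   `r_err`, `retained`).
#' @return A ggplot object.
#' @export
plot_absorbance <- function(absorbance) {
  if ("retained" %in% names(absorbance)) {
    absorbance <- absorbance[absorbance$retained, , drop = FALSE]
  }
  p <- ggplot2::ggplot(absorbance, ggplot2::aes(x = .data$wavelength, y = .data$r))
  if ("r_err" %in% names(absorbance)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$r - .data$r_err, ymax = .data$r + .data$r_err),
      alpha = 0.25
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "relative absorbance r") +
    ggplot2::theme_minimal()
}

#' Plot attenuation curves
#'
#' @param curves Long curve tibble (`wavelength`, `epsilon`, optionally
#'   `species`).
#' @return A ggplot object.
#' @export
plot_epsilon <- function(curves) {
  aes <- if ("species" %in% names(curves)) {
    ggplot2::aes(x = .data$wavelength, y = .data$epsilon, colour = .data$species)
  } else {
    ggplot2::aes(x = .data$wavelength, y = .data$epsilon)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wavelength (nm)",
      y = expression(epsilon ~ (dm^2 ~ mol^-1))
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot beer_fit
#' @export
autoplot.beer_fit <- function(object, ...) {
  dat <- object$fit$model
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$conc, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(
      method = "lm", se = FALSE,
      formula = if (object$intercept) y ~ x else y ~ x - 1
    ) +
    ggplot2::labs(
      x = expression(concentration ~ (mol ~ dm^-3)),
      y = "ln(1 - r)"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot lake_simulation
#' @export
autoplot.lake_simulation <- function(object, species = c("A", "B"), ...) {
  species <- match.arg(species)
  traj <- object$trajectory
  ggplot2::ggplot(
    traj,
    ggplot2::aes(x = .data$time, y = .data$depth, fill = .data[[species]])
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "grey90") +
    ggplot2::labs(
      x = "time (days)", y = "depth (m)",
      fill = if (species == "A") "[ferrocyanide] (M)" else "[nitroprusside] (M)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot survival time against depth with the fitted shadow slope
#'
#' @param sim A `lake_simulation`.
#' @param fit Optional `shadow_fit`; fitted from `sim` when omitted.
#' @return A ggplot object.
#' @export
plot_survival <- function(sim, fit = NULL) {
  sv <- sim$survival[!sim$survival$censored, , drop = FALSE]
  p <- ggplot2::ggplot(sv, ggplot2::aes(x = .data$depth, y = .data$time)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "depth (m)", y = "survival time (days)") +
    ggplot2::theme_minimal()
  if (is.null(fit) && nrow(sv) >= 3) fit <- shadow_slope(sim)
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      intercept = fit$intercept, slope = fit$slope,
      linetype = "dashed", colour = "red"
    )
  }
  p
}
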