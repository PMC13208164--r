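# Reduction of raw count triplets to relative absorbance: background
# subtraction against the blank-cuvette reference, signal-to-noise masking,
# and replicate statistics.

#' Read a two-column count spectrum
#'
#' Reads the tab- or whitespace-delimited two-column text format written by
#' [write_spectrum()]: wavelength (nm) and detector counts.
#'
#' @param path File path.
#' @return A tibble with columns `wavelength`, `counts`.
#' @export
read_count_spectrum <- function(path) {
  if (!file.exists(path)) abort(sprintf("Spectrum file not found: '%s'.", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tbl) < 2) abort(sprintf("'%s' is not a two-column spectrum file.", path))
  names(tbl)[1:2] <- c("wavelength", "counts")
  tbl[1:2]
}

#' Read an attenuation-curve table
#'
#' Two columns (wavelength, epsilon) or three (plus epsilon_err).
#'
#' @param path File path.
#' @param species Optional species label to attach.
#' @return A tibble with columns `wavelength`, `epsilon` and optionally
#'   `epsilon_err`, `species`.
#' @export
read_epsilon_curve <- function(path, species = NULL) {
  if (!file.exists(path)) abort(sprintf("Curve file not found: '%s'.", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1:2] <- c("wavelength", "epsilon")
  if (ncol(tbl) >= 3) names(tbl)[3] <- "epsilon_err"
  if (!is.null(species)) tbl$species <- species
  tbl
}

#' Relative absorbance from a count triplet
#'
#' Computes, per wavelength bin,
#' `r = 1 - (n_m - n_b) / (n_ref - n_b)`,
#' the fraction of reference-corrected light removed by the sample. Bins
#' where the reference does not exceed the background carry no usable
#' signal and are masked. Bins with `r >= 1` (sample counts at or below
#' background) are clipped to 1 and flagged `clipped`, since the optical
#' depth `-log(1 - r)` diverges there; bins with `r < 0` (noise overshoot)
#' are kept for averaging but must be excluded from log-domain fits.
#'
#' @param sample,background,reference Count spectra (tibbles with
#'   `wavelength`, `counts`) on a common grid.
#' @return A tibble with columns `wavelength`, `r`, `retained`, `clipped`.
#'   If every bin is masked the result carries attribute `empty = TRUE`.
#' @export
#' @examples
#' grid <- 300:310
#' bg <- tibble::tibble(wavelength = grid, counts = 100)
#' ref <- tibble::tibble(wavelength = grid, counts = 1100)
#' smp <- tibble::tibble(wavelength = grid, counts = 600)
#' relative_absorbance(smp, bg, ref) # r = 0.5 everywhere
relative_absorbance <- function(sample, background, reference) {
  check_same_grid(sample, background, "sample and background")
  check_same_grid(sample, reference, "sample and reference")
  num <- sample$counts - background$counts
  den <- reference$counts - background$counts
  ok <- is.finite(den) & den > 0 & is.finite(num)
  r <- ifelse(ok, 1 - num / den, NA_real_)
  clipped <- ok & r >= 1
  r[clipped] <- 1
  out <- tibble(
    wavelength = sample$wavelength,
    r = r,
    retained = ok,
    clipped = clipped
  )
  if (!any(out$retained)) {
    warn("All bins masked: reference never exceeds background.")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Signal-to-noise mask for a sample spectrum
#'
#' The per-bin signal-to-noise ratio is
#' `alpha = (n_m - n_b) / n_b`; bins with `alpha` below the cutoff are
#' judged background-dominated and excluded. The boundary is retained:
#' a bin is excluded iff `alpha < cutoff`. Bins with zero background
#' counts have undefined `alpha` and are excluded.
#'
#' @param sample,background Count spectra on a common grid.
#' @param cutoff Minimum signal-to-noise ratio for a bin to be retained
#'   (default 3).
#' @return A tibble with columns `wavelength`, `alpha`, `retained`.
#' @export
snr_mask <- function(sample, background, cutoff = 3) {
  check_same_grid(sample, background, "sample and background")
  defined <- background$counts > 0
  alpha <- ifelse(defined,
    (sample$counts - background$counts) / background$counts,
    NA_real_
  )
  tibble(
    wavelength = sample$wavelength,
    alpha = alpha,
    retained = defined & !is.na(alpha) & alpha >= cutoff
  )
}

#' Reduce a count triplet to masked relative absorbance
#'
#' Convenience composition of [relative_absorbance()] and [snr_mask()]:
#' a bin is retained only if it passes both the reference-signal and the
#' signal-to-noise checks.
#'
#' @param triplet Named list with elements `sample`, `background`,
#'   `reference` (as produced by [simulate_count_triplet()]).
#' @param cutoff Signal-to-noise cutoff passed to [snr_mask()].
#' @return A tibble with columns `wavelength`, `r`, `alpha`, `retained`,
#'   `clipped`.
#' @export
reduce_triplet <- function(triplet, cutoff = 3) {
  need <- c("sample", "background", "reference")
  missing <- setdiff(need, names(triplet))
  if (length(missing) > 0) {
    abort(sprintf("Triplet is missing role(s): %s.", paste(missing, collapse = ", ")))
  }
  ra <- relative_absorbance(triplet$sample, triplet$background, triplet$reference)
  sn <- snr_mask(triplet$sample, triplet$background, cutoff = cutoff)
  tibble(
    wavelength = ra$wavelength,
    r = ra$r,
    alpha = sn$alpha,
    retained = ra$retained & sn$retained,
    clipped = ra$clipped
  )
}

#' Aggregate replicate absorbance spectra
#'
#' Per-bin mean and sample (n - 1) standard deviation across replicates.
#' A bin is retained only if it is retained in every replicate (the
#' intersection mask), so masked bins never carry weight downstream.
#'
#' @param replicates A list of absorbance tibbles (columns `wavelength`,
#'   `r`, `retained`) on a common grid; at least 2.
#' @return A tibble with columns `wavelength`, `r`, `r_err`, `n`,
#'   `retained`.
#' @export
aggregate_replicates <- function(replicates) {
  if (length(replicates) < 2) abort("Need at least 2 replicates.")
  first <- replicates[[1]]
  for (rep in replicates[-1]) check_same_grid(first, rep, "replicates")
  rmat <- vapply(replicates, function(x) x$r, numeric(nrow(first)))
  kept <- vapply(
    replicates,
    function(x) if ("retained" %in% names(x)) x$retained else rep(TRUE, nrow(x)),
    logical(nrow(first))
  )
  tibble(
    wavelength = first$wavelength,
    r = rowMeans(rmat),
    r_err = apply(rmat, 1, stats::sd),
    n = length(replicates),
    retained = apply(kept, 1, all)
  )
}

#' Write an absorbance table
#'
#' Tab-delimited columns: wavelength, r, r_err (if present), retained.
#'
#' @param absorbance An absorbance tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_absorbance <- function(absorbance, path) {
  readr::write_tsv(absorbance, path)
  invisible(path)
}

#' @rdname write_absorbance
#' @export
read_absorbance <- function(path) {
  if (!file.exists(path)) abort(sprintf("Absorbance file not found: '%s'.", path))
  readr::read_tsv(path, show_col_types = FALSE)
}
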