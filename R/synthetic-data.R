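# Synthetic spectrometer data with known ground truth: a broadband source on
# an inverse-square track, Gaussian-band attenuation curves anchored at the
# measured peak coefficients, Beer-Lambert transmission through a cuvette,
# and Poisson counting noise.

#' Gaussian band specification for a synthetic attenuation curve
#'
#' One absorption band, parameterised as a Gaussian in wavelength. Heights
#' are molar attenuation coefficients at the band centre (dm^2 mol^-1);
#' `width` is the Gaussian standard deviation in nm.
#'
#' @param center Band centre, nm.
#' @param height Peak molar attenuation coefficient, dm^2 mol^-1 (>= 0).
#' @param width Gaussian standard deviation, nm (> 0). The default 25 nm
#'   corresponds to a full width at half maximum of about 5e3 cm^-1 at
#'   340 nm, typical of charge-transfer bands of transition-metal cyanide
#'   complexes in water.
#' @return A one-row tibble with columns `center`, `height`, `width`.
#' @export
#' @examples
#' epsilon_peak(340, 2200)
epsilon_peak <- function(center, height, width = 25) {
  if (height < 0) abort("`height` must be >= 0.")
  if (width <= 0) abort("`width` must be > 0.")
  tibble(center = center, height = height, width = width)
}

#' Default band sets for ferrocyanide and nitroprusside
#'
#' Ferrocyanide carries a single UV band at 340 nm with a peak coefficient
#' of 2.2e3 dm^2 mol^-1; nitroprusside carries three bands at 340, 400 and
#' 500 nm with peak coefficients 410, 171 and 62.1 dm^2 mol^-1. Peak
#' positions and heights are the measured values; band widths are a
#' modelling choice (see [epsilon_peak()]) and configurable.
#'
#' @param width Gaussian standard deviation applied to every band, nm.
#' @return A tibble of band specifications, one row per band.
#' @export
#' @examples
#' ferrocyanide_peaks()
#' nitroprusside_peaks(width = 30)
ferrocyanide_peaks <- function(width = 25) {
  epsilon_peak(340, 2200, width)
}

#' @rdname ferrocyanide_peaks
#' @export
nitroprusside_peaks <- function(width = 25) {
  dplyr::bind_rows(
    epsilon_peak(340, 410, width),
    epsilon_peak(400, 171, width),
    epsilon_peak(500, 62.1, width)
  )
}

#' Build an attenuation curve from Gaussian bands
#'
#' Evaluates the sum of Gaussian bands on a 1 nm wavelength grid:
#' eps(lambda) = sum_k height_k * exp(-(lambda - center_k)^2 / (2 width_k^2)).
#' An empty band set yields the zero curve.
#'
#' @param peaks A tibble of band specifications ([epsilon_peak()] rows).
#' @param grid Ascending wavelength grid with 1 nm steps, nm.
#' @param species Optional species label attached to the curve.
#' @return A tibble with columns `wavelength`, `epsilon` and, if `species`
#'   is given, `species`.
#' @export
#' @examples
#' make_epsilon_curve(ferrocyanide_peaks(), grid = 300:400)
make_epsilon_curve <- function(peaks, grid = 200:800, species = NULL) {
  check_grid(grid)
  if (nrow(peaks) > 0 && any(peaks$width <= 0)) abort("Band widths must be > 0.")
  if (nrow(peaks) > 0 && any(peaks$height < 0)) abort("Band heights must be >= 0.")
  eps <- rep(0, length(grid))
  for (k in seq_len(nrow(peaks))) {
    eps <- eps + peaks$height[k] *
      exp(-(grid - peaks$center[k])^2 / (2 * peaks$width[k]^2))
  }
  out <- tibble(wavelength = as.numeric(grid), epsilon = eps)
  if (!is.null(species)) out$species <- species
  out
}

#' Default two-species curve set on the lake-model grid
#'
#' Ferrocyanide and nitroprusside attenuation curves stacked long, ready for
#' [combine_spectra()] or [run_lake()].
#'
#' @param grid Wavelength grid, nm.
#' @param width Band width passed to the band sets, nm.
#' @return A long tibble with columns `wavelength`, `epsilon`, `species`.
#' @export
default_lake_curves <- function(grid = 200:799, width = 25) {
  dplyr::bind_rows(
    make_epsilon_curve(ferrocyanide_peaks(width), grid, species = "ferrocyanide"),
    make_epsilon_curve(nitroprusside_peaks(width), grid, species = "nitroprusside")
  )
}

#' Broadband source on an inverse-square track
#'
#' The source delivers a flat spectral profile whose received intensity
#' falls off with the square of the distance from the fibre tip; the
#' nearest track position, 81 mm, is the reference distance.
#'
#' @param grid Wavelength grid, nm.
#' @param counts_at_reference Expected detector counts per bin with the
#'   source at the reference distance (blank cuvette, background excluded).
#' @param reference_distance Distance at which `counts_at_reference` holds, mm.
#' @return An object of class `source_model`.
#' @export
source_model <- function(grid = 200:800, counts_at_reference = 48000,
                         reference_distance = 81) {
  check_grid(grid)
  if (counts_at_reference <= 0) abort("`counts_at_reference` must be > 0.")
  if (reference_distance <= 0) abort("`reference_distance` must be > 0.")
  structure(
    list(
      grid = as.numeric(grid),
      counts_at_reference = counts_at_reference,
      reference_distance = reference_distance
    ),
    class = "source_model"
  )
}

#' Received source intensity at a track distance
#'
#' Scales the source profile by the inverse-square law,
#' (d_ref / d)^2, exactly.
#'
#' @param source A [source_model()].
#' @param distance Source-to-cuvette distance, mm.
#' @return A tibble with columns `wavelength`, `intensity` (expected counts
#'   above background per bin).
#' @export
received_intensity <- function(source, distance = source$reference_distance) {
  if (distance <= 0) abort("`distance` must be > 0.")
  tibble(
    wavelength = source$grid,
    intensity = source$counts_at_reference *
      (source$reference_distance / distance)^2
  )
}

#' Detector noise description
#'
#' @param kind `"poisson"` for Poisson counting noise on every recorded
#'   count, `"none"` for deterministic expected counts.
#' @param background Expected background level, counts per bin.
#' @param jitter Fractional replicate-to-replicate intensity jitter applied
#'   multiplicatively to the source (0 disables it).
#' @param seed Optional integer seed; with `kind = "none"` and
#'   `jitter = 0` the output is deterministic regardless.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("poisson", "none"), background = 100,
                        jitter = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (background < 0) abort("`background` must be >= 0.")
  if (jitter < 0) abort("`jitter` must be >= 0.")
  structure(
    list(kind = kind, background = background, jitter = jitter, seed = seed),
    class = "noise_model"
  )
}

#' Cuvette contents for a simulated measurement
#'
#' @param concentrations Named numeric vector of species concentrations,
#'   mol dm^-3; names must match the `species` column of the curve set.
#' @param path_length Cuvette path length, dm (default 0.1 dm = 1 cm).
#' @return An object of class `mixture_sample`.
#' @export
mixture_sample <- function(concentrations, path_length = 0.1) {
  if (length(concentrations) > 0 &&
      (is.null(names(concentrations)) || any(names(concentrations) == ""))) {
    abort("`concentrations` must be a named vector.")
  }
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  if (path_length <= 0) abort("`path_length` must be > 0.")
  structure(
    list(concentrations = concentrations, path_length = path_length),
    class = "mixture_sample"
  )
}

# Decadal optical depth of a mixture on the curve grid.
mixture_decadal_od <- function(mixture, curves, grid) {
  od <- rep(0, length(grid))
  for (sp in names(mixture$concentrations)) {
    ci <- mixture$concentrations[[sp]]
    if (ci == 0) next
    cur <- curves[curves$species == sp, , drop = FALSE]
    if (nrow(cur) == 0) abort(sprintf("No attenuation curve for species '%s'.", sp))
    if (length(cur$wavelength) != length(grid) ||
        any(abs(cur$wavelength - grid) > 1e-9)) {
      abort("Curve grid does not match the source grid.")
    }
    od <- od + cur$epsilon * ci * mixture$path_length
  }
  od
}

# Evaluate f with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, f) {
  if (is.null(seed)) return(f())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  f()
}

#' Simulate a background / reference / sample count triplet
#'
#' Expected counts follow the measurement model: the background is the
#' detector with the source off, the reference is light through a blank
#' cuvette, and the sample attenuates the reference counts by the decadal
#' Beer-Lambert factor
#' `10^(-sum_i eps_i(lambda) c_i beta)`. With Poisson noise each recorded
#' count is drawn from a Poisson law at its expectation; replicate jitter
#' multiplies the source intensity by a log-normal-free Gaussian factor
#' `1 + jitter * z` (truncated at 0).
#'
#' @param source A [source_model()].
#' @param mixture A [mixture_sample()].
#' @param curves Long tibble of attenuation curves (`wavelength`, `epsilon`,
#'   `species`) covering the source grid.
#' @param noise A [noise_model()].
#' @param distance Track distance for this measurement, mm.
#' @return A named list of three tibbles (`background`, `reference`,
#'   `sample`), each with columns `wavelength`, `counts`.
#' @export
#' @examples
#' tri <- simulate_count_triplet(
#'   source_model(grid = 300:400),
#'   mixture_sample(c(ferrocyanide = 1e-3)),
#'   default_lake_curves(grid = 300:400),
#'   noise_model("none")
#' )
#' head(tri$sample)
simulate_count_triplet <- function(source, mixture, curves,
                                   noise = noise_model(),
                                   distance = source$reference_distance) {
  grid <- source$grid
  inten <- received_intensity(source, distance)$intensity
  od <- mixture_decadal_od(mixture, curves, grid)
  with_local_seed(noise$seed, function() {
    if (noise$jitter > 0) {
      inten <- inten * max(0, 1 + noise$jitter * stats::rnorm(1))
    }
    mu_bg <- rep(noise$background, length(grid))
    mu_ref <- mu_bg + inten
    mu_smp <- mu_bg + inten * 10^(-od)
    draw <- function(mu) {
      if (noise$kind == "poisson") as.numeric(stats::rpois(length(mu), mu)) else mu
    }
    list(
      background = tibble(wavelength = grid, counts = draw(mu_bg)),
      reference = tibble(wavelength = grid, counts = draw(mu_ref)),
      sample = tibble(wavelength = grid, counts = draw(mu_smp))
    )
  })
}

#' Simulate replicated triplets across track distances
#'
#' Reproduces the measurement protocol: each cuvette is measured in
#' triplicate at each of three track distances, nine triplets in all.
#'
#' @inheritParams simulate_count_triplet
#' @param distances Track distances, mm.
#' @param n_per_distance Replicates per distance.
#' @return A list of triplets (see [simulate_count_triplet()]).
#' @export
simulate_replicate_triplets <- function(source, mixture, curves,
                                        noise = noise_model(),
                                        distances = c(81, 231, 581),
                                        n_per_distance = 3) {
  runs <- expand.grid(rep = seq_len(n_per_distance), distance = distances)
  purrr::pmap(runs, function(rep, distance) {
    nz <- noise
    if (!is.null(noise$seed)) nz$seed <- noise$seed + 1000 * rep + round(distance)
    simulate_count_triplet(source, mixture, curves, nz, distance)
  })
}

#' Actinic flux on a 1 nm grid
#'
#' Either a flat spectrum or a Planck blackbody at a stated temperature,
#' optionally rescaled so that its integral over the grid equals a stated
#' total. With exact 1 nm bins the integral is the plain bin sum.
#'
#' @param grid Wavelength grid covering at least the photochemically active
#'   region, 1 nm steps, nm.
#' @param kind `"flat"` or `"blackbody"`.
#' @param value Bin value for the flat kind.
#' @param temperature Blackbody temperature, K (default the solar effective
#'   temperature).
#' @param total If given, the flux is rescaled so `sum(flux)` equals it.
#' @return A tibble with columns `wavelength`, `flux`.
#' @export
#' @examples
#' make_actinic_flux(200:400, "blackbody", total = 1)
make_actinic_flux <- function(grid = 200:400, kind = c("flat", "blackbody"),
                              value = 1, temperature = 5772, total = NULL) {
  kind <- match.arg(kind)
  check_grid(grid)
  flux <- switch(kind,
    flat = rep(value, length(grid)),
    blackbody = planck_radiance(grid, temperature)
  )
  if (!is.null(total)) {
    s <- sum(flux)
    if (s <= 0) abort("Cannot normalise a non-positive flux.")
    flux <- flux * total / s
  }
  tibble(wavelength = as.numeric(grid), flux = flux)
}

# Planck spectral radiance per unit wavelength (arbitrary scale), lambda nm.
planck_radiance <- function(lambda_nm, temperature) {
  h <- 6.62607015e-34; c <- 2.99792458e8; kB <- 1.380649e-23
  lam <- lambda_nm * 1e-9
  (2 * h * c^2 / lam^5) / (exp(h * c / (lam * kB * temperature)) - 1)
}

#' Write a two-column spectrum file
#'
#' Plain tab-delimited text with a header line, one row per wavelength bin:
#' the interchange format shared with [read_count_spectrum()] and
#' [read_epsilon_curve()].
#'
#' @param spectrum A tibble whose first column is `wavelength`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(spectrum, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @param triplet A triplet list from [simulate_count_triplet()].
#' @param dir Output directory.
#' @param prefix File-name prefix; files are named
#'   `<prefix>_<role>.tsv`.
#' @export
write_count_triplet <- function(triplet, dir, prefix = "run") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(triplet, function(tbl, role) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, role))
    write_spectrum(tbl, p)
    p
  })
  invisible(paths)
}
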