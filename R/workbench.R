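# Pipeline entry points: file-level reduction, calibration fitting and
# lake simulation, each leaving a manifest beside its outputs.

#' Write a run manifest
#'
#' Every output directory carries a manifest recording the command, the
#' input paths, the configuration snapshot, the seed and the package
#' version, so that a rerun with an identical manifest reproduces
#' identical deterministic outputs.
#'
#' @param command Command name.
#' @param inputs Character vector (or named list) of input paths.
#' @param config Configuration snapshot (list).
#' @param seed Seed in force, or `NULL`.
#' @param out_dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(command, inputs, config, seed, out_dir) {
  manifest <- list(
    command = command,
    inputs = inputs,
    config = config,
    seed = seed,
    package = "lakeshade",
    version = as.character(utils::packageVersion("lakeshade")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

check_role_file <- function(path, role) {
  if (is.null(path) || is.na(path) || !file.exists(path)) {
    abort(sprintf("Missing %s spectrum file: '%s'.", role, path))
  }
  path
}

#' Reduce count triplets to an aggregated absorbance table
#'
#' Reads one or more (sample, background, reference) file triplets,
#' reduces each to masked relative absorbance, aggregates the replicates,
#' and writes the per-replicate and aggregated tables plus a manifest.
#'
#' @param triplets A data frame with columns `sample`, `background`,
#'   `reference` holding file paths, one row per replicate.
#' @param out_dir Output directory (created if needed).
#' @param cutoff Signal-to-noise cutoff.
#' @return The aggregated absorbance tibble (or the single reduced table
#'   when only one replicate is given), invisibly.
#' @export
reduce_spectra <- function(triplets, out_dir, cutoff = 3) {
  if (!all(c("sample", "background", "reference") %in% names(triplets))) {
    abort("`triplets` needs columns sample, background, reference.")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reduced <- purrr::pmap(triplets, function(sample, background, reference, ...) {
    tri <- list(
      sample = read_count_spectrum(check_role_file(sample, "sample")),
      background = read_count_spectrum(check_role_file(background, "background")),
      reference = read_count_spectrum(check_role_file(reference, "reference"))
    )
    reduce_triplet(tri, cutoff = cutoff)
  })
  for (i in seq_along(reduced)) {
    write_absorbance(reduced[[i]],
                     file.path(out_dir, sprintf("replicate_%02d.tsv", i)))
  }
  out <- if (length(reduced) >= 2) aggregate_replicates(reduced) else reduced[[1]]
  write_absorbance(out, file.path(out_dir, "absorbance.tsv"))
  masked_frac <- mean(!out$retained)
  message(sprintf("reduce: %d replicate(s), %.1f%% of bins masked",
                  length(reduced), 100 * masked_frac))
  write_run_manifest(
    "reduce",
    as.list(triplets),
    list(cutoff = cutoff, masked_fraction = masked_frac),
    NULL, out_dir
  )
  invisible(out)
}

#' Fit a calibration curve from absorbance tables of standards
#'
#' Reads aggregated absorbance tables measured at known concentrations,
#' fits the per-wavelength Beer-Lambert regression, and writes the fitted
#' attenuation curve together with a report at the configured peak
#' wavelengths.
#'
#' @param standards A data frame with columns `path` (absorbance table)
#'   and `conc` (mol dm^-3); at least three concentrations.
#' @param out_dir Output directory.
#' @param beta Path length, dm.
#' @param peaks Peak wavelengths for the report, nm.
#' @param intercept Free intercept in the per-bin fits?
#' @return A list with `curve` and `peaks` tibbles, invisibly.
#' @export
fit_standards <- function(standards, out_dir, beta = 0.1,
                          peaks = c(340, 400, 500), intercept = TRUE) {
  if (!all(c("path", "conc") %in% names(standards))) {
    abort("`standards` needs columns path and conc.")
  }
  n_conc <- length(unique(standards$conc))
  if (n_conc < 3) {
    abort(sprintf("Need >= 3 standard concentrations, have %d.", n_conc))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  long <- purrr::pmap(standards, function(path, conc, ...) {
    tbl <- read_absorbance(check_role_file(path, "standard absorbance"))
    tbl$conc <- conc
    tbl
  }) |> dplyr::bind_rows()
  curve <- epsilon_curve_from_standards(long, beta = beta, intercept = intercept)
  peak_report <- peak_epsilon(curve, peaks)
  write_epsilon_curve(curve, file.path(out_dir, "epsilon_curve.tsv"))
  readr::write_tsv(peak_report, file.path(out_dir, "peak_report.tsv"))
  write_run_manifest(
    "fit",
    as.list(standards),
    list(beta = beta, peaks = peaks, intercept = intercept),
    NULL, out_dir
  )
  invisible(list(curve = curve, peaks = peak_report))
}

#' Read a lake configuration from a YAML file
#'
#' Keys mirror the arguments of [lake_config()].
#'
#' @param path YAML file path.
#' @return A [lake_config()].
#' @export
read_lake_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(lake_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(lake_config, vals)
}

#' Run the lake model and write its outputs
#'
#' Writes the thinned trajectory, the survival-by-depth table, and a
#' structured summary (shadow slope where at least three layers are
#' uncensored, per-layer peak nitroprusside, exposure delay at the lake
#' bottom), plus a manifest. Optional comparison variants rerun the model
#' with no ferrocyanide or without the configured extra absorbers into
#' subdirectories.
#'
#' @param config A [lake_config()] or the path of a YAML config file.
#' @param out_dir Output directory.
#' @param curves,flux Passed to [run_lake()]; defaults as there.
#' @param variants Character subset of
#'   `c("no_ferrocyanide", "no_extra_absorbers")`.
#' @return The `lake_simulation`, invisibly.
#' @export
simulate_lake <- function(config, out_dir, curves = NULL, flux = NULL,
                          variants = character()) {
  cfg_input <- if (is.character(config)) config else "<in-memory config>"
  if (is.character(config)) config <- read_lake_config(config)
  if (!inherits(config, "lake_config")) abort("`config` must be a lake_config.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(curves)) curves <- default_lake_curves(grid = lake_grid(config))
  if (is.null(flux)) flux <- make_actinic_flux(lake_grid(config))

  sim <- run_lake(config, curves, flux)
  readr::write_tsv(sim$trajectory, file.path(out_dir, "trajectory.tsv"))
  readr::write_tsv(sim$survival, file.path(out_dir, "survival.tsv"))
  readr::write_tsv(sim$peak_B, file.path(out_dir, "peak_nitroprusside.tsv"))

  summary <- as.list(glance(sim))
  if (sum(!sim$survival$censored) >= 3) {
    fit <- shadow_slope(sim)
    summary$shadow_slope_days_per_m <- fit$slope
    summary$shadow_slope_err <- fit$slope_err
    summary$shadow_r_squared <- fit$r_squared
  }
  delay <- exposure_delay(sim)
  summary$exposure_delay_days <- if (is.na(delay)) NULL else delay
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  snapshot <- config[setdiff(names(config), "extra_absorbers")]
  write_run_manifest("lake", cfg_input, snapshot, NULL, out_dir)

  for (v in variants) {
    vcfg <- config
    if (v == "no_ferrocyanide") {
      vcfg$initial_ferrocyanide <- 0
    } else if (v == "no_extra_absorbers") {
      vcfg$extra_absorbers <- NULL
    } else {
      abort(sprintf("Unknown variant '%s'.", v))
    }
    class(vcfg) <- "lake_config"
    vsim <- run_lake(vcfg, curves, flux)
    vdir <- file.path(out_dir, v)
    dir.create(vdir, showWarnings = FALSE)
    readr::write_tsv(vsim$trajectory, file.path(vdir, "trajectory.tsv"))
    readr::write_tsv(vsim$survival, file.path(vdir, "survival.tsv"))
    jsonlite::write_json(as.list(glance(vsim)), file.path(vdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(sim)
}

#' Benchmark deposited standards against the printed peak coefficients
#'
#' Runs the reduce-and-fit pipeline over a directory of deposited
#' standard measurements and reports the fitted peak coefficients. The
#' deposit is an optional external download; when the directory is absent
#' the function returns `NULL` invisibly. The expected layout is one
#' subdirectory per standard named `<species>_<conc>` containing
#' `sample.tsv`, `background.tsv`, `reference.tsv` triplet files (counts
#' against wavelength).
#'
#' @param dir Directory holding the deposited standards.
#' @param beta Path length, dm.
#' @return A peak-report tibble, or `NULL` when `dir` does not exist.
#' @export
benchmark_standards <- function(dir, beta = 0.1) {
  if (!dir.exists(dir)) return(invisible(NULL))
  runs <- list.dirs(dir, recursive = FALSE)
  parsed <- purrr::map(runs, function(d) {
    parts <- strsplit(basename(d), "_", fixed = TRUE)[[1]]
    conc <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (is.na(conc)) return(NULL)
    tri <- list(
      sample = read_count_spectrum(file.path(d, "sample.tsv")),
      background = read_count_spectrum(file.path(d, "background.tsv")),
      reference = read_count_spectrum(file.path(d, "reference.tsv"))
    )
    out <- reduce_triplet(tri)
    out$conc <- conc
    out
  })
  long <- dplyr::bind_rows(parsed)
  if (is.null(long) || nrow(long) == 0) return(invisible(NULL))
  curve <- epsilon_curve_from_standards(long, beta = beta)
  peak_epsilon(curve)
}
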