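test_that("file-level reduction reproduces the closed-form absorbance", {
  dir <- withr::local_tempdir()
  grid <- 320:360
  conc <- 5e-4
  tri <- noiseless_triplet(c(ferrocyanide = conc), grid = grid)
  paths <- write_count_triplet(tri, dir, prefix = "run1")
  out_dir <- file.path(dir, "reduced")
  suppressMessages(out <- reduce_spectra(
    data.frame(sample = paths[["sample"]], background = paths[["background"]],
               reference = paths[["reference"]]),
    out_dir
  ))
  curves <- default_lake_curves(grid = grid)
  od <- curves$epsilon[curves$species == "ferrocyanide"] * conc * 0.1
  expect_equal(out$r, 1 - 10^(-od), tolerance = 1e-12)
  expect_true(file.exists(file.path(out_dir, "absorbance.tsv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
})

test_that("reduction errors name the missing role", {
  dir <- withr::local_tempdir()
  tri <- noiseless_triplet(c(ferrocyanide = 1e-4), grid = 320:330)
  paths <- write_count_triplet(tri, dir, prefix = "x")
  expect_error(
    suppressMessages(reduce_spectra(
      data.frame(sample = paths[["sample"]],
                 background = file.path(dir, "nope.tsv"),
                 reference = paths[["reference"]]),
      file.path(dir, "out")
    )),
    "background"
  )
})

test_that("replicated reductions aggregate with a spread column", {
  dir <- withr::local_tempdir()
  grid <- 320:340
  reps <- simulate_replicate_triplets(
    source_model(grid = grid),
    mixture_sample(c(ferrocyanide = 5e-4)),
    default_lake_curves(grid = grid),
    noise_model("poisson", seed = 5)
  )
  manifest <- purrr::imap_dfr(reps, function(tri, i) {
    p <- write_count_triplet(tri, dir, prefix = sprintf("rep%02d", i))
    tibble::tibble(sample = p[["sample"]], background = p[["background"]],
                   reference = p[["reference"]])
  })
  out_dir <- file.path(dir, "agg")
  suppressMessages(out <- reduce_spectra(manifest, out_dir))
  expect_equal(out$n[1], 9)
  expect_true("r_err" %in% names(out))
  expect_equal(length(list.files(out_dir, pattern = "^replicate_")), 9)
})

test_that("standards fitting demands enough concentrations and reports peaks", {
  dir <- withr::local_tempdir()
  grid <- 300:520
  concs <- c(2e-3, 5e-3, 1e-2, 2e-2)
  files <- purrr::map2_chr(concs, seq_along(concs), function(ci, i) {
    tri <- simulate_count_triplet(
      source_model(grid = grid), mixture_sample(c(nitroprusside = ci)),
      default_lake_curves(grid = grid), noise_model("none")
    )
    p <- file.path(dir, sprintf("std%02d.tsv", i))
    write_absorbance(reduce_triplet(tri), p)
    p
  })
  expect_error(
    fit_standards(data.frame(path = files[1], conc = concs[1]),
                  file.path(dir, "f0")),
    "have 1"
  )
  res <- fit_standards(data.frame(path = files, conc = concs),
                       file.path(dir, "fit"))
  pk <- res$peaks
  # the fit recovers the generating curve: the total coefficient at each
  # peak, i.e. the band height plus the overlap of neighbouring bands
  truth <- make_epsilon_curve(nitroprusside_peaks(), grid = 300:520)
  expect_equal(pk$epsilon[pk$wavelength == 500],
               truth$epsilon[truth$wavelength == 500], tolerance = 1e-6)
  expect_equal(pk$epsilon[pk$wavelength == 400],
               truth$epsilon[truth$wavelength == 400], tolerance = 1e-6)
  # the 500 nm total also sits inside the printed band: 62.1 +/- 1.7
  expect_lt(abs(pk$epsilon[pk$wavelength == 500] - 62.1), 1.7)
  expect_true(file.exists(file.path(dir, "fit", "epsilon_curve.tsv")))
  expect_true(file.exists(file.path(dir, "fit", "peak_report.tsv")))
})

test_that("lake runs from a YAML config write deterministic tables", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "lake.yaml")
  yaml::write_yaml(
    list(depth = 0.05, horizon = 40, record_every = 10),
    cfg_path
  )
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  sim <- simulate_lake(cfg_path, out1)
  simulate_lake(cfg_path, out2)
  sv <- readr::read_tsv(file.path(out1, "survival.tsv"), show_col_types = FALSE)
  expect_true(all(diff(sv$time) >= -1e-9))
  summ <- jsonlite::read_json(file.path(out1, "summary.json"))
  expect_true(is.numeric(summ$shadow_slope_days_per_m))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # identical configuration, byte-identical tables
  expect_identical(
    readLines(file.path(out1, "survival.tsv")),
    readLines(file.path(out2, "survival.tsv"))
  )
  expect_identical(
    readLines(file.path(out1, "trajectory.tsv")),
    readLines(file.path(out2, "trajectory.tsv"))
  )
  expect_error(read_lake_config(file.path(dir, "missing.yaml")), "not found")
  yaml::write_yaml(list(depht = 1), cfg_path)
  expect_error(read_lake_config(cfg_path), "Unknown config key")
})

test_that("comparison variants run alongside the main simulation", {
  dir <- withr::local_tempdir()
  cfg <- lake_config(depth = 0.02, horizon = 5, record_every = 10)
  suppressMessages(simulate_lake(cfg, dir, variants = "no_ferrocyanide"))
  vsumm <- jsonlite::read_json(file.path(dir, "no_ferrocyanide", "summary.json"))
  # nothing to destroy, nothing produced beyond the nitrate path
  expect_equal(vsumm$max_peak_B, 0)
  vtraj <- readr::read_tsv(file.path(dir, "no_ferrocyanide", "trajectory.tsv"),
                           show_col_types = FALSE)
  # without absorbers every layer sees the surface flux
  expect_true(all(abs(vtraj$chi_k2[vtraj$time > 0] - 1) < 1e-12))
})

test_that("the deposited-standard benchmark harness degrades gracefully", {
  dir <- withr::local_tempdir()
  expect_null(benchmark_standards(file.path(dir, "absent")))
  # a synthetic stand-in deposit exercises the full reduce+fit path
  deposit <- file.path(dir, "deposit")
  for (ci in c(2e-3, 5e-3, 1e-2)) {
    sub <- file.path(deposit, sprintf("nitroprusside_%g", ci))
    dir.create(sub, recursive = TRUE)
    tri <- simulate_count_triplet(
      source_model(grid = 300:520), mixture_sample(c(nitroprusside = ci)),
      default_lake_curves(grid = 300:520), noise_model("none")
    )
    write_spectrum(tri$sample, file.path(sub, "sample.tsv"))
    write_spectrum(tri$background, file.path(sub, "background.tsv"))
    write_spectrum(tri$reference, file.path(sub, "reference.tsv"))
  }
  pk <- benchmark_standards(deposit)
  truth <- make_epsilon_curve(nitroprusside_peaks(), grid = 300:520)
  expect_equal(pk$epsilon[pk$wavelength == 500],
               truth$epsilon[truth$wavelength == 500], tolerance = 1e-6)
})

test_that("the command-line wrapper refuses malformed invocations", {
  cli <- system.file("cli", "lakeshade.R", package = "lakeshade")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- suppressWarnings(system2(
    rscript, c(cli, "frobnicate"),
    stdout = FALSE, stderr = FALSE
  ))
  expect_gt(status, 0)
})
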