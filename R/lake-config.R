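# Configuration and initial state of the layered stagnant-lake model.

#' Configure the layered lake model
#'
#' Collects the geometry, kinetics and numerical settings of the
#' stagnant-lake photochemistry simulation. All physical constants surface
#' here; nothing is buried in code.
#'
#' @param depth Lake depth, m. Must be an integer multiple of
#'   `layer_thickness`.
#' @param surface_area Lake surface area, m^2.
#' @param catchment Dimensionless catchment factor converting per-area
#'   atmospheric deposition to lake input.
#' @param layer_thickness Thickness of each model layer, m (default 1 cm).
#' @param k1 Surface rate constant of photo-oxidation (ferrocyanide to
#'   nitroprusside in the presence of nitrate), s^-1.
#' @param k2 Surface rate constant of photo-aquation (destruction of both
#'   complexes), s^-1.
#' @param lightning_rate Lightning energy dissipation rate, J m^-2 s^-1.
#' @param nox_yield NOx yield of lightning, mol J^-1.
#' @param hcn_rainout HCN rainout during the haze phase,
#'   molecules cm^-2 s^-1.
#' @param haze_duration Duration of the post-impact haze phase, years.
#' @param ferrocyanide_cap Solubility-limited ceiling on ferrocyanide,
#'   mol dm^-3.
#' @param initial_ferrocyanide Ferrocyanide concentration when the haze
#'   clears, mol dm^-3. The default 0.1 is the favourable upper limit used
#'   for the headline runs; set `NULL` to derive it from the haze-phase
#'   rainout budget instead (six cyanides per complex, capped at
#'   `ferrocyanide_cap`).
#' @param dt Time step, days.
#' @param band_k1,band_k2 Half-open wavelength intervals `[lo, hi)` (nm)
#'   whose flux attenuation scales `k1` (photo-oxidation, 200-300 nm) and
#'   `k2` (photo-aquation, 300-400 nm).
#' @param nitrate_mode `"saturated"` (default): `k1` is a first-order
#'   constant in s^-1 and photo-oxidation proceeds at `k1 [A]` whenever
#'   nitrate is available, consuming it mole for mole and clamped at the
#'   available stock. `"bimolecular"`: `k1` is read as
#'   dm^3 mol^-1 s^-1 and the production term is `k1 [A] [NO3-]`.
#' @param survival_threshold Fraction of the initial ferrocyanide below
#'   which a layer counts as depleted (default 1%).
#' @param horizon Maximum simulated time, days.
#' @param record_every Record the trajectory every this many steps.
#' @param nitroprusside_uv Treatment of nitroprusside attenuation in the
#'   `band_k1` region, where its coefficients are unmeasured: `"zero"`
#'   (default) or `"mirror"` (hold its 340 nm value).
#' @param extra_absorbers Optional static absorbers: a list with elements
#'   `curves` (long tibble `wavelength`, `epsilon`, `species`) and
#'   `concentrations` (named, mol dm^-3). Their optical depth is constant
#'   in time.
#' @return An object of class `lake_config`.
#' @export
#' @examples
#' lake_config(depth = 5)
lake_config <- function(depth = 1,
                        surface_area = 1e3,
                        catchment = 500,
                        layer_thickness = 0.01,
                        k1 = 2.59e-7,
                        k2 = 5.13e-5,
                        lightning_rate = 6.5e-5,
                        nox_yield = 2e-9,
                        hcn_rainout = 1e8,
                        haze_duration = 1e3,
                        ferrocyanide_cap = 0.1,
                        initial_ferrocyanide = 0.1,
                        dt = 0.07,
                        band_k1 = c(200, 300),
                        band_k2 = c(300, 400),
                        nitrate_mode = c("saturated", "bimolecular"),
                        survival_threshold = 0.01,
                        horizon = 3000,
                        record_every = 25,
                        nitroprusside_uv = c("zero", "mirror"),
                        extra_absorbers = NULL) {
  nitrate_mode <- match.arg(nitrate_mode)
  nitroprusside_uv <- match.arg(nitroprusside_uv)
  rates <- c(k1, k2, lightning_rate, nox_yield, hcn_rainout)
  if (any(rates < 0)) abort("All rates must be >= 0.")
  if (depth <= 0 || surface_area <= 0) abort("Lake geometry must be positive.")
  n_layers <- depth / layer_thickness
  if (abs(n_layers - round(n_layers)) > 1e-9) {
    abort("`depth` must be an integer multiple of `layer_thickness`.")
  }
  if (dt <= 0) abort("`dt` must be > 0.")
  if (survival_threshold < 0 || survival_threshold > 1) {
    abort("`survival_threshold` must be in [0, 1].")
  }
  if (band_k1[2] <= band_k1[1] || band_k2[2] <= band_k2[1]) {
    abort("Bands must be non-empty [lo, hi) intervals.")
  }
  # Frozen-rate stability guard: the per-step decay exponent of the fastest
  # first-order channel must stay below one per day-step.
  if ((k2 + k1) * SECONDS_PER_DAY * dt >= 1 && nitrate_mode == "saturated") {
    abort("Unstable configuration: (k1 + k2) * dt >= 1 in day units.")
  }
  structure(
    list(
      depth = depth,
      surface_area = surface_area,
      volume = surface_area * depth,
      catchment = catchment,
      layer_thickness = layer_thickness,
      n_layers = as.integer(round(n_layers)),
      k1 = k1,
      k2 = k2,
      lightning_rate = lightning_rate,
      nox_yield = nox_yield,
      hcn_rainout = hcn_rainout,
      haze_duration = haze_duration,
      ferrocyanide_cap = ferrocyanide_cap,
      initial_ferrocyanide = initial_ferrocyanide,
      dt = dt,
      band_k1 = band_k1,
      band_k2 = band_k2,
      nitrate_mode = nitrate_mode,
      survival_threshold = survival_threshold,
      horizon = horizon,
      record_every = record_every,
      nitroprusside_uv = nitroprusside_uv,
      extra_absorbers = extra_absorbers
    ),
    class = "lake_config"
  )
}

#' @export
print.lake_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<lake_config> %g m deep, %d layers of %g cm\n",
      "  k1 = %.3g s^-1 (%g-%g nm), k2 = %.3g s^-1 (%g-%g nm)\n",
      "  dt = %g d, nitrate mode '%s', survival threshold %g%%\n"
    ),
    x$depth, x$n_layers, 100 * x$layer_thickness,
    x$k1, x$band_k1[1], x$band_k1[2], x$k2, x$band_k2[1], x$band_k2[2],
    x$dt, x$nitrate_mode, 100 * x$survival_threshold
  ))
  invisible(x)
}

#' Nitrate supply rate from lightning over the catchment
#'
#' `C * l_r * r_NOx * sigma_lake / V_lake`, converted to mol dm^-3 s^-1.
#' Since `V = sigma * depth`, the rate scales with the inverse depth.
#'
#' @param config A [lake_config()].
#' @return Supply rate, mol dm^-3 s^-1.
#' @export
#' @examples
#' nitrate_supply_rate(lake_config(depth = 1)) # 6.5e-14
nitrate_supply_rate <- function(config) {
  if (config$volume <= 0) abort("Lake volume must be > 0.")
  config$catchment * config$lightning_rate * config$nox_yield *
    config$surface_area / config$volume / 1e3
}

#' Ferrocyanide accumulated over the haze phase
#'
#' Converts the HCN rainout column (catchment-amplified, six cyanide
#' ligands per complex, mixed over the lake depth) to a concentration, and
#' caps it at the solubility ceiling.
#'
#' @param config A [lake_config()].
#' @return Concentration, mol dm^-3.
#' @export
haze_ferrocyanide <- function(config) {
  # molecules cm^-2 s^-1 -> mol dm^-3 over the lake depth
  col_molecules_m2 <- config$hcn_rainout * 1e4 *
    config$haze_duration * SECONDS_PER_YEAR * config$catchment
  conc <- col_molecules_m2 / config$depth / AVOGADRO / 1e3 / 6
  min(config$ferrocyanide_cap, conc)
}

#' Lake state at the end of the haze phase
#'
#' While the haze blocks UV, ferrocyanide builds up (no photochemistry)
#' and lightning-derived nitrate accumulates at the supply rate; no
#' nitroprusside forms. Every layer starts identical.
#'
#' @param config A [lake_config()].
#' @return A tibble with one row per layer: `layer`, `depth` (mid-layer,
#'   m), `A` (ferrocyanide), `B` (nitroprusside), `N` (nitrate), all
#'   mol dm^-3, carrying `time = 0` as an attribute.
#' @export
init_haze_phase <- function(config) {
  a0 <- if (is.null(config$initial_ferrocyanide)) {
    haze_ferrocyanide(config)
  } else {
    min(config$ferrocyanide_cap, config$initial_ferrocyanide)
  }
  # no haze phase, nothing accumulated
  if (config$haze_duration <= 0) a0 <- 0
  n0 <- nitrate_supply_rate(config) * config$haze_duration * SECONDS_PER_YEAR
  n <- config$n_layers
  st <- tibble(
    layer = seq_len(n),
    depth = (seq_len(n) - 0.5) * config$layer_thickness,
    A = rep(a0, n),
    B = rep(0, n),
    N = rep(n0, n)
  )
  attr(st, "time") <- 0
  st
}
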