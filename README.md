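# lakeshade

UV–Vis spectral reduction and photochemical "sunscreen" modelling of
prebiotic lakes, in R.

Iron cyanide complexes — ferrocyanide, [Fe(CN)₆]⁴⁻, and nitroprusside,
[Fe(CN)₅(NO)]²⁻ — absorb strongly in the ultraviolet. Dissolved in a
stagnant lake, they shade the water below them, so photosensitive
compounds of interest to origin-of-life chemistry (NADH is the canonical
example, degraded by 300–400 nm light) can persist at depth long after
they would have been destroyed at the surface. `lakeshade` covers both
halves of that argument:

1. **Spectral reduction and calibration.** Raw spectrometer count triplets
   (background `n_b`, blank-cuvette reference `n_ref`, sample `n_m`) are
   reduced to the relative absorbance

   `r(λ) = 1 − (n_m − n_b) / (n_ref − n_b) = 1 − e^(−τ(λ))`,

   masked by the per-bin signal-to-noise ratio
   `α = (n_m − n_b)/n_b` (bins with `α < 3` are excluded), and averaged
   over replicates. Calibration ladders at known concentrations then give
   the molar attenuation coefficient per wavelength by ordinary least
   squares of `ln(1 − r)` against concentration `c`: the gradient is
   `m = −β N_A σ(λ)`, so `ε(λ) = −m / (β ln 10)` with `β` the cuvette
   path length (0.1 dm) and `Δε/ε = Δm/m`. Optical depths of mixtures
   add: `τ(λ) = Σᵢ σᵢ(λ) nᵢ β`, which lets single-species curves predict
   two-species spectra.

2. **The layered lake model.** A stagnant column (1 cm layers) starts, at
   the end of a post-impact hazy period, loaded with ferrocyanide (0.1 M
   in the favourable case) and lightning-derived nitrate. Per layer the
   kinetics are

   `d[A]/dt = −k₁[A]·𝟙([NO₃⁻]>0) − k₂[A]`,
   `d[B]/dt = +k₁[A]·𝟙([NO₃⁻]>0) − k₂[B]`,
   `d[NO₃⁻]/dt = C·l_r·r_NOx·σ_lake/V_lake − (consumption)`,

   with surface rate constants `k₁ = 2.59×10⁻⁷ s⁻¹` (photo-oxidation of
   ferrocyanide to nitroprusside, driven by 200–300 nm light) and
   `k₂ = 5.13×10⁻⁵ s⁻¹` (photo-aquation, destroying both complexes,
   driven by 300–400 nm light). Each layer's rate constants are scaled by
   the band-integrated flux ratio of the light entering it,
   `χₙ = ∫F₀(λ) Π_{m<n} z_m(λ) dλ / ∫F₀(λ) dλ`, where
   `z_m(λ) = 10^(−Σᵢ εᵢ(λ) cᵢ β_layer)` is one layer's decadal
   transmission. The column burns down from the top: each layer is
   shielded until the layers above it are depleted, so the time for a
   layer's ferrocyanide to fall below 1 % of its start grows nearly
   linearly with depth. The slope of that line (days per metre) is the
   **shadow slope**, and the time until a depth is exposed plus a
   compound's unprotected lifetime is its **protected lifetime**.

A synthetic-data generator supplies every input with known ground truth —
an inverse-square broadband source, Poisson counting noise, and
Gaussian-band attenuation curves anchored at the measured peak
coefficients (ferrocyanide: 2.2×10³ dm² mol⁻¹ at 340 nm; nitroprusside:
4.1×10², 1.71×10², 62.1 dm² mol⁻¹ at 340, 400, 500 nm) — so the whole
pipeline is testable offline.

## Worked example

Simulate a nitroprusside calibration ladder with counting noise, reduce
and fit it, then run a 1 m lake:

```r
library(lakeshade)

curves <- default_lake_curves(grid = 300:520)
concs <- c(0.002, 0.005, 0.01, 0.02)   # mol dm^-3
standards <- purrr::map_dfr(concs, function(ci) {
  tri <- simulate_count_triplet(
    source_model(grid = 300:520),
    mixture_sample(c(nitroprusside = ci)),
    curves,
    noise_model("poisson", seed = 7)
  )
  out <- reduce_triplet(tri)   # relative absorbance + SNR mask
  out$conc <- ci
  out
})
peak_epsilon(epsilon_curve_from_standards(standards))
#> # A tibble: 3 × 5
#>   wavelength epsilon epsilon_err r_squared     n
#>        <dbl>   <dbl>       <dbl>     <dbl> <int>
#> 1        340   420.      0.0715      1.000     4
#> 2        400   193.      0.0234      1.000     4
#> 3        500    62.0     0.00482     1.000     4
```

The fitted coefficients recover the generating curve: at 500 nm the value
is nitroprusside's peak alone (62.1), while at 340 and 400 nm the totals
include the overlap of the neighbouring bands (420 ≈ 410 + overlap,
193 ≈ 171 + overlap). The tiny `epsilon_err` reflects nine-figure count
statistics at these concentrations, not calibration accuracy.

```r
sim <- run_lake(lake_config(depth = 1, horizon = 200))
glance(sim)
#> # A tibble: 1 × 7
#>   depth n_layers    dt simulated_days n_censored deepest_survival max_peak_B
#>   <dbl>    <int> <dbl>          <dbl>      <int>            <dbl>      <dbl>
#> 1     1      100  0.07           87.6          0             87.6    0.00205

shadow_slope(sim)
#> <shadow_fit> survival ~ 87.5 d/m x depth (+ 0.6 d), R^2 = 1.0000, n = 100

protected_lifetime(exposure_delay(sim), 182.6)  # NADH: 6 unprotected months
#> [1] 270.2319
```

Reading: ferrocyanide at the bottom of a 1 m lake survives ~88 days
(versus ~1 day unshaded), survival grows linearly with depth at
~87.5 days per metre, each layer transiently hosts a nitroprusside pulse
(here capped by the accumulated nitrate stock, ~2 mM), and NADH stored at
1 m would last ~270 days instead of ~183. `autoplot(sim)` and
`plot_survival(sim)` draw the depth–time concentration field and the
survival line.

The file-level interface mirrors this: `reduce_spectra()`,
`fit_standards()` and `simulate_lake()` read and write delimited tables
with a JSON manifest per output directory, and
`inst/cli/lakeshade.R` exposes them as `reduce` / `fit` / `lake`
subcommands.

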