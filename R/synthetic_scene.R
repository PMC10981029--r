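# Synthetic scenes with known ground truth for every downstream stage:
# seasonal NDVI sinusoids with a drought-year suppression on damaged pixels,
# spatially smooth climate fields coupled to an altitude gradient, and a
# damage mask whose probability rises with aridity.

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth random surface: a mixture of low-frequency cosine waves, z-scored
smooth_field <- function(n_rows, n_cols, n_waves = 8, max_freq = 2.5) {
  x <- matrix(rep((seq_len(n_cols) - 0.5) / n_cols, each = n_rows),
              n_rows, n_cols)
  y <- matrix(rep((seq_len(n_rows) - 0.5) / n_rows, n_cols), n_rows, n_cols)
  f <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, -max_freq, max_freq)
    fy <- stats::runif(1, -max_freq, max_freq)
    a <- stats::rnorm(1)
    phi <- stats::runif(1, 0, 2 * pi)
    f <- f + a * cos(2 * pi * (fx * x + fy * y) + phi)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Parameters of a synthetic forest-drought scene
#'
#' Defaults describe the study conditions emulated throughout the package: a
#' four-year (2017--2020) series of 10-day NDVI composites over temperate
#' coniferous forest, with the severe drought in 2018 suppressing the
#' productivity of damaged stands, an elevation field spanning 75--950 m, and
#' climate that gets wetter and cooler with altitude so that aridity is
#' strongest in the lowlands.
#'
#' @param n_rows,n_cols Scene size in pixels (300 m analysis grid).
#' @param years Calendar years covered.
#' @param composites_per_month Composites per month (3 = 10-day cadence).
#' @param ndvi_base Mean NDVI of healthy forest (unitless).
#' @param ndvi_amplitude Seasonal (peak-to-mean) NDVI amplitude.
#' @param peak_doy Day of year of the seasonal NDVI peak (mid-July default).
#' @param noise_sd Standard deviation of per-composite NDVI noise.
#' @param drought_year First year of productivity suppression.
#' @param damage_fraction Fraction of forest pixels labelled damaged.
#' @param damage_suppression Multiplicative reduction of base and amplitude
#'   on damaged pixels from `drought_year` onward (0.4 = NDVI scaled by 0.6).
#' @param damage_severity_spread Relative spread of per-pixel damage
#'   severity: each damaged pixel draws its suppression from
#'   `damage_suppression * U(1 - spread, 1 + spread)`. 0 gives every
#'   damaged pixel the identical step change; the default emulates the
#'   severity gradient of real die-off patches.
#' @param mask_error_rate Fraction of damage labels that disagree with the
#'   true suppression (equal numbers of false positives and false
#'   negatives), emulating the misclassification of a change-detection
#'   damage product. 0 makes the label perfect.
#' @param recovery_rate Per-year fractional rebound of the suppression after
#'   the drought year; 0 keeps the step change persistent.
#' @param damage_coupling Strength in `[0, 1]` of the association between
#'   damage probability and aridity (0 = spatially random damage).
#' @param elevation_range_m Length-2 numeric, min and max elevation (m).
#' @param moisture_ndvi_range NDVI spread attributable to the moisture
#'   gradient (wetter pixels have a higher NDVI baseline).
#' @param climate_factor Climate-grid coarsening factor relative to the NDVI
#'   grid (3 emulates a 900 m climate product over a 300 m NDVI grid).
#' @param climate_elev_coupling Unitless multiplier on the elevation
#'   coupling of the climate fields; 1 gives a +35 % precipitation anomaly
#'   per elevation standard deviation and a 6.5 K/km temperature lapse,
#'   0 removes the altitude gradient entirely.
#' @param climate_spatial_sd Relative amplitude of each climate variable's
#'   own smooth spatial noise field.
#' @param climate_noise_sd Relative per-month, per-pixel climate noise.
#' @param dropout_rate Fraction of NDVI cells randomly flagged invalid.
#' @param cellsize Analysis-grid pixel size, metres.
#' @param seed Integer RNG seed; every generated artefact is a pure function
#'   of the parameter set.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(n_rows = 50, n_cols = 50, years = 2017:2020,
                         composites_per_month = 3, ndvi_base = 0.55,
                         ndvi_amplitude = 0.25, peak_doy = 196,
                         noise_sd = 0.02, drought_year = 2018,
                         damage_fraction = 0.3, damage_suppression = 0.4,
                         damage_severity_spread = 0.75, mask_error_rate = 0.02,
                         recovery_rate = 0, damage_coupling = 0.7,
                         elevation_range_m = c(75, 950),
                         moisture_ndvi_range = 0.05, climate_factor = 3,
                         climate_elev_coupling = 1,
                         climate_spatial_sd = 0.15, climate_noise_sd = 0.03,
                         dropout_rate = 0, cellsize = 300, seed = 1) {
  p <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            years = as.integer(years),
            composites_per_month = as.integer(composites_per_month),
            ndvi_base = ndvi_base, ndvi_amplitude = ndvi_amplitude,
            peak_doy = peak_doy, noise_sd = noise_sd,
            drought_year = as.integer(drought_year),
            damage_fraction = damage_fraction,
            damage_suppression = damage_suppression,
            damage_severity_spread = damage_severity_spread,
            mask_error_rate = mask_error_rate,
            recovery_rate = recovery_rate, damage_coupling = damage_coupling,
            elevation_range_m = as.numeric(elevation_range_m),
            moisture_ndvi_range = moisture_ndvi_range,
            climate_factor = as.integer(climate_factor),
            climate_elev_coupling = climate_elev_coupling,
            climate_spatial_sd = climate_spatial_sd,
            climate_noise_sd = climate_noise_sd,
            dropout_rate = dropout_rate, cellsize = cellsize,
            seed = as.integer(seed))
  if (p$n_rows < 1 || p$n_cols < 1) stop("scene must have >= 1 pixel")
  if (length(p$years) < 1) stop("at least one year required")
  if (p$composites_per_month < 1) stop("composites_per_month must be >= 1")
  if (p$damage_fraction < 0 || p$damage_fraction > 1) {
    stop("damage_fraction must be in [0, 1]")
  }
  if (p$damage_suppression < 0 || p$damage_suppression > 1) {
    stop("damage_suppression must be in [0, 1]")
  }
  if (p$damage_coupling < 0 || p$damage_coupling > 1) {
    stop("damage_coupling must be in [0, 1]")
  }
  if (p$damage_severity_spread < 0 || p$damage_severity_spread > 1 ||
      p$damage_suppression * (1 + p$damage_severity_spread) > 1) {
    stop("damage severity must stay within [0, 1]")
  }
  if (p$mask_error_rate < 0 || p$mask_error_rate > 0.5) {
    stop("mask_error_rate must be in [0, 0.5]")
  }
  if (p$noise_sd < 0 || p$dropout_rate < 0 || p$dropout_rate >= 1) {
    stop("noise_sd must be >= 0 and dropout_rate in [0, 1)")
  }
  if (diff(p$elevation_range_m) < 0) stop("elevation range must be ordered")
  hi <- abs(p$ndvi_base) + p$moisture_ndvi_range / 2 + p$ndvi_amplitude
  if (hi > 1) {
    stop("noiseless NDVI signal would leave [-1, 1]; reduce base/amplitude")
  }
  structure(p, class = "scene_params")
}

#' Ground truth of a synthetic scene
#'
#' Builds the static truth layers every generator and test can refer back
#' to: the elevation field (rescaled exactly to `elevation_range_m`), the
#' moisture gradient (higher = wetter, coupled to altitude), the per-pixel
#' pre-drought NDVI baseline, the forest mask, and the damage mask drawn by
#' [generate_damage_mask()].
#'
#' @param params A [scene_params()] object.
#' @return An object of class `scene_truth` with fields `elevation`,
#'   `moisture`, `base`, `amplitude`, `forest`, `damaged` (the label),
#'   `severity` and `suppressed` (the underlying truth), `grid`, `params`.
#' @export
scene_truth <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$n_rows; nc <- params$n_cols
  g <- grid_spec(nr, nc, xmin = 500000, ymin = 5600000,
                 cellsize = params$cellsize)
  fields <- with_seed(params$seed, {
    grad <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    relief <- smooth_field(nr, nc)
    noise <- smooth_field(nr, nc)
    list(grad = grad, relief = relief, noise = noise)
  })
  e <- 1.2 * fields$grad + fields$relief * 0.45
  rng <- range(e)
  if (diff(rng) == 0) {
    elevation <- matrix(mean(params$elevation_range_m), nr, nc)
  } else {
    elevation <- params$elevation_range_m[1] +
      (e - rng[1]) / diff(rng) * diff(params$elevation_range_m)
  }
  ez <- if (stats::sd(elevation) > 0) {
    (elevation - mean(elevation)) / stats::sd(elevation)
  } else matrix(0, nr, nc)
  moisture <- 0.85 * ez + 0.15 * fields$noise
  m01 <- if (diff(range(moisture)) > 0) {
    (moisture - min(moisture)) / diff(range(moisture))
  } else matrix(0.5, nr, nc)
  truth <- structure(
    list(elevation = elevation, moisture = moisture,
         base = params$ndvi_base + params$moisture_ndvi_range * (m01 - 0.5),
         amplitude = matrix(params$ndvi_amplitude, nr, nc),
         forest = matrix(TRUE, nr, nc),
         damaged = NULL, grid = g, params = params),
    class = "scene_truth")
  truth$damaged <- generate_damage_mask(truth, coupling = params$damage_coupling,
                                        damage_fraction = params$damage_fraction,
                                        seed = params$seed + 3000L)
  # per-pixel true suppression severity; the damage label may disagree with
  # it at mask_error_rate (false positives and false negatives in equal
  # number), as a change-detection damage product would
  sev <- matrix(0, nr, nc)
  dmg_idx <- which(truth$damaged)
  k <- length(dmg_idx)
  if (k > 0L && params$damage_suppression > 0) {
    draws <- with_seed(params$seed + 4000L, {
      sv <- params$damage_suppression *
        stats::runif(k, 1 - params$damage_severity_spread,
                     1 + params$damage_severity_spread)
      n_err <- round(params$mask_error_rate * k)
      fp <- if (n_err > 0L) sample(seq_len(k), n_err) else integer(0)
      healthy <- setdiff(which(truth$forest), dmg_idx)
      fn <- if (n_err > 0L && length(healthy) > 0L) {
        sample(healthy, min(n_err, length(healthy)))
      } else integer(0)
      fn_sev <- params$damage_suppression *
        stats::runif(length(fn), 1 - params$damage_severity_spread,
                     1 + params$damage_severity_spread)
      list(sv = sv, fp = fp, fn = fn, fn_sev = fn_sev)
    })
    sev[dmg_idx] <- draws$sv
    sev[dmg_idx[draws$fp]] <- 0
    sev[draws$fn] <- draws$fn_sev
  }
  truth$severity <- sev
  truth$suppressed <- sev > 0
  truth
}

#' Draw a binary damage mask coupled to aridity
#'
#' Damaged pixels are sampled without replacement from the forest pixels,
#' with sampling weights increasing with aridity (the negative of the truth
#' moisture field) when `coupling > 0`; `coupling = 0` gives spatially
#' random damage. Exactly `round(damage_fraction * n_forest)` pixels are
#' positive.
#'
#' @param truth A [scene_truth()] (the `damaged` field is ignored).
#' @param coupling Aridity-coupling strength in `[0, 1]`.
#' @param damage_fraction Fraction of forest pixels to mark; defaults to the
#'   scene parameter.
#' @param seed RNG seed.
#' @return Logical matrix.
#' @export
generate_damage_mask <- function(truth, coupling = NULL, damage_fraction = NULL,
                                 seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  if (is.null(coupling)) coupling <- truth$params$damage_coupling
  if (is.null(damage_fraction)) damage_fraction <- truth$params$damage_fraction
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  forest_idx <- which(truth$forest)
  k <- round(damage_fraction * length(forest_idx))
  mask <- matrix(FALSE, nrow(truth$forest), ncol(truth$forest))
  if (k == 0L) return(mask)
  aridity <- -truth$moisture[forest_idx]
  w <- (1 - coupling) + coupling * (rank(aridity, ties.method = "first") /
                                      length(aridity))^2
  sel <- with_seed(seed, sample(forest_idx, k, prob = w))
  mask[sel] <- TRUE
  mask
}

# dates of the composites of one calendar year
composite_dates <- function(year, per_month) {
  days <- round(seq(5, 25, length.out = per_month))
  if (per_month == 1L) days <- 15L
  as.Date(sprintf("%d-%02d-%02d", year, rep(1:12, each = per_month),
                  rep(days, 12)))
}

# per-pixel multiplier on base and amplitude in a given year
damage_multiplier <- function(params, truth, year) {
  if (year < params$drought_year) {
    return(matrix(1, nrow(truth$severity), ncol(truth$severity)))
  }
  1 - truth$severity *
    (1 - params$recovery_rate)^(year - params$drought_year)
}

#' Generate multi-year NDVI composite stacks
#'
#' Healthy pixels follow `NDVI(t) = base + amplitude * sin(2*pi*(doy -
#' phase)/365) + N(0, noise_sd)` with the seasonal peak at `peak_doy`;
#' damaged pixels have base and amplitude multiplied by `1 -
#' damage_suppression` from the drought year onward (optionally rebounding
#' at `recovery_rate` per year). Values are clipped to `[-1, 1]`; an
#' optional random dropout flags cells invalid.
#'
#' @param params A [scene_params()] object.
#' @param truth Optional [scene_truth()]; built from `params` when omitted.
#' @return A list with `stacks` (named list of [composite_stack()], one per
#'   year) and `truth`.
#' @export
generate_ndvi_stack <- function(params, truth = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(truth)) truth <- scene_truth(params)
  nr <- params$n_rows; nc <- params$n_cols
  phase <- params$peak_doy - 365 / 4
  stacks <- list()
  for (i in seq_along(params$years)) {
    yr <- params$years[i]
    dates <- composite_dates(yr, params$composites_per_month)
    doy <- as.POSIXlt(dates)$yday + 1
    seas <- sin(2 * pi * (doy - phase) / 365)
    mult <- damage_multiplier(params, truth, yr)
    vals <- array(NA_real_, c(length(dates), nr, nc))
    noise <- if (params$noise_sd > 0 || params$dropout_rate > 0) {
      with_seed(params$seed + 1000L + i, {
        n <- if (params$noise_sd > 0) {
          array(stats::rnorm(length(dates) * nr * nc, 0, params$noise_sd),
                c(length(dates), nr, nc))
        } else array(0, c(length(dates), nr, nc))
        drop <- if (params$dropout_rate > 0) {
          array(stats::runif(length(dates) * nr * nc) < params$dropout_rate,
                c(length(dates), nr, nc))
        } else array(FALSE, c(length(dates), nr, nc))
        list(n = n, drop = drop)
      })
    } else {
      list(n = array(0, c(length(dates), nr, nc)),
           drop = array(FALSE, c(length(dates), nr, nc)))
    }
    for (t in seq_along(dates)) {
      vals[t, , ] <- truth$base * mult + truth$amplitude * mult * seas[t] +
        noise$n[t, , ]
    }
    vals <- pmin(pmax(vals, -1), 1)
    vals[noise$drop] <- NA_real_
    stacks[[as.character(yr)]] <- composite_stack(vals, dates, truth$grid)
  }
  list(stacks = stacks, truth = truth)
}

#' Generate monthly climate grids for a scene
#'
#' Produces monthly total precipitation (mm), monthly mean of daily minimum
#' air temperature (deg C) and monthly total sunshine duration (h) on a grid
#' coarsened by `climate_factor` relative to the NDVI grid. Precipitation
#' increases and temperature decreases with elevation, so the de Martonne
#' aridity index is anti-correlated with altitude; the drought year carries
#' a dry, warm, sunny growing season (April--October).
#'
#' @param params A [scene_params()] object.
#' @param truth Optional [scene_truth()]; built from `params` when omitted.
#' @return An object of class `climate_grids`: arrays `precip`, `temp`,
#'   `sun` of shape `[n_months, rows, cols]`, `months` (first-of-month
#'   dates), `grid` (the coarse [grid_spec()]), and `elevation` (coarse).
#' @export
generate_climate_grids <- function(params, truth = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(truth)) truth <- scene_truth(params)
  f <- params$climate_factor
  g <- truth$grid
  nrc <- as.integer(ceiling(g$n_rows / f))
  ncc <- as.integer(ceiling(g$n_cols / f))
  cg <- grid_spec(nrc, ncc, xmin = g$xmin,
                  ymin = grid_ymax(g) - nrc * g$cellsize * f,
                  cellsize = g$cellsize * f, crs = g$crs)
  elev_c <- align_to_grid(truth$elevation, g, cg, "mean_aggregate")
  ez <- if (stats::sd(elev_c) > 0) (elev_c - mean(elev_c)) / stats::sd(elev_c)
        else matrix(0, nrc, ncc)
  nse <- with_seed(params$seed + 2000L, {
    list(p = smooth_field(nrc, ncc), t = smooth_field(nrc, ncc),
         s = smooth_field(nrc, ncc))
  })
  years <- params$years
  n_months <- 12L * length(years)
  mo <- rep(1:12, length(years))
  yr <- rep(years, each = 12)
  months <- as.Date(sprintf("%d-%02d-01", yr, mo))
  growing <- mo >= 4 & mo <= 10
  drought <- yr == params$drought_year & growing

  eps <- with_seed(params$seed + 2500L, {
    if (params$climate_noise_sd > 0) {
      array(stats::rnorm(3L * n_months * nrc * ncc), c(3L, n_months, nrc, ncc))
    } else array(0, c(3L, n_months, nrc, ncc))
  })
  cs <- params$climate_spatial_sd
  ce <- params$climate_elev_coupling
  cn <- params$climate_noise_sd
  precip <- temp <- sun <- array(NA_real_, c(n_months, nrc, ncc))
  lapse_c <- ce * 6.5 / 1000  # deg C per metre, scaled by the coupling
  for (m in seq_len(n_months)) {
    seas_p <- 1 + 0.3 * sin(2 * pi * (mo[m] - 4) / 12)
    p <- 70 * seas_p * (1 + 0.35 * ce * ez + cs * nse$p) *
      (if (drought[m]) 0.55 else 1) * (1 + cn * eps[1, m, , ])
    precip[m, , ] <- pmax(p, 0)
    t0 <- 5 - 7 * cos(2 * pi * (mo[m] - 1) / 12)
    temp[m, , ] <- t0 - lapse_c * (elev_c - min(elev_c)) + 2 * cs * nse$t +
      (if (drought[m]) 1.5 else 0) + 6 * cn * eps[2, m, , ]
    s0 <- 150 - 90 * cos(2 * pi * (mo[m] - 1) / 12)
    s <- s0 * (1 + 0.7 * cs * nse$s - 0.3 * cs * ez) *
      (if (drought[m]) 1.2 else 1) * (1 + cn * eps[3, m, , ])
    sun[m, , ] <- pmax(s, 0)
  }
  structure(list(precip = precip, temp = temp, sun = sun, months = months,
                 grid = cg, elevation = elev_c),
            class = "climate_grids")
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper building the static truth, the per-year NDVI stacks
#' and the monthly climate grids from one parameter set and one seed.
#'
#' @param params A [scene_params()] object.
#' @return A list with `truth`, `stacks`, `climate`.
#' @export
generate_scene <- function(params = scene_params()) {
  truth <- scene_truth(params)
  ndvi <- generate_ndvi_stack(params, truth)
  climate <- generate_climate_grids(params, truth)
  list(truth = truth, stacks = ndvi$stacks, climate = climate)
}
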