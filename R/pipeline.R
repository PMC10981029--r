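# End-to-end workflow: scene (or supplied inputs) -> DHI -> aridity
# zonation -> trends and zonal ratios -> group statistics -> health model,
# with every output written as plain-text rasters/CSV and a JSON manifest.

#' Configuration of a pipeline run
#'
#' @param out_dir Output directory.
#' @param scene A [scene_params()] object describing the synthetic inputs.
#' @param min_valid_fraction Per-pixel valid-composite threshold for the
#'   DHI (see [compute_dhi_year()]).
#' @param trend_method `"theil_sen"` or `"ols"`.
#' @param trend_pct Percentile threshold for [classify_trend()].
#' @param ols_window Moving-window size for [ols_slope()].
#' @param r_max,vif_max Collinearity-filter thresholds.
#' @param thin_distance_m Spatial thinning distance (0 disables).
#' @param seed Run seed (also reseeds the scene).
#' @param write_stacks Also write every NDVI composite raster (many small
#'   files); off by default.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, scene = scene_params(),
                       min_valid_fraction = 0.75,
                       trend_method = c("theil_sen", "ols"),
                       trend_pct = 20, ols_window = 3,
                       r_max = 0.8, vif_max = 5,
                       thin_distance_m = 600, seed = scene$seed,
                       write_stacks = FALSE) {
  trend_method <- match.arg(trend_method)
  if (trend_pct <= 0 || trend_pct >= 50) stop("trend_pct must be in (0, 50)")
  if (r_max <= 0 || r_max > 1) stop("r_max must be in (0, 1]")
  if (vif_max < 1) stop("vif_max must be >= 1")
  if (thin_distance_m < 0) stop("thin_distance_m must be >= 0")
  scene$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, scene = scene,
                 min_valid_fraction = min_valid_fraction,
                 trend_method = trend_method, trend_pct = trend_pct,
                 ols_window = ols_window, r_max = r_max, vif_max = vif_max,
                 thin_distance_m = thin_distance_m, seed = as.integer(seed),
                 write_stacks = write_stacks),
            class = "run_config")
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full drought-assessment pipeline
#'
#' Generates (or loads) the inputs, computes the per-year and long-term DHI
#' layers and the false-colour composite, derives monthly dMI, its
#' aggregates and the four aridity zones, estimates per-pixel trends and
#' the positive-to-negative ratio table by zone and health stratum, runs
#' the yearly damaged vs non-damaged ANOVA/Tukey comparisons and the
#' between-year contrasts, assembles and filters the sample table and fits
#' the logistic health model. All tables are written as CSV, rasters as
#' ASCII grids, and a JSON manifest records the configuration, seed, drop
#' counts and headline results.
#'
#' @param config A [run_config()].
#' @param scene Optional pre-generated scene (list with `truth`, `stacks`,
#'   `climate`) to reuse; generated from `config$scene` when omitted.
#' @return Invisibly, a list with every intermediate object (`scene`,
#'   `dhi`, `aggregates`, `zones`, `trends`, `ratios`, `anova`, `tukey`,
#'   `year_change`, `model`, `manifest`).
#' @export
run_pipeline <- function(config, scene = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  # --- inputs -----------------------------------------------------------
  if (is.null(scene)) scene <- generate_scene(config$scene)
  truth <- scene$truth
  g <- truth$grid
  forest <- truth$forest
  n_composites <- sum(vapply(scene$stacks, function(s) length(s$dates), 0L))
  if (config$write_stacks) {
    for (yr in names(scene$stacks)) {
      write_stack(scene$stacks[[yr]], out("ndvi"), prefix = paste0("ndvi_", yr))
    }
  }

  # --- DHI --------------------------------------------------------------
  dhi <- compute_dhi_multiyear(scene$stacks, config$min_valid_fraction)
  for (yr in names(dhi$years)) {
    s <- dhi$years[[yr]]
    write_raster(s$cum, g, out(sprintf("dhi_cum_%s.asc", yr)))
    write_raster(s$minimum, g, out(sprintf("dhi_min_%s.asc", yr)))
    write_raster(s$var, g, out(sprintf("dhi_var_%s.asc", yr)))
  }
  write_raster(dhi$longterm$cum, g, out("dhi_cum_longterm.asc"))
  write_raster(dhi$longterm$minimum, g, out("dhi_min_longterm.asc"))
  write_raster(dhi$longterm$var, g, out("dhi_var_longterm.asc"))
  total <- dhi_total_composite(dhi)
  for (b in 1:3) {
    write_raster(total[, , b], g,
                 out(sprintf("dhi_total_band%d.asc", b)))
  }
  comp_cor <- dhi_component_correlations(dhi, mask = forest)

  # --- climate, aridity zonation ---------------------------------------
  aggs_c <- climate_aggregates(scene$climate)
  cg <- scene$climate$grid
  agg_names <- grep("^(precip|temp|sun|dmi)_(cum|min|var)$", names(aggs_c),
                    value = TRUE)
  aggs <- lapply(aggs_c[agg_names], align_to_grid, src_grid = cg,
                 target = g, method = "bilinear")
  zones <- classify_aridity(aggs$dmi_cum, mask = forest)
  zmat <- zones$classes
  write_raster(zmat * 1.0, g, out("aridity_zones.asc"),
               extra = list(legend = as.list(stats::setNames(1:4, zones$labels)),
                            breaks = zones$breaks))
  alt_reg <- altitude_drought_regression(truth$elevation, aggs$dmi_cum,
                                         health = truth$damaged, mask = forest)
  write_csv_plain(alt_reg, out("altitude_drought_regression.csv"))

  # --- trends and zonal ratios -----------------------------------------
  components <- c(cum = "dhi_cum", minimum = "dhi_min", var = "dhi_var")
  years_n <- as.integer(names(dhi$years))
  trends <- list()
  ratios <- list()
  for (i in seq_along(components)) {
    comp_label <- unname(components[i])
    a <- annual_array(dhi, names(components)[i])
    slope <- if (config$trend_method == "theil_sen") {
      theil_sen_slope(a, years_n)
    } else {
      ols_slope(a, years_n, config$ols_window)
    }
    tm <- classify_trend(slope, mask = forest, pct = config$trend_pct,
                         method = config$trend_method)
    trends[[comp_label]] <- tm
    write_raster(tm$slope, g, out(sprintf("trend_slope_%s.asc", comp_label)))
    write_raster(tm$classes * 1.0, g,
                 out(sprintf("trend_class_%s.asc", comp_label)))
    ratios[[comp_label]] <- ratio_by_zone(tm, zones, truth$damaged,
                                             mask = forest,
                                             component = comp_label)
  }
  ratio_table <- do.call(rbind, ratios)
  rownames(ratio_table) <- NULL
  write_csv_plain(ratio_table, out("trend_ratios.csv"))

  # --- group statistics -------------------------------------------------
  anova_rows <- list()
  tukey_rows <- list()
  year_change <- list()
  sh_fail <- 0L
  for (i in seq_along(components)) {
    comp <- names(components)[i]
    comp_label <- unname(components[i])
    per_year_damaged <- list()
    for (yr in names(dhi$years)) {
      s <- dhi$years[[yr]]
      keep <- s$valid & forest & !is.na(s[[comp]])
      vals <- s[[comp]][keep]
      grp <- ifelse(truth$damaged[keep], "damaged", "non-damaged")
      av <- anova_oneway(vals, grp)
      chk <- check_assumptions(av$residuals, grp)
      if (chk$shapiro_p < 0.01) sh_fail <- sh_fail + 1L
      tk <- tukey_contrasts(vals, grp)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        component = comp_label, year = yr, f = av$f, p = av$p,
        shapiro_p = chk$shapiro_p, bartlett_p = chk$bartlett_p)
      tukey_rows[[length(tukey_rows) + 1L]] <- cbind(
        component = comp_label, year = yr, tk$contrasts)
      per_year_damaged[[yr]] <- vals[grp == "damaged"]
    }
    yc <- year_change_contrasts(
      unlist(per_year_damaged),
      rep(names(per_year_damaged), lengths(per_year_damaged)))
    year_change[[comp_label]] <- yc
    tukey_rows[[length(tukey_rows) + 1L]] <- cbind(
      component = comp_label, year = "damaged-change", yc$contrasts)
  }
  anova_table <- do.call(rbind, anova_rows)
  tukey_table <- do.call(rbind, tukey_rows)
  write_csv_plain(anova_table, out("anova_by_year.csv"))
  write_csv_plain(tukey_table, out("tukey_contrasts.csv"))
  climate_cor <- spearman_with_climate(dhi, aggs[agg_names], mask = forest)

  # --- health model -----------------------------------------------------
  dem_fine <- truth$elevation
  tab <- build_sample_table(dhi, aggs[agg_names], dem_fine, truth$damaged,
                            forest = forest)
  n_initial_predictors <- length(predictor_names(tab))
  tab_thin <- spatial_thin(tab, config$thin_distance_m,
                           seed = config$seed + 17L)
  tab_r <- filter_correlated(tab_thin, config$r_max)
  tab_v <- filter_vif(tab_r, config$vif_max)
  fit <- fit_logistic(tab_v)
  imp <- variable_importance(fit)
  moran <- residual_morans_i(fit, tab_v)
  write_csv_plain(tab_v, out("sample_table.csv"))
  write_csv_plain(fit$coefficients, out("model_coefficients.csv"))
  write_csv_plain(imp, out("variable_importance.csv"))

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    config = config[setdiff(names(config), "scene")],
    scene_params = unclass(config$scene),
    seed = config$seed,
    r_version = as.character(getRversion()),
    n_composites = n_composites,
    n_composites_per_year = vapply(scene$stacks,
                                   function(s) length(s$dates), 0L),
    grid = unclass(g),
    component_correlations = comp_cor,
    zone_breaks = zones$breaks,
    zone_counts = as.list(zones$counts),
    sample_drop_log = as.list(attr(tab, "drop_log")),
    n_samples_before_thinning = nrow(tab),
    n_samples = nrow(tab_v),
    n_initial_predictors = n_initial_predictors,
    removed_correlated = attr(tab_r, "removed")$variable,
    removed_vif = attr(tab_v, "removed")$variable,
    retained_predictors = fit$variables,
    mcfadden_r2 = fit$mcfadden,
    model_converged = fit$converged,
    separation = fit$separation,
    residual_moran_i = moran$moran_i,
    residual_moran_p = moran$p,
    anova_shapiro_failures = sh_fail)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, matrix = "rowmajor")

  invisible(list(scene = scene, dhi = dhi, component_correlations = comp_cor,
                 aggregates = aggs, zones = zones,
                 altitude_regression = alt_reg, trends = trends,
                 ratios = ratio_table, anova = anova_table,
                 tukey = tukey_table, year_change = year_change,
                 climate_correlations = climate_cor,
                 sample_table = tab_v, model = fit, importance = imp,
                 moran = moran, manifest = manifest))
}
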