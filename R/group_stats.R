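# Group comparisons of DHI components: one-way ANOVA with assumption
# checks, Tukey(-Kramer) simultaneous contrasts, and Spearman correlations
# with climate aggregates.

#' One-way analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels: at least 2 levels,
#'   each with at least 2 observations.
#' @return A list with `f`, `p`, `df` (between, within), `residuals` and
#'   the underlying `aov` fit.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  if (all(tapply(values, g, stats::sd) == 0)) {
    stop("zero within-group variance in every group")
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  list(f = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
       residuals = stats::residuals(fit), fit = fit)
}

#' ANOVA assumption checks
#'
#' Shapiro-Wilk normality test on the residuals, Bartlett's test of equal
#' group variances, and the ordered quantile pairs of a normal Q-Q plot.
#' No automatic accept/reject decision is taken.
#'
#' @param residuals Residual vector from [anova_oneway()].
#' @param groups Group labels aligned with the residuals.
#' @param max_shapiro Shapiro-Wilk sample cap (the test is defined for
#'   n <= 5000); larger residual vectors are deterministically subsampled.
#' @return A list with `shapiro_p`, `bartlett_p` and `qq` (list of `x`
#'   theoretical and `y` sample quantiles).
#' @export
check_assumptions <- function(residuals, groups, max_shapiro = 5000L) {
  if (length(residuals) < 3L) stop("need at least 3 residuals")
  if (stats::sd(residuals) == 0) stop("constant residuals")
  r <- residuals
  if (length(r) > max_shapiro) {
    r <- sort(r)[round(seq(1, length(r), length.out = max_shapiro))]
  }
  sh <- stats::shapiro.test(r)
  bt <- stats::bartlett.test(residuals, factor(groups))
  qq <- stats::qqnorm(residuals, plot.it = FALSE)
  o <- order(qq$x)
  list(shapiro_p = sh$p.value, bartlett_p = bt$p.value,
       qq = list(x = qq$x[o], y = qq$y[o]))
}

tidy_tukey <- function(ht, level) {
  tab <- ht[[1]]
  res <- data.frame(contrast = rownames(tab), diff = tab[, "diff"],
                    lower = tab[, "lwr"], upper = tab[, "upr"],
                    p_adj = tab[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(contrasts = res, level = level), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey simultaneous contrasts (%.0f%% family confidence)\n",
              100 * x$level))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Tukey simultaneous pairwise contrasts
#'
#' Tukey-Kramer simultaneous confidence intervals and adjusted p-values for
#' all pairwise differences of group means (valid for unbalanced groups).
#' An interval that excludes zero marks a significant pair at the family
#' level.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, every group of size >= 2.
#' @param level Family confidence level (default 0.95).
#' @return A `tukey_result`: data frame `contrasts` (contrast, diff, lower,
#'   upper, p_adj) and `level`.
#' @export
tukey_contrasts <- function(values, groups, level = 0.95) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ g)
  tidy_tukey(stats::TukeyHSD(fit, conf.level = level), level)
}

#' Between-year change contrasts for one stratum
#'
#' Runs the Tukey machinery with calendar years as the groups, giving every
#' year-pair contrast (e.g. 2019 vs 2017) with simultaneous intervals --
#' the tool for asking whether a component rebounded after the drought.
#'
#' @param values Numeric response vector (e.g. damaged-pixel cumulative DHI
#'   pooled over years).
#' @param years Year label per observation.
#' @param level Family confidence level.
#' @return A `tukey_result`; contrast `"B-A"` is mean(year B) - mean(year
#'   A).
#' @export
year_change_contrasts <- function(values, years, level = 0.95) {
  tukey_contrasts(values, factor(years), level = level)
}

#' Spearman correlations of DHI components with climate aggregates
#'
#' @param multiyear A `dhi_multiyear` object (long-term layers are used).
#' @param aggregates Named list of climate-aggregate matrices aligned to
#'   the DHI grid.
#' @param mask Optional logical matrix restricting the pixels.
#' @return Matrix of Spearman coefficients, rows = DHI components, columns
#'   = climate aggregates; constant variables give `NA` with a warning.
#' @export
spearman_with_climate <- function(multiyear, aggregates, mask = NULL) {
  stopifnot(inherits(multiyear, "dhi_multiyear"))
  lt <- multiyear$longterm
  comp <- list(dhi_cum = lt$cum, dhi_min = lt$minimum, dhi_var = lt$var)
  keep <- lt$valid & !is.na(lt$var)
  for (a in aggregates) keep <- keep & !is.na(a)
  if (!is.null(mask)) keep <- keep & mask
  if (sum(keep) < 3L) stop("need at least 3 valid pixels")
  out <- matrix(NA_real_, length(comp), length(aggregates),
                dimnames = list(names(comp), names(aggregates)))
  const_c <- vapply(comp, function(m) stats::sd(m[keep]) == 0, TRUE)
  const_a <- vapply(aggregates, function(m) stats::sd(m[keep]) == 0, TRUE)
  if (any(const_c) || any(const_a)) {
    warning("constant variable(s) in Spearman correlation: ",
            paste(c(names(comp)[const_c], names(aggregates)[const_a]),
                  collapse = ", "))
  }
  for (i in which(!const_c)) {
    ci <- comp[[i]][keep]
    for (j in which(!const_a)) {
      out[i, j] <- stats::cor(ci, aggregates[[j]][keep], method = "spearman")
    }
  }
  out
}
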