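# Logistic model of forest health status: sample-table assembly, spatial
# thinning, collinearity filtering (|r| then VIF), the binomial GLM
#   p(X) = exp(b0 + sum_i b_i X_i) / (1 + exp(b0 + sum_i b_i X_i)),
# McFadden's pseudo R-squared and |z|-based variable importance.

sample_meta_cols <- c("row", "col", "x", "y", "label")

predictor_names <- function(table) setdiff(names(table), sample_meta_cols)

#' Assemble the per-pixel sample table
#'
#' One row per forest pixel where every layer is valid: the three long-term
#' DHI components, the twelve climate aggregates (cumulative / minimum /
#' variation of precipitation, temperature, sunshine and monthly dMI),
#' elevation, and the binary health label (1 = damaged) -- sixteen candidate
#' predictors in total. Counts of pixels dropped per reason are attached as
#' the `"drop_log"` attribute.
#'
#' @param multiyear A `dhi_multiyear` object.
#' @param aggregates Named list of climate-aggregate matrices aligned to
#'   the DHI grid (as produced by [climate_aggregates()] after
#'   [align_to_grid()]).
#' @param dem Elevation matrix on the DHI grid.
#' @param damaged Logical damage matrix.
#' @param forest Optional logical forest mask; defaults to all pixels.
#' @return A data frame (`sample_table`) with coordinate columns, `label`
#'   and the predictor columns.
#' @export
build_sample_table <- function(multiyear, aggregates, dem, damaged,
                               forest = NULL) {
  stopifnot(inherits(multiyear, "dhi_multiyear"))
  g <- multiyear$grid
  lt <- multiyear$longterm
  layers <- c(list(dhi_cum = lt$cum, dhi_min = lt$minimum, dhi_var = lt$var),
              aggregates, list(dem = dem))
  if (is.null(forest)) forest <- matrix(TRUE, g$n_rows, g$n_cols)
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), c(g$n_rows, g$n_cols))) {
      stop("layer not aligned to the analysis grid: ", nm)
    }
  }
  n_all <- sum(forest, na.rm = TRUE)
  keep <- forest & !is.na(forest)
  drop_log <- c(outside_forest = g$n_rows * g$n_cols - n_all)
  for (nm in names(layers)) {
    bad <- keep & is.na(layers[[nm]])
    drop_log[paste0("invalid_", nm)] <- sum(bad)
    keep <- keep & !bad
  }
  if (!any(keep)) stop("no valid sample pixels remain")
  idx <- which(keep, arr.ind = TRUE)
  cc <- cell_centers(g)
  tab <- data.frame(row = idx[, 1], col = idx[, 2],
                    x = cc$x[idx[, 2]], y = cc$y[idx[, 1]],
                    label = as.integer(damaged[keep]))
  for (nm in names(layers)) tab[[nm]] <- layers[[nm]][keep]
  attr(tab, "drop_log") <- drop_log
  class(tab) <- c("sample_table", "data.frame")
  tab
}

#' Spatially thin a sample table
#'
#' Greedy random thinning: while any two retained samples are closer than
#' `min_distance_m`, the sample with the most neighbours inside the radius
#' is removed (ties broken at random under the seed). The result has no
#' pair closer than the threshold, with a maximal-effort retained count.
#'
#' @param table A `sample_table` with `x`/`y` coordinates in metres.
#' @param min_distance_m Minimum allowed pairwise distance; 0 is a no-op.
#' @param seed RNG seed for the tie-breaks.
#' @return The thinned table; removed row count in attribute
#'   `"n_removed"`.
#' @export
spatial_thin <- function(table, min_distance_m, seed = 1L) {
  if (min_distance_m < 0) stop("min_distance_m must be >= 0")
  n <- nrow(table)
  if (min_distance_m == 0 || n < 2L) {
    attr(table, "n_removed") <- 0L
    return(table)
  }
  d <- as.matrix(stats::dist(cbind(table$x, table$y)))
  adj <- d < min_distance_m
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  deg <- rowSums(adj)
  with_seed(seed, {
    while (TRUE) {
      mx <- max(deg[alive])
      if (mx == 0) break
      cand <- which(alive & deg == mx)
      drop <- if (length(cand) == 1L) cand else sample(cand, 1L)
      alive[drop] <- FALSE
      deg[adj[, drop]] <- deg[adj[, drop]] - 1L
      deg[drop] <- 0L
    }
  })
  out <- table[alive, , drop = FALSE]
  attr(out, "drop_log") <- attr(table, "drop_log")
  attr(out, "n_removed") <- sum(!alive)
  class(out) <- class(table)
  out
}

#' Remove strongly intercorrelated predictors
#'
#' While any predictor pair has `|Pearson r| > r_max`, the member of the
#' worst offending pair with the larger mean absolute correlation to all
#' other predictors is dropped (alphabetical tie-break). Deterministic.
#'
#' @param table A `sample_table`.
#' @param r_max Correlation threshold (default 0.8).
#' @return The filtered table; attribute `"removed"` lists dropped
#'   predictors with the `|r|` that triggered each removal.
#' @export
filter_correlated <- function(table, r_max = 0.8) {
  preds <- predictor_names(table)
  if (length(preds) < 2L) stop("need at least 2 predictors")
  removed <- data.frame(variable = character(), abs_r = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    cm <- abs(stats::cor(table[preds]))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= r_max || length(preds) < 2L) break
    pair <- which(cm == worst, arr.ind = TRUE)[1, ]
    cand <- colnames(cm)[pair]
    mean_abs <- colMeans(cm)[cand]
    drop <- cand[order(-mean_abs, cand)][1]
    removed <- rbind(removed, data.frame(variable = drop, abs_r = worst,
                                         stringsAsFactors = FALSE))
    preds <- setdiff(preds, drop)
  }
  out <- table[c(sample_meta_cols, preds)]
  attr(out, "drop_log") <- attr(table, "drop_log")
  attr(out, "removed") <- removed
  class(out) <- class(table)
  out
}

# VIF_j = 1 / (1 - R^2_j) from regressing predictor j on all the others
vif_values <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    if (ncol(x) == 1L) return(1)
    fit <- stats::lm(x[, j] ~ ., data = as.data.frame(x[, -j, drop = FALSE]))
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Remove predictors with a high variance inflation factor
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the auxiliary regression of predictor `j`
#' on all others. The largest-VIF predictor is removed iteratively until
#' all remaining VIFs are `<= vif_max`; perfect collinearity yields an
#' infinite VIF and is handled by removal rather than an error.
#'
#' @param table A `sample_table`.
#' @param vif_max VIF threshold (default 5).
#' @return The filtered table; attribute `"removed"` lists dropped
#'   predictors and their VIF at removal.
#' @export
filter_vif <- function(table, vif_max = 5) {
  preds <- predictor_names(table)
  if (length(preds) < 1L) stop("need at least 1 predictor")
  if (length(preds) == 1L) {
    # a lone predictor has VIF 1 by definition and is always retained
    attr(table, "removed") <- data.frame(variable = character(),
                                         vif = numeric(),
                                         stringsAsFactors = FALSE)
    return(table)
  }
  if (nrow(table) <= length(preds)) stop("need more samples than predictors")
  removed <- data.frame(variable = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    if (length(preds) < 2L) break
    v <- vif_values(as.matrix(table[preds]))
    names(v) <- preds
    if (max(v) <= vif_max) break
    drop <- names(which.max(v))
    removed <- rbind(removed, data.frame(variable = drop, vif = max(v),
                                         stringsAsFactors = FALSE))
    preds <- setdiff(preds, drop)
  }
  out <- table[c(sample_meta_cols, preds)]
  attr(out, "drop_log") <- attr(table, "drop_log")
  attr(out, "removed") <- removed
  class(out) <- class(table)
  out
}

#' Fit the binomial logistic model of health status
#'
#' Maximum-likelihood fit of the damage probability on the retained
#' predictors. Predictors are standardized for the IRLS iterations and the
#' coefficients and their full covariance are mapped back to the raw scale
#' by the exact affine transform, so the reported raw-scale estimates and
#' standard errors equal those of a direct raw-data fit. Perfect
#' separation and non-convergence are detected and recorded, not silently
#' ignored.
#'
#' @param table A filtered `sample_table` with both classes present.
#' @return An object of class `model_fit`: `coefficients` data frame
#'   (term, estimate, std_error, z, p, estimate_std), log-likelihoods
#'   `ll_fit` / `ll_null`, `mcfadden`, `converged`, `separation`, `n`,
#'   `variables`.
#' @export
fit_logistic <- function(table) {
  preds <- predictor_names(table)
  y <- table$label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(table[preds])
  sdev_all <- if (length(preds)) apply(x, 2L, stats::sd) else numeric(0)
  const <- sdev_all == 0
  active <- preds[!const]   # constant columns carry no information
  x <- x[, !const, drop = FALSE]
  mu <- if (length(active)) colMeans(x) else numeric(0)
  sdev <- sdev_all[!const]
  xs <- if (length(active)) {
    sweep(sweep(x, 2L, mu), 2L, sdev, "/")
  } else matrix(numeric(0), nrow(table), 0)
  df <- data.frame(y = y, xs)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("did not converge", msg)) {
        # recorded via fit$converged; not an exception
        invokeRestart("muffleWarning")
      }
    })
  bs <- stats::coef(fit)
  vc <- stats::vcov(fit)
  # affine map standardized -> raw: b_j = bs_j / sd_j ; b0 = bs0 - sum bs_j mu_j / sd_j
  A <- diag(c(1, 1 / sdev), nrow = 1 + length(active))
  if (length(active)) A[1, -1] <- -mu / sdev
  b_raw <- as.vector(A %*% bs)
  v_raw <- A %*% vc %*% t(A)
  se <- sqrt(diag(v_raw))
  z <- b_raw / se
  pv <- 2 * stats::pnorm(-abs(z))
  ll_fit <- as.numeric(stats::logLik(fit))
  ll_null <- as.numeric(stats::logLik(
    stats::glm(y ~ 1, family = stats::binomial())))
  terms_all <- c("(Intercept)", preds)
  lookup <- match(terms_all, c("(Intercept)", active))
  coefs <- data.frame(term = terms_all,
                      estimate = ifelse(is.na(lookup), 0, b_raw[lookup]),
                      std_error = se[lookup], z = z[lookup], p = pv[lookup],
                      estimate_std = ifelse(is.na(lookup), 0,
                                            unname(bs)[lookup]),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, ll_fit = ll_fit, ll_null = ll_null,
                 mcfadden = 1 - ll_fit / ll_null,
                 converged = fit$converged, separation = sep,
                 n = nrow(table), variables = preds, glm = fit,
                 center = mu, scale = sdev),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Binomial logistic health model: n = %d, %d predictor(s)\n",
              x$n, length(x$variables)))
  print(x$coefficients[c("term", "estimate", "std_error", "z", "p")],
        digits = 4)
  cat(sprintf("McFadden R2 = %.4f%s%s\n", x$mcfadden,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [separation detected]" else ""))
  invisible(x)
}

#' McFadden's pseudo R-squared
#'
#' `1 - LL_fit / LL_null`; 0 for an intercept-only model, approaching 1 as
#' the model approaches perfect prediction. Values above 0.40 are
#' conventionally read as a very good fit.
#'
#' @param fit A `model_fit`.
#' @return A single number.
#' @export
mcfadden_r2 <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$ll_null == 0) stop("degenerate null log-likelihood")
  1 - fit$ll_fit / fit$ll_null
}

#' Rank predictors by importance
#'
#' Importance of each retained predictor is the absolute Wald z statistic
#' (the GLM convention of the usual importance tooling), so the importance
#' ranking is exactly the ascending p-value ranking.
#'
#' @param fit A `model_fit`.
#' @return Data frame `variable`, `importance`, `rank`, sorted by
#'   descending importance.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  out <- data.frame(variable = cf$term, importance = abs(cf$z),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$variable), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Moran's I spatial autocorrelation of model residuals
#'
#' Inverse-distance weighted Moran's I of the response residuals, with a
#' normal-approximation p-value -- a diagnostic for residual spatial
#' structure after thinning, reported alongside the fit rather than used as
#' a gate.
#'
#' @param fit A `model_fit`.
#' @param table The `sample_table` the model was fitted on.
#' @param max_n Cap on the number of samples used (deterministic
#'   subsample) to bound the n^2 weight matrix.
#' @return List with `moran_i`, `expected`, `p`.
#' @export
residual_morans_i <- function(fit, table, max_n = 1500L) {
  stopifnot(inherits(fit, "model_fit"))
  r <- table$label - stats::fitted(fit$glm)
  idx <- seq_len(nrow(table))
  if (length(idx) > max_n) idx <- round(seq(1, length(idx), length.out = max_n))
  r <- r[idx]
  d <- as.matrix(stats::dist(cbind(table$x[idx], table$y[idx])))
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  n <- length(r)
  z <- r - mean(r)
  s0 <- sum(w)
  i_obs <- n / s0 * sum(w * outer(z, z)) / sum(z^2)
  e_i <- -1 / (n - 1)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / (sum(z^2)^2)
  var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
              b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
  zscore <- (i_obs - e_i) / sqrt(var_i)
  list(moran_i = i_obs, expected = e_i, p = 2 * stats::pnorm(-abs(zscore)))
}
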