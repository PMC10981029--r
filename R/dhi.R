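# Dynamic Habitat Index components. For a pixel's within-year productivity
# series p_t (here NDVI), the three components are
#   cumulative  = sum(p_t)          annual productivity
#   minimum     = min(p_t)          minimum cover
#   variation   = sd(p_t)/mean(p_t) seasonality (coefficient of variation)
# sd is the sample standard deviation (n - 1 denominator).

#' Compute the three DHI components for one year
#'
#' Components are computed over the valid composites of each pixel. The
#' cumulative component is rescaled by `n_total / n_valid` so gap-affected
#' pixels remain comparable to complete ones; pixels whose valid fraction
#' falls below `min_valid_fraction` (or with fewer than two valid
#' composites) are masked. The variation component is additionally masked
#' where the mean productivity is not positive, where a coefficient of
#' variation is not meaningful.
#'
#' @param stack A [composite_stack()] covering exactly one calendar year.
#' @param min_valid_fraction Minimum fraction of valid composites per pixel,
#'   in `(0, 1]`.
#' @return An object of class `dhi_layers`: matrices `cum`, `minimum`,
#'   `var`, logical `valid`, integer `n_valid`, plus `year`, `n_composites`
#'   and `grid`.
#' @export
compute_dhi_year <- function(stack, min_valid_fraction = 0.75) {
  stopifnot(inherits(stack, "composite_stack"))
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop("min_valid_fraction must be in (0, 1]")
  }
  yrs <- unique(format(stack$dates, "%Y"))
  if (length(yrs) != 1L) {
    stop("stack must cover exactly one calendar year, found: ",
         paste(yrs, collapse = ", "))
  }
  d <- dim(stack$values)
  n_t <- d[1]
  if (n_t == 0L) stop("empty composite stack")
  npix <- d[2] * d[3]
  x <- matrix(stack$values, n_t, npix)       # [time, pixel]
  ok <- matrix(stack$valid, n_t, npix) & !is.na(x)
  x0 <- ifelse(ok, x, 0)

  n_valid <- colSums(ok)
  vsum <- colSums(x0)
  mu <- vsum / n_valid
  # two-pass sample sd over the valid entries
  dev2 <- (x - rep(mu, each = n_t))^2
  dev2[!ok] <- 0
  s <- sqrt(colSums(dev2) / pmax(n_valid - 1, 1))

  valid <- n_valid >= min_valid_fraction * n_t & n_valid >= 2L
  cum <- ifelse(valid, vsum * n_t / n_valid, NA_real_)
  xmin <- x
  xmin[!ok] <- Inf
  minimum <- apply(xmin, 2L, min)
  minimum[!valid | !is.finite(minimum)] <- NA_real_
  cv <- ifelse(valid & mu > 0, s / mu, NA_real_)

  shape <- c(d[2], d[3])
  structure(list(
    year = as.integer(yrs),
    cum = matrix(cum, shape[1], shape[2]),
    minimum = matrix(minimum, shape[1], shape[2]),
    var = matrix(cv, shape[1], shape[2]),
    valid = matrix(valid, shape[1], shape[2]),
    n_valid = matrix(as.integer(n_valid), shape[1], shape[2]),
    n_composites = n_t, grid = stack$grid), class = "dhi_layers")
}

#' @export
print.dhi_layers <- function(x, ...) {
  cat(sprintf("dhi_layers %d: %d x %d pixels, %d composites, %d valid\n",
              x$year, x$grid$n_rows, x$grid$n_cols, x$n_composites,
              sum(x$valid)))
  invisible(x)
}

#' Compute per-year DHI layers and the long-term layer
#'
#' The long-term layer of each component is the element-wise median over the
#' years, defined only where at least half of the years are valid.
#'
#' @param stacks List of [composite_stack()], one per year.
#' @param min_valid_fraction Passed to [compute_dhi_year()].
#' @return An object of class `dhi_multiyear`: `years` (list of
#'   `dhi_layers`, named by year) and `longterm` (list with `cum`,
#'   `minimum`, `var`, `valid`).
#' @export
compute_dhi_multiyear <- function(stacks, min_valid_fraction = 0.75) {
  if (length(stacks) < 1L) stop("at least one yearly stack required")
  sets <- lapply(stacks, compute_dhi_year, min_valid_fraction = min_valid_fraction)
  g <- sets[[1]]$grid
  for (s in sets[-1]) stop_if_grid_mismatch(g, s$grid, "yearly stacks")
  names(sets) <- vapply(sets, function(s) as.character(s$year), "")
  ny <- length(sets)
  med_layer <- function(component) {
    a <- array(NA_real_, c(ny, g$n_rows, g$n_cols))
    for (i in seq_len(ny)) a[i, , ] <- sets[[i]][[component]]
    m <- apply(a, c(2, 3), stats::median, na.rm = TRUE)
    nok <- apply(!is.na(a), c(2, 3), sum)
    m[nok < ny / 2] <- NA_real_
    m
  }
  lt <- list(cum = med_layer("cum"), minimum = med_layer("minimum"),
             var = med_layer("var"))
  lt$valid <- !is.na(lt$cum) & !is.na(lt$minimum)
  structure(list(years = sets, longterm = lt, grid = g),
            class = "dhi_multiyear")
}

#' Merge the three components into a false-colour composite
#'
#' Cumulative productivity maps to the red band, minimum cover to green and
#' seasonality to blue, each min--max stretched over the valid pixels to
#' `[0, 255]`. High-seasonality, low-productivity pixels therefore appear
#' blueish, productive seasonal pixels reddish purple.
#'
#' @param set A `dhi_layers` or `dhi_multiyear` (its long-term layer).
#' @return Numeric array `[rows, cols, 3]` in `[0, 255]`, `NA` where
#'   invalid.
#' @export
dhi_total_composite <- function(set) {
  layers <- if (inherits(set, "dhi_multiyear")) {
    set$longterm[c("cum", "minimum", "var")]
  } else if (inherits(set, "dhi_layers")) {
    set[c("cum", "minimum", "var")]
  } else stop("need a dhi_layers or dhi_multiyear object")
  stretch <- function(m) {
    rng <- suppressWarnings(range(m, na.rm = TRUE))
    if (!is.finite(rng[1]) || rng[1] == rng[2]) {
      out <- m
      out[!is.na(out)] <- 0
      return(out)
    }
    (m - rng[1]) / (rng[2] - rng[1]) * 255
  }
  out <- array(NA_real_, c(nrow(layers[[1]]), ncol(layers[[1]]), 3L))
  for (b in 1:3) out[, , b] <- stretch(layers[[b]])
  out
}

#' Spearman correlations among the DHI components
#'
#' Rank correlations over the valid (optionally masked) pixels, pooled
#' across years for a multi-year set.
#'
#' @param sets A `dhi_layers` or `dhi_multiyear` object.
#' @param mask Optional logical matrix restricting the pixels.
#' @return Symmetric 3x3 matrix with unit diagonal; entries involving a
#'   constant component are `NA` with a warning.
#' @export
dhi_component_correlations <- function(sets, mask = NULL) {
  sets_list <- if (inherits(sets, "dhi_multiyear")) sets$years else list(sets)
  pull <- function(component) {
    unlist(lapply(sets_list, function(s) {
      keep <- s$valid & !is.na(s$var)
      if (!is.null(mask)) keep <- keep & mask
      s[[component]][keep]
    }))
  }
  m <- cbind(cum = pull("cum"), minimum = pull("minimum"), var = pull("var"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 valid pixels")
  const <- apply(m, 2L, function(v) stats::sd(v) == 0)
  res <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant component(s): ", paste(colnames(m)[const], collapse = ", "),
            "; correlations undefined")
    res[const, ] <- NA_real_
    res[, const] <- NA_real_
  }
  diag(res) <- 1
  res
}
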