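# Per-pixel multi-year trends and their zonal summary. Slopes are in DHI
# units per year; the trend class raster codes negative = -1, indifferent =
# 0, positive = +1.

# stack per-year component layers into [year, row, col]
annual_array <- function(multiyear, component = c("cum", "minimum", "var")) {
  component <- match.arg(component)
  stopifnot(inherits(multiyear, "dhi_multiyear"))
  sets <- multiyear$years
  g <- multiyear$grid
  a <- array(NA_real_, c(length(sets), g$n_rows, g$n_cols))
  for (i in seq_along(sets)) a[i, , ] <- sets[[i]][[component]]
  attr(a, "years") <- as.integer(names(sets))
  a
}

#' Theil-Sen trend slope per pixel
#'
#' The slope of each pixel is the median of all pairwise slopes
#' `(y_j - y_i) / (t_j - t_i)` over its valid years -- robust to outliers
#' and to missing years. Pixels with fewer than two valid years are masked.
#'
#' @param values Numeric array `[year, row, col]`.
#' @param years Numeric vector of year labels, strictly increasing.
#' @return Matrix of slopes.
#' @export
theil_sen_slope <- function(values, years) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (length(years) != d[1]) stop("one year label per layer required")
  if (anyDuplicated(years)) stop("duplicate year timestamps")
  x <- matrix(values, d[1], d[2] * d[3])
  pairs <- utils::combn(d[1], 2L)
  ps <- matrix(NA_real_, ncol(pairs), ncol(x))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ps[k, ] <- (x[j, ] - x[i, ]) / (years[j] - years[i])
  }
  slope <- apply(ps, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
  n_ok <- colSums(!is.na(x))
  slope[n_ok < 2L] <- NA_real_
  matrix(slope, d[2], d[3])
}

# NA-aware spatial moving-window mean (edge cells average what is in reach)
moving_window_mean <- function(m, window) {
  if (window == 1L) return(m)
  h <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -h:h) {
    r_dst <- max(1, 1 - dr):min(nr, nr - dr)
    r_src <- r_dst + dr
    for (dc in -h:h) {
      c_dst <- max(1, 1 - dc):min(nc, nc - dc)
      c_src <- c_dst + dc
      block <- m[r_src, c_src, drop = FALSE]
      okb <- !is.na(block)
      block[!okb] <- 0
      acc[r_dst, c_dst] <- acc[r_dst, c_dst] + block
      cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + okb
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' OLS trend slope per pixel with spatial pre-smoothing
#'
#' Each year's layer is first smoothed by a square moving-window mean of the
#' given size, then an ordinary least-squares slope over years is fitted per
#' pixel. Pixels with fewer than two valid years are masked.
#'
#' @param values Numeric array `[year, row, col]`.
#' @param years Numeric year labels.
#' @param window Odd window size (1 disables smoothing).
#' @return Matrix of slopes.
#' @export
ols_slope <- function(values, years, window = 3L) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (length(years) != d[1]) stop("one year label per layer required")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  if (window > d[2] || window > d[3]) stop("window larger than the raster")
  sm <- values
  if (window > 1L) {
    for (i in seq_len(d[1])) sm[i, , ] <- moving_window_mean(values[i, , ], window)
  }
  x <- matrix(sm, d[1], d[2] * d[3])
  ok <- !is.na(x)
  n <- colSums(ok)
  t_ <- matrix(years, d[1], ncol(x))
  t_[!ok] <- NA
  tbar <- colSums(ifelse(ok, t_, 0)) / n
  ybar <- colSums(ifelse(ok, x, 0)) / n
  dt <- t_ - rep(tbar, each = d[1])
  dy <- x - rep(ybar, each = d[1])
  num <- colSums(ifelse(ok, dt * dy, 0))
  den <- colSums(ifelse(ok, dt^2, 0))
  slope <- num / den
  slope[n < 2L | den == 0] <- NA_real_
  matrix(slope, d[2], d[3])
}

#' Classify trend slopes by a percentile threshold
#'
#' Pixels in the lower `pct` percent of the masked slope distribution that
#' are also truly decreasing (`slope < 0`) are classed negative; pixels in
#' the upper `pct` percent that are increasing are classed positive; all
#' others are indifferent. The sign guard keeps a one-sided slope
#' distribution from producing spurious classes of the opposite sign.
#'
#' @param slope Matrix of slopes.
#' @param mask Optional logical matrix; the percentile thresholds are
#'   computed over masked valid pixels only.
#' @param pct Percentile threshold in `(0, 50)`; 20 reproduces the usual
#'   "considerable trend" cutoff.
#' @param method Label recorded in the result (`"theil_sen"` or `"ols"`).
#' @return An object of class `trend_map`: `slope`, integer `classes`
#'   (-1/0/+1, `NA` outside the mask), `thresholds` (lower, upper), `pct`,
#'   `method`.
#' @export
classify_trend <- function(slope, mask = NULL, pct = 20,
                           method = c("theil_sen", "ols")) {
  method <- match.arg(method)
  stopifnot(is.matrix(slope))
  if (pct <= 0 || pct >= 50) stop("pct must be in (0, 50)")
  keep <- !is.na(slope)
  if (!is.null(mask)) keep <- keep & mask
  v <- slope[keep]
  if (length(v) == 0L) stop("no valid slopes to classify")
  thr <- stats::quantile(v, c(pct, 100 - pct) / 100, names = FALSE)
  cls <- matrix(NA_integer_, nrow(slope), ncol(slope))
  cls[keep] <- 0L
  if (thr[1] < thr[2]) { # all-equal slopes stay indifferent
    cls[keep & slope <= thr[1] & slope < 0] <- -1L
    cls[keep & slope >= thr[2] & slope > 0] <- 1L
  }
  structure(list(slope = slope, classes = cls, thresholds = thr,
                 pct = pct, method = method), class = "trend_map")
}

#' Positive-to-negative trend ratios by aridity zone and health stratum
#'
#' For each aridity zone and each stratum (`total`, `damaged`,
#' `non-damaged`), counts positively and negatively trending pixels and
#' reports their ratio. A zone with no negative pixels gets an `NA` ratio
#' (flagged undefined rather than infinite); a stratum-zone cell with no
#' pixels at all is flagged `empty`.
#'
#' @param trend A [classify_trend()] result.
#' @param zones An [classify_aridity()] result on the same grid.
#' @param damaged Logical damage matrix.
#' @param mask Optional logical matrix (e.g. the forest mask).
#' @param component Component label written into the table.
#' @return Data frame with columns `component`, `stratum`, `zone`,
#'   `positive_px`, `negative_px`, `ratio`, `empty`.
#' @export
ratio_by_zone <- function(trend, zones, damaged, mask = NULL,
                          component = "dhi_cum") {
  stopifnot(inherits(trend, "trend_map"), inherits(zones, "aridity_zones"))
  if (!identical(dim(trend$classes), dim(zones$classes))) {
    stop("trend and zone rasters are not aligned")
  }
  strata <- list(total = !logical(length(damaged)),
                 damaged = as.vector(damaged),
                 `non-damaged` = !as.vector(damaged))
  cls <- as.vector(trend$classes)
  zn <- as.vector(zones$classes)
  keep0 <- !is.na(cls) & !is.na(zn)
  if (!is.null(mask)) keep0 <- keep0 & as.vector(mask)
  rows <- list()
  for (s in names(strata)) {
    for (z in 1:4) {
      sel <- keep0 & strata[[s]] & zn == z
      pos <- sum(cls[sel] == 1L)
      neg <- sum(cls[sel] == -1L)
      rows[[length(rows) + 1L]] <- data.frame(
        component = component, stratum = s, zone = zones$labels[z],
        positive_px = pos, negative_px = neg,
        ratio = if (neg > 0) pos / neg else NA_real_,
        empty = sum(sel) == 0L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
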