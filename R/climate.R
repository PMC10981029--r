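# de Martonne aridity index and climate aggregation. The monthly index is
#   dMI = P / (T + 10)
# with P the monthly precipitation (mm) and T the air temperature (deg C);
# lower values indicate drier conditions.

#' de Martonne aridity index
#'
#' Element-wise `P / (T + 10)`. Cells where `T <= -10` (non-positive
#' denominator) are masked rather than returned as infinities; their count
#' is reported in a warning and as the `n_masked` attribute.
#'
#' @param P Precipitation, mm (matrix or array).
#' @param T_ Air temperature, deg C, same shape.
#' @return dMI values, same shape as the inputs, with attribute `n_masked`.
#' @export
de_martonne <- function(P, T_) {
  if (!identical(dim(P), dim(T_)) || length(P) != length(T_)) {
    stop("P and T grids must have identical shape")
  }
  bad <- !is.na(T_) & T_ <= -10
  out <- P / (T_ + 10)
  out[bad] <- NA_real_
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(sprintf("%d cell(s) with T <= -10 masked in de Martonne index",
                    n_bad))
  }
  attr(out, "n_masked") <- n_bad
  out
}

#' Aggregate a monthly stack to a single grid
#'
#' The same three summaries used for the habitat index: `cumulative` (sum),
#' `minimum`, and `variation` (sample SD / mean). Variation is masked where
#' the mean is zero or where fewer than two months are valid.
#'
#' @param stack Numeric array `[month, row, col]`.
#' @param statistic One of `"cumulative"`, `"minimum"`, `"variation"`.
#' @return Matrix `[row, col]`.
#' @export
aggregate_monthly <- function(stack,
                              statistic = c("cumulative", "minimum",
                                            "variation")) {
  statistic <- match.arg(statistic)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  d <- dim(stack)
  if (statistic == "variation" && d[1] < 2L) {
    stop("variation needs at least 2 months")
  }
  x <- matrix(stack, d[1], d[2] * d[3])
  ok <- !is.na(x)
  n <- colSums(ok)
  out <- switch(statistic,
    cumulative = {
      v <- colSums(ifelse(ok, x, 0))
      v[n == 0] <- NA_real_
      v
    },
    minimum = {
      xm <- x; xm[!ok] <- Inf
      v <- apply(xm, 2L, min)
      v[!is.finite(v)] <- NA_real_
      v
    },
    variation = {
      mu <- colSums(ifelse(ok, x, 0)) / n
      dev2 <- (x - rep(mu, each = d[1]))^2
      dev2[!ok] <- 0
      s <- sqrt(colSums(dev2) / pmax(n - 1, 1))
      v <- s / mu
      v[n < 2 | mu == 0 | !is.finite(v)] <- NA_real_
      v
    })
  matrix(out, d[2], d[3])
}

#' Classify accumulated aridity into four zones
#'
#' Splits the range of the accumulated de Martonne index over the (masked)
#' valid pixels into four equal-width intervals: the lowest interval is
#' `arid`, then `semi-arid`, `semi-humid`, `humid`. Intervals are half-open
#' with the top class closed -- a value exactly on a break belongs to the
#' upper class.
#'
#' @param cum_dmi Matrix of accumulated dMI.
#' @param mask Optional logical matrix; breaks and classes are computed over
#'   masked pixels only.
#' @return An object of class `aridity_zones`: integer matrix `classes`
#'   (1 = arid .. 4 = humid, `NA` outside), numeric `breaks` (3 interior
#'   break values), `range`, `labels` and per-class `counts`.
#' @export
classify_aridity <- function(cum_dmi, mask = NULL) {
  stopifnot(is.matrix(cum_dmi))
  keep <- !is.na(cum_dmi)
  if (!is.null(mask)) keep <- keep & mask
  v <- cum_dmi[keep]
  if (length(v) < 2L || diff(range(v)) == 0) {
    stop("need at least 2 distinct valid values to form equal intervals")
  }
  rng <- range(v)
  breaks <- rng[1] + (1:3) * diff(rng) / 4
  cls <- matrix(NA_integer_, nrow(cum_dmi), ncol(cum_dmi))
  cls[keep] <- findInterval(v, breaks) + 1L
  labels <- c("arid", "semi-arid", "semi-humid", "humid")
  counts <- tabulate(cls[keep], 4L)
  names(counts) <- labels
  structure(list(classes = cls, breaks = breaks, range = rng,
                 labels = labels, counts = counts),
            class = "aridity_zones")
}

#' @export
print.aridity_zones <- function(x, ...) {
  cat("aridity_zones: breaks", paste(signif(x$breaks, 5), collapse = ", "),
      "\n")
  print(x$counts)
  invisible(x)
}

#' Linear regression of accumulated aridity on elevation
#'
#' Ordinary least squares of the accumulated dMI on elevation, fitted
#' separately per health class when a damage mask is supplied (and always
#' for all pixels pooled).
#'
#' @param dem Elevation matrix, m.
#' @param cum_dmi Accumulated dMI matrix, same shape.
#' @param health Optional logical matrix (TRUE = damaged).
#' @param mask Optional logical matrix restricting the pixels.
#' @return Data frame with columns `class`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
altitude_drought_regression <- function(dem, cum_dmi, health = NULL,
                                        mask = NULL) {
  stopifnot(identical(dim(dem), dim(cum_dmi)))
  keep <- !is.na(dem) & !is.na(cum_dmi)
  if (!is.null(mask)) keep <- keep & mask
  fit_one <- function(sel, label) {
    x <- dem[sel]; y <- cum_dmi[sel]
    if (length(x) < 3L) stop("need at least 3 valid paired samples")
    if (stats::sd(x) == 0) stop("zero elevation variance")
    f <- stats::lm(y ~ x)
    r2 <- 1 - sum(stats::residuals(f)^2) / sum((y - mean(y))^2)
    data.frame(class = label,
               slope = unname(stats::coef(f)[2]),
               intercept = unname(stats::coef(f)[1]),
               r_squared = r2,
               n = length(x), stringsAsFactors = FALSE)
  }
  out <- fit_one(keep, "all")
  if (!is.null(health)) {
    out <- rbind(out,
                 fit_one(keep & health, "damaged"),
                 fit_one(keep & !health, "non-damaged"))
  }
  rownames(out) <- NULL
  out
}

#' Climate aggregate layers for the analysis
#'
#' Computes, on the climate grid, the cumulative / minimum / variation
#' aggregates of precipitation, temperature, sunshine duration and the
#' monthly de Martonne index over the full period.
#'
#' @param climate A `climate_grids` object (see
#'   [generate_climate_grids()]), or any list with `precip`, `temp`, `sun`
#'   arrays and a `grid`.
#' @return A list with named matrices (`precip_cum`, `precip_min`,
#'   `precip_var`, `temp_cum`, ..., `dmi_var`), the monthly `dmi` array and
#'   the `grid`.
#' @export
climate_aggregates <- function(climate) {
  dmi <- de_martonne(climate$precip, climate$temp)
  vars <- list(precip = climate$precip, temp = climate$temp,
               sun = climate$sun, dmi = dmi)
  stats_ <- c(cum = "cumulative", min = "minimum", var = "variation")
  out <- list()
  for (v in names(vars)) {
    for (s in names(stats_)) {
      out[[paste(v, s, sep = "_")]] <- aggregate_monthly(vars[[v]], stats_[[s]])
    }
  }
  out$dmi <- dmi
  out$grid <- climate$grid
  out
}
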