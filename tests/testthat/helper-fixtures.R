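# Fixtures built in code: toy composite stacks, random stacks with gaps,
# and a brute-force per-pixel DHI oracle kept deliberately dumb.

toy_grid <- function(nr, nc) grid_spec(nr, nc, cellsize = 300, crs = "EPSG:32632")

# replicate one within-year series across every pixel of an nr x nc scene
toy_stack <- function(series, nr = 1, nc = 1, year = 2017) {
  n_t <- length(series)
  dates <- seq(as.Date(sprintf("%d-01-05", year)), by = "10 days",
               length.out = n_t)
  vals <- array(rep(series, nr * nc), c(n_t, nr, nc))
  composite_stack(vals, dates, toy_grid(nr, nc), range = NULL)
}

# random stack with missing entries, one calendar year
random_stack <- function(n_t = 36, nr = 10, nc = 10, na_frac = 0.1,
                         year = 2017, seed = 1) {
  set.seed(seed)
  vals <- array(runif(n_t * nr * nc, -0.2, 0.9), c(n_t, nr, nc))
  vals[runif(length(vals)) < na_frac] <- NA_real_
  dates <- composite_dates_seq(year, n_t)
  composite_stack(vals, dates, toy_grid(nr, nc))
}

composite_dates_seq <- function(year, n_t) {
  seq(as.Date(sprintf("%d-01-02", year)), by = "10 days", length.out = n_t)
}

# scalar per-pixel DHI oracle: explicit loops, base-R summaries only
dhi_loop_oracle <- function(stack, min_valid_fraction = 0.75) {
  d <- dim(stack$values)
  cum <- minimum <- cv <- matrix(NA_real_, d[2], d[3])
  for (r in seq_len(d[2])) {
    for (c in seq_len(d[3])) {
      v <- stack$values[, r, c]
      v <- v[!is.na(v)]
      if (length(v) < 2 || length(v) < min_valid_fraction * d[1]) next
      cum[r, c] <- sum(v) * d[1] / length(v)
      minimum[r, c] <- min(v)
      if (mean(v) > 0) cv[r, c] <- sd(v) / mean(v)
    }
  }
  list(cum = cum, minimum = minimum, var = cv)
}

# default synthetic study scene, generated once per test run
acceptance_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scene(scene_params(seed = 42))
    cache
  }
})
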