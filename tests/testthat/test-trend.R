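# Theil-Sen and moving-window OLS slopes, percentile trend classification
# and the zonal positive-to-negative ratio table.

years4 <- 1:4

arr_from <- function(series_list, nr = 1, nc = 1) {
  # series_list: one numeric vector per pixel (recycled row-major)
  ny <- length(series_list[[1]])
  a <- array(NA_real_, c(ny, nr, nc))
  k <- 1
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a[, r, c] <- series_list[[(k - 1) %% length(series_list) + 1]]
    k <- k + 1
  }
  a
}

test_that("Theil-Sen is exact on linear data and zero on constants", {
  a <- arr_from(list(c(1, 2, 3, 4), c(5, 5, 5, 5), c(3, 1, -1, -3)),
                nr = 1, nc = 3)
  s <- theil_sen_slope(a, years4)
  expect_equal(as.vector(s), c(1, 0, -2))
  expect_error(theil_sen_slope(a, c(1, 2, 2, 3)), "duplicate")
})

test_that("Theil-Sen equals the median of explicitly enumerated pair slopes", {
  v <- c(1, 2, 3, 100)
  oracle <- local({
    ps <- c()
    for (i in 1:3) for (j in (i + 1):4) {
      ps <- c(ps, (v[j] - v[i]) / (j - i))
    }
    median(ps)
  })
  s <- theil_sen_slope(arr_from(list(v)), years4)
  expect_equal(s[1, 1], oracle)
  # and on random series
  set.seed(13)
  for (k in 1:10) {
    w <- rnorm(6)
    yrs <- c(1, 2, 4, 5, 8, 9)
    ps <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      ps <- c(ps, (w[j] - w[i]) / (yrs[j] - yrs[i]))
    }
    expect_equal(theil_sen_slope(arr_from(list(w)), yrs)[1, 1], median(ps))
  }
})

test_that("Theil-Sen shrugs off a single outlier with five or more years", {
  base <- 2 * (1:5) + 3
  spiked <- base
  spiked[3] <- 1000
  s <- theil_sen_slope(arr_from(list(base, spiked), nc = 2), 1:5)
  expect_equal(s[1, 1], 2)
  expect_equal(s[1, 2], 2)
})

test_that("pixels with fewer than two valid years are masked", {
  a <- arr_from(list(c(1, NA, NA, NA), c(1, NA, 3, NA)), nc = 2)
  s <- theil_sen_slope(a, years4)
  expect_true(is.na(s[1, 1]))
  expect_equal(s[1, 2], 1)
})

test_that("OLS with window 1 equals the closed-form slope; Theil-Sen agrees on noiseless data", {
  set.seed(21)
  nr <- 5; nc <- 4
  intercepts <- matrix(rnorm(nr * nc), nr, nc)
  slopes <- matrix(rnorm(nr * nc), nr, nc)
  a <- array(NA_real_, c(4, nr, nc))
  for (t in 1:4) a[t, , ] <- intercepts + slopes * years4[t]
  expect_equal(ols_slope(a, years4, window = 1), slopes)
  expect_equal(theil_sen_slope(a, years4), slopes)
})

test_that("window 3 on a spatially constant field equals window 1", {
  a <- array(NA_real_, c(4, 6, 6))
  for (t in 1:4) a[t, , ] <- 0.2 * t + 1
  expect_equal(ols_slope(a, years4, 3), ols_slope(a, years4, 1))
  expect_error(ols_slope(a, years4, 2), "odd")
  expect_error(ols_slope(a, years4, 9), "larger")
})

test_that("moving-window OLS matches a nested-loop oracle on a random field", {
  set.seed(31)
  nr <- 6; nc <- 5
  a <- array(rnorm(4 * nr * nc), c(4, nr, nc))
  got <- ols_slope(a, years4, 3)
  # oracle: average each 3x3 in-bounds neighbourhood, then fit lm per pixel
  sm <- array(NA_real_, c(4, nr, nc))
  for (t in 1:4) for (r in 1:nr) for (c in 1:nc) {
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    sm[t, r, c] <- mean(a[t, rs, cs])
  }
  oracle <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    oracle[r, c] <- unname(coef(lm(sm[, r, c] ~ years4))[2])
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("percentile classification matches a sort-and-count oracle", {
  slopes <- matrix(1:100, 10, 10)
  tm <- classify_trend(slopes, pct = 20)
  q80 <- quantile(1:100, 0.8, names = FALSE)
  expect_equal(sum(tm$classes == 1L), sum(1:100 >= q80))
  expect_equal(sum(tm$classes == -1L), 0)   # sign guard: all slopes positive
  expect_true(all(tm$slope[tm$classes == 1L] >= q80))
})

test_that("a symmetric slope field classifies symmetrically", {
  k <- 50
  slopes <- matrix(c(-k:-1, 1:k), 10, 10)
  tm <- classify_trend(slopes, pct = 20)
  expect_equal(sum(tm$classes == 1L), sum(tm$classes == -1L))
  expect_true(all(tm$slope[tm$classes == -1L] < 0))
})

test_that("the non-indifferent fraction never exceeds twice the percentile", {
  set.seed(41)
  for (k in 1:5) {
    slopes <- matrix(rnorm(400), 20, 20)
    tm <- classify_trend(slopes, pct = 20)
    expect_lte(sum(tm$classes != 0L), 0.4 * 400)
  }
  flat <- matrix(1, 5, 5)
  tm0 <- classify_trend(flat, pct = 20)
  expect_true(all(tm0$classes == 0L))
  expect_error(classify_trend(flat, pct = 60), "pct")
})

fake_zones <- function(classes_mat) {
  structure(list(classes = classes_mat, breaks = c(1, 2, 3),
                 range = c(0, 4), labels = c("arid", "semi-arid",
                                             "semi-humid", "humid"),
                 counts = tabulate(classes_mat, 4L)),
            class = "aridity_zones")
}

fake_trend <- function(classes_mat) {
  structure(list(slope = classes_mat * 0.1, classes = classes_mat,
                 thresholds = c(-0.05, 0.05), pct = 20,
                 method = "theil_sen"), class = "trend_map")
}

test_that("zonal ratios count positives over negatives and flag zero divisions", {
  cls <- matrix(c(rep(1L, 10), rep(-1L, 5), rep(0L, 9)), 4, 6)
  zn <- matrix(1L, 4, 6)
  tab <- ratio_by_zone(fake_trend(cls), fake_zones(zn),
                       damaged = matrix(FALSE, 4, 6))
  arid_total <- tab[tab$stratum == "total" & tab$zone == "arid", ]
  expect_equal(arid_total$positive_px, 10)
  expect_equal(arid_total$negative_px, 5)
  expect_equal(arid_total$ratio, 2)
  humid <- tab[tab$stratum == "total" & tab$zone == "humid", ]
  expect_true(is.na(humid$ratio))
  expect_true(humid$empty)
  # all-positive zone: ratio undefined, not infinite
  cls2 <- matrix(1L, 2, 2)
  tab2 <- ratio_by_zone(fake_trend(cls2), fake_zones(matrix(2L, 2, 2)),
                        damaged = matrix(FALSE, 2, 2))
  sa <- tab2[tab2$stratum == "total" & tab2$zone == "semi-arid", ]
  expect_equal(sa$positive_px, 4)
  expect_true(is.na(sa$ratio))
})

test_that("stratum counts partition the classified pixels", {
  set.seed(51)
  cls <- matrix(sample(c(-1L, 0L, 1L), 100, replace = TRUE), 10, 10)
  zn <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
  dmg <- matrix(runif(100) < 0.3, 10, 10)
  tab <- ratio_by_zone(fake_trend(cls), fake_zones(zn), damaged = dmg)
  tot <- tab[tab$stratum == "total", ]
  expect_equal(sum(tot$positive_px), sum(cls == 1L))
  expect_equal(sum(tot$negative_px), sum(cls == -1L))
  for (z in unique(tab$zone)) {
    sub <- tab[tab$zone == z, ]
    expect_equal(sum(sub$positive_px[sub$stratum != "total"]),
                 sub$positive_px[sub$stratum == "total"])
  }
})

test_that("damaged stands trend worse than healthy ones in every zone", {
  sc <- acceptance_scene()
  my <- compute_dhi_multiyear(sc$stacks)
  a <- annual_array <- array(NA_real_, c(4, 50, 50))
  for (i in 1:4) a[i, , ] <- my$years[[i]]$cum
  tm <- classify_trend(theil_sen_slope(a, 2017:2020), mask = sc$truth$forest)
  aggs <- climate_aggregates(sc$climate)
  cum_dmi <- align_to_grid(aggs$dmi_cum, sc$climate$grid, sc$truth$grid,
                           "bilinear")
  zones <- classify_aridity(cum_dmi, mask = sc$truth$forest)
  tab <- ratio_by_zone(tm, zones, damaged = sc$truth$damaged,
                       mask = sc$truth$forest)
  # ratio with zero negatives compares as +Inf
  r <- function(stratum, zone) {
    row <- tab[tab$stratum == stratum & tab$zone == zone, ]
    if (row$empty) return(NA_real_)
    if (is.na(row$ratio)) Inf else row$ratio
  }
  for (z in c("arid", "semi-arid", "semi-humid", "humid")) {
    rd <- r("damaged", z); rn <- r("non-damaged", z)
    if (!is.na(rd) && !is.na(rn)) expect_lt(rd, rn)
  }
})
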