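# Sample-table assembly, spatial thinning, collinearity filtering, the
# logistic health model and its diagnostics.

scene_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- acceptance_scene()
      my <- compute_dhi_multiyear(sc$stacks)
      aggs_c <- climate_aggregates(sc$climate)
      nm <- grep("^(precip|temp|sun|dmi)_(cum|min|var)$", names(aggs_c),
                 value = TRUE)
      aggs <- lapply(aggs_c[nm], align_to_grid, src_grid = sc$climate$grid,
                     target = sc$truth$grid, method = "bilinear")
      cache <<- build_sample_table(my, aggs, sc$truth$elevation,
                                   sc$truth$damaged, sc$truth$forest)
    }
    cache
  }
})

# small synthetic logistic table with independent predictors
sim_table <- function(n, beta0, betas, seed) {
  set.seed(seed)
  p <- length(betas)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  eta <- beta0 + x %*% betas
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  tab <- data.frame(row = seq_len(n), col = 1L, x = runif(n) * 1e4,
                    y = runif(n) * 1e4, label = y, x)
  class(tab) <- c("sample_table", "data.frame")
  tab
}

test_that("the sample table has one row per fully valid forest pixel", {
  tab <- scene_table()
  expect_equal(nrow(tab), 2500L)
  expect_length(predictor_names(tab), 16L)
  expect_true(all(tab$label %in% 0:1))
  expect_false(anyNA(tab))

  # knocking out one climate pixel drops exactly that row, with a logged reason
  sc <- acceptance_scene()
  my <- compute_dhi_multiyear(sc$stacks)
  aggs_c <- climate_aggregates(sc$climate)
  nm <- grep("^(precip|temp|sun|dmi)_(cum|min|var)$", names(aggs_c),
             value = TRUE)
  aggs <- lapply(aggs_c[nm], align_to_grid, src_grid = sc$climate$grid,
                 target = sc$truth$grid, method = "bilinear")
  aggs$precip_cum[10, 10] <- NA
  tab2 <- build_sample_table(my, aggs, sc$truth$elevation, sc$truth$damaged,
                             sc$truth$forest)
  expect_equal(nrow(tab2), 2499L)
  expect_equal(unname(attr(tab2, "drop_log")["invalid_precip_cum"]), 1L)
})

test_that("spatial thinning enforces the minimum pairwise distance", {
  tab <- scene_table()
  expect_identical(nrow(spatial_thin(tab, 0)), nrow(tab))

  thinned <- spatial_thin(tab, 600, seed = 3)
  d <- dist(cbind(thinned$x, thinned$y))
  expect_gte(min(d), 600)
  expect_gt(nrow(thinned), 0.15 * nrow(tab))
  # reproducible under the seed
  expect_identical(thinned, spatial_thin(tab, 600, seed = 3))

  two <- tab[c(1, 1), ]
  class(two) <- class(tab)
  expect_equal(nrow(spatial_thin(two, 600, seed = 1)), 1L)
})

test_that("correlation filtering drops the worse member of each tight pair", {
  set.seed(5)
  n <- 200
  a <- rnorm(n)
  tab <- data.frame(row = 1:n, col = 1L, x = runif(n), y = runif(n),
                    label = rbinom(n, 1, 0.5),
                    a = a, a_copy = a, b = rnorm(n))
  class(tab) <- c("sample_table", "data.frame")
  out <- filter_correlated(tab, 0.8)
  expect_length(predictor_names(out), 2L)
  expect_equal(nrow(attr(out, "removed")), 1L)
  expect_true(attr(out, "removed")$variable %in% c("a", "a_copy"))

  # nothing below the threshold is touched
  tab2 <- tab[c("row", "col", "x", "y", "label", "a", "b")]
  class(tab2) <- class(tab)
  out2 <- filter_correlated(tab2, 0.8)
  expect_length(predictor_names(out2), 2L)
  expect_equal(nrow(attr(out2, "removed")), 0L)
})

test_that("VIF filtering matches explicit auxiliary regressions and car::vif", {
  set.seed(7)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, sd = 0.01)
  tab <- data.frame(row = 1:n, col = 1L, x = runif(n), y = runif(n),
                    label = rbinom(n, 1, 0.5), x1 = x1, x2 = x2, x3 = x3)
  class(tab) <- c("sample_table", "data.frame")
  out <- filter_vif(tab, 5)
  rem <- attr(out, "removed")
  expect_equal(nrow(rem), 1L)
  expect_true(rem$variable %in% c("x1", "x2", "x3"))
  expect_length(predictor_names(out), 2L)

  # the removed variable had the largest VIF, cross-checked against car
  vifs <- car::vif(lm(rnorm(n) ~ x1 + x2 + x3))
  expect_equal(names(which.max(vifs)), rem$variable)
  expect_equal(unname(vifs[rem$variable]), rem$vif, tolerance = 1e-8)

  # orthogonal predictors all survive with VIF ~ 1
  ortho <- tab
  ortho$x3 <- rnorm(n)
  out2 <- filter_vif(ortho, 5)
  expect_length(predictor_names(out2), 3L)

  # a single predictor is retained by definition
  solo <- tab[c("row", "col", "x", "y", "label", "x1")]
  class(solo) <- class(tab)
  expect_length(predictor_names(filter_vif(solo, 5)), 1L)
})

test_that("correlation then VIF filtering keeps 7 of the 16 candidates", {
  tab <- spatial_thin(scene_table(), 600, seed = 17)
  tab_r <- filter_correlated(tab, 0.8)
  tab_v <- filter_vif(tab_r, 5)
  removed <- nrow(attr(tab_r, "removed")) + nrow(attr(tab_v, "removed"))
  expect_equal(removed, 9L)
  expect_length(predictor_names(tab_v), 7L)
})

test_that("the logistic fit recovers a hand-computed 2x2 log odds ratio", {
  # single binary predictor: slope = log OR of the contingency table
  counts <- c(n00 = 40, n01 = 20, n10 = 15, n11 = 45)
  tab <- data.frame(
    row = 1:120, col = 1L, x = runif(120), y = runif(120),
    label = c(rep(0, 40), rep(1, 20), rep(0, 15), rep(1, 45)),
    v = c(rep(0, 60), rep(1, 60)))
  class(tab) <- c("sample_table", "data.frame")
  fit <- fit_logistic(tab)
  log_or <- log((45 / 15) / (20 / 40))
  expect_equal(fit$coefficients$estimate[2], log_or, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[1], log(20 / 40), tolerance = 1e-6)
})

test_that("balanced labels with constant predictors give a zero fit", {
  tab <- data.frame(row = 1:40, col = 1L, x = runif(40), y = runif(40),
                    label = rep(0:1, 20), v1 = 0, v2 = 0)
  class(tab) <- c("sample_table", "data.frame")
  fit <- fit_logistic(tab)
  expect_equal(fit$coefficients$estimate, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(mcfadden_r2(fit), 0)
})

test_that("parameter recovery on simulated data stays within 3 SE", {
  beta0 <- -1; betas <- c(2, -0.5)
  hits <- 0L; total <- 0L; biases <- c()
  for (k in 1:20) {
    tab <- sim_table(2000, beta0, betas, seed = 100 + k)
    fit <- fit_logistic(tab)
    est <- fit$coefficients$estimate
    se <- fit$coefficients$std_error
    truth <- c(beta0, betas)
    hits <- hits + sum(abs(est - truth) <= 3 * se)
    total <- total + length(truth)
    biases <- c(biases, est - truth)
  }
  expect_gte(hits / total, 0.95)
  expect_lt(median(abs(biases)), 0.1)
})

test_that("raw-scale coefficients equal a direct unstandardized glm fit", {
  tab <- sim_table(500, -0.5, c(1, -2, 0.3), seed = 31)
  fit <- fit_logistic(tab)
  direct <- glm(label ~ v1 + v2 + v3, family = binomial(), data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(direct)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$std_error,
               unname(sqrt(diag(vcov(direct)))), tolerance = 1e-5)
})

test_that("duplicating the data keeps estimates and shrinks SEs by sqrt(2)", {
  tab <- sim_table(400, 0.5, c(1, -1), seed = 37)
  tab2 <- rbind(tab, tab)
  class(tab2) <- class(tab)
  f1 <- fit_logistic(tab)
  f2 <- fit_logistic(tab2)
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f2$coefficients$std_error,
               f1$coefficients$std_error / sqrt(2), tolerance = 1e-6)
})

test_that("McFadden R2 is affine-invariant and separation is flagged", {
  tab <- sim_table(600, -0.5, c(1.5, -0.7), seed = 41)
  f1 <- fit_logistic(tab)
  resc <- tab
  resc$v1 <- resc$v1 * 1000 + 5
  resc$v2 <- resc$v2 / 100 - 2
  f2 <- fit_logistic(resc)
  expect_equal(mcfadden_r2(f2), mcfadden_r2(f1), tolerance = 1e-8)
  expect_true(mcfadden_r2(f1) > 0 && mcfadden_r2(f1) < 1)

  # perfectly separable labels approach a pseudo-R2 of 1
  sep_tab <- data.frame(row = 1:100, col = 1L, x = runif(100), y = runif(100),
                        label = rep(0:1, each = 50),
                        v = c(rnorm(50, -5), rnorm(50, 5)))
  class(sep_tab) <- c("sample_table", "data.frame")
  fs <- fit_logistic(sep_tab)
  expect_true(fs$separation)
  expect_gt(mcfadden_r2(fs), 0.95)
})

test_that("importance ranks by |z| and mirrors the p-value order", {
  tab <- sim_table(1500, 0, c(3, 0.3, -0.1), seed = 43)
  fit <- fit_logistic(tab)
  imp <- variable_importance(fit)
  expect_equal(imp$variable[1], "v1")
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_equal(imp$variable, cf$term[order(cf$p)])
  expect_equal(imp$rank, seq_len(3))

  # cross-check against the reference importance tooling for GLMs
  ref <- caret::varImp(fit$glm)
  expect_equal(imp$importance[match(rownames(ref), imp$variable)],
               ref$Overall, tolerance = 1e-8)
})

test_that("residual Moran's I is near its null expectation for random labels", {
  tab <- sim_table(300, 0, c(1, -1), seed = 47)
  fit <- fit_logistic(tab)
  mi <- residual_morans_i(fit, tab)
  expect_equal(mi$expected, -1 / 299)
  expect_gt(mi$p, 1e-4)
})
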