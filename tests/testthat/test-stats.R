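# Statistical workflow: normality, Spearman, screen, VIF, stepwise search

test_that("shapiro_wilk_screen annotates columns and flags constants", {
  set.seed(5)
  d <- data.frame(norm = rnorm(60), const = rep(2, 60))
  res <- shapiro_wilk_screen(d)
  expect_true(res$p_value[res$variable == "norm"] > 0)
  expect_identical(res$flag[res$variable == "const"], "constant_or_short")

  # power against extreme tails: t_1 samples at n = 50 reject almost always
  set.seed(6)
  rej <- mean(replicate(100, {
    shapiro_wilk_screen(data.frame(x = rt(50, df = 1)))$p_value < 0.05
  }))
  expect_gt(rej, 0.9)
  # near-nominal size on normal data
  set.seed(7)
  size <- mean(replicate(200, {
    shapiro_wilk_screen(data.frame(x = rnorm(40)))$p_value < 0.05
  }))
  expect_lt(size, 0.12)
})

test_that("spearman_with_ci matches rank oracles and exact enumeration", {
  # monotone invariance
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 6.0, 7.7)
  r <- spearman_with_ci(x, exp(x), n_boot = 100, seed = 1)
  expect_equal(r$rho, 1)
  r2 <- spearman_with_ci(x, -x^3, n_boot = 100, seed = 1)
  expect_equal(r2$rho, -1)

  # closed-form oracle on 10 untied pairs
  xf <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 8, 7)
  yf <- c(2, 1, 5, 3, 10, 4, 6, 3.4, 9, 8)
  rf <- spearman_with_ci(xf, yf, n_boot = 100, seed = 1)
  expect_equal(rf$rho, rho_closed_form(xf, yf), tolerance = 1e-12)
  expect_identical(rf$p_method, "exact-permutation")

  # exhaustive permutation-null oracle at n = 6
  x6 <- c(1, 5, 2, 8, 3, 9); y6 <- c(2, 4, 1, 9, 5, 7)
  obs <- abs(rho_closed_form(x6, y6))
  nulls <- vapply(all_permutations(1:6),
                  function(p) rho_closed_form(x6, y6[p]), numeric(1))
  p_oracle <- mean(abs(nulls) >= obs - 1e-12)
  r6 <- spearman_with_ci(x6, y6, n_boot = 100, seed = 1)
  expect_equal(r6$p_value, p_oracle, tolerance = 1e-12)

  # bootstrap CI: clamped, seeded-deterministic, brackets rho
  ra <- spearman_with_ci(xf, yf, n_boot = 2000, seed = 9)
  rb <- spearman_with_ci(xf, yf, n_boot = 2000, seed = 9)
  expect_identical(ra$ci95, rb$ci95)
  expect_true(all(ra$ci95 >= -1 & ra$ci95 <= 1))
  expect_true(ra$ci95[1] <= ra$rho && ra$rho <= ra$ci95[2])
  rz <- spearman_with_ci(xf, yf, ci_method = "fisher-z")
  expect_true(all(rz$ci95 >= -1 & rz$ci95 <= 1))

  expect_error(spearman_with_ci(rep(1, 6), 1:6), class = "ZeroVariance")
})

test_that("correlation_screen retains monotone associates and tolerates degenerates", {
  set.seed(12)
  d <- data.frame(x = rnorm(12))
  d$race_time_min <- 100 - 3 * d$x          # strictly decreasing in x
  d$noise <- rnorm(12)
  sc <- correlation_screen(d, "race_time_min", n_boot = 100, seed = 1)
  expect_true(sc$retained[sc$variable == "x"])
  expect_equal(sc$rho[sc$variable == "x"], -1)
  expect_match(attr(sc, "note"), "multiplicity")

  d$flat <- 1
  sc2 <- correlation_screen(d, "race_time_min", n_boot = 100, seed = 1)
  expect_false(sc2$retained[sc2$variable == "flat"])
  expect_true(is.na(sc2$rho[sc2$variable == "flat"]))
})

test_that("vif_filter matches the regression oracle and removes collinear terms", {
  # orthogonal design: all VIF exactly 1
  X <- qr.Q(qr(matrix(rnorm(200 * 4), 200, 4)))
  d <- as.data.frame(X); names(d) <- paste0("v", 1:4)
  res <- vif_filter(d, threshold = 5)
  expect_identical(res$retained, names(d))
  # columns are mutually orthogonal but not exactly mean-centred, so VIFs sit
  # a hair above 1
  expect_lt(max(abs(res$vif_table$vif - 1)), 1e-3)

  # near-duplicated pair: exactly one of the two removed
  set.seed(33)
  d2 <- data.frame(x1 = rnorm(50), x3 = rnorm(50))
  d2$x2 <- d2$x1 + rnorm(50, 0, 1e-6)
  res2 <- vif_filter(d2, threshold = 5)
  expect_length(intersect(c("x1", "x2"), res2$retained), 1L)
  expect_true("x3" %in% res2$retained)

  # oracle identity: VIF_j = 1 / (1 - R^2_j) via independent lm fits
  set.seed(34)
  for (k in 1:20) {
    n <- 40
    Z <- matrix(rnorm(n * 4), n, 4)
    Z[, 2] <- Z[, 1] * 0.8 + Z[, 2] * 0.6
    dd <- as.data.frame(Z); names(dd) <- paste0("p", 1:4)
    first_iter <- vif_filter(dd, threshold = 1e9)$vif_table
    for (j in names(dd)) {
      oracle <- 1 / (1 - summary(
        lm(reformulate(setdiff(names(dd), j), j), data = dd))$r.squared)
      expect_equal(first_iter$vif[first_iter$variable == j &
                                    first_iter$iteration == 1],
                   oracle, tolerance = 1e-8)
    }
  }

  # perfect collinearity: flagged InfiniteVIF
  d3 <- data.frame(a = rnorm(30))
  d3$b <- 2 * d3$a
  d3$c <- rnorm(30)
  res3 <- vif_filter(d3, threshold = 5)
  expect_true(any(grepl("InfiniteVIF", res3$flags)))
})

test_that("backward_eliminate drops noise terms and records its trace", {
  set.seed(41)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d$y <- 3 + 2 * d$x1 + rnorm(50, 0, 0.1)
  res <- backward_eliminate(d, "y", c("x1", "x2"))
  expect_identical(res$retained, "x1")
  expect_identical(res$trace$dropped, "x2")

  single <- backward_eliminate(d, "y", "x1")
  expect_identical(single$retained, "x1")
  expect_equal(nrow(single$trace), 0)

  # trace length can never exceed the starting predictor count
  d$x3 <- rnorm(50); d$x4 <- rnorm(50)
  res4 <- backward_eliminate(d, "y", c("x1", "x2", "x3", "x4"))
  expect_lte(nrow(res4$trace), 4)
})

test_that("forward_select_and_fit recovers an exact generative equation", {
  cfg <- generator_config(n_athletes = 30, seed = 11, race_noise_sd_min = 0)
  tr <- sample_cohort_truth(cfg)
  d <- as.data.frame(t(vapply(tr, function(s) s$markers_rel, numeric(6))))
  d$race_time_min <- vapply(tr, function(s) s$race_time_min, numeric(1))
  m <- suppressWarnings(forward_select_and_fit(
    d, "race_time_min", c("po_x2", "po_x4", "po_vo2max")))
  expect_setequal(m$predictors, c("po_x2", "po_x4", "po_vo2max"))
  expect_equal(unname(m$coefficients["(Intercept)"]), 255.86, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["po_vo2max"]), -32.87, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["po_x4"]), -51.18, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["po_x2"]), 60.77, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)

  # df bookkeeping at n = 9 with three entered predictors: F uses (3, 5)
  set.seed(52)
  d9 <- data.frame(a = rnorm(9), b = rnorm(9), c = rnorm(9))
  d9$race_time_min <- 90 - 5 * d9$a + 4 * d9$b - 3 * d9$c + rnorm(9, 0, 0.01)
  m9 <- suppressWarnings(
    forward_select_and_fit(d9, "race_time_min", c("a", "b", "c")))
  expect_identical(unname(m9$df), c(3L, 5L))
  expect_equal(m9$f_statistic,
               (m9$r_squared / 3) / ((1 - m9$r_squared) / 5),
               tolerance = 1e-10)

  # constant outcome: intercept-only report
  dc <- data.frame(a = rnorm(12), race_time_min = rep(80, 12))
  mc <- suppressWarnings(forward_select_and_fit(dc, "race_time_min", "a"))
  expect_length(mc$predictors, 0)
  expect_equal(mc$r_squared, 0)
})

test_that("F and R-squared are mutually consistent across random fits", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(12:40, 1)
    d <- data.frame(a = rnorm(n), b = rnorm(n))
    d$race_time_min <- 80 - 2 * d$a + rnorm(n)
    m <- forward_select_and_fit(d, "race_time_min", c("a", "b"))
    if (!length(m$predictors)) next
    df1 <- unname(m$df["df1"]); df2 <- unname(m$df["df2"])
    expect_equal(m$f_statistic,
                 (m$r_squared / df1) / ((1 - m$r_squared) / df2),
                 tolerance = 1e-10)
  }
})

test_that("predict_race_time is affine and validates inputs", {
  cfg <- generator_config(n_athletes = 30, seed = 11, race_noise_sd_min = 0)
  tr <- sample_cohort_truth(cfg)
  d <- as.data.frame(t(vapply(tr, function(s) s$markers_rel, numeric(6))))
  d$race_time_min <- vapply(tr, function(s) s$race_time_min, numeric(1))
  m <- suppressWarnings(forward_select_and_fit(
    d, "race_time_min", c("po_x2", "po_x4", "po_vo2max")))

  # published squad means: 255.86 - 32.87*5.29 - 51.18*3.86 + 60.77*3.24
  pred <- predict_race_time(m, c(po_vo2max = 5.29, po_x4 = 3.86, po_x2 = 3.24))
  expect_equal(pred, 81.3177, tolerance = 1e-6)

  # affine property: prediction differences equal sum(b_i * delta_i)
  x0 <- c(po_vo2max = 5.0, po_x4 = 3.7, po_x2 = 3.1)
  dx <- c(po_vo2max = 0.2, po_x4 = -0.1, po_x2 = 0.05)
  lhs <- predict_race_time(m, as.list(x0 + dx)) - predict_race_time(m, as.list(x0))
  rhs <- sum(m$coefficients[names(dx)] * dx)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  expect_error(predict_race_time(m, c(po_x2 = 3.2)), class = "MissingPredictor")
})
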