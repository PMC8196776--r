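# Lactate curve fitting and threshold extraction

test_that("fit_lactate_curve reproduces data it nests and matches the normal equations", {
  tt <- quadratic_step_test()
  cv <- fit_lactate_curve(tt, 3)
  expect_lt(cv$rss, 1e-18)
  expect_equal(eval_lactate_curve(cv, tt$stages$power), tt$stages$lactate,
               tolerance = 1e-9)
  expect_identical(cv$domain, c(150, 300))

  # independent normal-equations oracle on noisy stages
  set.seed(31)
  P <- seq(150, 275, by = 25)
  L <- 1 + 0.5 * exp((P - 150) / 60) + rnorm(6, 0, 0.1)
  tt2 <- step_test("a", 1, P, L)
  cv2 <- fit_lactate_curve(tt2, 3)
  X <- outer(P, 0:3, `^`)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% L, tol = 1e-30)
  expect_equal(cv2$coefficients, as.numeric(beta_oracle), tolerance = 1e-8)
})

test_that("fit_lactate_curve enforces stage arity and design rank", {
  short <- step_test("a", 1, c(150, 175, 200), c(1, 1.5, 2.5))
  expect_error(fit_lactate_curve(short, 3), class = "InsufficientStages")
  expect_error(fit_lactate_curve(short, 4), class = "InsufficientStages")
  ok4 <- step_test("a", 1, seq(150, 225, 25), c(1, 1.4, 2.0, 3.1))
  expect_error(fit_lactate_curve(ok4, 4), class = "InsufficientStages")
  expect_s3_class(fit_lactate_curve(ok4, 3), "lactate_curve")
})

test_that("po_at_fixed_lactate inverts linear and fitted curves", {
  # linear curve c(P) = P / 50: 4 mmol/L at exactly 200 W
  P <- seq(150, 300, 25)
  lin <- fit_lactate_curve(step_test("a", 1, P, P / 50), 3)
  expect_equal(po_at_fixed_lactate(lin, 4), 200, tolerance = 1e-9)

  # bisection oracle on a curve fitted to a noiseless simulated test
  st <- make_truth()
  tt <- simulate_step_test(st, noise_sd = 0, seed = 1)
  cv <- fit_lactate_curve(tt, 3)
  for (ct in c(2, 4)) {
    got <- po_at_fixed_lactate(cv, ct)
    oracle <- uniroot(function(p) eval_lactate_curve(cv, p) - ct,
                      cv$domain, tol = 1e-10)$root
    expect_lt(abs(got - oracle), 0.011)
    # inverse consistency: curve at the root returns the target
    expect_equal(eval_lactate_curve(cv, oracle), ct, tolerance = 1e-6)
  }
  # recovery of the generative truth on this well-behaved athlete; the cubic
  # carries ~1.4 W deterministic lack-of-fit against the exponential world
  expect_lt(abs(po_at_fixed_lactate(cv, 2) - st$po_x2_w), 2)

  # error taxonomy
  low <- fit_lactate_curve(step_test("a", 1, P, 1 + P / 1000), 3)  # max 1.3
  expect_error(po_at_fixed_lactate(low, 4), class = "NotReached")
  high <- fit_lactate_curve(step_test("a", 4.5, P, 5 + P / 100), 3)
  expect_error(po_at_fixed_lactate(high, 4), class = "AlreadyExceeded")
})

test_that("po_lt1 applies the stage-discrete +1 mmol/L rule", {
  tt <- step_test("a", 1.5, c(150, 175, 200, 225), c(1.6, 1.9, 2.3, 2.7))
  expect_equal(po_lt1(tt), 200)  # first >= 2.5 is 225 W; preceding stage

  first_high <- step_test("a", 1.0, c(150, 175, 200, 225), c(2.4, 2.6, 3, 4))
  expect_error(po_lt1(first_high), class = "UndeterminedLow")
  never <- step_test("a", 1.0, c(150, 175, 200, 225), c(1.1, 1.2, 1.3, 1.4))
  expect_error(po_lt1(never), class = "UndeterminedHigh")

  # noiseless synthetic test: grid power just below the exact exponential solve
  st <- make_truth()
  sim <- simulate_step_test(st, noise_sd = 0, seed = 1)
  exact <- log((1 + st$baseline_lactate - st$baseline_lactate) / st$lac_a) /
    st$lac_k  # c(P) = c_b + 1  =>  a exp(kP) = 1
  grid_below <- max(sim$stages$power[sim$stages$power <= exact])
  expect_equal(po_lt1(sim), grid_below)
})

test_that("po_lt2 finds the acceleration maximum in closed form", {
  # quartic with c''(P) = -1e-4 (P - 220)^2 + 0.01 on [150, 300]
  b4 <- -1e-4 / 12
  b3 <- 2 * 1e-4 * 220 / 6
  b2 <- (0.01 - 1e-4 * 220^2) / 2
  cv <- make_curve(c(1, 0.001, b2, b3, b4), c(150, 300), degree = 4L)
  expect_equal(as.numeric(po_lt2(cv)), 220, tolerance = 1e-9)
  expect_null(attr(po_lt2(cv), "flag"))

  # convex second derivative (c'''' > 0): boundary maximum, flagged
  cvx <- make_curve(c(1, 0.001, -0.5, 0.001, 1e-6), c(150, 300), degree = 4L)
  out <- po_lt2(cvx)
  expect_identical(attr(out, "flag"), "BoundaryMaximum")
  expect_true(as.numeric(out) %in% c(150, 300))

  # degree guard
  cv3 <- fit_lactate_curve(quadratic_step_test(), 3)
  expect_error(po_lt2(cv3), class = "InvalidDegree")

  # grid oracle over random quartic fits
  set.seed(7)
  for (i in 1:50) {
    P <- seq(150, 150 + 25 * sample(5:8, 1), by = 25)
    L <- sort(1 + cumsum(abs(rnorm(length(P), 0.4, 0.3))))
    cv4 <- fit_lactate_curve(step_test("a", 1, P, L), 4)
    expect_lt(abs(as.numeric(po_lt2(cv4)) - lt2_grid_oracle(cv4)), 0.011)
  }
})

test_that("po_dmax matches symmetry and the grid-search oracle", {
  # parabola a (P - P0)^2 on a symmetric domain: tangent parallel to the
  # chord at the midpoint
  P <- seq(150, 350, by = 25)
  tt <- step_test("a", 0.4, P, 2e-4 * (P - 150)^2 + 0.5)
  cv <- fit_lactate_curve(tt, 3)
  expect_lt(abs(po_dmax(cv, tt) - (150 + 350) / 2), 0.02)

  # grid oracle on curves fitted to noisy simulated tests
  cfgs <- lapply(1:40, function(i) make_truth(index = i))
  set.seed(11)
  for (st in cfgs) {
    tt2 <- simulate_step_test(st, noise_sd = 0.15, seed = 11)
    if (nrow(tt2$stages) < 4) next
    cv2 <- fit_lactate_curve(tt2, 3)
    d <- tryCatch(po_dmax(cv2, tt2), xcp_error = function(e) NA_real_)
    if (is.na(d)) next
    expect_lt(abs(d - dmax_grid_oracle(cv2, tt2)), 0.011)
  }

  # perfectly linear lactate profile: chord and curve coincide
  lint <- step_test("a", 1, seq(150, 300, 25), seq(150, 300, 25) / 60)
  lincv <- fit_lactate_curve(lint, 3)
  expect_error(po_dmax(lincv, lint), class = "DegenerateChord")
})

test_that("extract_thresholds bundles markers and degrades with flags", {
  st <- make_truth()
  tt <- simulate_step_test(st, noise_sd = 0, seed = 1)
  th <- extract_thresholds(tt)
  # fixed-concentration markers recover the generative truth on this athlete
  # (bound is the measured cubic-vs-exponential lack of fit, ~1.4 W)
  expect_lt(abs(th$values[["po_x2_w"]] - st$po_x2_w), 2)
  expect_lt(abs(th$values[["po_x4_w"]] - st$po_x4_w), 2)
  expect_false(is.na(th$values[["po_lt1_w"]]))
  expect_false(is.na(th$values[["po_dmax_w"]]))
  # LT2 on exponential-shaped data peaks at the domain boundary: value
  # present, flag recorded
  expect_false(is.na(th$values[["po_lt2_w"]]))
  expect_true(any(grepl("po_lt2_w:BoundaryMaximum", th$flags)))
  # every determined marker lies inside the stage power range
  dom <- range(tt$stages$power)
  vals <- th$values[!is.na(th$values)]
  expect_true(all(vals >= dom[1] & vals <= dom[2]))

  # 4-stage test: degree-4 curve impossible, LT2 flagged undetermined
  tt4 <- step_test("a", 1, seq(150, 225, 25), c(1.2, 1.6, 2.4, 4.1))
  th4 <- extract_thresholds(tt4)
  expect_true(is.na(th4$values[["po_lt2_w"]]))
  expect_true(any(grepl("po_lt2_w:InsufficientStages", th4$flags)))
  expect_false(is.na(th4$values[["po_x4_w"]]))
})

test_that("noiseless synthetic tests keep the threshold order PO_X2 < PO_X4", {
  for (i in 1:20) {
    st <- make_truth(index = i, po_x2_wkg = 3.0 + i * 0.03,
                     po_x4_wkg = 3.7 + i * 0.03)
    tt <- simulate_step_test(st, noise_sd = 0, seed = 2)
    th <- extract_thresholds(tt)
    x2 <- th$values[["po_x2_w"]]; x4 <- th$values[["po_x4_w"]]
    if (!is.na(x2) && !is.na(x4)) expect_lt(x2, x4)
  }
})
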