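# Lactate step-test analysis: polynomial lactate-power curve fitting and the
# five threshold markers (PO_LT1, PO_LT2, PO at 2 / 4 mmol/L, PO_Dmax).

#' Construct a lactate step test
#'
#' Bundles one athlete's incremental test: a resting baseline lactate sample
#' and an ordered series of constant-power stages with end-stage blood lactate
#' (optionally heart rate and RPE). The standard protocol starts at 150 W and
#' adds 25 W per stage until lactate exceeds 4 mmol/L.
#'
#' @param athlete_id identifier (scalar).
#' @param baseline_lactate resting blood lactate, mmol/L (> 0).
#' @param power stage power outputs in W, strictly increasing.
#' @param lactate end-stage blood lactate, mmol/L, same length as `power`.
#' @param hr optional end-stage heart rate, bpm.
#' @param rpe optional end-stage rating of perceived exertion (Borg 1-10).
#' @return An object of class `step_test`.
#' @export
step_test <- function(athlete_id, baseline_lactate, power, lactate,
                      hr = NULL, rpe = NULL) {
  stopifnot(length(athlete_id) == 1L, length(baseline_lactate) == 1L)
  xcp_assert(is.numeric(power) && is.numeric(lactate) &&
               length(power) == length(lactate),
             "InvalidStepTest", "power and lactate must be numeric, same length")
  xcp_assert(all(diff(power) > 0), "InvalidStepTest",
             "stage powers must be strictly increasing")
  xcp_assert(all(lactate > 0), "InvalidStepTest", "lactate values must be > 0")
  xcp_assert(baseline_lactate > 0, "InvalidStepTest", "baseline lactate must be > 0")
  structure(
    list(athlete_id = athlete_id,
         baseline_lactate = as.numeric(baseline_lactate),
         stages = data.frame(
           power = as.numeric(power),
           lactate = as.numeric(lactate),
           hr = if (is.null(hr)) NA_real_ else as.numeric(hr),
           rpe = if (is.null(rpe)) NA_real_ else as.numeric(rpe))),
    class = "step_test")
}

#' @export
print.step_test <- function(x, ...) {
  cat(sprintf("Lactate step test: athlete %s, baseline %.2f mmol/L, %d stages (%g-%g W)\n",
              x$athlete_id, x$baseline_lactate, nrow(x$stages),
              min(x$stages$power), max(x$stages$power)))
  invisible(x)
}

#' Fit a polynomial lactate-power curve
#'
#' Ordinary least-squares polynomial of the end-stage lactate values on stage
#' power. The resting baseline is excluded (it is not taken at a work rate).
#' Degree 3 is the convention for fixed-concentration and Dmax markers; degree
#' 4 is required for the second lactate threshold, whose definition (maximum of
#' the second derivative) needs a curve whose acceleration can peak in the
#' interior of the power range.
#'
#' @param test a [step_test()].
#' @param degree polynomial degree, 3 or 4.
#' @return An object of class `lactate_curve` with fields `degree`,
#'   `coefficients` (ascending powers), `domain` (first/last stage power) and
#'   `rss` (residual sum of squares).
#' @export
fit_lactate_curve <- function(test, degree = 3L) {
  stopifnot(inherits(test, "step_test"))
  degree <- as.integer(degree)
  xcp_assert(degree %in% c(3L, 4L), "InvalidDegree", "degree must be 3 or 4")
  P <- test$stages$power
  L <- test$stages$lactate
  xcp_assert(length(P) >= degree + 1L, "InsufficientStages",
             sprintf("degree-%d fit needs >= %d stages, got %d",
                     degree, degree + 1L, length(P)))
  X <- outer(P, 0:degree, `^`)
  qr_x <- qr(X)
  if (qr_x$rank < degree + 1L)
    xcp_error("DegenerateDesign", "rank-deficient design (duplicate powers?)")
  beta <- qr.coef(qr_x, L)
  res <- L - drop(X %*% beta)
  structure(
    list(degree = degree,
         coefficients = as.numeric(beta),
         domain = c(P[1L], P[length(P)]),
         rss = sum(res^2),
         n_stages = length(P)),
    class = "lactate_curve")
}

#' Evaluate a fitted lactate curve
#'
#' @param curve a `lactate_curve`.
#' @param power numeric vector of powers (W).
#' @return predicted lactate, mmol/L.
#' @export
eval_lactate_curve <- function(curve, power) {
  stopifnot(inherits(curve, "lactate_curve"))
  poly_eval(curve$coefficients, power)
}

#' @export
print.lactate_curve <- function(x, ...) {
  cat(sprintf("Lactate curve: degree %d on [%g, %g] W, RSS %.3g\n",
              x$degree, x$domain[1], x$domain[2], x$rss))
  invisible(x)
}

#' Power output at a fixed blood lactate concentration
#'
#' Inverts the fitted curve at `c_target` (e.g. 2 or 4 mmol/L): the smallest
#' real root of `curve(P) = c_target` inside the curve's domain at which the
#' curve is locally increasing. Spurious polynomial roots on a decreasing
#' branch are rejected because the physiological curve is monotone.
#'
#' @param curve a `lactate_curve`.
#' @param c_target target concentration, mmol/L (> 0).
#' @param resolution reported power resolution in W.
#' @return power in W, rounded to `resolution` (ties toward lower power).
#' @export
po_at_fixed_lactate <- function(curve, c_target, resolution = 0.01) {
  stopifnot(inherits(curve, "lactate_curve"))
  xcp_assert(is.numeric(c_target) && length(c_target) == 1L && c_target > 0,
             "InvalidTarget", "c_target must be a positive scalar")
  dom <- curve$domain
  coefs <- curve$coefficients
  coefs[1L] <- coefs[1L] - c_target
  eps <- 1e-9 * max(1, abs(dom))
  roots <- poly_real_roots(coefs)
  roots <- roots[roots >= dom[1L] - eps & roots <= dom[2L] + eps]
  roots <- pmin(pmax(roots, dom[1L]), dom[2L])
  if (length(roots)) {
    dcoefs <- poly_deriv(curve$coefficients)
    incr <- poly_eval(dcoefs, roots) > 0
    # exact tangency (derivative == 0) counts as increasing-side touch
    incr <- incr | abs(poly_eval(dcoefs, roots)) < 1e-12
    roots <- roots[incr]
  }
  if (!length(roots)) {
    if (eval_lactate_curve(curve, dom[1L]) > c_target)
      xcp_error("AlreadyExceeded",
                sprintf("curve already above %.3g mmol/L at first stage", c_target))
    xcp_error("NotReached",
              sprintf("curve never attains %.3g mmol/L in [%g, %g] W",
                      c_target, dom[1L], dom[2L]))
  }
  round_resolution(min(roots), resolution)
}

#' First lactate threshold (stage rule)
#'
#' The work rate preceding the first stage whose *measured* lactate rises at
#' least 1 mmol/L above the resting baseline. A stage-discrete rule on
#' observed values; no curve fit is involved.
#'
#' @param test a [step_test()].
#' @param delta rise above baseline defining the threshold, mmol/L.
#' @return power in W (one of the stage powers).
#' @export
po_lt1 <- function(test, delta = 1.0) {
  stopifnot(inherits(test, "step_test"))
  xcp_assert(nrow(test$stages) >= 2L, "InsufficientStages", "need >= 2 stages")
  cut <- test$baseline_lactate + delta
  idx <- which(test$stages$lactate >= cut)
  if (!length(idx))
    xcp_error("UndeterminedHigh",
              sprintf("no stage reaches baseline + %.2f mmol/L", delta))
  first <- min(idx)
  if (first == 1L)
    xcp_error("UndeterminedLow",
              "first stage already exceeds baseline + 1 mmol/L")
  test$stages$power[first - 1L]
}

#' Second lactate threshold (maximum acceleration)
#'
#' The power at which the second derivative of the fitted lactate curve is
#' maximal. For a degree-4 curve the second derivative is a quadratic in P, so
#' the maximiser is found in closed form from its vertex and the domain
#' endpoints. A cubic's second derivative is linear (maximised only at a
#' boundary), hence the degree-4 requirement.
#'
#' @param curve a degree-4 `lactate_curve`.
#' @param resolution reported power resolution in W.
#' @return power in W, with attribute `flag = "BoundaryMaximum"` when the
#'   maximiser falls on a domain endpoint.
#' @export
po_lt2 <- function(curve, resolution = 0.01) {
  stopifnot(inherits(curve, "lactate_curve"))
  xcp_assert(curve$degree == 4L, "InvalidDegree",
             "PO_LT2 needs a degree-4 curve (interior acceleration maximum)")
  # c''(P) = 2 b2 + 6 b3 P + 12 b4 P^2  (coefficients ascending b0..b4)
  b <- curve$coefficients
  d2 <- c(2 * b[3L], 6 * b[4L], 12 * b[5L])
  dom <- curve$domain
  cand <- dom
  if (d2[3L] < 0) {                      # concave quadratic: interior vertex
    vertex <- -d2[2L] / (2 * d2[3L])
    if (vertex > dom[1L] && vertex < dom[2L]) cand <- c(cand, vertex)
  }
  vals <- poly_eval(d2, cand)
  best <- cand[which.max(vals)]
  # ties toward lower power
  best <- min(cand[abs(vals - max(vals)) < 1e-12])
  out <- round_resolution(best, resolution)
  if (abs(best - dom[1L]) < 1e-9 || abs(best - dom[2L]) < 1e-9)
    attr(out, "flag") <- "BoundaryMaximum"
  out
}

#' Dmax lactate threshold
#'
#' The power maximising the perpendicular distance from the chord joining the
#' first and last *measured* lactate points to the fitted curve, both axes in
#' raw units (W, mmol/L). Because the chord is fixed, the maximiser is a root
#' of `curve'(P) = slope(chord)`; candidates are screened for the maximal
#' signed distance.
#'
#' @param curve a `lactate_curve` fitted to `test`.
#' @param test the [step_test()] providing the chord endpoints.
#' @param resolution reported power resolution in W.
#' @return power in W.
#' @export
po_dmax <- function(curve, test, resolution = 0.01) {
  stopifnot(inherits(curve, "lactate_curve"), inherits(test, "step_test"))
  xcp_assert(nrow(test$stages) >= 2L, "InsufficientStages", "need >= 2 stages")
  P1 <- test$stages$power[1L]
  P2 <- test$stages$power[nrow(test$stages)]
  L1 <- test$stages$lactate[1L]
  L2 <- test$stages$lactate[nrow(test$stages)]
  slope <- (L2 - L1) / (P2 - P1)
  # distance(P) proportional to |curve(P) - (L1 + slope (P - P1))|;
  # stationary points: curve'(P) = slope
  dcoefs <- poly_deriv(curve$coefficients)
  dcoefs[1L] <- dcoefs[1L] - slope
  cand <- poly_real_roots(dcoefs)
  cand <- cand[cand > P1 & cand < P2]
  if (!length(cand)) xcp_error("DegenerateChord",
                               "no interior stationary point of chord distance")
  gap <- function(P) abs(eval_lactate_curve(curve, P) - (L1 + slope * (P - P1)))
  g <- gap(cand)
  if (max(g) < 1e-6)
    xcp_error("DegenerateChord", "curve collinear with chord (all distances < 1e-6)")
  best <- min(cand[abs(g - max(g)) < 1e-12])  # ties toward lower power
  round_resolution(best, resolution)
}

#' Extract the full threshold set from a step test
#'
#' Orchestrates the five markers: a degree-3 curve for the fixed 2 / 4 mmol/L
#' powers and Dmax, a degree-4 curve for PO_LT2 (when the stage count allows),
#' and the stage-discrete PO_LT1 rule. Per-marker failures are recorded as
#' `NA` with a reason flag; the athlete is never aborted.
#'
#' @param test a [step_test()].
#' @return An object of class `threshold_set`: named numeric `values`
#'   (po_lt1_w, po_lt2_w, po_x2_w, po_x4_w, po_dmax_w) and character `flags`.
#' @export
extract_thresholds <- function(test) {
  stopifnot(inherits(test, "step_test"))
  values <- c(po_lt1_w = NA_real_, po_lt2_w = NA_real_, po_x2_w = NA_real_,
              po_x4_w = NA_real_, po_dmax_w = NA_real_)
  flags <- character(0)
  grab <- function(name, expr) {
    res <- tryCatch(expr, xcp_error = function(e) {
      flags <<- c(flags, paste0(name, ":", class(e)[1L]))
      NA_real_
    })
    if (!is.null(attr(res, "flag"))) {
      flags <<- c(flags, paste0(name, ":", attr(res, "flag")))
      attributes(res) <- NULL
    }
    values[[name]] <<- res
  }
  curve3 <- tryCatch(fit_lactate_curve(test, 3L), xcp_error = function(e) {
    flags <<- c(flags, paste0("curve3:", class(e)[1L])); NULL
  })
  curve4 <- tryCatch(fit_lactate_curve(test, 4L), xcp_error = function(e) {
    flags <<- c(flags, paste0("po_lt2_w:", class(e)[1L])); NULL
  })
  grab("po_lt1_w", po_lt1(test))
  if (!is.null(curve3)) {
    grab("po_x2_w", po_at_fixed_lactate(curve3, 2))
    grab("po_x4_w", po_at_fixed_lactate(curve3, 4))
    grab("po_dmax_w", po_dmax(curve3, test))
  }
  if (!is.null(curve4)) grab("po_lt2_w", po_lt2(curve4))
  structure(list(athlete_id = test$athlete_id, values = values, flags = flags),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Thresholds for athlete %s:\n", x$athlete_id))
  for (nm in names(x$values))
    cat(sprintf("  %-10s %s\n", nm,
                ifelse(is.na(x$values[[nm]]), "undetermined",
                       sprintf("%.2f W", x$values[[nm]]))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
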