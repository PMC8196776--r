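# Power-profile reduction: mean maximal power, the critical-power (CP/W')
# hyperbola fitted on the P vs 1/t line, the Kuipers maximal-aerobic-power
# equation, the graded-test validity rule, and body-mass normalisation.

#' Mean maximal power over a rolling window
#'
#' Maximum over all contiguous windows of `window_s` samples of the window
#' mean, for a 1 Hz power stream.
#'
#' @param stream numeric vector of 1 Hz power samples (W).
#' @param window_s window length in seconds (>= 1).
#' @return mean maximal power, W.
#' @export
mean_max_power <- function(stream, window_s) {
  window_s <- as.integer(window_s)
  xcp_assert(window_s >= 1L, "InvalidWindow", "window_s must be >= 1")
  xcp_assert(length(stream) >= window_s, "InsufficientSamples",
             sprintf("stream has %d samples, window needs %d",
                     length(stream), window_s))
  cs <- cumsum(c(0, stream))
  n <- length(stream)
  sums <- cs[(window_s + 1L):(n + 1L)] - cs[1:(n - window_s + 1L)]
  max(sums) / window_s
}

#' Fit the critical-power model
#'
#' Linearised two-parameter power-duration model: ordinary least squares of
#' mean power on 1/t across timed maximal efforts, so the intercept is CP
#' (W, the asymptote) and the slope is W' (J, the finite work capacity above
#' CP). The standard input is the 60 s, 5 min and 10 min effort means.
#'
#' @param t_s effort durations, seconds (>= 3 distinct values).
#' @param power_w mean power of each effort, W.
#' @return An object of class `cp_model` with `cp_w`, `w_prime_j`,
#'   `w_prime_kj`, `r_squared` and the points used.
#' @export
fit_cp <- function(t_s, power_w) {
  xcp_assert(length(t_s) == length(power_w) && length(t_s) >= 3L,
             "InsufficientPoints", "need >= 3 (duration, power) points")
  xcp_assert(!anyDuplicated(t_s), "DegenerateDesign", "durations must be distinct")
  xcp_assert(all(t_s > 0) && all(power_w > 0), "InvalidPoints",
             "durations and powers must be positive")
  inv_t <- 1 / t_s
  fit <- stats::lm.fit(cbind(1, inv_t), power_w)
  beta <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((power_w - mean(power_w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(cp_w = unname(beta[1L]), w_prime_j = unname(beta[2L]),
         w_prime_kj = unname(beta[2L]) / 1000, r_squared = r2,
         points = data.frame(t_s = t_s, power_w = power_w)),
    class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf("CP model: CP %.1f W, W' %.1f kJ, R^2 %.4f (%d efforts)\n",
              x$cp_w, x$w_prime_kj, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Graded-test endpoint
#'
#' Endpoint of a 25 W / 1 min ramp to exhaustion: last completed workload and
#' seconds ridden into the uncompleted stage, plus the exhaustion criteria
#' inputs (maximal RPE and HR, age).
#'
#' @param last_completed_w last fully completed workload, W.
#' @param seconds_into_stage time into the uncompleted stage, s (0 <= t < 60).
#' @param max_rpe maximal RPE (Borg 1-10), optional.
#' @param max_hr maximal heart rate, bpm, optional.
#' @param age_yr athlete age in years, optional.
#' @param stage_increment_w ramp increment, W.
#' @param stage_duration_s stage duration, s.
#' @return object of class `graded_endpoint`.
#' @export
graded_endpoint <- function(last_completed_w, seconds_into_stage,
                            max_rpe = NA_real_, max_hr = NA_real_,
                            age_yr = NA_real_,
                            stage_increment_w = 25, stage_duration_s = 60) {
  xcp_assert(seconds_into_stage >= 0 && seconds_into_stage < stage_duration_s,
             "InvalidEndpoint",
             sprintf("seconds_into_stage must lie in [0, %g)", stage_duration_s))
  xcp_assert(last_completed_w > 0, "InvalidEndpoint", "workload must be positive")
  structure(list(last_completed_w = last_completed_w,
                 seconds_into_stage = seconds_into_stage,
                 max_rpe = max_rpe, max_hr = max_hr, age_yr = age_yr,
                 stage_increment_w = stage_increment_w,
                 stage_duration_s = stage_duration_s),
            class = "graded_endpoint")
}

#' Maximal aerobic power from a graded-test endpoint (Kuipers equation)
#'
#' `PO_VO2max = W_f + (t / stage_duration) * stage_increment`: the last
#' completed workload plus the completed fraction of the final, uncompleted
#' stage, for the standard 25 W / 1 min ramp.
#'
#' @param endpoint a [graded_endpoint()].
#' @return power at VO2max, W.
#' @export
kuipers_po_vo2max <- function(endpoint) {
  stopifnot(inherits(endpoint, "graded_endpoint"))
  endpoint$last_completed_w +
    endpoint$seconds_into_stage / endpoint$stage_duration_s *
    endpoint$stage_increment_w
}

#' Graded-test validity rule
#'
#' A maximal test is accepted when RPE exceeded 9 on the Borg 1-10 scale and
#' maximal HR exceeded 80% of the age-predicted maximum (220 - age). Invalid
#' tests are flagged, not dropped.
#'
#' @param endpoint a [graded_endpoint()] carrying `max_rpe`, `max_hr`, `age_yr`.
#' @return `"valid"`, `"invalid"`, or `"UnknownValidity"` when a field is
#'   missing.
#' @export
check_test_validity <- function(endpoint) {
  stopifnot(inherits(endpoint, "graded_endpoint"))
  if (is.na(endpoint$max_rpe) || is.na(endpoint$max_hr) || is.na(endpoint$age_yr))
    return("UnknownValidity")
  hr_cut <- 0.8 * (220 - endpoint$age_yr)
  if (endpoint$max_rpe > 9 && endpoint$max_hr > hr_cut) "valid" else "invalid"
}

#' Normalise power markers to body mass
#'
#' @param markers named numeric vector of absolute markers (W).
#' @param mass_kg body mass, kg (> 0).
#' @return markers in W/kg, same names.
#' @export
normalise_markers <- function(markers, mass_kg) {
  xcp_assert(is.numeric(mass_kg) && length(mass_kg) == 1L && mass_kg > 0,
             "InvalidMass", "mass_kg must be a positive scalar")
  markers / mass_kg
}
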