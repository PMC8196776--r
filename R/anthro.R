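# Anthropometric indices: sum of six skinfolds, five-way tissue fractionation
# against the phantom reference, squat-jump height from flight time, and
# isometric knee-extension summaries.

# md5 of the shipped constants fixtures; a mismatch aborts (edited constants
# must not silently change every downstream mass).
.phantom_md5 <- c(
  phantom_indicators_synthetic.csv = "ac5609acf83205dc817d0f82b16ebccf",
  phantom_tissues_synthetic.csv    = "746e183306448cd040bdd663f7873604")

.phantom_cache <- new.env(parent = emptyenv())

PHANTOM_STATURE_CM <- 170.18

phantom_constants <- function() {
  if (!is.null(.phantom_cache$tab)) return(.phantom_cache$tab)
  paths <- vapply(names(.phantom_md5), function(f)
    system.file("extdata", f, package = "xcprofiler", mustWork = TRUE),
    character(1))
  sums <- tools::md5sum(paths)
  ok <- unname(sums) == unname(.phantom_md5)
  if (!all(ok))
    xcp_error("ConstantsChecksumMismatch",
              paste("phantom constants fixture fails its checksum:",
                    paste(names(.phantom_md5)[!ok], collapse = ", ")))
  tab <- list(
    indicators = utils::read.csv(paths[1L], stringsAsFactors = FALSE),
    tissues = utils::read.csv(paths[2L], stringsAsFactors = FALSE))
  .phantom_cache$tab <- tab
  tab
}

.sf_sites <- c("triceps", "subscapular", "supraspinale", "abdominal",
               "front_thigh", "medial_calf")
.girth_sites <- c("arm_relaxed", "arm_flexed", "forearm", "chest", "waist",
                  "hip", "thigh", "calf", "head")
.breadth_sites <- c("biacromial", "biiliocristal", "humerus", "femur", "wrist")

#' Construct a full anthropometric measurement set
#'
#' Container for the restricted-profile measurements the five-way
#' fractionation needs: six skinfolds (mm), girths (cm), bone breadths (cm),
#' stature and body mass.
#'
#' @param height_cm stature, cm (100-220).
#' @param mass_kg body mass, kg (30-120).
#' @param skinfolds named numeric, mm: triceps, subscapular, supraspinale,
#'   abdominal, front_thigh, medial_calf.
#' @param girths named numeric, cm: arm_relaxed, arm_flexed, forearm, chest,
#'   waist, hip, thigh, calf, head (any subset; missing sites flag the tissues
#'   that need them).
#' @param breadths named numeric, cm: biacromial, biiliocristal, humerus,
#'   femur, wrist.
#' @return object of class `anthro_measures`.
#' @export
anthro_measures <- function(height_cm, mass_kg, skinfolds = numeric(),
                            girths = numeric(), breadths = numeric()) {
  xcp_assert(height_cm >= 100 && height_cm <= 220, "InvalidMeasure",
             "height_cm outside 100-220 cm")
  xcp_assert(mass_kg >= 30 && mass_kg <= 120, "InvalidMeasure",
             "mass_kg outside 30-120 kg")
  all_vals <- c(skinfolds, girths, breadths)
  xcp_assert(all(all_vals > 0), "InvalidMeasure", "all measurements must be > 0")
  structure(list(height_cm = height_cm, mass_kg = mass_kg,
                 skinfolds = skinfolds, girths = girths, breadths = breadths),
            class = "anthro_measures")
}

#' Sum of six skinfolds
#'
#' Adiposity index: triceps + subscapular + supraspinale (suprailiac) +
#' abdominal + front thigh + medial calf, in mm.
#'
#' @param measures an [anthro_measures()].
#' @return sum in mm.
#' @export
sum6_skinfolds <- function(measures) {
  stopifnot(inherits(measures, "anthro_measures"))
  missing <- setdiff(.sf_sites, names(measures$skinfolds))
  if (length(missing))
    xcp_error("MissingSkinfold",
              paste("missing skinfold site(s):", paste(missing, collapse = ", ")))
  sum(measures$skinfolds[.sf_sites])
}

# Indicator values derivable from a measurement set; corrected girths subtract
# the overlying skinfold (pi * mm / 10 converts the fold to a girth decrement).
indicator_value <- function(measures, indicator) {
  sf <- measures$skinfolds
  g <- measures$girths
  b <- measures$breadths
  pick <- function(v, nm) if (nm %in% names(v)) unname(v[[nm]]) else NA_real_
  corr <- function(girth, fold) {
    gv <- pick(g, girth); fv <- pick(sf, fold)
    if (is.na(gv) || is.na(fv)) NA_real_ else gv - pi * fv / 10
  }
  switch(indicator,
    sf_triceps = pick(sf, "triceps"),
    sf_subscapular = pick(sf, "subscapular"),
    sf_supraspinale = pick(sf, "supraspinale"),
    sf_abdominal = pick(sf, "abdominal"),
    sf_front_thigh = pick(sf, "front_thigh"),
    sf_medial_calf = pick(sf, "medial_calf"),
    girth_arm_relaxed_corr = corr("arm_relaxed", "triceps"),
    girth_forearm = pick(g, "forearm"),
    girth_chest_corr = corr("chest", "subscapular"),
    girth_thigh_corr = corr("thigh", "front_thigh"),
    girth_calf_corr = corr("calf", "medial_calf"),
    breadth_biacromial = pick(b, "biacromial"),
    breadth_biiliocristal = pick(b, "biiliocristal"),
    breadth_humerus = pick(b, "humerus"),
    breadth_femur = pick(b, "femur"),
    breadth_wrist = pick(b, "wrist"),
    girth_waist = pick(g, "waist"),
    girth_hip = pick(g, "hip"),
    girth_head = pick(g, "head"),
    NA_real_)
}

#' Five-way tissue fractionation
#'
#' Partitions body mass into adipose, muscle, bone, residual and skin tissue
#' masses via phantom z-scores: each indicator is height-standardised to the
#' 170.18 cm phantom, z-scored against the phantom mean/SD, and the mean
#' tissue z maps back to a mass rescaled by `(height / 170.18)^3`.
#' Percentages are taken against the *measured* body mass, so the five
#' fractions need not sum to exactly 100% (the method's known tolerance is a
#' few percent either way).
#'
#' @param measures an [anthro_measures()].
#' @return object of class `fiveway_masses`: data frame with tissue, mass_kg,
#'   pct_body_mass, mean z and n_indicators; tissues with missing indicators
#'   are NA and flagged.
#' @export
five_way_fractionation <- function(measures) {
  stopifnot(inherits(measures, "anthro_measures"))
  const <- phantom_constants()
  hratio <- PHANTOM_STATURE_CM / measures$height_cm
  out <- const$tissues
  out$z <- NA_real_
  out$n_indicators <- 0L
  out$mass_kg <- NA_real_
  out$pct_body_mass <- NA_real_
  flags <- character(0)
  for (i in seq_len(nrow(out))) {
    tis <- out$tissue[i]
    ind <- const$indicators[const$indicators$tissue == tis, ]
    x <- vapply(ind$indicator, function(nm) indicator_value(measures, nm),
                numeric(1))
    if (anyNA(x)) {
      flags <- c(flags, paste0(tis, ":MissingIndicator:",
                               paste(ind$indicator[is.na(x)], collapse = "+")))
      next
    }
    z <- (x * hratio^ind$exponent - ind$phantom_mean) / ind$phantom_sd
    zbar <- mean(z)
    mass <- (zbar * out$phantom_sd_kg[i] + out$phantom_mass_kg[i]) / hratio^3
    out$z[i] <- zbar
    out$n_indicators[i] <- length(z)
    out$mass_kg[i] <- mass
    out$pct_body_mass[i] <- 100 * mass / measures$mass_kg
    if (mass <= 0) flags <- c(flags, paste0(tis, ":NonPositiveMass"))
  }
  structure(list(table = out[, c("tissue", "mass_kg", "pct_body_mass", "z",
                                 "n_indicators")],
                 mass_kg = measures$mass_kg, flags = flags),
            class = "fiveway_masses")
}

#' @export
print.fiveway_masses <- function(x, ...) {
  cat("Five-way fractionation (body mass", sprintf("%.2f kg):\n", x$mass_kg))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Squat-jump height from flight time
#'
#' Ballistic flight: `h = g t^2 / 8` with standard gravity
#' g = 9.80665 m/s^2, returned in cm.
#'
#' @param flight_time_s flight time, s (0 < t < 1.2).
#' @return jump height, cm.
#' @export
jump_height_from_flight <- function(flight_time_s) {
  xcp_assert(is.numeric(flight_time_s) && all(flight_time_s > 0) &&
               all(flight_time_s < 1.2),
             "InvalidFlightTime", "flight time must lie in (0, 1.2) s")
  9.80665 * flight_time_s^2 / 8 * 100
}

#' Isometric knee-extension summary
#'
#' Per-leg maximum across maximal attempts, absolute asymmetry |R - L|, and
#' body-mass-normalised forces.
#'
#' @param right_n numeric vector of right-leg attempt maxima, N (>= 1).
#' @param left_n numeric vector of left-leg attempt maxima, N (>= 1).
#' @param mass_kg body mass for normalisation, kg.
#' @param squat_jump_flight_s optional squat-jump flight times, s; the best
#'   attempt defines jump height.
#' @return object of class `strength_profile`.
#' @export
isometric_summary <- function(right_n, left_n, mass_kg,
                              squat_jump_flight_s = NULL) {
  xcp_assert(length(right_n) >= 1L && length(left_n) >= 1L, "NoAttempts",
             "need at least one attempt per leg")
  xcp_assert(all(c(right_n, left_n) > 0), "InvalidForce", "forces must be > 0")
  xcp_assert(mass_kg > 0, "InvalidMass", "mass must be > 0")
  r <- max(right_n); l <- max(left_n)
  sj <- if (is.null(squat_jump_flight_s)) NA_real_ else
    max(jump_height_from_flight(squat_jump_flight_s))
  structure(list(right_max_n = r, left_max_n = l,
                 asymmetry_n = abs(r - l),
                 right_n_per_kg = r / mass_kg, left_n_per_kg = l / mass_kg,
                 squat_jump_cm = sj),
            class = "strength_profile")
}

#' @export
print.strength_profile <- function(x, ...) {
  cat(sprintf(
    "Strength: R %.0f N, L %.0f N, asymmetry %.0f N (%.1f / %.1f N/kg)%s\n",
    x$right_max_n, x$left_max_n, x$asymmetry_n,
    x$right_n_per_kg, x$left_n_per_kg,
    if (is.na(x$squat_jump_cm)) "" else
      sprintf("; squat jump %.1f cm", x$squat_jump_cm)))
  invisible(x)
}
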