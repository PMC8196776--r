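# Synthetic cohort generator. Emulates a 10-rider junior national squad:
# normalised power markers drawn around the published squad moments with a
# single latent ability factor inducing their collinearity, an exponential
# lactate-power curve anchored exactly at the 2 and 4 mmol/L powers, field
# efforts on the CP/W' hyperbola, and race time generated from the published
# three-marker equation plus noise. Everything is seeded and reproducible;
# per-athlete substreams are derived from the athlete index so cohorts are
# extensible without reshuffling earlier athletes.

# Published squad moments (normalised W/kg unless noted)
.default_marker_means <- c(po_x2 = 3.24, po_x4 = 3.86, po_vo2max = 5.29,
                           cp = 3.91, p_30s = 10.45, p_sprint = 13.52)
.default_marker_sds <- c(po_x2 = 0.49, po_x4 = 0.43, po_vo2max = 0.38,
                         cp = 0.65, p_30s = 0.94, p_sprint = 2.80)

# Race-time truth: the published three-marker equation (min, inputs W/kg)
RACE_EQ_COEF <- c(intercept = 255.86, po_vo2max = -32.87,
                  po_x4 = -51.18, po_x2 = 60.77)

race_time_from_markers <- function(po_vo2max_rel, po_x4_rel, po_x2_rel) {
  RACE_EQ_COEF[["intercept"]] +
    RACE_EQ_COEF[["po_vo2max"]] * po_vo2max_rel +
    RACE_EQ_COEF[["po_x4"]] * po_x4_rel +
    RACE_EQ_COEF[["po_x2"]] * po_x2_rel
}

#' Generator configuration
#'
#' Defaults restate the published squad: 10 riders, body mass 67.22 +/- 7.49
#' kg, marker means/SDs from the squad's normalised (W/kg) profile, latent
#' correlation 0.85, race noise 2 min, stage lactate noise 0.15 mmol/L,
#' effort power CV 2%, baseline lactate 1.0 +/- 0.2 mmol/L. W'/kg defaults to
#' 282 +/- 40 J/kg so the 5 min - 10 min effort gap matches the squad's.
#'
#' @param n_athletes cohort size (>= 1).
#' @param seed integer master seed.
#' @param marker_means,marker_sds named numeric, normalised markers (W/kg).
#' @param mass_mean_kg,mass_sd_kg body-mass moments.
#' @param r latent correlation in [0, 1).
#' @param race_noise_sd_min race-time noise SD, minutes (>= 0).
#' @param stage_lactate_noise_sd measured stage lactate noise, mmol/L.
#' @param effort_power_noise_cv multiplicative CV on effort means.
#' @param baseline_lactate_mean,baseline_lactate_sd resting lactate moments.
#' @param w_prime_per_kg_mean,w_prime_per_kg_sd W' per kg moments (J/kg).
#' @param age_mean_yr,age_sd_yr,height_mean_cm,height_sd_cm cohort moments.
#' @param sum6_mean_mm,sum6_sd_mm six-skinfold-sum moments.
#' @param squat_jump_mean_cm,squat_jump_sd_cm squat-jump moments.
#' @param knee_right_mean_n,knee_right_sd_n,knee_left_mean_n,knee_left_sd_n
#'   isometric knee-extension moments.
#' @param drop_one drop one athlete at random from the written cohort (mimics
#'   a regression run on one fewer complete case); default off.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_athletes = 10L, seed = 42L,
                             marker_means = .default_marker_means,
                             marker_sds = .default_marker_sds,
                             mass_mean_kg = 67.22, mass_sd_kg = 7.49,
                             r = 0.85,
                             race_noise_sd_min = 2.0,
                             stage_lactate_noise_sd = 0.15,
                             effort_power_noise_cv = 0.02,
                             baseline_lactate_mean = 1.0,
                             baseline_lactate_sd = 0.2,
                             w_prime_per_kg_mean = 282,
                             w_prime_per_kg_sd = 40,
                             age_mean_yr = 16.3, age_sd_yr = 0.95,
                             height_mean_cm = 176.74, height_sd_cm = 4.23,
                             sum6_mean_mm = 47.71, sum6_sd_mm = 8.24,
                             squat_jump_mean_cm = 26.6, squat_jump_sd_cm = 3.72,
                             knee_right_mean_n = 3827.1, knee_right_sd_n = 900.3,
                             knee_left_mean_n = 3274.6, knee_left_sd_n = 1849.9,
                             drop_one = FALSE) {
  xcp_assert(n_athletes >= 1L, "InvalidConfig", "n_athletes must be >= 1")
  xcp_assert(r >= 0 && r < 1, "InvalidConfig", "r must lie in [0, 1)")
  sds <- c(marker_sds, mass_sd_kg, race_noise_sd_min, stage_lactate_noise_sd,
           effort_power_noise_cv, baseline_lactate_sd, w_prime_per_kg_sd)
  xcp_assert(all(sds >= 0), "InvalidConfig", "all SDs must be >= 0")
  xcp_assert(identical(sort(names(marker_means)), sort(names(marker_sds))),
             "InvalidConfig", "marker_means and marker_sds must share names")
  needed <- c("po_x2", "po_x4", "po_vo2max", "cp")
  xcp_assert(all(needed %in% names(marker_means)), "InvalidConfig",
             paste("marker_means must include", paste(needed, collapse = ", ")))
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

#' Sample the latent truth for a cohort
#'
#' Each normalised marker is `mean + sd * (sqrt(r) A + sqrt(1-r) eps)` with a
#' per-athlete latent ability A and idiosyncratic eps, all standard normal;
#' absolute watts are normalised values times body mass. The exponential
#' lactate curve `c(P) = c_b + a exp(k P)` is solved so that it passes exactly
#' through 2 mmol/L at the athlete's PO_X2 and 4 mmol/L at PO_X4. True race
#' time is the published equation on the normalised markers plus
#' `Normal(0, race_noise_sd_min)`, floored at 30 min. Draws violating the
#' marker ordering PO_X2 < PO_X4 < PO_VO2max, a non-physiological body mass,
#' or an unsolvable lactate curve are rejected and redrawn (logged via the
#' `redraws` attribute).
#'
#' @param config a [generator_config()].
#' @return list of per-athlete truth states (class `athlete_truth`), with
#'   attribute `redraws` counting rejected draws.
#' @export
sample_cohort_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mm <- config$marker_means
  ms <- config$marker_sds
  redraws <- 0L
  out <- vector("list", config$n_athletes)
  for (i in seq_len(config$n_athletes)) {
    set.seed(derive_seed(config$seed, i, salt = 1L))
    repeat {
      A <- stats::rnorm(1)
      eps <- stats::rnorm(length(mm))
      rel <- mm + ms * (sqrt(config$r) * A + sqrt(1 - config$r) * eps)
      names(rel) <- names(mm)
      mass <- stats::rnorm(1, config$mass_mean_kg, config$mass_sd_kg)
      c_b <- stats::rnorm(1, config$baseline_lactate_mean,
                          config$baseline_lactate_sd)
      wpk <- stats::rnorm(1, config$w_prime_per_kg_mean,
                          config$w_prime_per_kg_sd)
      ok <- rel[["po_x2"]] < rel[["po_x4"]] &&
        rel[["po_x4"]] < rel[["po_vo2max"]] &&
        all(rel > 0) && wpk > 0 &&
        mass > 40 && mass < 110 &&
        c_b > 0.4 && c_b < 1.8
      if (ok) break
      redraws <- redraws + 1L
    }
    age <- stats::rnorm(1, config$age_mean_yr, config$age_sd_yr)
    height <- min(max(stats::rnorm(1, config$height_mean_cm,
                                   config$height_sd_cm), 150), 210)
    x2_w <- rel[["po_x2"]] * mass
    x4_w <- rel[["po_x4"]] * mass
    k <- log((4 - c_b) / (2 - c_b)) / (x4_w - x2_w)
    a <- (2 - c_b) * exp(-k * x2_w)
    race <- race_time_from_markers(rel[["po_vo2max"]], rel[["po_x4"]],
                                   rel[["po_x2"]]) +
      stats::rnorm(1, 0, config$race_noise_sd_min)
    race <- max(race, 30)
    out[[i]] <- structure(list(
      athlete_id = sprintf("ath%02d", i),
      index = i,
      age_yr = age,
      height_cm = height,
      mass_kg = mass,
      latent_ability = A,
      markers_rel = rel,
      po_x2_w = x2_w,
      po_x4_w = x4_w,
      po_vo2max_w = rel[["po_vo2max"]] * mass,
      cp_w = rel[["cp"]] * mass,
      w_prime_j = wpk * mass,
      baseline_lactate = c_b,
      lac_a = a,
      lac_k = k,
      race_time_min = race), class = "athlete_truth")
  }
  attr(out, "redraws") <- redraws
  out
}

# True lactate at power P for an athlete's generative curve
true_lactate <- function(state, power) {
  state$baseline_lactate + state$lac_a * exp(state$lac_k * power)
}

#' Simulate a lactate step test from an athlete's truth
#'
#' Stages at `start_w`, `start_w + increment_w`, ...; measured lactate is the
#' generative curve plus Normal(0, noise_sd) clipped at 0.4 mmol/L (analyser
#' floor). The protocol stops at the first stage whose *noiseless* lactate
#' exceeds 4 mmol/L (that stage is ridden and sampled), so stage counts are
#' stable across noise settings. HR and RPE are filled with plausible ramps.
#'
#' @param state an `athlete_truth`.
#' @param noise_sd lactate measurement noise, mmol/L.
#' @param start_w,increment_w protocol grid, W.
#' @param seed integer seed for the measurement noise.
#' @return a [step_test()].
#' @export
simulate_step_test <- function(state, noise_sd = 0.15, start_w = 150,
                               increment_w = 25, seed = 1L) {
  stopifnot(inherits(state, "athlete_truth"))
  if (true_lactate(state, start_w) > 4)
    xcp_error("UnusableProtocol",
              "first stage already beyond the 4 mmol/L stop rule")
  powers <- start_w
  while (true_lactate(state, powers[length(powers)]) <= 4)
    powers <- c(powers, powers[length(powers)] + increment_w)
  set.seed(derive_seed(seed, state$index, salt = 2L))
  lac <- pmax(true_lactate(state, powers) + stats::rnorm(length(powers), 0,
                                                         noise_sd), 0.4)
  base <- pmax(state$baseline_lactate + stats::rnorm(1, 0, noise_sd), 0.4)
  hr <- round(120 + (powers - start_w) / (max(powers) - start_w + 1e-9) * 60 +
                stats::rnorm(length(powers), 0, 3))
  rpe <- pmin(round(2 + (powers - start_w) / increment_w * 1.2 +
                      stats::rnorm(length(powers), 0, 0.5)), 10)
  step_test(state$athlete_id, base, powers, lac, hr = hr,
            rpe = pmax(rpe, 1))
}

#' Simulate a field power profile from an athlete's truth
#'
#' The 1, 5 and 10 min effort means sit on the athlete's CP/W' hyperbola
#' (`CP + W'/t`), each scaled by multiplicative Normal(1, cv) noise; the 6 s
#' sprint and 30 s means come from the drawn anaerobic markers. Optional 1 Hz
#' streams are constant power plus white noise around each effort mean.
#'
#' @param state an `athlete_truth`.
#' @param config a [generator_config()] (for the effort CV).
#' @param streams emit 1 Hz streams as well?
#' @param stream_noise_sd_w white-noise SD around each effort mean, W.
#' @param seed integer seed.
#' @return list with `efforts` (data frame: effort, t_s, mean_power_w) and,
#'   when requested, `streams` (data frame: effort, t_s, power_w).
#' @export
simulate_power_profile <- function(state, config, streams = FALSE,
                                   stream_noise_sd_w = 5, seed = 1L) {
  stopifnot(inherits(state, "athlete_truth"), inherits(config, "generator_config"))
  xcp_assert(state$cp_w > 0 && state$w_prime_j > 0, "InvalidConfig",
             "CP and W' must be positive")
  set.seed(derive_seed(seed, state$index, salt = 3L))
  cv <- config$effort_power_noise_cv
  t_aero <- c(p_1min = 60, p_5min = 300, p_10min = 600)
  p_aero <- (state$cp_w + state$w_prime_j / t_aero) *
    stats::rnorm(3, 1, cv)
  p_anaer <- c(
    p_sprint = state$markers_rel[["p_sprint"]] * state$mass_kg,
    p_30s = state$markers_rel[["p_30s"]] * state$mass_kg) *
    stats::rnorm(2, 1, cv)
  efforts <- data.frame(
    effort = c("sprint6s", "p30s", "p1min", "p5min", "p10min"),
    t_s = c(6, 30, 60, 300, 600),
    mean_power_w = unname(c(p_anaer[["p_sprint"]], p_anaer[["p_30s"]],
                            p_aero)))
  out <- list(efforts = efforts)
  if (streams) {
    st <- lapply(seq_len(nrow(efforts)), function(j) {
      n <- efforts$t_s[j]
      data.frame(effort = efforts$effort[j], t_s = seq_len(n),
                 power_w = efforts$mean_power_w[j] +
                   stats::rnorm(n, 0, stream_noise_sd_w))
    })
    out$streams <- do.call(rbind, st)
  }
  out
}

# Graded-test endpoint consistent with the truth: the Kuipers equation
# inverts it exactly. Start load is two 25 W steps below the athlete's
# (grid-rounded) 4 mmol/L power, per protocol.
simulate_graded_test <- function(state, seed = 1L) {
  set.seed(derive_seed(seed, state$index, salt = 4L))
  v <- state$po_vo2max_w
  wf <- 25 * floor(v / 25)
  t <- (v - wf) / 25 * 60
  if (t >= 60) { wf <- wf + 25; t <- 0 }  # guard fp edge
  hr <- round(0.88 * (220 - state$age_yr) + stats::rnorm(1, 0, 4))
  data.frame(athlete_id = state$athlete_id,
             start_w = 25 * round((state$po_x4_w - 50) / 25),
             last_completed_w = wf,
             seconds_into_stage = t,
             max_rpe = 10,
             max_hr = hr)
}

# Anthropometric measurement set tuned to the fractionation method: geometry
# is phantom-proportional at the athlete's stature, skinfolds are shrunk to a
# lean six-fold sum, and a single girth/breadth scale factor is solved so the
# five tissue masses sum to the athlete's body mass (the method's own scale
# laws then put adipose near the published squad fraction).
simulate_anthropometry <- function(state, config, seed = 1L) {
  set.seed(derive_seed(seed, state$index, salt = 5L))
  const <- phantom_constants()
  h <- state$height_cm
  H <- h / PHANTOM_STATURE_CM
  phant_sf <- c(triceps = 15.4, subscapular = 17.2, supraspinale = 15.4,
                abdominal = 25.4, front_thigh = 27.0, medial_calf = 16.0)
  phant_g <- c(arm_relaxed = 26.89, arm_flexed = 29.41, forearm = 25.13,
               chest = 87.86, waist = 71.91, hip = 94.67, thigh = 55.82,
               calf = 35.25, head = 56.0)
  phant_b <- c(biacromial = 38.04, biiliocristal = 28.84, humerus = 6.48,
               femur = 9.52, wrist = 5.21)
  sum6_target <- max(stats::rnorm(1, config$sum6_mean_mm, config$sum6_sd_mm),
                     20)
  sf_jit <- stats::rnorm(length(phant_sf), 1, 0.05)
  sf <- phant_sf * H * sf_jit
  sf <- sf * sum6_target / sum(sf)          # exact six-fold sum by design
  gb_jit_g <- stats::rnorm(length(phant_g), 1, 0.015)
  gb_jit_b <- stats::rnorm(length(phant_b), 1, 0.015)
  build <- function(gamma) {
    anthro_measures(height_cm = h, mass_kg = state$mass_kg,
                    skinfolds = sf,
                    girths = phant_g * H * gamma * gb_jit_g,
                    breadths = phant_b * H * gamma * gb_jit_b)
  }
  target <- function(gamma) {
    fw <- five_way_fractionation(build(gamma))
    sum(fw$table$mass_kg) - state$mass_kg
  }
  gamma <- tryCatch(stats::uniroot(target, c(0.85, 1.20))$root,
                    error = function(e) 1.0)
  build(gamma)
}

simulate_strength <- function(state, config, seed = 1L) {
  set.seed(derive_seed(seed, state$index, salt = 6L))
  sj_cm <- max(stats::rnorm(1, config$squat_jump_mean_cm,
                            config$squat_jump_sd_cm), 8)
  flight_best <- sqrt(8 * sj_cm / 100 / 9.80665)
  r_best <- max(stats::rnorm(1, config$knee_right_mean_n,
                             config$knee_right_sd_n), 600)
  l_best <- max(stats::rnorm(1, config$knee_left_mean_n,
                             config$knee_left_sd_n), 600)
  sub <- function(best) best * (1 - stats::runif(2, 0.02, 0.08))
  data.frame(
    athlete_id = state$athlete_id,
    measure = rep(c("sj_flight_s", "knee_right_n", "knee_left_n"), each = 3),
    attempt = rep(1:3, times = 3),
    value = c(flight_best, flight_best * (1 - stats::runif(2, 0.01, 0.04)),
              r_best, sub(r_best), l_best, sub(l_best)))
}

simulate_race <- function(state, seed = 1L, n_laps = 4L) {
  set.seed(derive_seed(seed, state$index, salt = 7L))
  w <- abs(stats::rnorm(n_laps, 1, 0.04))
  w <- w / sum(w)
  data.frame(athlete_id = state$athlete_id,
             lap_index = seq_len(n_laps),
             lap_time_s = state$race_time_min * 60 * w)
}

#' Simulate a full cohort
#'
#' Samples the truth and derives every raw-data table the pipeline consumes.
#'
#' @param config a [generator_config()].
#' @return list with `truth` (list of `athlete_truth`) and `tables` (named
#'   list of data frames matching the CSV schemas).
#' @export
simulate_cohort <- function(config) {
  truth <- sample_cohort_truth(config)
  keep <- seq_along(truth)
  if (isTRUE(config$drop_one) && length(truth) > 1L) {
    set.seed(derive_seed(config$seed, 0L, salt = 9L))
    keep <- setdiff(keep, sample(seq_along(truth), 1L))
  }
  athletes <- lactate <- efforts <- graded <- anthro <- strength <- race <-
    list()
  for (i in keep) {
    st <- truth[[i]]
    test <- simulate_step_test(st, noise_sd = config$stage_lactate_noise_sd,
                               seed = config$seed)
    pp <- simulate_power_profile(st, config, seed = config$seed)
    am <- simulate_anthropometry(st, config, seed = config$seed)
    athletes[[i]] <- data.frame(
      athlete_id = st$athlete_id, age_yr = st$age_yr,
      height_cm = st$height_cm, mass_kg = st$mass_kg,
      baseline_lactate_mmol_l = test$baseline_lactate)
    lactate[[i]] <- data.frame(
      athlete_id = st$athlete_id,
      stage_index = seq_len(nrow(test$stages)),
      stage_power_w = test$stages$power,
      lactate_mmol_l = test$stages$lactate,
      hr_bpm = test$stages$hr,
      rpe_1_10 = test$stages$rpe)
    efforts[[i]] <- cbind(athlete_id = st$athlete_id,
                          pp$efforts[c("effort", "mean_power_w")])
    graded[[i]] <- simulate_graded_test(st, seed = config$seed)
    anthro[[i]] <- data.frame(
      athlete_id = st$athlete_id, height_cm = am$height_cm,
      mass_kg = am$mass_kg,
      t(stats::setNames(am$skinfolds, paste0("sf_", names(am$skinfolds), "_mm"))),
      t(stats::setNames(am$girths, paste0("girth_", names(am$girths), "_cm"))),
      t(stats::setNames(am$breadths,
                        paste0("breadth_", names(am$breadths), "_cm"))))
    strength[[i]] <- simulate_strength(st, config, seed = config$seed)
    race[[i]] <- simulate_race(st, seed = config$seed)
  }
  truth_df <- do.call(rbind, lapply(truth[keep], function(st)
    data.frame(athlete_id = st$athlete_id, age_yr = st$age_yr,
               height_cm = st$height_cm, mass_kg = st$mass_kg,
               latent_ability = st$latent_ability,
               po_x2_wkg = st$markers_rel[["po_x2"]],
               po_x4_wkg = st$markers_rel[["po_x4"]],
               po_vo2max_wkg = st$markers_rel[["po_vo2max"]],
               cp_wkg = st$markers_rel[["cp"]],
               p_30s_wkg = st$markers_rel[["p_30s"]],
               p_sprint_wkg = st$markers_rel[["p_sprint"]],
               po_x2_w = st$po_x2_w, po_x4_w = st$po_x4_w,
               po_vo2max_w = st$po_vo2max_w, cp_w = st$cp_w,
               w_prime_j = st$w_prime_j,
               baseline_lactate = st$baseline_lactate,
               lac_a = st$lac_a, lac_k = st$lac_k,
               race_time_min = st$race_time_min)))
  list(truth = truth,
       tables = list(
         athletes = do.call(rbind, athletes),
         lactate_tests = do.call(rbind, lactate),
         power_efforts = do.call(rbind, efforts),
         graded_test = do.call(rbind, graded),
         anthropometry = do.call(rbind, anthro),
         strength = do.call(rbind, strength),
         race = do.call(rbind, race),
         truth = truth_df))
}

#' Write a simulated cohort to CSV files
#'
#' Emits athletes.csv, lactate_tests.csv, power_efforts.csv, graded_test.csv,
#' anthropometry.csv, strength.csv, race.csv and the latent truth.csv (for
#' recovery tests) into `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir existing writable directory.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  xcp_assert(dir.exists(dir), "MissingDirectory",
             sprintf("directory does not exist: %s", dir))
  paths <- character(0)
  for (nm in names(cohort$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(cohort$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a cohort directory back into tables
#'
#' @param dir directory holding the CSVs from [write_cohort()].
#' @param require_truth error if truth.csv is absent?
#' @return named list of data frames.
#' @export
read_cohort <- function(dir, require_truth = FALSE) {
  need <- c("athletes", "lactate_tests", "power_efforts", "graded_test",
            "anthropometry", "strength", "race")
  if (require_truth) need <- c(need, "truth")
  out <- list()
  for (nm in need) {
    p <- file.path(dir, paste0(nm, ".csv"))
    xcp_assert(file.exists(p), "MissingFile", sprintf("missing file: %s", p))
    out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  tp <- file.path(dir, "truth.csv")
  if (!require_truth && file.exists(tp))
    out$truth <- utils::read.csv(tp, stringsAsFactors = FALSE)
  out
}
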