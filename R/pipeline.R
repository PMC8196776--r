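# Pipeline orchestration: simulate -> markers -> analyze -> report, with flat
# CSV/JSON file contracts. Per-athlete physiological anomalies degrade to
# flags; only structural input problems abort.

#' Pipeline configuration
#'
#' @param alpha_screen correlation-screen retention threshold.
#' @param vif_threshold VIF removal threshold.
#' @param alpha_stay backward-elimination stay threshold.
#' @param alpha_enter forward-selection entry threshold.
#' @param n_boot bootstrap replicates for Spearman CIs.
#' @param seed analysis seed (bootstrap).
#' @param cp_durations_s durations used for the CP fit, s.
#' @param curve_degree_fixed polynomial degree for fixed-concentration / Dmax.
#' @param curve_degree_lt2 polynomial degree for the LT2 curve.
#' @param ci_method "bootstrap" or "fisher-z" for Spearman CIs.
#' @param normalise divide power markers by body mass for the analysis?
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_screen = 0.05, vif_threshold = 5,
                            alpha_stay = 0.05, alpha_enter = 0.05,
                            n_boot = 2000L, seed = 1L,
                            cp_durations_s = c(60, 300, 600),
                            curve_degree_fixed = 3L, curve_degree_lt2 = 4L,
                            ci_method = "bootstrap", normalise = TRUE) {
  xcp_assert(alpha_screen > 0 && alpha_screen < 1 &&
               alpha_stay > 0 && alpha_stay < 1 &&
               alpha_enter > 0 && alpha_enter < 1,
             "InvalidConfig", "alpha thresholds must lie in (0, 1)")
  xcp_assert(curve_degree_fixed %in% c(3L, 4L) &&
               curve_degree_lt2 %in% c(3L, 4L),
             "InvalidConfig", "curve degrees must be 3 or 4")
  xcp_assert(!anyDuplicated(cp_durations_s) && length(cp_durations_s) >= 3L,
             "InvalidConfig", "cp_durations_s must be >= 3 distinct durations")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Simulate a cohort to disk
#'
#' [simulate_cohort()] + [write_cohort()] plus a manifest echoing the
#' configuration and seed.
#'
#' @param generator_cfg a [generator_config()].
#' @param out_dir output directory (created if missing).
#' @param force overwrite a non-empty directory?
#' @return invisibly, `out_dir`.
#' @export
run_simulate <- function(generator_cfg, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    xcp_error("DirectoryNotEmpty",
              sprintf("%s is not empty; use force = TRUE", out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(generator_cfg)
  write_cohort(cohort, out_dir)
  manifest <- list(
    tool = "xcprofiler",
    version = as.character(utils::packageVersion("xcprofiler")),
    seed = generator_cfg$seed,
    n_athletes = generator_cfg$n_athletes,
    config = generator_cfg[!vapply(generator_cfg, is.function, logical(1))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Per-athlete marker derivation from the raw tables. Returns a one-row data
# frame plus flags; never aborts an athlete.
derive_athlete_markers <- function(id, tables, cfg) {
  flags <- character(0)
  ath <- tables$athletes[tables$athletes$athlete_id == id, ]
  mass <- ath$mass_kg[1]
  lt <- tables$lactate_tests[tables$lactate_tests$athlete_id == id, ]
  lt <- lt[order(lt$stage_index), ]
  thr <- tryCatch({
    test <- step_test(id, ath$baseline_lactate_mmol_l[1],
                      lt$stage_power_w, lt$lactate_mmol_l,
                      hr = lt$hr_bpm, rpe = lt$rpe_1_10)
    extract_thresholds(test)
  }, error = function(e) {
    flags <<- c(flags, paste0("steptest:", conditionMessage(e)))
    list(values = c(po_lt1_w = NA_real_, po_lt2_w = NA_real_,
                    po_x2_w = NA_real_, po_x4_w = NA_real_,
                    po_dmax_w = NA_real_), flags = character(0))
  })
  flags <- c(flags, thr$flags)

  ef <- tables$power_efforts[tables$power_efforts$athlete_id == id, ]
  get_eff <- function(nm) {
    v <- ef$mean_power_w[ef$effort == nm]
    if (length(v)) v[1] else NA_real_
  }
  p <- c(sprint6s = get_eff("sprint6s"), p30s = get_eff("p30s"),
         p1min = get_eff("p1min"), p5min = get_eff("p5min"),
         p10min = get_eff("p10min"))
  if (!is.na(p[["p5min"]]) && !is.na(p[["p10min"]]) &&
      p[["p5min"]] < p[["p10min"]])
    flags <- c(flags, "efforts:P5minBelowP10min")
  cp_pts <- data.frame(t_s = c(60, 300, 600),
                       power_w = c(p[["p1min"]], p[["p5min"]], p[["p10min"]]))
  cp_pts <- cp_pts[cp_pts$t_s %in% cfg$cp_durations_s & !is.na(cp_pts$power_w), ]
  cpm <- tryCatch(fit_cp(cp_pts$t_s, cp_pts$power_w),
                  xcp_error = function(e) {
                    flags <<- c(flags, paste0("cp:", class(e)[1L])); NULL
                  })

  gt <- tables$graded_test[tables$graded_test$athlete_id == id, ]
  vo2 <- NA_real_; validity <- "UnknownValidity"
  if (nrow(gt)) {
    ep <- tryCatch(graded_endpoint(
      gt$last_completed_w[1], gt$seconds_into_stage[1],
      max_rpe = gt$max_rpe[1] %||% NA_real_,
      max_hr = gt$max_hr[1] %||% NA_real_,
      age_yr = ath$age_yr[1]), xcp_error = function(e) {
        flags <<- c(flags, paste0("graded:", class(e)[1L])); NULL
      })
    if (!is.null(ep)) {
      vo2 <- kuipers_po_vo2max(ep)
      validity <- check_test_validity(ep)
      if (validity != "valid") flags <- c(flags, paste0("graded:", validity))
    }
  } else flags <- c(flags, "graded:Missing")

  an <- tables$anthropometry[tables$anthropometry$athlete_id == id, ]
  sum6 <- NA_real_; adipose_pct <- muscle_pct <- NA_real_
  fw_sum <- NA_real_
  if (nrow(an)) {
    grab_set <- function(prefix, suffix) {
      cols <- grep(paste0("^", prefix, ".*", suffix, "$"), names(an),
                   value = TRUE)
      v <- as.numeric(an[1, cols])
      names(v) <- sub(suffix, "", sub(paste0("^", prefix), "", cols))
      v[!is.na(v)]
    }
    am <- tryCatch(anthro_measures(
      an$height_cm[1], an$mass_kg[1],
      skinfolds = grab_set("sf_", "_mm"),
      girths = grab_set("girth_", "_cm"),
      breadths = grab_set("breadth_", "_cm")),
      error = function(e) {
        flags <<- c(flags, paste0("anthro:", conditionMessage(e))); NULL
      })
    if (!is.null(am)) {
      sum6 <- tryCatch(sum6_skinfolds(am), xcp_error = function(e) {
        flags <<- c(flags, "anthro:MissingSkinfold"); NA_real_
      })
      fw <- tryCatch(five_way_fractionation(am), xcp_error = function(e) {
        flags <<- c(flags, paste0("anthro:", class(e)[1L])); NULL
      })
      if (!is.null(fw)) {
        flags <- c(flags, fw$flags)
        tab <- fw$table
        adipose_pct <- tab$pct_body_mass[tab$tissue == "adipose"]
        muscle_pct <- tab$pct_body_mass[tab$tissue == "muscle"]
        fw_sum <- sum(tab$mass_kg)
        if (is.finite(fw_sum) &&
            abs(fw_sum - an$mass_kg[1]) > 0.08 * an$mass_kg[1])
          flags <- c(flags, "anthro:FractionSumOutsideTolerance")
      }
    }
  }

  stg <- tables$strength[tables$strength$athlete_id == id, ]
  sj <- kr <- kl <- asym <- NA_real_
  if (nrow(stg)) {
    gv <- function(m) stg$value[stg$measure == m]
    sp <- tryCatch(isometric_summary(gv("knee_right_n"), gv("knee_left_n"),
                                     mass, squat_jump_flight_s = gv("sj_flight_s")),
                   xcp_error = function(e) {
                     flags <<- c(flags, paste0("strength:", class(e)[1L])); NULL
                   })
    if (!is.null(sp)) {
      sj <- sp$squat_jump_cm; kr <- sp$right_max_n; kl <- sp$left_max_n
      asym <- sp$asymmetry_n
    }
  }

  watts <- c(po_lt1_w = unname(thr$values[["po_lt1_w"]]),
             po_lt2_w = unname(thr$values[["po_lt2_w"]]),
             po_x2_w = unname(thr$values[["po_x2_w"]]),
             po_x4_w = unname(thr$values[["po_x4_w"]]),
             po_dmax_w = unname(thr$values[["po_dmax_w"]]),
             po_vo2max_w = vo2,
             cp_w = if (is.null(cpm)) NA_real_ else cpm$cp_w,
             p_sprint_w = unname(p[["sprint6s"]]),
             p_30s_w = unname(p[["p30s"]]),
             p_1min_w = unname(p[["p1min"]]),
             p_5min_w = unname(p[["p5min"]]),
             p_10min_w = unname(p[["p10min"]]))
  wkg <- normalise_markers(watts, mass)
  names(wkg) <- sub("_w$", "_wkg", names(watts))
  row <- data.frame(athlete_id = id, mass_kg = mass, t(watts), t(wkg),
                    w_prime_kj = if (is.null(cpm)) NA_real_ else cpm$w_prime_kj,
                    cp_r2 = if (is.null(cpm)) NA_real_ else cpm$r_squared,
                    validity_flag = validity,
                    sum6_mm = sum6, adipose_pct = adipose_pct,
                    muscle_pct = muscle_pct, fiveway_sum_kg = fw_sum,
                    squat_jump_cm = sj, knee_right_n = kr, knee_left_n = kl,
                    knee_asymmetry_n = asym,
                    flags = paste(flags, collapse = ";"))
  row
}

#' Derive per-athlete markers from a cohort directory
#'
#' Reads the raw-data CSVs, derives the threshold set, CP/W', maximal aerobic
#' power, anthropometric and strength indices for every athlete, and writes
#' markers.csv. Per-athlete failures degrade to entries in the flags column;
#' no athlete is dropped.
#'
#' @param dir cohort directory.
#' @param cfg a [pipeline_config()].
#' @return the markers data frame, invisibly (also written to
#'   `dir`/markers.csv).
#' @export
run_markers <- function(dir, cfg = pipeline_config()) {
  tables <- read_cohort(dir)
  ids <- tables$athletes$athlete_id
  rows <- lapply(ids, derive_athlete_markers, tables = tables, cfg = cfg)
  markers <- do.call(rbind, rows)
  utils::write.csv(markers, file.path(dir, "markers.csv"), row.names = FALSE)
  invisible(markers)
}

# Total race time (min) per athlete from the lap table
total_race_time <- function(race) {
  agg <- stats::aggregate(lap_time_s ~ athlete_id, data = race, FUN = sum)
  agg$race_time_min <- agg$lap_time_s / 60
  agg[c("athlete_id", "race_time_min")]
}

#' Run the statistical analysis stage
#'
#' Correlation screen of every W/kg marker against total race time, VIF
#' filter, backward elimination, forward selection, and the final fitted
#' model with per-athlete predictions, written to report.json (plus flat
#' report.csv tables).
#'
#' @param dir cohort directory holding markers.csv and race.csv.
#' @param cfg a [pipeline_config()].
#' @param candidates optional explicit candidate columns (default: every
#'   `_wkg` column in markers.csv).
#' @return the report list, invisibly (also written to `dir`/report.json).
#' @export
run_analyze <- function(dir, cfg = pipeline_config(), candidates = NULL) {
  mpath <- file.path(dir, "markers.csv")
  rpath <- file.path(dir, "race.csv")
  xcp_assert(file.exists(mpath), "MissingFile", paste("missing", mpath))
  xcp_assert(file.exists(rpath), "MissingFile", paste("missing", rpath))
  markers <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  race <- total_race_time(utils::read.csv(rpath, stringsAsFactors = FALSE))
  dat <- merge(markers, race, by = "athlete_id")
  if (is.null(candidates))
    candidates <- grep("_wkg$", names(dat), value = TRUE)
  analysis <- analyze_markers(dat, candidates, cfg)
  analysis$provenance <- list(
    tool = "xcprofiler",
    version = as.character(utils::packageVersion("xcprofiler")),
    seed = cfg$seed,
    config_hash = config_hash(cfg))
  json_payload <- analysis[setdiff(names(analysis), "model_object")]
  jsonlite::write_json(json_payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  utils::write.csv(analysis$correlations, file.path(dir, "report.csv"),
                   row.names = FALSE)
  invisible(analysis)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), collapse = "|")
  # tiny stable FNV-1a style hash; avoids a digest dependency
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- bitwXor(h, ch) * 16777619 %% 2^32
  sprintf("%08x", h %% 2^32)
}

#' Analysis core on an in-memory marker matrix
#'
#' The screen -> VIF -> backward -> forward chain on a data frame that
#' already holds the candidate columns and `race_time_min`.
#'
#' @param dat data frame with candidates and `race_time_min`.
#' @param candidates candidate column names.
#' @param cfg a [pipeline_config()].
#' @return list: correlations, vif, elimination, model, predictions, warnings.
#' @export
analyze_markers <- function(dat, candidates, cfg = pipeline_config()) {
  outcome <- "race_time_min"
  cc <- stats::complete.cases(dat[c(outcome, candidates)])
  warnings <- character(0)
  if (sum(cc) < nrow(dat))
    warnings <- c(warnings, sprintf(
      "complete cases (%d) < athletes (%d); incomplete athletes excluded from the fit",
      sum(cc), nrow(dat)))
  if (sum(cc) < 6L)
    xcp_error("SampleTooSmall",
              sprintf("only %d complete cases; need >= 6", sum(cc)))
  d <- dat[cc, c(outcome, candidates)]
  normality <- shapiro_wilk_screen(d)
  screen <- correlation_screen(d, outcome, alpha = cfg$alpha_screen,
                               n_boot = cfg$n_boot, seed = cfg$seed,
                               ci_method = cfg$ci_method)
  retained <- screen$variable[screen$retained]
  vif_res <- NULL
  after_vif <- retained
  if (length(retained) >= 2L) {
    vif_res <- vif_filter(d[retained], threshold = cfg$vif_threshold)
    after_vif <- vif_res$retained
  }
  back <- if (length(after_vif))
    backward_eliminate(d, outcome, after_vif, alpha_stay = cfg$alpha_stay)
  else list(retained = character(0),
            trace = data.frame(step = integer(0), dropped = character(0),
                               p_value = numeric(0)),
            flags = "NothingRetainedByScreen")
  model <- forward_select_and_fit(d, outcome, back$retained,
                                  alpha_enter = cfg$alpha_enter)
  ids <- if ("athlete_id" %in% names(dat)) dat$athlete_id[cc] else
    which(cc)
  preds <- data.frame(athlete_id = ids, observed_min = d[[outcome]])
  preds$predicted_min <- if (length(model$predictors))
    predict_race_time(model, d[model$predictors]) else
      rep(unname(model$coefficients["(Intercept)"]), nrow(d))
  list(normality = normality,
       correlations = screen,
       screen_note = attr(screen, "note"),
       vif = vif_res,
       elimination = back,
       model = list(predictors = model$predictors,
                    coefficients = as.list(model$coefficients),
                    r_squared = model$r_squared,
                    f_statistic = model$f_statistic,
                    df1 = unname(model$df["df1"]),
                    df2 = unname(model$df["df2"]),
                    model_p = model$model_p,
                    n = model$n),
       model_object = model,
       predictions = preds,
       warnings = warnings)
}

#' Human-readable summary of a report.json
#'
#' @param dir cohort directory holding report.json.
#' @return invisibly, the parsed report.
#' @export
run_report <- function(dir) {
  p <- file.path(dir, "report.json")
  xcp_assert(file.exists(p), "MissingFile", paste("missing", p))
  rep <- jsonlite::read_json(p, simplifyVector = TRUE)
  num <- function(x) if (is.null(x) || !length(x) || is.na(x)) NA_real_ else x
  cat("== xcprofiler analysis report ==\n")
  cat(sprintf("Model: n = %s, R^2 = %.3f, F(%s,%s) = %.3f, p = %.4g\n",
              num(rep$model$n), num(rep$model$r_squared), num(rep$model$df1),
              num(rep$model$df2), num(rep$model$f_statistic),
              num(rep$model$model_p)))
  co <- unlist(rep$model$coefficients)
  cat("Race time (min) =", sprintf("%.2f", co[["(Intercept)"]]))
  for (nm in setdiff(names(co), "(Intercept)"))
    cat(sprintf(" %+.2f x %s", co[[nm]], nm))
  cat("\nRetained by screen:",
      paste(rep$correlations$variable[rep$correlations$retained],
            collapse = ", "), "\n")
  if (length(rep$warnings)) cat("Warnings:", paste(rep$warnings, collapse = "; "),
                                "\n")
  invisible(rep)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `markers`, `analyze`, `report`. Shared flags:
#' `--out DIR` (or positional dir for markers/analyze/report), `--seed INT`,
#' `--n INT` (simulate), `--force`.
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
xcp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: xcprofiler <simulate|markers|analyze|report> [--out DIR]",
    "[--seed INT] [--n INT] [--force]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- list(out = ".", seed = 42L, n = 10L, force = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--force") { opts$force <- TRUE; i <- i + 1L }
    else if (a %in% c("--out", "--seed", "--n")) {
      xcp_assert(i < length(args), "InvalidCLI", paste("missing value for", a))
      key <- sub("^--", "", a)
      opts[[key]] <- if (key == "out") args[i + 1L] else
        as.integer(args[i + 1L])
      i <- i + 2L
    } else if (is.null(opts$dir_positional)) {
      opts$dir_positional <- a; i <- i + 1L
    } else xcp_error("InvalidCLI", paste("unrecognised argument:", a))
  }
  dir <- opts$dir_positional %||% opts$out
  status <- tryCatch({
    switch(cmd,
      simulate = {
        run_simulate(generator_config(n_athletes = opts$n, seed = opts$seed),
                     dir, force = opts$force)
        message("cohort written to ", dir)
      },
      markers = {
        run_markers(dir, pipeline_config(seed = opts$seed))
        message("markers.csv written to ", dir)
      },
      analyze = {
        run_analyze(dir, pipeline_config(seed = opts$seed))
        message("report.json written to ", dir)
      },
      report = run_report(dir),
      xcp_error("InvalidCLI", paste("unknown subcommand:", cmd)))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
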