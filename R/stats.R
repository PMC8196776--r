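# Statistical workflow: Shapiro-Wilk normality annotation, Spearman rho with
# bootstrap (or Fisher-z) 95% CIs, the p < alpha correlation screen, iterative
# VIF filtering, backward elimination and forward selection, and prediction
# from the fitted race-time model.

#' Shapiro-Wilk screen across columns
#'
#' Normality annotation used to justify the rank-based correlation screen.
#' Constant columns are flagged (the statistic is undefined there).
#'
#' @param data data frame or matrix of numeric columns (n >= 3 rows).
#' @return data frame with variable, W, p_value, flag.
#' @export
shapiro_wilk_screen <- function(data) {
  data <- as.data.frame(data)
  xcp_assert(nrow(data) >= 3L, "SampleTooSmall", "Shapiro-Wilk needs n >= 3")
  res <- lapply(names(data), function(nm) {
    x <- data[[nm]][is.finite(data[[nm]])]
    if (length(unique(x)) <= 1L || length(x) < 3L)
      return(data.frame(variable = nm, W = NA_real_, p_value = NA_real_,
                        flag = "constant_or_short"))
    sw <- stats::shapiro.test(x)
    data.frame(variable = nm, W = unname(sw$statistic),
               p_value = sw$p.value, flag = "")
  })
  do.call(rbind, res)
}

# Exhaustive permutation null for Spearman rho (test oracle scale only).
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

#' Spearman correlation with a 95% confidence interval
#'
#' rho is the Pearson correlation of (average) ranks. The p-value uses the
#' exact permutation distribution when n <= 10 and there are no ties
#' (deterministic), otherwise the t approximation. The 95% CI is a seeded
#' bootstrap percentile interval over athletes, clamped to [-1, 1] (this
#' reproduces the hard +/-1 bounds such intervals show at n = 10); a Fisher-z
#' interval is available as an alternative.
#'
#' @param x,y numeric vectors, n >= 4, finite.
#' @param n_boot bootstrap replicates for the CI.
#' @param seed integer seed for the bootstrap.
#' @param ci_method "bootstrap" (default) or "fisher-z".
#' @return object of class `correlation_result`: list with rho, p_value,
#'   ci95 (lo, hi), n, method labels.
#' @export
spearman_with_ci <- function(x, y, n_boot = 10000L, seed = 1L,
                             ci_method = c("bootstrap", "fisher-z")) {
  ci_method <- match.arg(ci_method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  xcp_assert(n >= 4L, "SampleTooSmall", "Spearman CI needs n >= 4")
  if (length(unique(x)) <= 1L || length(unique(y)) <= 1L)
    xcp_error("ZeroVariance", "rank variance is zero; rho undefined")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  rho <- spearman_rho(x, y)
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 10L && !ties))$p.value)
  if (ci_method == "bootstrap") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- idx[b, ]
      if (length(unique(x[i])) <= 1L || length(unique(y[i])) <= 1L)
        return(NA_real_)
      spearman_rho(x[i], y[i])
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  } else {
    z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
    se <- 1.06 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  ci <- pmin(pmax(ci, -1), 1)
  structure(list(rho = rho, p_value = p, ci95 = ci, n = n,
                 p_method = if (n <= 10L && !ties) "exact-permutation"
                            else "t-approximation",
                 ci_method = ci_method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (%s), 95%% CI [%.2f, %.2f], n = %d\n",
              x$rho, x$p_value, x$p_method, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Correlation screen against the outcome
#'
#' Spearman rho of every candidate column against the outcome; candidates
#' with p < alpha are retained. No multiplicity correction is applied (the
#' family-wise error is inflated accordingly; a note flags this).
#'
#' @param data data frame of candidates plus the outcome column.
#' @param outcome name of the outcome column.
#' @param alpha retention threshold on the per-candidate p-value.
#' @param n_boot,seed,ci_method passed to [spearman_with_ci()].
#' @return data frame (one row per candidate: rho, p_value, ci_lo, ci_hi, n,
#'   retained) with attribute `note` on multiplicity.
#' @export
correlation_screen <- function(data, outcome, alpha = 0.05,
                               n_boot = 2000L, seed = 1L,
                               ci_method = "bootstrap") {
  data <- as.data.frame(data)
  xcp_assert(outcome %in% names(data), "MissingOutcome",
             sprintf("outcome column '%s' not found", outcome))
  y <- data[[outcome]]
  cands <- setdiff(names(data), outcome)
  rows <- lapply(seq_along(cands), function(i) {
    nm <- cands[i]
    r <- tryCatch(
      spearman_with_ci(data[[nm]], y, n_boot = n_boot,
                       seed = derive_seed(seed, i), ci_method = ci_method),
      xcp_error = function(e) NULL)
    if (is.null(r))
      return(data.frame(variable = nm, rho = NA_real_, p_value = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, n = NA_integer_,
                        retained = FALSE))
    data.frame(variable = nm, rho = r$rho, p_value = r$p_value,
               ci_lo = r$ci95[1], ci_hi = r$ci95[2], n = r$n,
               retained = is.finite(r$p_value) && r$p_value < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "note") <-
    "per-candidate alpha with no multiplicity correction; family-wise error inflated"
  out
}

#' Variance-inflation-factor filter
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' predictors (with intercept). While any VIF exceeds the threshold the
#' largest-VIF predictor is removed; ties break alphabetically so the filter
#' is deterministic. Perfectly collinear predictors get infinite VIF and are
#' removed first with an InfiniteVIF flag.
#'
#' @param data data frame of candidate predictors (numeric columns).
#' @param threshold removal threshold (default 5).
#' @return list with `retained` (names), `removed` (names in removal order),
#'   `vif_table` (data frame per iteration), `flags`.
#' @export
vif_filter <- function(data, threshold = 5) {
  data <- as.data.frame(data)
  preds <- names(data)
  xcp_assert(length(preds) >= 2L, "TooFewPredictors", "need >= 2 predictors")
  xcp_assert(nrow(data) > length(preds) + 1L, "SampleTooSmall",
             "need n > predictors + 1 for VIF")
  removed <- character(0)
  flags <- character(0)
  trace <- list()
  iter <- 0L
  while (length(preds) >= 2L) {
    iter <- iter + 1L
    vifs <- vapply(preds, function(j) compute_vif(data, j, setdiff(preds, j)),
                   numeric(1))
    trace[[iter]] <- data.frame(iteration = iter, variable = preds,
                                vif = unname(vifs), row.names = NULL)
    if (all(vifs <= threshold, na.rm = TRUE) && !any(is.infinite(vifs))) break
    worst <- max(vifs)
    drop_nm <- sort(preds[vifs == worst])[1L]    # alphabetical tie-break
    if (is.infinite(worst)) flags <- c(flags, paste0(drop_nm, ":InfiniteVIF"))
    removed <- c(removed, drop_nm)
    preds <- setdiff(preds, drop_nm)
  }
  list(retained = preds, removed = removed,
       vif_table = do.call(rbind, trace), flags = flags)
}

compute_vif <- function(data, target, others) {
  y <- data[[target]]
  X <- cbind(1, as.matrix(data[others]))
  fit <- stats::lm.fit(X, y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(NA_real_)
  r2 <- 1 - ss_res / ss_tot
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

# p-values of the slope terms of an OLS fit y ~ X (data frame of predictors)
ols_fit <- function(data, outcome, predictors) {
  f <- stats::as.formula(paste(
    outcome, "~", if (length(predictors)) paste(sprintf("`%s`", predictors),
                                                collapse = " + ") else "1"))
  stats::lm(f, data = data)
}

slope_p_values <- function(fit) {
  s <- summary(fit)$coefficients
  p <- s[, "Pr(>|t|)"]
  p[setdiff(rownames(s), "(Intercept)")]
}

#' Backward elimination by slope p-value
#'
#' Fits the full model and repeatedly drops the slope with the largest
#' p-value while it exceeds `alpha_stay`, recording each step. If the initial
#' set cannot be fitted (too few complete cases), the most redundant
#' predictor (largest mean absolute pairwise correlation) is pre-dropped with
#' a flag until the model is estimable.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of starting predictors.
#' @param alpha_stay stay threshold on slope p-values.
#' @return list with `retained`, `trace` (data frame: step, dropped, p_value),
#'   `flags`.
#' @export
backward_eliminate <- function(data, outcome, predictors, alpha_stay = 0.05) {
  data <- as.data.frame(data)
  flags <- character(0)
  cc <- stats::complete.cases(data[c(outcome, predictors)])
  n <- sum(cc)
  # pre-drop while the saturated model has no residual df
  while (length(predictors) && n < length(predictors) + 2L) {
    cm <- abs(stats::cor(data[cc, predictors, drop = FALSE],
                         method = "spearman"))
    diag(cm) <- NA
    red <- rowMeans(cm, na.rm = TRUE)
    drop_nm <- sort(names(red)[red == max(red)])[1L]
    flags <- c(flags, paste0(drop_nm, ":PreDroppedUnfittable"))
    predictors <- setdiff(predictors, drop_nm)
  }
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_value = numeric(0))
  step <- 0L
  while (length(predictors)) {
    fit <- ols_fit(data[cc, , drop = FALSE], outcome, predictors)
    p <- slope_p_values(fit)
    p[is.na(p)] <- Inf                       # aliased term: drop first
    if (max(p) <= alpha_stay) break
    step <- step + 1L
    worst <- max(p)
    drop_nm <- sort(names(p)[p == worst])[1L]
    drop_nm <- gsub("`", "", drop_nm)
    trace <- rbind(trace, data.frame(step = step, dropped = drop_nm,
                                     p_value = unname(worst)))
    predictors <- setdiff(predictors, drop_nm)
  }
  if (!length(predictors)) flags <- c(flags, "AllDropped")
  list(retained = predictors, trace = trace, flags = flags)
}

#' Forward selection and final fit
#'
#' Greedy forward addition from `candidates`: at each round the candidate
#' giving the largest R-squared gain enters if its slope p-value in the
#' augmented model is below `alpha_enter`; otherwise selection stops. The
#' final ordinary-least-squares model is reported with coefficients,
#' R-squared, F = (R^2/df1) / ((1-R^2)/df2), df and model p-value.
#'
#' @param data data frame holding outcome and candidates.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictors (typically the
#'   survivors of [backward_eliminate()]).
#' @param alpha_enter entry threshold.
#' @return object of class `regression_report`.
#' @export
forward_select_and_fit <- function(data, outcome, candidates,
                                   alpha_enter = 0.05) {
  data <- as.data.frame(data)
  cc <- stats::complete.cases(data[c(outcome, candidates)])
  d <- data[cc, , drop = FALSE]
  selected <- character(0)
  pool <- candidates
  entry_trace <- data.frame(step = integer(0), entered = character(0),
                            r_squared = numeric(0), p_value = numeric(0))
  step <- 0L
  repeat {
    if (!length(pool)) break
    gains <- vapply(pool, function(nm) {
      fit <- ols_fit(d, outcome, c(selected, nm))
      summary(fit)$r.squared
    }, numeric(1))
    if (!any(is.finite(gains))) break    # constant outcome or all-degenerate
    best <- sort(names(gains)[gains == max(gains, na.rm = TRUE)])[1L]
    fit_try <- ols_fit(d, outcome, c(selected, best))
    p_best <- slope_p_values(fit_try)[sprintf("`%s`", best)]
    if (is.na(p_best)) p_best <- slope_p_values(fit_try)[best]
    if (!is.finite(p_best) || p_best >= alpha_enter) break
    step <- step + 1L
    entry_trace <- rbind(entry_trace,
                         data.frame(step = step, entered = best,
                                    r_squared = max(gains),
                                    p_value = unname(p_best)))
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
  }
  fit <- ols_fit(d, outcome, selected)
  sm <- summary(fit)
  r2 <- sm$r.squared
  df1 <- length(selected)
  df2 <- nrow(d) - df1 - 1L
  if (df1 > 0L) {
    f_stat <- (r2 / df1) / ((1 - r2) / df2)
    model_p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  } else {
    f_stat <- NA_real_; model_p <- NA_real_; r2 <- 0
  }
  co <- stats::coef(fit)
  names(co) <- gsub("`", "", names(co))
  structure(list(
    outcome = outcome,
    predictors = selected,
    coefficients = co,
    r_squared = r2,
    f_statistic = f_stat,
    df = c(df1 = df1, df2 = df2),
    model_p = model_p,
    n = nrow(d),
    entry_trace = entry_trace,
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit)),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Race-time model: n = %d, R^2 = %.3f, F(%d,%d) = %.3f, p = %.4g\n",
              x$n, x$r_squared, x$df[1], x$df[2], x$f_statistic, x$model_p))
  cat("  ", x$outcome, "=",
      sprintf("%.4g", x$coefficients[1]),
      if (length(x$coefficients) > 1)
        paste(sprintf("%+.4g * %s", x$coefficients[-1],
                      names(x$coefficients)[-1]), collapse = " "),
      "\n")
  invisible(x)
}

#' Predict race time from a fitted report
#'
#' Affine prediction `a + sum(b_i x_i)` using the report's coefficients.
#'
#' @param report a `regression_report`.
#' @param newdata data frame or named list/vector supplying every model
#'   predictor (same units as the fit, typically W/kg).
#' @return predicted outcome (minutes for the race-time model).
#' @export
predict_race_time <- function(report, newdata) {
  stopifnot(inherits(report, "regression_report"))
  nd <- as.data.frame(as.list(newdata))
  missing <- setdiff(report$predictors, names(nd))
  if (length(missing))
    xcp_error("MissingPredictor",
              paste("missing predictor(s):", paste(missing, collapse = ", ")))
  b <- report$coefficients
  out <- rep(unname(b["(Intercept)"]), nrow(nd))
  for (nm in report$predictors) out <- out + b[[nm]] * nd[[nm]]
  out
}
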