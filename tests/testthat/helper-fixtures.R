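# Shared fixtures and independent oracles for the test suite.

# A well-behaved step test lying exactly on c(P) = 1 + ((P - 150) / 100)^2
quadratic_step_test <- function(powers = seq(150, 300, by = 25)) {
  step_test("fx-quad", baseline_lactate = 1.0, power = powers,
            lactate = 1 + ((powers - 150) / 100)^2)
}

# Build a lactate_curve object directly from known coefficients
make_curve <- function(coefs, domain, degree = length(coefs) - 1L) {
  structure(list(degree = as.integer(degree), coefficients = coefs,
                 domain = domain, rss = 0, n_stages = NA_integer_),
            class = "lactate_curve")
}

# Build an athlete_truth state directly (for protocol edge cases)
make_truth <- function(index = 1L, mass_kg = 67.22, c_b = 1.0,
                       po_x2_wkg = 3.24, po_x4_wkg = 3.86,
                       po_vo2max_wkg = 5.29, cp_wkg = 3.91,
                       p_30s_wkg = 10.45, p_sprint_wkg = 13.52,
                       w_prime_per_kg = 282) {
  x2 <- po_x2_wkg * mass_kg
  x4 <- po_x4_wkg * mass_kg
  k <- log((4 - c_b) / (2 - c_b)) / (x4 - x2)
  a <- (2 - c_b) * exp(-k * x2)
  rel <- c(po_x2 = po_x2_wkg, po_x4 = po_x4_wkg, po_vo2max = po_vo2max_wkg,
           cp = cp_wkg, p_30s = p_30s_wkg, p_sprint = p_sprint_wkg)
  structure(list(
    athlete_id = sprintf("fx%02d", index), index = index,
    age_yr = 16.3, height_cm = 176.74, mass_kg = mass_kg,
    latent_ability = 0, markers_rel = rel,
    po_x2_w = x2, po_x4_w = x4,
    po_vo2max_w = po_vo2max_wkg * mass_kg, cp_w = cp_wkg * mass_kg,
    w_prime_j = w_prime_per_kg * mass_kg,
    baseline_lactate = c_b, lac_a = a, lac_k = k,
    race_time_min = 81), class = "athlete_truth")
}

# Phantom-reference measurement set (all sites at the phantom values)
phantom_measures <- function(scale = 1) {
  anthro_measures(
    height_cm = 170.18 * scale, mass_kg = 64.58 * scale^3,
    skinfolds = c(triceps = 15.4, subscapular = 17.2, supraspinale = 15.4,
                  abdominal = 25.4, front_thigh = 27.0,
                  medial_calf = 16.0) * scale,
    girths = c(arm_relaxed = 26.89, arm_flexed = 29.41, forearm = 25.13,
               chest = 87.86, waist = 71.91, hip = 94.67, thigh = 55.82,
               calf = 35.25, head = 56.0) * scale,
    breadths = c(biacromial = 38.04, biiliocristal = 28.84, humerus = 6.48,
                 femur = 9.52, wrist = 5.21) * scale)
}

# Independent Spearman oracles
rho_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Grid-search oracle for the Dmax point on a fitted curve
dmax_grid_oracle <- function(curve, test, by = 0.01) {
  P <- test$stages$power
  L <- test$stages$lactate
  n <- length(P)
  slope <- (L[n] - L[1]) / (P[n] - P[1])
  grid <- seq(P[1], P[n], by = by)
  dist <- abs(eval_lactate_curve(curve, grid) - (L[1] + slope * (grid - P[1])))
  inner <- grid > P[1] & grid < P[n]
  grid[inner][which.max(dist[inner])]
}

# Grid-search oracle for the LT2 (max second derivative) point
lt2_grid_oracle <- function(curve, by = 0.01) {
  b <- curve$coefficients
  grid <- seq(curve$domain[1], curve$domain[2], by = by)
  acc <- 2 * b[3] + 6 * b[4] * grid + 12 * b[5] * grid^2
  grid[which.max(acc)]
}

# Brute-force rolling-mean maximum
mmp_brute_force <- function(stream, w) {
  max(vapply(seq_len(length(stream) - w + 1L),
             function(j) mean(stream[j:(j + w - 1L)]), numeric(1)))
}
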