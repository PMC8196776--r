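Package: xcprofiler
Title: Physiological Profiling and Race-Time Prediction for Youth
    Cross-Country Cyclists
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to derive maximal and submaximal aerobic power markers
    from cycling test data and to model cross-country race performance.
    Fits lactate-power curves from incremental step tests and extracts the
    power outputs at fixed blood lactate concentrations (2 and 4 mmol/L),
    the first and second lactate thresholds and the Dmax point; fits the
    critical-power (CP/W') hyperbola from timed field efforts; computes
    maximal aerobic power from a graded test endpoint (Kuipers equation);
    derives anthropometric indices including five-way tissue fractionation
    and the sum of six skinfolds, squat-jump height from flight time and
    isometric strength summaries; and predicts official race time from
    body-mass-normalised markers via a Spearman correlation screen followed
    by VIF-gated backward-elimination / forward-selection multiple
    regression. Includes a seeded synthetic-cohort generator that emulates
    a 10-rider junior national squad for parameter-recovery testing, and a
    command-line pipeline (simulate, markers, analyze, report).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
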