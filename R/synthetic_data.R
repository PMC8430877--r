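#' Chamber scenario configuration
#'
#' Describes a closed-chamber disinfectant emission experiment. Emission
#' shapes are phenomenological: liquid, stock-solution and spray products
#' follow a saturating rise `C(t) = plateau * (1 - exp(-rise_rate * t))`;
#' gel products emit in two linear phases, with the early phase suppressed
#' by the gel matrix until `lag_time`. The spray plateau scales sublinearly
#' with the number of sprays (`amount^spray_exponent`), reflecting the
#' diminishing return observed when more product is applied. pH and dilution
#' are carried as metadata only — hypochlorite speciation chemistry is out
#' of scope, and chamber measurements show dilution barely changes the
#' emitted chlorine level.
#'
#' @param product_type One of `"liquid"`, `"spray"`, `"gel"`,
#'   `"stock_solution"`.
#' @param amount Product amount: mL for liquid/stock solution, number of
#'   sprays for spray, grams for gel. Defaults per type: 200 mL liquid,
#'   1 spray, 50.8 g gel, 20 mL stock solution.
#' @param dilution_factor Dilution of liquid bleach, >= 1 (metadata).
#' @param chamber_volume Chamber volume, m3 (default 0.125, a 125 L box).
#' @param plateau_ppbv Asymptotic (liquid/stock/spray, per unit amount for
#'   spray) or end-of-run (gel) concentration, ppbv. Defaults per type:
#'   1160 (liquid/stock), 204 (spray, 1 spray), 900 (gel).
#' @param rise_rate Saturating-rise rate constant, h-1 (default 1).
#' @param lag_time Gel early-phase duration, hours (default 1.5).
#' @param duration_h Profile length, hours (default 3).
#' @param dt_min Profile time resolution, minutes (default 0.5, a typical
#'   PTR-MS cycle).
#' @param spray_exponent Sublinearity exponent for the spray plateau
#'   (default 0.7; a configuration default, not a claim).
#' @param gel_slope_ratio Late:early emission slope ratio for gel
#'   (default 6; configuration default representing the thickener-suppressed
#'   early phase).
#' @param pH Product pH, metadata only.
#' @param seed Integer seed driving every random draw derived from this
#'   scenario.
#' @return Object of class `ppas_scenario`.
#' @export
scenario_config <- function(product_type = c("liquid", "spray", "gel",
                                             "stock_solution"),
                            amount = NULL, dilution_factor = 1,
                            chamber_volume = 0.125, plateau_ppbv = NULL,
                            rise_rate = 1, lag_time = 1.5, duration_h = 3,
                            dt_min = 0.5, spray_exponent = 0.7,
                            gel_slope_ratio = 6, pH = NA_real_, seed = 1L) {
  product_type <- match.arg(product_type)
  if (is.null(amount))
    amount <- switch(product_type, liquid = 200, spray = 1, gel = 50.8,
                     stock_solution = 20)
  if (is.null(plateau_ppbv))
    plateau_ppbv <- switch(product_type, liquid = 1160, spray = 204,
                           gel = 900, stock_solution = 1160)
  chk_num(amount, "amount", lower = 0, len = 1L)
  chk_num(dilution_factor, "dilution_factor", lower = 1, len = 1L)
  chk_num(chamber_volume, "chamber_volume", lower = 0, strict = TRUE,
          len = 1L)
  chk_num(plateau_ppbv, "plateau_ppbv", lower = 0, len = 1L)
  chk_num(rise_rate, "rise_rate", lower = 0, len = 1L)
  chk_num(lag_time, "lag_time", lower = 0, len = 1L)
  chk_num(duration_h, "duration_h", lower = 0, strict = TRUE, len = 1L)
  chk_num(dt_min, "dt_min", lower = 0, strict = TRUE, len = 1L)
  chk_num(spray_exponent, "spray_exponent", lower = 0, len = 1L)
  chk_num(gel_slope_ratio, "gel_slope_ratio", lower = 1, strict = TRUE,
          len = 1L)
  if (product_type == "gel" && lag_time >= duration_h)
    stop_input("lag_time must be < duration_h for a gel scenario")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_input("seed must be a single integer")
  structure(list(product_type = product_type, amount = amount,
                 dilution_factor = dilution_factor,
                 chamber_volume = chamber_volume,
                 plateau_ppbv = plateau_ppbv, rise_rate = rise_rate,
                 lag_time = lag_time, duration_h = duration_h,
                 dt_min = dt_min, spray_exponent = spray_exponent,
                 gel_slope_ratio = gel_slope_ratio, pH = pH,
                 seed = as.integer(seed)),
            class = "ppas_scenario")
}

#' Deterministic chamber emission profile for a scenario
#'
#' * liquid / stock solution: `C(t) = plateau * (1 - exp(-rise_rate t))`.
#' * spray: same shape with plateau `plateau_ppbv * amount^spray_exponent`
#'   (sublinear in the number of sprays).
#' * gel: two linear phases; the early slope (up to `lag_time`) is
#'   `1 / gel_slope_ratio` of the late slope, and the profile reaches
#'   `plateau_ppbv` at `duration_h`.
#'
#' Pure function of the scenario — no randomness.
#'
#' @param scenario A [scenario_config()].
#' @return An [air_series()] on the scenario's time grid.
#' @export
emission_profile <- function(scenario) {
  stopifnot(inherits(scenario, "ppas_scenario"))
  t_min <- seq(0, scenario$duration_h * 60, by = scenario$dt_min)
  t_h <- t_min / 60
  conc <- switch(
    scenario$product_type,
    liquid = ,
    stock_solution =
      scenario$plateau_ppbv * (1 - exp(-scenario$rise_rate * t_h)),
    spray = scenario$plateau_ppbv * scenario$amount^scenario$spray_exponent *
      (1 - exp(-scenario$rise_rate * t_h)),
    gel = {
      lag <- scenario$lag_time
      ratio <- scenario$gel_slope_ratio
      s1 <- scenario$plateau_ppbv /
        (lag + ratio * (scenario$duration_h - lag))
      ifelse(t_h <= lag, s1 * t_h, s1 * lag + ratio * s1 * (t_h - lag))
    }
  )
  air_series(t_min, pmax(conc, 0))
}

#' Generate a synthetic chamber experiment
#'
#' Emulates the closed-chamber protocol end to end: the scenario's emission
#' profile drives the forward uptake model; for every deployment time and
#' replicate the simulated reacted-chlorine load is inverted into a
#' noise-free dye-consumption difference `C_i - C_f`, to which multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` is applied
#' independently per replicate. Draws that would imply dye creation
#' (`C_f > C_i`) or negative `C_f` are floored; if more than 1% of draws
#' need flooring a warning is emitted. Every draw uses a counter-derived
#' seed, so regenerating with the same scenario seed is bit-for-bit
#' reproducible and adding replicates never perturbs earlier ones.
#'
#' @param scenario [scenario_config()] (its `seed` drives the noise).
#' @param params True [sampler_params()].
#' @param deployment_times Sorted positive deployment times, hours.
#' @param n_replicates Replicates per deployment time, >= 1 (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative noise in
#'   `[0, 1)` (default 0.05).
#' @param cond [gas_conditions()].
#' @param C_i Blank extraction concentration, g L-1 (default 0.1).
#' @param V_E Extraction volume, L (default 0.01).
#' @param mode Forward-model mode for [simulate_uptake()].
#' @param cal Optional [ptrms_calibration()]; when supplied, synthetic
#'   PTR-MS channel responses for the emission series are included.
#' @return Object of class `ppas_synthetic_experiment`: `scenario`,
#'   `params`, `air` (truth series), `truth` (per-deployment C_s and TWA),
#'   `measurements` ([extraction_measurements()]), `channels` (or NULL),
#'   `seed`.
#' @export
generate_experiment <- function(scenario, params = sampler_params(),
                                deployment_times, n_replicates = 3,
                                noise_cv = 0.05, cond = gas_conditions(),
                                C_i = 0.1, V_E = 0.01,
                                mode = c("two_state", "quasi_steady"),
                                cal = NULL) {
  stopifnot(inherits(scenario, "ppas_scenario"),
            inherits(params, "sampler_params"))
  mode <- match.arg(mode)
  chk_num(deployment_times, "deployment_times", lower = 0, strict = TRUE)
  chk_increasing(deployment_times, "deployment_times")
  if (n_replicates < 1L) stop_input("n_replicates must be >= 1")
  chk_num(noise_cv, "noise_cv", lower = 0, len = 1L)
  if (noise_cv >= 1) stop_input("noise_cv must be < 1")
  chk_num(C_i, "C_i", lower = 0, strict = TRUE, len = 1L)
  chk_num(V_E, "V_E", lower = 0, strict = TRUE, len = 1L)

  air <- emission_profile(scenario)
  horizon <- max(deployment_times)
  if (horizon > scenario$duration_h + 1e-9)
    stop_input("deployment_times exceed the scenario duration")
  traj <- simulate_uptake(params, air, duration = horizon, step = 0.005,
                          mode = mode, cond = cond)
  cs_true <- approx(traj$time_h, traj$C_s_mol_m3,
                    xout = deployment_times)$y
  twa_true <- vapply(deployment_times,
                     function(tt) twa(air, 0, tt * 60), numeric(1))
  delta_true <- cs_true * params$stoich * M_W_DIANISIDINE * params$V_s / V_E

  rows <- list()
  n_floored <- 0L
  for (i in seq_along(deployment_times)) {
    for (j in seq_len(n_replicates)) {
      set.seed(seed_stream(scenario$seed, i, j))
      z <- rnorm(1)
      d <- delta_true[i] * (1 + noise_cv * z)
      if (d < 0 || d > C_i) n_floored <- n_floored + 1L
      d <- min(max(d, 0), C_i)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = sprintf("t%02d_r%02d", i, j),
        deployment_h = deployment_times[i],
        Ci_g_per_L = C_i, Cf_g_per_L = C_i - d, VE_L = V_E,
        stringsAsFactors = FALSE)
    }
  }
  n_draws <- length(deployment_times) * n_replicates
  if (n_floored > 0.01 * n_draws)
    warning(sprintf(
      "%d of %d noise draws floored to keep 0 <= Cf <= Ci; noise_cv may be too large",
      n_floored, n_draws))
  meas <- do.call(rbind, rows)
  meas <- extraction_measurements(meas$replicate_id, meas$deployment_h,
                                  meas$Ci_g_per_L, meas$Cf_g_per_L,
                                  meas$VE_L)
  channels <- if (!is.null(cal))
    generate_ptrms_channels(air, cal, noise_cv = noise_cv,
                            seed = seed_stream(scenario$seed, 0L, 0L))
  structure(list(scenario = scenario, params = params, air = air,
                 truth = data.frame(deployment_h = deployment_times,
                                    C_s_true = cs_true,
                                    twa_true_ppbv = twa_true),
                 measurements = meas, channels = channels,
                 seed = scenario$seed),
            class = "ppas_synthetic_experiment")
}

#' @export
print.ppas_synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "synthetic %s-scenario experiment: %d deployment time(s) x %d replicate(s), seed %d\n",
    x$scenario$product_type, nrow(x$truth),
    nrow(x$measurements) / max(1L, nrow(x$truth)), x$seed))
  invisible(x)
}

#' Generate synthetic PTR-MS channel responses for a concentration series
#'
#' The total net response `slope * C + intercept` is split across the
#' m/z 70/72/74 channels by the isotopologue fractions; outside-chamber
#' channels sit at a baseline level. Multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` is applied independently per channel
#' and timestamp. With `noise_cv = 0` the generation inverts exactly under
#' [instantaneous_concentration()].
#'
#' @param series An [air_series()].
#' @param cal A [ptrms_calibration()].
#' @param noise_cv Per-channel multiplicative noise CV (default 0).
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @param cl35_abundance 35Cl atom fraction (default natural, 0.7577).
#' @param baseline Outside-chamber baseline counts per channel (default 0).
#' @return A [channel_series()].
#' @export
generate_ptrms_channels <- function(series, cal, noise_cv = 0, seed = NULL,
                                    cl35_abundance = 0.7577, baseline = 0) {
  series <- as_air_series(series)
  if (!inherits(cal, "ptrms_calibration"))
    stop_input("cal must be a ptrms_calibration")
  chk_num(noise_cv, "noise_cv", lower = 0, len = 1L)
  if (noise_cv > 0 && is.null(seed))
    stop_input("seed is required when noise_cv > 0")
  f <- isotopologue_fractions(cl35_abundance)
  n <- nrow(series)
  signal <- cal$slope * series$ppbv + cal$intercept
  if (noise_cv > 0) set.seed(as.integer(seed))
  noisy <- function(x) {
    if (noise_cv == 0) x else pmax(x * (1 + noise_cv * rnorm(n)), 0)
  }
  # fixed draw order: in70, in72, in74 (outside channels are noiseless
  # baseline so that the noise-free identity holds exactly at baseline 0)
  in_70 <- noisy(f[["m70"]] * signal) + baseline
  in_72 <- noisy(f[["m72"]] * signal) + baseline
  in_74 <- noisy(f[["m74"]] * signal) + baseline
  channel_series(series$time_min, in_70, in_72, in_74,
                 rep(baseline, n), rep(baseline, n), rep(baseline, n))
}

#' Write a synthetic experiment to a directory
#'
#' Writes `emission.csv` (truth air series), `measurements.csv`,
#' `trajectory.csv` is left to [cmd_simulate()], optional `channels.csv`,
#' and a `truth.json` sidecar holding the scenario, true parameters, seed
#' and per-deployment truth table.
#'
#' @param x A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param comments Optional provenance comment lines for the CSVs.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir, comments = NULL) {
  stopifnot(inherits(x, "ppas_synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_air_series(x$air, file.path(dir, "emission.csv"), comments)
  write_ppas_csv(x$measurements, file.path(dir, "measurements.csv"),
                 comments)
  if (!is.null(x$channels))
    write_channel_series(x$channels, file.path(dir, "channels.csv"),
                         comments)
  truth <- list(scenario = unclass(x$scenario),
                params = unclass(x$params), seed = x$seed,
                truth = x$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
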