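#' Fit uptake-model parameters to observed reacted-chlorine data
#'
#' Least-squares fit of a subset of the kinetic parameters (any of `k_O`,
#' `k_reac`, `C_cap`) to observed `C_s(t)`, given the air-concentration
#' series the sampler saw. Parameters are fitted on the log scale (which
#' enforces positivity) with five deterministic multi-starts around the
#' initial values to escape local minima; ties are broken by the lowest sum
#' of squares, then by the smallest log-distance from the initial values.
#' `K_SA` is structurally weakly identified in the reaction-fast regime and
#' is always held fixed.
#'
#' @param time_h Observation times, hours, strictly increasing (>= 4
#'   observations and at least one more than the number of free
#'   parameters).
#' @param C_s Observed reacted chlorine, mol m-3, >= 0.
#' @param air [air_series()] covering the observation window.
#' @param init [sampler_params()] giving initial values and every fixed
#'   parameter.
#' @param free Character subset of `c("k_O", "k_reac", "C_cap")` to fit
#'   (default `c("k_O", "C_cap")` — `k_reac` is unidentified when the
#'   reaction is fast).
#' @param mode Forward model used in the objective: `"quasi_steady"`
#'   (default; the single-state reduction, cheap and accurate whenever the
#'   dissolved pool is fast) or `"two_state"`.
#' @param n_starts Number of multi-starts (default 5, the first being
#'   `init` itself).
#' @param cond [gas_conditions()].
#' @return Object of class `ppas_fit`: `estimates` (named), `residual_rms`
#'   (mol m-3), `convergence_flag` (`"converged"`, `"max_iterations"`,
#'   `"boundary"`), `n_obs`, `fixed_params`, `sse`, `starts` (per-start
#'   summary), `starts_agree` (fraction of starts landing within 1% of the
#'   best).
#' @export
fit_uptake <- function(time_h, C_s, air, init = sampler_params(),
                       free = c("k_O", "C_cap"),
                       mode = c("quasi_steady", "two_state"),
                       n_starts = 5, cond = gas_conditions()) {
  chk_num(time_h, "time_h")
  chk_increasing(time_h, "time_h")
  chk_num(C_s, "C_s", lower = 0)
  if (length(time_h) != length(C_s))
    stop_input("time_h and C_s must have equal length")
  mode <- match.arg(mode)
  stopifnot(inherits(init, "sampler_params"))
  free <- match.arg(free, c("k_O", "k_reac", "C_cap"), several.ok = TRUE)
  n_obs <- length(time_h)
  if (n_obs < 4L) stop_input("need >= 4 observations, got ", n_obs)
  if (n_obs <= length(free))
    stop_input("need more observations (", n_obs,
               ") than free parameters (", length(free), ")")
  air <- as_air_series(air)
  if (max(air$time_min) / 60 < max(time_h) - 1e-9)
    stop_input("air series does not cover the observation window")

  ca_fun <- air_series_fun(air, cond)
  sim_times <- c(0, time_h)
  plan <- qs_plan(ca_fun, sim_times, h_max = 0.02)
  model_cs <- function(p) {
    if (mode == "quasi_steady") {
      qs_run(p, plan)[-1L]
    } else {
      tr <- simulate_uptake(p, air, duration = max(time_h),
                            step = max(time_h) / 400, mode = "two_state",
                            cond = cond)
      approx(tr$time_h, tr$C_s_mol_m3, xout = time_h)$y
    }
  }
  objective <- function(logpar) {
    p <- update_params(init, as.list(setNames(exp(logpar), free)))
    sum((model_cs(p) - C_s)^2)
  }

  init_log <- log(unlist(unclass(init)[free]))
  # deterministic multi-start pattern: cyclic x1/3, x3, x1/5, x5 factors
  base_fac <- c(1 / 3, 3, 1 / 5, 5)
  starts <- lapply(seq_len(n_starts), function(s) {
    if (s == 1L) return(init_log)
    init_log + log(base_fac[((s - 2L + seq_along(free) - 1L) %% 4L) + 1L])
  })

  runs <- lapply(starts, function(p0) {
    opt <- tryCatch(
      if (length(free) == 1L)
        optim(p0, objective, method = "Brent", lower = p0 - log(1e6),
              upper = p0 + log(1e6))
      else
        optim(p0, objective, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    list(par = opt$par, sse = opt$value, conv = opt$convergence,
         dist = sqrt(sum((opt$par - init_log)^2)))
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs))
    stop_convergence("all optimisation starts failed")
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  dists <- vapply(runs, `[[`, numeric(1), "dist")
  best_i <- order(sses, dists)[1L]
  best <- runs[[best_i]]
  est <- setNames(exp(best$par), free)

  rel_best <- vapply(runs, function(r) {
    max(abs(exp(r$par) - est) / pmax(est, 1e-300))
  }, numeric(1))
  agree <- mean(rel_best < 0.01)

  flag <- if (any(est / exp(init_log) < 1e-4 | est / exp(init_log) > 1e4))
    "boundary"
  else if (best$conv != 0) "max_iterations"
  else "converged"

  structure(list(
    estimates = est,
    residual_rms = sqrt(best$sse / n_obs),
    convergence_flag = flag,
    n_obs = n_obs,
    fixed_params = unclass(init)[setdiff(c("k_O", "k_reac", "C_cap", "K_SA"),
                                         free)],
    sse = best$sse,
    starts = data.frame(start = seq_along(runs), sse = sses,
                        converged = vapply(runs, function(r) r$conv == 0,
                                           logical(1))),
    starts_agree = agree,
    free = free, mode = mode
  ), class = "ppas_fit")
}

#' @export
print.ppas_fit <- function(x, ...) {
  cat("uptake-model fit (", x$mode, "): ", x$convergence_flag, "\n",
      sep = "")
  print(signif(x$estimates, 6))
  cat(sprintf("residual RMS %.3g mol m-3 on %d obs; %d%% of starts agree\n",
              x$residual_rms, x$n_obs, round(100 * x$starts_agree)))
  invisible(x)
}

#' Estimate the sampler capacity from a saturating trajectory
#'
#' Finds the terminal run of observations whose local relative slope
#' (interval slope divided by the local concentration, per hour) stays
#' below `slope_tol`, and returns the mean reacted-chlorine level over that
#' run — the plateau. If the trajectory never flattens (e.g. a still-linear
#' series), a not-plateaued marker is returned instead of a number.
#'
#' @param time_h Observation times, hours, strictly increasing, >= 3.
#' @param C_s Observed reacted chlorine, mol m-3.
#' @param slope_tol Relative-slope threshold, per hour (default 0.02).
#' @return Object of class `ppas_capacity`: `capacity` (mol m-3, `NA` when
#'   not plateaued), `plateaued` (logical), `n_points` used.
#' @export
estimate_capacity <- function(time_h, C_s, slope_tol = 0.02) {
  chk_num(time_h, "time_h")
  chk_increasing(time_h, "time_h")
  chk_num(C_s, "C_s")
  if (length(time_h) != length(C_s))
    stop_input("time_h and C_s must have equal length")
  n <- length(time_h)
  if (n < 3L) stop_input("need >= 3 observations, got ", n)
  slopes <- diff(C_s) / diff(time_h)
  level <- pmax(abs(C_s[-1L]), .Machine$double.eps)
  flat <- abs(slopes) / level < slope_tol
  # terminal maximal run of flat intervals
  k <- n - 1L
  while (k >= 1L && flat[k]) k <- k - 1L
  run_len <- (n - 1L) - k
  if (run_len < 1L || run_len + 1L < 2L)
    return(structure(list(capacity = NA_real_, plateaued = FALSE,
                          n_points = 0L), class = "ppas_capacity"))
  idx <- (k + 1L):n
  structure(list(capacity = mean(C_s[idx]), plateaued = TRUE,
                 n_points = length(idx)), class = "ppas_capacity")
}

#' @export
print.ppas_capacity <- function(x, ...) {
  if (x$plateaued)
    cat(sprintf("plateau capacity %.4g mol m-3 (mean of %d points)\n",
                x$capacity, x$n_points))
  else cat("trajectory not plateaued; no capacity estimate\n")
  invisible(x)
}

#' Linear-phase slope of an uptake series
#'
#' Ordinary least-squares line through the observations inside a time
#' window. In the linear (unsaturated, reaction-fast) regime the slope obeys
#' `dC_s/dt = R_s * C_A / V_s`, so when sampler parameters are supplied the
#' implied TWA air concentration is also reported.
#'
#' @param time_h Observation times, hours.
#' @param C_s Observed reacted chlorine, mol m-3.
#' @param window Optional `c(start, end)` in hours; default all points.
#' @param params Optional [sampler_params()] for the implied concentration.
#' @param cond [gas_conditions()].
#' @return List of class `ppas_linear_phase`: `slope` (mol m-3 h-1),
#'   `intercept`, `r_squared`, `n`, and (with `params`)
#'   `implied_CA_mol_m3`, `implied_CA_ppbv`.
#' @export
linear_phase_slope <- function(time_h, C_s, window = NULL, params = NULL,
                               cond = gas_conditions()) {
  chk_num(time_h, "time_h")
  chk_num(C_s, "C_s")
  if (length(time_h) != length(C_s))
    stop_input("time_h and C_s must have equal length")
  if (!is.null(window)) {
    chk_num(window, "window", len = 2L)
    keep <- time_h >= window[1] & time_h <= window[2]
    time_h <- time_h[keep]; C_s <- C_s[keep]
  }
  if (length(unique(time_h)) < 2L)
    stop_input("window contains fewer than 2 distinct time points")
  fit <- lm.fit(cbind(1, time_h), C_s)
  sse <- sum(fit$residuals^2)
  sst <- sum((C_s - mean(C_s))^2)
  out <- list(slope = unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]),
              r_squared = if (sst > 0) 1 - sse / sst else 1,
              n = length(C_s))
  if (!is.null(params)) {
    ca <- out$slope * params$V_s / params$R_s
    out$implied_CA_mol_m3 <- ca
    out$implied_CA_ppbv <- molar_to_ppbv(max(ca, 0), cond)
  }
  structure(out, class = "ppas_linear_phase")
}

# SSE of the best OLS line for every prefix/suffix, via cumulative sums
seg_sse_cum <- function(t, y) {
  n <- length(t)
  cs <- function(v) cumsum(v)
  Sx <- cs(t); Sy <- cs(y); Sxx <- cs(t^2); Sxy <- cs(t * y); Syy <- cs(y^2)
  k <- seq_len(n)
  sxx <- Sxx - Sx^2 / k
  sxy <- Sxy - Sx * Sy / k
  syy <- Syy - Sy^2 / k
  sse <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
  pmax(sse, 0)
}

#' Two-phase changepoint check on an uptake or emission series
#'
#' Exhaustively scans every interior split of the series into two segments
#' (each with at least `min_seg` points), fits an OLS line to each segment,
#' and finds the split minimising the total SSE. A changepoint is declared
#' only when that two-segment SSE improves on the single-line SSE by at
#' least `min_improvement` (fraction). The split time is reported as the
#' intersection of the two fitted lines (falling back to the last time of
#' the first segment when the lines are near-parallel or the intersection
#' falls outside the series). Ties are broken toward the earliest split.
#'
#' Designed for dense (instrument-resolution) series: the improvement
#' threshold does not control the false-positive rate on short noisy
#' series.
#'
#' @param time_h Observation times, hours, strictly increasing, >= 5.
#' @param C_s Series values (reacted chlorine or concentration).
#' @param min_improvement Minimum fractional SSE improvement (default 0.1).
#' @param min_seg Minimum points per segment (default 2).
#' @return Object of class `ppas_changepoint`: `changepoint` (logical),
#'   `split_time` (h; `NA` when none), `split_grid_time` (last time of the
#'   first segment), `slope_early`, `slope_late`, `slope_ratio`,
#'   `sse_improvement`.
#' @export
changepoint_check <- function(time_h, C_s, min_improvement = 0.1,
                              min_seg = 2L) {
  chk_num(time_h, "time_h")
  chk_increasing(time_h, "time_h")
  chk_num(C_s, "C_s")
  n <- length(time_h)
  if (length(C_s) != n) stop_input("time_h and C_s must have equal length")
  if (n < 5L) stop_input("need >= 5 observations, got ", n)

  sse_pre <- seg_sse_cum(time_h, C_s)
  sse_suf <- rev(seg_sse_cum(rev(-time_h), rev(C_s)))
  sse_one <- sse_pre[n]
  ks <- min_seg:(n - min_seg)               # split after index k
  tot <- sse_pre[ks] + sse_suf[ks + 1L]
  best_k <- ks[which.min(tot)]              # which.min -> earliest tie
  sse_two <- min(tot)
  improvement <- if (sse_one > 0) (sse_one - sse_two) / sse_one
                 else as.numeric(sse_two < sse_one)

  f1 <- lm.fit(cbind(1, time_h[1:best_k]), C_s[1:best_k])$coefficients
  f2 <- lm.fit(cbind(1, time_h[(best_k + 1L):n]),
               C_s[(best_k + 1L):n])$coefficients
  split_grid <- time_h[best_k]
  tx <- (f1[1] - f2[1]) / (f2[2] - f1[2])
  split <- if (is.finite(tx) && tx >= time_h[1] && tx <= time_h[n]) tx
           else split_grid
  found <- improvement >= min_improvement
  structure(list(
    changepoint = found,
    split_time = if (found) unname(split) else NA_real_,
    split_grid_time = if (found) split_grid else NA_real_,
    slope_early = unname(f1[2]), slope_late = unname(f2[2]),
    slope_ratio = unname(f2[2] / f1[2]),
    sse_improvement = improvement,
    sse_one_segment = sse_one, sse_two_segment = sse_two
  ), class = "ppas_changepoint")
}

#' @export
print.ppas_changepoint <- function(x, ...) {
  if (x$changepoint)
    cat(sprintf(
      "changepoint at %.3g h (slopes %.3g -> %.3g, SSE improvement %.0f%%)\n",
      x$split_time, x$slope_early, x$slope_late, 100 * x$sse_improvement))
  else cat(sprintf("no changepoint (SSE improvement %.0f%% < threshold)\n",
                   100 * x$sse_improvement))
  invisible(x)
}

#' Parameter-recovery simulation study
#'
#' Repeats generate-then-fit `n_reps` times with counter-split seeds:
#' each repetition draws a fresh noisy synthetic experiment from the
#' scenario under `true_params`, recovers `C_s` observations through the
#' extraction equation, fits the free parameters, and the study tabulates
#' per-parameter mean bias and RMSE against the truth. Individual fit
#' failures are recorded, not fatal; more than 20% failures aborts.
#'
#' @param true_params True [sampler_params()].
#' @param scenario [scenario_config()] driving the emission profile.
#' @param n_reps Number of repetitions, >= 2.
#' @param noise_cv Extraction noise CV (default 0.05).
#' @param seed Integer master seed; repetitions use split seeds.
#' @param deployment_times Observation times, hours (default 12 points from
#'   0.25 h to the scenario duration, spanning linear rise and plateau at
#'   the default scenario).
#' @param free Parameters to fit, as in [fit_uptake()].
#' @param mode Forward-model mode for the generator (default
#'   `"quasi_steady"`, indistinguishable from the two-state model in the
#'   reaction-fast regime and ~100x cheaper over many repetitions).
#' @param cond [gas_conditions()].
#' @return data.frame of class `ppas_recovery` with one row per free
#'   parameter: `truth`, `mean_est`, `bias`, `rel_bias`, `rmse`,
#'   `rel_rmse`, `n_ok`, `n_fail`; attribute `estimates` holds the
#'   rep-by-parameter estimate matrix.
#' @export
recovery_study <- function(true_params, scenario, n_reps, noise_cv = 0.05,
                           seed = 1L, deployment_times = NULL,
                           free = c("k_O", "C_cap"),
                           mode = c("quasi_steady", "two_state"),
                           cond = gas_conditions()) {
  stopifnot(inherits(true_params, "sampler_params"),
            inherits(scenario, "ppas_scenario"))
  mode <- match.arg(mode)
  if (n_reps < 2L) stop_input("n_reps must be >= 2")
  if (is.null(deployment_times))
    deployment_times <- seq(0.25, scenario$duration_h, length.out = 12)
  free <- match.arg(free, c("k_O", "k_reac", "C_cap"), several.ok = TRUE)

  ests <- matrix(NA_real_, n_reps, length(free),
                 dimnames = list(NULL, free))
  fails <- character(0)
  for (r in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- seed_stream(seed, r)
    fit <- tryCatch({
      exp_r <- generate_experiment(sc, true_params, deployment_times,
                                   n_replicates = 1, noise_cv = noise_cv,
                                   cond = cond, mode = mode)
      obs <- cs_from_extraction(exp_r$measurements, true_params)
      fit_uptake(deployment_times, obs, exp_r$air, init = true_params,
                 free = free, mode = mode, cond = cond)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      fails <- c(fails, sprintf("rep %d: %s", r, conditionMessage(fit)))
    } else {
      ests[r, ] <- fit$estimates[free]
    }
  }
  n_fail <- length(fails)
  if (n_fail > 0.2 * n_reps)
    stop_convergence("recovery study aborted: ", n_fail, "/", n_reps,
                     " fits failed\n", paste(head(fails, 5), collapse = "\n"))

  truth <- unlist(unclass(true_params)[free])
  ok <- stats::complete.cases(ests)
  tab <- data.frame(
    parameter = free,
    truth = unname(truth),
    mean_est = colMeans(ests[ok, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  tab$bias <- tab$mean_est - tab$truth
  tab$rel_bias <- tab$bias / tab$truth
  tab$rmse <- sqrt(colMeans((ests[ok, , drop = FALSE] -
                               rep(truth, each = sum(ok)))^2))
  tab$rel_rmse <- tab$rmse / tab$truth
  tab$n_ok <- sum(ok)
  tab$n_fail <- n_fail
  rownames(tab) <- NULL
  structure(tab, class = c("ppas_recovery", "data.frame"),
            estimates = ests, seed = seed, failures = fails)
}
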