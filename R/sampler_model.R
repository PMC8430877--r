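#' Passive sampler geometry and kinetic parameters
#'
#' Houses every constant of the uptake model. Defaults describe the
#' o-dianisidine/PDMS patch: a 1.5 cm x 1.5 cm sheet (effective exchange
#' area `A_s` = 2.25e-4 m2) of 0.55 mm thickness, sampling rate
#' `R_s` = 2.53e-3 m3 h-1, and a reacted-chlorine capacity of 1.8 mol per m3
#' of sampler. The overall mass-transfer coefficient `k_O` defaults to
#' `R_s / A_s` so that the reaction-fast linear-regime sampling rate equals
#' `R_s` exactly (see [sampling_rate_identity()]). The sampler-air partition
#' constant `K_SA` is not experimentally constrained; it only enters the
#' reversible back-diffusion term, to which reaction-fast results are
#' insensitive, and its default (10) is flagged in reports.
#'
#' @param A_s Sampler exchange surface area, m2.
#' @param delta Sampler sheet thickness, m.
#' @param V_s Sampler volume, m3; defaults to `A_s * delta`.
#' @param K_SA Dimensionless sampler-air partition constant.
#' @param k_O Overall mass-transfer coefficient, m h-1; defaults to
#'   `R_s / A_s`.
#' @param k_reac First-order rate constant of the dye redox reaction, h-1.
#' @param C_cap Maximum reacted-chlorine capacity, mol m-3.
#' @param R_s Sampling rate, m3 h-1.
#' @param stoich Moles of dye consumed per mole of Cl2 reacted (default 2).
#' @param capacity_model `"smooth"` (reaction rate proportional to the
#'   remaining dye fraction, smooth approach to the plateau) or `"hard"`
#'   (full rate until exhaustion, the piecewise-linear idealisation).
#' @return An object of class `sampler_params`.
#' @export
sampler_params <- function(A_s = 2.25e-4, delta = 5.5e-4, V_s = NULL,
                           K_SA = 10, k_O = NULL, k_reac = 100,
                           C_cap = 1.8, R_s = 2.53e-3, stoich = 2,
                           capacity_model = c("smooth", "hard")) {
  chk_num(A_s, "A_s", lower = 0, strict = TRUE, len = 1L)
  chk_num(delta, "delta", lower = 0, strict = TRUE, len = 1L)
  chk_num(K_SA, "K_SA", lower = 0, strict = TRUE, len = 1L)
  chk_num(k_reac, "k_reac", lower = 0, strict = TRUE, len = 1L)
  chk_num(C_cap, "C_cap", lower = 0, strict = TRUE, len = 1L)
  chk_num(R_s, "R_s", lower = 0, strict = TRUE, len = 1L)
  chk_num(stoich, "stoich", lower = 0, strict = TRUE, len = 1L)
  if (is.null(V_s)) V_s <- A_s * delta
  chk_num(V_s, "V_s", lower = 0, strict = TRUE, len = 1L)
  if (is.null(k_O)) k_O <- R_s / A_s
  chk_num(k_O, "k_O", lower = 0, strict = TRUE, len = 1L)
  capacity_model <- match.arg(capacity_model)
  structure(list(A_s = A_s, delta = delta, V_s = V_s, K_SA = K_SA,
                 k_O = k_O, k_reac = k_reac, C_cap = C_cap, R_s = R_s,
                 stoich = stoich, capacity_model = capacity_model),
            class = "sampler_params")
}

#' @export
print.sampler_params <- function(x, ...) {
  cat("sampler parameters:\n")
  cat(sprintf("  A_s    %.4g m2      delta  %.4g m     V_s %.4g m3\n",
              x$A_s, x$delta, x$V_s))
  cat(sprintf("  k_O    %.4g m/h    k_reac %.4g /h    K_SA %.4g (assumed)\n",
              x$k_O, x$k_reac, x$K_SA))
  cat(sprintf("  C_cap  %.4g mol/m3  R_s    %.4g m3/h  stoich %g  capacity: %s\n",
              x$C_cap, x$R_s, x$stoich, x$capacity_model))
  invisible(x)
}

# replace a named subset of kinetic parameters, revalidating
update_params <- function(params, updates) {
  stopifnot(inherits(params, "sampler_params"))
  p <- unclass(params)
  for (nm in names(updates)) p[[nm]] <- updates[[nm]]
  sampler_params(A_s = p$A_s, delta = p$delta, V_s = p$V_s, K_SA = p$K_SA,
                 k_O = p$k_O, k_reac = p$k_reac, C_cap = p$C_cap,
                 R_s = p$R_s, stoich = p$stoich,
                 capacity_model = p$capacity_model)
}

#' Capacity-limiting factor
#'
#' Scales the reaction flux by the remaining dye fraction
#' `r = 1 - C_s / C_cap`: `g(r) = r` for the `"smooth"` model (reaction rate
#' proportional to remaining dye, exponential approach to the plateau) or
#' `g(r) = 1(r > 0)` for the `"hard"` model (full rate until exhaustion).
#'
#' @param r Remaining dye fraction in `[0, 1]` (clamped; vectorised).
#' @param model `"smooth"` or `"hard"`.
#' @return Limiting factor in `[0, 1]`.
#' @export
capacity_factor <- function(r, model = c("smooth", "hard")) {
  model <- match.arg(model)
  r <- pmin(pmax(r, 0), 1)
  if (model == "smooth") r else as.numeric(r > 0)
}

#' Fickian diffusion flux from air into the sampler
#'
#' `F_diffusion = k_O * A_s * (C_A - c_free / K_SA)`: first-law mass flow
#' driven by the difference between the air concentration and the
#' back-pressure of chlorine already dissolved (unreacted) in the sampler.
#' Negative values mean outgassing.
#'
#' @param params [sampler_params()].
#' @param C_A Air-side chlorine concentration, mol m-3, >= 0.
#' @param c_free Dissolved unreacted chlorine in the sampler, mol m-3, >= 0.
#' @return Flux, mol h-1.
#' @export
diffusion_flux <- function(params, C_A, c_free) {
  chk_num(C_A, "C_A", lower = 0)
  chk_num(c_free, "c_free", lower = 0)
  params$k_O * params$A_s * (C_A - c_free / params$K_SA)
}

#' First-order reaction flux of chlorine with the dye
#'
#' `F_reaction = k_reac * A_s * c_free / delta * g(dye_remaining)`, where
#' `g` is the [capacity_factor()]; the flux vanishes when the sampler is
#' exhausted.
#'
#' @param params [sampler_params()].
#' @param c_free Dissolved unreacted chlorine, mol m-3, >= 0.
#' @param dye_remaining Remaining dye fraction in `[0, 1]` (default 1).
#' @return Flux, mol h-1.
#' @export
reaction_flux <- function(params, c_free, dye_remaining = 1) {
  chk_num(c_free, "c_free", lower = 0)
  chk_num(dye_remaining, "dye_remaining", lower = 0, upper = 1)
  g <- capacity_factor(dye_remaining, params$capacity_model)
  params$k_reac * params$A_s * c_free / params$delta * g
}

#' Harmonic (series-resistance) combination of two fluxes
#'
#' Literal two-resistance composition `1 / (1/F_diff + 1/F_reac)`,
#' kept as a diagnostic evaluator: it is degenerate at start-up (zero
#' dissolved chlorine forces a zero reaction flux and hence zero total flux,
#' contradicting the observed initial linear uptake), which is why the
#' integrators in [simulate_uptake()] use the two-state formulation instead.
#'
#' @param F_diff,F_reac Fluxes, mol h-1, >= 0.
#' @return Combined flux, mol h-1; 0 when either input is 0.
#' @export
total_flux_literal <- function(F_diff, F_reac) {
  chk_num(F_diff, "F_diff", lower = 0)
  chk_num(F_reac, "F_reac", lower = 0)
  out <- numeric(length(F_diff))
  ok <- F_diff > 0 & F_reac > 0
  out[ok] <- 1 / (1 / F_diff[ok] + 1 / F_reac[ok])
  out
}

#' Quasi-steady uptake flux (series-resistance closed form)
#'
#' Closed form obtained by letting the small pool of dissolved unreacted
#' chlorine relax instantaneously between diffusion supply and reactive
#' consumption:
#' `F = A_s * C_A / (1/k_O + delta / (k_reac * K_SA * g))`.
#' It reduces to the diffusion-limited `k_O * A_s * C_A` when the reaction
#' is fast, and to zero when the dye is exhausted — the two limits the
#' uptake data exhibit.
#'
#' @param params [sampler_params()].
#' @param C_A Air-side concentration, mol m-3, >= 0 (vectorised).
#' @param dye_remaining Remaining dye fraction in `[0, 1]` (default 1).
#' @return Flux, mol h-1.
#' @export
quasi_steady_flux <- function(params, C_A, dye_remaining = 1) {
  chk_num(C_A, "C_A", lower = 0)
  chk_num(dye_remaining, "dye_remaining", lower = 0, upper = 1)
  g <- capacity_factor(dye_remaining, params$capacity_model)
  n <- max(length(C_A), length(g))
  out <- numeric(n)
  C_A <- rep_len(C_A, n)
  g <- rep_len(g, n)
  pos <- g > 0
  out[pos] <- params$A_s * C_A[pos] /
    (1 / params$k_O + params$delta / (params$k_reac * params$K_SA * g[pos]))
  out
}

#' Effective sampling rate in the reaction-fast linear regime
#'
#' In the linear regime the uptake flux is `k_O * A_s * C_A`, i.e. the
#' sampler clears `k_O * A_s` cubic metres of air per hour. With the default
#' `k_O = R_s / A_s` this returns the calibrated sampling rate `R_s`
#' exactly, reconciling the kinetic model with the rate used in the exposure
#' equation.
#'
#' @param params [sampler_params()].
#' @return Sampling rate, m3 h-1.
#' @export
sampling_rate_identity <- function(params) {
  params$k_O * params$A_s
}

#' Simulate chlorine uptake into the sampler
#'
#' Integrates the uptake model against an air-concentration series.
#' Two formulations are available:
#'
#' * `"two_state"` (mechanistic default): free dissolved chlorine `c_free`
#'   and cumulative reacted chlorine `C_s` evolve as
#'   `dc_free/dt = (F_diffusion - F_reaction) / V_s`,
#'   `dC_s/dt = F_reaction / V_s`, integrated with an adaptive stiff solver
#'   (deSolve::lsoda, atol 1e-12, rtol 1e-8); deterministic and seedless.
#' * `"quasi_steady"`: single-state reduction
#'   `dC_s/dt = quasi_steady_flux / V_s`, integrated with a fixed-step RK4;
#'   cheap and non-stiff, agreeing with the two-state model whenever the
#'   dissolved pool relaxes quickly (the reaction-fast regime).
#'
#' The air series is interpolated linearly between points and held constant
#' beyond its last point (zero-order hold).
#'
#' @param params [sampler_params()].
#' @param air An [air_series()] covering time 0 (minutes scale).
#' @param duration Simulated deployment, hours, > 0.
#' @param step Output time step, hours (default 0.01).
#' @param mode `"two_state"` or `"quasi_steady"`.
#' @param cond [gas_conditions()] for the ppbv -> molar conversion.
#' @return A data.frame of class `ppas_uptake_trajectory` with columns
#'   `time_h`, `c_free_mol_m3`, `C_s_mol_m3`, `flux_mol_h` (total uptake
#'   flux from air) and, for the two-state mode, `uptake_mol_m3`
#'   (cumulative uptake per sampler volume, for mass-balance checks).
#' @examples
#' air <- air_series(c(0, 180), c(500, 500))
#' tr <- simulate_uptake(sampler_params(), air, duration = 3)
#' tail(tr, 1)$C_s_mol_m3
#' @export
simulate_uptake <- function(params, air, duration, step = 0.01,
                            mode = c("two_state", "quasi_steady"),
                            cond = gas_conditions()) {
  stopifnot(inherits(params, "sampler_params"))
  mode <- match.arg(mode)
  chk_num(duration, "duration", lower = 0, strict = TRUE, len = 1L)
  chk_num(step, "step", lower = 0, strict = TRUE, len = 1L)
  air <- as_air_series(air)
  if (min(air$time_min) > 1e-9)
    stop_input("air series must cover time 0 (first timestamp ",
               min(air$time_min), " min)")
  ca_fun <- air_series_fun(air, cond)
  times <- seq(0, duration, by = step)
  if (tail(times, 1L) < duration) times <- c(times, duration)

  if (mode == "two_state") {
    rhs <- function(t, y, parms) {
      cf <- max(y[1], 0)
      r <- 1 - y[2] / params$C_cap
      g <- capacity_factor(r, params$capacity_model)
      Fd <- params$k_O * params$A_s * (ca_fun(t) - cf / params$K_SA)
      Fr <- params$k_reac * params$A_s * cf / params$delta * g
      list(c((Fd - Fr) / params$V_s, Fr / params$V_s, Fd / params$V_s))
    }
    sol <- deSolve::lsoda(y = c(c_free = 0, C_s = 0, uptake = 0),
                          times = times, func = rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-12, maxsteps = 50000)
    c_free <- pmax(sol[, "c_free"], 0)
    C_s <- pmin(cummax(pmax(sol[, "C_s"], 0)), params$C_cap)
    flux <- params$k_O * params$A_s *
      (ca_fun(sol[, "time"]) - c_free / params$K_SA)
    out <- data.frame(time_h = sol[, "time"], c_free_mol_m3 = c_free,
                      C_s_mol_m3 = C_s, flux_mol_h = flux,
                      uptake_mol_m3 = sol[, "uptake"])
  } else {
    C_s <- qs_solve(params, ca_fun, times)
    r <- 1 - C_s / params$C_cap
    flux <- quasi_steady_flux(params, ca_fun(times), r)
    g <- capacity_factor(r, params$capacity_model)
    # dissolved pool implied by the quasi-steady balance F_diff = F_reaction
    c_free <- ifelse(g > 0,
                     params$k_O * ca_fun(times) /
                       (params$k_O / params$K_SA +
                          params$k_reac * g / params$delta),
                     params$K_SA * ca_fun(times))
    out <- data.frame(time_h = times, c_free_mol_m3 = c_free,
                      C_s_mol_m3 = C_s, flux_mol_h = flux)
  }
  structure(out, class = c("ppas_uptake_trajectory", "data.frame"),
            params = params, mode = mode)
}

# Fixed-step RK4 machinery for the single-state quasi-steady model.
# The substep grid and the air concentration evaluated on it depend only on
# (air series, output times), not on the kinetic parameters, so parameter
# fitting builds the plan once and reruns only the arithmetic loop.
qs_plan <- function(ca_fun_molar, times, h_max = 0.01) {
  stopifnot(length(times) >= 1L, !is.unsorted(times))
  ts <- times[1]
  out_idx <- integer(length(times)); out_idx[1] <- 1L
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    nsub <- max(1L, ceiling((t1 - t0) / h_max - 1e-9))
    ts <- c(ts, t0 + (t1 - t0) * seq_len(nsub) / nsub)
    out_idx[i + 1L] <- length(ts)
  }
  list(ts = ts, out_idx = out_idx,
       h = diff(ts),
       ca0 = ca_fun_molar(ts),
       ca_mid = ca_fun_molar((head(ts, -1L) + tail(ts, -1L)) / 2))
}

qs_run <- function(params, plan) {
  A_s <- params$A_s; k_O <- params$k_O; delta <- params$delta
  k_reac <- params$k_reac; K_SA <- params$K_SA; C_cap <- params$C_cap
  V_s <- params$V_s
  hard <- params$capacity_model == "hard"
  rki <- 1 / k_O
  cf <- A_s / V_s
  rr <- delta / (k_reac * K_SA)
  rhs <- function(ca, cs) {
    r <- 1 - cs / C_cap
    if (r <= 0) return(0)
    g <- if (hard) 1 else r
    cf * ca / (rki + rr / g)
  }
  n <- length(plan$ts)
  y <- numeric(n)
  h <- plan$h; ca0 <- plan$ca0; cam <- plan$ca_mid
  for (j in seq_len(n - 1L)) {
    hj <- h[j]; yj <- y[j]
    k1 <- rhs(ca0[j], yj)
    k2 <- rhs(cam[j], yj + hj / 2 * k1)
    k3 <- rhs(cam[j], yj + hj / 2 * k2)
    k4 <- rhs(ca0[j + 1L], yj + hj * k3)
    yn <- yj + hj / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[j + 1L] <- min(max(yn, 0), C_cap)
  }
  y[plan$out_idx]
}

qs_solve <- function(params, ca_fun_molar, times, h_max = 0.01) {
  qs_run(params, qs_plan(ca_fun_molar, times, h_max))
}

#' Read / write an uptake trajectory CSV
#'
#' Columns `time_h,c_free_mol_m3,C_s_mol_m3,flux_mol_h`; `#` comment lines
#' allowed.
#'
#' @param path File path.
#' @return [read_uptake_trajectory()] returns a data.frame.
#' @export
read_uptake_trajectory <- function(path) {
  read_ppas_csv(path, c("time_h", "c_free_mol_m3", "C_s_mol_m3",
                        "flux_mol_h"))
}

#' @param x A trajectory from [simulate_uptake()].
#' @param comments Optional `#` comment lines (provenance).
#' @rdname read_uptake_trajectory
#' @export
write_uptake_trajectory <- function(x, path, comments = NULL) {
  write_ppas_csv(x, path, comments)
}
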