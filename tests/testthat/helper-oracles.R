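# Independent oracles and fixture builders used across the suite.

# Explicit fixed-step Euler integration of the two-state uptake equations,
# written directly from the flux definitions (independent of the package's
# integrators). Returns C_s at the end of the run.
euler_two_state <- function(par, ca_fun_molar, duration, h = 1e-4) {
  c_free <- 0
  C_s <- 0
  n <- round(duration / h)
  for (i in seq_len(n)) {
    t <- (i - 1) * h
    r <- 1 - C_s / par$C_cap
    g <- max(min(r, 1), 0)                      # smooth capacity model
    Fd <- par$k_O * par$A_s * (ca_fun_molar(t) - c_free / par$K_SA)
    Fr <- par$k_reac * par$A_s * c_free / par$delta * g
    c_free <- max(c_free + h * (Fd - Fr) / par$V_s, 0)
    C_s <- min(C_s + h * Fr / par$V_s, par$C_cap)
  }
  C_s
}

# Random parameter sets in the explicit-Euler stability region at h = 1e-4 h:
# the dissolved-pool relaxation rate k_O*A_s/(K_SA*V_s) + k_reac*A_s/(delta*V_s)
# must stay below 2/h = 2e4 h-1, which bounds k_reac by ~1.5e-3 h-1 at the
# default geometry (reaction-limited regime; a numerical check, not a
# physical-regime claim).
random_euler_params <- function(seed) {
  set.seed(seed)
  sampler_params(
    k_O = runif(1, 2, 15),
    k_reac = exp(runif(1, log(1e-4), log(1.5e-3))),
    K_SA = runif(1, 5, 50),
    C_cap = runif(1, 0.5, 3)
  )
}

const_air <- function(ppbv, dur_min = 360) {
  air_series(c(0, dur_min), c(ppbv, ppbv))
}

# naive two-segment scan (double lm loop), oracle for changepoint_check
naive_two_segment <- function(t, y, min_seg = 2L) {
  n <- length(t)
  sse <- function(i, j) {
    f <- lm(y[i:j] ~ t[i:j])
    sum(resid(f)^2)
  }
  sse_one <- sse(1, n)
  best <- Inf
  best_k <- NA_integer_
  for (k in min_seg:(n - min_seg)) {
    s <- sse(1, k) + sse(k + 1, n)
    if (s < best - 1e-15) {
      best <- s
      best_k <- k
    }
  }
  list(sse_one = sse_one, sse_two = best, split_idx = best_k)
}

# series noised through the PTR-MS channel model and recovered, the
# generator's noise pathway for concentration series
noisy_recovered_series <- function(series, noise_cv, seed,
                                   cal = ptrms_calibration(10)) {
  ch <- generate_ptrms_channels(series, cal, noise_cv = noise_cv,
                                seed = seed)
  instantaneous_concentration(ch, cal)
}
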