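# hand-evaluated flux oracles at k_O = 11.244 m/h, A_s = 2.25e-4 m2,
# C_A = 500 ppbv at standard conditions = 2.0437e-5 mol m-3
CA_500 <- 500 * 4.087404756242854e-08

test_that("diffusion flux follows Fick's law with a partition back-pressure", {
  p <- sampler_params(k_O = 11.244)
  expect_equal(diffusion_flux(p, CA_500, 0),
               11.244 * 2.25e-4 * CA_500, tolerance = 1e-12)
  expect_equal(diffusion_flux(p, CA_500, 0), 5.170363e-08, tolerance = 1e-6)
  # equilibrium null point
  expect_equal(diffusion_flux(p, CA_500, p$K_SA * CA_500), 0)
  # outgassing allowed
  expect_lt(diffusion_flux(p, 0, 1e-4), 0)
  # linear in k_O
  p2 <- sampler_params(k_O = 2 * 11.244)
  expect_equal(diffusion_flux(p2, CA_500, 0),
               2 * diffusion_flux(p, CA_500, 0), tolerance = 1e-12)
})

test_that("reaction flux is first order in dissolved chlorine and dye-limited", {
  p <- sampler_params(k_reac = 100)
  expect_equal(reaction_flux(p, 0, 1), 0)
  expect_equal(reaction_flux(p, 1e-5, 0), 0)      # exhausted sampler
  # 100 * 2.25e-4 * 1e-5 / 5.5e-4
  expect_equal(reaction_flux(p, 1e-5, 1), 4.090909090909091e-04,
               tolerance = 1e-12)
  expect_equal(reaction_flux(p, 1e-5, 0.5), 0.5 * reaction_flux(p, 1e-5, 1))
  ph <- sampler_params(k_reac = 100, capacity_model = "hard")
  expect_equal(reaction_flux(ph, 1e-5, 0.5), reaction_flux(ph, 1e-5, 1))
})

test_that("literal harmonic flux combination behaves as series resistances", {
  expect_equal(total_flux_literal(3, 6), 2)
  expect_equal(total_flux_literal(5, 5), 2.5)
  expect_equal(total_flux_literal(1, 1e12), 1, tolerance = 1e-9)
  expect_equal(total_flux_literal(0, 7), 0)    # degenerate at start-up
  expect_equal(total_flux_literal(7, 0), 0)
  expect_error(total_flux_literal(-1, 3), "F_diff",
               class = "ppas_input_error")
})

test_that("quasi-steady flux interpolates between its two limits", {
  p <- sampler_params(k_O = 11.244, k_reac = 100, K_SA = 10)
  # hand evaluation: 2.25e-4 * CA / (1/11.244 + 5.5e-4/(100*10))
  expect_equal(quasi_steady_flux(p, CA_500, 1), 5.170330672050456e-08,
               tolerance = 1e-9)
  # reaction-fast limit -> diffusion-limited flux
  pf <- sampler_params(k_O = 11.244, k_reac = 1e9)
  expect_equal(quasi_steady_flux(pf, CA_500, 1),
               11.244 * 2.25e-4 * CA_500, tolerance = 1e-6)
  expect_equal(quasi_steady_flux(p, CA_500, 0), 0)
  # slower reaction strictly reduces the flux
  ps <- sampler_params(k_O = 11.244, k_reac = 1e-3)
  expect_lt(quasi_steady_flux(ps, CA_500, 1), quasi_steady_flux(p, CA_500, 1))
})

test_that("linear-regime sampling rate identity reproduces R_s", {
  p <- sampler_params()
  expect_equal(sampling_rate_identity(p), p$R_s, tolerance = 1e-12)
  expect_equal(sampling_rate_identity(p), 2.53e-3, tolerance = 1e-12)
  p2 <- sampler_params(A_s = 2 * 2.25e-4, k_O = p$k_O)
  expect_equal(sampling_rate_identity(p2), 2 * sampling_rate_identity(p))
  p3 <- sampler_params(k_O = 1e-6)
  expect_lt(sampling_rate_identity(p3), 1e-9)
})

test_that("uptake simulation is null without a source and respects invariants", {
  p <- sampler_params()
  tr <- simulate_uptake(p, const_air(0), duration = 2)
  expect_true(all(tr$C_s_mol_m3 == 0))
  expect_true(all(tr$c_free_mol_m3 == 0))

  tr2 <- simulate_uptake(p, const_air(800), duration = 4)
  expect_true(all(diff(tr2$C_s_mol_m3) >= -1e-12))
  expect_true(all(tr2$C_s_mol_m3 >= 0 & tr2$C_s_mol_m3 <= p$C_cap))
  expect_true(all(tr2$c_free_mol_m3 >= 0))
  expect_equal(tr2$C_s_mol_m3[1], 0)
  # mass conservation: cumulative uptake = dissolved + reacted
  rel <- abs(tr2$uptake_mol_m3 - (tr2$c_free_mol_m3 + tr2$C_s_mol_m3)) /
    pmax(tr2$uptake_mol_m3, 1e-12)
  expect_lt(max(rel[-1]), 1e-6)
})

test_that("early uptake slope equals the diffusion-limited sampling rate", {
  p <- sampler_params()
  tr <- simulate_uptake(p, const_air(500), duration = 0.05, step = 0.005)
  slope <- tail(tr$C_s_mol_m3, 1) / 0.05
  expect_equal(slope, p$k_O * p$A_s * CA_500 / p$V_s, tolerance = 0.01)
})

test_that("plateau reaches capacity regardless of mass-transfer speed", {
  # the fan effect: a 5-fold k_O change alters the approach speed but not
  # the saturation level
  p_slow <- sampler_params()
  p_fast <- sampler_params(k_O = 5 * p_slow$k_O)
  air <- const_air(5000, dur_min = 48 * 60)
  tr_s <- simulate_uptake(p_slow, air, duration = 48, step = 0.05)
  tr_f <- simulate_uptake(p_fast, air, duration = 48, step = 0.05)
  end_s <- tail(tr_s$C_s_mol_m3, 1)
  end_f <- tail(tr_f$C_s_mol_m3, 1)
  expect_equal(end_s, p_slow$C_cap, tolerance = 5e-3)
  expect_equal(end_f, p_slow$C_cap, tolerance = 5e-3)
  expect_equal(end_s, end_f, tolerance = 5e-3)
  t90 <- function(tr) tr$time_h[which(tr$C_s_mol_m3 >= 0.9 * 1.8)[1]]
  expect_gt(t90(tr_s) / t90(tr_f), 2)
})

test_that("accumulated C_s is monotone in concentration, kinetics and time", {
  base <- list(ppbv = 300, k_O = 11.244, k_reac = 100, dur = 2)
  end_cs <- function(ppbv = base$ppbv, k_O = base$k_O, k_reac = base$k_reac,
                     dur = base$dur) {
    p <- sampler_params(k_O = k_O, k_reac = k_reac)
    tail(simulate_uptake(p, const_air(ppbv, 60 * dur), dur,
                         step = 0.05)$C_s_mol_m3, 1)
  }
  ref <- end_cs()
  expect_gt(end_cs(ppbv = 600), ref)
  expect_gt(end_cs(k_O = 22), ref)
  expect_gte(end_cs(k_reac = 1000), ref - 1e-9)
  expect_gt(end_cs(dur = 6), ref)
  expect_lt(end_cs(ppbv = 150), ref)
})

test_that("two-state and quasi-steady modes agree when the pool is fast", {
  air <- const_air(1000, 6 * 60)
  for (k_reac in c(100, 1000, 2e4)) {
    p <- sampler_params(k_reac = k_reac)
    a <- tail(simulate_uptake(p, air, 5, step = 0.05)$C_s_mol_m3, 1)
    b <- tail(simulate_uptake(p, air, 5, step = 0.05,
                              mode = "quasi_steady")$C_s_mol_m3, 1)
    expect_equal(a, b, tolerance = 0.02)
  }
})

test_that("adaptive integrator matches the explicit-Euler oracle", {
  # light version of the randomized-equivalence check (more sets in the
  # acceptance suite)
  for (seed in 1:5) {
    p <- random_euler_params(seed)
    set.seed(seed + 100)
    ppbv <- runif(1, 200, 2000)
    air <- const_air(ppbv, 180)
    ref <- euler_two_state(p, air_series_fun(air, gas_conditions()), 2)
    got <- tail(simulate_uptake(p, air, 2, step = 0.02)$C_s_mol_m3, 1)
    expect_equal(got, ref, tolerance = 1e-3)
  }
})

test_that("trajectories survive a CSV round trip", {
  p <- sampler_params()
  tr <- simulate_uptake(p, const_air(500), 1, step = 0.1)
  f <- tempfile(fileext = ".csv")
  write_uptake_trajectory(tr[c("time_h", "c_free_mol_m3", "C_s_mol_m3",
                               "flux_mol_h")], f, comments = "fixture")
  tr2 <- read_uptake_trajectory(f)
  expect_equal(tr2$C_s_mol_m3, tr$C_s_mol_m3, tolerance = 1e-12)
})

test_that("simulation inputs are validated", {
  p <- sampler_params()
  expect_error(simulate_uptake(p, const_air(1), duration = -1), "duration")
  expect_error(simulate_uptake(p, const_air(1), 1, step = 0), "step")
  late <- air_series(c(10, 60), c(5, 5))
  expect_error(simulate_uptake(p, late, 1), "cover",
               class = "ppas_input_error")
  expect_error(sampler_params(delta = 0), "delta")
  expect_error(sampler_params(C_cap = -1), "C_cap")
})
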