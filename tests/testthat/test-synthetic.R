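test_that("emission profiles have the scenario-specific shapes", {
  # zero plateau -> identically zero
  z <- emission_profile(scenario_config("liquid", plateau_ppbv = 0))
  expect_true(all(z$ppbv == 0))
  # liquid: saturating rise toward the plateau
  liq <- emission_profile(scenario_config("liquid", plateau_ppbv = 1160,
                                          rise_rate = 1, duration_h = 3))
  expect_true(all(diff(liq$ppbv) > 0))
  expect_true(all(liq$ppbv < 1160))
  expect_equal(tail(liq$ppbv, 1), 1160 * (1 - exp(-3)), tolerance = 1e-12)
  # high rise rate approaches the plateau within the run
  fast <- emission_profile(scenario_config("liquid", plateau_ppbv = 1160,
                                           rise_rate = 50))
  expect_equal(tail(fast$ppbv, 1), 1160, tolerance = 1e-6)
  # gel: early slope strictly below late slope
  gel <- emission_profile(scenario_config("gel", lag_time = 1.5,
                                          duration_h = 3))
  th <- gel$time_min / 60
  early <- diff(range(gel$ppbv[th <= 1.5])) / 1.5
  late <- diff(range(gel$ppbv[th >= 1.5])) / 1.5
  expect_lt(early, late)
  expect_equal(late / early, scenario_config("gel")$gel_slope_ratio,
               tolerance = 1e-9)
  expect_equal(tail(gel$ppbv, 1), scenario_config("gel")$plateau_ppbv,
               tolerance = 1e-9)
})

test_that("spray plateaus grow sublinearly with the number of sprays", {
  plat <- vapply(c(1, 5, 10), function(n) {
    max(emission_profile(scenario_config("spray", amount = n,
                                         rise_rate = 50))$ppbv)
  }, numeric(1))
  expect_true(all(diff(plat) > 0))             # ordered
  expect_lt(plat[2], 5 * plat[1])              # sublinear
  expect_lt(plat[3], 2 * plat[2])
  expect_equal(plat[3] / plat[1], 10^0.7, tolerance = 1e-6)
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario_config("gel", lag_time = 4, duration_h = 3),
               "lag_time", class = "ppas_input_error")
  expect_error(scenario_config("liquid", dilution_factor = 0.5),
               "dilution_factor")
  expect_error(scenario_config("nonsense"))
})

test_that("experiments regenerate bit-for-bit from the same seed", {
  p <- sampler_params()
  sc <- scenario_config("liquid", seed = 42)
  dep <- c(0.5, 1, 2)
  e1 <- generate_experiment(sc, p, dep, n_replicates = 3, noise_cv = 0.05)
  e2 <- generate_experiment(sc, p, dep, n_replicates = 3, noise_cv = 0.05)
  expect_identical(e1$measurements, e2$measurements)
  expect_identical(e1$truth, e2$truth)
  sc2 <- scenario_config("liquid", seed = 43)
  e3 <- generate_experiment(sc2, p, dep, n_replicates = 3, noise_cv = 0.05)
  expect_false(identical(e1$measurements$Cf_g_per_L,
                         e3$measurements$Cf_g_per_L))
})

test_that("adding replicates never perturbs earlier ones", {
  p <- sampler_params()
  sc <- scenario_config("liquid", seed = 9)
  dep <- c(0.5, 1.5)
  e2 <- generate_experiment(sc, p, dep, n_replicates = 2, noise_cv = 0.05)
  e4 <- generate_experiment(sc, p, dep, n_replicates = 4, noise_cv = 0.05)
  first_two <- function(e, n) do.call(rbind, lapply(split(
    as.data.frame(e$measurements), e$measurements$deployment_h),
    function(d) d[1:n, ]))
  expect_equal(first_two(e2, 2), first_two(e4, 2), ignore_attr = TRUE)
})

test_that("noise-free generation inverts exactly through the extraction equation", {
  p <- sampler_params()
  sc <- scenario_config("liquid", seed = 3)
  dep <- c(0.25, 0.5, 1)
  e <- generate_experiment(sc, p, dep, n_replicates = 2, noise_cv = 0)
  cs <- cs_from_extraction(e$measurements, p)
  expect_equal(cs, rep(e$truth$C_s_true, each = 2), tolerance = 1e-9)
})

test_that("extraction noise has the configured coefficient of variation", {
  p <- sampler_params()
  sc <- scenario_config("liquid", seed = 101)
  e <- generate_experiment(sc, p, deployment_times = 1,
                           n_replicates = 100, noise_cv = 0.05)
  cs <- cs_from_extraction(e$measurements, p)
  cv <- sd(cs) / mean(cs)
  expect_gt(cv, 0.03)
  expect_lt(cv, 0.07)
})

test_that("excessive noise draws are floored with a warning", {
  p <- sampler_params()
  # tiny blank concentration forces the cap C_f >= 0 to bite
  sc <- scenario_config("stock_solution", plateau_ppbv = 5000, seed = 4)
  expect_warning(
    generate_experiment(sc, p, deployment_times = c(2, 3),
                        n_replicates = 30, noise_cv = 0.6, C_i = 1e-4),
    "floored")
})

test_that("synthetic channels split by isotopologue fractions", {
  s <- air_series(c(0, 10, 20), c(100, 200, 300))
  cal <- ptrms_calibration(10)
  ch <- generate_ptrms_channels(s, cal, noise_cv = 0)
  f <- isotopologue_fractions()
  tot <- ch$in_70 + ch$in_72 + ch$in_74
  expect_equal(ch$in_70 / tot, rep(f[["m70"]], 3), tolerance = 1e-12)
  expect_equal(ch$in_72 / tot, rep(f[["m72"]], 3), tolerance = 1e-12)
  expect_equal(ch$in_74 / tot, rep(f[["m74"]], 3), tolerance = 1e-12)
  # zero concentration -> inside equals the outside baseline
  z <- generate_ptrms_channels(air_series(c(0, 5), c(0, 0)), cal,
                               baseline = 20)
  expect_true(all(z$in_70 == 20 & z$out_70 == 20))
  # seeded noise is reproducible
  n1 <- generate_ptrms_channels(s, cal, noise_cv = 0.05, seed = 8)
  n2 <- generate_ptrms_channels(s, cal, noise_cv = 0.05, seed = 8)
  expect_identical(n1, n2)
  expect_error(generate_ptrms_channels(s, cal, noise_cv = 0.05),
               "seed", class = "ppas_input_error")
})

test_that("experiment directories carry a readable truth sidecar", {
  p <- sampler_params()
  sc <- scenario_config("gel", seed = 6)
  e <- generate_experiment(sc, p, c(1, 2), n_replicates = 1, noise_cv = 0,
                           cal = ptrms_calibration(10))
  dir <- file.path(tempdir(), "ppas-exp-test")
  write_experiment(e, dir)
  expect_true(all(file.exists(file.path(
    dir, c("emission.csv", "measurements.csv", "channels.csv",
           "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_equal(truth$truth$C_s_true, e$truth$C_s_true, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
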