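model <- load_pathway()
lab6 <- labeling_state("lysine", 6, model)

test_that("noiseless time courses close the stoichiometric balance exactly", {
  eq <- ref_lysine_equation()
  sim <- sim_growth_timecourse(eq, substrate_mM = 16.8, seed = 1)
  final <- sim$record[sim$record$time_h == max(sim$record$time_h), ]
  expect_equal(final$delta_mM[final$compound == "lysine"], 16.8)
  expect_equal(final$delta_mM[final$compound == "butyrate"], 16.8)
  expect_equal(final$delta_mM[final$compound == "acetate"], 16.8)
  expect_equal(final$delta_mM[final$compound == "ammonia"], 33.6)
  expect_equal(carbon_recovery(final)$recovery, 1, tolerance = 1e-9)
})

test_that("anabolic product losses reproduce the measured endpoint recovery", {
  eq <- ref_lysine_equation()
  sim <- sim_growth_timecourse(
    eq, substrate_mM = 16.8,
    product_scale = c(butyrate = 0.845, acetate = 0.929, ammonia = 0.658),
    seed = 1)
  final <- sim$record[sim$record$time_h == max(sim$record$time_h), ]
  expect_equal(final$delta_mM[final$compound == "butyrate"], 16.8 * 0.845)
  expect_equal(carbon_recovery(final)$recovery, 0.873, tolerance = 1e-3)
})

test_that("generators are deterministic given the seed", {
  eq <- ref_lysine_equation()
  a <- sim_growth_timecourse(eq, noise_sd_od = 0.01, noise_sd_conc = 0.3,
                             seed = 42)
  b <- sim_growth_timecourse(eq, noise_sd_od = 0.01, noise_sd_conc = 0.3,
                             seed = 42)
  expect_identical(a, b)
  c <- sim_growth_timecourse(eq, noise_sd_od = 0.01, noise_sd_conc = 0.3,
                             seed = 43)
  expect_false(identical(a$record$delta_mM, c$record$delta_mM))

  h1 <- sim_hmbc_integrals(c(p2 = 0.2, p4 = 0.5, p24 = 0.3), 10,
                           noise_sd = 0.1, seed = 9)
  h2 <- sim_hmbc_integrals(c(p2 = 0.2, p4 = 0.5, p24 = 0.3), 10,
                           noise_sd = 0.1, seed = 9)
  expect_identical(h1, h2)

  fx <- flux_config(0.6, c(lysine_c1c2 = 0.7, recycled = 0.3))
  o1 <- sim_labeling_observation(model, lab6, fx, noise_sd = 0.05, seed = 5)
  o2 <- sim_labeling_observation(model, lab6, fx, noise_sd = 0.05, seed = 5)
  expect_identical(o1, o2)
})

test_that("simulated growth curves fit back to the generating parameters", {
  eq <- ref_lysine_equation()
  sim <- sim_growth_timecourse(eq, A = 2, mu_max = 0.1, lambda = 5,
                               od0 = 0.02, seed = 1)
  fit <- fit_gompertz(sim$curve, od0 = 0.02)
  expect_equal(fit$mu_max, 0.1, tolerance = 1e-6)
  expect_equal(fit$lambda, 5, tolerance = 1e-5)
})

test_that("HMBC generation followed by estimation is the identity at zero noise", {
  set.seed(31)
  for (i in 1:50) {
    p <- stats::runif(3)
    p <- p / sum(p)
    atten <- stats::runif(2, 0.1, 5)
    ints <- sim_hmbc_integrals(c(p2 = p[1], p4 = p[2], p24 = p[3]),
                               total_signal = stats::runif(1, 1, 100),
                               attenuation = atten)
    est <- estimate_butyrate_fractions(ints)
    expect_equal(c(est$p2, est$p4, est$p24), p, tolerance = 1e-9)
  }
})

test_that("zero-noise labelling observations equal the tracer output", {
  fx <- flux_config(0.7, c(lysine_c1c2 = 0.6, recycled = 0.4))
  cf <- to_class_fractions(propagate_labels(model, lab6, fx))
  obs <- sim_labeling_observation(model, lab6, fx, noise_sd = 0)
  expect_equal(c(obs$p2, obs$p4, obs$p24), c(cf$p2, cf$p4, cf$p24))
})

test_that("multiplicative noise spreads fractions at the nominal scale", {
  fx <- flux_config(0.6, c(lysine_c1c2 = 0.7, recycled = 0.3))
  truth <- sim_labeling_observation(model, lab6, fx, noise_sd = 0)
  p4 <- vapply(1:50, function(s)
    sim_labeling_observation(model, lab6, fx, noise_sd = 0.05,
                             seed = s)$p4, numeric(1))
  # first-order (delta method) spread of log p4 after renormalization:
  # sd = sigma * sqrt((1 - p4)^2 + p2^2 + p24^2)
  pred_sd <- 0.05 * sqrt((1 - truth$p4)^2 + truth$p2^2 + truth$p24^2)
  emp_sd <- stats::sd(log(p4))
  expect_gt(emp_sd / pred_sd, 0.6)
  expect_lt(emp_sd / pred_sd, 1.6)
  expect_lt(abs(stats::median(p4) - truth$p4) / truth$p4, 0.05)
})
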