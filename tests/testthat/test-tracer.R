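model <- load_pathway()
lab6 <- labeling_state("lysine", 6, model)
lab2 <- labeling_state("lysine", 2, model)

test_that("pure lysine-branch flux converts [6-13C]lysine to [4-13C]butyrate only", {
  pr <- propagate_labels(model, lab6, flux_config(theta_lys = 1))
  but <- pr$distributions$butyrate
  expect_equal(unname(but[["0001"]]), 1)
  expect_equal(sum(but), 1, tolerance = 1e-9)
  expect_equal(unname(pr$distributions$acetate[["00"]]), 1)
  cf <- to_class_fractions(pr)
  expect_equal(c(cf$p2, cf$p4, cf$p24), c(0, 1, 0))
})

test_that("mixed flux reproduces the full observed isotopomer set from [6-13C]lysine", {
  fx <- flux_config(theta_lys = 0.7,
                    weights = c(lysine_c1c2 = 0.6, recycled = 0.4))
  pr <- propagate_labels(model, lab6, fx)
  cf <- to_class_fractions(pr)
  # all three labelled butyrate classes present: [4-13C], [2-13C], [2,4-13C]
  expect_true(cf$p4 > 0 && cf$p2 > 0 && cf$p24 > 0)
  expect_gt(cf$p4, cf$p2)  # lysine branch dominates
  # minor [2-13C]acetate appears (methyl label via thiolytic recycling),
  # unlabelled acetate dominates
  ace <- pr$distributions$acetate
  expect_gt(ace[["01"]], 0)
  expect_gt(ace[["00"]], 0.5)
  expect_equal(unname(ace[["10"]] + ace[["11"]]), 0)
})

test_that("[2-13C]lysine labels the acetate pool at C2", {
  fx <- flux_config(theta_lys = 0.7,
                    weights = c(lysine_c1c2 = 0.6, recycled = 0.4))
  pr <- propagate_labels(model, lab2, fx)
  ace <- pr$distributions$acetate
  expect_gt(ace[["01"]], 0.1)  # lysine C2 -> acetyl methyl
  but <- pr$distributions$butyrate
  expect_equal(unname(but[["0000"]] + but[["0100"]] + but[["0001"]] +
                        but[["0101"]]), 1, tolerance = 1e-9)
})

test_that("distributions are probability vectors under randomized fluxes", {
  set.seed(11)
  for (i in 1:25) {
    w <- stats::runif(4)
    fx <- flux_config(theta_lys = stats::runif(1),
                      weights = c(lysine_c1c2 = w[1], recycled = w[2] * 0.9,
                                  exogenous_acetate = w[3],
                                  glycolysis = w[4]))
    pr <- propagate_labels(model, lab6, fx)
    for (d in pr$distributions) {
      expect_true(all(d >= -1e-12))
      expect_equal(sum(d), 1, tolerance = 1e-9)
    }
  }
})

test_that("analytic fixed point matches the Monte-Carlo oracle", {
  set.seed(7)
  for (i in 1:6) {
    theta <- stats::runif(1, 0.2, 0.95)
    w <- c(lysine_c1c2 = stats::runif(1, 0.1, 1),
           recycled = stats::runif(1, 0, 0.8),
           exogenous_acetate = stats::runif(1, 0, 0.5),
           glycolysis = 0)
    pos <- sample(list(6L, 2L, c(2L, 6L)), 1)[[1]]
    pr <- propagate_labels(model, labeling_state("lysine", pos, model),
                           flux_config(theta, w))
    mc <- mc_trace_lysine(pos, theta, w, n = 2e4, seed = 100 + i)
    se <- sqrt(pmax(pr$distributions$butyrate *
                      (1 - pr$distributions$butyrate), 1e-12) / mc$n)
    expect_true(all(abs(pr$distributions$butyrate - as.numeric(mc$butyrate))
                    <= pmax(3 * se, 5 / mc$n)))
    se2 <- sqrt(pmax(pr$distributions$acetate *
                       (1 - pr$distributions$acetate), 1e-12) / mc$n)
    expect_true(all(abs(pr$distributions$acetate - as.numeric(mc$acetate))
                    <= pmax(3 * se2, 5 / mc$n)))
  }
})

test_that("13C atoms are conserved from substrate to products on the lysine branch", {
  # theta = 1 with the C1-C2 fragment as sole acetyl source: one butyrate and
  # one acetate per lysine carry all six carbons
  for (pos in list(2L, 6L, c(2L, 6L), 1:6)) {
    pr <- propagate_labels(model, labeling_state("lysine", pos, model),
                           flux_config(theta_lys = 1,
                                       weights = c(lysine_c1c2 = 1)))
    got <- expected_labels(pr$distributions$butyrate) +
      expected_labels(pr$distributions$acetate)
    expect_equal(got, length(pos), tolerance = 1e-9)
  }
})

test_that("p4 decreases as flux shifts away from the lysine branch", {
  thetas <- seq(1, 0.2, by = -0.1)
  p4 <- vapply(thetas, function(th) {
    pr <- propagate_labels(model, lab6,
                           flux_config(th, c(lysine_c1c2 = 0.6,
                                             recycled = 0.4)))
    to_class_fractions(pr)$p4
  }, numeric(1))
  expect_true(all(diff(p4) <= 1e-12))
})

test_that("degenerate closed-loop flux configurations are rejected", {
  expect_error(
    propagate_labels(model, lab6,
                     flux_config(theta_lys = 0, weights = c(recycled = 1))),
    "closed.*recycling loop|degenerate"
  )
  expect_error(flux_config(0.5, c(lysine_c1c2 = -0.2, recycled = 1.2)),
               ">= 0")
  expect_error(flux_config(0.5, c(bogus_source = 1)), "unknown")
})

test_that("class marginalization handles off-diagonal labelling", {
  # uniform over {C2 only, C4 only, C2&C4, C1 only}
  d <- numeric(16)
  names(d) <- apply(expand_patterns(4), 1, paste, collapse = "")
  d[c("0100", "0001", "0101", "1000")] <- 0.25
  cf <- to_class_fractions(d)
  expect_equal(c(cf$p2, cf$p4, cf$p24), rep(1 / 3, 3))
  expect_equal(cf$p_other, 0.25)

  point <- numeric(16)
  point[9] <- 1  # pattern 0001 = C4 only
  cf2 <- to_class_fractions(point)
  expect_equal(c(cf2$p2, cf2$p4, cf2$p24), c(0, 1, 0))

  unlab <- numeric(16)
  unlab[1] <- 1
  expect_error(to_class_fractions(unlab), "undefined")
})

test_that("flux split is recovered from noise-free observations", {
  fx <- flux_config(0.55, c(lysine_c1c2 = 0.65, recycled = 0.35))
  obs <- to_class_fractions(propagate_labels(model, lab6, fx))
  fit <- fit_flux_split(obs, model, lab6)
  expect_lt(abs(fit$flux$theta_lys - 0.55), 0.02)
  expect_lt(fit$residual, 1e-10)
  expect_false(fit$non_identifiable)
})

test_that("pure [4-13C]butyrate observations recover theta_lys = 1", {
  fit <- fit_flux_split(c(p2 = 0, p4 = 1, p24 = 0), model, lab6)
  expect_equal(fit$flux$theta_lys, 1)
  expect_true(fit$non_identifiable)  # flat in the recycling weight
})

test_that("flux split estimation is robust to 5% multiplicative noise", {
  fx <- flux_config(0.6, c(lysine_c1c2 = 0.7, recycled = 0.3))
  errs <- vapply(1:50, function(s) {
    obs <- sim_labeling_observation(model, lab6, fx, noise_sd = 0.05,
                                    seed = 2000 + s)
    fit <- fit_flux_split(obs, model, lab6,
                          theta_grid = seq(0, 1, by = 0.05),
                          w_rec_grid = seq(0, 0.9, by = 0.1))
    abs(fit$flux$theta_lys - 0.6)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})
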