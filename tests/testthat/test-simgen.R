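# Ground-truth population model: dose response, delivery, degradation
# kinetics, calibration and the spatial delivery mode.

test_that("zero SLO dose yields no permeabilization and no delivery", {
  gt <- sample_population(tiny_config(slo_dose = 0))
  expect_true(all(!gt$permeabilized))
  expect_true(all(gt$A == 0))
  expect_equal(gt$X, gt$X0)
})

test_that("target is untouched without kinetics or with the NC antibody", {
  cfg <- tiny_config(deg_kinetics = list(k_max = 0, K_A = 500, K_T = 300,
                                         f_res = 0))
  gt <- sample_population(cfg)
  expect_equal(gt$X, gt$X0)
  gt_nc <- sample_population(tiny_config(condition = "NC"))
  expect_equal(gt_nc$X, gt_nc$X0)
})

test_that("degradation follows the saturating closed form exactly", {
  cfg <- tiny_config(n_cells = 50, seed = 11)
  gt <- sample_population(cfg)
  kin <- cfg$deg_kinetics
  k <- kin$k_max * (gt$A / (gt$A + kin$K_A)) * (gt$T21 / (gt$T21 + kin$K_T))
  expected <- gt$X0 * (kin$f_res + (1 - kin$f_res) *
                         exp(-k * cfg$incubation_h))
  expected[gt$A == 0] <- gt$X0[gt$A == 0]
  expect_equal(gt$X, expected, tolerance = 1e-12)
  expect_true(all(gt$X <= gt$X0 + 1e-12))
  expect_true(all(gt$A[!gt$permeabilized] == 0))
})

test_that("remaining fraction approaches the resistant fraction in the
           saturated long-time limit", {
  cfg <- tiny_config(
    deg_kinetics = list(k_max = 5, K_A = 500, K_T = 300, f_res = 0.2),
    antibody_lognormal = c(meanlog = log(1e9), sdlog = 0.1),
    trim21_lognormal = c(meanlog = log(1e9), sdlog = 0.1),
    incubation_h = 1e6)
  gt <- sample_population(cfg)
  perm <- gt$permeabilized
  expect_true(any(perm))
  expect_equal(gt$X[perm] / gt$X0[perm], rep(0.2, sum(perm)),
               tolerance = 1e-6)
})

test_that("SLO-titration preset hits the calibrated permeabilized
           fraction at dose 0.2", {
  cfg <- preset_config("SLO-titration-HEK", seed = 101)
  cfg$field_shape <- c(3600L, 3600L)
  cfg$n_cells <- 10000L
  gt <- sample_population(cfg)
  p <- mean(gt$permeabilized)
  ci_half <- 2.576 * sqrt(0.746 * 0.254 / 10000)
  expect_lt(abs(p - 0.746), ci_half)
})

test_that("knockdown calibration honors trivial targets and the
           feasibility ceiling", {
  cfg <- sim_config(seed = 1)
  cfg <- calibrate_permeabilization(cfg, 0.746, dose = 0.2)
  c0 <- calibrate_knockdown(cfg, 0)
  expect_equal(c0$deg_kinetics$k_max, 0)
  # ~50% permeabilized at a reduced dose cannot support a 65% bulk target
  low <- cfg
  low$slo_dose <- 0.112
  expect_error(calibrate_knockdown(low, 0.65), "ceiling")
})

test_that("calibrated kinetics reproduce the bulk knockdown on a fresh
           population", {
  cfg <- preset_config("IKKa-3h", seed = 202)
  cfg$field_shape <- c(3600L, 3600L)
  cfg$n_cells <- 8000L
  gt <- sample_population(cfg)
  live <- !gt$died
  kd <- 1 - mean(gt$X[live]) / mean(gt$X0[live])
  expect_lt(abs(kd - 0.65), 0.02)
})

test_that("permeabilization is monotone in dose and degradation monotone
           in incubation time", {
  doses <- c(0.025, 0.05, 0.1, 0.2, 0.4)
  p_by_dose <- sapply(doses, function(d) {
    gt <- sample_population(tiny_config(n_cells = 40, seed = 5,
                                        slo_dose = d))
    mean(gt$perm_prob)
  })
  expect_true(all(diff(p_by_dose) >= 0))
  gt1 <- sample_population(tiny_config(n_cells = 40, seed = 5,
                                       incubation_h = 1))
  gt3 <- sample_population(tiny_config(n_cells = 40, seed = 5,
                                       incubation_h = 3))
  expect_equal(gt1$A, gt3$A)  # same draws, only the kinetics differ
  expect_true(all(gt3$X <= gt1$X + 1e-12))
})

test_that("bulk knockdown never exceeds permeabilized fraction times
           (1 - resistant fraction)", {
  set.seed(42)
  for (i in 1:5) {
    cfg <- tiny_config(
      n_cells = 50, seed = 100 + i,
      slo_dose = runif(1, 0.05, 0.6),
      incubation_h = runif(1, 0.5, 12),
      deg_kinetics = list(k_max = runif(1, 0, 5), K_A = 500, K_T = 300,
                          f_res = runif(1, 0, 0.5)))
    gt <- sample_population(cfg)
    kd <- 1 - mean(gt$X) / mean(gt$X0)
    ceiling_kd <- mean(gt$permeabilized) * (1 - cfg$deg_kinetics$f_res)
    expect_lte(kd, ceiling_kd + 0.05)
  }
})

test_that("cell centers always respect the minimum spacing", {
  for (s in c(3, 19)) {
    cfg <- sim_config(n_cells = 500L, seed = s, field_shape = c(800L, 800L))
    gt <- sample_population(cfg)
    d <- as.matrix(stats::dist(gt[, c("row", "col")]))
    diag(d) <- Inf
    expect_gte(min(d), cfg$min_spacing_px)
  }
})

test_that("identical config and seed give bit-identical truth and images", {
  cfg <- tiny_config(n_cells = 15, seed = 33)
  expect_identical(sample_population(cfg), sample_population(cfg))
  i1 <- simulate_field(cfg)
  i2 <- simulate_field(cfg)
  expect_identical(i1$rounds, i2$rounds)
  expect_identical(attr(i1, "truth"), attr(i2, "truth"))
})

test_that("uniform and zero-amplitude spatial modes leave the population
           unchanged", {
  cfg <- tiny_config(n_cells = 25, seed = 8)
  gt <- sample_population(cfg)
  expect_identical(apply_spatial_mode(gt, cfg), gt)
  cfg0 <- cfg
  cfg0$spatial_mode <- "center_gradient"
  cfg0$spatial_params["amplitude"] <- 0
  expect_identical(apply_spatial_mode(gt, cfg0), gt)
})

test_that("center-gradient mode concentrates delivery at the field
           center", {
  cfg <- sim_config(n_cells = 4000L, seed = 9,
                    field_shape = c(2400L, 2400L),
                    spatial_mode = "center_gradient")
  gt <- apply_spatial_mode(sample_population(cfg), cfg)
  ctr <- cfg$field_shape / 2
  R <- min(cfg$field_shape) / 2
  r <- sqrt((gt$row - ctr[1])^2 + (gt$col - ctr[2])^2) / R
  inner <- r <= 0.2
  outer <- r >= 0.8
  expect_gt(sum(inner), 30)
  expect_gt(sum(outer), 100)
  pos_in <- mean(gt$A[inner] > 0)
  pos_out <- mean(gt$A[outer] > 0)
  expect_gte(pos_in, 3 * pos_out)
})

test_that("malformed configurations are rejected with the field name", {
  expect_error(tiny_config(slo_dose = NaN), "slo_dose")
  expect_error(tiny_config(reseal_fail_prob = 1.5), "reseal_fail_prob")
  expect_error(tiny_config(deg_kinetics = list(k_max = -1, K_A = 1,
                                               K_T = 1, f_res = 0)),
               "k_max")
  expect_error(tiny_config(rounds = list(c("ab", "target"))), "nuclear")
  expect_error(tiny_config(nonsense = 1), "unknown")
})
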