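# Gating, percentile filtering, knockdown estimation, separation and
# condition comparisons.

# Truth-level cell table: intensities taken directly from the latent
# truths plus measurement-like jitter; fast stand-in for statistical
# properties that do not exercise the imaging stages.
truth_table <- function(gt, bg = 12, sd = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(gt)
  data.frame(cell_id = gt$cell_id, condition = gt$condition,
             died = gt$died,
             r1_ab_mean = bg + gt$A + rnorm(n, 0, sd),
             r1_target_mean = bg + gt$X + rnorm(n, 0, sd))
}

big_truth <- function(condition = "targeting", seed = 71, n = 5000,
                      slo_dose = 0.4) {
  cfg <- preset_config("IKKa-3h", seed = seed)
  cfg$condition <- condition
  cfg$slo_dose <- slo_dose
  cfg$field_shape <- c(2800L, 2800L)
  cfg$n_cells <- as.integer(n)
  sample_population(cfg)
}

test_that("gating against its own null flags about one percent of
           cells", {
  set.seed(5)
  nullt <- data.frame(r1_ab_mean = rnorm(3000, 12, 1))
  g <- gate_positive(nullt, "r1_ab_mean", nullt)
  expect_lt(abs(g$positive_fraction - 0.01), 0.007)
  expect_equal(g$n, 3000)
})

test_that("cells entirely above the null are all gated positive", {
  nullt <- data.frame(r1_ab_mean = runif(500, 0, 10))
  treat <- data.frame(r1_ab_mean = runif(200, 20, 30))
  g <- gate_positive(treat, "r1_ab_mean", nullt)
  expect_equal(g$positive_fraction, 1)
  expect_error(gate_positive(treat[0, , drop = FALSE], "r1_ab_mean", nullt),
               "empty")
})

test_that("the gating threshold is monotone in the quantile and the
           positive fraction non-increasing in the threshold", {
  set.seed(6)
  nullt <- data.frame(r1_ab_mean = rlnorm(2000, 2, 0.5))
  treat <- data.frame(r1_ab_mean = rlnorm(2000, 3, 0.8))
  qs <- c(0.8, 0.9, 0.95, 0.99)
  gs <- lapply(qs, function(q)
    gate_positive(treat, "r1_ab_mean", nullt,
                  rule = list(type = "quantile", q = q)))
  thr <- vapply(gs, `[[`, 0, "threshold")
  pf <- vapply(gs, `[[`, 0, "positive_fraction")
  expect_true(all(diff(thr) >= 0))
  expect_true(all(diff(pf) <= 0))
})

test_that("top-percentile filtering selects exactly the largest values
           and nests", {
  tab <- data.frame(condition = "all", r1_ab_mean = sample(1:20))
  top5 <- top_percentile_filter(tab, "r1_ab_mean", 25)
  expect_setequal(top5$r1_ab_mean, 16:20)
  expect_identical(top_percentile_filter(tab, "r1_ab_mean", 100), tab)
  expect_error(top_percentile_filter(tab, "r1_ab_mean", 0), "top_pct")
  set.seed(7)
  tab2 <- data.frame(condition = rep(c("a", "b"), each = 200),
                     r1_ab_mean = rlnorm(400))
  ids <- lapply(c(5, 10, 25, 50), function(p)
    rownames(top_percentile_filter(tab2, "r1_ab_mean", p)))
  expect_true(all(ids[[1]] %in% ids[[2]]))
  expect_true(all(ids[[2]] %in% ids[[3]]))
  expect_true(all(ids[[3]] %in% ids[[4]]))
})

test_that("knockdown of a table against itself is exactly zero and
           errors are informative", {
  tab <- data.frame(r1_target_mean = rlnorm(100, 5, 1))
  kd <- estimate_knockdown(tab, tab, "r1_target_mean", n_boot = 50)
  expect_equal(kd$fraction, 0)
  expect_lte(kd$fraction, 1)
  neg <- data.frame(r1_target_mean = rep(-1, 10))
  expect_error(estimate_knockdown(tab, neg, "r1_target_mean", n_boot = 0),
               "control mean")
  expect_error(estimate_knockdown(tab, tab, "r1_target_mean",
                                  mode = "gated"),
               "gating")
})

test_that("gated knockdown exceeds bulk knockdown when non-permeabilized
           cells dilute the population", {
  gt_t <- big_truth("targeting", seed = 72)
  gt_c <- big_truth("NC", seed = 73)
  tt <- truth_table(gt_t, seed = 74)
  cc <- truth_table(gt_c, seed = 75)
  nullt <- truth_table(big_truth("NC", seed = 76, n = 1500, slo_dose = 0),
                       seed = 77)
  g <- gate_positive(tt, "r1_ab_mean", nullt)
  kb <- estimate_knockdown(tt, cc, "r1_target_mean", mode = "bulk",
                           n_boot = 0)
  kg <- estimate_knockdown(tt, cc, "r1_target_mean", mode = "gated",
                           gating = g, n_boot = 0)
  expect_gt(mean(!gt_t$permeabilized), 0.05)
  expect_gt(kg$fraction, kb$fraction)
  # bootstrap CI brackets the point estimate
  kci <- estimate_knockdown(tt, cc, "r1_target_mean", mode = "bulk",
                            n_boot = 200, seed = 3)
  expect_lt(kci$ci[1], kci$fraction)
  expect_gt(kci$ci[2], kci$fraction)
})

test_that("ratio features divide channels and flag non-positive
           denominators", {
  tab <- data.frame(num = c(8, 8, 8), den = c(2, 0, -1))
  out <- ratio_features(tab, list(c("num", "den")))
  expect_equal(out$ratio_num_over_den, c(4, NA, NA))
  expect_equal(out$ratio_num_over_den_undefined, c(FALSE, TRUE, TRUE))
  same <- ratio_features(tab, list(c("num", "num")))
  expect_true(all(same$ratio_num_over_num == 1))
  expect_error(ratio_features(tab, list(c("num", "missing"))), "missing")
})

test_that("separation effect sizes vanish for identical distributions
           and match the hand-computed two-point case", {
  set.seed(8)
  a <- data.frame(condition = "targeting", f = rnorm(2000),
                  ab = rlnorm(2000))
  b <- data.frame(condition = "NC", f = rnorm(2000), ab = rlnorm(2000))
  sc <- separation_curve(a, b, "f", filter_channel = "ab")
  expect_true(all(sc$effect < 0.15))
  expect_true(all(sc$reliable))
  # two-point distributions: SMD = |0.5 - 1.5| / sqrt((1/3 + 1/3)/2)
  t2 <- data.frame(condition = "targeting", f = rep(c(0, 1), 50),
                   ab = 1:100)
  c2 <- data.frame(condition = "NC", f = rep(c(1, 2), 50), ab = 1:100)
  v <- stats::var(rep(c(0, 1), 50))
  smd_hand <- 1 / sqrt((v + v) / 2)
  sc2 <- separation_curve(t2, c2, "f", filter_channel = "ab",
                          percentiles = c(100, 50))
  expect_equal(sc2$effect[1], smd_hand, tolerance = 1e-12)
  # sparse subsets are marked unreliable
  sc3 <- separation_curve(t2[1:30, ], c2[1:30, ], "f",
                          filter_channel = "ab",
                          percentiles = c(100, 10))
  expect_false(sc3$reliable[2])
})

test_that("Welch's statistic and degrees of freedom match the direct
           formulas", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  w <- compare_conditions(a, b)
  se2a <- stats::var(a) / 5; se2b <- stats::var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_hand <- (se2a + se2b)^2 /
    (se2a^2 / (5 - 1) + se2b^2 / (5 - 1))
  expect_equal(w$statistic, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  same <- compare_conditions(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_conditions(1, b), "n >= 2")
})

test_that("Welch test holds its nominal type-I error under the null", {
  set.seed(123)
  reps <- 10000
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(10); y <- rnorm(10)
    if (compare_conditions(x, y)$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / reps
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("many-to-one comparisons apply a family-wise adjustment", {
  set.seed(9)
  ref <- rnorm(20)
  gr <- list(g1 = rnorm(20), g2 = rnorm(20, 2), g3 = rnorm(20))
  res <- compare_many_to_one(gr, ref)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_lt(res$p_adjusted[res$group == "g2"], 0.05)
})
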