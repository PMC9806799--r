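# Projection, per-cell measurement and colocalization.

test_that("max projection matches the per-pixel brute-force maximum", {
  one <- array(matrix(1:64, 8), dim = c(1, 8, 8))
  expect_equal(max_project(one), matrix(1:64, 8))
  two <- array(0, dim = c(2, 4, 4)); two[2, , ] <- 7
  expect_equal(max_project(two), matrix(7, 4, 4))
  set.seed(1)
  st <- array(rnorm(4 * 8 * 8), dim = c(4, 8, 8))
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) oracle[r, c] <- max(st[, r, c])
  expect_equal(max_project(st), oracle)
  expect_equal(max_project(oracle), oracle)  # idempotent on 2D
  expect_error(max_project(array(0, dim = c(0, 4, 4))), "empty")
})

test_that("a constant channel over a small cell gives the exact mean and
           sum", {
  lab <- matrix(0L, 16, 16)
  lab[5, 3:12] <- 1L  # a 10-pixel cell
  lab <- trimcycif:::.label_objects(lab, "cell")
  iset <- fake_image_set(list(dapi = matrix(100, 16, 16)))
  tab <- measure_cells(lab, iset, guard_px = 0)
  expect_equal(tab$r1_dapi_mean, 100)
  expect_equal(tab$r1_dapi_sum, 1000)
})

test_that("noise-free pipeline measurements equal the generator truths
           exactly", {
  cfg <- noise_free(tiny_config(n_cells = 18, seed = 61))
  iset <- render_rounds(sample_population(cfg), cfg)
  gt <- attr(iset, "truth")
  nuc <- segment_nuclei(iset$rounds[[1]]$channels$dapi)
  cells <- expand_cells(nuc, cfg$cyto_radius_px)
  tab <- measure_cells(cells, iset, nuclei = nuc)
  m <- match_truth(tab, gt)
  # antibody is constant over the whole cell: exact under the guard
  expect_equal(tab$r1_ab_mean, gt$true_ab[m], tolerance = 1e-9)
  # target differs between nucleus and cytosol, so the guard reweights
  # the compartments by a few percent for cells with touching neighbors
  expect_equal(tab$r1_target_mean, gt$true_target[m], tolerance = 0.03)
  # sum = mean x measured area for every channel
  expect_equal(tab$r1_ab_sum, tab$r1_ab_mean * tab$area_measured_px,
               tolerance = 1e-9)
})

test_that("measured means track true means with unit slope under default
           noise", {
  cfg <- sim_config(n_cells = 500L, seed = 62, field_shape = c(900L, 900L))
  iset <- simulate_field(cfg)
  gt <- attr(iset, "truth")
  nuc <- segment_nuclei(iset$rounds[[1]]$channels$dapi)
  cells <- expand_cells(nuc, cfg$cyto_radius_px)
  tab <- measure_cells(cells, iset, nuclei = nuc)
  m <- match_truth(tab, gt)
  fit <- stats::lm(tab$r1_target_mean ~ gt$true_target[m])
  slope <- unname(stats::coef(fit)[2])
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("measurement is invariant to label renumbering up to row
           order", {
  lab <- matrix(0L, 20, 20)
  lab[3:6, 3:6] <- 1L
  lab[12:15, 12:16] <- 2L
  img <- matrix(seq_len(400), 20, 20)
  iset <- fake_image_set(list(dapi = img))
  t1 <- measure_cells(trimcycif:::.label_objects(lab, "cell"), iset,
                      guard_px = 0)
  swapped <- lab
  swapped[lab == 1L] <- 2L; swapped[lab == 2L] <- 1L
  t2 <- measure_cells(trimcycif:::.label_objects(swapped, "cell"), iset,
                      guard_px = 0)
  expect_equal(t1$r1_dapi_mean, rev(t2$r1_dapi_mean))
  expect_equal(sort(t1$r1_dapi_sum), sort(t2$r1_dapi_sum))
})

test_that("per-cell Pearson matches the closed form and its affine
           invariances", {
  lab <- matrix(0L, 8, 8)
  lab[2, 1:6] <- 1L
  cyt <- trimcycif:::.label_objects(lab, "cytosol")
  a <- matrix(0, 8, 8); b <- matrix(0, 8, 8)
  av <- c(1, 2, 3, 4, 5, 6); bv <- c(2, 1, 4, 3, 6, 5)
  a[2, 1:6] <- av; b[2, 1:6] <- bv
  # closed form evaluated directly
  r_hand <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  res <- colocalize(cyt, a, b)
  expect_equal(res$pearson[1], r_hand, tolerance = 1e-12)
  expect_equal(colocalize(cyt, a, a)$pearson[1], 1)
  expect_equal(colocalize(cyt, a, 2 * a + 5)$pearson[1], 1)
  expect_equal(colocalize(cyt, a, -a)$pearson[1], -1)
  expect_true(abs(res$pearson[1]) <= 1)
})

test_that("tiny or degenerate cytosols yield missing correlations", {
  lab <- matrix(0L, 8, 8)
  lab[2, 1:2] <- 1L          # 2 pixels: too few
  lab[5, 1:5] <- 2L          # 5 pixels, constant channel: no variance
  cyt <- trimcycif:::.label_objects(lab, "cytosol")
  a <- matrix(rnorm(64), 8, 8)
  b <- matrix(1, 8, 8)
  res <- colocalize(cyt, a, b)
  expect_true(is.na(res$pearson[1]))
  expect_true(is.na(res$pearson[2]))
})
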