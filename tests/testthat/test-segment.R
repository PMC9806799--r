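# Nuclear segmentation, constrained thickening and cytosol derivation.

disc_image <- function(shape, centers, radii, value = 1000) {
  img <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    rr <- outer(seq_len(shape[1]) - centers[i, 1],
                seq_len(shape[2]) - centers[i, 2],
                function(a, b) a^2 + b^2)
    img[rr <= radii[i]^2] <- value
  }
  img
}

test_that("a blank image yields zero objects with a warning", {
  expect_warning(lab <- segment_nuclei(matrix(0, 64, 64)),
                 "no objects")
  expect_equal(nrow(label_objects(lab)), 0)
})

test_that("well-separated noise-free nuclei are all found with high
           overlap", {
  cfg <- noise_free(sim_config(n_cells = 50, seed = 41,
                               field_shape = c(420L, 420L)))
  iset <- render_rounds(sample_population(cfg), cfg)
  lab <- segment_nuclei(iset$rounds[[1]]$channels$dapi)
  ev <- evaluate_segmentation(lab, attr(iset, "truth"), cfg)
  expect_equal(ev$n_pred, 50)
  expect_true(all(ev$iou >= 0.8))
})

test_that("touching nuclei split only when watershed splitting is on", {
  img <- disc_image(c(80, 80), rbind(c(40, 30), c(40, 52)), c(12, 12))
  lab_off <- segment_nuclei(img, list(threshold = 500,
                                      split_touching = FALSE))
  lab_on <- segment_nuclei(img, list(threshold = 500,
                                     split_touching = TRUE))
  expect_equal(nrow(label_objects(lab_off)), 1)
  expect_equal(nrow(label_objects(lab_on)), 2)
})

test_that("expansion by radius zero is the identity", {
  img <- disc_image(c(64, 64), rbind(c(32, 32)), 10)
  nuc <- segment_nuclei(img, list(threshold = 500))
  cells <- expand_cells(nuc, 0)
  expect_equal(unclass(cells)[, ], unclass(nuc)[, ], ignore_attr = TRUE)
})

test_that("disc expansion matches the brute-force distance oracle", {
  img <- disc_image(c(64, 64), rbind(c(32, 32)), 10)
  nuc <- segment_nuclei(img, list(threshold = 500))
  cells <- expand_cells(nuc, 5)
  # oracle: distance from every pixel to the nearest nucleus pixel
  nuc_px <- which(unclass(nuc) == 1L, arr.ind = TRUE)
  all_px <- as.matrix(expand.grid(r = 1:64, c = 1:64))
  d2 <- outer(all_px[, 1], nuc_px[, 1], "-")^2 +
    outer(all_px[, 2], nuc_px[, 2], "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  oracle <- matrix(0L, 64, 64)
  oracle[all_px[dmin <= 5, , drop = FALSE]] <- 1L
  expect_equal(unclass(cells)[, ], oracle[, ], ignore_attr = TRUE)
  # and the area is close to the rasterized radius-15 disc
  disc15 <- sum(outer((1:64) - 32, (1:64) - 32,
                      function(a, b) a^2 + b^2) <= 15^2)
  expect_lt(abs(sum(cells > 0) - disc15) / disc15, 0.05)
})

test_that("the boundary between two expanded equal nuclei lies on the
           perpendicular bisector", {
  img <- disc_image(c(100, 120), rbind(c(50, 45), c(50, 75)), c(8, 8))
  nuc <- segment_nuclei(img, list(threshold = 500))
  cells <- expand_cells(nuc, 20)
  lab <- unclass(cells)
  # brute-force nearest-center assignment over all covered pixels
  cov <- which(lab > 0L, arr.ind = TRUE)
  d1 <- (cov[, 1] - 50)^2 + (cov[, 2] - 45)^2
  d2 <- (cov[, 1] - 50)^2 + (cov[, 2] - 75)^2
  expected <- ifelse(d1 <= d2, 1L, 2L)
  got <- lab[cov]
  # pixels deeper than 1 px from the bisector must agree exactly
  clear <- abs(sqrt(d1) - sqrt(d2)) > 2
  expect_equal(got[clear], expected[clear])
})

test_that("cytosol is the exact set difference and empty cytosols are
           flagged", {
  img <- disc_image(c(64, 64), rbind(c(32, 32)), 10)
  nuc <- segment_nuclei(img, list(threshold = 500))
  cells <- expand_cells(nuc, 5)
  cyt <- derive_cytosol(cells, nuc)
  expect_equal(sum(cyt > 0), sum(cells > 0) - sum(nuc > 0))
  expect_true(all(unclass(cyt)[unclass(nuc) > 0] == 0))
  cyt0 <- derive_cytosol(expand_cells(nuc, 0), nuc)
  expect_true(all(label_objects(cyt0)$empty))
})

test_that("cell areas never shrink as the thickening radius grows", {
  cfg <- noise_free(tiny_config(n_cells = 12, seed = 51))
  iset <- render_rounds(sample_population(cfg), cfg)
  nuc <- segment_nuclei(iset$rounds[[1]]$channels$dapi)
  a5 <- label_objects(expand_cells(nuc, 5))$area_px
  a10 <- label_objects(expand_cells(nuc, 10))$area_px
  expect_true(all(a10 >= a5))
})

test_that("nucleus-cytosol areas partition the cell areas on a rendered
           field", {
  cfg <- noise_free(tiny_config(n_cells = 20, seed = 52))
  iset <- render_rounds(sample_population(cfg), cfg)
  nuc <- segment_nuclei(iset$rounds[[1]]$channels$dapi)
  cells <- expand_cells(nuc, 12)
  cyt <- derive_cytosol(cells, nuc)
  expect_equal(sum(label_objects(nuc)$area_px) +
                 sum(label_objects(cyt)$area_px),
               sum(label_objects(cells)$area_px))
})
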