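test_that("centroid sampling respects bounds, spacing, capacity and seed", {
  cents <- generate_centroids(30, c(64, 64), seed = 7)
  expect_equal(dim(cents), c(30, 2))
  expect_true(all(cents[, 1] >= 0 & cents[, 1] <= 63))
  expect_true(all(cents[, 2] >= 0 & cents[, 2] <= 63))
  expect_gte(min(dist(cents)), 2)
  expect_identical(cents, generate_centroids(30, c(64, 64), seed = 7))
  expect_false(identical(cents, generate_centroids(30, c(64, 64), seed = 8)))
  expect_error(generate_centroids(2000, c(32, 32), seed = 1), "capacity")
  expect_error(generate_centroids(2, c(64, 64), seed = 1))
})

test_that("tessellation assigns every pixel to its nearest centroid", {
  # quadrant symmetry for 4 corner-ish centroids
  cents <- cbind(c(8, 24, 8, 24), c(8, 8, 24, 24))
  lab <- tessellate(cents, c(32, 32))
  expect_setequal(unique(as.vector(lab)), 1:4)
  expect_equal(lab[1, 1], 1L)       # (u=0, v=0) nearest to centroid 1
  expect_equal(lab[32, 32], 4L)
  # 17 x 17 quadrant: boundary pixels tie and go to the lower cell id
  expect_equal(sum(lab == 1), 289)

  # brute-force nearest-centroid oracle on an irregular configuration
  cents <- random_coords(12, seed = 3, scale = 40)
  lab <- tessellate(cents, c(48, 48))
  for (r in seq(1, 48, by = 5)) for (cc in seq(1, 48, by = 5)) {
    d <- (cc - 1 - cents[, 1])^2 + (r - 1 - cents[, 2])^2
    expect_equal(lab[r, cc], which.min(d))
  }
  expect_error(tessellate(cents[c(1, 1, 2), ], c(48, 48)), "duplicate")
})

test_that("rendered channels follow the spatially varying linear model", {
  cents <- generate_centroids(40, c(64, 64), seed = 1)
  lab <- tessellate(cents, c(64, 64))
  score <- seq(-1, 1, length.out = 40)

  # noise-free constant fields: every cell mean equals beta0
  tr <- synthetic_truth(list(m = list(beta0 = field_spec("constant", 2),
                                      beta1 = field_spec("constant", 0))),
                        noise_sd = 0)
  ch <- render_channels(lab, cents, score, tr, seed = 5)
  means <- tapply(as.vector(ch$m), as.vector(lab), mean)
  expect_equal(unname(as.vector(means)), rep(2, 40), tolerance = 1e-12)

  # noise-free gradient slope: cell means reproduce beta0 + beta1 * x
  tr2 <- synthetic_truth(list(m = list(
    beta0 = field_spec("constant", 3),
    beta1 = field_spec("linear-gradient", 1))), noise_sd = 0)
  ch2 <- render_channels(lab, cents, score, tr2, seed = 5)
  b1 <- eval_field(tr2$markers$m$beta1, cents[, 1], cents[, 2], c(64, 64))
  means2 <- as.vector(tapply(as.vector(ch2$m), as.vector(lab), mean))
  expect_equal(means2, 3 + b1 * score, tolerance = 1e-10)

  # rendering is deterministic given the seed
  tr3 <- default_truth("m")
  expect_identical(render_channels(lab, cents, score, tr3, seed = 9),
                   render_channels(lab, cents, score, tr3, seed = 9))
})

test_that("cell-level noise SD is recovered empirically", {
  tr <- synthetic_truth(list(m = list(beta0 = field_spec("constant", 5),
                                      beta1 = field_spec("constant", 0))),
                        noise_sd = 0.1)
  sc <- simulate_cells(500, c(256, 256), truth = tr, seed = 11)
  resid_sd <- sd(sc$values[, "m"] - 5)
  expect_lt(abs(resid_sd - 0.1) / 0.1, 0.2)
})

test_that("simulate_sample is reproducible and internally consistent", {
  s1 <- simulate_sample(60, c(96, 96), marker_names = c("a", "b"), seed = 2)
  s2 <- simulate_sample(60, c(96, 96), marker_names = c("a", "b"), seed = 2)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$label_image, s2$label_image)
  # tessellation covers the raster with labels 1..n
  expect_setequal(unique(as.vector(s1$label_image)), 1:60)
  expect_equal(length(s1$morph_score), 60)
  expect_equal(mean(s1$morph_score), 0, tolerance = 1e-10)
  # with zero noise, OLS on a constant-beta sample recovers beta exactly
  tr <- synthetic_truth(list(m = list(beta0 = field_spec("constant", 2),
                                      beta1 = field_spec("constant", 1.5))),
                        noise_sd = 0)
  sc <- simulate_cells(80, c(128, 128), truth = tr, seed = 4)
  fit <- fit_ols(obs_table(sc$values[, "m"],
                           cbind(1, sc$morph_score), sc$centroids))
  expect_equal(unname(fit$betas), c(2, 1.5), tolerance = 1e-10)
})

test_that("samples round-trip through the TIFF + JSON directory layout", {
  s <- simulate_sample(25, c(64, 64), marker_names = "mk", seed = 6)
  dir <- withr::local_tempdir()
  write_sample(s, dir)
  loaded <- load_sample(dir)
  expect_identical(loaded$label_image, s$label_image)
  expect_equal(loaded$channels$mk, s$channels$mk, tolerance = 1e-6)
  expect_equal(loaded$meta$noise_sd, s$truth$noise_sd)
  # shape-mismatched channel is reported with the offending file
  bad <- matrix(0.5, 32, 32)
  tiff::writeTIFF(bad, file.path(dir, "mk.tif"), bits.per.sample = 32)
  expect_error(load_sample(dir), "mk.tif")
})
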