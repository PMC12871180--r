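test_that("gini matches the pairwise-difference oracle and its degenerate rules", {
  expect_equal(gini(c(5, 5, 5)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(0, 0, 0)), 0)
  set.seed(1)
  for (rep in 1:5) {
    v <- rgamma(20, shape = 0.7)
    expect_equal(gini(v), brute_gini(v), tolerance = 1e-12)
    expect_equal(gini(13 * v), gini(v), tolerance = 1e-12)  # scale invariance
  }
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("thresholds separate bimodal pixels and degrade gracefully", {
  expect_equal(cell_threshold(rep(0.3, 50)), Inf)           # constant: no positives
  set.seed(2)
  px <- c(rnorm(100, 0.1, 0.01), rnorm(100, 0.9, 0.01))
  thr <- cell_threshold(px)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  # two-valued input falls back to Otsu, threshold in (0, 1]
  thr2 <- cell_threshold(rep(c(0, 1), 25))
  expect_gt(thr2, 0); expect_lte(thr2, 1)
  # Otsu against exhaustive between-class-variance search
  v <- c(rnorm(60, 1, 0.2), rnorm(40, 4, 0.3))
  cand <- sort(unique(v)); cand <- (cand[-1] + cand[-length(cand)]) / 2
  bcv <- vapply(cand, function(t) {
    a <- v[v <= t]; b <- v[v > t]
    length(a) / length(v) * length(b) / length(v) * (mean(a) - mean(b))^2
  }, 0)
  expect_equal(otsu_threshold(v), cand[which.max(bcv)], tolerance = 1e-12)
  expect_error(cell_threshold(numeric(0)), "empty")
})

test_that("blob counting equals the flood-fill/graph oracle", {
  expect_equal(count_blobs(matrix(FALSE, 5, 5)), 0L)
  two <- matrix(FALSE, 8, 8)
  two[1:2, 1:2] <- TRUE
  two[6:7, 6:7] <- TRUE
  expect_equal(count_blobs(two), 2L)
  # diagonal touch merges under 8-connectivity
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(count_blobs(diag2), 1L)
  set.seed(3)
  for (rep in 1:8) {
    m <- matrix(runif(100) < 0.35, 10, 10)
    expect_equal(count_blobs(m), igraph_blob_count(m))
  }
})

test_that("intensity features match direct counting", {
  z <- intensity_features(rep(0, 30), 0.5, cbind(rep(0:5, 5), rep(0:4, each = 6)))
  expect_equal(z[["positive_fraction"]], 0)
  expect_equal(z[["integrated_density"]], 0)
  expect_equal(z[["blob_count"]], 0)

  ones <- intensity_features(rep(1, 20), 0.5, cbind(0:19, rep(0L, 20)))
  expect_equal(ones[["positive_fraction"]], 1)
  expect_equal(ones[["top5_mean"]], 1)
  expect_equal(ones[["integrated_density"]], 20)
  expect_equal(ones[["blob_count"]], 1)

  f <- intensity_features(c(0, 0, 0, 1), 0.5, cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  expect_equal(f[["positive_fraction"]], 0.25)
  expect_equal(f[["log1p_integrated_density"]], log1p(1))
  expect_equal(f[["sqrt_top5_mean"]], 1)

  # ordering invariants on a random nonnegative signal
  set.seed(4)
  px <- rexp(57)
  g <- intensity_features(px, median(px))
  expect_gte(g[["top5_mean"]], mean(px))
  expect_gte(g[["max_intensity"]], g[["top5_mean"]])
  # permutation invariance of order-free features
  h <- intensity_features(sample(px), median(px))
  expect_equal(g[setdiff(names(g), "blob_count")],
               h[setdiff(names(h), "blob_count")])
})

test_that("morphometrics agree with closed forms", {
  sq <- expand.grid(u = 0:9, v = 0:9)
  m <- morphometrics(as.matrix(sq))
  expect_equal(m[["area"]], 100)
  expect_equal(m[["extent"]], 1)
  expect_equal(m[["solidity"]], 1)
  expect_equal(m[["equivalent_diameter"]], sqrt(400 / pi), tolerance = 1e-10)
  expect_equal(m[["perimeter"]], 40)
  expect_lt(m[["eccentricity"]], 1e-8)

  line <- morphometrics(cbind(0:19, rep(0L, 20)))
  expect_gt(line[["eccentricity"]], 0.99)

  # rasterized disk of radius 5: nearly convex
  g <- as.matrix(expand.grid(u = -7:7, v = -7:7))
  disk <- g[g[, 1]^2 + g[, 2]^2 <= 25, ]
  d <- morphometrics(disk)
  expect_gte(d[["solidity"]], 0.95)
  expect_error(morphometrics(matrix(0, 0, 2)), "empty")
})

test_that("MorphScore is the signed first PC of z-scored morphometrics", {
  set.seed(5)
  a <- rnorm(50)
  # two perfectly correlated columns: PC1 explains everything
  ms <- morph_score(data.frame(area = a, perimeter = 2 * a + 3))
  expect_equal(ms$explained_variance_ratio, 1, tolerance = 1e-12)
  expect_equal(mean(ms$score), 0, tolerance = 1e-10)
  # sign convention: larger area scores higher
  expect_gt(cor(ms$score, a), 0)
  # 1-D case reduces to the z-score
  one <- morph_score(data.frame(area = a, junk = rep(1, 50)))
  expect_identical(one$dropped, "junk")
  expect_equal(one$score, as.vector(scale(a)), tolerance = 1e-10)
  expect_true(all(diff(one$score[order(a)]) > 0))
  # affine rescaling of a column does not change the score
  x2 <- rnorm(50)
  s1 <- morph_score(data.frame(area = a, ecc = x2))
  s2 <- morph_score(data.frame(area = a, ecc = 100 * x2 - 7))
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
  expect_error(morph_score(data.frame(area = a[1:2])), "at least 3")
  expect_error(morph_score(data.frame(area = rep(1, 10))), "constant")
})

test_that("cell tables carry marker feature blocks keyed by marker name", {
  s <- simulate_sample(40, c(96, 96), marker_names = c("cd8", "au"), seed = 12)
  cells <- build_cell_table(s$label_image, s$channels)
  expect_equal(nrow(cells), 40)
  expect_true(all(c("morph_score", "cd8__gini", "au__blob_count",
                    "cd8__log1p_integrated_density") %in% names(cells)))
  expect_true(all(cells$au__positive_fraction >= 0 &
                  cells$au__positive_fraction <= 1))
  # blob_count = 0 exactly when positive_fraction = 0
  expect_equal(cells$cd8__blob_count == 0, cells$cd8__positive_fraction == 0)
  # per-image thresholding is accepted and changes only intensity blocks
  cells2 <- build_cell_table(s$label_image, s$channels,
                             threshold_scope = "image")
  expect_equal(cells2$morph_score, cells$morph_score)
})
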