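test_that("the hand-computed threshold example is reproduced exactly", {
  X <- data.frame(x = c(0, 1, 2, 10))
  apd <- fit_apd(X, "euclidean", Z = 0.5)
  # pairwise {1,2,10,1,9,8}; mean 5.1667; retained {1,2,1}
  expect_equal(apd$d_mean, 4 / 3, tolerance = 1e-10)
  expect_equal(apd$d_sd, sd(c(1, 2, 1)), tolerance = 1e-10)
  expect_equal(apd$threshold, 1.6220, tolerance = 1e-4)
  expect_equal(apd$threshold, brute_apd_euclidean(X, 0.5),
               tolerance = 1e-10)
  # Z = 0 collapses the threshold to the retained mean
  expect_equal(fit_apd(X, "euclidean", Z = 0)$threshold, 4 / 3)
})

test_that("euclidean thresholds match the brute-force oracle on random
           sets", {
  set.seed(73)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    X <- as.data.frame(matrix(rnorm(n * 3), n))
    apd <- fit_apd(X, "euclidean", Z = 0.5)
    expect_equal(apd$threshold, brute_apd_euclidean(X, 0.5),
                 tolerance = 1e-10)
  }
})

test_that("degenerate distance sets are rejected with guidance", {
  # two rows: a single pairwise distance can never fall below its mean
  expect_error(fit_apd(data.frame(x = c(0, 1), y = c(0, 0)), "euclidean"),
               "at least 3")
  # equilateral set: all distances equal
  tri <- data.frame(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2))
  expect_error(fit_apd(tri, "euclidean"), "below their mean")
  # categorical columns are refused for the euclidean metric
  expect_error(fit_apd(data.frame(x = 1:5, g = letters[1:5]), "euclidean"),
               "numeric")
})

test_that("gower distances follow the closed forms", {
  # identical rows
  expect_equal(gower_distance(c(1, 2), c(1, 2), ranges = c(4, 4)), 0)
  # full-range numeric difference plus categorical mismatch, equal weights
  expect_equal(gower_distance(list(0, "a"), list(10, "b"),
                              weights = c(1, 1), ranges = c(10, NA),
                              categorical = c(FALSE, TRUE)), 1)
  # half range, categorical match
  expect_equal(gower_distance(list(0, "a"), list(5, "a"),
                              weights = c(1, 1), ranges = c(10, NA),
                              categorical = c(FALSE, TRUE)), 0.25)
  # zero range skips the feature with a warning
  expect_warning(
    d <- gower_distance(list(1, "a"), list(1, "b"), weights = c(1, 1),
                        ranges = c(0, NA), categorical = c(FALSE, TRUE)),
    "skipped")
  expect_equal(d, 1)
  expect_error(gower_distance(c(1), c(2), weights = 0, ranges = 1),
               "weights")
})

test_that("gower is a bounded symmetric dissimilarity on random mixed
           rows", {
  set.seed(79)
  rng <- c(5, 10, NA)
  cat_mask <- c(FALSE, FALSE, TRUE)
  for (rep in 1:30) {
    x <- list(runif(1, 0, 5), runif(1, 0, 10), sample(letters[1:3], 1))
    y <- list(runif(1, 0, 5), runif(1, 0, 10), sample(letters[1:3], 1))
    w <- runif(3, 0.1, 2)
    dxy <- gower_distance(x, y, w, rng, cat_mask)
    dyx <- gower_distance(y, x, w, rng, cat_mask)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_equal(gower_distance(x, x, w, rng, cat_mask), 0)
    expect_equal(dxy, brute_gower(x, y, w, rng, cat_mask),
                 tolerance = 1e-12)
  }
})

test_that("gower agrees with the cluster package on numeric-range data", {
  skip_if_not_installed("cluster")
  set.seed(83)
  df <- data.frame(a = runif(12, 0, 3), b = runif(12, -2, 2),
                   g = factor(sample(c("u", "v"), 12, TRUE)))
  daisy_d <- as.matrix(cluster::daisy(df, metric = "gower"))
  rng <- c(diff(range(df$a)), diff(range(df$b)), NA)
  for (i in 1:5) for (j in 6:10) {
    ours <- gower_distance(list(df$a[i], df$b[i], as.character(df$g[i])),
                           list(df$a[j], df$b[j], as.character(df$g[j])),
                           weights = c(1, 1, 1), ranges = rng,
                           categorical = c(FALSE, FALSE, TRUE))
    expect_equal(ours, daisy_d[i, j], tolerance = 1e-8)
  }
})

test_that("domain gating is inclusive at the threshold and flags far
           queries", {
  set.seed(89)
  X <- as.data.frame(matrix(rnorm(40 * 2), 40,
                            dimnames = list(NULL, c("u", "v"))))
  apd <- fit_apd(X, "euclidean", Z = 0.5)
  # a training row itself is in-domain
  res <- in_domain(X[3, , drop = FALSE], apd)
  expect_equal(res$nearest_distance, 0)
  expect_true(res$reliable)
  # every training row is in-domain against the others (statistically: all
  # rows of a compact Gaussian cloud)
  res_all <- in_domain(X, apd, exclude_self = TRUE)
  expect_gt(mean(res_all$reliable), 0.9)
  # far outside the cloud (10x the data range)
  far <- data.frame(u = 10 * diff(range(X$u)), v = 10 * diff(range(X$v)))
  expect_false(in_domain(far, apd)$reliable)
  # exactly at the threshold is reliable ("exceeds" reads strictly)
  q <- data.frame(u = X$u[1] + apd$threshold, v = X$v[1])
  nearest <- min(sqrt((X$u - q$u)^2 + (X$v - q$v)^2))
  if (abs(nearest - apd$threshold) < 1e-12)
    expect_true(in_domain(q, apd)$reliable)
  # missing feature errors by name
  expect_error(in_domain(data.frame(u = 0), apd), "v")
})

test_that("gower APD handles mixed types end to end", {
  set.seed(97)
  X <- data.frame(size = runif(30, 5, 20),
                  dose = exp(runif(30, 1, 5)),
                  coat = sample(0:3, 30, TRUE))
  apd <- fit_apd(X, "gower", Z = 0.5, weights = c(2, 3, 1),
                 categorical = c(FALSE, FALSE, TRUE))
  expect_gte(apd$threshold, apd$d_mean)
  expect_lte(apd$threshold, 1.5)
  expect_true(in_domain(X[5, , drop = FALSE], apd)$reliable)
  out <- data.frame(size = 400, dose = 1e5, coat = 9)
  expect_false(in_domain(out, apd)$reliable)
})
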