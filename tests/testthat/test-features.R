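test_that("derived axes follow the Euclidean-norm formulas", {
  f <- data.frame(ax = 3, ay = 4, az = 0, wx = 0, wy = 0, wz = 0)
  d <- derive_axes(f)
  expect_equal(d$a_norm, 5)
  expect_equal(d$a_norm_xy, 5)
  expect_equal(d$a_norm_xz, 3)
  expect_equal(d$a_norm_yz, 4)

  z <- derive_axes(data.frame(ax = 0, ay = 0, az = 0, wx = 0, wy = 0,
                              wz = 0))
  expect_true(all(z == 0))

  set.seed(4)
  r <- as.data.frame(matrix(rnorm(60), ncol = 6,
                            dimnames = list(NULL, c("ax", "ay", "az", "wx",
                                                    "wy", "wz"))))
  d <- derive_axes(r)
  expect_equal(d$a_norm, sqrt(r$ax^2 + r$ay^2 + r$az^2))
  expect_equal(d$w_norm, sqrt(r$wx^2 + r$wy^2 + r$wz^2))
  # invariants: a_norm dominates its planar projections; Pythagorean splits
  expect_true(all(d$a_norm >= pmax(d$a_norm_xy, d$a_norm_xz, d$a_norm_yz)))
  expect_equal(d$a_norm^2, d$a_norm_xy^2 + r$az^2)
  expect_equal(d$a_norm^2, d$a_norm_yz^2 + r$ax^2)
})

test_that("window features have the canonical 88-dimension layout", {
  rec <- random_recording(n = 64L)
  v <- extract_window_features(rec$samples)
  expect_length(v, 88L)
  expect_identical(names(v), feature_names())
  # statistic-major, axis-minor: first 11 are means, last 11 skewness
  expect_identical(names(v)[1:3], c("mean_ax", "mean_ay", "mean_az"))
  expect_identical(names(v)[88], "skewness_a_norm_xz")
  expect_true(all(is.finite(v)))
  expect_error(extract_window_features(rec$samples[1, ]), "at least 2")
})

test_that("each statistic matches an independent moment oracle", {
  rec <- random_recording(n = 160L, seed = 8L)
  v <- extract_window_features(rec$samples)
  chans <- cbind(rec$samples, derive_axes(rec$samples))
  axes <- c("ax", "ay", "az", "wx", "wy", "wz", "a_norm", "w_norm",
            "a_norm_xy", "a_norm_yz", "a_norm_xz")
  for (a in axes) {
    o <- oracle_stats(chans[[a]])
    for (s in names(o)) {
      expect_equal(v[[paste(s, a, sep = "_")]], o[[s]], tolerance = 1e-9,
                   label = paste(s, a))
    }
  }
})

test_that("constant windows hit the degenerate-moment conventions", {
  const <- data.frame(ax = rep(2, 10), ay = 0, az = 1, wx = 0, wy = 0,
                      wz = 0)
  v <- extract_window_features(const)
  expect_equal(v[["mean_ax"]], 2)
  expect_equal(v[["max_ax"]], 2)
  expect_equal(v[["min_ax"]], 2)
  expect_equal(v[["sd_ax"]], 0)
  expect_equal(v[["variance_ax"]], 0)
  expect_equal(v[["range_ax"]], 0)
  expect_equal(v[["kurtosis_ax"]], 0)  # zero-variance convention
  expect_equal(v[["skewness_ax"]], 0)
})

test_that("sip features append duration as the 89th feature", {
  rec <- random_recording(n = 128L)
  v <- extract_sip_features(rec$samples, 1.0)
  expect_length(v, 89L)
  expect_equal(unname(v[89]), 1.0)
  expect_identical(names(v)[89], "duration")
  # same frames, different durations: vectors differ only at f89
  v2 <- extract_sip_features(rec$samples, 2.0)
  expect_equal(v[1:88], v2[1:88])
  expect_equal(unname(v2[89]), 2.0)
  # first 88 entries shared with the detection features
  expect_equal(v[1:88], extract_window_features(rec$samples))
  expect_error(extract_sip_features(rec$samples, 0), "positive")
})

test_that("norm features are invariant under fixed rotations of the accelerometer", {
  set.seed(5)
  rec <- random_recording(n = 100L, seed = 5L)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  acc <- as.matrix(rec$samples[, c("ax", "ay", "az")]) %*% t(R)
  rot <- rec$samples
  rot[, c("ax", "ay", "az")] <- acc
  v1 <- extract_window_features(rec$samples)
  v2 <- extract_window_features(rot)
  anorm_feats <- paste(c("mean", "sd", "variance", "max", "min", "range",
                         "kurtosis", "skewness"), "a_norm", sep = "_")
  expect_equal(v1[anorm_feats], v2[anorm_feats], tolerance = 1e-9)
})

test_that("min <= mean <= max and range = max - min for every axis block", {
  rec <- random_recording(n = 77L, seed = 13L)
  v <- extract_window_features(rec$samples)
  for (a in c("ax", "wy", "a_norm", "a_norm_yz")) {
    expect_lte(v[[paste0("min_", a)]], v[[paste0("mean_", a)]])
    expect_lte(v[[paste0("mean_", a)]], v[[paste0("max_", a)]])
    expect_equal(v[[paste0("range_", a)]],
                 v[[paste0("max_", a)]] - v[[paste0("min_", a)]])
  }
})
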