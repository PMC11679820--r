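test_that("standard_frame_count is the minimum clip length", {
  df <- tibble::tibble(
    clip_id = c(rep("a", 5), rep("b", 3), rep("c", 9)),
    frame = c(1:5, 1:3, 1:9)
  )
  expect_identical(standard_frame_count(df), 3L)
  expect_error(standard_frame_count(df[0, ]), "empty")
})

test_that("subsample_frames keeps order, hits the target length, and is seeded", {
  ds <- tiny_dataset(clips_per_class = 2L, seed = 11L)
  n <- standard_frame_count(ds)
  sub <- subsample_frames(ds, n, seed = 4L)
  lens <- table(sub$clip_id)
  expect_true(all(lens == n))
  for (id in unique(sub$clip_id)) {
    fr <- sub$frame[sub$clip_id == id]
    expect_true(all(diff(fr) > 0)) # strictly increasing: ordered subsample
    expect_true(all(fr %in% ds$frame[ds$clip_id == id]))
  }
  # seeded determinism and seed sensitivity
  expect_identical(sub, subsample_frames(ds, n, seed = 4L))
  sub2 <- subsample_frames(ds, n, seed = 5L)
  expect_false(identical(sub$frame, sub2$frame))
  # n equal to the clip length is the identity; n above it errors
  one <- ds[ds$clip_id == ds$clip_id[1], ]
  expect_identical(subsample_frames(one, nrow(one)), one)
  expect_error(subsample_frames(one, nrow(one) + 1L), "exceeds clip length")
})

test_that("central_point matches the hand-computed torso midpoint construction", {
  # worked example: M1 = midpoint(p1, p2), M2 = midpoint(p3, p4), C = midpoint(M1, M2)
  p1 <- c(0.2, 0.1, 0.0) # left shoulder
  p2 <- c(0.6, 0.9, 0.2) # right hip
  p3 <- c(0.4, 0.1, -0.1) # right shoulder
  p4 <- c(0.3, 0.8, 0.1) # left hip
  clip <- torso_clip(p1, p2, p3, p4)
  cp <- central_point(clip)
  m1 <- (p1 + p2) / 2
  m2 <- (p3 + p4) / 2
  expect_equal(unlist(cp[1, c("cx", "cy", "cz")]),
    c(cx = (m1[1] + m2[1]) / 2, cy = (m1[2] + m2[2]) / 2, cz = (m1[3] + m2[3]) / 2),
    tolerance = 1e-12
  )
  # property: equals the mean of the four landmarks for random inputs
  set.seed(31)
  for (i in 1:20) {
    q <- replicate(4, stats::runif(3), simplify = FALSE)
    cp2 <- central_point(torso_clip(q[[1]], q[[2]], q[[3]], q[[4]]))
    expect_equal(unname(unlist(cp2[1, c("cx", "cy", "cz")])),
      (q[[1]] + q[[2]] + q[[3]] + q[[4]]) / 4,
      tolerance = 1e-12
    )
  }
})

test_that("speed_series matches hand-computed displacements and is translation invariant", {
  pos <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  expect_equal(speed_series(pos), c(0, 5, 12), tolerance = 1e-12)
  # first element is always zero; translation leaves speeds unchanged
  set.seed(17)
  r <- matrix(stats::rnorm(60), ncol = 3)
  s1 <- speed_series(r)
  s2 <- speed_series(sweep(r, 2, c(10, -3, 0.5), "+"))
  expect_identical(s1[1], 0)
  expect_equal(s1, s2, tolerance = 1e-10)
  # 2-D variant ignores the third column
  expect_equal(
    speed_series(r[, 1:2, drop = FALSE]),
    c(0, sqrt(rowSums(diff(r[, 1:2])^2))),
    tolerance = 1e-12
  )
})

test_that("min-max normalization matches its definition and attains [0, 1]", {
  ds <- tiny_dataset(clips_per_class = 1L, seed = 13L)
  feats <- build_features(ds, seed = 1L)
  params <- fit_minmax(feats)
  norm <- apply_minmax(feats, params)
  all_raw <- do.call(rbind, feats$features)
  all_norm <- do.call(rbind, norm$features)
  # brute-force oracle per channel
  for (j in seq_len(ncol(all_raw))) {
    x <- all_raw[, j]
    expected <- if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else rep(0, length(x))
    expect_equal(all_norm[, j], expected, tolerance = 1e-12)
  }
  # each non-constant channel attains 0 and 1
  nonconst <- params$x_max > params$x_min
  expect_true(all(abs(apply(all_norm[, nonconst], 2, min) - 0) < 1e-12))
  expect_true(all(abs(apply(all_norm[, nonconst], 2, max) - 1) < 1e-12))
})

test_that("normalization round-trips through the inverse affine map", {
  ds <- tiny_dataset(clips_per_class = 1L, seed = 14L)
  feats <- build_features(ds, seed = 2L)
  params <- fit_minmax(feats)
  norm <- apply_minmax(feats, params)
  rng <- params$x_max - params$x_min
  back <- sweep(sweep(norm$features[[1]], 2, rng, "*"), 2, params$x_min, "+")
  nonconst <- rng > 0
  expect_equal(back[, nonconst], feats$features[[1]][, nonconst], tolerance = 1e-10)
})

test_that("minmax_from_pairs recovers parameters from worked pairs", {
  x_min <- 0.2
  x_max <- 1.4
  raw <- c(0.5, 0.9, 1.1)
  normalized <- (raw - x_min) / (x_max - x_min)
  sol <- minmax_from_pairs(raw, normalized)
  expect_equal(sol$x_min, x_min, tolerance = 1e-10)
  expect_equal(sol$x_max, x_max, tolerance = 1e-10)
  expect_error(minmax_from_pairs(c(1, 1), c(0.2, 0.2)), "constant")
})

test_that("build_features yields the documented channel sets", {
  ds <- tiny_dataset(clips_per_class = 1L, seed = 15L)
  f <- build_features(ds, seed = 1L)
  expect_identical(ncol(f$features[[1]]), 102L) # 99 coords + 3 speeds
  expect_true(all(speed_columns() %in% feature_channels(f)))
  expect_true(all(vapply(f$features, nrow, integer(1)) == attr(f, "n_frames")))

  f2 <- build_features(ds, seed = 1L, include_visibility = TRUE, nose_speed = TRUE)
  expect_identical(ncol(f2$features[[1]]), 136L) # + 33 visibility + nose speed
  expect_true("Nose_Speed" %in% feature_channels(f2))

  # the positional channels stay raw by default
  clip1 <- ds[ds$clip_id == f$clip_id[1], ]
  sub <- subsample_frames(ds, attr(f, "n_frames"), seed = 1L)
  raw1 <- as.matrix(sub[sub$clip_id == f$clip_id[1], coord_cols()])
  expect_equal(unname(f$features[[1]][, coord_cols()]), unname(raw1), tolerance = 1e-12)
})

test_that("a static clip has (near-)zero speed channels after smoothing", {
  clip <- torso_clip(c(0.3, 0.2, 0), c(0.5, 0.8, 0), c(0.5, 0.2, 0), c(0.3, 0.8, 0))
  # stretch to 12 identical frames
  clip <- clip[rep(1, 12), ]
  clip$frame <- 1:12
  f <- build_features(clip)
  sp <- f$features[[1]][, speed_columns()]
  expect_lt(max(abs(sp)), 1e-8)
})

test_that("features_to_array stacks clips faithfully", {
  ds <- tiny_dataset(clips_per_class = 1L, seed = 16L)
  f <- build_features(ds, seed = 3L)
  arr <- features_to_array(f)
  expect_identical(dim(arr$x), c(7L, attr(f, "n_frames"), 102L))
  i <- 4L
  expect_equal(arr$x[i, , ], unname(f$features[[i]]), tolerance = 0, ignore_attr = TRUE)
  expect_identical(levels(arr$y), posture_classes())
  expect_identical(as.character(arr$y), f$label)
})
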