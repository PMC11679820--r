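# shared fixtures, built in code

# tiny but complete generated dataset (cached per test run)
tiny_dataset <- local({
  cache <- new.env()
  function(clips_per_class = 2L, seed = 1L, ...) {
    key <- paste(clips_per_class, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_dataset(
        generator_config(clips_per_class = clips_per_class, seed = seed, ...)
      )
    }
    cache[[key]]
  }
})

# handmade single-clip keypoint tibble with all landmarks at given rows
# of coordinates; coords: T x 3 matrix applied to every landmark, or a
# function(landmark_index) -> T x 3
manual_clip <- function(coords, clip_id = "falling_001", label = "falling") {
  T_len <- nrow(if (is.function(coords)) coords(0L) else coords)
  df <- tibble::tibble(
    clip_id = clip_id, frame = seq_len(T_len), label = label
  )
  for (i in 0:32) {
    m <- if (is.function(coords)) coords(i) else coords
    df[[sprintf("%d_x_(%s)", i, landmark_names()[i + 1])]] <- m[, 1]
    df[[sprintf("%d_y_(%s)", i, landmark_names()[i + 1])]] <- m[, 2]
    df[[sprintf("%d_z_(%s)", i, landmark_names()[i + 1])]] <- m[, 3]
  }
  df
}

# place the four torso landmarks explicitly (others zero)
torso_clip <- function(p1, p2, p3, p4) {
  # p1 = left shoulder (11), p2 = right hip (24), p3 = right shoulder (12), p4 = left hip (23)
  manual_clip(function(i) {
    v <- switch(as.character(i),
      "11" = p1, "24" = p2, "12" = p3, "23" = p4,
      c(0, 0, 0)
    )
    matrix(rep(v, 2), nrow = 2, byrow = TRUE)
  })
}

expect_rows_sum_to_one <- function(probs, tol = 1e-6) {
  expect_true(all(abs(rowSums(probs) - 1) < tol))
}

# handmade feature set: class-dependent mean + small noise
make_feats <- function(n_per_class, T_len = 6L, D = 4L,
                       classes = c("falling", "lie"), sep = 2, seed = 1L) {
  set.seed(seed)
  chan <- paste0("ch", seq_len(D))
  rows <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      m <- matrix(sep * (ci - 1) + 0.3 * stats::rnorm(T_len * D), T_len, D)
      colnames(m) <- chan
      rows[[k]] <- tibble::tibble(
        clip_id = sprintf("%s_%03d", classes[ci], j),
        label = classes[ci], features = list(m)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "channel_names") <- chan
  attr(out, "n_frames") <- T_len
  out
}
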