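#' Standard frame count of a dataset
#'
#' The sequence length every clip is reduced to: the minimum frame count
#' over all clips, so no clip ever needs upsampling.
#'
#' @param df Keypoint tibble.
#' @return Integer minimum clip length.
#' @export
standard_frame_count <- function(df) {
  if (is.null(df) || nrow(df) == 0L) stop("empty dataset")
  min(table(df$clip_id))
}

#' Subsample every clip to a fixed frame count
#'
#' Draws, independently per clip, a uniformly random size-`n` subset of
#' its frames without replacement and emits the kept frames in their
#' original temporal order, preserving the action sequence.
#'
#' @param df Keypoint tibble.
#' @param n Target frame count (2 <= n <= every clip's length).
#' @param seed Optional integer; when given the draw is deterministic and
#'   the caller's RNG state is untouched.
#' @return Keypoint tibble with exactly `n` frames per clip.
#' @export
subsample_frames <- function(df, n, seed = NULL) {
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, subsample_frames(df, n, seed = NULL)))
  }
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  idx_by_clip <- split(seq_len(nrow(df)), factor(df$clip_id, levels = unique(df$clip_id)))
  keep <- unlist(lapply(idx_by_clip, function(ix) {
    T_len <- length(ix)
    if (n > T_len) {
      stop(sprintf(
        "n = %d exceeds clip length %d for clip '%s' (upsampling is never performed)",
        n, T_len, df$clip_id[ix[1]]
      ))
    }
    if (n == T_len) ix else ix[sort(sample.int(T_len, n))]
  }), use.names = FALSE)
  df[keep, ]
}

#' Central body point of each frame
#'
#' The torso-center proxy: the midpoint M1 of the left shoulder and
#' right hip, the midpoint M2 of the right shoulder and left hip, and
#' their midpoint C — algebraically the mean of the four landmarks,
#' computed per axis.
#'
#' @param df Keypoint tibble (or any frame rows with the shoulder/hip
#'   coordinate columns).
#' @return Tibble with `clip_id`, `frame` and the central point `cx`,
#'   `cy`, `cz`.
#' @export
central_point <- function(df) {
  p1 <- landmark_matrix(df, .LM$left_shoulder)
  p2 <- landmark_matrix(df, .LM$right_hip)
  p3 <- landmark_matrix(df, .LM$right_shoulder)
  p4 <- landmark_matrix(df, .LM$left_hip)
  m1 <- (p1 + p2) / 2
  m2 <- (p3 + p4) / 2
  C <- (m1 + m2) / 2
  tibble::tibble(
    clip_id = df$clip_id, frame = df$frame,
    cx = C[, 1], cy = C[, 2], cz = C[, 3]
  )
}

#' Instantaneous speed of a tracked point
#'
#' Euclidean distance between consecutive positions; the first element
#' is 0 (no movement is assumed at the initial state).
#'
#' @param positions Numeric T x d matrix (rows ordered in time) or a
#'   numeric vector for one-dimensional positions.
#' @return Numeric vector of length T, first element 0, all elements
#'   non-negative.
#' @export
speed_series <- function(positions) {
  P <- if (is.null(dim(positions))) matrix(positions, ncol = 1L) else as.matrix(positions)
  if (nrow(P) < 1L) stop("positions must have length >= 1")
  if (nrow(P) == 1L) {
    return(0)
  }
  d <- P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  c(0, sqrt(rowSums(d * d)))
}

#' Build per-clip feature matrices
#'
#' The feature pipeline: subsample every clip to a common frame count,
#' Kalman-smooth the tracked landmark trajectories (shoulders and hips —
#' from which the central point is formed — plus nose and both knees),
#' compute instantaneous speeds of the tracked points from the smoothed
#' trajectories, and assemble the channel layout: 33 x (x, y, z) raw
#' coordinates (optionally followed by 33 visibility channels) and the
#' speed channels (central body, left knee, right knee, optionally nose).
#'
#' @param df Keypoint tibble.
#' @param n_frames Target sequence length; default
#'   [standard_frame_count()] of `df`.
#' @param kalman [kalman_params()] used per axis for smoothing.
#' @param seed Optional integer controlling the subsampling draw.
#' @param include_visibility Emit the 33 visibility channels?
#' @param nose_speed Emit the nose (head) speed channel in addition to
#'   the three-column default?
#' @param smooth_all Replace the positional channels with their smoothed
#'   versions too (default: only the tracked points feeding the speed
#'   channels are smoothed, and raw coordinates remain the positional
#'   channels)?
#' @param dims_2d Compute speeds from (x, y) displacements only,
#'   ignoring the noisier depth estimate?
#' @return A nested tibble (`clip_id`, `label`, `features`) where
#'   `features` holds one T x D matrix per clip; the channel names are
#'   the matrix column names and in `attr(, "channel_names")`.
#' @export
build_features <- function(df, n_frames = NULL, kalman = kalman_params(),
                           seed = NULL, include_visibility = FALSE,
                           nose_speed = FALSE, smooth_all = FALSE,
                           dims_2d = FALSE) {
  if (is.null(n_frames)) n_frames <- standard_frame_count(df)
  df <- subsample_frames(df, n_frames, seed = seed)

  vis_cols <- coord_cols("v")
  if (include_visibility && !all(vis_cols %in% names(df))) {
    stop("include_visibility = TRUE but the dataset has no visibility columns")
  }
  sp_names <- speed_columns(nose = nose_speed)
  channels <- c(coord_cols(), if (include_visibility) vis_cols, sp_names)
  sdim <- if (dims_2d) 1:2 else 1:3

  by_clip <- split(
    seq_len(nrow(df)),
    factor(df$clip_id, levels = unique(df$clip_id))
  )
  labels <- vapply(by_clip, function(ix) df$label[ix[1]], character(1))

  feats <- lapply(by_clip, function(ix) {
    clip <- df[ix, ]
    tracked <- c(
      .LM$left_shoulder, .LM$right_shoulder, .LM$left_hip, .LM$right_hip,
      .LM$nose, .LM$left_knee, .LM$right_knee
    )
    sm <- lapply(tracked, function(i) kalman_smooth(landmark_matrix(clip, i), kalman))
    names(sm) <- as.character(tracked)
    cp <- (sm[[as.character(.LM$left_shoulder)]] + sm[[as.character(.LM$right_hip)]] +
      sm[[as.character(.LM$right_shoulder)]] + sm[[as.character(.LM$left_hip)]]) / 4

    speeds <- cbind(
      speed_series(cp[, sdim, drop = FALSE]),
      speed_series(sm[[as.character(.LM$left_knee)]][, sdim, drop = FALSE]),
      speed_series(sm[[as.character(.LM$right_knee)]][, sdim, drop = FALSE])
    )
    if (nose_speed) {
      speeds <- cbind(speeds, speed_series(sm[[as.character(.LM$nose)]][, sdim, drop = FALSE]))
    }

    pos <- as.matrix(clip[, coord_cols()])
    if (smooth_all) {
      for (i in 0:32) {
        cols <- c(lm_col(i, "x"), lm_col(i, "y"), lm_col(i, "z"))
        pos[, cols] <- kalman_smooth(pos[, cols, drop = FALSE], kalman)
      }
    }
    m <- cbind(
      pos,
      if (include_visibility) as.matrix(clip[, vis_cols]),
      speeds
    )
    colnames(m) <- channels
    m
  })

  out <- tibble::tibble(
    clip_id = names(by_clip),
    label = unname(labels),
    features = unname(feats)
  )
  attr(out, "channel_names") <- channels
  attr(out, "n_frames") <- as.integer(n_frames)
  out
}

#' Channel names of a feature set
#'
#' @param features Nested feature tibble from [build_features()].
#' @return Character vector of channel names.
#' @export
feature_channels <- function(features) {
  ch <- attr(features, "channel_names")
  if (is.null(ch)) ch <- colnames(features$features[[1]])
  ch
}

#' Fit min-max normalization parameters
#'
#' Per-channel minimum and maximum over every frame of every clip in the
#' (training) feature set. Fit on the training split only and apply the
#' same parameters to validation/test data to avoid leakage.
#'
#' @param features Nested feature tibble from [build_features()].
#' @return Tibble (`channel`, `x_min`, `x_max`), one row per channel.
#' @export
fit_minmax <- function(features) {
  if (is.null(features) || nrow(features) == 0L) stop("empty feature set")
  all_mat <- do.call(rbind, features$features)
  tibble::tibble(
    channel = colnames(all_mat),
    x_min = apply(all_mat, 2L, min),
    x_max = apply(all_mat, 2L, max)
  )
}

#' Apply min-max normalization
#'
#' Maps every value through `(x - x_min) / (x_max - x_min)` with the
#' fitted per-channel parameters. Constant channels (`x_max == x_min`)
#' map to 0. Values outside the fitted range are NOT clipped and fall
#' outside \[0, 1\]; this happens when the parameters come from a
#' different (training) split.
#'
#' @param features Nested feature tibble.
#' @param params Tibble from [fit_minmax()].
#' @return Feature tibble of the same shape with normalized matrices.
#' @export
apply_minmax <- function(features, params) {
  ch <- feature_channels(features)
  if (!identical(sort(ch), sort(params$channel))) {
    stop("channel mismatch between features and normalization parameters")
  }
  p <- params[match(ch, params$channel), ]
  rng <- p$x_max - p$x_min
  scale <- ifelse(rng > 0, 1 / rng, 0)
  features$features <- lapply(features$features, function(m) {
    sweep(sweep(m, 2L, p$x_min, "-"), 2L, scale, "*")
  })
  features
}

#' Recover min-max parameters from worked (raw, normalized) pairs
#'
#' Solves the affine normalization map from known corresponding raw and
#' normalized values of one channel: with two (or more) distinct pairs
#' the slope `1/(x_max - x_min)` and intercept determine `x_min` and
#' `x_max` exactly. Useful for checking published worked examples of the
#' normalization and for inverting a normalization whose parameters were
#' not stored.
#'
#' @param raw,normalized Numeric vectors (length >= 2) of corresponding
#'   values; with more than two pairs a least-squares line is used.
#' @return One-row tibble (`x_min`, `x_max`).
#' @export
minmax_from_pairs <- function(raw, normalized) {
  stopifnot(length(raw) == length(normalized), length(raw) >= 2L)
  if (max(raw) - min(raw) <= 0) stop("raw values must not be constant")
  fit <- stats::lm.fit(cbind(1, raw), normalized)
  b <- fit$coefficients[1]
  a <- fit$coefficients[2]
  if (!is.finite(a) || a == 0) stop("degenerate pair set: zero slope")
  x_min <- -b / a
  tibble::tibble(x_min = unname(x_min), x_max = unname(x_min + 1 / a))
}

#' Stack a feature set into an array
#'
#' @param features Nested feature tibble (all clips same length).
#' @return List with `x` (N x T x D array), `y` (factor of labels in the
#'   seven-class vocabulary) and `channels`.
#' @export
features_to_array <- function(features) {
  Ts <- vapply(features$features, nrow, integer(1))
  if (length(unique(Ts)) != 1L) stop("clips have unequal frame counts; subsample first")
  D <- ncol(features$features[[1]])
  x <- array(0, dim = c(nrow(features), Ts[1], D))
  for (i in seq_len(nrow(features))) x[i, , ] <- features$features[[i]]
  list(
    x = x,
    y = factor(features$label, levels = posture_classes()),
    channels = feature_channels(features),
    clip_id = features$clip_id
  )
}
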