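#' Motion template for one posture class
#'
#' A template is a parametric description of how the torso center and
#' body inclination evolve over a clip: start/end height (image y, which
#' grows downward, so descent increases y), start/end inclination (0 =
#' upright, pi/2 = horizontal), a logistic transition with a midpoint and
#' sharpness, optional lateral drift, and a duration range in frames.
#' The nominal peak central-point speed implied by the template
#' (`peak_speed_scale`, image units per frame) is derived from these
#' fields, not set directly: it is the total central-point displacement
#' times the logistic's maximal slope at the midrange duration.
#'
#' @param label Posture class name.
#' @param duration_range Integer interval of clip lengths (frames).
#' @param y_start,y_end Torso-center image-y at clip start/end.
#' @param incl_start,incl_end Inclination (radians) at start/end.
#' @param midpoint Transition midpoint as a fraction of clip time.
#' @param sharpness Logistic steepness; larger = faster transition.
#' @param x_drift Total lateral drift over the clip (image units).
#' @return A `motion_template` list.
#' @export
motion_template <- function(label, duration_range, y_start, y_end,
                            incl_start, incl_end,
                            midpoint = 0.5, sharpness = 6, x_drift = 0) {
  stopifnot(
    length(duration_range) == 2L, duration_range[1] >= 2L,
    duration_range[2] >= duration_range[1], sharpness > 0
  )
  displacement <- sqrt(x_drift^2 + (y_end - y_start)^2)
  t_mid <- mean(duration_range)
  peak <- if (displacement > 0) displacement * sharpness / (4 * (t_mid - 1)) else 0
  structure(
    list(
      label = label, duration_range = as.integer(duration_range),
      y_start = y_start, y_end = y_end,
      incl_start = incl_start, incl_end = incl_end,
      midpoint = midpoint, sharpness = sharpness, x_drift = x_drift,
      peak_speed_scale = peak
    ),
    class = "motion_template"
  )
}

#' Default motion templates for the seven posture classes
#'
#' Falls are short, sharp descents with rotation to horizontal; `lie` is
#' the same descent stretched over roughly twice the duration;
#' `sit_down`/`stand_up` are gentle partial descents/ascents; `standing`
#' and `sleeping` are static (upright and horizontal respectively); and
#' `lie_down` is a static horizontal posture with a slow lateral drift.
#'
#' @return Named list of [motion_template()] objects, one per class.
#' @export
default_templates <- function() {
  list(
    falling = motion_template("falling", c(35L, 55L), 0.42, 0.78, 0, 1.45,
      midpoint = 0.5, sharpness = 28
    ),
    lie = motion_template("lie", c(45L, 70L), 0.42, 0.78, 0, 1.45, sharpness = 6),
    lie_down = motion_template("lie_down", c(45L, 70L), 0.78, 0.78, 1.2, 1.2,
      x_drift = 0.05
    ),
    sit_down = motion_template("sit_down", c(40L, 60L), 0.42, 0.60, 0, 0.35,
      sharpness = 6
    ),
    sleeping = motion_template("sleeping", c(45L, 70L), 0.78, 0.78, 1.45, 1.45),
    standing = motion_template("standing", c(35L, 55L), 0.42, 0.42, 0, 0),
    stand_up = motion_template("stand_up", c(40L, 60L), 0.60, 0.42, 0.35, 0,
      sharpness = 6
    )
  )
}

#' Generator configuration
#'
#' @param clips_per_class Clips generated per posture class (default 100,
#'   matching a balanced 100-clip-per-class collection design).
#' @param templates Named list of [motion_template()]s covering every class.
#' @param coordinate_noise_sd Additive Gaussian observation noise on each
#'   landmark coordinate (image-normalized units). The default 0.005
#'   keeps static-posture jitter an order of magnitude below fall-peak
#'   speeds while giving the Kalman filter measurable work.
#' @param occlusion_rate Per-frame-per-landmark probability of a
#'   low-visibility occlusion (visibility < 0.5 and 5x noise).
#' @param scale Torso half-length in image units.
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of this configuration.
#' @return A `generator_config` list.
#' @export
generator_config <- function(clips_per_class = 100L,
                             templates = default_templates(),
                             coordinate_noise_sd = 0.005,
                             occlusion_rate = 0.02,
                             scale = 0.12,
                             seed = 42L) {
  stopifnot(
    clips_per_class >= 1L, coordinate_noise_sd >= 0,
    occlusion_rate >= 0, occlusion_rate < 1, scale > 0
  )
  missing <- setdiff(posture_classes(), names(templates))
  if (length(missing) > 0L) {
    stop("templates missing for class(es): ", paste(missing, collapse = ", "))
  }
  ps <- vapply(templates, function(tp) tp$peak_speed_scale, numeric(1))
  if (!(ps[["falling"]] > ps[["sit_down"]] && ps[["falling"]] > ps[["lie"]])) {
    stop("falling template must have strictly the largest peak_speed_scale among transitions")
  }
  structure(
    list(
      clips_per_class = as.integer(clips_per_class), templates = templates,
      coordinate_noise_sd = coordinate_noise_sd,
      occlusion_rate = occlusion_rate, scale = scale, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# articulated offset table: (along-axis, lateral, depth) in torso
# half-length units; shoulders average to the torso top (a = 1) and hips
# to the torso bottom (a = -1) so their grand midpoint is the center.
skeleton_offsets <- function() {
  m <- rbind(
    Nose = c(1.45, 0.00, -0.10),
    Left_Eye_Inner = c(1.54, 0.06, -0.12), Left_Eye = c(1.56, 0.10, -0.12),
    Left_Eye_Outer = c(1.58, 0.14, -0.12),
    Right_Eye_Inner = c(1.54, -0.06, -0.12), Right_Eye = c(1.56, -0.10, -0.12),
    Right_Eye_Outer = c(1.58, -0.14, -0.12),
    Left_Ear = c(1.50, 0.22, -0.05), Right_Ear = c(1.50, -0.22, -0.05),
    Mouth_Left = c(1.38, 0.07, -0.10), Mouth_Right = c(1.38, -0.07, -0.10),
    Left_Shoulder = c(1.00, 0.55, 0.02), Right_Shoulder = c(1.00, -0.55, -0.02),
    Left_Elbow = c(0.40, 0.72, 0.05), Right_Elbow = c(0.40, -0.72, -0.05),
    Left_Wrist = c(-0.15, 0.80, 0.06), Right_Wrist = c(-0.15, -0.80, -0.06),
    Left_Pinky = c(-0.32, 0.84, 0.06), Right_Pinky = c(-0.32, -0.84, -0.06),
    Left_Index = c(-0.34, 0.82, 0.05), Right_Index = c(-0.34, -0.82, -0.05),
    Left_Thumb = c(-0.30, 0.78, 0.04), Right_Thumb = c(-0.30, -0.78, -0.04),
    Left_Hip = c(-1.00, 0.35, 0.01), Right_Hip = c(-1.00, -0.35, -0.01),
    Left_Knee = c(-2.10, 0.36, 0.03), Right_Knee = c(-2.10, -0.36, -0.03),
    Left_Ankle = c(-3.10, 0.36, 0.05), Right_Ankle = c(-3.10, -0.36, -0.05),
    Left_Heel = c(-3.25, 0.34, 0.08), Right_Heel = c(-3.25, -0.34, -0.08),
    Left_Foot_Index = c(-3.35, 0.42, -0.05), Right_Foot_Index = c(-3.35, -0.42, 0.05)
  )
  stopifnot(identical(rownames(m), landmark_names()))
  m
}

#' Place all 33 landmarks for one pose state
#'
#' Realizes a stick figure from a torso center, a body inclination and a
#' torso half-length, using a fixed articulated offset table. At
#' inclination 0 the body is upright (nose above hips; image y grows
#' downward); at pi/2 it is horizontal.
#'
#' @param torso_center Numeric length-3 (x, y, z) in image-normalized units.
#' @param inclination Radians from upright.
#' @param scale Torso half-length (> 0) in image units.
#' @return A 33 x 3 matrix (rows = landmarks in index order, columns x/y/z).
#' @export
skeleton_from_pose_state <- function(torso_center, inclination, scale) {
  stopifnot(length(torso_center) == 3L, scale > 0)
  off <- skeleton_offsets()
  d_axis <- c(sin(inclination), -cos(inclination)) # toward the head
  d_lat <- c(cos(inclination), sin(inclination)) # subject's left
  x <- torso_center[1] + scale * (off[, 1] * d_axis[1] + off[, 2] * d_lat[1])
  y <- torso_center[2] + scale * (off[, 1] * d_axis[2] + off[, 2] * d_lat[2])
  z <- torso_center[3] + scale * off[, 3]
  out <- cbind(x = x, y = y, z = z)
  rownames(out) <- landmark_names()
  out
}

# logistic transition rescaled to traverse exactly [0, 1] over the clip
transition_curve <- function(t_norm, midpoint, sharpness) {
  s <- stats::plogis(sharpness * (t_norm - midpoint))
  s0 <- stats::plogis(sharpness * (0 - midpoint))
  s1 <- stats::plogis(sharpness * (1 - midpoint))
  if (s1 - s0 < .Machine$double.eps) {
    return(rep(0, length(t_norm)))
  }
  (s - s0) / (s1 - s0)
}

#' Generate one labeled clip
#'
#' Draws a clip length from the class template's duration range, follows
#' the template's torso trajectory, realizes each frame as a 33-landmark
#' stick figure, and adds Gaussian observation noise plus occasional
#' low-visibility occlusions (occluded landmarks get visibility < 0.5 and
#' inflated noise).
#'
#' @param label Posture class.
#' @param cfg A [generator_config()].
#' @param clip_id Clip identifier attached to the rows.
#' @param seed Optional integer; when given, the clip is a deterministic
#'   function of (label, cfg, seed) and the caller's RNG state is left
#'   untouched. When `NULL`, the current RNG stream is consumed.
#' @return Keypoint tibble for one clip (frames 1..T, coordinate,
#'   visibility and speed columns, label attached).
#' @export
generate_clip <- function(label, cfg = generator_config(), clip_id = label, seed = NULL) {
  if (!label %in% posture_classes()) stop("unknown label: ", label)
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, generate_clip(label, cfg, clip_id, seed = NULL)))
  }
  tp <- cfg$templates[[label]]
  T_len <- if (tp$duration_range[1] == tp$duration_range[2]) {
    tp$duration_range[1]
  } else {
    sample(seq(tp$duration_range[1], tp$duration_range[2]), 1L)
  }
  t_norm <- seq(0, 1, length.out = T_len)
  s <- transition_curve(t_norm, tp$midpoint, tp$sharpness)
  x0 <- stats::runif(1, 0.35, 0.65)
  z0 <- stats::runif(1, -0.05, 0.05)
  cx <- x0 + tp$x_drift * t_norm
  cy <- tp$y_start + (tp$y_end - tp$y_start) * s
  incl <- tp$incl_start + (tp$incl_end - tp$incl_start) * s

  coords <- matrix(0, nrow = T_len, ncol = 99L)
  vis <- matrix(1, nrow = T_len, ncol = 33L)
  for (t in seq_len(T_len)) {
    sk <- skeleton_from_pose_state(c(cx[t], cy[t], z0), incl[t], cfg$scale)
    if (cfg$occlusion_rate > 0 || cfg$coordinate_noise_sd > 0) {
      occ <- if (cfg$occlusion_rate > 0) {
        stats::runif(33) < cfg$occlusion_rate
      } else {
        rep(FALSE, 33)
      }
      sd_lm <- cfg$coordinate_noise_sd * ifelse(occ, 5, 1)
      if (cfg$coordinate_noise_sd > 0) {
        sk <- sk + matrix(stats::rnorm(99, sd = rep(sd_lm, 3L)), ncol = 3L)
      }
      vis[t, ] <- ifelse(occ, stats::runif(33, 0.05, 0.45), 1)
    }
    coords[t, ] <- as.numeric(t(sk)) # landmark-major x,y,z triples
  }

  df <- tibble::as_tibble(as.data.frame(coords), .name_repair = "minimal")
  names(df) <- coord_cols()
  vdf <- tibble::as_tibble(as.data.frame(vis), .name_repair = "minimal")
  names(vdf) <- coord_cols("v")
  out <- dplyr::bind_cols(
    tibble::tibble(clip_id = clip_id, frame = seq_len(T_len), label = label),
    df, vdf
  )
  # precomputed raw-coordinate speed columns, mirroring the export layout
  cp <- central_point(out)
  out$Central_Body_Speed <- speed_series(as.matrix(cp[, c("cx", "cy", "cz")]))
  out$Left_Knee_Speed <- speed_series(landmark_matrix(out, .LM$left_knee))
  out$Right_Knee_Speed <- speed_series(landmark_matrix(out, .LM$right_knee))
  out
}

#' Generate a full labeled dataset
#'
#' Produces `clips_per_class` clips for each of the seven posture
#' classes, shuffles clip order with the configuration seed, and assigns
#' canonical clip ids `"<label>_<ordinal>"` in final order. The result is
#' a deterministic function of the configuration.
#'
#' @param cfg A [generator_config()].
#' @return Keypoint tibble of 7 x `clips_per_class` clips with variable
#'   clip lengths.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  with_preserved_seed(cfg$seed, {
    classes <- posture_classes()
    clips <- vector("list", length(classes) * cfg$clips_per_class)
    k <- 0L
    for (cl in classes) {
      for (i in seq_len(cfg$clips_per_class)) {
        k <- k + 1L
        clips[[k]] <- generate_clip(cl, cfg, clip_id = sprintf("tmp_%06d", k))
      }
    }
    clips <- clips[sample.int(length(clips))]
    counter <- stats::setNames(integer(length(classes)), classes)
    for (j in seq_along(clips)) {
      cl <- clips[[j]]$label[1]
      counter[cl] <- counter[cl] + 1L
      clips[[j]]$clip_id <- sprintf("%s_%03d", cl, counter[cl])
    }
    dplyr::bind_rows(clips)
  })
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# T x 3 coordinate matrix of one landmark from a keypoint tibble
landmark_matrix <- function(df, index) {
  as.matrix(df[, c(lm_col(index, "x"), lm_col(index, "y"), lm_col(index, "z"))])
}
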