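#' The 33-landmark pose schema
#'
#' Landmark names for the MediaPipe Pose topology, ordered by landmark
#' index 0--32. These names appear (parenthesised) in the CSV column
#' headers of keypoint tables, e.g. `0_x_(Nose)`.
#'
#' @return Character vector of length 33.
#' @export
#' @examples
#' landmark_names()[c(1, 12, 26)]
landmark_names <- function() {
  c(
    "Nose",
    "Left_Eye_Inner", "Left_Eye", "Left_Eye_Outer",
    "Right_Eye_Inner", "Right_Eye", "Right_Eye_Outer",
    "Left_Ear", "Right_Ear",
    "Mouth_Left", "Mouth_Right",
    "Left_Shoulder", "Right_Shoulder",
    "Left_Elbow", "Right_Elbow",
    "Left_Wrist", "Right_Wrist",
    "Left_Pinky", "Right_Pinky",
    "Left_Index", "Right_Index",
    "Left_Thumb", "Right_Thumb",
    "Left_Hip", "Right_Hip",
    "Left_Knee", "Right_Knee",
    "Left_Ankle", "Right_Ankle",
    "Left_Heel", "Right_Heel",
    "Left_Foot_Index", "Right_Foot_Index"
  )
}

# landmark indices the pipeline tracks explicitly
.LM <- list(
  nose = 0L,
  left_shoulder = 11L, right_shoulder = 12L,
  left_hip = 23L, right_hip = 24L,
  left_knee = 25L, right_knee = 26L
)

#' The seven posture classes
#'
#' Class vocabulary for clip labels, in canonical order: a sudden fall,
#' two lying-related transitions/postures, sitting, sleeping, standing,
#' and rising.
#'
#' @return Character vector of length 7.
#' @export
posture_classes <- function() {
  c("falling", "lie", "lie_down", "sit_down", "sleeping", "standing", "stand_up")
}

#' Keypoint-table column names
#'
#' Builds the wide column layout used by keypoint tables: per landmark
#' `"<idx>_<axis>_(<Name>)"` for axes x, y, z (and optionally v for
#' visibility), followed by speed columns and the label column `Y`.
#'
#' @param visibility Include per-landmark visibility columns?
#' @param speeds Character vector of speed column names to append
#'   (default the three-column layout); use `character(0)` for none.
#' @return Character vector of column names (without `clip`/`frame` keys).
#' @export
keypoint_columns <- function(visibility = FALSE,
                             speeds = speed_columns()) {
  axes <- if (visibility) c("x", "y", "z", "v") else c("x", "y", "z")
  nm <- landmark_names()
  per_lm <- unlist(lapply(seq_along(nm) - 1L, function(i) {
    sprintf("%d_%s_(%s)", i, axes, nm[i + 1L])
  }))
  c(per_lm, speeds, "Y")
}

#' Canonical speed column names
#'
#' @param nose Include the nose (head) speed column? The default
#'   three-column layout carries central-body and both knee speeds.
#' @return Character vector of speed column names.
#' @export
speed_columns <- function(nose = FALSE) {
  out <- c("Central_Body_Speed", "Left_Knee_Speed", "Right_Knee_Speed")
  if (nose) out <- c(out, "Nose_Speed")
  out
}

# column name for one landmark/axis, e.g. lm_col(0, "x") -> "0_x_(Nose)"
lm_col <- function(index, axis) {
  sprintf("%d_%s_(%s)", index, axis, landmark_names()[index + 1L])
}

# all coordinate columns for a set of axes, ordered landmark-major
coord_cols <- function(axes = c("x", "y", "z")) {
  nm <- landmark_names()
  unlist(lapply(seq_along(nm) - 1L, function(i) sprintf("%d_%s_(%s)", i, axes, nm[i + 1L])))
}
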