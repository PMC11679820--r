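#' Read a keypoint-sequence table
#'
#' Reads a clip dataset of pose keypoint time series from disk. The CSV
#' dialect mirrors the wide MediaPipe export layout: an `Index` column
#' (per-class clip ordinal), a `Frame` column, one column per landmark
#' axis named `"<idx>_<axis>_(<Name>)"`, optional per-landmark visibility
#' columns (`<idx>_v_...`), optional precomputed speed columns, and the
#' label column `Y`. The JSONL dialect stores one frame per line with an
#' explicit `clip_id` and nested landmark records.
#'
#' Any speed columns found in the file are preserved as-is; the
#' preprocessing pipeline recomputes speeds from coordinates and does not
#' rely on them.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @return A tibble with one row per frame: `clip_id`, `frame`, `label`,
#'   33x3 coordinate columns (plus visibility and speed columns when
#'   present in the file), frames sorted within clip.
#' @seealso [write_keypoint_table()], [validate_keypoints()]
#' @export
read_keypoint_table <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") read_keypoint_csv(path) else read_keypoint_jsonl(path)

  short <- df |>
    dplyr::count(.data$clip_id, name = "n_frames") |>
    dplyr::filter(.data$n_frames < 2L)
  if (nrow(short) > 0L) {
    stop(
      "validation error: clip(s) with fewer than 2 frames: ",
      paste(short$clip_id, collapse = ", ")
    )
  }
  df |>
    dplyr::arrange(match(.data$clip_id, unique(.data$clip_id)), .data$frame)
}

read_keypoint_csv <- function(path) {
  # raw header parse: readr would silently repair duplicated names
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), ",", fixed = TRUE)[[1]]
  check_schema_columns(header)

  coord <- coord_cols()
  vis <- coord_cols("v")
  has_vis <- all(vis %in% header)
  speeds <- intersect(c(speed_columns(nose = TRUE)), header)

  num_cols <- c("Index", "Frame", coord, if (has_vis) vis, speeds)
  spec <- do.call(readr::cols, c(
    stats::setNames(rep(list(readr::col_double()), length(num_cols)), num_cols),
    list(Y = readr::col_character(), .default = readr::col_skip())
  ))
  df <- suppressWarnings(readr::read_csv(path, col_types = spec, progress = FALSE))
  pr <- readr::problems(df)
  if (nrow(pr) > 0L) {
    stop(sprintf(
      "parse error: non-numeric value at file line %d, column %s",
      pr$row[1], as.character(pr$col[1])
    ))
  }
  # the label column applies to a whole clip; files may leave repeats blank
  df <- df |> tidyr::fill("Y", .direction = "down")
  if (anyNA(df$Y)) stop("parse error: missing label (Y) before first labelled row")

  df |>
    dplyr::mutate(
      clip_id = sprintf("%s_%03d", .data$Y, as.integer(.data$Index)),
      frame = as.integer(.data$Frame),
      label = .data$Y,
      .keep = "unused"
    ) |>
    dplyr::select("clip_id", "frame", "label", dplyr::all_of(c(coord, if (has_vis) vis, speeds)))
}

read_keypoint_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    lm <- rec$landmarks
    if (is.null(lm) || nrow(lm) != 33L || !identical(sort(lm$index), 0:32)) {
      stop("schema error: frame without exactly 33 landmarks (indices 0..32) in ", path)
    }
    lm <- lm[order(lm$index), ]
    vals <- c(t(as.matrix(lm[, c("x", "y", "z")])))
    out <- c(
      list(clip_id = rec$clip_id, frame = as.integer(rec$frame), label = rec$label),
      stats::setNames(as.list(vals), coord_cols())
    )
    if (!is.null(lm$visibility)) {
      out <- c(out, stats::setNames(as.list(lm$visibility), coord_cols("v")))
    }
    if (!is.null(rec$speeds)) out <- c(out, as.list(rec$speeds))
    out
  })
  dplyr::bind_rows(rows)
}

check_schema_columns <- function(header) {
  required <- c("Index", "Frame", coord_cols(), "Y")
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  dup <- unique(header[duplicated(header)])
  dup <- intersect(dup, c(coord_cols(), coord_cols("v")))
  if (length(dup) > 0L) {
    stop("schema error: duplicate landmark column(s): ", paste(dup, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a keypoint-sequence table
#'
#' Serializes a keypoint tibble (see [read_keypoint_table()]) to disk.
#' CSV output uses the wide layout with a per-class clip `Index`; reading
#' it back yields canonical clip ids `"<label>_<index>"`. JSONL output
#' preserves `clip_id` verbatim.
#'
#' @param df Keypoint tibble (`clip_id`, `frame`, `label`, coordinate
#'   columns, optional visibility/speed columns).
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_keypoint_table <- function(df, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  stopifnot(all(c("clip_id", "frame", "label") %in% names(df)))
  if (format == "csv") {
    coord <- coord_cols()
    vis <- intersect(coord_cols("v"), names(df))
    speeds <- intersect(speed_columns(nose = TRUE), names(df))
    out <- df |>
      dplyr::group_by(.data$label) |>
      dplyr::mutate(Index = match(.data$clip_id, unique(.data$clip_id))) |>
      dplyr::ungroup() |>
      dplyr::mutate(Frame = .data$frame, Y = .data$label) |>
      dplyr::select("Index", "Frame", dplyr::all_of(c(coord, vis, speeds)), "Y")
    readr::write_csv(out, path, progress = FALSE)
  } else {
    vis <- intersect(coord_cols("v"), names(df))
    speeds <- intersect(speed_columns(nose = TRUE), names(df))
    con <- file(path, open = "wt")
    on.exit(close(con))
    cm <- as.matrix(df[, coord_cols()])
    vm <- if (length(vis) == 33L) as.matrix(df[, vis]) else NULL
    for (i in seq_len(nrow(df))) {
      lm <- data.frame(
        index = 0:32,
        x = cm[i, seq(1, 99, 3)],
        y = cm[i, seq(2, 99, 3)],
        z = cm[i, seq(3, 99, 3)]
      )
      if (!is.null(vm)) lm$visibility <- as.numeric(vm[i, ])
      rec <- list(
        clip_id = df$clip_id[i], frame = df$frame[i], label = df$label[i],
        landmarks = lm
      )
      if (length(speeds) > 0L) rec$speeds <- as.list(df[i, speeds])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, dataframe = "rows"), con)
    }
  }
  invisible(path)
}

#' Validate a keypoint dataset
#'
#' Checks a keypoint tibble against the schema invariants: all 33
#' landmark coordinate columns present and finite, visibility (when
#' present) within \[0, 1\], labels drawn from the seven-class
#' vocabulary, at least two frames per clip, strictly increasing frame
#' numbers with no duplicates, and one label per clip.
#'
#' @param df Keypoint tibble.
#' @return A tibble of violations (`clip_id`, `frame`, `rule`, `detail`);
#'   zero rows when the dataset conforms.
#' @export
validate_keypoints <- function(df) {
  v <- list()
  add <- function(clip_id, frame, rule, detail) {
    tibble::tibble(
      clip_id = as.character(clip_id), frame = as.integer(frame),
      rule = rule, detail = detail
    )
  }

  missing_cols <- setdiff(c("clip_id", "frame", "label", coord_cols()), names(df))
  if (length(missing_cols) > 0L) {
    v[[length(v) + 1L]] <- add(NA, NA, "missing_column", paste(missing_cols, collapse = ", "))
    return(dplyr::bind_rows(v))
  }

  bad_label <- df |>
    dplyr::distinct(.data$clip_id, .data$label) |>
    dplyr::filter(!.data$label %in% posture_classes())
  if (nrow(bad_label) > 0L) {
    v[[length(v) + 1L]] <- add(
      bad_label$clip_id, NA, "unknown_label",
      sprintf("label '%s' not in the 7-class vocabulary", bad_label$label)
    )
  }

  multi_label <- df |>
    dplyr::group_by(.data$clip_id) |>
    dplyr::summarise(n_labels = dplyr::n_distinct(.data$label), .groups = "drop") |>
    dplyr::filter(.data$n_labels > 1L)
  if (nrow(multi_label) > 0L) {
    v[[length(v) + 1L]] <- add(multi_label$clip_id, NA, "multiple_labels", "clip carries more than one label")
  }

  per_clip <- df |>
    dplyr::group_by(.data$clip_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      dup_frames = anyDuplicated(.data$frame) > 0L,
      nondecreasing = is.unsorted(.data$frame, strictly = TRUE),
      .groups = "drop"
    )
  short <- dplyr::filter(per_clip, .data$n_frames < 2L)
  if (nrow(short) > 0L) {
    v[[length(v) + 1L]] <- add(short$clip_id, NA, "too_few_frames", sprintf("%d frame(s); need >= 2", short$n_frames))
  }
  dup <- dplyr::filter(per_clip, .data$dup_frames)
  if (nrow(dup) > 0L) {
    v[[length(v) + 1L]] <- add(dup$clip_id, NA, "duplicate_frame_index", "frame numbers repeat within clip")
  }
  unsrt <- dplyr::filter(per_clip, .data$nondecreasing & !.data$dup_frames)
  if (nrow(unsrt) > 0L) {
    v[[length(v) + 1L]] <- add(unsrt$clip_id, NA, "frames_not_increasing", "frame numbers not strictly increasing")
  }

  cm <- as.matrix(df[, coord_cols()])
  bad <- which(!is.finite(cm), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rows <- unique(bad[, 1])
    v[[length(v) + 1L]] <- add(
      df$clip_id[rows], df$frame[rows], "nonfinite_coordinate",
      "missing or non-finite landmark coordinate"
    )
  }

  vis <- intersect(coord_cols("v"), names(df))
  if (length(vis) > 0L) {
    vmat <- as.matrix(df[, vis])
    out_rows <- which(apply(vmat, 1L, function(r) any(!is.finite(r) | r < 0 | r > 1)))
    if (length(out_rows) > 0L) {
      v[[length(v) + 1L]] <- add(
        df$clip_id[out_rows], df$frame[out_rows], "visibility_out_of_range",
        "visibility must lie in [0, 1]"
      )
    }
  }

  if (length(v) == 0L) {
    return(tibble::tibble(
      clip_id = character(), frame = integer(),
      rule = character(), detail = character()
    ))
  }
  dplyr::bind_rows(v)
}
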