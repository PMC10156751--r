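#' Per-frame feature streams
#'
#' A `frame_stream` holds the per-frame computer-vision outputs for one
#' recording session: head-pose angles in degrees (yaw = left-right,
#' pitch = up-down, roll = tilt), a gaze-on-screen flag, the normalized
#' horizontal gaze coordinate (0 = left screen edge, 1 = right; `NA` when
#' the gaze is off-screen or unavailable), an eyes-open flag, the AU45
#' (blink action unit) intensity on the tracker's 0-5 scale, and the
#' tracker confidence in \[0, 1\]. All vectors share one length; the frame
#' rate is carried alongside.
#'
#' @param yaw_deg,pitch_deg,roll_deg numeric, head-pose angles (degrees).
#' @param gaze_on_screen logical, gaze estimated to be on the screen.
#' @param gaze_x_norm numeric in \[0, 1\] or `NA`.
#' @param eyes_open logical.
#' @param au45 numeric >= 0, AU45 intensity.
#' @param confidence numeric in \[0, 1\].
#' @param fps frames per second (> 0, default 30).
#' @return A `frame_stream` object (list of per-frame vectors plus `fps`).
#' @export
frame_stream <- function(yaw_deg, gaze_on_screen, eyes_open, au45,
                         confidence, gaze_x_norm = NULL, pitch_deg = NULL,
                         roll_deg = NULL, fps = 30) {
  n <- length(yaw_deg)
  if (is.null(gaze_x_norm)) gaze_x_norm <- rep(NA_real_, n)
  if (is.null(pitch_deg)) pitch_deg <- rep(0, n)
  if (is.null(roll_deg)) roll_deg <- rep(0, n)
  x <- list(yaw_deg = as.numeric(yaw_deg),
            pitch_deg = as.numeric(pitch_deg),
            roll_deg = as.numeric(roll_deg),
            gaze_on_screen = as.logical(gaze_on_screen),
            gaze_x_norm = as.numeric(gaze_x_norm),
            eyes_open = as.logical(eyes_open),
            au45 = as.numeric(au45),
            confidence = as.numeric(confidence),
            fps = fps)
  class(x) <- "frame_stream"
  validate_frame_stream(x)
}

#' @export
length.frame_stream <- function(x) length(x$yaw_deg)

validate_frame_stream <- function(x) {
  lens <- vapply(x[c("yaw_deg", "pitch_deg", "roll_deg", "gaze_on_screen",
                     "gaze_x_norm", "eyes_open", "au45", "confidence")],
                 length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all per-frame vectors must share one length; got: ",
         paste(lens, collapse = ", "))
  }
  if (x$fps <= 0) stop("fps must be > 0")
  if (any(x$au45 < 0, na.rm = TRUE)) stop("au45 must be non-negative")
  if (any(x$confidence < 0 | x$confidence > 1, na.rm = TRUE)) {
    stop("confidence must lie in [0, 1]")
  }
  gx <- x$gaze_x_norm
  if (any(gx < 0 | gx > 1, na.rm = TRUE)) {
    stop("gaze_x_norm must lie in [0, 1] when present")
  }
  x
}

STREAM_COLUMNS <- c("frame", "yaw_deg", "pitch_deg", "roll_deg",
                    "gaze_on_screen", "gaze_x_norm", "eyes_open", "au45",
                    "confidence")

#' Read/write frame-stream CSV files
#'
#' One row per frame with columns `frame` (0-based index), `yaw_deg`,
#' `pitch_deg`, `roll_deg`, `gaze_on_screen` (0/1), `gaze_x_norm`,
#' `eyes_open` (0/1), `au45`, `confidence`; header required, missing values
#' empty. Lines starting with `#` are treated as comments.
#'
#' @param path CSV file path.
#' @param fps frames per second of the recording (default 30).
#' @return `read_frame_stream()` returns a [frame_stream()];
#'   `write_frame_stream()` invisibly returns `path`.
#' @rdname stream_csv
#' @export
read_frame_stream <- function(path, fps = 30) {
  df <- read_csv_prov(path)
  missing_cols <- setdiff(setdiff(STREAM_COLUMNS, "frame"), names(df))
  if (length(missing_cols) > 0) {
    stop("frame-stream CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  frame_stream(
    yaw_deg = df$yaw_deg, pitch_deg = df$pitch_deg, roll_deg = df$roll_deg,
    gaze_on_screen = df$gaze_on_screen > 0,
    gaze_x_norm = df$gaze_x_norm,
    eyes_open = df$eyes_open > 0,
    au45 = df$au45, confidence = df$confidence, fps = fps
  )
}

#' @param stream a [frame_stream()].
#' @param seed,config_hash recorded in the provenance comment line.
#' @rdname stream_csv
#' @export
write_frame_stream <- function(stream, path, seed = NA, config_hash = NA) {
  n <- length(stream)
  df <- data.frame(
    frame = seq_len(n) - 1L,
    yaw_deg = round(stream$yaw_deg, 4),
    pitch_deg = round(stream$pitch_deg, 4),
    roll_deg = round(stream$roll_deg, 4),
    gaze_on_screen = as.integer(stream$gaze_on_screen),
    gaze_x_norm = round(stream$gaze_x_norm, 4),
    eyes_open = as.integer(stream$eyes_open),
    au45 = round(stream$au45, 4),
    confidence = round(stream$confidence, 4)
  )
  write_csv_prov(df, path, seed = seed, config_hash = config_hash)
}

#' Convert an OpenFace-style CSV to a frame stream
#'
#' Maps the columns an OpenFace export provides: `pose_Ry`/`pose_Rx`/
#' `pose_Rz` (radians; yaw/pitch/roll) to degrees, `AU45_r` to `au45`, and
#' `confidence`. OpenFace does not emit gaze-on-screen or eyes-open flags;
#' when absent they default to `TRUE` for frames with `success == 1` (or
#' all frames if no `success` column), and `gaze_x_norm` to `NA`, so
#' downstream gating then rests on pose, motion and confidence alone.
#'
#' @param path OpenFace CSV path.
#' @param fps frames per second (default 30).
#' @return A [frame_stream()].
#' @export
read_openface_csv <- function(path, fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  names(df) <- trimws(names(df))
  need <- c("pose_Ry", "AU45_r", "confidence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("OpenFace CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  rad2deg <- 180 / pi
  n <- nrow(df)
  ok <- if ("success" %in% names(df)) df$success > 0 else rep(TRUE, n)
  frame_stream(
    yaw_deg = df$pose_Ry * rad2deg,
    pitch_deg = (df$pose_Rx %||% rep(0, n)) * rad2deg,
    roll_deg = (df$pose_Rz %||% rep(0, n)) * rad2deg,
    gaze_on_screen = ok,
    eyes_open = ok,
    au45 = pmax(df$AU45_r, 0),
    confidence = pmin(pmax(df$confidence, 0), 1),
    fps = fps
  )
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("frame_stream: %d frames at %g fps (%.1f s)\n",
              length(x), x$fps, length(x) / x$fps))
  invisible(x)
}
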