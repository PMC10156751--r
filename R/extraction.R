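#' Extraction configuration
#'
#' Tunable parameters of the facing-forward and blink pipelines. The yaw
#' gate (25 degrees), the rapid-motion ratio (a frame counts as rapid head
#' motion when the smoothed absolute yaw exceeds 150% of the previous
#' frame's) and the tracker-confidence floor (0.75) are fixed by the
#' method; the smoothing windows and peak criteria are implementation
#' tunables with physiologically motivated defaults (blinks last roughly
#' 100-400 ms, i.e. 3-12 frames at 30 fps).
#'
#' @param yaw_threshold_deg facing gate on absolute yaw, degrees (default 25).
#' @param yaw_smooth_window centered moving-average window for yaw, frames
#'   (odd, default 5, ~167 ms at 30 fps).
#' @param rapid_ratio rapid-motion ratio threshold (default 1.5).
#' @param rapid_eps_deg floor on the denominator of the rapid-motion ratio,
#'   degrees (default 1); guards the ratio near zero yaw.
#' @param au45_smooth_window AU45 smoothing window, frames (odd, default 3).
#' @param blink_min_height minimum smoothed-AU45 peak height (default 1).
#' @param blink_min_separation minimum frames between kept peaks (default 3).
#' @param confidence_threshold valid-frame confidence floor (default 0.75).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(yaw_threshold_deg = 25,
                              yaw_smooth_window = 5,
                              rapid_ratio = 1.5,
                              rapid_eps_deg = 1.0,
                              au45_smooth_window = 3,
                              blink_min_height = 1.0,
                              blink_min_separation = 3,
                              confidence_threshold = 0.75) {
  cfg <- list(yaw_threshold_deg = yaw_threshold_deg,
              yaw_smooth_window = as.integer(yaw_smooth_window),
              rapid_ratio = rapid_ratio,
              rapid_eps_deg = rapid_eps_deg,
              au45_smooth_window = as.integer(au45_smooth_window),
              blink_min_height = blink_min_height,
              blink_min_separation = as.integer(blink_min_separation),
              confidence_threshold = confidence_threshold)
  for (w in c("yaw_smooth_window", "au45_smooth_window")) {
    if (cfg[[w]] < 1L || cfg[[w]] %% 2L == 0L) {
      stop(w, " must be an odd integer >= 1")
    }
  }
  if (cfg$blink_min_separation < 1L) stop("blink_min_separation must be >= 1")
  num <- c("yaw_threshold_deg", "rapid_ratio", "rapid_eps_deg",
           "blink_min_height", "confidence_threshold")
  if (any(unlist(cfg[num]) < 0)) stop("thresholds must be >= 0")
  structure(cfg, class = "extraction_config")
}

#' Read/write an extraction configuration (YAML or JSON)
#'
#' Format is inferred from the file extension (`.yaml`/`.yml` vs `.json`).
#' Missing fields fall back to the [extraction_config()] defaults.
#'
#' @param path file path.
#' @rdname extraction_config_io
#' @export
read_extraction_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  do.call(extraction_config, vals[names(vals) %in%
                                    names(formals(extraction_config))])
}

#' @param config an [extraction_config()].
#' @rdname extraction_config_io
#' @export
write_extraction_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Smooth a per-frame signal
#'
#' Centered moving average; edge frames average over the available
#' neighbours only (shrunken windows), so output length equals input
#' length and no padding values are invented.
#'
#' @param x numeric per-frame signal.
#' @param window odd integer window (frames).
#' @return Smoothed numeric vector.
#' @examples
#' smooth_series(c(0, 3, 0), 3)  # 1.5 1.0 1.5
#' @export
smooth_series <- function(x, window) moving_average(x, window)

#' Flag rapid head motion
#'
#' Frame t (t >= 2) is flagged when the smoothed absolute yaw exceeds
#' `rapid_ratio` times the previous frame's, i.e.
#' `|yaw'[t]| > rapid_ratio * max(|yaw'[t-1]|, rapid_eps_deg)`. The epsilon
#' floor keeps the ratio meaningful near zero yaw; the first frame is never
#' flagged.
#'
#' @param yaw_smooth smoothed yaw series (degrees).
#' @param rapid_ratio ratio threshold (default 1.5).
#' @param rapid_eps_deg denominator floor in degrees (default 1).
#' @return Logical vector, same length.
#' @export
flag_rapid_motion <- function(yaw_smooth, rapid_ratio = 1.5,
                              rapid_eps_deg = 1.0) {
  n <- length(yaw_smooth)
  if (n < 1L) stop("series must have at least one frame")
  a <- abs(yaw_smooth)
  flags <- c(FALSE, a[-1] > rapid_ratio * pmax(a[-n], rapid_eps_deg))
  flags
}

#' Per-frame facing-forward mask
#'
#' A frame counts as facing forward when the absolute raw yaw is below the
#' threshold, the gaze is on the screen, the eyes are open, and the frame
#' is not flagged as rapid head motion (flags computed on the smoothed yaw).
#'
#' @param stream a [frame_stream()].
#' @param config an [extraction_config()].
#' @return Logical vector over frames.
#' @export
facing_forward_mask <- function(stream, config = extraction_config()) {
  if (length(stream) == 0L) stop("stream has no frames")
  rapid <- flag_rapid_motion(
    smooth_series(stream$yaw_deg, config$yaw_smooth_window),
    config$rapid_ratio, config$rapid_eps_deg
  )
  abs(stream$yaw_deg) < config$yaw_threshold_deg &
    stream$gaze_on_screen & stream$eyes_open & !rapid
}

#' Total time facing forward (percent)
#'
#' @param mask logical facing-forward series over one movie's frames.
#' @return Percent of frames facing forward in \[0, 100\]; `NA` for an
#'   empty series (movie not reached by the recording).
#' @export
total_facing_forward <- function(mask) {
  if (length(mask) == 0L) return(NA_real_)
  100 * mean(mask)
}

#' Valid-frame mask
#'
#' A frame is valid when the participant is facing forward and the tracker
#' confidence is at or above the threshold. Blink rates are normalized by
#' valid time only.
#'
#' @param facing logical facing-forward series.
#' @param confidence numeric confidence series.
#' @param confidence_threshold floor, default 0.75 (inclusive).
#' @return Logical vector.
#' @export
valid_frame_mask <- function(facing, confidence,
                             confidence_threshold = 0.75) {
  if (length(facing) != length(confidence)) {
    stop("facing and confidence must have equal length")
  }
  facing & (confidence >= confidence_threshold)
}

#' Detect blinks from the AU45 series
#'
#' Smooths the AU45 intensity, finds interior local maxima (a strict rise
#' into the peak or its plateau and a strict fall out of it; series
#' endpoints are never peaks; a plateau contributes its first frame), keeps
#' peaks of height at least `blink_min_height`, then enforces the minimum
#' peak separation greedily by descending height (ties broken toward the
#' earlier frame).
#'
#' @param au45 non-negative AU45 intensity series.
#' @param config an [extraction_config()].
#' @return Integer vector of 1-based apex frame indices, in frame order.
#' @export
detect_blinks <- function(au45, config = extraction_config()) {
  n <- length(au45)
  if (n == 0L) stop("au45 series has no frames")
  s <- smooth_series(au45, config$au45_smooth_window)
  cand <- local_maxima(s)
  cand <- cand[s[cand] >= config$blink_min_height]
  if (length(cand) <= 1L) return(as.integer(cand))
  enforce_separation(cand, s[cand], config$blink_min_separation)
}

# interior local maxima with plateau handling: first index of every run of
# equal values that is strictly above both neighbouring runs
local_maxima <- function(s) {
  r <- rle(s)
  v <- r$values
  k <- length(v)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- seq_len(k)
  is_peak <- idx > 1L & idx < k &
    v > c(Inf, v[-k]) & v > c(v[-1], Inf)
  as.integer(starts[is_peak])
}

# greedy non-maximum suppression: keep higher peaks first (ties: earlier)
enforce_separation <- function(idx, height, min_sep) {
  ord <- order(-height, idx)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_sep)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Blink rate per minute of valid time
#'
#' Counts blinks whose apex frame is valid and divides by the valid time in
#' minutes. A blink is attributed to its apex frame only.
#'
#' @param blinks integer apex frame indices (1-based, within bounds).
#' @param valid logical valid-frame series.
#' @param fps frames per second.
#' @return Blinks per minute of valid time; `NA` when no frame is valid.
#' @export
blink_rate <- function(blinks, valid, fps = 30) {
  if (length(blinks) > 0 &&
      (min(blinks) < 1L || max(blinks) > length(valid))) {
    stop("blink indices out of bounds")
  }
  n_valid <- sum(valid)
  if (n_valid == 0L) return(NA_real_)
  n_blinks <- if (length(blinks) > 0) sum(valid[blinks]) else 0L
  n_blinks / (n_valid / fps / 60)
}

#' Percent of on-screen gaze on the social half
#'
#' For a mixed movie showing social content on one screen half: among
#' frames with on-screen gaze and a horizontal gaze coordinate, the percent
#' falling on the social half (left half: `gaze_x_norm < 0.5`; right half:
#' `gaze_x_norm >= 0.5`). Off-screen frames are excluded from the
#' denominator.
#'
#' @param gaze_on_screen logical series over the movie's frames.
#' @param gaze_x_norm numeric series in \[0, 1\] (NA allowed).
#' @param social_side `"left"` or `"right"`.
#' @return Percent in \[0, 100\], or `NA` when no qualifying frame exists.
#' @export
gaze_percent_social <- function(gaze_on_screen, gaze_x_norm, social_side) {
  if (!social_side %in% c("left", "right")) {
    stop("gaze_percent_social applies to mixed movies only ",
         "(social_side must be 'left' or 'right')")
  }
  ok <- gaze_on_screen & !is.na(gaze_x_norm)
  if (!any(ok)) return(NA_real_)
  x <- gaze_x_norm[ok]
  social <- if (social_side == "left") x < 0.5 else x >= 0.5
  100 * mean(social)
}
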