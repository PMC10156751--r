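#' Extract per-movie and aggregate attention features for one participant
#'
#' Computes the facing-forward mask, valid-frame mask and blink apexes once
#' over the whole recording (the signal is continuous across movie
#' boundaries), segments frames against the schedule, and derives for every
#' movie the total-time-facing-forward percentage (TFF), valid-frame count,
#' blink count and blink rate per minute of valid time. Aggregates are the
#' unweighted means of the per-movie values by stimulus type -- mixed
#' movies excluded -- plus the mean gaze-percent-social (MGPS) over the two
#' mixed movies. Movies beyond the end of a short recording yield missing
#' features; recordings shorter than the schedule are allowed.
#'
#' @param stream a [frame_stream()].
#' @param schedule a [stimulus_schedule()]; defaults to [default_schedule()].
#' @param config an [extraction_config()].
#' @param participant_id optional identifier carried into the result.
#' @return A `participant_features` object: list with `participant_id`,
#'   `per_movie` (data frame: `movie`, `movie_type`, `n_frames`, `n_facing`,
#'   `tff_pct`, `n_valid`, `n_blinks`, `blink_rate`, `gps`), and scalars
#'   `mean_tff_social`, `mean_tff_nonsocial`, `mean_br_social`,
#'   `mean_br_nonsocial`, `mgps`.
#' @export
extract_participant <- function(stream, schedule = default_schedule(),
                                config = extraction_config(),
                                participant_id = NA_character_) {
  stopifnot(inherits(stream, "frame_stream"))
  n <- length(stream)
  facing <- facing_forward_mask(stream, config)
  valid <- valid_frame_mask(facing, stream$confidence,
                            config$confidence_threshold)
  blinks <- detect_blinks(stream$au45, config)
  blink_valid <- if (length(blinks)) blinks[valid[blinks]] else integer(0)

  seg <- segment_frames(n, schedule)
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    if (seg$n_frames[i] == 0L) {
      return(data.frame(movie = seg$name[i], movie_type = seg$movie_type[i],
                        n_frames = 0L, n_facing = NA_integer_,
                        tff_pct = NA_real_, n_valid = NA_integer_,
                        n_blinks = NA_integer_, blink_rate = NA_real_,
                        gps = NA_real_, stringsAsFactors = FALSE))
    }
    idx <- seg$first_frame[i]:seg$last_frame[i]
    f <- facing[idx]
    v <- valid[idx]
    nb <- sum(blink_valid >= seg$first_frame[i] &
                blink_valid <= seg$last_frame[i])
    n_valid <- sum(v)
    rate <- if (n_valid == 0L) NA_real_ else
      nb / (n_valid / stream$fps / 60)
    gps <- if (seg$movie_type[i] == "mixed") {
      gaze_percent_social(stream$gaze_on_screen[idx],
                          stream$gaze_x_norm[idx], seg$social_side[i])
    } else NA_real_
    data.frame(movie = seg$name[i], movie_type = seg$movie_type[i],
               n_frames = length(idx), n_facing = sum(f),
               tff_pct = total_facing_forward(f), n_valid = n_valid,
               n_blinks = nb, blink_rate = rate, gps = gps,
               stringsAsFactors = FALSE)
  })
  per_movie <- do.call(rbind, rows)

  type_mean <- function(col, type) {
    vals <- per_movie[[col]][per_movie$movie_type == type]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  mgps_vals <- per_movie$gps[per_movie$movie_type == "mixed"]
  out <- list(
    participant_id = participant_id,
    per_movie = per_movie,
    mean_tff_social = type_mean("tff_pct", "social"),
    mean_tff_nonsocial = type_mean("tff_pct", "nonsocial"),
    mean_br_social = type_mean("blink_rate", "social"),
    mean_br_nonsocial = type_mean("blink_rate", "nonsocial"),
    mgps = if (all(is.na(mgps_vals))) NA_real_ else
      mean(mgps_vals, na.rm = TRUE)
  )
  class(out) <- "participant_features"
  out
}

#' @export
print.participant_features <- function(x, ...) {
  cat(sprintf("participant_features%s\n",
              if (is.na(x$participant_id)) "" else
                paste0(" [", x$participant_id, "]")))
  cat(sprintf("  mean TFF  social %.1f%%  nonsocial %.1f%%\n",
              x$mean_tff_social, x$mean_tff_nonsocial))
  cat(sprintf("  blink/min social %.1f   nonsocial %.1f\n",
              x$mean_br_social, x$mean_br_nonsocial))
  cat(sprintf("  MGPS %.1f%%\n", x$mgps))
  invisible(x)
}

# flatten a participant_features object into one cohort-table row
features_row <- function(pf) {
  pm <- pf$per_movie
  slugs <- movie_slug(pm$movie)
  row <- data.frame(participant_id = pf$participant_id,
                    mean_tff_social = pf$mean_tff_social,
                    mean_tff_nonsocial = pf$mean_tff_nonsocial,
                    mean_br_social = pf$mean_br_social,
                    mean_br_nonsocial = pf$mean_br_nonsocial,
                    mgps = pf$mgps, stringsAsFactors = FALSE)
  for (i in seq_along(slugs)) {
    row[[paste0("tff_", slugs[i])]] <- pm$tff_pct[i]
    row[[paste0("br_", slugs[i])]] <- pm$blink_rate[i]
  }
  row
}
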