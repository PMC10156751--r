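#' Stimulus schedules
#'
#' The presentation task shows eleven short movies back-to-back, in the same
#' order for every participant, while the device camera records the child at a
#' fixed frame rate. A `stimulus_schedule` is a data frame with one row per
#' movie (`name`, `movie_type`, `duration_s`, `onset_s`, `social_side`) and an
#' `fps` attribute. Movie types are `"social"`, `"nonsocial"` or `"mixed"`;
#' mixed movies show social and nonsocial content on opposite screen halves
#' and carry a `social_side` of `"left"` or `"right"` (all other movies have
#' `social_side = "none"`).
#'
#' @name stimulus_schedule
NULL

MOVIE_TYPES <- c("social", "nonsocial", "mixed")
SOCIAL_SIDES <- c("left", "right", "none")

#' Construct a stimulus schedule
#'
#' Onsets are computed cumulatively: movies are assumed back-to-back with no
#' inter-movie gaps.
#'
#' @param name character vector of movie names.
#' @param movie_type character vector, one of `"social"`, `"nonsocial"`,
#'   `"mixed"`.
#' @param duration_s numeric vector of positive durations in seconds.
#' @param social_side character vector; `"left"`/`"right"` for mixed movies,
#'   `"none"` otherwise.
#' @param fps frames per second of the recording (default 30).
#' @return A `stimulus_schedule` data frame.
#' @export
stimulus_schedule <- function(name, movie_type, duration_s,
                              social_side = NULL, fps = 30) {
  stopifnot(length(name) == length(movie_type),
            length(name) == length(duration_s))
  if (is.null(social_side)) {
    social_side <- ifelse(movie_type == "mixed", "right", "none")
  }
  if (!all(movie_type %in% MOVIE_TYPES)) {
    stop("movie_type must be one of: ", paste(MOVIE_TYPES, collapse = ", "))
  }
  if (!all(social_side %in% SOCIAL_SIDES)) {
    stop("social_side must be one of: ", paste(SOCIAL_SIDES, collapse = ", "))
  }
  if (any(duration_s <= 0)) stop("duration_s must be > 0")
  if (fps <= 0) stop("fps must be > 0")
  bad <- xor(movie_type == "mixed", social_side != "none")
  if (any(bad)) {
    stop("social_side must be 'none' exactly for non-mixed movies: ",
         paste(name[bad], collapse = ", "))
  }
  onset_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  out <- data.frame(
    name = as.character(name),
    movie_type = as.character(movie_type),
    duration_s = as.numeric(duration_s),
    onset_s = as.numeric(onset_s),
    social_side = as.character(social_side),
    stringsAsFactors = FALSE
  )
  attr(out, "fps") <- fps
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

#' The default eleven-movie schedule
#'
#' The fixed presentation sequence used by the screening app: Floating
#' Bubbles (35 s, nonsocial), Dog in Grass (16 s, nonsocial), Dog in Grass
#' RRL (40 s, nonsocial), Spinning Top (53 s, mixed), Mechanical Puppy
#' (25 s, nonsocial), Blowing Bubbles (64 s, mixed), Rhymes (30 s, social),
#' Toys (19 s, nonsocial), Make Me Laugh (56 s, social), Playing with Blocks
#' (71 s, social) and Fun at the Park (51 s, social); 460 s (~8 min) total.
#' Spinning Top and Blowing Bubbles present social and nonsocial content on
#' opposite screen halves and are treated as mixed: they are excluded from
#' the social/nonsocial aggregates and used only for the gaze-percent-social
#' metric. Which half is social is a fixed convention here (Spinning Top:
#' right, Blowing Bubbles: left).
#'
#' @param fps frames per second (default 30).
#' @return A [stimulus_schedule()].
#' @examples
#' sched <- default_schedule()
#' sum(sched$duration_s)  # 460 seconds
#' @export
default_schedule <- function(fps = 30) {
  stimulus_schedule(
    name = c("Floating Bubbles", "Dog in Grass", "Dog in Grass RRL",
             "Spinning Top", "Mechanical Puppy", "Blowing Bubbles",
             "Rhymes", "Toys", "Make Me Laugh", "Playing with Blocks",
             "Fun at the Park"),
    movie_type = c("nonsocial", "nonsocial", "nonsocial", "mixed",
                   "nonsocial", "mixed", "social", "nonsocial", "social",
                   "social", "social"),
    duration_s = c(35, 16, 40, 53, 25, 64, 30, 19, 56, 71, 51),
    social_side = c("none", "none", "none", "right", "none", "left",
                    "none", "none", "none", "none", "none"),
    fps = fps
  )
}

# short machine-friendly identifiers used as CSV column suffixes
movie_slug <- function(name) {
  gsub("[^a-z0-9]+", "_", tolower(name))
}

#' Map recording frames onto schedule movies
#'
#' Frame ranges are half-open on a 0-based frame axis,
#' `[round(onset * fps), round((onset + duration) * fps))`, with rounding
#' half away from zero, then clipped to the number of recorded frames.
#' In the returned table `first_frame`/`last_frame` are 1-based inclusive R
#' indices into the stream (`NA` for movies entirely beyond the recording).
#'
#' @param n_frames number of frames in the recording (> 0).
#' @param schedule a [stimulus_schedule()].
#' @return Data frame with columns `name`, `movie_type`, `social_side`,
#'   `start0` and `end0` (the 0-based half-open range), `first_frame`,
#'   `last_frame`, `n_frames`.
#' @export
segment_frames <- function(n_frames, schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"), n_frames > 0)
  fps <- attr(schedule, "fps")
  start0 <- round_half_away(schedule$onset_s * fps)
  end0 <- round_half_away((schedule$onset_s + schedule$duration_s) * fps)
  start0 <- pmin(start0, n_frames)
  end0 <- pmin(end0, n_frames)
  nf <- pmax(end0 - start0, 0)
  data.frame(
    name = schedule$name,
    movie_type = schedule$movie_type,
    social_side = schedule$social_side,
    start0 = start0,
    end0 = end0,
    first_frame = ifelse(nf > 0, start0 + 1, NA_integer_),
    last_frame = ifelse(nf > 0, end0, NA_integer_),
    n_frames = nf,
    stringsAsFactors = FALSE
  )
}

#' Read/write a schedule as JSON
#'
#' The JSON layout is `{"fps": 30, "movies": [{"name", "type", "duration_s",
#' "social_side"}, ...]}`; onsets are recomputed cumulatively on read.
#'
#' @param path file path.
#' @rdname schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  m <- obj$movies
  stimulus_schedule(
    name = m$name, movie_type = m$type, duration_s = m$duration_s,
    social_side = m$social_side %||% NULL, fps = obj$fps %||% 30
  )
}

#' @param schedule a [stimulus_schedule()].
#' @rdname schedule_json
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- list(
    fps = attr(schedule, "fps"),
    movies = data.frame(
      name = schedule$name, type = schedule$movie_type,
      duration_s = schedule$duration_s, social_side = schedule$social_side,
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule: %d movies, %.0f s total, %g fps\n",
              nrow(x), sum(x$duration_s), attr(x, "fps")))
  print.data.frame(x, ...)
  invisible(x)
}
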