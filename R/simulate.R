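#' Group-level generator parameters
#'
#' Parameters of the synthetic session generator for one diagnostic group.
#' Facing probabilities are the stationary fraction of time spent attending
#' per stimulus type; blink rates are the Poisson blink intensities in
#' blinks per minute; `p_social_gaze` is the per-frame probability that
#' on-screen gaze during a mixed movie lands on the social half;
#' `dwell_mean_s` is the mean attend/away bout length of the two-state
#' attention process; `conf_low_rate` is the fraction of frames with
#' tracker confidence below the 0.75 validity floor.
#'
#' @param label group label: `"NT"`, `"AUT"` or `"LDDD"`.
#' @param p_facing_social,p_facing_nonsocial probabilities in \[0, 1\].
#' @param br_social,br_nonsocial blink intensities, blinks/min (>= 0).
#' @param p_social_gaze probability in \[0, 1\].
#' @param dwell_mean_s mean bout length in seconds (> 0, default 3).
#' @param conf_low_rate fraction of low-confidence frames (default 0.05).
#' @return A `group_params` list.
#' @export
group_params <- function(label, p_facing_social, p_facing_nonsocial,
                         br_social, br_nonsocial, p_social_gaze,
                         dwell_mean_s = 3, conf_low_rate = 0.05) {
  stopifnot(label %in% c("NT", "AUT", "LDDD"),
            p_facing_social >= 0, p_facing_social <= 1,
            p_facing_nonsocial >= 0, p_facing_nonsocial <= 1,
            p_social_gaze >= 0, p_social_gaze <= 1,
            br_social >= 0, br_nonsocial >= 0, dwell_mean_s > 0,
            conf_low_rate >= 0, conf_low_rate <= 1)
  structure(list(label = label,
                 p_facing_social = p_facing_social,
                 p_facing_nonsocial = p_facing_nonsocial,
                 br_social = br_social, br_nonsocial = br_nonsocial,
                 p_social_gaze = p_social_gaze,
                 dwell_mean_s = dwell_mean_s,
                 conf_low_rate = conf_low_rate),
            class = "group_params")
}

#' Study-like generator presets
#'
#' Encodes the qualitative group-by-stimulus pattern of the screening
#' cohort: neurotypical toddlers face the screen more and blink less during
#' social than nonsocial movies and favour the social half of mixed movies;
#' autistic toddlers face the screen less during social than nonsocial
#' movies, blink at an equal, higher rate for both types, and look less at
#' the social half.
#'
#' @return Named list of [group_params()] for `NT`, `AUT` and `LDDD`.
#' @export
preset_group_params <- function() {
  list(
    NT = group_params("NT", p_facing_social = 0.95,
                      p_facing_nonsocial = 0.85,
                      br_social = 12, br_nonsocial = 18,
                      p_social_gaze = 0.70),
    AUT = group_params("AUT", p_facing_social = 0.75,
                       p_facing_nonsocial = 0.85,
                       br_social = 22, br_nonsocial = 22,
                       p_social_gaze = 0.45),
    LDDD = group_params("LDDD", p_facing_social = 0.85,
                        p_facing_nonsocial = 0.85,
                        br_social = 18, br_nonsocial = 18,
                        p_social_gaze = 0.55)
  )
}

#' Cohort-level generator configuration
#'
#' Defaults mirror the screening study's composition: 416 neurotypical and
#' 43 autistic toddlers (a third LDDD preset exists but defaults to zero),
#' ages ~N(20.6, 3.2) and ~N(24.3, 4.6) months. `clinical_effects` are the
#' slopes tying the latent social/nonsocial attention traits to the ADOS
#' severity and Mullen cognitive scores of the autistic group (zero slopes
#' give null correlations).
#'
#' @param n_per_group named counts per group label.
#' @param group_params named list of [group_params()].
#' @param age_months named list of `c(mean, sd)` per group.
#' @param clinical_effects list with `ados_slope` and `mullen_slope`.
#' @param seed integer seed driving all randomness.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(NT = 416, AUT = 43, LDDD = 0),
                          group_params = preset_group_params(),
                          age_months = list(NT = c(20.59, 3.18),
                                            AUT = c(24.32, 4.64),
                                            LDDD = c(22, 4)),
                          clinical_effects = list(ados_slope = 1.2,
                                                  mullen_slope = 8),
                          seed = 1L) {
  stopifnot(all(n_per_group >= 0), all(names(n_per_group) %in%
                                         c("NT", "AUT", "LDDD")))
  structure(list(n_per_group = n_per_group, group_params = group_params,
                 age_months = age_months,
                 clinical_effects = clinical_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# per-participant dispersion constants (the study prints no within-group
# dispersions; these are free parameters, documented in the vignette)
SD_P_FACING <- 0.04   # sd of facing probability, probability scale
SD_P_GAZE <- 0.10     # sd of social-half gaze probability
BLINK_GAMMA_SHAPE <- 25  # multiplicative blink heterogeneity, cv = 0.2
BLINK_REFRACTORY_S <- 0.3  # minimum blink apex spacing, seconds

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate one synthetic session
#'
#' Simulates a per-frame feature stream for one participant watching the
#' schedule. Attention is a two-state (attend/away) semi-Markov process per
#' movie with exponential bout lengths whose stationary attending fraction
#' equals the facing probability for the movie's type (mixed movies use the
#' mean of the two). Attending frames carry small, slowly varying yaw
#' (constant per bout, magnitude 5-18 degrees, AR noise sd 0.3), on-screen
#' gaze and open eyes; away bouts are a 50/50 mixture of gaze-off (yaw
#' small) and head-turn (|yaw| in 30-60 degrees) modes. Blink counts per
#' movie are Poisson at the type's intensity; apexes are placed uniformly
#' with a 300-ms refractory spacing and rendered as 3-7-frame triangular
#' AU45 pulses with apex intensity in \[2, 4\]. The eyes-open flag models
#' sustained closure/occlusion and stays TRUE through blink pulses.
#' Confidence is 1 except for a `conf_low_rate` fraction of frames drawn
#' below 0.75. On-screen frames of mixed movies draw the gaze half
#' Bernoulli(`p_social_gaze`); other movies draw the coordinate uniformly.
#'
#' @param params a [group_params()] (possibly participant-specific).
#' @param schedule a [stimulus_schedule()].
#' @param seed integer seed; equal seeds give identical streams.
#' @return A [frame_stream()] covering the full schedule.
#' @export
generate_session <- function(params, schedule = default_schedule(),
                             seed = 1L) {
  stopifnot(inherits(params, "group_params"),
            inherits(schedule, "stimulus_schedule"))
  fps <- attr(schedule, "fps")
  set.seed(as.integer(seed))
  total_frames <- round_half_away(sum(schedule$duration_s) * fps)
  seg <- segment_frames(total_frames, schedule)

  gaze_x <- rep(NA_real_, total_frames)
  eyes <- rep(TRUE, total_frames)
  au45 <- abs(stats::rnorm(total_frames, 0, 0.03))
  conf <- rep(1, total_frames)
  attend <- logical(total_frames)

  # attention bouts per movie (the stationary fraction is type-specific)...
  for (i in seq_len(nrow(seg))) {
    nf <- seg$n_frames[i]
    if (nf == 0L) next
    idx <- seg$first_frame[i]:seg$last_frame[i]
    type <- seg$movie_type[i]
    p <- switch(type,
                social = params$p_facing_social,
                nonsocial = params$p_facing_nonsocial,
                mixed = (params$p_facing_social +
                           params$p_facing_nonsocial) / 2)
    attend[idx] <- simulate_bouts(nf, p, params$dwell_mean_s, fps)
  }
  # ...but the head-pose process spans the session, so an attending spell
  # crossing a movie boundary keeps one yaw base and triggers no spurious
  # rapid-motion flag there
  mv <- simulate_pose(attend, fps)
  yaw <- mv$yaw
  gaze_on <- mv$gaze_on

  for (i in seq_len(nrow(seg))) {
    nf <- seg$n_frames[i]
    if (nf == 0L) next
    idx <- seg$first_frame[i]:seg$last_frame[i]
    type <- seg$movie_type[i]
    br <- switch(type,
                 social = params$br_social,
                 nonsocial = params$br_nonsocial,
                 mixed = (params$br_social + params$br_nonsocial) / 2)

    on <- which(gaze_on[idx])
    if (length(on) > 0) {
      if (type == "mixed") {
        social <- stats::runif(length(on)) < params$p_social_gaze
        lo <- if (seg$social_side[i] == "left") 0 else 0.5
        x <- ifelse(social, stats::runif(length(on), lo, lo + 0.5),
                    stats::runif(length(on), 0.5 - lo, 1 - lo))
        gaze_x[idx[on]] <- x
      } else {
        gaze_x[idx[on]] <- stats::runif(length(on))
      }
    }

    apexes <- place_blinks(nf, br, fps)
    au45[idx] <- au45[idx] + render_pulses(nf, apexes)

    low <- stats::runif(nf) < params$conf_low_rate
    conf[idx][low] <- stats::runif(sum(low), 0, 0.74)
  }

  frame_stream(yaw_deg = yaw, gaze_on_screen = gaze_on, eyes_open = eyes,
               au45 = au45, confidence = conf, gaze_x_norm = gaze_x,
               fps = fps)
}

# alternate attend/away exponential bouts; stationary attending fraction p.
# mean attend bout = 2*dwell*p, mean away bout = 2*dwell*(1-p), so the
# average bout length is dwell and the attending fraction is p.
simulate_bouts <- function(n_frames, p, dwell_mean_s, fps) {
  if (p >= 0.999) return(rep(TRUE, n_frames))
  if (p <= 0.001) return(rep(FALSE, n_frames))
  m_a <- 2 * dwell_mean_s * p * fps
  m_w <- 2 * dwell_mean_s * (1 - p) * fps
  state <- stats::runif(1) < p
  out <- logical(0)
  while (length(out) < n_frames) {
    len <- max(1L, round(stats::rexp(1, rate = 1 / (if (state) m_a else m_w))))
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n_frames)]
}

# yaw and gaze flags given the attend mask; per-bout constant yaw bases
simulate_pose <- function(attend, fps) {
  n <- length(attend)
  r <- rle(attend)
  yaw <- numeric(n)
  gaze_on <- logical(n)
  pos <- 1L
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]
    idx <- pos:(pos + len - 1L)
    if (r$values[j]) {
      base <- sample(c(-1, 1), 1) * stats::runif(1, 5, 18)
      yaw[idx] <- base + stats::rnorm(len, 0, 0.3)
      gaze_on[idx] <- TRUE
    } else if (stats::runif(1) < 0.5) {
      # gaze-off mode: head still roughly frontal, gaze off the screen
      base <- sample(c(-1, 1), 1) * stats::runif(1, 5, 18)
      yaw[idx] <- base + stats::rnorm(len, 0, 0.3)
      gaze_on[idx] <- FALSE
    } else {
      # head-turn mode
      base <- sample(c(-1, 1), 1) * stats::runif(1, 30, 60)
      yaw[idx] <- base + stats::rnorm(len, 0, 0.5)
      gaze_on[idx] <- FALSE
    }
    pos <- pos + len
  }
  list(yaw = yaw, gaze_on = gaze_on)
}

# Poisson blink count over the movie; apexes uniform with refractory spacing
place_blinks <- function(n_frames, rate_per_min, fps) {
  min_gap <- max(3L, round(BLINK_REFRACTORY_S * fps))
  margin <- 4L
  if (rate_per_min <= 0 || n_frames <= 2 * margin) return(integer(0))
  n_b <- stats::rpois(1, rate_per_min * n_frames / fps / 60)
  n_max <- (n_frames - 2 * margin) %/% min_gap + 1L
  n_b <- min(n_b, n_max)
  if (n_b == 0L) return(integer(0))
  for (try in 1:200) {
    apex <- sort(sample((margin + 1L):(n_frames - margin), n_b))
    if (n_b == 1L || all(diff(apex) >= min_gap)) return(apex)
  }
  # fall back: deterministic thinning of an even grid
  as.integer(round(seq(margin + 1L, n_frames - margin, length.out = n_b)))
}

# triangular AU45 pulses: total length 3/5/7 frames, apex in [2, 4]
render_pulses <- function(n_frames, apexes) {
  au <- numeric(n_frames)
  for (a in apexes) {
    half <- sample(1:3, 1)
    amp <- stats::runif(1, 2, 4)
    off <- (-half):half
    pulse <- amp * (1 - abs(off) / (half + 1))
    ok <- a + off >= 1 & a + off <= n_frames
    au[a + off[ok]] <- au[a + off[ok]] + pulse[ok]
  }
  au
}

#' Generate a full synthetic cohort
#'
#' Draws per-participant parameters around the group presets (facing
#' probabilities jittered with sd 0.04 on the probability scale, blink
#' intensities scaled by a mean-one gamma multiplier shared across stimulus
#' types, social-gaze probability jittered with sd 0.10), simulates each
#' session, and generates ages, sex and -- for the autistic group --
#' clinical scores whose construction ties ADOS social-affect/total
#' severity negatively to the latent social-attention trait and the Mullen
#' composite/visual-reception scores negatively to the nonsocial trait.
#'
#' @param config a [cohort_config()].
#' @param schedule a [stimulus_schedule()].
#' @param keep_streams keep generated streams in memory (`TRUE`), or pass
#'   each to `stream_fun` and drop it (used by the disk writer and the
#'   fused extractor).
#' @param stream_fun optional `function(participant_id, stream)` called per
#'   session when `keep_streams = FALSE`.
#' @param generate_streams set `FALSE` to skip session synthesis entirely
#'   (manifest, clinical scores and realized parameters only).
#' @return List with `manifest` (participant_id, group, age_months, sex),
#'   `clinical` (ADOS/Mullen scores, autistic rows populated), `params`
#'   (per-participant realized generator parameters) and, if kept,
#'   `streams` (named list of [frame_stream()]).
#' @export
generate_cohort <- function(config = cohort_config(),
                            schedule = default_schedule(),
                            keep_streams = TRUE, stream_fun = NULL,
                            generate_streams = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$n_per_group)[config$n_per_group > 0]
  manifest <- list(); clinical <- list(); params_tbl <- list()
  streams <- if (keep_streams) list() else NULL
  counter <- 0L
  for (g in groups) {
    n <- config$n_per_group[[g]]
    gp <- config$group_params[[g]]
    age <- config$age_months[[g]]
    for (i in seq_len(n)) {
      counter <- counter + 1L
      pid <- sprintf("%s%04d", g, i)
      dseed <- derive_seed(config$seed, counter)
      set.seed(dseed)
      u_s <- stats::rnorm(1); u_ns <- stats::rnorm(1)
      u_g <- stats::rnorm(1)
      bmul <- stats::rgamma(1, shape = BLINK_GAMMA_SHAPE,
                            rate = BLINK_GAMMA_SHAPE)
      pp <- group_params(
        label = gp$label,
        p_facing_social = clamp(gp$p_facing_social + SD_P_FACING * u_s,
                                0.02, 0.999),
        p_facing_nonsocial = clamp(gp$p_facing_nonsocial +
                                     SD_P_FACING * u_ns, 0.02, 0.999),
        br_social = gp$br_social * bmul,
        br_nonsocial = gp$br_nonsocial * bmul,
        p_social_gaze = clamp(gp$p_social_gaze + SD_P_GAZE * u_g,
                              0.02, 0.98),
        dwell_mean_s = gp$dwell_mean_s,
        conf_low_rate = gp$conf_low_rate
      )
      age_i <- clamp(stats::rnorm(1, age[1], age[2]), 16, 38)
      p_boy <- switch(g, NT = 209 / 416, AUT = 32 / 43, LDDD = 0.6)
      sex_i <- if (stats::runif(1) < p_boy) "boy" else "girl"

      clin <- clinical_row(pid, g, u_s, u_ns, config$clinical_effects)

      if (generate_streams) {
        stream <- generate_session(pp, schedule,
                                   seed = derive_seed(dseed, 1L))
        if (keep_streams) {
          streams[[pid]] <- stream
        } else if (!is.null(stream_fun)) {
          stream_fun(pid, stream)
        }
      }
      manifest[[pid]] <- data.frame(participant_id = pid, group = g,
                                    age_months = round(age_i, 2),
                                    sex = sex_i, stringsAsFactors = FALSE)
      clinical[[pid]] <- clin
      params_tbl[[pid]] <- data.frame(
        participant_id = pid, group = g,
        p_facing_social = pp$p_facing_social,
        p_facing_nonsocial = pp$p_facing_nonsocial,
        br_social = pp$br_social, br_nonsocial = pp$br_nonsocial,
        p_social_gaze = pp$p_social_gaze, stringsAsFactors = FALSE)
    }
  }
  out <- list(manifest = do.call(rbind, manifest),
              clinical = do.call(rbind, clinical),
              params = do.call(rbind, params_tbl))
  rownames(out$manifest) <- rownames(out$clinical) <-
    rownames(out$params) <- NULL
  if (keep_streams) out$streams <- streams
  out
}

# clinical scores; only the autistic group receives non-missing values
clinical_row <- function(pid, group, u_s, u_ns, eff) {
  if (group != "AUT") {
    return(data.frame(participant_id = pid, ados_total = NA_real_,
                      ados_sa = NA_real_, ados_rrb = NA_real_,
                      mullen_elc = NA_real_, mullen_vr = NA_real_,
                      stringsAsFactors = FALSE))
  }
  sa <- clamp(7.6 + eff$ados_slope * (-u_s) + stats::rnorm(1, 0, 0.8),
              1, 10)
  total <- clamp(sa + stats::rnorm(1, 0, 0.7), 1, 10)
  rrb <- clamp(7 + stats::rnorm(1, 0, 1.5), 1, 10)
  elc <- 63.15 + eff$mullen_slope * (-u_ns) + stats::rnorm(1, 0, 4)
  vr <- 33.22 + 0.8 * eff$mullen_slope * (-u_ns) + stats::rnorm(1, 0, 5)
  data.frame(participant_id = pid, ados_total = round(total, 1),
             ados_sa = round(sa, 1), ados_rrb = round(rrb, 1),
             mullen_elc = round(elc, 1), mullen_vr = round(vr, 1),
             stringsAsFactors = FALSE)
}

#' Generate and extract a cohort in one pass
#'
#' Streams are generated one at a time, run through
#' [extract_participant()], and discarded, so full-size cohorts fit in
#' memory. Returns the analysis-ready cohort table (one row per
#' participant: group, age, sex, aggregate endpoints, per-movie TFF and
#' blink-rate columns, clinical scores).
#'
#' @inheritParams generate_cohort
#' @param ex_config an [extraction_config()].
#' @return List with `cohort` (the feature table), `manifest`, `clinical`
#'   and `params` as in [generate_cohort()].
#' @export
simulate_and_extract <- function(config = cohort_config(),
                                 schedule = default_schedule(),
                                 ex_config = extraction_config()) {
  rows <- list()
  gen <- generate_cohort(config, schedule, keep_streams = FALSE,
                         stream_fun = function(pid, stream) {
                           pf <- extract_participant(stream, schedule,
                                                     ex_config, pid)
                           rows[[pid]] <<- features_row(pf)
                         })
  feats <- do.call(rbind, rows)
  rownames(feats) <- NULL
  cohort <- merge(gen$manifest, feats, by = "participant_id", sort = FALSE)
  cohort <- merge(cohort, gen$clinical, by = "participant_id", sort = FALSE)
  cohort <- cohort[order(cohort$participant_id), ]
  rownames(cohort) <- NULL
  list(cohort = cohort, manifest = gen$manifest, clinical = gen$clinical,
       params = gen$params)
}

#' Fast feature-level cohort sampler
#'
#' Draws the per-participant aggregate endpoints directly from the
#' generator's marginal model -- facing probabilities jittered then
#' converted to TFF percentages with small measurement noise, blink rates
#' as gamma-scaled Poisson counts over the schedule's per-type valid time,
#' MGPS from jittered social-gaze probabilities with binomial gaze noise --
#' without synthesizing 30-fps streams. Used for large replicate studies
#' (test calibration, classifier seed sweeps) where the object of interest
#' is the downstream statistics, not the extractor.
#'
#' @param config a [cohort_config()].
#' @param schedule a [stimulus_schedule()] (sets per-type durations).
#' @return A cohort data frame with `participant_id`, `group`,
#'   `age_months`, the four aggregate endpoints, `mgps`, and the clinical
#'   columns (populated for the autistic group, generated from the same
#'   latent traits as the attention endpoints).
#' @export
simulate_feature_table <- function(config = cohort_config(),
                                   schedule = default_schedule()) {
  set.seed(config$seed)
  dur_social <- sum(schedule$duration_s[schedule$movie_type == "social"])
  dur_nonsocial <- sum(schedule$duration_s[schedule$movie_type ==
                                             "nonsocial"])
  dur_mixed <- sum(schedule$duration_s[schedule$movie_type == "mixed"])
  groups <- names(config$n_per_group)[config$n_per_group > 0]
  rows <- lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    gp <- config$group_params[[g]]
    age <- config$age_months[[g]]
    u_s <- stats::rnorm(n); u_ns <- stats::rnorm(n)
    p_s <- clamp(gp$p_facing_social + SD_P_FACING * u_s, 0.02, 0.999)
    p_ns <- clamp(gp$p_facing_nonsocial + SD_P_FACING * u_ns, 0.02, 0.999)
    tff_s <- clamp(100 * p_s + stats::rnorm(n, 0, 1.5), 0, 100)
    tff_ns <- clamp(100 * p_ns + stats::rnorm(n, 0, 1.5), 0, 100)
    bmul <- stats::rgamma(n, BLINK_GAMMA_SHAPE, BLINK_GAMMA_SHAPE)
    min_s <- pmax(p_s * dur_social / 60, 1e-6)
    min_ns <- pmax(p_ns * dur_nonsocial / 60, 1e-6)
    br_s <- stats::rpois(n, gp$br_social * bmul * min_s) / min_s
    br_ns <- stats::rpois(n, gp$br_nonsocial * bmul * min_ns) / min_ns
    pg <- clamp(gp$p_social_gaze + SD_P_GAZE * stats::rnorm(n), 0.02, 0.98)
    n_gaze <- round(pmax(p_s, 0.05) * dur_mixed * attr(schedule, "fps"))
    mgps <- 100 * stats::rbinom(n, n_gaze, pg) / pmax(n_gaze, 1)
    eff <- config$clinical_effects
    if (g == "AUT") {
      sa <- clamp(7.6 + eff$ados_slope * (-u_s) + stats::rnorm(n, 0, 0.8),
                  1, 10)
      clin <- data.frame(
        ados_total = round(clamp(sa + stats::rnorm(n, 0, 0.7), 1, 10), 1),
        ados_sa = round(sa, 1),
        ados_rrb = round(clamp(7 + stats::rnorm(n, 0, 1.5), 1, 10), 1),
        mullen_elc = round(63.15 + eff$mullen_slope * (-u_ns) +
                             stats::rnorm(n, 0, 4), 1),
        mullen_vr = round(33.22 + 0.8 * eff$mullen_slope * (-u_ns) +
                            stats::rnorm(n, 0, 5), 1))
    } else {
      clin <- data.frame(ados_total = rep(NA_real_, n), ados_sa = NA_real_,
                         ados_rrb = NA_real_, mullen_elc = NA_real_,
                         mullen_vr = NA_real_)
    }
    cbind(data.frame(
      participant_id = sprintf("%s%04d", g, seq_len(n)), group = g,
      age_months = round(clamp(stats::rnorm(n, age[1], age[2]), 16, 38), 2),
      mean_tff_social = tff_s, mean_tff_nonsocial = tff_ns,
      mean_br_social = br_s, mean_br_nonsocial = br_ns, mgps = mgps,
      stringsAsFactors = FALSE), clin)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
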