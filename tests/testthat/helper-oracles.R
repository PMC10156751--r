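# Independent brute-force oracles. These re-derive the expected behaviour
# from first principles with naive loops, deliberately sharing no code with
# the package implementation.

# naive centered moving average, shrunken edge windows
oracle_smooth <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1, t - h); hi <- min(n, t + h)
    out[t] <- mean(x[lo:hi])
  }
  out
}

# frame-by-frame facing-forward decision
oracle_facing <- function(stream, config) {
  n <- length(stream$yaw_deg)
  s <- oracle_smooth(stream$yaw_deg, config$yaw_smooth_window)
  out <- logical(n)
  for (t in seq_len(n)) {
    rapid <- FALSE
    if (t >= 2) {
      rapid <- abs(s[t]) >
        config$rapid_ratio * max(abs(s[t - 1]), config$rapid_eps_deg)
    }
    out[t] <- abs(stream$yaw_deg[t]) < config$yaw_threshold_deg &&
      stream$gaze_on_screen[t] && stream$eyes_open[t] && !rapid
  }
  out
}

# blink peaks: scan smoothed series for strict-rise/strict-fall local maxima
# (plateaus report their first frame, endpoints excluded), filter by height,
# then drop close peaks keeping the higher (ties: earlier)
oracle_blinks <- function(au45, config) {
  s <- oracle_smooth(au45, config$au45_smooth_window)
  n <- length(s)
  cand <- integer(0)
  for (t in 2:max(2, n - 1)) {
    if (n < 3) break
    if (s[t] <= s[t - 1]) next
    # walk the plateau forward
    u <- t
    while (u < n && s[u + 1] == s[t]) u <- u + 1
    if (u < n && s[u + 1] < s[t]) cand <- c(cand, t)
  }
  cand <- cand[s[cand] >= config$blink_min_height]
  keep <- integer(0)
  for (i in cand[order(-s[cand], cand)]) {
    if (length(keep) == 0 ||
        all(abs(i - keep) >= config$blink_min_separation)) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

# random short stream for oracle-equivalence checks
random_stream <- function(n) {
  frame_stream(
    yaw_deg = stats::runif(n, -60, 60),
    gaze_on_screen = stats::runif(n) < 0.8,
    eyes_open = stats::runif(n) < 0.9,
    au45 = pmax(0, stats::rnorm(n, 0.5, 1.2)),
    confidence = stats::runif(n),
    gaze_x_norm = stats::runif(n), fps = 30
  )
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
oracle_mwu_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  pool <- c(a, b)
  idx <- utils::combn(na + nb, na)
  us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exact two-sided Wilcoxon signed-rank p over all 2^n sign patterns
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  t_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ts <- as.vector(signs %*% rk)
  p_lo <- mean(ts <= t_obs); p_hi <- mean(ts >= t_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# independent mixed-ANOVA oracle: R's aov() with an Error() stratum for
# subjects (a general-linear-model projection, sharing no code with the
# package's closed-form decomposition)
oracle_mixed_anova <- function(long) {
  d <- long
  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$stimulus_type <- factor(d$stimulus_type, c("social", "nonsocial"))
  fit <- stats::aov(value ~ group * stimulus_type + Error(participant_id),
                    data = d)
  sm <- summary(fit)
  betw <- as.data.frame(sm[["Error: participant_id"]][[1]])
  with <- as.data.frame(sm[["Error: Within"]][[1]])
  pick <- function(tab, term) {
    i <- which(trimws(rownames(tab)) == term)
    err <- which(trimws(rownames(tab)) == "Residuals")
    ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[err, "Sum Sq"]
    data.frame(effect = term, F = tab[i, "F value"],
               df1 = tab[i, "Df"], df2 = tab[err, "Df"],
               p = tab[i, "Pr(>F)"], eta_p2 = ss_e / (ss_e + ss_r),
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(betw, "group"),
               pick(with, "stimulus_type"),
               pick(with, "group:stimulus_type"))
  rownames(out) <- NULL
  out
}

# small long-format dataset with random values (optionally unbalanced)
random_long <- function(n_nt, n_aut = n_nt, seed = 1) {
  set.seed(seed)
  n_per_group <- NULL
  ids <- sprintf("p%02d", seq_len(n_nt + n_aut))
  grp <- rep(c("NT", "AUT"), c(n_nt, n_aut))
  n <- n_nt + n_aut
  data.frame(
    participant_id = rep(ids, 2),
    group = rep(grp, 2),
    stimulus_type = rep(c("social", "nonsocial"), each = n),
    value = stats::rnorm(2 * n, 50, 10),
    stringsAsFactors = FALSE)
}
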