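#' Cohort statistics
#'
#' The group-comparison battery applied to a cohort table (one row per
#' participant with group label, age and the extracted attention
#' endpoints): a 2x2 mixed ANOVA (between factor group, within factor
#' stimulus type) with partial eta squared, within-group Wilcoxon
#' signed-rank and between-group Mann-Whitney U tests with rank-biserial
#' effect sizes, age-adjusted ANCOVA, per-movie comparisons, a
#' sensitivity subset restricted to high-TFF participants, Pearson
#' correlations with clinical scores, and demographic comparisons.
#' P-values are reported unadjusted throughout: the analysis battery
#' applies no multiple-testing correction, mirroring common practice for
#' this design, and documents that choice rather than hiding it.
#'
#' @name group_stats
NULL

#' Reshape a cohort table to long format for the mixed ANOVA
#'
#' @param cohort cohort data frame.
#' @param measure `"tff"` or `"br"`.
#' @return Long data frame with columns `participant_id`, `group`,
#'   `stimulus_type`, `value` (rows with missing values dropped).
#' @export
cohort_long <- function(cohort, measure = c("tff", "br")) {
  measure <- match.arg(measure)
  cols <- if (measure == "tff") {
    c(social = "mean_tff_social", nonsocial = "mean_tff_nonsocial")
  } else {
    c(social = "mean_br_social", nonsocial = "mean_br_nonsocial")
  }
  keep <- stats::complete.cases(cohort[, cols])
  sub <- cohort[keep, ]
  long <- data.frame(
    participant_id = rep(sub$participant_id, 2),
    group = rep(sub$group, 2),
    stimulus_type = rep(c("social", "nonsocial"), each = nrow(sub)),
    value = c(sub[[cols["social"]]], sub[[cols["nonsocial"]]]),
    stringsAsFactors = FALSE
  )
  long
}

#' Two-by-two mixed ANOVA
#'
#' One between-subject factor (group) and one within-subject factor
#' (stimulus type, two levels per participant, so sphericity is vacuous).
#' F statistics come from the standard mixed-design sums-of-squares
#' decomposition (between-subject stratum for group; within-subject
#' stratum, sequential, for stimulus type and the interaction); partial
#' eta squared is SS_effect / (SS_effect + SS_error) within each stratum.
#'
#' @param long data frame with columns `participant_id`, `group`,
#'   `stimulus_type`, `value`; every participant must contribute exactly
#'   one value per stimulus type.
#' @return An `ff_anova` data frame: one row per effect (`group`,
#'   `stimulus_type`, `group:stimulus_type`) with `F`, `df1`, `df2`, `p`,
#'   `eta_p2`.
#' @export
mixed_anova_2x2 <- function(long) {
  req <- c("participant_id", "group", "stimulus_type", "value")
  stopifnot(all(req %in% names(long)))
  counts <- table(long$participant_id)
  bad <- names(counts)[counts != 2L]
  tt <- table(long$participant_id, long$stimulus_type)
  bad <- union(bad, rownames(tt)[apply(tt != 1L, 1, any)])
  if (length(bad) > 0) {
    stop("participants without exactly one value per stimulus type: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (min(table(unique(long[, c("participant_id", "group")])$group)) < 2) {
    stop("need at least 2 participants per group")
  }
  soc <- long[long$stimulus_type == "social", ]
  non <- long[long$stimulus_type == "nonsocial", ]
  non <- non[match(soc$participant_id, non$participant_id), ]
  g <- factor(soc$group)
  N <- nrow(soc)
  # between-subject stratum: subject means (weight 2 per subject)
  m <- (soc$value + non$value) / 2
  fit_m <- tapply(m, g, mean)[g]
  ss_group <- 2 * sum((fit_m - mean(m))^2)
  ss_sub_err <- 2 * sum((m - fit_m)^2)
  # within-subject stratum on the unit-norm contrast (s - ns)/sqrt(2):
  # sequential decomposition, stimulus type before the interaction
  cv <- (soc$value - non$value) / sqrt(2)
  ss_type <- N * mean(cv)^2
  fit_c <- tapply(cv, g, mean)[g]
  ss_inter <- sum((fit_c - mean(cv))^2)
  ss_w_err <- sum((cv - fit_c)^2)
  df2 <- N - 2L
  frow <- function(effect, ss_e, ss_r) {
    # exact-zero guard: an absent effect reports F = 0, p = 1 rather than
    # a 0/0 ratio of rounding noise
    scale <- max(ss_e + ss_r, sum(long$value^2), .Machine$double.eps)
    if (ss_e <= 1e-12 * scale) {
      return(data.frame(effect = effect, F = 0, df1 = 1L, df2 = df2,
                        p = 1, eta_p2 = 0, stringsAsFactors = FALSE))
    }
    f <- if (ss_r <= 1e-12 * scale) Inf else (ss_e / 1) / (ss_r / df2)
    data.frame(effect = effect, F = f, df1 = 1L, df2 = df2,
               p = stats::pf(f, 1, df2, lower.tail = FALSE),
               eta_p2 = ss_e / (ss_e + ss_r), stringsAsFactors = FALSE)
  }
  out <- rbind(frow("group", ss_group, ss_sub_err),
               frow("stimulus_type", ss_type, ss_w_err),
               frow("group:stimulus_type", ss_inter, ss_w_err))
  rownames(out) <- NULL
  class(out) <- c("ff_anova", "data.frame")
  out
}

#' @export
print.ff_anova <- function(x, ...) {
  cat("2x2 mixed ANOVA\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s F(%d, %d) = %.2f, p = %.3g, eta_p^2 = %.3f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$eta_p2[i]))
  }
  invisible(x)
}

new_ff_test <- function(method, statistic, p, r, n) {
  structure(list(method = method, statistic = unname(statistic),
                 p = unname(p), r = unname(r), n = n),
            class = "ff_test")
}

#' @export
print.ff_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, r = %.3f (n = %s)\n",
              x$method, x$statistic, x$p, x$r,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Two-sided paired test. Zero differences are dropped (Wilcoxon's
#' original rule); the null is exact for up to 25 non-zero differences
#' without ties, otherwise a tie- and continuity-corrected normal
#' approximation is used. The effect size is the matched-pairs
#' rank-biserial correlation r = (T+ - T-) / (T+ + T-), computed on
#' midranks.
#'
#' @param x,y paired numeric vectors.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` selects by sample size and ties.
#' @return An `ff_test` with `statistic` (T+, the positive-rank sum), `p`,
#'   `r` and `n` (number of non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  dnz <- d[d != 0]
  n <- length(dnz)
  if (n == 0L) {
    return(new_ff_test("Wilcoxon signed-rank (degenerate)", 0, 1, 0, 0))
  }
  rk <- rank(abs(dnz))
  t_plus <- sum(rk[dnz > 0])
  t_minus <- sum(rk[dnz < 0])
  r <- (t_plus - t_minus) / (t_plus + t_minus)
  ties <- any(duplicated(abs(dnz)))
  if (is.null(exact)) exact <- n <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    dnz, alternative = "two.sided", mu = 0, exact = exact,
    correct = TRUE))
  method <- if (exact && !ties) "Wilcoxon signed-rank (exact)" else
    "Wilcoxon signed-rank (normal approximation)"
  new_ff_test(method, t_plus, wt$p.value, r, n)
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided test of two independent samples. The null is exact for
#' combined samples of at most 12 without ties, otherwise a tie- and
#' continuity-corrected normal approximation. U counts pairs where `a`
#' exceeds `b` (half-credit for ties); the rank-biserial effect size is
#' r = 1 - 2U / (n_a n_b), so r = 1 when every `a` is below every `b`.
#'
#' @param a,b numeric samples.
#' @param exact force exact/approximate; default selects by size and ties.
#' @return An `ff_test` with `statistic` (U), `p`, `r` and `n = c(n_a, n_b)`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty")
  }
  na <- length(a); nb <- length(b)
  if (length(unique(c(a, b))) == 1L) {
    # fully tied data: no ordering information
    return(new_ff_test("Mann-Whitney U (degenerate)", na * nb / 2, 1, 0,
                       c(na, nb)))
  }
  ties <- any(duplicated(c(a, b)))
  if (is.null(exact)) exact <- (na + nb) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  r <- 1 - 2 * u / (na * nb)
  method <- if (exact && !ties) "Mann-Whitney U (exact)" else
    "Mann-Whitney U (normal approximation)"
  new_ff_test(method, u, wt$p.value, r, c(na, nb))
}

#' One-way ANCOVA with a linear age covariate
#'
#' Tests the group effect on `value` adjusting for a linear `covariate`
#' term, via the nested-model F: RSS(value ~ covariate) against
#' RSS(value ~ covariate + group). A constant covariate triggers a warning
#' and reduces to the one-way ANOVA.
#'
#' @param value numeric response.
#' @param group group labels.
#' @param covariate numeric covariate (age in months).
#' @return An `ff_ancova` list with `F`, `df1`, `df2`, `p`, `n`.
#' @export
ancova_group <- function(value, group, covariate) {
  keep <- stats::complete.cases(value, group, covariate)
  value <- value[keep]; group <- factor(group[keep])
  covariate <- covariate[keep]
  if (any(table(group) < 3)) stop("need at least 3 participants per group")
  if (stats::var(covariate) == 0) {
    warning("constant covariate; reducing to one-way ANOVA")
    fit0 <- stats::lm(value ~ 1)
  } else {
    fit0 <- stats::lm(value ~ covariate)
  }
  fit1 <- stats::update(fit0, . ~ . + group)
  an <- stats::anova(fit0, fit1)
  structure(list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                 p = an$`Pr(>F)`[2], n = length(value)),
            class = "ff_ancova")
}

#' @export
print.ff_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA group effect: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$df1, x$df2, x$F, x$p, x$n))
  invisible(x)
}

#' Per-movie group comparisons
#'
#' Mann-Whitney U (NT vs AUT) for the TFF and blink rate of every
#' non-mixed movie, and for the TFF of the mixed movies where the columns
#' exist.
#'
#' @param cohort cohort data frame with per-movie `tff_*`/`br_*` columns.
#' @param schedule a [stimulus_schedule()].
#' @return Data frame with one row per (movie, measure): `movie`,
#'   `movie_type`, `measure`, `n_nt`, `n_aut`, `statistic`, `p`, `r`.
#' @export
per_movie_comparisons <- function(cohort, schedule = default_schedule()) {
  rows <- list()
  for (i in seq_len(nrow(schedule))) {
    slug <- movie_slug(schedule$name[i])
    measures <- if (schedule$movie_type[i] == "mixed") "tff" else
      c("tff", "br")
    for (m in measures) {
      col <- paste0(m, "_", slug)
      if (!col %in% names(cohort)) next
      a <- cohort[[col]][cohort$group == "NT"]
      b <- cohort[[col]][cohort$group == "AUT"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) == 0 || length(b) == 0) next
      tst <- mann_whitney_u(a, b)
      rows[[paste(slug, m)]] <- data.frame(
        movie = schedule$name[i], movie_type = schedule$movie_type[i],
        measure = m, n_nt = length(a), n_aut = length(b),
        statistic = tst$statistic, p = tst$p, r = tst$r,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' High-attention sensitivity subset
#'
#' Retains participants whose mean TFF across the analyzed (non-mixed)
#' movies exceeds the floor. The conventional floor of 0.80 on the
#' fractional scale corresponds to 80 TFF points.
#'
#' @param cohort cohort data frame.
#' @param tff_floor percent floor (default 80).
#' @param schedule a [stimulus_schedule()].
#' @return The filtered cohort; errors if no participant qualifies.
#' @export
sensitivity_subset <- function(cohort, tff_floor = 80,
                               schedule = default_schedule()) {
  slugs <- movie_slug(schedule$name[schedule$movie_type != "mixed"])
  cols <- intersect(paste0("tff_", slugs), names(cohort))
  if (length(cols) == 0) {
    # fall back to the aggregate endpoints when per-movie columns absent
    cols <- intersect(c("mean_tff_social", "mean_tff_nonsocial"),
                      names(cohort))
  }
  mean_tff <- rowMeans(cohort[, cols, drop = FALSE], na.rm = TRUE)
  keep <- !is.na(mean_tff) & mean_tff > tff_floor
  if (!any(keep)) {
    stop("no participant exceeds a mean TFF of ", tff_floor,
         "; lower the floor")
  }
  cohort[keep, , drop = FALSE]
}

ATTENTION_VARS <- c("mean_tff_social", "mean_tff_nonsocial",
                    "mean_br_social", "mean_br_nonsocial")
CLINICAL_VARS <- c("mullen_elc", "mullen_vr", "ados_rrb", "ados_sa",
                   "ados_total")

#' Pearson correlations between attention endpoints and clinical scores
#'
#' Computed on the autistic subset (clinical instruments are administered
#' to referred children only). Cells with a constant column or fewer than
#' 3 complete pairs are returned as missing with a warning.
#'
#' @param cohort cohort data frame containing clinical columns.
#' @param attention_vars,clinical_vars column sets to correlate.
#' @return Data frame with one row per (attention, clinical) pair: `r`,
#'   `p`, `n` and a `sig` star at p < 0.05.
#' @export
clinical_correlations <- function(cohort,
                                  attention_vars = ATTENTION_VARS,
                                  clinical_vars = CLINICAL_VARS) {
  sub <- cohort[cohort$group == "AUT", , drop = FALSE]
  rows <- list()
  for (av in attention_vars) {
    for (cv in clinical_vars) {
      if (!av %in% names(sub) || !cv %in% names(sub)) next
      ok <- stats::complete.cases(sub[[av]], sub[[cv]])
      n <- sum(ok)
      if (n < 3 || stats::var(sub[[av]][ok]) == 0 ||
          stats::var(sub[[cv]][ok]) == 0) {
        warning("correlation not estimable for ", av, " vs ", cv)
        rows[[paste(av, cv)]] <- data.frame(
          attention = av, clinical = cv, r = NA_real_, p = NA_real_,
          n = n, sig = "", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(sub[[av]][ok], sub[[cv]][ok],
                            method = "pearson")
      rows[[paste(av, cv)]] <- data.frame(
        attention = av, clinical = cv, r = unname(ct$estimate),
        p = ct$p.value, n = n,
        sig = if (ct$p.value < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demographic comparisons
#'
#' One-way ANOVA on age between groups and Pearson chi-square tests
#' (without continuity correction) on each categorical column. A warning
#' is attached when any expected cell count falls below 1.
#'
#' @param manifest data frame with `group`, `age_months` and categorical
#'   columns.
#' @param categorical columns to chi-square test (default `"sex"` if
#'   present).
#' @return Data frame with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p`, `note`.
#' @export
demographics_tests <- function(manifest, categorical = NULL) {
  if (is.null(categorical)) {
    categorical <- intersect("sex", names(manifest))
  }
  rows <- list()
  if ("age_months" %in% names(manifest)) {
    fit <- stats::aov(age_months ~ factor(group), data = manifest)
    tab <- summary(fit)[[1]]
    rows[["age"]] <- data.frame(
      variable = "age_months", test = "one-way ANOVA",
      statistic = tab[1, "F value"], df = tab[1, "Df"],
      p = tab[1, "Pr(>F)"], note = "", stringsAsFactors = FALSE)
  }
  for (cv in categorical) {
    tb <- table(manifest$group, manifest[[cv]])
    ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    note <- if (any(ct$expected < 1)) "expected cell count < 1" else ""
    rows[[cv]] <- data.frame(
      variable = cv, test = "Pearson chi-square",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p = ct$p.value, note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
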