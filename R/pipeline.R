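#' Pipeline runners
#'
#' `run_simulate()`, `run_extract()`, `run_analyze()` and `run_classify()`
#' chain the modules into a file-based pipeline (`run_all()` runs the four
#' stages); each stage reads and writes plain CSV/JSON under an output
#' directory, and every CSV carries a one-line provenance comment (tool
#' version, seed, configuration hash). A thin command-line wrapper around
#' these functions ships at `system.file("cli", "facefwd.R", package =
#' "facefwd")` with subcommands `simulate | extract | analyze | classify |
#' all`.
#'
#' @name pipeline
NULL

config_hash <- function(config) {
  fnv1a(paste(utils::capture.output(utils::str(config)), collapse = "\n"))
}

ensure_outdir <- function(dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory ", dir,
         " exists and is not empty; use force = TRUE to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  invisible(dir)
}

#' Simulate a cohort to disk
#'
#' Writes `streams/<participant_id>.csv` per session plus `manifest.csv`
#' and `clinical.csv`. Byte-identical across runs with equal
#' configuration.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param schedule a [stimulus_schedule()].
#' @param force overwrite a non-empty output directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), out_dir,
                         schedule = default_schedule(), force = FALSE) {
  ensure_outdir(out_dir, force)
  h <- config_hash(config)
  sdir <- file.path(out_dir, "streams")
  dir.create(sdir, showWarnings = FALSE)
  gen <- generate_cohort(config, schedule, keep_streams = FALSE,
                         stream_fun = function(pid, stream) {
                           write_frame_stream(
                             stream, file.path(sdir, paste0(pid, ".csv")),
                             seed = config$seed, config_hash = h)
                         })
  write_csv_prov(gen$manifest, file.path(out_dir, "manifest.csv"),
                 seed = config$seed, config_hash = h)
  write_csv_prov(gen$clinical, file.path(out_dir, "clinical.csv"),
                 seed = config$seed, config_hash = h)
  write_schedule_json(schedule, file.path(out_dir, "schedule.json"))
  invisible(out_dir)
}

#' Extract cohort features from a simulated/recorded session directory
#'
#' Expects `manifest.csv` and `streams/<id>.csv` under `in_dir`. Failures
#' on individual sessions are logged (message) and skipped, not fatal.
#'
#' @param in_dir directory produced by [run_simulate()] (or arranged the
#'   same way for recorded data).
#' @param out_file output cohort CSV path (default
#'   `<in_dir>/cohort.csv`).
#' @param schedule a [stimulus_schedule()]; when `in_dir` contains a
#'   `schedule.json` that file wins.
#' @param ex_config an [extraction_config()].
#' @return The cohort data frame, invisibly.
#' @export
run_extract <- function(in_dir, out_file = file.path(in_dir, "cohort.csv"),
                        schedule = default_schedule(),
                        ex_config = extraction_config()) {
  man_path <- file.path(in_dir, "manifest.csv")
  if (!file.exists(man_path)) stop("missing manifest: ", man_path)
  manifest <- read_csv_prov(man_path)
  sched_path <- file.path(in_dir, "schedule.json")
  if (file.exists(sched_path)) schedule <- read_schedule_json(sched_path)
  fps <- attr(schedule, "fps")
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$participant_id[i]
    path <- file.path(in_dir, "streams", paste0(pid, ".csv"))
    res <- tryCatch({
      stream <- read_frame_stream(path, fps = fps)
      features_row(extract_participant(stream, schedule, ex_config, pid))
    }, error = function(e) {
      message("skipping participant ", pid, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[pid]] <- res
  }
  if (length(rows) == 0) stop("no session could be extracted")
  feats <- do.call(rbind, rows)
  cohort <- merge(manifest, feats, by = "participant_id", sort = FALSE)
  clin_path <- file.path(in_dir, "clinical.csv")
  if (file.exists(clin_path)) {
    cohort <- merge(cohort, read_csv_prov(clin_path),
                    by = "participant_id", sort = FALSE)
  }
  cohort <- cohort[order(cohort$participant_id), ]
  rownames(cohort) <- NULL
  write_csv_prov(cohort, out_file, config_hash = config_hash(ex_config))
  invisible(cohort)
}

# round numerics for a stable JSON report
report_num <- function(x, digits = 6) {
  if (is.numeric(x)) round(x, digits) else x
}

test_block <- function(tst) {
  list(method = tst$method, statistic = report_num(tst$statistic),
       p = report_num(tst$p), r = report_num(tst$r), n = tst$n)
}

#' Run the group-statistics battery
#'
#' Computes, for both endpoints (TFF and blink rate): the 2x2 mixed
#' ANOVA, within-group Wilcoxon signed-rank tests (social vs nonsocial per
#' group), between-group Mann-Whitney tests (NT vs AUT per stimulus type),
#' age-adjusted ANCOVA per cell, per-movie comparisons, the TFF > 80
#' sensitivity re-run of the ANOVA, clinical Pearson correlations, and
#' demographic tests. Writes `analysis.json` plus tidy CSVs.
#'
#' @param cohort cohort data frame or path to a cohort CSV.
#' @param out_dir output directory.
#' @param schedule a [stimulus_schedule()].
#' @param tff_floor sensitivity-subset floor in TFF points (default 80).
#' @param force overwrite a non-empty output directory.
#' @return The report list, invisibly.
#' @export
run_analyze <- function(cohort, out_dir = NULL,
                        schedule = default_schedule(), tff_floor = 80,
                        force = FALSE) {
  if (is.character(cohort)) cohort <- read_csv_prov(cohort)
  if (length(unique(cohort$group)) < 2) {
    stop("need at least 2 groups to analyze")
  }
  report <- list()
  for (measure in c("tff", "br")) {
    long <- cohort_long(cohort, measure)
    an <- mixed_anova_2x2(long)
    cols <- if (measure == "tff") {
      c("mean_tff_social", "mean_tff_nonsocial")
    } else c("mean_br_social", "mean_br_nonsocial")
    cc <- cohort[stats::complete.cases(cohort[, cols]), ]
    within <- lapply(intersect(c("NT", "AUT"), unique(cc$group)),
                     function(g) {
      sub <- cc[cc$group == g, ]
      c(list(group = g,
             mean_social = report_num(mean(sub[[cols[1]]])),
             mean_nonsocial = report_num(mean(sub[[cols[2]]]))),
        test_block(wilcoxon_signed_rank(sub[[cols[1]]], sub[[cols[2]]])))
    })
    between <- lapply(seq_along(cols), function(k) {
      c(list(stimulus_type = c("social", "nonsocial")[k]),
        test_block(mann_whitney_u(cc[[cols[k]]][cc$group == "NT"],
                                  cc[[cols[k]]][cc$group == "AUT"])))
    })
    ancova <- lapply(seq_along(cols), function(k) {
      a <- ancova_group(cc[[cols[k]]], cc$group, cc$age_months)
      list(stimulus_type = c("social", "nonsocial")[k],
           F = report_num(a$F), df1 = a$df1, df2 = a$df2,
           p = report_num(a$p), n = a$n)
    })
    report[[measure]] <- list(
      anova = lapply(seq_len(nrow(an)), function(i) {
        list(effect = an$effect[i], F = report_num(an$F[i]),
             df1 = an$df1[i], df2 = an$df2[i], p = report_num(an$p[i]),
             eta_p2 = report_num(an$eta_p2[i]))
      }),
      within_group = within, between_group = between, ancova = ancova,
      n = nrow(cc))
  }
  pm <- per_movie_comparisons(cohort, schedule)
  report$per_movie <- pm
  sens <- tryCatch(sensitivity_subset(cohort, tff_floor, schedule),
                   error = function(e) NULL)
  if (!is.null(sens) && length(unique(sens$group)) >= 2 &&
      min(table(sens$group)) >= 2) {
    report$sensitivity <- list(
      tff_floor = tff_floor,
      n_retained = as.list(table(sens$group)),
      tff_anova = lapply(seq_len(3), function(i) {
        an <- mixed_anova_2x2(cohort_long(sens, "tff"))
        list(effect = an$effect[i], F = report_num(an$F[i]),
             p = report_num(an$p[i]), eta_p2 = report_num(an$eta_p2[i]))
      }))
  }
  if (any(!is.na(cohort$ados_sa %||% NA))) {
    report$clinical <- clinical_correlations(cohort)
  }
  report$demographics <- demographics_tests(cohort)
  ok <- stats::complete.cases(cohort$mean_tff_social,
                              cohort$mean_br_social)
  report$tff_br_correlation <- report_num(
    stats::cor(cohort$mean_tff_social[ok], cohort$mean_br_social[ok]))

  if (!is.null(out_dir)) {
    ensure_outdir(out_dir, force)
    jsonlite::write_json(report, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    if (!is.null(pm)) write_csv_prov(pm, file.path(out_dir,
                                                   "per_movie.csv"))
    if (!is.null(report$clinical)) {
      write_csv_prov(report$clinical,
                     file.path(out_dir, "clinical_correlations.csv"))
    }
    write_csv_prov(report$demographics,
                   file.path(out_dir, "demographics.csv"))
  }
  invisible(report)
}

#' Run the classifier stage
#'
#' Evaluates the four feature subsets and writes `roc_summary.json`,
#' per-subset ROC point CSVs and the pooled out-of-fold scores.
#'
#' @param cohort cohort data frame or path to a cohort CSV.
#' @param out_dir output directory (optional).
#' @param force overwrite a non-empty output directory.
#' @return The [compare_feature_sets()] result, invisibly.
#' @export
run_classify <- function(cohort, out_dir = NULL, force = FALSE) {
  if (is.character(cohort)) cohort <- read_csv_prov(cohort)
  res <- compare_feature_sets(cohort)
  if (!is.null(out_dir)) {
    ensure_outdir(out_dir, force)
    jsonlite::write_json(
      lapply(seq_len(nrow(res$table)), function(i) {
        list(subset = res$table$subset[i],
             features = res$table$features[i],
             n_pos = res$table$n_pos[i], n_neg = res$table$n_neg[i],
             auc = report_num(res$table$auc[i]),
             ci_lo = report_num(res$table$ci_lo[i]),
             ci_hi = report_num(res$table$ci_hi[i]))
      }),
      file.path(out_dir, "roc_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (s in names(res$rocs)) {
      write_csv_prov(res$rocs[[s]]$roc_points,
                     file.path(out_dir, paste0("roc_points_", s, ".csv")))
    }
    sc <- data.frame(group = res$rocs$D$labels,
                     score_D = round(res$rocs$D$scores, 6))
    write_csv_prov(sc, file.path(out_dir, "scores.csv"))
  }
  invisible(res)
}

#' Run the full pipeline
#'
#' simulate -> extract -> analyze -> classify under one output directory
#' (`streams/`, `cohort.csv`, `analysis/`, `classify/`). Fully
#' deterministic for a fixed configuration seed.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param schedule a [stimulus_schedule()].
#' @param ex_config an [extraction_config()].
#' @param force overwrite a non-empty output directory.
#' @return List with `cohort`, `analysis`, `classify`, invisibly.
#' @export
run_all <- function(config = cohort_config(), out_dir,
                    schedule = default_schedule(),
                    ex_config = extraction_config(), force = FALSE) {
  ensure_outdir(out_dir, force)
  run_simulate(config, out_dir, schedule, force = TRUE)
  cohort <- run_extract(in_dir = out_dir, schedule = schedule,
                        ex_config = ex_config)
  analysis <- run_analyze(cohort, file.path(out_dir, "analysis"),
                          schedule, force = TRUE)
  classify <- run_classify(cohort, file.path(out_dir, "classify"),
                           force = TRUE)
  invisible(list(cohort = cohort, analysis = analysis,
                 classify = classify))
}
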