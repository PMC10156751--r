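#' Classification of diagnostic group from attention features
#'
#' A linear logistic classifier on subsets of the three attention
#' endpoints (mean social TFF, mean social blink rate, MGPS), evaluated by
#' leave-one-out cross-validation with the out-of-fold scores pooled into
#' a single ROC curve. A small fixed L2 (ridge) penalty keeps the fit
#' finite under complete separation; features are z-scored with
#' training-fold statistics only. The AUC confidence interval uses the
#' Hanley-McNeil standard error.
#'
#' @name classification
NULL

# fixed ridge penalty on standardized coefficients (not the intercept);
# an unpenalized fit diverges under separation
RIDGE_LAMBDA <- 1.0

# ridge-penalized logistic regression by iteratively reweighted least
# squares; X excludes the intercept column
ridge_logistic_fit <- function(X, y, lambda = RIDGE_LAMBDA,
                               max_iter = 100, tol = 1e-9) {
  X1 <- cbind(1, X)
  k <- ncol(X1)
  pen <- diag(c(0, rep(lambda, k - 1)), nrow = k)
  beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X1, X1 * w) + pen
    g <- crossprod(X1, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Leave-one-out cross-validated classifier scores
#'
#' For each participant, fits the ridge-penalized logistic regression on
#' all other participants (features standardized using the training fold's
#' mean and standard deviation only) and scores the held-out participant.
#' Deterministic given the data.
#'
#' The returned score is the logistic transform of the discriminant (the
#' standardized linear predictor excluding the fold intercept). The
#' intercept is deliberately dropped from pooled scores: it tracks the
#' training fold's class prevalence, which differs by exactly one case
#' between folds holding out a case versus a control, so with weak
#' features the pooled ranking would encode the held-out label itself and
#' drive null AUC far below 0.5. Scores are therefore rankings, not
#' calibrated probabilities.
#'
#' @param X numeric feature matrix (rows = participants).
#' @param labels group labels; `positive` is coded 1.
#' @param positive positive-class label (default `"AUT"`).
#' @param lambda ridge penalty (default 1).
#' @return Numeric vector of out-of-fold scores in (0, 1).
#' @export
loocv_scores <- function(X, labels, positive = "AUT",
                         lambda = RIDGE_LAMBDA) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix must have no missing values")
  y <- as.integer(labels == positive)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 participants")
  if (length(unique(y)) < 2) stop("both classes must be present")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      stop("training fold ", i, " contains a single class")
    }
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    beta <- ridge_logistic_fit(Ztr, ytr, lambda)
    zi <- (X[i, ] - mu) / sdv
    scores[i] <- stats::plogis(sum(zi * beta[-1]))
  }
  scores
}

#' ROC curve and AUC
#'
#' The ROC is traced by sweeping a threshold over the unique scores; the
#' AUC uses the Mann-Whitney identity (concordant pairs, half credit for
#' ties), which equals the trapezoid area under the tie-grouped curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels group labels.
#' @param positive positive-class label (default `"AUT"`).
#' @return An `ff_roc` list: `scores`, `labels`, `roc_points` (data frame
#'   `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`, and a
#'   Hanley-McNeil `ci95`.
#' @export
roc_auc <- function(scores, labels, positive = "AUT") {
  y <- as.integer(labels == positive)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  rk <- rank(scores)  # midranks: half credit for ties
  auc <- (sum(rk[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- unique(pts)
  ci <- hanley_mcneil_ci(auc, n_pos, n_neg)
  structure(list(scores = scores, labels = labels, roc_points = pts,
                 auc = auc, n_pos = n_pos, n_neg = n_neg, ci95 = ci),
            class = "ff_roc")
}

#' @export
print.ff_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, 95%% CI [%.3f, %.3f] (pos = %d, neg = %d)\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.ff_roc <- function(x, ...) {
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "s",
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Hanley-McNeil 95% confidence interval for an AUC
#'
#' SE^2 = \[A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)\] /
#' (n_pos n_neg), with Q1 = A / (2 - A) and Q2 = 2 A^2 / (1 + A); the
#' interval is A +/- 1.96 SE, clipped to \[0, 1\].
#'
#' @param auc area under the curve in \[0, 1\].
#' @param n_pos,n_neg class sizes (>= 2).
#' @return Numeric `c(lower, upper)`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 2, n_neg >= 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se2 <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
            (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  se <- sqrt(max(se2, 0))
  c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
}

FEATURE_SETS <- list(
  A = "mean_tff_social",
  B = "mean_br_social",
  C = "mgps",
  D = c("mean_tff_social", "mean_br_social", "mgps")
)

#' Compare the four feature subsets
#'
#' Runs LOOCV scoring, ROC/AUC and the Hanley-McNeil CI for the four
#' feature subsets: A = mean social TFF, B = mean social blink rate,
#' C = MGPS, D = all three. Participants with any missing value in the
#' three features are dropped so every subset is evaluated on the same
#' sample.
#'
#' @param cohort cohort data frame with the three feature columns and a
#'   `group` column restricted (or restrictable) to NT vs AUT.
#' @param lambda ridge penalty (default 1).
#' @return An `ff_rocset`: list with `table` (subset, features, n_pos,
#'   n_neg, auc, ci_lo, ci_hi), `rocs` (named list of `ff_roc`), `n`.
#' @export
compare_feature_sets <- function(cohort, lambda = RIDGE_LAMBDA) {
  feats <- unique(unlist(FEATURE_SETS))
  missing_cols <- setdiff(c(feats, "group"), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sub <- cohort[cohort$group %in% c("NT", "AUT"), , drop = FALSE]
  sub <- sub[stats::complete.cases(sub[, feats]), , drop = FALSE]
  rocs <- list(); rows <- list()
  for (s in names(FEATURE_SETS)) {
    cols <- FEATURE_SETS[[s]]
    sc <- loocv_scores(as.matrix(sub[, cols, drop = FALSE]), sub$group,
                       positive = "AUT", lambda = lambda)
    roc <- roc_auc(sc, sub$group, positive = "AUT")
    rocs[[s]] <- roc
    rows[[s]] <- data.frame(
      subset = s, features = paste(cols, collapse = "+"),
      n_pos = roc$n_pos, n_neg = roc$n_neg, auc = roc$auc,
      ci_lo = roc$ci95[1], ci_hi = roc$ci95[2], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, rocs = rocs, n = nrow(sub)),
            class = "ff_rocset")
}

#' @export
print.ff_rocset <- function(x, ...) {
  cat(sprintf("LOOCV logistic ROC on %d participants\n", x$n))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %s (%s): AUC = %.3f [%.3f, %.3f]\n",
                x$table$subset[i], x$table$features[i], x$table$auc[i],
                x$table$ci_lo[i], x$table$ci_hi[i]))
  }
  invisible(x)
}
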