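# Train/test comparison of candidate training sets on one fixed held-out
# test set: accuracy, ROC/PR AUC, precision/recall/F1 at threshold 0.5,
# group-fairness gaps, and t-based confidence intervals over repeated runs.

.as01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  y <- as.integer(as.character(labels))
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  y
}

#' Threshold and ranking metrics for binary classification
#'
#' Accuracy, precision, recall and F1 at the decision threshold; ROC-AUC
#' by the trapezoid rule over the score ranking (ties handled by midranks)
#' and PR-AUC by step interpolation over distinct score thresholds. With
#' single-class labels the AUCs are reported as `NA` with a warning;
#' precision is `NA` when nothing is predicted positive.
#'
#' @param labels Binary 0/1 labels (factor or numeric).
#' @param scores Predicted positive-class probabilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector: `accuracy`, `precision`, `recall`, `f1`,
#'   `roc_auc`, `pr_auc`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  y <- .as01(labels)
  stopifnot(length(y) == length(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  acc <- (tp + tn) / length(y)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class labels: AUCs undefined", call. = FALSE)
    roc <- pr <- NA_real_
  } else {
    r <- rank(scores)
    roc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    o <- order(scores, decreasing = TRUE)
    ys <- y[o]
    s <- scores[o]
    tpc <- cumsum(ys)
    fpc <- cumsum(1 - ys)
    last <- c(s[-1] != s[-length(s)], TRUE)
    tpc <- tpc[last]
    fpc <- fpc[last]
    recall <- tpc / n1
    precis <- tpc / (tpc + fpc)
    pr <- sum(diff(c(0, recall)) * precis)
  }
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    roc_auc = roc, pr_auc = pr)
}

#' Group-fairness gaps
#'
#' Demographic-parity gap: max minus min of the per-group
#' positive-prediction rate. Equalized-odds gap: the worse of the TPR and
#' FPR across-group ranges; groups without positives (negatives) are
#' omitted from the TPR (FPR) part with a warning.
#'
#' @param labels Binary 0/1 labels.
#' @param predictions Binary 0/1 predictions (or logical).
#' @param groups Factor/character of protected-group membership.
#' @return Named vector `c(equalized_odds, demographic_parity)`.
#' @export
fairness_metrics <- function(labels, predictions, groups) {
  y <- .as01(labels)
  pred <- if (is.logical(predictions)) as.integer(predictions)
          else .as01(predictions)
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  pr <- tapply(pred, g, mean)
  dp <- max(pr) - min(pr)
  has_pos <- tapply(y, g, function(v) any(v == 1))
  has_neg <- tapply(y, g, function(v) any(v == 0))
  if (any(!has_pos))
    warning("group(s) without positives omitted from the TPR gap: ",
            paste(names(has_pos)[!has_pos], collapse = ", "), call. = FALSE)
  tpr <- tapply(seq_along(y), g, function(ix) {
    p <- y[ix] == 1
    if (!any(p)) NA_real_ else mean(pred[ix][p])
  })
  fpr <- tapply(seq_along(y), g, function(ix) {
    ng <- y[ix] == 0
    if (!any(ng)) NA_real_ else mean(pred[ix][ng])
  })
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else max(v) - min(v)
  }
  c(equalized_odds = max(rng(tpr), rng(fpr)),
    demographic_parity = unname(dp))
}

.t_ci <- function(x) {
  n <- length(x)
  m <- mean(x, na.rm = TRUE)
  if (n < 2) return(c(mean = m, ci_low = NA_real_, ci_high = NA_real_))
  s <- stats::sd(x, na.rm = TRUE)
  h <- stats::qt(0.975, n - 1) * s / sqrt(n)
  c(mean = m, ci_low = m - h, ci_high = m + h)
}

#' Evaluate candidate training datasets on a common test set
#'
#' Each candidate is either a fixed [bb_dataset()] or a generator
#' `function(seed)` returning one (so resampling ties and stochastic
#' preprocessing are reseeded per run). Per run, a Naive Bayes model is
#' trained on each candidate and scored on the same held-out test set;
#' means and t-based 95% confidence intervals are reported over runs.
#'
#' @param candidates Named list of datasets and/or generator functions.
#' @param test Held-out test [bb_dataset()]; never used for training.
#' @param target Target column (default: the test schema's).
#' @param n_runs Number of repeated runs (default 10; a single run yields
#'   means without CIs, with a warning).
#' @param seed Master integer seed; run r uses `seed + r`.
#' @param protected Optional protected column; when given, fairness gaps
#'   are computed on the test set predictions.
#' @param threshold Decision threshold (default 0.5).
#' @return Long data frame (`dataset`, `metric`, `mean`, `ci_low`,
#'   `ci_high`), class `bb_eval_report`.
#' @export
evaluate_candidates <- function(candidates, test, target = NULL,
                                n_runs = 10, seed = 1, protected = NULL,
                                threshold = 0.5) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  if (n_runs < 2)
    warning("fewer than two runs: confidence intervals unavailable",
            call. = FALSE)
  if (is.null(target)) target <- test$schema$target
  ylab <- test$data[[target]]
  g <- if (!is.null(protected)) test$data[[protected]]
  metric_names <- c("accuracy", "precision", "recall", "f1", "roc_auc",
                    "pr_auc",
                    if (!is.null(protected))
                      c("equalized_odds", "demographic_parity"))
  res <- array(NA_real_,
               dim = c(n_runs, length(candidates), length(metric_names)),
               dimnames = list(NULL, names(candidates), metric_names))
  for (r in seq_len(n_runs)) {
    rs <- seed + r
    for (cn in names(candidates)) {
      cand <- candidates[[cn]]
      ds <- if (is.function(cand)) cand(rs) else cand
      model <- train_nb(ds, target)
      p <- predict_proba(model, test)
      cm <- classification_metrics(ylab, p, threshold)
      res[r, cn, names(cm)] <- cm
      if (!is.null(protected)) {
        fm <- fairness_metrics(ylab, as.integer(p >= threshold), g)
        res[r, cn, names(fm)] <- fm
      }
    }
  }
  rows <- list()
  for (cn in names(candidates)) for (mn in metric_names) {
    ci <- .t_ci(res[, cn, mn])
    rows[[length(rows) + 1L]] <-
      data.frame(dataset = cn, metric = mn, mean = ci[["mean"]],
                 ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_runs") <- n_runs
  class(out) <- c("bb_eval_report", "data.frame")
  out
}

#' Fairness-driven alternative selection of uncertain cases
#'
#' Experimental reconstruction of selecting "uncertain" cases by a group
#' fairness gap instead of the probability interval: validation rows are
#' taken from the group(s) on the disadvantaged side of the chosen gap
#' (lowest TPR for equalized odds, lowest positive-prediction rate for
#' demographic parity), most-ambiguous first, capped at the number the
#' probability-interval filter would have selected. A zero-gap input
#' yields an empty selection with a warning.
#'
#' @param model A `bb_nb`.
#' @param validation A [bb_dataset()].
#' @param protected Protected column (default: the schema's).
#' @param metric `"equalized_odds"` or `"demographic_parity"`.
#' @param p1,p2 Interval used only to compute the selection cap.
#' @param threshold Decision threshold (default 0.5).
#' @return A [bb_dataset()] with role `"uncertain"` (possibly zero rows).
#' @export
fairness_uncertain_set <- function(model, validation, protected = NULL,
                                   metric = c("equalized_odds",
                                              "demographic_parity"),
                                   p1 = 0.4, p2 = 0.7, threshold = 0.5) {
  metric <- match.arg(metric)
  if (is.null(protected)) protected <- validation$schema$protected
  p <- predict_proba(model, validation)
  pred <- as.integer(p >= threshold)
  y <- .as01(validation$data[[model$target]])
  g <- droplevels(factor(validation$data[[protected]]))
  stat <- if (metric == "equalized_odds") {
    tapply(seq_along(y), g, function(ix) {
      pos <- y[ix] == 1
      if (!any(pos)) NA_real_ else mean(pred[ix][pos])
    })
  } else {
    tapply(pred, g, mean)
  }
  stat <- stat[!is.na(stat)]
  if (length(stat) < 2 || max(stat) - min(stat) <= 0) {
    warning("no disparity under ", metric, ": empty selection",
            call. = FALSE)
    return(subset_rows(validation, integer(0), role = "uncertain"))
  }
  worst <- names(stat)[stat == min(stat)]
  cap <- sum(p >= p1 & p <= p2)
  cand <- which(as.character(g) %in% worst)
  cand <- cand[order(abs(p[cand] - 0.5))]
  sel <- sort(utils::head(cand, cap))
  subset_rows(validation, sel, role = "uncertain")
}
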