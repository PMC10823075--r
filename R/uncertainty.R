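# Bias detection: a mixed-data Naive Bayes classifier, probability-interval
# uncertainty thresholds with optional quartile-mean calibration, and
# extraction of the uncertain set whose protected-attribute distribution is
# compared against the suspect data.

#' Uncertainty-analysis settings
#'
#' @param p1,p2 Lower/upper probability thresholds of the uncertain band
#'   (defaults 0.4 and 0.7); the band is closed at both ends and applies to
#'   the predicted probability of the positive class.
#' @param n_calibration_repeats Repeated classifications used when
#'   recalibrating the thresholds (default 10).
#' @param p1_interval,p2_interval Half-open `(low, high]` probability
#'   intervals whose mean predicted probability defines the recalibrated
#'   p1 and p2.
#' @param val_fraction Share of rows held out as the validation set in
#'   each calibration split and in the detection pipeline (default 0.3).
#' @return Object of class `bb_uncertainty_config`.
#' @export
uncertainty_config <- function(p1 = 0.4, p2 = 0.7,
                               n_calibration_repeats = 10,
                               p1_interval = c(0.25, 0.5),
                               p2_interval = c(0.5, 0.75),
                               val_fraction = 0.3) {
  stopifnot(p1 > 0, p1 < p2, p2 < 1, n_calibration_repeats >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(p1 = p1, p2 = p2,
                 n_calibration_repeats = as.integer(n_calibration_repeats),
                 p1_interval = p1_interval, p2_interval = p2_interval,
                 val_fraction = val_fraction),
            class = "bb_uncertainty_config")
}

#' Train a mixed-data Naive Bayes classifier
#'
#' Class priors are relative frequencies; categorical likelihoods are
#' Laplace-smoothed tables; numeric likelihoods are per-class Gaussians
#' with the variance floored at `1e-9`.
#'
#' @param dataset Training [bb_dataset()].
#' @param target Target column (default: the schema's target).
#' @param laplace_alpha Smoothing pseudo-count (default 1).
#' @return Object of class `bb_nb`.
#' @export
train_nb <- function(dataset, target = NULL, laplace_alpha = 1) {
  stopifnot(inherits(dataset, "bb_dataset"))
  sch <- dataset$schema
  if (is.null(target)) target <- sch$target
  if (is.null(target)) stop("no target variable", call. = FALSE)
  df <- dataset$data
  y <- factor(as.character(df[[target]]), levels = c("0", "1"))
  counts <- table(y)
  if (any(counts == 0))
    stop("training data contains a single class", call. = FALSE)
  features <- setdiff(names(df), target)
  tables <- list()
  moments <- list()
  for (v in features) {
    if (is.factor(df[[v]])) {
      tab <- table(df[[v]], y)
      k <- nrow(tab)
      lik <- sweep(tab + laplace_alpha, 2,
                   as.numeric(counts) + laplace_alpha * k, "/")
      tables[[v]] <- unclass(lik)
    } else {
      x <- df[[v]]
      mu <- tapply(x, y, mean)
      s2 <- pmax(tapply(x, y, stats::var), 1e-9)
      s2[is.na(s2)] <- 1e-9
      moments[[v]] <- rbind(mean = mu, var = s2)
    }
  }
  structure(list(prior = as.numeric(counts) / sum(counts),
                 counts = as.numeric(counts),
                 tables = tables, moments = moments,
                 alpha = laplace_alpha, target = target,
                 features = features),
            class = "bb_nb")
}

#' Predicted probability of the positive class
#'
#' Log-space accumulation of the Naive Bayes likelihoods. Levels unseen at
#' training time contribute the pure-alpha likelihood
#' `alpha / (n_class + alpha * k)` (logged once per variable).
#'
#' @param model A `bb_nb`.
#' @param newdata A [bb_dataset()] or data frame with the model's feature
#'   columns.
#' @return Numeric vector in \[0, 1\], one entry per row.
#' @export
predict_proba <- function(model, newdata) {
  df <- if (inherits(newdata, "bb_dataset")) newdata$data
        else as.data.frame(newdata)
  n <- nrow(df)
  ll0 <- rep(log(model$prior[1]), n)
  ll1 <- rep(log(model$prior[2]), n)
  for (v in model$features) {
    if (!v %in% names(df)) stop("missing feature '", v, "'", call. = FALSE)
    if (v %in% names(model$tables)) {
      tab <- model$tables[[v]]
      k <- nrow(tab)
      i <- match(as.character(df[[v]]), rownames(tab))
      if (anyNA(i))
        message("predict_proba: unseen level in '", v,
                "' treated as pure-alpha likelihood")
      fall <- model$alpha / (model$counts + model$alpha * k)
      l0 <- ifelse(is.na(i), fall[1], tab[i, 1])
      l1 <- ifelse(is.na(i), fall[2], tab[i, 2])
      ll0 <- ll0 + log(l0)
      ll1 <- ll1 + log(l1)
    } else {
      m <- model$moments[[v]]
      x <- as.numeric(df[[v]])
      ll0 <- ll0 + stats::dnorm(x, m["mean", 1], sqrt(m["var", 1]),
                                log = TRUE)
      ll1 <- ll1 + stats::dnorm(x, m["mean", 2], sqrt(m["var", 2]),
                                log = TRUE)
    }
  }
  stats::plogis(ll1 - ll0)
}

# mean predicted probability within a half-open (low, high] interval
.interval_mean <- function(p, interval) {
  sel <- p > interval[1] & p <= interval[2]
  if (!any(sel)) return(NA_real_)
  mean(p[sel])
}

#' Calibrate the uncertainty thresholds
#'
#' Repeats a stratified split / train / predict cycle; within each repeat,
#' p1 is the mean predicted positive-class probability over validation
#' cases falling in the lower quartile interval and p2 the mean over the
#' upper one; the per-repeat values are averaged. An interval empty in
#' every repeat falls back to the configured default with a warning.
#'
#' @param dataset A [bb_dataset()].
#' @param target,protected Column names (defaults: the schema's).
#' @param config An [uncertainty_config()].
#' @param seed Integer seed.
#' @return Named vector `c(p1, p2)`.
#' @export
calibrate_thresholds <- function(dataset, target = NULL, protected = NULL,
                                 config = uncertainty_config(), seed = 1) {
  sch <- dataset$schema
  if (is.null(target)) target <- sch$target
  if (is.null(protected)) protected <- sch$protected
  p1s <- p2s <- numeric(0)
  for (r in seq_len(config$n_calibration_repeats)) {
    sp <- stratified_split(dataset, protected, 1 - config$val_fraction,
                           seed = seed + r)
    model <- tryCatch(train_nb(sp$a, target),
                      error = function(e) NULL)
    if (is.null(model)) next
    p <- predict_proba(model, sp$b)
    p1s <- c(p1s, .interval_mean(p, config$p1_interval))
    p2s <- c(p2s, .interval_mean(p, config$p2_interval))
  }
  p1 <- mean(p1s, na.rm = TRUE)
  p2 <- mean(p2s, na.rm = TRUE)
  if (!is.finite(p1)) {
    warning("lower calibration interval empty in every repeat: ",
            "falling back to default p1", call. = FALSE)
    p1 <- config$p1
  }
  if (!is.finite(p2)) {
    warning("upper calibration interval empty in every repeat: ",
            "falling back to default p2", call. = FALSE)
    p2 <- config$p2
  }
  if (p1 >= p2) {
    warning("calibrated thresholds violate p1 < p2: falling back to ",
            "defaults", call. = FALSE)
    p1 <- config$p1
    p2 <- config$p2
  }
  c(p1 = p1, p2 = p2)
}

#' Extract the uncertain set
#'
#' Returns the validation rows whose predicted positive-class probability
#' lies in the closed interval \[p1, p2\]; original feature values are
#' retained and the per-row probabilities are attached as attribute
#' `"bb_probs"`.
#'
#' @param model A `bb_nb`.
#' @param validation A [bb_dataset()].
#' @param p1,p2 Thresholds with `p1 < p2`.
#' @return A [bb_dataset()] with role `"uncertain"`.
#' @export
extract_uncertain <- function(model, validation, p1 = 0.4, p2 = 0.7) {
  stopifnot(p1 < p2)
  p <- predict_proba(model, validation)
  keep <- which(p >= p1 & p <= p2)
  if (!length(keep))
    stop("no rows fall in [p1, p2]; widen the thresholds", call. = FALSE)
  out <- subset_rows(validation, keep, role = "uncertain")
  attr(out, "bb_probs") <- p[keep]
  out
}

#' Compare protected-group shares between a reference set and the
#' uncertain set
#'
#' A level is flagged as under-represented exactly when its share among
#' the uncertain cases exceeds its share in the reference data; levels
#' absent from both are omitted.
#'
#' @param reference Reference [bb_dataset()] (the data suspected of bias).
#' @param d_unc The uncertain set from [extract_uncertain()].
#' @param protected Column name (default: the schema's protected
#'   attribute).
#' @return Data frame with columns `level`, `reference_share`,
#'   `uncertain_share`, `flagged`.
#' @export
representation_report <- function(reference, d_unc, protected = NULL) {
  if (is.null(protected)) protected <- reference$schema$protected
  lev <- schema_levels(reference$schema, protected)
  rs <- table(factor(reference$data[[protected]], levels = lev))
  us <- table(factor(d_unc$data[[protected]], levels = lev))
  keep <- as.numeric(rs) + as.numeric(us) > 0
  ref_share <- as.numeric(rs) / sum(rs)
  unc_share <- as.numeric(us) / sum(us)
  out <- data.frame(level = lev,
                    reference_share = ref_share,
                    uncertain_share = unc_share,
                    flagged = unc_share > ref_share,
                    stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  class(out) <- c("bb_representation", "data.frame")
  out
}
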