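# Quantile discretization and its inverse. The Bayesian-network machinery is
# fully discrete, so numeric variables are binned before any network step and
# inverted by uniform-within-bin sampling afterwards.

.bin_label <- function(low, high, last) {
  f <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  sprintf(if (last) "[%s,%s]" else "[%s,%s)", f(low), f(high))
}

.parse_bin_label <- function(labels) {
  m <- regmatches(labels,
                  regexec("^\\[([^,]+),([^])]+)[])]$", labels))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("malformed bin label: ", labels[which(bad)[1]], call. = FALSE)
  data.frame(label = labels,
             low = as.numeric(vapply(m, `[`, character(1), 2)),
             high = as.numeric(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Discretize numeric variables into quantile bins
#'
#' Each numeric variable is replaced by a categorical variable whose levels
#' are empirical-quantile bins; a binning map is returned so the operation
#' can be inverted by [undiscretize()]. Constant columns collapse to a
#' single bin with a warning.
#'
#' @param dataset A [bb_dataset()].
#' @param n_bins Number of quantile bins per numeric variable (>= 2).
#' @return List with `dataset` (all-categorical [bb_dataset()]) and `map`
#'   (class `bb_binning`).
#' @export
discretize <- function(dataset, n_bins = 5) {
  stopifnot(inherits(dataset, "bb_dataset"), n_bins >= 2)
  sch <- dataset$schema
  num_vars <- variable_names(sch)[vapply(variable_names(sch),
                                         function(v) is_numeric_var(sch, v),
                                         logical(1))]
  map <- list()
  df <- dataset$data
  vars2 <- sch$variables
  for (v in num_vars) {
    x <- df[[v]]
    qs <- unique(as.numeric(stats::quantile(
      x, probs = seq(0, 1, length.out = n_bins + 1), type = 7,
      names = FALSE)))
    if (length(qs) < 2) {
      warning("numeric variable '", v,
              "' is constant: single-bin discretization", call. = FALSE)
      qs <- c(qs, qs)
    }
    low <- qs[-length(qs)]
    high <- qs[-1]
    nb <- length(low)
    labels <- vapply(seq_len(nb), function(i)
      .bin_label(low[i], high[i], i == nb), character(1))
    if (nb == 1) {
      f <- factor(rep(labels, length(x)), levels = labels)
    } else {
      f <- cut(x, breaks = qs, labels = labels, right = FALSE,
               include.lowest = TRUE)
    }
    df[[v]] <- f
    map[[v]] <- data.frame(label = labels, low = low, high = high,
                           stringsAsFactors = FALSE)
    vars2[[v]] <- labels
  }
  sch2 <- bb_schema(vars2, target = sch$target, protected = sch$protected)
  list(dataset = bb_dataset(df, sch2, role = dataset$role,
                            provenance = dataset$provenance),
       map = structure(map, class = "bb_binning"))
}

.undiscretize_impl <- function(dataset, map) {
  sch <- dataset$schema
  df <- dataset$data
  vars2 <- sch$variables
  for (v in names(map)) {
    b <- map[[v]]
    lab <- as.character(df[[v]])
    m <- match(lab, b$label)
    if (anyNA(m))
      stop("unknown bin label '", lab[which(is.na(m))[1]], "' in '", v, "'",
           call. = FALSE)
    width <- b$high[m] - b$low[m]
    df[[v]] <- b$low[m] + stats::runif(length(m)) * width
    vars2[[v]] <- "numeric"
  }
  sch2 <- bb_schema(vars2, target = sch$target, protected = sch$protected)
  bb_dataset(df, sch2, role = dataset$role, provenance = dataset$provenance)
}

#' Invert a quantile discretization
#'
#' Each binned cell is replaced by a value drawn uniformly within its bin's
#' real interval; deterministic under the seed.
#'
#' @param dataset A discrete [bb_dataset()] whose binned variables appear in
#'   `map`.
#' @param map A `bb_binning` from [discretize()].
#' @param seed Integer seed.
#' @return A [bb_dataset()] with those variables numeric again.
#' @export
undiscretize <- function(dataset, map, seed) {
  withr::with_seed(seed, .undiscretize_impl(dataset, map))
}

#' Distance between two empirical distributions
#'
#' Total variation distance for categorical columns (over the union of
#' observed levels), two-sample Kolmogorov-Smirnov statistic for numeric
#' columns; both lie in \[0, 1\].
#'
#' @param column_a,column_b Two columns of the same kind (factor/character
#'   or numeric).
#' @return A nonnegative scalar in \[0, 1\].
#' @export
distribution_distance <- function(column_a, column_b) {
  if (length(column_a) == 0 || length(column_b) == 0)
    stop("empty column", call. = FALSE)
  cat_a <- is.factor(column_a) || is.character(column_a)
  cat_b <- is.factor(column_b) || is.character(column_b)
  if (cat_a != cat_b)
    stop("columns must be of the same kind", call. = FALSE)
  if (cat_a) {
    a <- as.character(column_a)
    b <- as.character(column_b)
    lev <- union(unique(a), unique(b))
    p <- table(factor(a, levels = lev)) / length(a)
    q <- table(factor(b, levels = lev)) / length(b)
    0.5 * sum(abs(as.numeric(p) - as.numeric(q)))
  } else {
    unname(suppressWarnings(
      stats::ks.test(column_a, column_b)$statistic))
  }
}
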