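# exact Bayes posterior on a tiny all-categorical problem, enumerated by
# hand from the training counts (the oracle shares no code with the model)
enum_posterior <- function(df, target, newrow, alpha = 1) {
  y <- df[[target]]
  features <- setdiff(names(df), target)
  lik <- function(cls) {
    n_c <- sum(y == cls)
    p <- sum(y == cls) / length(y)
    for (v in features) {
      k <- nlevels(df[[v]])
      cnt <- sum(df[[v]] == newrow[[v]] & y == cls)
      p <- p * (cnt + alpha) / (n_c + alpha * k)
    }
    p
  }
  lik("1") / (lik("1") + lik("0"))
}

test_that("naive Bayes likelihoods follow the Laplace formula", {
  df <- data.frame(
    f = factor(rep(c("a", "b", "a", "b"), c(8, 2, 2, 8)),
               levels = c("a", "b")),
    y = factor(rep(c("1", "0"), c(10, 10)), levels = c("0", "1")))
  ds <- bb_dataset(df, bb_schema(list(f = c("a", "b"), y = c("0", "1")),
                                 target = "y"))
  m <- train_nb(ds)
  expect_equal(m$tables$f["a", "1"], 9 / 12)
  expect_equal(m$tables$f["a", "0"], 3 / 12)
  expect_error(train_nb(subset_rows(ds, 1:10)), "single class")
})

test_that("posteriors match exact enumeration to 1e-12", {
  withr::with_seed(61, {
    df <- data.frame(
      f1 = factor(sample(c("a", "b"), 60, TRUE)),
      f2 = factor(sample(c("u", "v", "w"), 60, TRUE)),
      y = factor(sample(c("0", "1"), 60, TRUE), levels = c("0", "1")))
  })
  sch <- bb_schema(list(f1 = c("a", "b"), f2 = c("u", "v", "w"),
                        y = c("0", "1")), target = "y")
  ds <- bb_dataset(df, sch)
  m <- train_nb(ds)
  p <- predict_proba(m, ds)
  for (i in c(1, 7, 23, 60))
    expect_equal(p[i], enum_posterior(df, "y", df[i, ]),
                 tolerance = 1e-12)
})

test_that("posterior is symmetric, monotone, and prior-reverting", {
  # feature independent of class: posterior equals the prior
  df <- data.frame(
    f = factor(rep(c("a", "b"), 50), levels = c("a", "b")),
    y = factor(rep(c("0", "1"), each = 50), levels = c("0", "1")))
  ds <- bb_dataset(df, bb_schema(list(f = c("a", "b"), y = c("0", "1")),
                                 target = "y"))
  m <- train_nb(ds)
  expect_equal(unique(round(predict_proba(m, ds), 12)), 0.5)
  # monotone in a numeric feature that favours class 1
  d2 <- toy_dataset(400, seed = 62)
  m2 <- train_nb(d2)
  grid <- data.frame(gender = "M", age = c(30, 50, 70), stroke = "0")
  p <- predict_proba(m2, grid)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("unseen prediction levels fall back to the pure-alpha
          likelihood", {
  df <- data.frame(
    f = factor(rep(c("a", "b"), c(12, 8)), levels = c("a", "b")),
    y = factor(rep(c("0", "1"), 10), levels = c("0", "1")))
  ds <- bb_dataset(df, bb_schema(list(f = c("a", "b"), y = c("0", "1")),
                                 target = "y"))
  m <- train_nb(ds)
  new <- data.frame(f = factor("c"), y = "0")
  expect_message(p <- predict_proba(m, new), "unseen level")
  # both classes get alpha/(n_c + alpha k) with equal n_c: prior returned
  expect_equal(p, 0.5, tolerance = 1e-12)
})

test_that("threshold calibration averages the quartile intervals", {
  expect_equal(bayesboost:::.interval_mean(c(0.3, 0.4, 0.6, 0.7),
                                           c(0.25, 0.5)), 0.35)
  expect_equal(bayesboost:::.interval_mean(c(0.3, 0.4, 0.6, 0.7),
                                           c(0.5, 0.75)), 0.65)
  # half-open: 0.25 excluded, 0.5 included below
  expect_equal(bayesboost:::.interval_mean(c(0.25, 0.5), c(0.25, 0.5)),
               0.5)
  expect_true(is.na(bayesboost:::.interval_mean(c(0.9), c(0.25, 0.5))))
  # uniform probabilities average to the interval midpoints
  withr::with_seed(63, u <- runif(20000))
  expect_equal(bayesboost:::.interval_mean(u, c(0.25, 0.5)), 0.375,
               tolerance = 0.01)
  expect_equal(bayesboost:::.interval_mean(u, c(0.5, 0.75)), 0.625,
               tolerance = 0.01)
})

test_that("calibrate_thresholds returns an ordered pair or falls back", {
  d <- toy_dataset(600, seed = 64)
  thr <- calibrate_thresholds(d, config = uncertainty_config(
    n_calibration_repeats = 3), seed = 65)
  expect_true(thr[["p1"]] < thr[["p2"]])
  expect_true(thr[["p1"]] > 0.25 && thr[["p1"]] <= 0.5)
  expect_true(thr[["p2"]] > 0.5 && thr[["p2"]] <= 0.75)
})

test_that("extract_uncertain keeps the closed probability band", {
  d <- toy_dataset(300, seed = 66)
  m <- train_nb(d)
  p <- predict_proba(m, d)
  unc <- extract_uncertain(m, d, 0.1, 0.9)
  expect_identical(nrow(unc$data), sum(p >= 0.1 & p <= 0.9))
  expect_true(all(attr(unc, "bb_probs") >= 0.1 &
                    attr(unc, "bb_probs") <= 0.9))
  # full interval is the identity
  all_rows <- extract_uncertain(m, d, 0, 1)
  expect_identical(nrow(all_rows$data), nrow(d$data))
  # boundary semantics on a synthetic probability vector
  probs <- c(0.1, 0.4, 0.55, 0.7, 0.9)
  keep <- probs >= 0.4 & probs <= 0.7
  expect_identical(which(keep), 2:4)
})

test_that("representation report flags excess uncertain share and is
          scale-free", {
  sch <- bb_schema(list(g = c("a", "b", "c"), y = c("0", "1")),
                   target = "y", protected = "g")
  ref <- bb_dataset(data.frame(
    g = rep(c("a", "b", "c"), c(90, 5, 5)), y = "0"), sch)
  unc <- bb_dataset(data.frame(
    g = rep(c("a", "b", "c"), c(80, 12, 8)), y = "0"), sch,
    role = "uncertain")
  rep1 <- representation_report(ref, unc)
  expect_identical(rep1$flagged, c(FALSE, TRUE, TRUE))
  expect_equal(rep1$uncertain_share[2], 0.12)
  # duplicating every row changes nothing
  ref2 <- subset_rows(ref, rep(seq_len(100), 2))
  unc2 <- subset_rows(unc, rep(seq_len(100), 2))
  expect_equal(representation_report(ref2, unc2), rep1)
  # identical distributions flag nothing
  rep3 <- representation_report(ref, retag(subset_rows(ref,
    seq_len(100)), "uncertain"))
  expect_false(any(rep3$flagged))
})

test_that("naive Bayes agrees with the reference implementation", {
  skip_if_not_installed("e1071")
  d <- toy_dataset(500, seed = 67)
  m <- train_nb(d)
  ref <- e1071::naiveBayes(stroke ~ gender + age, data = d$data,
                           laplace = 1)
  p_ref <- stats::predict(ref, d$data, type = "raw")[, "1"]
  p <- predict_proba(m, d)
  expect_equal(p, unname(p_ref), tolerance = 1e-6)
})
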