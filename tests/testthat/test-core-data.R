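test_that("schema validation rejects malformed declarations", {
  expect_error(bb_schema(list(a = c("x", "y"), b = "numeric"),
                         target = "a"), "levels \\{0, 1\\}")
  expect_error(bb_schema(list(a = c("0", "1")), protected = "missing"),
               "not a declared")
  expect_error(bb_schema(list(a = c("0", "1"), a = "numeric")),
               "unique|named")
})

test_that("dataset construction validates levels and target", {
  sch <- toy_schema()
  df <- data.frame(gender = c("M", "F", "X"), age = c(30, 40, 50),
                   stroke = c("0", "1", "0"))
  expect_error(bb_dataset(df, sch), "unknown level 'X' in column 'gender'")
  df$gender[3] <- "F"
  df$stroke[2] <- NA
  expect_error(bb_dataset(df, sch), "missing values in target")
})

test_that("CSV round trip preserves a dataset", {
  ds <- toy_dataset(100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  expect_identical(length(readLines(path)), 101L)
  back <- read_dataset(path, ds$schema)
  expect_equal(back$data$gender, ds$data$gender)
  expect_equal(back$data$age, ds$data$age, tolerance = 1e-12)
  expect_equal(back$data$stroke, ds$data$stroke)
})

test_that("provenance column round-trips only when requested", {
  ds <- toy_dataset(20)
  ds$provenance <- rep(c("original", "synthetic"), 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  expect_false("provenance" %in% names(utils::read.csv(path)))
  write_dataset(ds, path, include_provenance = TRUE)
  back <- read_dataset(path, ds$schema)
  expect_identical(back$provenance, ds$provenance)
})

test_that("stratified split hits round(fraction * count) per level", {
  lev <- c(rep("a", 500), rep("b", 300), rep("c", 200))
  ds <- bb_dataset(
    data.frame(g = lev, age = seq_len(1000), y = rep(c("0", "1"), 500)),
    bb_schema(list(g = c("a", "b", "c"), age = "numeric",
                   y = c("0", "1")), target = "y", protected = "g"))
  sp <- stratified_split(ds, "g", 0.3, seed = 1)
  expect_identical(as.vector(table(sp$a$data$g)), c(150L, 90L, 60L))
  expect_identical(nrow(sp$a$data) + nrow(sp$b$data), 1000L)
  sp2 <- stratified_split(ds, "g", 0.3, seed = 1)
  expect_identical(sp$a$data, sp2$a$data)
  # 70% train share on target strata, the standard experimental split
  sp3 <- stratified_split(ds, "y", 0.7, seed = 2)
  expect_identical(nrow(sp3$a$data), 700L)
})

test_that("discretize uses empirical quantile bins and round-trips", {
  x <- rep(20:79, length.out = 600)
  ds <- bb_dataset(
    data.frame(g = rep(c("a", "b"), 300), age = x,
               y = rep(c("0", "1"), 300)),
    bb_schema(list(g = c("a", "b"), age = "numeric", y = c("0", "1")),
              target = "y"))
  out <- discretize(ds, n_bins = 4)
  qs <- unname(stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1)))
  expect_equal(out$map$age$low, qs[1:4], tolerance = 1e-10)
  expect_equal(out$map$age$high, qs[2:5], tolerance = 1e-10)
  expect_identical(out$dataset$data$g, ds$data$g)  # categoricals untouched
  # round trip: every inverted value lands in its original bin
  inv <- undiscretize(out$dataset, out$map, seed = 9)
  redisc <- discretize(inv, n_bins = 4)
  m <- out$map$age
  bin_of <- function(v) findInterval(v, m$low, rightmost.closed = TRUE)
  expect_identical(bin_of(inv$data$age), bin_of(ds$data$age))
})

test_that("undiscretize is seeded uniform within bins", {
  sch <- bb_schema(list(x = "numeric", y = c("0", "1")), target = "y")
  ds <- bb_dataset(data.frame(x = runif(10000), y = "0"), sch)
  dd <- discretize(ds, n_bins = 2)
  a <- undiscretize(dd$dataset, dd$map, seed = 5)
  b <- undiscretize(dd$dataset, dd$map, seed = 5)
  expect_identical(a$data$x, b$data$x)
  m <- dd$map$x
  for (i in seq_len(nrow(m))) {
    inbin <- a$data$x[dd$dataset$data$x == m$label[i]]
    expect_true(all(inbin >= m$low[i] & inbin <= m$high[i]))
    mid <- (m$low[i] + m$high[i]) / 2
    tol <- 3 * (m$high[i] - m$low[i]) / sqrt(12 * length(inbin))
    expect_lt(abs(mean(inbin) - mid), tol)
  }
})

test_that("constant numeric columns collapse to a single bin", {
  sch <- bb_schema(list(x = "numeric", y = c("0", "1")), target = "y")
  ds <- bb_dataset(data.frame(x = rep(1.5, 10), y = "0"), sch)
  expect_warning(dd <- discretize(ds), "constant")
  expect_identical(nlevels(dd$dataset$data$x), 1L)
})

test_that("distribution distance matches hand-computed values", {
  a <- c(rep("x", 50), rep("y", 50))
  b <- c(rep("x", 90), rep("y", 10))
  expect_equal(distribution_distance(a, b), 0.4)
  expect_equal(distribution_distance(a, a), 0)
  expect_equal(distribution_distance(rep("x", 10), rep("y", 10)), 1)
  expect_error(distribution_distance(character(0), a), "empty")
  expect_error(distribution_distance(a, 1:10), "same kind")
  expect_gte(distribution_distance(rnorm(50), rnorm(50) + 10), 0.99)
})

test_that("categorical distance is symmetric and satisfies the triangle
          inequality on random triples", {
  withr::with_seed(11, {
    for (i in 1:20) {
      lev <- letters[1:4]
      a <- sample(lev, 60, replace = TRUE, prob = rgamma(4, 1))
      b <- sample(lev, 80, replace = TRUE, prob = rgamma(4, 1))
      c <- sample(lev, 50, replace = TRUE, prob = rgamma(4, 1))
      dab <- distribution_distance(a, b)
      expect_equal(dab, distribution_distance(b, a))
      expect_lte(dab,
                 distribution_distance(a, c) + distribution_distance(c, b)
                 + 1e-12)
    }
  })
})
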