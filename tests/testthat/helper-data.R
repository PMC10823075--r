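# Small in-code fixtures shared across the suite.

toy_schema <- function() {
  bb_schema(
    list(gender = c("M", "F"), age = "numeric", stroke = c("0", "1")),
    target = "stroke", protected = "gender")
}

toy_dataset <- function(n = 100, seed = 42) {
  withr::with_seed(seed, {
    gender <- sample(c("M", "F"), n, replace = TRUE)
    age <- round(runif(n, 20, 80), 1)
    p <- plogis(-3 + 0.05 * (age - 20) + ifelse(gender == "M", 0.5, 0))
    stroke <- as.character(rbinom(n, 1, p))
  })
  bb_dataset(data.frame(gender, age, stroke), toy_schema())
}

# hand-built A -> B oracle network, same parameters as the pinned fixture
toy_ab_bn <- function() {
  bayesboost:::new_bn(
    nodes = c("A", "B"),
    levels = list(A = c("0", "1"), B = c("0", "1")),
    parents = list(A = character(), B = "A"),
    cpts = list(
      A = array(c(0.7, 0.3), dim = 2, dimnames = list(c("0", "1"))),
      B = array(c(0.8, 0.2, 0.2, 0.8), dim = c(2, 2),
                dimnames = list(c("0", "1"), c("0", "1")))))
}

# random small discrete network over 3 binary/ternary variables
random_small_bn <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(2:3, 3, replace = TRUE)
    nodes <- c("X", "Y", "Z")
    levels <- lapply(k, function(ki) as.character(seq_len(ki) - 1))
    names(levels) <- nodes
    parents <- list(X = character(), Y = "X", Z = sample(list("Y", c("X", "Y")), 1)[[1]])
    cpts <- list()
    for (j in nodes) {
      q <- prod(vapply(parents[[j]], function(p) length(levels[[p]]),
                       integer(1)))
      if (!length(parents[[j]])) q <- 1
      kj <- length(levels[[j]])
      M <- matrix(rgamma(kj * q, 2) + 0.2, nrow = kj)
      M <- sweep(M, 2, colSums(M), "/")
      cpts[[j]] <- array(M, dim = c(kj, vapply(parents[[j]], function(p)
        length(levels[[p]]), integer(1))),
        dimnames = c(list(levels[[j]]), levels[parents[[j]]]))
    }
    bayesboost:::new_bn(nodes, levels, parents, cpts)
  })
}

expect_within_3se <- function(emp, exact, n) {
  se <- sqrt(exact * (1 - exact) / n)
  expect_lt(abs(emp - exact), 3 * se + 1e-12)
}
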