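# Independent oracle: score every DAG on 3 nodes with a from-scratch BIC
# implementation (counts via table(), no shared code path with the
# hill-climbing learner).
all_3node_dags <- function(nodes) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  dags <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    st <- c(s1, s2, s3)
    parents <- stats::setNames(rep(list(character()), 3), nodes)
    ok <- TRUE
    for (e in 1:3) {
      if (st[e] == 0) next
      p <- pairs[[e]]
      if (st[e] == 2) p <- rev(p)
      parents[[nodes[p[2]]]] <- c(parents[[nodes[p[2]]]], nodes[p[1]])
    }
    # reject the two 3-cycles
    ok <- !is.null(tryCatch(bayesboost:::.topo_order(nodes, parents),
                            error = function(e) NULL))
    if (ok) dags[[length(dags) + 1]] <- parents
  }
  dags
}

oracle_bic <- function(df, parents) {
  n <- nrow(df)
  tot <- 0
  for (j in names(parents)) {
    pa <- parents[[j]]
    if (!length(pa)) {
      tab <- table(df[[j]])
      ll <- sum(tab * log(tab / n))
      q <- 1
    } else {
      cfg <- interaction(df[pa], drop = FALSE)
      tab <- table(df[[j]], cfg)
      rowtot <- colSums(tab)
      ll <- sum(tab[tab > 0] *
                  log(tab[tab > 0] /
                        rep(rowtot, each = nrow(tab))[tab > 0]))
      q <- prod(vapply(df[pa], nlevels, integer(1)))
    }
    tot <- tot + ll - 0.5 * log(n) * (nlevels(df[[j]]) - 1) * q
  }
  tot
}

test_that("hill climbing recovers a strong chain and matches the
          exhaustive-search score on 3 nodes", {
  bn <- random_small_bn(1)
  # strong chain A -> B -> C
  chain <- bayesboost:::new_bn(
    nodes = c("A", "B", "C"),
    levels = list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")),
    parents = list(A = character(), B = "A", C = "B"),
    cpts = list(
      A = array(c(0.5, 0.5), 2, dimnames = list(c("0", "1"))),
      B = array(c(0.9, 0.1, 0.1, 0.9), c(2, 2),
                dimnames = list(c("0", "1"), c("0", "1"))),
      C = array(c(0.85, 0.15, 0.15, 0.85), c(2, 2),
                dimnames = list(c("0", "1"), c("0", "1")))))
  df <- logic_sample(chain, 5000, seed = 2)
  dag <- learn_structure(df)
  edges <- function(p) sort(unlist(lapply(names(p), function(j)
    paste(pmin(p[[j]], j), pmax(p[[j]], j)))))
  expect_identical(edges(dag$parents), c("A B", "B C"))
  # exhaustive oracle over all 25 acyclic 3-node graphs
  dags <- all_3node_dags(c("A", "B", "C"))
  expect_identical(length(dags), 25L)
  scores <- vapply(dags, function(p) oracle_bic(df, p), numeric(1))
  expect_equal(bic_score(df, dag), max(scores), tolerance = 1e-8)
  # same data, same result
  expect_identical(learn_structure(df)$parents, dag$parents)
})

test_that("independent columns yield an empty edge set and scores beat
          the empty graph", {
  df <- withr::with_seed(3, data.frame(
    a = factor(sample(c("0", "1"), 2000, TRUE)),
    b = factor(sample(c("x", "y", "z"), 2000, TRUE)),
    c = factor(sample(c("0", "1"), 2000, TRUE))))
  dag <- learn_structure(df)
  expect_identical(sum(lengths(dag$parents)), 0L)
  # score consistency: any learned DAG never scores below the empty DAG
  bn <- random_small_bn(4)
  s <- logic_sample(bn, 1500, seed = 5)
  d2 <- learn_structure(s)
  empty <- bayesboost:::new_dag(names(s),
    stats::setNames(rep(list(character()), 3), names(s)))
  expect_gte(bic_score(s, d2), bic_score(s, empty))
})

test_that("roots constraint forbids incoming edges", {
  chain <- toy_ab_bn()
  df <- logic_sample(chain, 4000, seed = 6)
  dag <- learn_structure(df, roots = "B")
  expect_identical(dag$parents$B, character(0))
  # dependence still representable in the allowed direction
  expect_identical(dag$parents$A, "B")
})

test_that("parameter fitting applies the Laplace formula", {
  df <- data.frame(a = factor(rep(c("0", "1"), c(70, 30)),
                              levels = c("0", "1")))
  dag <- bayesboost:::new_dag("a", list(a = character()))
  bn0 <- fit_parameters(df, dag, laplace_alpha = 0)
  expect_equal(as.numeric(bn0$cpts$a), c(0.70, 0.30))
  df2 <- data.frame(
    p = factor(rep(c("u", "v"), c(10, 0)), levels = c("u", "v")),
    x = factor(rep(c("a", "b"), c(8, 2)), levels = c("a", "b")))
  dag2 <- bayesboost:::new_dag(c("p", "x"),
                               list(p = character(), x = "p"))
  bn1 <- fit_parameters(df2, dag2, laplace_alpha = 1)
  expect_equal(bn1$cpts$x[, "u"], c(a = 9 / 12, b = 3 / 12))
  expect_equal(bn1$cpts$x[, "v"], c(a = 0.5, b = 0.5))  # unseen config
})

test_that("logic sampling matches exact marginals on the toy network", {
  bn <- toy_ab_bn()
  expect_equal(exact_marginal(bn, "B"),
               c("0" = 0.62, "1" = 0.38), tolerance = 1e-12)
  s <- logic_sample(bn, 50000, seed = 7)
  expect_within_3se(mean(s$B == "1"), 0.38, 50000)
  expect_identical(nrow(logic_sample(bn, 1, seed = 8)), 1L)
  # degenerate one-hot CPTs give constant samples
  det <- override_cpt(override_cpt(bn, "A", c(0, 1)), "B", c(1, 0))
  sdet <- logic_sample(det, 20, seed = 9)
  expect_true(all(sdet$A == "1" & sdet$B == "0"))
})

test_that("evidence sampling follows the Bayes-rule conditional", {
  bn <- toy_ab_bn()
  exact <- 0.24 / 0.38  # P(A=1 | B=1)
  s <- sample_with_evidence(bn, list(B = "1"), 50000, seed = 10)
  expect_true(all(s$B == "1"))
  expect_within_3se(mean(s$A == "1"), exact, 50000)
  # full conditioning returns the evidence verbatim
  sf <- sample_with_evidence(bn, list(A = "0", B = "1"), 50, seed = 11)
  expect_true(all(sf$A == "0" & sf$B == "1"))
  # root evidence equals forward sampling from the clamped network
  sr <- sample_with_evidence(bn, list(A = "1"), 50000, seed = 12)
  expect_within_3se(mean(sr$B == "1"), 0.8, 50000)
  # contradictory evidence errors with the assignment named
  imp <- override_cpt(bn, "A", c(1, 0))
  expect_error(sample_with_evidence(imp, list(A = "1"), 10, seed = 13),
               "zero likelihood.*A=1")
})

test_that("samplers agree with enumeration on random small networks", {
  for (seed in c(21, 22, 23)) {
    bn <- random_small_bn(seed)
    s <- logic_sample(bn, 20000, seed = seed + 100)
    for (v in bn$nodes) {
      ex <- exact_marginal(bn, v)
      for (l in names(ex))
        expect_within_3se(mean(s[[v]] == l), ex[[l]], 20000)
    }
    ev <- stats::setNames(list(bn$levels$Z[1]), "Z")
    exA <- exact_marginal(bn, "X", evidence = ev)
    se <- sample_with_evidence(bn, ev, 20000, seed = seed + 200)
    for (l in names(exA))
      expect_within_3se(mean(se$X == l), exA[[l]], 20000)
  }
})

test_that("CPT override fixes the marginal for every parent
          configuration", {
  bn <- random_small_bn(31)
  d <- c(0.3, rep(0.7 / (length(bn$levels$Y) - 1),
                  length(bn$levels$Y) - 1))
  bn2 <- override_cpt(bn, "Y", d)
  ex <- exact_marginal(bn2, "Y")
  expect_equal(unname(ex), d, tolerance = 1e-9)
  expect_error(override_cpt(bn, "Y", c(0.5, 0.6)), "sum")
  # identity override leaves the distribution unchanged
  bn3 <- override_cpt(toy_ab_bn(), "A", c(0.7, 0.3))
  expect_equal(exact_marginal(bn3, "B"), c("0" = 0.62, "1" = 0.38),
               tolerance = 1e-12)
})

test_that("every CPT row sums to one and YAML round-trips a network", {
  bn <- random_small_bn(41)
  for (j in bn$nodes) {
    M <- matrix(as.numeric(bn$cpts[[j]]), nrow = length(bn$levels[[j]]))
    expect_equal(colSums(M), rep(1, ncol(M)), tolerance = 1e-9)
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  bn_write_yaml(bn, path)
  back <- bn_read_yaml(path)
  expect_identical(back$nodes, bn$nodes)
  expect_identical(back$parents, bn$parents)
  for (j in bn$nodes)
    expect_equal(as.numeric(back$cpts[[j]]), as.numeric(bn$cpts[[j]]),
                 tolerance = 1e-10)
})

test_that("exact_marginal guards its preconditions", {
  bn <- toy_ab_bn()
  expect_equal(sum(exact_marginal(bn, "B")), 1)
  ex <- exact_marginal(bn, "B", evidence = list(A = "1", B = "0"))
  expect_equal(unname(ex), c(1, 0))
})
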