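# Discrete Bayesian networks: structure learning (greedy hill climbing over
# add/remove/reverse moves, BIC score), Laplace-smoothed parameter fitting,
# logic (ancestral) sampling, likelihood-weighted evidence sampling, exact
# enumeration for test oracles, and YAML serialization.

new_dag <- function(nodes, parents) {
  parents <- lapply(parents, function(p) p[order(match(p, nodes))])
  structure(list(nodes = nodes, parents = parents), class = "bb_dag")
}

#' @export
print.bb_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat("<bb_dag> ", length(x$nodes), " nodes, ", ne, " edges\n", sep = "")
  for (j in x$nodes)
    if (length(x$parents[[j]]))
      cat("  ", paste(x$parents[[j]], collapse = ","), " -> ", j, "\n",
          sep = "")
  invisible(x)
}

# directed path from -> to following parent->child edges
.has_path <- function(from, to, parents) {
  nodes <- names(parents)
  children <- lapply(nodes, function(v)
    nodes[vapply(nodes, function(w) v %in% parents[[w]], logical(1))])
  names(children) <- nodes
  seen <- character()
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    if (to %in% nxt) return(TRUE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

.topo_order <- function(nodes, parents) {
  remaining <- nodes
  ord <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      !any(parents[[v]] %in% remaining), logical(1))]
    if (!length(ready)) stop("graph is cyclic", call. = FALSE)
    ord <- c(ord, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  ord
}

# accept a discrete bb_dataset or a data.frame of factors
as_factor_frame <- function(data) {
  if (inherits(data, "bb_dataset")) {
    sch <- data$schema
    num <- vapply(variable_names(sch), function(v) is_numeric_var(sch, v),
                  logical(1))
    if (any(num))
      stop("dataset has numeric variables; discretize() first",
           call. = FALSE)
    return(data$data)
  }
  df <- as.data.frame(data)
  for (v in names(df))
    if (!is.factor(df[[v]])) df[[v]] <- factor(df[[v]])
  df
}

.int_matrix <- function(df) {
  X <- vapply(df, as.integer, integer(nrow(df)))
  if (is.null(dim(X))) X <- matrix(X, nrow = nrow(df))
  colnames(X) <- names(df)
  levels <- lapply(df, levels)
  list(X = X, nlev = vapply(levels, length, integer(1)), levels = levels)
}

# linear parent-configuration index, first parent varying fastest
.config_index <- function(X, pa, nlev) {
  if (!length(pa)) return(rep(1L, nrow(X)))
  cfg <- X[, pa[1]] - 1L
  stride <- nlev[[pa[1]]]
  for (p in pa[-1]) {
    cfg <- cfg + (X[, p] - 1L) * stride
    stride <- stride * nlev[[p]]
  }
  cfg + 1L
}

.family_counts <- function(X, nlev, j, pa) {
  kj <- nlev[[j]]
  q <- if (length(pa)) prod(nlev[pa]) else 1L
  cfg <- .config_index(X, pa, nlev)
  joint <- (cfg - 1L) * kj + X[, j]
  matrix(tabulate(joint, q * kj), nrow = kj)
}

.family_bic <- function(X, nlev, j, pa, N) {
  M <- .family_counts(X, nlev, j, pa)
  tot <- rep(colSums(M), each = nrow(M))
  cnt <- as.numeric(M)
  nz <- cnt > 0
  ll <- sum(cnt[nz] * log(cnt[nz] / tot[nz]))
  q <- ncol(M)
  ll - 0.5 * log(N) * (nlev[[j]] - 1) * q
}

#' BIC score of a DAG on discrete data
#'
#' Decomposable log-likelihood minus `0.5 * log(n)` per free parameter,
#' summed over node families. Used both by the hill-climbing learner and as
#' a test-facing diagnostic.
#'
#' @param data Discrete [bb_dataset()] or data frame of factors.
#' @param dag A `bb_dag`.
#' @return Scalar score (larger is better).
#' @export
bic_score <- function(data, dag) {
  df <- as_factor_frame(data)
  im <- .int_matrix(df)
  N <- nrow(df)
  sum(vapply(dag$nodes, function(j)
    .family_bic(im$X, im$nlev, j, dag$parents[[j]], N), numeric(1)))
}

#' Learn a network structure by greedy hill climbing
#'
#' Starts from the empty graph and repeatedly applies the single
#' add/remove/reverse edge move that most improves the BIC score, subject to
#' acyclicity and an in-degree cap. Tie-breaking is deterministic (first
#' move in enumeration order wins), so the result depends only on the data.
#'
#' @param data Discrete [bb_dataset()] or data frame of factors.
#' @param max_parents In-degree cap (default 3).
#' @param seed Accepted for interface uniformity; the search itself is
#'   deterministic.
#' @param roots Nodes forbidden from receiving incoming edges. Declaring
#'   demographic/protected attributes exogenous this way keeps their
#'   conditional effects on downstream variables intact when their own
#'   distribution is later rewritten.
#' @return A `bb_dag`.
#' @export
learn_structure <- function(data, max_parents = 3, seed = NULL,
                            roots = character()) {
  df <- as_factor_frame(data)
  nodes <- names(df)
  parents <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  if (length(nodes) < 2) {
    warning("fewer than two variables: returning empty DAG", call. = FALSE)
    return(new_dag(nodes, parents))
  }
  im <- .int_matrix(df)
  N <- nrow(df)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fam <- function(j, pa) {
    key <- paste(j, paste(sort(pa), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- .family_bic(im$X, im$nlev, j, pa, N)
      cache[[key]] <- val
    }
    val
  }
  repeat {
    best <- 1e-10
    best_move <- NULL
    for (j in nodes) for (i in nodes) {
      if (i == j) next
      pa <- parents[[j]]
      if (i %in% pa) {
        d <- fam(j, setdiff(pa, i)) - fam(j, pa)
        if (d > best) {
          best <- d
          best_move <- list(op = "remove", i = i, j = j)
        }
        if (length(parents[[i]]) < max_parents && !i %in% roots) {
          tmp <- parents
          tmp[[j]] <- setdiff(pa, i)
          if (!.has_path(i, j, tmp)) {
            d2 <- (fam(j, setdiff(pa, i)) - fam(j, pa)) +
              (fam(i, c(parents[[i]], j)) - fam(i, parents[[i]]))
            if (d2 > best) {
              best <- d2
              best_move <- list(op = "reverse", i = i, j = j)
            }
          }
        }
      } else if (length(pa) < max_parents && !j %in% roots &&
                 !.has_path(j, i, parents)) {
        d <- fam(j, c(pa, i)) - fam(j, pa)
        if (d > best) {
          best <- d
          best_move <- list(op = "add", i = i, j = j)
        }
      }
    }
    if (is.null(best_move)) break
    i <- best_move$i
    j <- best_move$j
    if (best_move$op == "add") {
      parents[[j]] <- c(parents[[j]], i)
    } else if (best_move$op == "remove") {
      parents[[j]] <- setdiff(parents[[j]], i)
    } else {
      parents[[j]] <- setdiff(parents[[j]], i)
      parents[[i]] <- c(parents[[i]], j)
    }
    parents <- lapply(parents, function(p) p[order(match(p, nodes))])
  }
  new_dag(nodes, parents)
}

new_bn <- function(nodes, levels, parents, cpts) {
  for (j in nodes) {
    M <- matrix(as.numeric(cpts[[j]]), nrow = length(levels[[j]]))
    if (any(M < 0) || any(abs(colSums(M) - 1) > 1e-9))
      stop("CPT of '", j, "' has a row not summing to 1", call. = FALSE)
  }
  structure(list(nodes = nodes, levels = levels, parents = parents,
                 cpts = cpts, order = .topo_order(nodes, parents)),
            class = "bb_bn")
}

#' @export
print.bb_bn <- function(x, ...) {
  cat("<bb_bn> ", length(x$nodes), " nodes, ",
      sum(lengths(x$parents)), " edges, joint states = ",
      format(prod(lengths(x$levels))), "\n", sep = "")
  invisible(x)
}

#' Fit conditional probability tables on a DAG
#'
#' Each CPT row is `(count + alpha) / (row_total + alpha * n_levels)`.
#' With `alpha = 0`, parent configurations never observed fall back to a
#' uniform row (logged).
#'
#' @param data Discrete [bb_dataset()] or data frame of factors.
#' @param dag A `bb_dag` whose nodes are columns of `data`.
#' @param laplace_alpha Smoothing pseudo-count (default 1).
#' @return A `bb_bn`.
#' @export
fit_parameters <- function(data, dag, laplace_alpha = 1) {
  df <- as_factor_frame(data)
  if (!all(dag$nodes %in% names(df)))
    stop("DAG nodes must be dataset columns", call. = FALSE)
  im <- .int_matrix(df)
  cpts <- list()
  for (j in dag$nodes) {
    pa <- dag$parents[[j]]
    M <- .family_counts(im$X, im$nlev, j, pa)
    if (laplace_alpha == 0 && any(colSums(M) == 0))
      message("fit_parameters: unobserved parent configuration for '", j,
              "'; uniform row used")
    A <- M + laplace_alpha
    tot <- colSums(A)
    if (any(tot == 0)) A[, tot == 0] <- 1
    P <- sweep(A, 2, colSums(A), "/")
    dims <- c(im$nlev[[j]], if (length(pa)) im$nlev[pa])
    cpts[[j]] <- array(as.numeric(P), dim = dims,
                       dimnames = c(list(im$levels[[j]]),
                                    im$levels[pa]))
  }
  new_bn(dag$nodes, im$levels[dag$nodes], dag$parents, cpts)
}

.sample_node <- function(bn, j, X) {
  kj <- length(bn$levels[[j]])
  pa <- bn$parents[[j]]
  n <- nrow(X)
  if (!length(pa)) {
    p <- as.numeric(bn$cpts[[j]])
    sample.int(kj, n, replace = TRUE, prob = p)
  } else {
    nlev <- lengths(bn$levels)
    cfg <- .config_index(X, pa, nlev)
    km <- matrix(as.numeric(bn$cpts[[j]]), nrow = kj)
    cum <- apply(km, 2, cumsum)
    M <- t(cum)[cfg, , drop = FALSE]
    u <- stats::runif(n)
    as.integer(rowSums(u > M) + 1L)
  }
}

.int_to_frame <- function(bn, X) {
  out <- lapply(bn$nodes, function(j)
    factor(bn$levels[[j]][X[, j]], levels = bn$levels[[j]]))
  names(out) <- bn$nodes
  as.data.frame(out, stringsAsFactors = FALSE)
}

.logic_sample_impl <- function(bn, n) {
  X <- matrix(0L, nrow = n, ncol = length(bn$nodes),
              dimnames = list(NULL, bn$nodes))
  for (j in bn$order) X[, j] <- .sample_node(bn, j, X)
  .int_to_frame(bn, X)
}

#' Forward (logic) sampling from a Bayesian network
#'
#' Ancestral sampling in topological order; deterministic under the seed.
#'
#' @param network A `bb_bn`.
#' @param n Number of rows (>= 1).
#' @param seed Integer seed.
#' @return Data frame of factors, one column per node.
#' @export
logic_sample <- function(network, n, seed) {
  stopifnot(inherits(network, "bb_bn"), n >= 1)
  withr::with_seed(seed, .logic_sample_impl(network, n))
}

.check_evidence <- function(bn, evidence) {
  ev <- vapply(evidence, as.character, character(1))
  if (is.null(names(ev)) || any(!nzchar(names(ev))))
    stop("evidence must be a named list/vector", call. = FALSE)
  for (v in names(ev)) {
    if (!v %in% bn$nodes)
      stop("evidence variable '", v, "' not in network", call. = FALSE)
    if (!ev[[v]] %in% bn$levels[[v]])
      stop("evidence value '", ev[[v]], "' is not a level of '", v, "'",
           call. = FALSE)
  }
  ev
}

.sample_with_evidence_impl <- function(bn, evidence, n,
                                       n_weighted = NULL) {
  ev <- .check_evidence(bn, evidence)
  if (is.null(n_weighted)) n_weighted <- max(1000L, 4L * as.integer(n))
  nlev <- lengths(bn$levels)
  X <- matrix(0L, nrow = n_weighted, ncol = length(bn$nodes),
              dimnames = list(NULL, bn$nodes))
  logw <- numeric(n_weighted)
  for (j in bn$order) {
    if (j %in% names(ev)) {
      lvl <- match(ev[[j]], bn$levels[[j]])
      X[, j] <- lvl
      kj <- nlev[[j]]
      cfg <- .config_index(X, bn$parents[[j]], nlev)
      pj <- as.numeric(bn$cpts[[j]])[(cfg - 1L) * kj + lvl]
      logw <- logw + log(pj)
    } else {
      X[, j] <- .sample_node(bn, j, X)
    }
  }
  mx <- max(logw)
  if (!is.finite(mx))
    stop("evidence has zero likelihood under the network: ",
         paste(names(ev), ev, sep = "=", collapse = ", "), call. = FALSE)
  w <- exp(logw - mx)
  ess <- sum(w)^2 / sum(w^2)
  if (ess < n / 10)
    message("sample_with_evidence: effective sample size ",
            round(ess, 1), " is below n/10")
  pick <- sample.int(n_weighted, n, replace = TRUE, prob = w)
  .int_to_frame(bn, X[pick, , drop = FALSE])
}

#' Evidence-conditioned sampling via likelihood weighting
#'
#' Draws weighted forward samples with evidence variables clamped, then
#' resamples `n` rows with replacement proportional to the evidence
#' likelihood. Every output row carries the evidence values exactly.
#'
#' @param network A `bb_bn`.
#' @param evidence Named list/vector mapping variables to levels.
#' @param n Number of rows (>= 1).
#' @param seed Integer seed.
#' @param n_weighted Number of weighted draws before resampling
#'   (default `max(1000, 4 n)`).
#' @return Data frame of factors.
#' @export
sample_with_evidence <- function(network, evidence, n, seed,
                                 n_weighted = NULL) {
  stopifnot(inherits(network, "bb_bn"), n >= 1)
  withr::with_seed(seed,
    .sample_with_evidence_impl(network, evidence, n, n_weighted))
}

#' Exact conditional marginal by joint enumeration
#'
#' Brute-force oracle for small networks: enumerates the full joint state
#' space (capped at 1e6 states), conditions on the evidence, and returns
#' the marginal distribution of one variable.
#'
#' @param network A `bb_bn` with at most 1e6 joint states.
#' @param variable Node whose marginal is wanted.
#' @param evidence Optional named list/vector of clamped values.
#' @return Named probability vector over the variable's levels.
#' @export
exact_marginal <- function(network, variable, evidence = NULL) {
  stopifnot(inherits(network, "bb_bn"), variable %in% network$nodes)
  nlev <- lengths(network$levels)
  if (prod(nlev) > 1e6)
    stop("state space exceeds 1e6: use sampling instead", call. = FALSE)
  G <- as.matrix(expand.grid(lapply(nlev, seq_len)))
  colnames(G) <- network$nodes
  lp <- numeric(nrow(G))
  for (j in network$nodes) {
    kj <- nlev[[j]]
    cfg <- .config_index(G, network$parents[[j]], nlev)
    lp <- lp + log(as.numeric(network$cpts[[j]])[(cfg - 1L) * kj + G[, j]])
  }
  p <- exp(lp)
  if (!is.null(evidence)) {
    ev <- .check_evidence(network, evidence)
    keep <- rep(TRUE, nrow(G))
    for (v in names(ev))
      keep <- keep & G[, v] == match(ev[[v]], network$levels[[v]])
    p[!keep] <- 0
  }
  if (sum(p) == 0)
    stop("evidence has zero probability under the network", call. = FALSE)
  k <- nlev[[variable]]
  res <- vapply(seq_len(k), function(l) sum(p[G[, variable] == l]),
                numeric(1))
  stats::setNames(res / sum(res), network$levels[[variable]])
}

#' Replace a node's conditional distribution wholesale
#'
#' The variable's CPT is overwritten with the given probability vector for
#' every parent configuration, which makes that vector the variable's
#' marginal regardless of its parents.
#'
#' @param network A `bb_bn`.
#' @param variable Node to override.
#' @param new_distribution Probability vector over the variable's levels
#'   (named or in level order); must sum to 1 within 1e-9.
#' @return The modified `bb_bn`.
#' @export
override_cpt <- function(network, variable, new_distribution) {
  stopifnot(inherits(network, "bb_bn"), variable %in% network$nodes)
  lev <- network$levels[[variable]]
  d <- new_distribution
  if (!is.null(names(d))) {
    if (!setequal(names(d), lev))
      stop("distribution names must match levels of '", variable, "'",
           call. = FALSE)
    d <- d[lev]
  }
  d <- as.numeric(d)
  if (length(d) != length(lev) || any(d < 0) || abs(sum(d) - 1) > 1e-9)
    stop("new_distribution must be a probability vector over ",
         length(lev), " levels summing to 1", call. = FALSE)
  q <- length(network$cpts[[variable]]) / length(lev)
  network$cpts[[variable]][] <- rep(d, q)
  network
}

#' Write a network to YAML
#'
#' CPT rows are listed in parent-configuration order with the first parent
#' varying fastest, matching the internal array layout.
#'
#' @param network A `bb_bn`.
#' @param path Output file.
#' @export
bn_write_yaml <- function(network, path) {
  doc <- list(nodes = lapply(network$nodes, function(j) {
    kj <- length(network$levels[[j]])
    M <- matrix(as.numeric(network$cpts[[j]]), nrow = kj)
    list(name = j,
         levels = as.list(network$levels[[j]]),
         parents = as.list(network$parents[[j]]),
         cpt = lapply(seq_len(ncol(M)), function(c) as.list(M[, c])))
  }))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a network from YAML
#'
#' @param path File written by [bn_write_yaml()] (or hand-authored in the
#'   same layout).
#' @return A `bb_bn`.
#' @export
bn_read_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  nodes <- vapply(doc$nodes, `[[`, character(1), "name")
  levels <- stats::setNames(lapply(doc$nodes, function(x)
    as.character(unlist(x$levels))), nodes)
  parents <- stats::setNames(lapply(doc$nodes, function(x)
    as.character(unlist(x$parents))), nodes)
  cpts <- stats::setNames(lapply(doc$nodes, function(x) {
    j <- x$name
    kj <- length(unlist(x$levels))
    vals <- unlist(x$cpt)
    pa <- as.character(unlist(x$parents))
    dims <- c(kj, if (length(pa))
      vapply(pa, function(p) length(levels[[p]]), integer(1)))
    array(as.numeric(vals), dim = dims,
          dimnames = c(list(levels[[j]]), levels[pa]))
  }), nodes)
  new_bn(nodes, levels, parents, cpts)
}
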