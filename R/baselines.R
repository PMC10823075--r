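# Comparison resamplers. Mixed-type SMOTE follows the SMOTE-NC convention:
# Euclidean distance on standardized numerics with each categorical
# mismatch contributing the median of the standardized numeric standard
# deviations (i.e. 1), numeric interpolation along the segment to a random
# nearest neighbour, and categorical values by majority vote among the
# neighbours.

#' Privileged/unprivileged partition of a protected attribute
#'
#' @param privileged_levels Nonempty proper subset of the protected
#'   attribute's levels regarded as privileged.
#' @param protected Optional protected column name (defaults to the
#'   schema's at use time).
#' @return Object of class `bb_privilege_map`.
#' @export
privilege_map <- function(privileged_levels, protected = NULL) {
  stopifnot(is.character(privileged_levels), length(privileged_levels) >= 1)
  structure(list(privileged_levels = privileged_levels,
                 protected = protected),
            class = "bb_privilege_map")
}

.feature_parts <- function(df, schema) {
  vars <- setdiff(variable_names(schema), schema$target)
  num <- vars[vapply(vars, function(v) is_numeric_var(schema, v),
                     logical(1))]
  cat <- setdiff(vars, num)
  NUM <- NULL
  if (length(num)) {
    NUM <- vapply(num, function(v) {
      x <- df[[v]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) s <- 1
      (x - mean(x)) / s
    }, numeric(nrow(df)))
    if (is.null(dim(NUM))) NUM <- matrix(NUM, nrow = nrow(df))
  }
  CAT <- NULL
  if (length(cat)) {
    CAT <- vapply(cat, function(v) as.integer(df[[v]]),
                  integer(nrow(df)))
    if (is.null(dim(CAT))) CAT <- matrix(CAT, nrow = nrow(df))
  }
  list(num = NUM, cat = CAT, num_vars = num, cat_vars = cat)
}

# k nearest pool rows for each query row; returns a length(query) x k
# matrix of positions into `pool`
.knn_idx <- function(parts, query, pool, k, exclude_self = TRUE) {
  nq <- length(query)
  np <- length(pool)
  out <- matrix(0L, nrow = nq, ncol = k)
  chunk <- max(1L, as.integer(2e6 / max(np, 1)))
  pn <- if (!is.null(parts$num)) parts$num[pool, , drop = FALSE]
  pc <- if (!is.null(parts$cat)) parts$cat[pool, , drop = FALSE]
  pn2 <- if (!is.null(pn)) rowSums(pn^2)
  for (s in seq(1, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    qi <- query[s:e]
    D <- matrix(0, nrow = length(qi), ncol = np)
    if (!is.null(pn)) {
      qn <- parts$num[qi, , drop = FALSE]
      D <- D + outer(rowSums(qn^2), pn2, "+") - 2 * tcrossprod(qn, pn)
    }
    if (!is.null(pc)) {
      qc <- parts$cat[qi, , drop = FALSE]
      for (c in seq_len(ncol(pc)))
        D <- D + outer(qc[, c], pc[, c], "!=")
    }
    if (exclude_self) {
      hit <- match(qi, pool)
      ok <- !is.na(hit)
      D[cbind(which(ok), hit[ok])] <- Inf
    }
    for (r in seq_len(nrow(D)))
      out[s + r - 1L, ] <- order(D[r, ])[seq_len(k)]
  }
  out
}

# majority vote (ties to the earlier level) over neighbour integer codes
.vote <- function(codes) {
  tab <- tabulate(codes)
  which.max(tab)
}

# generate `counts[i]` synthetic rows from pool row i, interpolating
# numerics toward a random one of its k nearest pool neighbours and voting
# categoricals among those neighbours; `fixed` columns are copied from a
# template
.smote_rows <- function(df, schema, pool, counts, k, fixed = list()) {
  parts <- .feature_parts(df, schema)
  nn <- .knn_idx(parts, pool, pool, k)
  votes <- list()
  for (v in parts$cat_vars) {
    code <- as.integer(df[[v]])[pool]
    votes[[v]] <- vapply(seq_along(pool), function(i)
      .vote(code[nn[i, ]]), integer(1))
  }
  src <- rep(seq_along(pool), counts)
  if (!length(src)) return(df[integer(0), , drop = FALSE])
  nb <- nn[cbind(src, sample.int(k, length(src), replace = TRUE))]
  gap <- stats::runif(length(src))
  out <- df[pool[src], , drop = FALSE]
  for (v in parts$num_vars) {
    x <- df[[v]][pool]
    out[[v]] <- x[src] + gap * (x[nb] - x[src])
  }
  for (v in parts$cat_vars)
    out[[v]] <- factor(levels(df[[v]])[votes[[v]][src]],
                       levels = levels(df[[v]]))
  for (v in names(fixed))
    out[[v]] <- factor(rep(fixed[[v]], nrow(out)), levels = levels(df[[v]]))
  rownames(out) <- NULL
  out
}

.check_k <- function(pool_n, k) {
  if (pool_n <= k) {
    k2 <- pool_n - 1L
    if (k2 < 1L)
      stop("too few rows (", pool_n, ") to interpolate", call. = FALSE)
    warning("k_neighbors reduced to ", k2, call. = FALSE)
    return(k2)
  }
  as.integer(k)
}

.even_counts <- function(n_pool, need) {
  base <- need %/% n_pool
  m <- rep.int(base, n_pool)
  extra <- need %% n_pool
  if (extra > 0) m[seq_len(extra)] <- m[seq_len(extra)] + 1L
  as.integer(m)
}

#' SMOTE oversampling of the minority class
#'
#' Brings the minority class up to the majority count. Balanced input is
#' returned unchanged.
#'
#' @param dataset A [bb_dataset()] with a binary target.
#' @param target Target column (default: the schema's).
#' @param k_neighbors Number of minority nearest neighbours (default 5),
#'   reduced with a warning when the minority class is too small.
#' @param seed Integer seed.
#' @return A [bb_dataset()] with role `"baseline"` and provenance tags.
#' @export
smote <- function(dataset, target = NULL, k_neighbors = 5, seed = 1) {
  sch <- dataset$schema
  if (is.null(target)) target <- sch$target
  df <- dataset$data
  y <- df[[target]]
  tab <- table(y)
  prov <- rep("original", nrow(df))
  if (length(unique(as.numeric(tab))) == 1 || min(tab) == max(tab))
    return(bb_dataset(df, sch, role = "baseline", provenance = prov))
  minority <- names(tab)[which.min(tab)]
  need <- as.integer(max(tab) - min(tab))
  pool <- which(as.character(y) == minority)
  k <- .check_k(length(pool), k_neighbors)
  syn <- withr::with_seed(seed,
    .smote_rows(df, sch, pool, .even_counts(length(pool), need), k,
                fixed = stats::setNames(list(minority), target)))
  bb_dataset(rbind(df, syn), sch, role = "baseline",
             provenance = c(prov, rep("synthetic", nrow(syn))))
}

#' AdaSyn adaptive oversampling of the minority class
#'
#' As [smote()], but each minority row's share of the synthetic rows is
#' proportional to the fraction of majority rows among its k nearest
#' neighbours in the full dataset, so generation concentrates where the
#' classes overlap. Falls back to uniform allocation (with a warning) when
#' every minority row is surrounded purely by minority rows.
#'
#' @inheritParams smote
#' @export
adasyn <- function(dataset, target = NULL, k_neighbors = 5, seed = 1) {
  sch <- dataset$schema
  if (is.null(target)) target <- sch$target
  df <- dataset$data
  y <- df[[target]]
  tab <- table(y)
  prov <- rep("original", nrow(df))
  if (min(tab) == max(tab))
    return(bb_dataset(df, sch, role = "baseline", provenance = prov))
  minority <- names(tab)[which.min(tab)]
  need <- as.integer(max(tab) - min(tab))
  pool <- which(as.character(y) == minority)
  k <- .check_k(length(pool), k_neighbors)
  out <- withr::with_seed(seed, {
    parts <- .feature_parts(df, sch)
    nn_all <- .knn_idx(parts, pool, seq_len(nrow(df)), k)
    is_maj <- as.character(y) != minority
    r <- rowMeans(matrix(is_maj[nn_all], nrow = length(pool)))
    if (sum(r) == 0) {
      warning("all minority neighbourhoods are pure minority: uniform ",
              "allocation", call. = FALSE)
      counts <- .even_counts(length(pool), need)
    } else {
      counts <- largest_remainder(r / sum(r), need)
    }
    .smote_rows(df, sch, pool, counts, k,
                fixed = stats::setNames(list(minority), target))
  })
  bb_dataset(rbind(df, out), sch, role = "baseline",
             provenance = c(prov, rep("synthetic", nrow(out))))
}

#' Simplified Fair-SMOTE subgroup balancing
#'
#' Binarizes the protected attribute by the privilege map, then oversamples
#' each of the four (class x privilege) subgroups to the size of the
#' largest using the SMOTE mechanism with neighbours restricted to the
#' subgroup. The full published situation-testing variant is deliberately
#' not implemented; this is the simplified balancing used as a comparison
#' baseline.
#'
#' @param dataset A [bb_dataset()].
#' @param target Target column (default: the schema's).
#' @param privilege_map A [privilege_map()].
#' @param k_neighbors,seed As in [smote()].
#' @return A [bb_dataset()] with role `"baseline"`.
#' @export
fair_smote <- function(dataset, target = NULL, privilege_map,
                       k_neighbors = 5, seed = 1) {
  sch <- dataset$schema
  if (is.null(target)) target <- sch$target
  prot <- privilege_map$protected
  if (is.null(prot)) prot <- sch$protected
  lev <- schema_levels(sch, prot)
  priv <- privilege_map$privileged_levels
  if (!all(priv %in% lev) || length(priv) == 0 || length(priv) >= length(lev))
    stop("privileged_levels must be a nonempty proper subset of the ",
         "levels of '", prot, "'", call. = FALSE)
  df <- dataset$data
  y <- as.character(df[[target]])
  flag <- ifelse(df[[prot]] %in% priv, "privileged", "unprivileged")
  grp <- paste(ifelse(y == "1", "class 1", "class 0"), flag, sep = " / ")
  groups <- split(seq_len(nrow(df)), grp)
  expected <- as.vector(outer(c("class 0", "class 1"),
                              c("privileged", "unprivileged"),
                              paste, sep = " / "))
  missing <- setdiff(expected, names(groups))
  if (length(missing))
    stop("empty subgroup: ", paste(missing, collapse = "; "), call. = FALSE)
  tmax <- max(lengths(groups))
  syn_parts <- withr::with_seed(seed, {
    parts <- list()
    for (g in expected) {
      idx <- groups[[g]]
      need <- tmax - length(idx)
      if (need == 0) next
      k <- .check_k(length(idx), k_neighbors)
      cls <- if (startsWith(g, "class 1")) "1" else "0"
      parts[[g]] <- .smote_rows(df, sch, idx, .even_counts(length(idx), need),
                                k, fixed = stats::setNames(list(cls), target))
    }
    parts
  })
  syn <- if (length(syn_parts)) do.call(rbind, syn_parts) else
    df[integer(0), , drop = FALSE]
  rownames(syn) <- NULL
  bb_dataset(rbind(df, syn), sch, role = "baseline",
             provenance = c(rep("original", nrow(df)),
                            rep("synthetic", nrow(syn))))
}
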