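# Controlled injection of representation bias: learn a network from the
# source data, rewrite the protected attribute's conditional probabilities
# (or condition on evidence), sample, then learn a second network from that
# sample and draw the final biased dataset from it, so the output is fully
# separated from the original rows.

#' Specify a representation-bias injection
#'
#' @param protected_name Protected attribute to distort.
#' @param target_distribution Named probability vector over the protected
#'   levels: the desired post-bias marginal.
#' @param n_out Size of the biased dataset (>= 100).
#' @param n_intermediate Sample size drawn from the first network
#'   (default `n_out`).
#' @return Object of class `bb_bias_spec`.
#' @export
bias_spec <- function(protected_name, target_distribution, n_out,
                      n_intermediate = n_out) {
  d <- target_distribution
  if (is.null(names(d)) || any(!nzchar(names(d))))
    stop("target_distribution must be named by protected level",
         call. = FALSE)
  if (any(d < 0) || abs(sum(d) - 1) > 1e-9)
    stop("target_distribution must be a probability vector summing to 1",
         call. = FALSE)
  if (n_out < 100 || n_intermediate < 100)
    stop("n_out and n_intermediate must be >= 100", call. = FALSE)
  structure(list(protected_name = protected_name,
                 target_distribution = d,
                 n_intermediate = as.integer(n_intermediate),
                 n_out = as.integer(n_out)),
            class = "bb_bias_spec")
}

#' Inject representation bias into a dataset
#'
#' Two-network pipeline: discretize; learn and fit a network on the source;
#' force the protected attribute's distribution (CPT override, or per-level
#' evidence quotas with `mechanism = "evidence"`); logic-sample an
#' intermediate dataset; learn a second network from that sample to fully
#' separate the output from the original rows; logic-sample the final
#' biased dataset and invert the discretization. The realized protected
#' marginal is checked against the target within 3 binomial standard
#' errors and a warning is raised on drift.
#'
#' @param dataset Source [bb_dataset()].
#' @param spec A [bias_spec()].
#' @param seed Integer seed.
#' @param mechanism `"override"` (default) rewrites the protected CPT;
#'   `"evidence"` samples per-level quotas by likelihood weighting.
#' @param n_bins,max_parents,laplace_alpha Passed to the discretization and
#'   network steps.
#' @return A [bb_dataset()] with role `"biased"`.
#' @export
inject_bias <- function(dataset, spec, seed,
                        mechanism = c("override", "evidence"),
                        n_bins = 5, max_parents = 3, laplace_alpha = 1) {
  stopifnot(inherits(dataset, "bb_dataset"), inherits(spec, "bb_bias_spec"))
  mechanism <- match.arg(mechanism)
  prot <- spec$protected_name
  sch <- dataset$schema
  if (!prot %in% variable_names(sch) || is_numeric_var(sch, prot))
    stop("protected attribute '", prot, "' must be a categorical variable",
         call. = FALSE)
  lev <- schema_levels(sch, prot)
  d <- spec$target_distribution
  if (!setequal(names(d), lev))
    stop("target_distribution names must match the levels of '", prot, "'",
         call. = FALSE)
  d <- d[lev]
  obs <- table(dataset$data[[prot]])
  if (any(obs == 0 & d > 0))
    stop("protected level(s) absent from data: ",
         paste(lev[obs == 0 & d > 0], collapse = ", "), call. = FALSE)
  if (max(d) == 1)
    warning("degenerate one-hot target distribution", call. = FALSE)
  out <- withr::with_seed(seed, {
    disc <- discretize(dataset, n_bins)
    dag1 <- learn_structure(disc$dataset, max_parents, roots = prot)
    bn1 <- fit_parameters(disc$dataset, dag1, laplace_alpha)
    s1 <- if (mechanism == "override") {
      .logic_sample_impl(override_cpt(bn1, prot, d), spec$n_intermediate)
    } else {
      quota <- largest_remainder(d, spec$n_intermediate)
      parts <- lapply(which(quota > 0), function(i)
        .sample_with_evidence_impl(bn1, stats::setNames(lev[i], prot),
                                   quota[i]))
      do.call(rbind, parts)
    }
    dag2 <- learn_structure(s1, max_parents, roots = prot)
    bn2 <- fit_parameters(s1, dag2, laplace_alpha)
    s2 <- .logic_sample_impl(bn2, spec$n_out)
    disc_out <- bb_dataset(s2, disc$dataset$schema, role = "biased")
    .undiscretize_impl(disc_out, disc$map)
  })
  emp <- measure_representation(out, prot)[lev]
  se <- sqrt(d * (1 - d) / spec$n_out)
  drift <- abs(emp - d) > 3 * se + 1e-12
  if (any(drift))
    warning("protected marginal drifted beyond 3 SE for level(s): ",
            paste(lev[drift], collapse = ", "), call. = FALSE)
  out
}

#' Empirical level shares of a categorical variable
#'
#' @param dataset A [bb_dataset()] (or a factor/character vector).
#' @param variable Column name (ignored when a vector is given).
#' @return Named numeric vector of shares summing to 1.
#' @export
measure_representation <- function(dataset, variable = NULL) {
  x <- if (inherits(dataset, "bb_dataset")) dataset$data[[variable]]
       else dataset
  if (is.null(x) || length(x) == 0)
    stop("empty dataset or unknown variable", call. = FALSE)
  if (!is.factor(x)) x <- factor(x)
  tab <- table(x)
  stats::setNames(as.numeric(tab) / length(x), names(tab))
}
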