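# Correction: order attributes by distributional divergence between the
# suspect data and the uncertain set, compute per-row generation counts for
# a boosting fraction, generate evidence-conditioned synthetic rows from a
# network trained on the suspect data, and merge into the boosted dataset.

#' Order attributes by distributional divergence
#'
#' Every non-target variable is scored with [distribution_distance()]
#' between its column in the suspect data and in the uncertain set, and
#' sorted descending (ties broken by schema order). High-ranked variables
#' are the ones whose distribution the uncertain set says is most off, and
#' they serve as sampling evidence during boosting.
#'
#' @param d_bias Suspect [bb_dataset()].
#' @param d_unc Uncertain [bb_dataset()] sharing the schema.
#' @return Data frame (`variable`, `distance`), class `bb_ordering`.
#' @export
order_attributes <- function(d_bias, d_unc) {
  sch <- d_bias$schema
  vars <- setdiff(variable_names(sch), sch$target)
  sc <- vapply(vars, function(v)
    distribution_distance(d_bias$data[[v]], d_unc$data[[v]]), numeric(1))
  o <- order(-sc, seq_along(vars))
  out <- data.frame(variable = vars[o], distance = sc[o],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bb_ordering", "data.frame")
  out
}

#' Per-uncertain-row synthetic generation counts
#'
#' The total synthetic target is `round(fraction * n_bias)` (round half
#' up); it is spread over the uncertain rows as evenly as possible
#' (`floor` everywhere, remainder to the lowest-index rows), so all counts
#' differ by at most one and sum exactly to the target.
#'
#' @param n_bias Number of rows in the suspect data.
#' @param n_unc Number of uncertain rows (>= 1).
#' @param fraction Boosting level; 0.5, 1 and 2 are the standard settings.
#' @return List with `fraction`, `total` and integer vector `m`, class
#'   `bb_boost_plan`.
#' @export
compute_m <- function(n_bias, n_unc, fraction) {
  stopifnot(n_unc >= 1, fraction > 0)
  total <- as.integer(rhu(fraction * n_bias))
  if (total == 0) stop("requested synthetic total is zero", call. = FALSE)
  base <- total %/% n_unc
  extra <- total %% n_unc
  m <- rep.int(base, n_unc)
  if (extra > 0) m[seq_len(extra)] <- m[seq_len(extra)] + 1L
  structure(list(fraction = fraction, total = total, m = as.integer(m)),
            class = "bb_boost_plan")
}

# evidence values (as character) for the uncertain rows on the given
# variables; numeric values are mapped to their bin labels in `map`,
# clamped to the end bins outside the observed range
.evidence_matrix <- function(d_unc, ev_vars, map) {
  sch <- d_unc$schema
  EV <- matrix("", nrow = nrow(d_unc$data), ncol = length(ev_vars),
               dimnames = list(NULL, ev_vars))
  for (v in ev_vars) {
    if (is_numeric_var(sch, v)) {
      b <- map[[v]]
      i <- findInterval(d_unc$data[[v]], b$low)
      i <- pmin(pmax(i, 1L), nrow(b))
      EV[, v] <- b$label[i]
    } else {
      EV[, v] <- as.character(d_unc$data[[v]])
    }
  }
  EV
}

#' Generate the boosted dataset
#'
#' Learns and fits a network on the discretized suspect data, then, for
#' each uncertain row, samples its share of synthetic rows conditioned on
#' evidence built from the row's protected-attribute value plus its values
#' on the top-k attributes of the divergence ordering. Identical evidence
#' configurations are pooled into one sampling call. Rows whose evidence
#' has zero likelihood are retried with the protected attribute alone and
#' skipped (with their counts redistributed) if still contradictory. The
#' synthetic rows (provenance `"synthetic"`, sampled target labels) are
#' merged with the suspect rows (provenance `"original"`).
#'
#' @param d_bias Suspect [bb_dataset()].
#' @param d_unc Uncertain [bb_dataset()].
#' @param plan A [compute_m()] plan consistent with `nrow(d_unc)`.
#' @param ordering An [order_attributes()] result.
#' @param seed Integer seed.
#' @param evidence_depth Number of top-ranked ordering variables clamped as
#'   evidence in addition to the protected attribute (default 3).
#' @param n_bins,max_parents,laplace_alpha Network-stage settings.
#' @return A [bb_dataset()] with role `"boosted"`.
#' @export
boost <- function(d_bias, d_unc, plan, ordering, seed, evidence_depth = 3,
                  n_bins = 5, max_parents = 3, laplace_alpha = 1) {
  stopifnot(inherits(plan, "bb_boost_plan"),
            length(plan$m) == nrow(d_unc$data))
  prot <- d_bias$schema$protected
  if (is.null(prot)) stop("schema has no protected attribute", call. = FALSE)
  top <- utils::head(setdiff(ordering$variable, prot), evidence_depth)
  ev_vars <- c(prot, top)
  syn <- withr::with_seed(seed, {
    disc <- discretize(d_bias, n_bins)
    dag <- learn_structure(disc$dataset, max_parents, roots = prot)
    bn <- fit_parameters(disc$dataset, dag, laplace_alpha)
    EV <- .evidence_matrix(d_unc, ev_vars, disc$map)
    key <- apply(EV, 1, paste, collapse = "\x1f")
    first <- !duplicated(key)
    group_n <- tapply(plan$m, factor(key, levels = unique(key)), sum)
    parts <- list()
    deficit <- 0L
    ok_ev <- NULL
    for (g in seq_along(group_n)) {
      ng <- as.integer(group_n[[g]])
      if (ng == 0) next
      ev <- stats::setNames(EV[which(first)[g], ], ev_vars)
      res <- tryCatch(.sample_with_evidence_impl(bn, ev, ng),
                      error = function(e) e)
      if (inherits(res, "error")) {
        res <- tryCatch(.sample_with_evidence_impl(bn, ev[prot], ng),
                        error = function(e) e)
        if (inherits(res, "error")) {
          warning("skipping contradictory evidence group (",
                  conditionMessage(res), "); counts redistributed",
                  call. = FALSE)
          deficit <- deficit + ng
          next
        }
        message("boost: evidence reduced to protected attribute for one ",
                "group")
      }
      parts[[length(parts) + 1L]] <- res
      ok_ev <- ev
    }
    if (deficit > 0L) {
      if (is.null(ok_ev))
        stop("all evidence groups were contradictory", call. = FALSE)
      parts[[length(parts) + 1L]] <-
        .sample_with_evidence_impl(bn, ok_ev, deficit)
    }
    sdf <- do.call(rbind, parts)
    sds <- bb_dataset(sdf, disc$dataset$schema, role = "boosted")
    .undiscretize_impl(sds, disc$map)
  })
  merged <- rbind(d_bias$data, syn$data)
  bb_dataset(merged, d_bias$schema, role = "boosted",
             provenance = c(rep("original", nrow(d_bias$data)),
                            rep("synthetic", nrow(syn$data))))
}

#' Run the full detection-and-correction pipeline
#'
#' Stratified validation extraction on the protected attribute, Naive
#' Bayes training, optional threshold calibration, uncertain-set
#' extraction, attribute ordering, and one boosted dataset per requested
#' fraction, plus the representation report and a run manifest.
#'
#' @param d_bias Suspect [bb_dataset()] (schema must designate target and
#'   protected).
#' @param fractions Boosting levels (default `c(0.5, 1, 2)`, i.e. the
#'   BB50/BB100/BB200 settings).
#' @param calibrate Recalibrate p1/p2 by [calibrate_thresholds()]?
#' @param config An [uncertainty_config()].
#' @param seed Integer seed.
#' @param evidence_depth,n_bins,max_parents,laplace_alpha Stage settings.
#' @return List with `bb` (named list of boosted datasets), `d_unc`,
#'   `ordering`, `thresholds`, `report`, `manifest`.
#' @export
bayesboost <- function(d_bias, fractions = c(0.5, 1, 2), calibrate = FALSE,
                       config = uncertainty_config(), seed = 1,
                       evidence_depth = 3, n_bins = 5, max_parents = 3,
                       laplace_alpha = 1) {
  sch <- d_bias$schema
  if (is.null(sch$target) || is.null(sch$protected))
    stop("schema must designate target and protected variables",
         call. = FALSE)
  sp <- stratified_split(d_bias, sch$protected, 1 - config$val_fraction,
                         seed = seed)
  model <- train_nb(sp$a, sch$target)
  thr <- if (calibrate)
    calibrate_thresholds(d_bias, sch$target, sch$protected, config,
                         seed = seed + 1000L)
  else c(p1 = config$p1, p2 = config$p2)
  d_unc <- extract_uncertain(model, sp$b, thr[["p1"]], thr[["p2"]])
  if (nrow(d_unc$data) == 0)
    stop("empty uncertain set: nothing to boost", call. = FALSE)
  ordering <- order_attributes(d_bias, d_unc)
  bb <- list()
  for (f in fractions) {
    plan <- compute_m(nrow(d_bias$data), nrow(d_unc$data), f)
    bb[[paste0("BB", round(100 * f))]] <-
      boost(d_bias, d_unc, plan, ordering,
            seed = seed + 10L + as.integer(round(100 * f)),
            evidence_depth = evidence_depth, n_bins = n_bins,
            max_parents = max_parents, laplace_alpha = laplace_alpha)
  }
  report <- representation_report(d_bias, d_unc, sch$protected)
  manifest <- list(
    n_bias = nrow(d_bias$data), n_uncertain = nrow(d_unc$data),
    fractions = fractions, thresholds = as.list(thr),
    calibrated = calibrate, evidence_depth = evidence_depth,
    n_bins = n_bins, max_parents = max_parents,
    laplace_alpha = laplace_alpha, seed = seed,
    val_fraction = config$val_fraction)
  structure(list(bb = bb, d_unc = d_unc, ordering = ordering,
                 thresholds = thr, report = report, manifest = manifest),
            class = "bb_boost_result")
}
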