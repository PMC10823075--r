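# End-to-end experiment harness wiring the stages together: 70/30 split,
# optional bias injection on the training side, detection + boosting,
# baseline resamplers, evaluation on the untouched test partition, and a
# manifest of every seed and parameter. Internal row ids guarantee the test
# partition never flows into any training stage.

#' Configure an end-to-end experiment
#'
#' Two designs are supported: `"simulation"` injects a known
#' representation bias into the training partition first (so recovery can
#' be verified against the injected truth), while `"direct"` carries the
#' training partition forward as the data suspected of bias.
#'
#' @param experiment `"simulation"` or `"direct"`.
#' @param data A [bb_dataset()], or `NULL` to use a fixture.
#' @param fixture Fixture spec `list(name, n)` with name `"cvd_like"` or
#'   `"covid_like"` (used when `data` is NULL).
#' @param bias A [bias_spec()] (required for simulation, forbidden for
#'   direct).
#' @param fractions Boosting levels.
#' @param uncertainty An [uncertainty_config()].
#' @param calibrate Recalibrate p1/p2?
#' @param baselines Run SMOTE/AdaSyn (and Fair-SMOTE when a privilege map
#'   is given)?
#' @param privilege_map Optional [privilege_map()].
#' @param n_runs Evaluation repeats.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Object of class `bb_run_config`.
#' @export
run_config <- function(experiment = c("simulation", "direct"), data = NULL,
                       fixture = NULL, bias = NULL,
                       fractions = c(0.5, 1, 2),
                       uncertainty = uncertainty_config(),
                       calibrate = FALSE, baselines = TRUE,
                       privilege_map = NULL, n_runs = 10, seed = 1,
                       out_dir = "bayesboost-run") {
  experiment <- match.arg(experiment)
  if (experiment == "simulation" && is.null(bias))
    stop("simulation experiments require a bias spec", call. = FALSE)
  if (experiment == "direct" && !is.null(bias))
    stop("direct experiments must not carry a bias spec", call. = FALSE)
  if (is.null(data) && is.null(fixture))
    stop("either data or a fixture spec is required", call. = FALSE)
  structure(list(experiment = experiment, data = data, fixture = fixture,
                 bias = bias, fractions = fractions,
                 uncertainty = uncertainty, calibrate = calibrate,
                 baselines = baselines, privilege_map = privilege_map,
                 n_runs = n_runs, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "bb_run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run a full experiment
#'
#' Splits the data 70/30 (stratified on the target), builds the suspect
#' dataset (by bias injection for simulation, identity for direct), runs
#' the detection-and-correction pipeline, the baseline resamplers, and the
#' evaluation harness on the held-out 30%, writing every intermediate
#' dataset, the representation report, the evaluation report, a grouped
#' bar chart of the representation shares and a JSON manifest into the
#' output directory.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "bb_run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  d0 <- .stage("load", {
    if (!is.null(config$data)) config$data
    else switch(config$fixture$name,
                cvd_like = make_cvd_like(config$fixture$n, seed),
                covid_like = make_covid_like(config$fixture$n, seed),
                stop("unknown fixture '", config$fixture$name, "'"))
  })
  sch <- d0$schema
  idx <- .stage("split",
    stratified_split_idx(d0, sch$target, 0.7, seed = seed + 1L))
  train <- subset_rows(d0, idx$a)
  test <- subset_rows(d0, idx$b)
  stopifnot(length(intersect(idx$a, idx$b)) == 0,
            length(union(idx$a, idx$b)) == nrow(d0$data))
  d_bias <- .stage("bias", {
    if (config$experiment == "simulation")
      inject_bias(train, config$bias, seed = seed + 2L)
    else retag(train, "biased")
  })
  write_dataset(d_bias, file.path(out, "d_bias.csv"))
  bres <- .stage("bayesboost",
    bayesboost(d_bias, fractions = config$fractions,
               calibrate = config$calibrate, config = config$uncertainty,
               seed = seed + 3L))
  write_dataset(bres$d_unc, file.path(out, "d_unc.csv"))
  for (nm in names(bres$bb))
    write_dataset(bres$bb[[nm]], file.path(out, paste0(nm, ".csv")),
                  include_provenance = TRUE)
  utils::write.csv(bres$report, file.path(out, "representation_report.csv"),
                   row.names = FALSE)
  candidates <- list()
  if (config$experiment == "simulation") candidates$D <- train
  candidates$D_Bias <- d_bias
  for (f in config$fractions) {
    nm <- paste0("BB", round(100 * f))
    plan <- compute_m(nrow(d_bias$data), nrow(bres$d_unc$data), f)
    local({
      plan_f <- plan
      candidates[[nm]] <<- function(s)
        boost(d_bias, bres$d_unc, plan_f, bres$ordering, seed = s)
    })
  }
  if (config$baselines) {
    candidates$SMOTE <- function(s) smote(d_bias, seed = s)
    candidates$AdaSyn <- function(s) adasyn(d_bias, seed = s)
    if (!is.null(config$privilege_map))
      candidates$F_SMOTE <- function(s)
        fair_smote(d_bias, privilege_map = config$privilege_map, seed = s)
  }
  eval_report <- .stage("evaluate",
    evaluate_candidates(candidates, test, n_runs = config$n_runs,
                        seed = seed + 4L, protected = sch$protected))
  utils::write.csv(eval_report, file.path(out, "evaluation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(eval_report, file.path(out, "evaluation.json"),
                       dataframe = "rows", digits = NA)
  .stage("plot",
    plot_representation(bres$report,
                        boosted = bres$bb[[length(bres$bb)]],
                        file = file.path(out, "representation.png")))
  manifest <- list(
    experiment = config$experiment,
    fixture = config$fixture,
    target = sch$target, protected = sch$protected,
    n_total = nrow(d0$data), n_train = length(idx$a),
    n_test = length(idx$b),
    bias = if (!is.null(config$bias)) unclass(config$bias),
    pipeline = bres$manifest,
    n_runs = config$n_runs, seed = seed,
    package_version = as.character(utils::packageVersion("bayesboost")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}

#' Grouped bar chart of protected-group shares
#'
#' Reference vs uncertain-set shares from a representation report, with an
#' optional boosted dataset's shares alongside.
#'
#' @param report A [representation_report()] result.
#' @param boosted Optional boosted [bb_dataset()].
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @export
plot_representation <- function(report, boosted = NULL, file = NULL) {
  h <- rbind(reference = report$reference_share,
             uncertain = report$uncertain_share)
  if (!is.null(boosted)) {
    prot <- boosted$schema$protected
    sh <- measure_representation(boosted, prot)[report$level]
    h <- rbind(h, boosted = as.numeric(sh))
  }
  colnames(h) <- report$level
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(h, beside = TRUE, las = 2,
                    col = c("forestgreen", "goldenrod",
                            "steelblue")[seq_len(nrow(h))],
                    ylab = "share",
                    legend.text = rownames(h),
                    args.legend = list(x = "topright", bty = "n"))
  invisible(NULL)
}
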