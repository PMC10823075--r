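# Seeded generators of primary-care-like datasets drawn from hand-authored
# networks with known parameters (committed as YAML), so detection and
# correction can be tested by parameter recovery. These are structural
# stand-ins for licence-restricted primary-care extracts, not replicas.

.fixture_env <- new.env(parent = emptyenv())

fixture_network <- function(name) {
  if (is.null(.fixture_env[[name]])) {
    path <- system.file("extdata", paste0(name, "_bn.yaml"),
                        package = "bayesboost")
    if (!nzchar(path)) stop("fixture network '", name, "' not installed",
                            call. = FALSE)
    .fixture_env[[name]] <- bn_read_yaml(path)
  }
  .fixture_env[[name]]
}

# draw from a pinned network and convert interval-labelled nodes to numerics
.sample_fixture <- function(bn, n, numeric_vars) {
  df <- .logic_sample_impl(bn, n)
  for (v in numeric_vars) {
    b <- .parse_bin_label(levels(df[[v]]))
    m <- match(as.character(df[[v]]), b$label)
    df[[v]] <- b$low[m] + stats::runif(n) * (b$high[m] - b$low[m])
  }
  df
}

.fixture_schema <- function(bn, numeric_vars, target, protected,
                            extra = list()) {
  vars <- lapply(bn$nodes, function(j)
    if (j %in% numeric_vars) "numeric" else bn$levels[[j]])
  names(vars) <- bn$nodes
  vars <- c(vars, extra)
  bb_schema(vars, target = target, protected = protected)
}

#' Generate a cardiovascular-risk-like synthetic cohort
#'
#' Draws `n` patients from a pinned, enumerable network over gender,
#' ethnicity (10 levels), region (10 levels), age, smoking, BMI and
#' systolic blood pressure, with three binary disease targets
#' (`stroke_heart_attack`, `atrial_fibrillation`, `type2_diabetes`) that
#' depend on age, smoking, BMI and the protected attributes. Disease
#' positives are the minority class; the ethnicity baseline is heavily
#' skewed toward "White or not stated".
#'
#' @param n Number of rows (>= 100).
#' @param seed Integer seed.
#' @param target Which disease column to designate as the target.
#' @param protected Which attribute to designate as protected.
#' @return A [bb_dataset()] with role `"ground_truth"`.
#' @export
make_cvd_like <- function(n, seed, target = "stroke_heart_attack",
                          protected = "ethnicity") {
  if (n < 100) stop("cvd_like fixture requires n >= 100", call. = FALSE)
  bn <- fixture_network("cvd_like")
  numeric_vars <- c("age", "bmi", "systolic_bp")
  df <- withr::with_seed(seed, .sample_fixture(bn, n, numeric_vars))
  sch <- .fixture_schema(bn, numeric_vars, target, protected)
  bb_dataset(df, sch, role = "ground_truth")
}

.covid_bands <- data.frame(
  label = c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80-94"),
  low = c(18, 30, 40, 50, 60, 70, 80),
  high = c(30, 40, 50, 60, 70, 80, 95),
  stringsAsFactors = FALSE)

.age_category <- function(age) {
  i <- findInterval(age, .covid_bands$low)
  factor(.covid_bands$label[i], levels = .covid_bands$label)
}

#' Generate a pandemic-testing-like synthetic cohort
#'
#' Draws `n` patients from a pinned network over gender, region (10
#' levels) and age, with a binary `covid_diagnosis` target; an
#' `age_category` column is derived deterministically from numeric age so
#' the two are consistent by construction.
#'
#' @inheritParams make_cvd_like
#' @export
make_covid_like <- function(n, seed, target = "covid_diagnosis",
                            protected = "region") {
  if (n < 100) stop("covid_like fixture requires n >= 100", call. = FALSE)
  bn <- fixture_network("covid_like")
  df <- withr::with_seed(seed, .sample_fixture(bn, n, "age"))
  df$age_category <- .age_category(df$age)
  sch <- .fixture_schema(bn, "age", target, protected,
                         extra = list(age_category = .covid_bands$label))
  bb_dataset(df, sch, role = "ground_truth")
}

#' The pinned two-node oracle network
#'
#' A -> B with P(A=1) = 0.3, P(B=1|A=1) = 0.8, P(B=1|A=0) = 0.2; small
#' enough to enumerate exactly, used as the sampling/inference oracle.
#'
#' @return A `bb_bn`.
#' @export
make_toy_bn <- function() fixture_network("toy")
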