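#' Read a dataset from CSV against a declared schema
#'
#' @param path CSV file with a header row matching the schema's variable
#'   names (a `provenance` column, if present, is picked up as row
#'   provenance).
#' @param schema A [bb_schema()].
#' @param role Role tag for the resulting dataset.
#' @return A [bb_dataset()].
#' @export
read_dataset <- function(path, schema, role = "ground_truth") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  miss <- setdiff(variable_names(schema), names(raw))
  if (length(miss))
    stop("CSV header does not match schema; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(schema$target)) {
    tv <- raw[[schema$target]]
    if (anyNA(tv) || any(!nzchar(tv)))
      stop("missing values in target '", schema$target, "'", call. = FALSE)
  }
  prov <- NULL
  if ("provenance" %in% names(raw)) prov <- raw[["provenance"]]
  bb_dataset(raw, schema, role = role, provenance = prov)
}

#' Write a dataset to CSV
#'
#' Columns are emitted in schema order; categorical values as their level
#' strings. The provenance column is included only on request.
#'
#' @param dataset A [bb_dataset()].
#' @param path Output file.
#' @param include_provenance Append the per-row provenance column?
#' @export
write_dataset <- function(dataset, path, include_provenance = FALSE) {
  stopifnot(inherits(dataset, "bb_dataset"))
  df <- dataset$data
  for (v in names(df)) if (is.factor(df[[v]])) df[[v]] <- as.character(df[[v]])
  if (include_provenance && !is.null(dataset$provenance))
    df$provenance <- dataset$provenance
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

# index version used where leakage bookkeeping needs the row ids
stratified_split_idx <- function(dataset, strata, fraction, seed) {
  stopifnot(inherits(dataset, "bb_dataset"),
            fraction > 0, fraction < 1)
  x <- dataset$data[[strata]]
  if (is.null(x)) stop("unknown strata variable '", strata, "'", call. = FALSE)
  by_level <- split(seq_len(nrow(dataset$data)), x)
  empty <- names(by_level)[lengths(by_level) == 0]
  if (length(empty)) {
    warning("strata level(s) with no rows skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
    by_level <- by_level[lengths(by_level) > 0]
  }
  a_idx <- withr::with_seed(seed, {
    unlist(lapply(by_level, function(ix) {
      n_a <- rhu(fraction * length(ix))
      if (n_a == 0) return(integer())
      sample(ix)[seq_len(n_a)]
    }), use.names = FALSE)
  })
  a_idx <- sort(a_idx)
  list(a = a_idx, b = setdiff(seq_len(nrow(dataset$data)), a_idx))
}

#' Stratified random split
#'
#' Within each level of the strata variable, `round(fraction * n_level)`
#' rows (round half up) go to the first part; the remainder to the second.
#' The union is a partition of the input and the result is deterministic
#' under a fixed seed.
#'
#' @param dataset A [bb_dataset()].
#' @param strata Name of a categorical variable whose levels are the strata.
#' @param fraction Share of each stratum assigned to the first part,
#'   in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `a` and `b`, both [bb_dataset()]s.
#' @export
stratified_split <- function(dataset, strata, fraction, seed) {
  idx <- stratified_split_idx(dataset, strata, fraction, seed)
  list(a = subset_rows(dataset, idx$a), b = subset_rows(dataset, idx$b))
}

#' Serialize a schema to YAML
#'
#' @param schema A [bb_schema()].
#' @param path Output file.
#' @export
schema_to_yaml <- function(schema, path) {
  doc <- list(
    variables = lapply(schema$variables, function(v)
      if (identical(v, "numeric")) "numeric" else as.list(v)),
    target = schema$target,
    protected = schema$protected
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a schema from YAML
#'
#' @param path YAML file written by [schema_to_yaml()] (or hand-authored in
#'   the same layout).
#' @return A [bb_schema()].
#' @export
schema_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  vars <- lapply(doc$variables, function(v)
    if (identical(v, "numeric")) "numeric" else unlist(v))
  bb_schema(vars, target = doc$target, protected = doc$protected)
}
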