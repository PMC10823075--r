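#' Declare the schema of a patient-level tabular dataset
#'
#' A schema names every variable, declares it categorical (with its full set
#' of levels) or numeric, and optionally designates a binary disease target
#' and a discrete protected attribute whose levels define the population
#' groups audited for under-representation.
#'
#' @param variables Named list. Each element is either the character vector
#'   of declared levels (categorical) or the string `"numeric"`.
#' @param target Optional name of the target variable; must be categorical
#'   with levels exactly `c("0", "1")`.
#' @param protected Optional name of the protected attribute; must be
#'   categorical with at least two levels.
#' @return An object of class `bb_schema`.
#' @examples
#' bb_schema(
#'   list(gender = c("M", "F"), age = "numeric", stroke = c("0", "1")),
#'   target = "stroke", protected = "gender"
#' )
#' @export
bb_schema <- function(variables, target = NULL, protected = NULL) {
  if (!is.list(variables) || length(variables) == 0)
    stop("'variables' must be a non-empty named list", call. = FALSE)
  nm <- names(variables)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every variable must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("variable names must be unique", call. = FALSE)
  kinds <- vapply(variables, function(v)
    if (length(v) == 1 && identical(v, "numeric")) "numeric" else "categorical",
    character(1))
  for (i in seq_along(variables)) {
    if (kinds[[i]] == "categorical") {
      lev <- variables[[i]]
      if (!is.character(lev) || length(lev) < 1 || anyDuplicated(lev) ||
          anyNA(lev))
        stop("categorical variable '", nm[[i]],
             "' needs distinct character levels", call. = FALSE)
    }
  }
  if (!is.null(target)) {
    if (!target %in% nm)
      stop("target '", target, "' is not a declared variable", call. = FALSE)
    if (kinds[[target]] != "categorical" ||
        !setequal(variables[[target]], c("0", "1")))
      stop("target '", target, "' must be categorical with levels {0, 1}",
           call. = FALSE)
  }
  if (!is.null(protected)) {
    if (!protected %in% nm)
      stop("protected '", protected, "' is not a declared variable",
           call. = FALSE)
    if (kinds[[protected]] != "categorical" ||
        length(variables[[protected]]) < 2)
      stop("protected attribute '", protected,
           "' must be categorical with at least two levels", call. = FALSE)
  }
  structure(list(variables = variables, kinds = kinds,
                 target = target, protected = protected),
            class = "bb_schema")
}

variable_names <- function(schema) names(schema$variables)

schema_levels <- function(schema, var) schema$variables[[var]]

is_numeric_var <- function(schema, var) schema$kinds[[var]] == "numeric"

#' @export
print.bb_schema <- function(x, ...) {
  cat("<bb_schema> ", length(x$variables), " variables\n", sep = "")
  for (v in variable_names(x)) {
    tag <- if (!is.null(x$target) && v == x$target) " [target]"
           else if (!is.null(x$protected) && v == x$protected) " [protected]"
           else ""
    if (is_numeric_var(x, v)) cat("  ", v, ": numeric", tag, "\n", sep = "")
    else cat("  ", v, ": ", length(schema_levels(x, v)), " levels", tag,
             "\n", sep = "")
  }
  invisible(x)
}

.bb_roles <- c("ground_truth", "biased", "uncertain", "boosted", "baseline")

#' Construct a typed tabular dataset
#'
#' Wraps a data frame with its schema, a role tag describing where the data
#' sits in the detection/correction pipeline, and an optional per-row
#' provenance tag. Categorical cells are validated against their declared
#' levels; missing target values are rejected.
#'
#' @param data Data frame (or coercible) with one column per schema variable.
#' @param schema A [bb_schema()].
#' @param role One of `"ground_truth"`, `"biased"`, `"uncertain"`,
#'   `"boosted"`, `"baseline"`.
#' @param provenance Optional character vector (`"original"`/`"synthetic"`),
#'   one entry per row.
#' @return An object of class `bb_dataset`.
#' @export
bb_dataset <- function(data, schema, role = "ground_truth",
                       provenance = NULL) {
  stopifnot(inherits(schema, "bb_schema"))
  role <- match.arg(role, .bb_roles)
  data <- as.data.frame(data)
  miss <- setdiff(variable_names(schema), names(data))
  if (length(miss))
    stop("columns missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data[variable_names(schema)]
  for (v in variable_names(schema)) {
    if (is_numeric_var(schema, v)) {
      x <- out[[v]]
      was_na <- is.na(x)
      x <- suppressWarnings(as.numeric(as.character(x)))
      if (any(is.na(x) & !was_na))
        stop("non-numeric value in column '", v, "'", call. = FALSE)
      out[[v]] <- x
    } else {
      lev <- schema_levels(schema, v)
      x <- as.character(out[[v]])
      f <- factor(x, levels = lev)
      bad <- which(is.na(f) & !is.na(x))
      if (length(bad))
        stop("unknown level '", x[bad[1]], "' in column '", v, "'",
             call. = FALSE)
      out[[v]] <- f
    }
  }
  if (!is.null(schema$target) && anyNA(out[[schema$target]]))
    stop("missing values in target '", schema$target, "'", call. = FALSE)
  if (nrow(out) == 0)
    stop("dataset must contain at least one row", call. = FALSE)
  if (!is.null(provenance)) {
    provenance <- as.character(provenance)
    if (length(provenance) != nrow(out) ||
        !all(provenance %in% c("original", "synthetic")))
      stop("provenance must be 'original'/'synthetic', one per row",
           call. = FALSE)
  }
  rownames(out) <- NULL
  structure(list(data = out, schema = schema, role = role,
                 provenance = provenance),
            class = "bb_dataset")
}

# row subset preserving schema/provenance; bypasses the non-empty check so
# degenerate selections (e.g. a zero-gap fairness criterion) stay representable
subset_rows <- function(ds, idx, role = ds$role) {
  new <- ds$data[idx, , drop = FALSE]
  rownames(new) <- NULL
  structure(list(data = new, schema = ds$schema, role = role,
                 provenance = if (!is.null(ds$provenance)) ds$provenance[idx]),
            class = "bb_dataset")
}

retag <- function(ds, role) {
  role <- match.arg(role, .bb_roles)
  ds$role <- role
  ds
}

#' @export
dim.bb_dataset <- function(x) dim(x$data)

#' @export
as.data.frame.bb_dataset <- function(x, ...) x$data

#' @export
print.bb_dataset <- function(x, ...) {
  cat("<bb_dataset> ", nrow(x$data), " rows x ", ncol(x$data),
      " variables, role = ", x$role, "\n", sep = "")
  if (!is.null(x$provenance)) {
    tab <- table(x$provenance)
    cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# round-half-up, used for every size contract
rhu <- function(x) floor(x + 0.5)

# deterministic largest-remainder apportionment of `total` across weights w
largest_remainder <- function(w, total) {
  if (total == 0) return(integer(length(w)))
  raw <- w / sum(w) * total
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    o <- order(raw - base, seq_along(raw), decreasing = c(TRUE, FALSE),
               method = "radix")
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}
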