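# Categorical variables and cohort tables.
#
# A variable is a name plus an ordered set of mutually exclusive state labels;
# a cohort table is an n x p data.frame of factors whose levels are exactly the
# declared states. State labels are compared verbatim after trimming outer
# whitespace; the declared spellings are canonical.

#' Define a categorical variable
#'
#' @param name Variable name (non-empty string).
#' @param states Character vector of at least two unique state labels, in
#'   their canonical declaration order.
#' @return An object of class `catvar` with elements `name` and `states`.
#' @examples
#' categorical_variable("T2D", c("Yes", "No"))
#' @export
categorical_variable <- function(name, states) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  states <- trimws(as.character(states))
  if (length(states) < 2L)
    stop("variable '", name, "' needs at least 2 states")
  if (anyDuplicated(states))
    stop("variable '", name, "' has duplicated state labels")
  structure(list(name = name, states = states), class = "catvar")
}

#' @export
print.catvar <- function(x, ...) {
  cat(sprintf("<%s: %s>\n", x$name, paste(x$states, collapse = ", ")))
  invisible(x)
}

#' The 12 study variables of the T2D cohort
#'
#' The canonical variable set of the prediabetes-to-T2D domain: demographics
#' (GENDER, AGE, SOCIALs), lifestyle (SMOKING, PA, DIET), clinical markers
#' (HbA1c, FLI, BMI, BP, TG) and the diagnostic outcome T2D. State labels and
#' the variable order are canonical for all cohort I/O in this package.
#'
#' @return Named list of 12 [categorical_variable()] objects, in canonical
#'   column order.
#' @examples
#' names(t2d_variables())
#' t2d_variables()$FLI$states
#' @export
t2d_variables <- function() {
  vars <- list(
    categorical_variable("GENDER",  c("Men", "Women")),
    categorical_variable("T2D",     c("Yes", "No")),
    categorical_variable("SOCIALs", c("I", "II", "III")),
    categorical_variable("SMOKING", c("No", "Former smoker", "Yes")),
    categorical_variable("PA",      c("Yes", "No")),
    categorical_variable("DIET",    c("Yes", "No")),
    categorical_variable("HbA1c",   c("Less 6.0", "More 6.0")),
    categorical_variable("FLI",     c("Less 30", "30-60", "More 60")),
    categorical_variable("BMI",     c("Underweight", "Normal weight",
                                      "Overweight", "Obesity")),
    categorical_variable("BP",      c("Normal", "High", "Grade 1", "Grade 2")),
    categorical_variable("TG",      c("Normal", "Limit", "Hyper")),
    categorical_variable("AGE",     c("18-32", "33-47", "48-62"))
  )
  stats::setNames(vars, vapply(vars, `[[`, "", "name"))
}

#' Expert block ordering of the study variables
#'
#' Background variables precede lifestyle ("conditional") variables, which
#' precede intermediate clinical markers, which precede the diagnostic
#' outcome. Arcs from a later block into an earlier block are causally
#' implausible and are blacklisted during structure learning
#' (see [blacklist_from_blocks()]).
#'
#' @return Ordered list of character vectors of variable names.
#' @export
t2d_blocks <- function() {
  list(
    background   = c("GENDER", "AGE", "SOCIALs"),
    conditional  = c("DIET", "SMOKING", "PA", "BMI"),
    intermediate = c("HbA1c", "FLI", "BP", "TG"),
    diagnostic   = "T2D"
  )
}

#' Construct and validate a cohort table
#'
#' Coerces a data.frame of observed categorical records into the canonical
#' cohort representation: one factor column per variable with levels equal to
#' the declared states. Cells are trimmed of outer whitespace and compared
#' verbatim to the declared labels. `NA` cells are admitted as an explicit
#' missing marker, but every learning and validation operation in this
#' package rejects missing data with an error (complete-case semantics).
#'
#' @param data A data.frame (or object coercible to one) whose columns cover
#'   `variables`.
#' @param variables Named list of [categorical_variable()]s (default the 12
#'   study variables restricted to the columns present).
#' @return A data.frame of class `cohort` with columns in declaration order.
#' @export
as_cohort <- function(data, variables = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) < 1L) stop("a cohort table needs at least one record")
  if (anyDuplicated(names(data))) stop("duplicated column names in cohort")
  if (is.null(variables)) {
    variables <- t2d_variables()
    variables <- variables[names(variables) %in% names(data)]
    if (length(variables) == 0L)
      stop("no known study variables among columns: supply 'variables'")
  }
  vn <- vapply(variables, `[[`, "", "name")
  names(variables) <- vn
  missing_cols <- setdiff(vn, names(data))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  out <- data[vn]
  for (v in variables) {
    col <- out[[v$name]]
    if (is.factor(col)) col <- as.character(col)
    col <- trimws(as.character(col))
    bad <- !is.na(col) & !(col %in% v$states)
    if (any(bad))
      stop(sprintf("column '%s' contains values outside its domain: %s",
                   v$name, paste(unique(col[bad]), collapse = ", ")))
    out[[v$name]] <- factor(col, levels = v$states)
  }
  attr(out, "variables") <- variables
  class(out) <- c("cohort", "data.frame")
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort table: %d records x %d variables\n", nrow(x), ncol(x)))
  NextMethod()
}

cohort_variables <- function(data) {
  v <- attr(data, "variables")
  if (!is.null(v)) return(v)
  stats::setNames(
    lapply(names(data), function(nm) categorical_variable(nm, levels(data[[nm]]))),
    names(data))
}

# Integer matrix view used by counting/likelihood kernels; errors on NA.
cohort_codes <- function(data, allow_missing = FALSE) {
  m <- vapply(data, as.integer, integer(nrow(data)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(data),
                                 dimnames = list(NULL, names(data)))
  if (!allow_missing && anyNA(m))
    stop("cohort contains missing values; complete cases are required here")
  m
}

#' Read / write a cohort table as CSV
#'
#' Plain UTF-8 comma-separated text with a header row; cells are state labels.
#' Writing then reading restores the table cell-for-cell.
#'
#' @param path File path.
#' @param variables As in [as_cohort()].
#' @return `read_cohort` returns a `cohort` data.frame; `write_cohort`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path, variables = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  as_cohort(df, variables)
}

#' @rdname read_cohort
#' @param data A `cohort` (or coercible data.frame).
#' @export
write_cohort <- function(data, path) {
  df <- as.data.frame(lapply(data, as.character), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
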