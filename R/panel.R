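#' Variable schema for the two-wave mediation panel
#'
#' One row per variable: its role in the mediation model and, for bounded
#' scale scores, the response-scale bounds used for validation, truncation
#' of simulated values, and clipping of imputed values. Demographic bounds
#' are `NA` (unchecked) except for the binary gender indicator and the
#' three-level immigrant-generation code.
#'
#' Roles: `id`, `predictor` (T1 perceived impact of SB 1070, 1-9),
#' `mediator` (T2 ethnic centrality / private regard / public regard),
#' `outcome` (T2 self-esteem), `lagged` (T1 measures of the four repeated
#' constructs, covariates in every equation), `auxiliary` (T0 measures, used
#' only to inform imputation), and `demographic`.
#'
#' @return A tibble with columns `variable`, `role`, `lo`, `hi`.
#' @export
default_panel_schema <- function() {
  tibble::tribble(
    ~variable,    ~role,         ~lo, ~hi,
    "subject_id", "id",          NA,  NA,
    "x_t1",       "predictor",   1,   9,
    "m1_t2",      "mediator",    1,   5,
    "m2_t2",      "mediator",    1,   5,
    "m3_t2",      "mediator",    1,   4,
    "y_t2",       "outcome",     1,   4,
    "u1_t1",      "lagged",      1,   5,
    "u2_t1",      "lagged",      1,   5,
    "u3_t1",      "lagged",      1,   4,
    "u4_t1",      "lagged",      1,   4,
    "aux1_t0",    "auxiliary",   1,   5,
    "aux2_t0",    "auxiliary",   1,   5,
    "aux3_t0",    "auxiliary",   1,   4,
    "aux4_t0",    "auxiliary",   1,   4,
    "gender",     "demographic", 0,   1,
    "generation", "demographic", 1,   3,
    "age",        "demographic", NA,  NA
  )
}

#' Names of the analysis variables (the nine variables in the path model)
#' @param schema A panel schema tibble.
#' @return Character vector.
#' @export
analysis_vars <- function(schema = default_panel_schema()) {
  schema$variable[schema$role %in% c("predictor", "mediator", "outcome", "lagged")]
}

auxiliary_vars <- function(schema = default_panel_schema()) {
  schema$variable[schema$role == "auxiliary"]
}

demographic_vars <- function(schema = default_panel_schema()) {
  schema$variable[schema$role == "demographic"]
}

#' Construct and validate a panel table
#'
#' A panel table is a tibble of subject-level records for the two-wave
#' mediation design, validated against a schema: subject ids must be unique
#' and every observed value of a bounded variable must lie inside its
#' response-scale bounds. Missing cells are `NA`; the boolean missingness
#' mask is available via [missingness_mask()] and agrees with the data
#' cell-by-cell by construction.
#'
#' @param df A data frame with a `subject_id` column and any subset of the
#'   schema's variables.
#' @param schema A schema tibble, by default [default_panel_schema()].
#' @return A tibble of class `panel_table` with the schema attached.
#' @export
panel_table <- function(df, schema = default_panel_schema()) {
  df <- tibble::as_tibble(df)
  if (!"subject_id" %in% names(df)) abort("A `subject_id` column is required.")
  unknown <- setdiff(names(df), schema$variable)
  if (length(unknown)) {
    abort(sprintf("Unknown columns not in the schema: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(df$subject_id)) {
    abort("`subject_id` values must be unique.")
  }
  for (v in setdiff(names(df), "subject_id")) {
    row <- schema[schema$variable == v, ]
    vals <- df[[v]]
    if (!is.numeric(vals)) {
      abort(sprintf("Column `%s` must be numeric.", v))
    }
    if (!is.na(row$lo)) {
      obs <- vals[!is.na(vals)]
      if (any(obs < row$lo | obs > row$hi)) {
        abort(sprintf(
          "Observed values of `%s` fall outside its scale bounds [%g, %g].",
          v, row$lo, row$hi
        ))
      }
    }
  }
  structure(df, schema = schema,
            class = c("panel_table", class(tibble::tibble())))
}

#' @export
print.panel_table <- function(x, ...) {
  n_miss <- sum(is.na(as.data.frame(x)[setdiff(names(x), "subject_id")]))
  cat(sprintf("<panel_table> %d subjects, %d variables, %d missing cells\n",
              nrow(x), ncol(x) - 1, n_miss))
  NextMethod()
}

panel_schema <- function(tbl) {
  attr(tbl, "schema") %||% default_panel_schema()
}

#' Boolean missingness mask of a panel table
#'
#' @param tbl A [panel_table()].
#' @return Logical matrix, `TRUE` where the cell is missing; rows follow the
#'   table, columns are the non-id variables.
#' @export
missingness_mask <- function(tbl) {
  vars <- setdiff(names(tbl), "subject_id")
  m <- is.na(as.matrix(as.data.frame(tbl)[vars]))
  rownames(m) <- tbl$subject_id
  m
}

#' Read a panel table from CSV
#'
#' One row per subject, header row, a configurable missing-value token
#' (default: the empty cell). Validation is as in [panel_table()]: duplicate
#' ids, unknown columns, and observed values outside their scale bounds are
#' errors.
#'
#' @param path CSV file path.
#' @param schema Panel schema tibble.
#' @param na Missing-value token(s).
#' @return A [panel_table()].
#' @export
read_panel <- function(path, schema = default_panel_schema(), na = "") {
  df <- readr::read_csv(path, na = na, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double(),
                                                subject_id = readr::col_character()))
  panel_table(df, schema = schema)
}

#' Write a panel table to CSV
#'
#' Missing cells are written as the empty token so that
#' `read_panel(write_panel(x))` round-trips both data and mask.
#'
#' @param tbl A [panel_table()].
#' @param path Output CSV path.
#' @param na Token used for missing cells.
#' @return `path`, invisibly.
#' @export
write_panel <- function(tbl, path, na = "") {
  readr::write_csv(tibble::as_tibble(tbl), path, na = na)
  invisible(path)
}

#' Per-variable missingness summary
#'
#' Reports, for each non-id variable, the number and percentage of missing
#' cells, together with the complete-case count over the analysis variables
#' (attached as attribute `n_complete` and shown by `print`).
#'
#' @param tbl A [panel_table()].
#' @return A tibble with columns `variable`, `n`, `n_missing`, `pct_missing`.
#' @export
summarize_missingness <- function(tbl) {
  vars <- setdiff(names(tbl), "subject_id")
  out <- tibble::tibble(
    variable = vars,
    n = nrow(tbl),
    n_missing = unname(vapply(vars, function(v) sum(is.na(tbl[[v]])), integer(1))),
  )
  out$pct_missing <- 100 * out$n_missing / out$n
  av <- intersect(analysis_vars(panel_schema(tbl)), names(tbl))
  attr(out, "n_complete") <- sum(complete.cases(as.data.frame(tbl)[av]))
  out
}
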