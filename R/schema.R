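#' Declare one variable of a cohort schema
#'
#' A schema entry records how a column is read and how downstream stages may
#' treat it: its measurement role, an optional admissible range enforced by
#' value screening, the ordered level labels of ordinal/categorical variables,
#' whether the variable is exempt from discretization, and whether it is
#' blacklisted as an arc sink (no incoming arcs in any learned DAG).
#'
#' @param name column name (single string).
#' @param role one of `"continuous"`, `"ordinal"`, `"categorical"`.
#' @param range optional closed numeric interval `c(lower, upper)`,
#'   `lower < upper`; only meaningful for numeric-valued variables.
#' @param levels ordered character vector of labels; required for ordinal and
#'   categorical roles (labels are encoded to integer codes `1..L` in this
#'   order), forbidden for continuous ones.
#' @param discretization_exempt if `TRUE` the variable passes through
#'   discretization unchanged.
#' @param blacklist if `TRUE` the variable may not receive incoming arcs
#'   during structure learning.
#' @return an object of class `consnet_varschema`.
#' @export
variable_schema <- function(name, role = c("continuous", "ordinal", "categorical"),
                            range = NULL, levels = NULL,
                            discretization_exempt = FALSE, blacklist = FALSE) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (role == "continuous" && !is.null(levels))
    stop("continuous variable '", name, "' must not declare levels")
  if (role != "continuous" && is.null(levels))
    stop(role, " variable '", name, "' requires ordered levels")
  if (!is.null(levels) && anyDuplicated(levels))
    stop("duplicate levels for variable '", name, "'")
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, is.numeric(range), all(is.finite(range)))
    if (range[1] >= range[2]) stop("admissible range for '", name,
                                   "' must have lower < upper")
  }
  structure(list(name = name, role = role, range = range,
                 levels = if (is.null(levels)) NULL else as.character(levels),
                 discretization_exempt = isTRUE(discretization_exempt),
                 blacklist = isTRUE(blacklist)),
            class = "consnet_varschema")
}

#' Assemble a cohort schema
#'
#' @param ... `variable_schema` entries (or a single list of them).
#' @return an object of class `consnet_schema`: a named list of entries in
#'   declaration order (the stable column order of the cohort).
#' @export
cohort_schema <- function(...) {
  vs <- list(...)
  if (length(vs) == 1L && !inherits(vs[[1]], "consnet_varschema")) vs <- vs[[1]]
  ok <- vapply(vs, inherits, logical(1), what = "consnet_varschema")
  if (!all(ok)) stop("all schema entries must be variable_schema objects")
  nms <- vapply(vs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in schema")
  structure(setNames(vs, nms), class = "consnet_schema")
}

#' Read a schema from a JSON configuration file
#'
#' One object per variable with fields `name`, `role`, optional `range`,
#' `levels`, `discretization_exempt`, `blacklist`.
#'
#' @param path path to a JSON file.
#' @return a `consnet_schema`.
#' @export
schema_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  cohort_schema(lapply(raw, function(e) {
    variable_schema(name = e$name, role = e$role,
                    range = if (is.null(e$range)) NULL else as.numeric(unlist(e$range)),
                    levels = if (is.null(e$levels)) NULL else as.character(unlist(e$levels)),
                    discretization_exempt = isTRUE(e$discretization_exempt),
                    blacklist = isTRUE(e$blacklist))
  }))
}

#' Write a schema to JSON
#' @param schema a `consnet_schema`.
#' @param path output path.
#' @export
schema_to_json <- function(schema, path) {
  jsonlite::write_json(lapply(unname(schema), unclass), path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Construct a cohort table from in-memory data
#'
#' Columns are matched to the schema by name (order-insensitive; stored in
#' schema order). Ordinal/categorical labels are mapped to integer codes
#' `1..L` in the schema-declared level order; already-numeric codes are
#' accepted if they fall in `1..L`.
#'
#' @param data a data.frame, one row per participant.
#' @param schema a `consnet_schema`.
#' @return an object of class `consnet_cohort` with elements `data` (numeric
#'   data.frame in schema column order), `schema`, and `codes` (the label
#'   mapping per encoded variable).
#' @export
cohort_table <- function(data, schema) {
  stopifnot(inherits(schema, "consnet_schema"))
  nms <- names(schema)
  extra <- setdiff(names(data), nms)
  if (length(extra)) stop("column not declared in schema: ",
                          paste(extra, collapse = ", "))
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols)) stop("schema variable absent from data: ",
                                 paste(missing_cols, collapse = ", "))
  if (anyDuplicated(names(data))) stop("duplicate column in data")
  out <- vector("list", length(nms))
  codes <- list()
  for (k in seq_along(nms)) {
    v <- schema[[k]]
    x <- data[[v$name]]
    if (v$role == "continuous") {
      if (is.character(x)) {
        xx <- suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
        bad <- which(!is.na(x) & x != "" & is.na(xx))
        if (length(bad)) stop("unparseable cell in column '", v$name,
                              "' at row ", bad[1], ": '", x[bad[1]], "'")
        x <- xx
      }
      out[[k]] <- as.numeric(x)
    } else {
      L <- length(v$levels)
      if (is.numeric(x)) {
        bad <- which(!is.na(x) & (x < 1 | x > L | x != round(x)))
        if (length(bad)) stop("code out of range for '", v$name,
                              "' at row ", bad[1])
        out[[k]] <- as.numeric(x)
      } else {
        x <- as.character(x)
        x[x == ""] <- NA
        m <- match(x, v$levels)
        # integer codes written back by write_cohort_csv round-trip too
        num <- suppressWarnings(as.numeric(x))
        codes_ok <- !is.na(num) & num >= 1 & num <= L & num == round(num)
        m[is.na(m) & codes_ok] <- num[is.na(m) & codes_ok]
        bad <- which(!is.na(x) & is.na(m))
        if (length(bad)) stop("unparseable cell in column '", v$name,
                              "' at row ", bad[1], ": '", x[bad[1]], "'")
        out[[k]] <- as.numeric(m)
      }
      codes[[v$name]] <- v$levels
    }
  }
  df <- as.data.frame(setNames(out, nms), check.names = FALSE)
  structure(list(data = df, schema = schema, codes = codes),
            class = "consnet_cohort")
}

#' @export
dim.consnet_cohort <- function(x) dim(x$data)

#' @export
print.consnet_cohort <- function(x, ...) {
  cat("<consnet_cohort> ", nrow(x$data), " participants x ",
      ncol(x$data), " variables\n", sep = "")
  invisible(x)
}

#' Load a cohort CSV against a schema
#'
#' @param csv_path path to an RFC-4180 CSV with a header row.
#' @param schema a `consnet_schema`.
#' @param na_tokens strings treated as missing.
#' @return a `consnet_cohort` with missing cells flagged as `NA`.
#' @export
load_cohort <- function(csv_path, schema, na_tokens = c("", "NA")) {
  df <- utils::read.csv(csv_path, check.names = FALSE, colClasses = "character",
                        na.strings = na_tokens)
  cohort_table(df, schema)
}

#' Declare a value-screening rule
#'
#' `less_than`/`greater_than` remove values strictly below/above the
#' threshold; `at_least` removes values greater than or equal to it.
#'
#' @param variable schema variable name.
#' @param predicate one of `"less_than"`, `"greater_than"`, `"at_least"`.
#' @param threshold finite numeric threshold in the variable's units.
#' @return an object of class `consnet_screen`.
#' @export
screening_rule <- function(variable, predicate = c("less_than", "greater_than", "at_least"),
                           threshold) {
  predicate <- match.arg(predicate)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  structure(list(variable = variable, predicate = predicate, threshold = threshold),
            class = "consnet_screen")
}

new_exclusion_log <- function(n_initial) {
  structure(list(
    n_initial = n_initial, n_final = n_initial,
    removed_values = data.frame(row = integer(), variable = character(),
                                value = numeric(), rule = character(),
                                stringsAsFactors = FALSE),
    removed_rows_incomplete = integer(),
    counts = c(values_removed = 0L, rows_removed = 0L)
  ), class = "consnet_exclusion_log")
}

#' @export
print.consnet_exclusion_log <- function(x, ...) {
  cat("<exclusion log> n: ", x$n_initial, " -> ", x$n_final,
      "; values removed: ", x$counts[["values_removed"]],
      "; incomplete rows removed: ", x$counts[["rows_removed"]], "\n", sep = "")
  invisible(x)
}

#' Apply value screens to a cohort
#'
#' Offending cells are set to missing (value-level removal); rows are not
#' dropped here, so the two-stage accounting "values removed, then partial
#' observations removed" is reproduced by following with [complete_cases()].
#'
#' @param table a `consnet_cohort`.
#' @param rules list of [screening_rule()] objects.
#' @return list with elements `table` (screened cohort) and `log`
#'   (`consnet_exclusion_log` recording each removed value and its rule).
#' @export
apply_screens <- function(table, rules) {
  stopifnot(inherits(table, "consnet_cohort"))
  if (inherits(rules, "consnet_screen")) rules <- list(rules)
  log <- new_exclusion_log(nrow(table$data))
  df <- table$data
  for (r in rules) {
    if (!r$variable %in% names(df))
      stop("screening rule references unknown variable '", r$variable, "'")
    x <- df[[r$variable]]
    off <- switch(r$predicate,
                  less_than = !is.na(x) & x < r$threshold,
                  greater_than = !is.na(x) & x > r$threshold,
                  at_least = !is.na(x) & x >= r$threshold)
    if (any(off)) {
      idx <- which(off)
      log$removed_values <- rbind(log$removed_values, data.frame(
        row = idx, variable = r$variable, value = x[idx],
        rule = paste0(r$variable, " ", r$predicate, " ", r$threshold),
        stringsAsFactors = FALSE))
      df[[r$variable]][idx] <- NA_real_
    }
  }
  log$counts[["values_removed"]] <- nrow(log$removed_values)
  table$data <- df
  list(table = table, log = log)
}

#' Drop rows with any missing cell
#'
#' @param table a `consnet_cohort`.
#' @param log optionally, the log returned by [apply_screens()], to be
#'   extended; a fresh log is opened otherwise.
#' @return list with elements `table` (complete-case cohort) and `log`.
#' @export
complete_cases <- function(table, log = NULL) {
  stopifnot(inherits(table, "consnet_cohort"))
  if (is.null(log)) log <- new_exclusion_log(nrow(table$data))
  keep <- stats::complete.cases(table$data)
  if (!any(keep)) stop("no complete observations remain")
  log$removed_rows_incomplete <- which(!keep)
  log$counts[["rows_removed"]] <- sum(!keep)
  log$n_final <- sum(keep)
  table$data <- table$data[keep, , drop = FALSE]
  rownames(table$data) <- NULL
  list(table = table, log = log)
}

#' Write an exclusion log to JSON
#' @param log a `consnet_exclusion_log`.
#' @param path output path.
#' @export
exclusion_log_to_json <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cohort back to CSV (codes as integers, `NA` as empty cells)
#' @param table a `consnet_cohort`.
#' @param path output path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  invisible(path)
}
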