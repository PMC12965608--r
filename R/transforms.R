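#' Discretization settings for the mutual-information (Hartemink) method
#'
#' @param levels target number of ordered bins per variable (3 or 5 in the
#'   standard suite).
#' @param initial_bins number of seed bins before merging (default 100).
#' @param initial_method `"interval"` (equal width) or `"quantile"` seed cut.
#' @param exempt_variables names passed through unchanged.
#' @return object of class `consnet_discspec`.
#' @export
discretization_spec <- function(levels, initial_bins = 100L,
                                initial_method = c("interval", "quantile"),
                                exempt_variables = character()) {
  initial_method <- match.arg(initial_method)
  stopifnot(levels >= 2, levels <= initial_bins)
  structure(list(levels = as.integer(levels),
                 initial_bins = as.integer(initial_bins),
                 initial_method = initial_method,
                 exempt_variables = exempt_variables),
            class = "consnet_discspec")
}

new_view <- function(kind, table, removed_rows = integer(), spec = NULL,
                     source_hash = NULL) {
  structure(list(kind = kind, table = table, removed_rows = removed_rows,
                 provenance = list(source_hash = source_hash, spec = spec)),
            class = "consnet_view")
}

#' @export
print.consnet_view <- function(x, ...) {
  cat("<consnet_view '", x$kind, "'> ", nrow(x$table$data), " x ",
      ncol(x$table$data), "\n", sep = "")
  invisible(x)
}

view_data <- function(view) {
  if (inherits(view, "consnet_view")) view$table$data
  else if (inherits(view, "consnet_cohort")) view$data
  else as.data.frame(view)
}

view_schema <- function(view) {
  if (inherits(view, "consnet_view")) view$table$schema
  else if (inherits(view, "consnet_cohort")) view$schema
  else NULL
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Empirical mutual information between two discrete codings
#'
#' @param x,y integer (or integer-valued) vectors of equal length.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  n <- length(x)
  N <- table(x, y)
  sum(xlogx(N)) / n - sum(xlogx(rowSums(N))) / n - sum(xlogx(colSums(N))) / n + log(n)
}

# total pairwise MI over all unordered column pairs of a code matrix
total_pairwise_mi <- function(codes) {
  p <- ncol(codes)
  tot <- 0
  if (p < 2) return(0)
  for (i in seq_len(p - 1))
    for (j in (i + 1):p)
      tot <- tot + mutual_information(codes[, i], codes[, j])
  tot
}

# initial seed cut; returns dense codes 1..b over occupied bins only
seed_cut <- function(x, initial_bins, method) {
  if (length(unique(x)) == 1L) return(rep(1L, length(x)))
  if (method == "interval") {
    br <- seq(min(x), max(x), length.out = initial_bins + 1L)
  } else {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = initial_bins + 1L)))
  }
  code <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(match(code, sort(unique(code))))  # drop empty bins, keep order
}

# loss in n*MI(x_v, u) for every adjacent bin merge of v, vectorized over pairs
merge_deltas_vs <- function(Nvu) {
  b <- nrow(Nvu)
  A <- Nvu[-b, , drop = FALSE] + Nvu[-1, , drop = FALSE]
  r <- rowSums(Nvu)
  rowSums(xlogx(A) - xlogx(Nvu[-b, , drop = FALSE]) - xlogx(Nvu[-1, , drop = FALSE])) -
    (xlogx(r[-b] + r[-1]) - xlogx(r[-b]) - xlogx(r[-1]))
}

#' Mutual-information-preserving discretization
#'
#' Each non-exempt numeric variable is first cut into `initial_bins`
#' equal-width (or equal-frequency) seed bins; adjacent bins are then merged
#' greedily, one pair at a time in a round-robin sweep over variables in
#' schema order, choosing at each step the merge that minimizes the loss of
#' total pairwise mutual information with all other variables, until `levels`
#' bins remain. Output codes are `1..levels` in value order, so the map is
#' monotone in the original values.
#'
#' @param table a `consnet_cohort` (complete cases).
#' @param spec a [discretization_spec()].
#' @return a `consnet_view` of kind `disc3`/`disc5` (by `spec$levels`).
#' @export
discretize_hartemink <- function(table, spec) {
  stopifnot(inherits(table, "consnet_cohort"), inherits(spec, "consnet_discspec"))
  df <- table$data
  if (anyNA(df)) stop("discretization requires complete cases")
  nms <- names(df)
  work <- setdiff(nms, spec$exempt_variables)
  codes <- matrix(0L, nrow(df), length(work), dimnames = list(NULL, work))
  nbins <- integer(length(work))
  for (k in seq_along(work)) {
    x <- df[[work[k]]]
    if (!is.numeric(x)) stop("non-exempt variable '", work[k], "' is not numeric")
    codes[, k] <- seed_cut(x, spec$initial_bins, spec$initial_method)
    nbins[k] <- max(codes[, k])
    if (nbins[k] == 1L)
      warning("constant column '", work[k], "': single-category output")
  }
  # the MI objective runs over the variables being discretized, matching the
  # reference semantics in which exempt variables are never passed to the
  # discretizer; with fewer than two work variables that objective is empty,
  # so exempt columns then serve as fixed reference columns instead
  # (high-cardinality ones skipped)
  ref <- list()
  if (length(work) < 2L) {
    for (v in intersect(spec$exempt_variables, nms)) {
      u <- sort(unique(df[[v]]))
      if (length(u) <= 50L) ref[[v]] <- match(df[[v]], u)
    }
  }
  # round-robin greedy merging
  repeat {
    merged_any <- FALSE
    for (k in seq_along(work)) {
      if (nbins[k] <= spec$levels) next
      b <- nbins[k]
      delta <- numeric(b - 1L)
      for (m in seq_along(work)) {
        if (m == k) next
        N <- matrix(tabulate((codes[, m] - 1L) * b + codes[, k], b * nbins[m]),
                    nrow = b, ncol = nbins[m])
        delta <- delta + merge_deltas_vs(N)
      }
      for (rc in ref) {
        L <- max(rc)
        N <- matrix(tabulate((rc - 1L) * b + codes[, k], b * L),
                    nrow = b, ncol = L)
        delta <- delta + merge_deltas_vs(N)
      }
      i <- which.max(delta)  # smallest MI loss; ties -> lowest pair
      codes[, k] <- codes[, k] - (codes[, k] > i)
      nbins[k] <- b - 1L
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  out <- df
  for (k in seq_along(work)) out[[work[k]]] <- as.numeric(codes[, k])
  tab <- table
  tab$data <- out
  new_view(paste0("disc", spec$levels), tab, spec = unclass(spec),
           source_hash = object_hash(df))
}

#' Nonparanormal shrinkage transform
#'
#' Each cell is replaced by `qnorm(r/(n+1))` where `r` is its within-column
#' average rank; every column is then divided by one common factor, the
#' standard deviation of the tie-free reference column
#' `qnorm((1:n)/(n+1))`, so untied columns have unit sample SD.
#'
#' @param table a `consnet_cohort` (complete cases, all numeric).
#' @return a `consnet_view` of kind `npn`.
#' @export
npn_shrinkage <- function(table) {
  stopifnot(inherits(table, "consnet_cohort"))
  df <- table$data
  if (anyNA(df)) stop("NPN requires complete cases")
  n <- nrow(df)
  const <- vapply(df, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) stop("constant column: ", names(df)[which(const)[1]])
  Z <- vapply(df, function(x) stats::qnorm(rank(x, ties.method = "average") / (n + 1)),
              numeric(n))
  f <- stats::sd(stats::qnorm(seq_len(n) / (n + 1)))
  out <- as.data.frame(Z / f)
  names(out) <- names(df)
  tab <- table
  tab$data <- out
  new_view("npn", tab, source_hash = object_hash(df))
}

#' Inverse normal transformation
#'
#' Per column, observations are rank-ordered (ties get average ranks) and
#' converted to percentiles `(rank - 1)/(n - 1)`; any row carrying a
#' percentile of exactly 0 or 1 in any column (which would map to infinity)
#' is removed, and surviving percentiles are mapped to standard-normal
#' quantiles.
#'
#' @param table a `consnet_cohort` (complete cases, all numeric).
#' @return a `consnet_view` of kind `int` with `removed_rows` logged.
#' @export
int_transform <- function(table) {
  stopifnot(inherits(table, "consnet_cohort"))
  df <- table$data
  if (anyNA(df)) stop("INT requires complete cases")
  n <- nrow(df)
  const <- vapply(df, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) stop("constant column: ", names(df)[which(const)[1]])
  P <- vapply(df, function(x) (rank(x, ties.method = "average") - 1) / (n - 1),
              numeric(n))
  extreme <- apply(P == 0 | P == 1, 1, any)
  keep <- which(!extreme)
  if (length(keep) < 3L) stop("fewer than 3 rows remain after removing extreme percentiles")
  out <- as.data.frame(stats::qnorm(P[keep, , drop = FALSE]))
  names(out) <- names(df)
  rownames(out) <- NULL
  tab <- table
  tab$data <- out
  new_view("int", tab, removed_rows = which(extreme),
           source_hash = object_hash(df))
}

#' Build the four-view transform suite
#'
#' @param table the post-exclusion complete-case `consnet_cohort`.
#' @param spec3,spec5 discretization specs for the 3- and 5-level views; by
#'   default 100 equal-width seed bins with the schema's
#'   discretization-exempt variables passed through.
#' @return named list with exactly the views `disc3`, `disc5`, `npn`, `int`,
#'   each independently derived from `table`.
#' @export
make_transform_suite <- function(table, spec3 = NULL, spec5 = NULL) {
  stopifnot(inherits(table, "consnet_cohort"))
  exempt <- names(table$schema)[vapply(table$schema, `[[`, logical(1),
                                       "discretization_exempt")]
  if (is.null(spec3)) spec3 <- discretization_spec(3, exempt_variables = exempt)
  if (is.null(spec5)) spec5 <- discretization_spec(5, exempt_variables = exempt)
  stopifnot(spec3$levels == 3L, spec5$levels == 5L)
  list(disc3 = discretize_hartemink(table, spec3),
       disc5 = discretize_hartemink(table, spec5),
       npn = npn_shrinkage(table),
       int = int_transform(table))
}
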