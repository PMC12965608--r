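#' Directed acyclic graph structure
#'
#' @param nodes character vector of node names.
#' @param arcs two-column character matrix or data.frame of ordered pairs
#'   `(from, to)`; may have zero rows.
#' @param check if `TRUE` (default) validate acyclicity, self-loops and
#'   duplicates.
#' @return object of class `consnet_dag`.
#' @export
dag_structure <- function(nodes, arcs = NULL, check = TRUE) {
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- matrix(character(), 0, 2, dimnames = list(NULL, c("from", "to")))
  } else {
    arcs <- as.matrix(arcs)[, 1:2, drop = FALSE]
    storage.mode(arcs) <- "character"
    colnames(arcs) <- c("from", "to")
  }
  if (check) {
    if (!all(arcs %in% nodes)) stop("arc endpoint not among nodes")
    if (any(arcs[, 1] == arcs[, 2])) stop("self-loop in arc set")
    if (anyDuplicated(paste(arcs[, 1], arcs[, 2]))) stop("duplicate arc")
    if (is.null(topological_order(nodes, arcs))) stop("arc set contains a cycle")
  }
  structure(list(nodes = nodes, arcs = arcs), class = "consnet_dag")
}

#' @export
print.consnet_dag <- function(x, ...) {
  cat("<consnet_dag> ", length(x$nodes), " nodes, ", nrow(x$arcs), " arcs",
      if (!is.null(attr(x, "score"))) paste0(" (score ", signif(attr(x, "score"), 6), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Topological order of a directed graph, or NULL if cyclic
#' @param nodes node names.
#' @param arcs two-column (from, to) matrix.
#' @return character vector of nodes in topological order, or `NULL`.
#' @export
topological_order <- function(nodes, arcs) {
  arcs <- as.matrix(arcs)
  indeg <- setNames(integer(length(nodes)), nodes)
  if (nrow(arcs)) {
    tb <- table(arcs[, 2])
    indeg[names(tb)] <- as.integer(tb)
  }
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  active <- nrow(arcs) > 0
  arcl <- if (active) arcs else NULL
  while (length(avail)) {
    u <- avail[1]
    avail <- avail[-1]
    order <- c(order, u)
    if (!is.null(arcl) && nrow(arcl)) {
      out <- arcl[, 1] == u
      if (any(out)) {
        for (v in arcl[out, 2]) {
          indeg[v] <- indeg[v] - 1L
          if (indeg[v] == 0L) avail <- sort(c(avail, v))
        }
        arcl <- arcl[!out, , drop = FALSE]
      }
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

#' Is a graph acyclic?
#' @param dag a `consnet_dag`, or anything with `nodes`/`arcs`.
#' @return `TRUE`/`FALSE`.
#' @export
is_acyclic <- function(dag) !is.null(topological_order(dag$nodes, dag$arcs))

#' Arc blacklist
#'
#' @param forbidden optional two-column (from, to) matrix/data.frame of
#'   individually forbidden arcs.
#' @param sink_forbidden variable names that may not receive incoming arcs
#'   (expands to all arcs into those variables).
#' @return object of class `consnet_blacklist`.
#' @export
blacklist <- function(forbidden = NULL, sink_forbidden = character()) {
  if (!is.null(forbidden)) {
    forbidden <- as.matrix(forbidden)[, 1:2, drop = FALSE]
    storage.mode(forbidden) <- "character"
  }
  structure(list(forbidden = forbidden, sink_forbidden = sink_forbidden),
            class = "consnet_blacklist")
}

#' Blacklist from a cohort schema's blacklist flags
#' @param schema a `consnet_schema`.
#' @return a `consnet_blacklist` with the flagged variables sink-forbidden.
#' @export
blacklist_from_schema <- function(schema) {
  blacklist(sink_forbidden = names(schema)[vapply(schema, `[[`, logical(1),
                                                  "blacklist")])
}

# p x p logical matrix: TRUE at (i, j) means arc i -> j is forbidden
blacklist_matrix <- function(bl, nodes) {
  p <- length(nodes)
  M <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (is.null(bl)) return(M)
  stopifnot(inherits(bl, "consnet_blacklist"))
  if (!is.null(bl$forbidden) && nrow(bl$forbidden)) {
    if (!all(bl$forbidden %in% nodes)) stop("blacklist names unknown variable")
    M[bl$forbidden] <- TRUE
  }
  for (v in bl$sink_forbidden) {
    if (!v %in% nodes) stop("blacklist names unknown variable '", v, "'")
    M[, v] <- TRUE
    M[v, v] <- FALSE
  }
  M
}

# ---------------------------------------------------------------------------
# data preparation for the score/test cores
# ---------------------------------------------------------------------------

# discretized views carry codes but possibly sparse (e.g. 1,3,5); densify
prep_learn_data <- function(view, family = NULL) {
  df <- view_data(view)
  kind <- if (inherits(view, "consnet_view")) view$kind else NULL
  if (is.null(family)) {
    family <- if (!is.null(kind) && kind %in% c("disc3", "disc5"))
      "bic_discrete" else "bic_gaussian"
  }
  M <- as.matrix(df)
  if (family == "bic_discrete") {
    nlev <- integer(ncol(M))
    for (j in seq_len(ncol(M))) {
      u <- sort(unique(M[, j]))
      M[, j] <- match(M[, j], u)
      nlev[j] <- length(u)
    }
    list(M = M, type = 1L, nlev = nlev, family = family, nodes = colnames(M))
  } else {
    list(M = M, type = 0L, nlev = integer(ncol(M)), family = family,
         nodes = colnames(M))
  }
}

#' Score specification for structure learning
#' @param family `"bic_discrete"` (multinomial BIC) or `"bic_gaussian"`
#'   (linear-Gaussian BIC); both are log-likelihood minus
#'   `(log n / 2) * parameter count` and decompose over nodes.
#' @return object of class `consnet_scorespec`.
#' @export
score_spec <- function(family = c("bic_gaussian", "bic_discrete")) {
  structure(list(family = match.arg(family)), class = "consnet_scorespec")
}

#' Decomposable BIC score of a DAG
#'
#' @param dag a `consnet_dag` over the data's variables.
#' @param data a `consnet_view` (or data.frame).
#' @param spec a [score_spec()]; inferred from the view kind when omitted.
#' @return list with `total` and `by_node` (named numeric decomposition).
#' @export
score_dag <- function(dag, data, spec = NULL) {
  pd <- prep_learn_data(data, if (is.null(spec)) NULL else spec$family)
  stopifnot(setequal(dag$nodes, pd$nodes))
  by_node <- setNames(numeric(length(pd$nodes)), pd$nodes)
  for (v in pd$nodes) {
    pa <- dag$arcs[dag$arcs[, 2] == v, 1]
    by_node[v] <- cc_local_score(pd$M, pd$type, pd$nlev,
                                 match(v, pd$nodes),
                                 match(pa, pd$nodes))
  }
  list(total = sum(by_node), by_node = by_node)
}

cc_result_to_dag <- function(res, nodes) {
  arcs <- if (nrow(res$arcs)) cbind(from = nodes[res$arcs[, 1]],
                                    to = nodes[res$arcs[, 2]])
          else NULL
  d <- dag_structure(nodes, arcs)
  attr(d, "score") <- res$score
  attr(d, "truncated") <- res$truncated
  # post-hoc audits: acyclicity is re-checked by dag_structure()
  d
}

#' Hill-climbing structure search
#'
#' Greedy search over single-arc additions, deletions and reversals from the
#' empty graph; every move must keep the graph acyclic, respect the
#' blacklist, and strictly improve the decomposable BIC score. Deterministic
#' given the data (ties break lexicographically by `(from, to)`); the `seed`
#' argument is accepted for interface symmetry but unused.
#'
#' @param data a `consnet_view` (or data.frame).
#' @param spec optional [score_spec()]; inferred from the view kind.
#' @param bl optional [blacklist()].
#' @param max_iter move budget; exceeded searches return the current DAG
#'   with attribute `truncated = TRUE`.
#' @param seed unused (search is deterministic).
#' @return a `consnet_dag` with attributes `score` and `truncated`.
#' @export
hill_climb <- function(data, spec = NULL, bl = NULL, max_iter = 500L, seed = NULL) {
  pd <- prep_learn_data(data, if (is.null(spec)) NULL else spec$family)
  res <- cc_search(pd$M, pd$type, pd$nlev, blacklist_matrix(bl, pd$nodes),
                   NULL, 0L, 0L, 0L, as.integer(max_iter))
  audit_blacklist(cc_result_to_dag(res, pd$nodes), bl)
}

#' Tabu-list structure search
#'
#' Hill climbing extended with a fixed-length list of recently visited
#' structures and a bounded number of non-improving moves; returns the best
#' structure visited. With `tabu_length = 0` and `max_worsening_moves = 0`
#' it degenerates to [hill_climb()].
#'
#' @inheritParams hill_climb
#' @param tabu_length number of recent structures barred from revisiting.
#' @param max_worsening_moves non-improving moves allowed since the best.
#' @return a `consnet_dag` with attributes `score` and `truncated`.
#' @export
tabu_search <- function(data, spec = NULL, bl = NULL, tabu_length = 10L,
                        max_worsening_moves = 10L, max_iter = 500L, seed = NULL) {
  pd <- prep_learn_data(data, if (is.null(spec)) NULL else spec$family)
  res <- cc_search(pd$M, pd$type, pd$nlev, blacklist_matrix(bl, pd$nodes),
                   NULL, 1L, as.integer(tabu_length),
                   as.integer(max_worsening_moves), as.integer(max_iter))
  audit_blacklist(cc_result_to_dag(res, pd$nodes), bl)
}

#' Conditional-independence test specification
#' @param test `"auto"` picks mutual-information (G-squared) for discrete
#'   views and Fisher-z on partial correlations for continuous ones.
#' @param alpha significance level in `(0, 1)`.
#' @return object of class `consnet_citest`.
#' @export
ci_test_spec <- function(test = "auto", alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(test = test, alpha = alpha), class = "consnet_citest")
}

#' Conditional independence test p-value
#'
#' Fisher-z on the partial correlation (continuous data) or the G-squared
#' mutual-information test (discrete data).
#'
#' @param data a `consnet_view` or data.frame.
#' @param x,y variable names.
#' @param z conditioning variable names (possibly empty).
#' @param family optional score family tag to force the data type.
#' @return p-value.
#' @export
ci_test <- function(data, x, y, z = character(), family = NULL) {
  pd <- prep_learn_data(data, family)
  cc_citest(pd$M, pd$type, pd$nlev, match(x, pd$nodes), match(y, pd$nodes),
            match(z, pd$nodes))
}

#' Undirected skeleton by parents-and-children discovery
#'
#' `mmpc` grows each node's candidate parents-and-children set with the
#' max-min association heuristic and shrinks it by conditional-independence
#' tests over subsets; `hpc` first builds a parents-and-children superset
#' (marginal dependence pruned by single-variable conditioning), expands it
#' by one neighborhood, then applies the same subset-filtered search to the
#' pool. Both AND-symmetrize the neighbor relation. Pairs blacklisted in
#' both directions are forced absent.
#'
#' @param data a `consnet_view` (or data.frame).
#' @param method `"mmpc"` or `"hpc"`.
#' @param test a [ci_test_spec()].
#' @param bl optional [blacklist()].
#' @param family optional score-family tag forcing the data type.
#' @return symmetric logical adjacency matrix with dimnames.
#' @export
learn_skeleton <- function(data, method = c("mmpc", "hpc"),
                           test = ci_test_spec(), bl = NULL, family = NULL) {
  method <- match.arg(method)
  pd <- prep_learn_data(data, family)
  adj <- cc_skeleton(pd$M, pd$type, pd$nlev,
                     if (method == "mmpc") 0L else 1L, test$alpha)
  dimnames(adj) <- list(pd$nodes, pd$nodes)
  blm <- blacklist_matrix(bl, pd$nodes)
  both <- blm & t(blm)
  adj[both] <- FALSE
  adj | t(adj)  # guard: symmetric by construction
}

#' Hybrid (restrict-then-maximize) structure learning
#'
#' Learns a skeleton (`mmhc` via MMPC, `h2pc` via HPC) and then runs hill
#' climbing in which arc additions are confined to skeleton-adjacent pairs
#' (deletions and reversals are unrestricted). The blacklist is enforced in
#' both phases.
#'
#' @inheritParams hill_climb
#' @param method `"mmhc"` or `"h2pc"`.
#' @param test a [ci_test_spec()].
#' @param skeleton optional precomputed adjacency matrix (overrides
#'   `method`'s restrict phase).
#' @return a `consnet_dag` with attributes `score`, `truncated`, `skeleton`.
#' @export
hybrid_learn <- function(data, method = c("mmhc", "h2pc"), spec = NULL,
                         test = ci_test_spec(), bl = NULL, max_iter = 500L,
                         seed = NULL, skeleton = NULL) {
  method <- match.arg(method)
  pd <- prep_learn_data(data, if (is.null(spec)) NULL else spec$family)
  if (is.null(skeleton)) {
    skeleton <- learn_skeleton(data, if (method == "mmhc") "mmpc" else "hpc",
                               test, bl,
                               family = if (is.null(spec)) NULL else spec$family)
  }
  stopifnot(identical(dim(skeleton), c(length(pd$nodes), length(pd$nodes))))
  res <- cc_search(pd$M, pd$type, pd$nlev, blacklist_matrix(bl, pd$nodes),
                   skeleton, 0L, 0L, 0L, as.integer(max_iter))
  d <- audit_blacklist(cc_result_to_dag(res, pd$nodes), bl)
  attr(d, "skeleton") <- skeleton
  d
}

# post-hoc audit: learner outputs can never violate the blacklist
audit_blacklist <- function(dag, bl) {
  if (is.null(bl)) return(dag)
  M <- blacklist_matrix(bl, dag$nodes)
  if (nrow(dag$arcs) && any(M[dag$arcs]))
    stop("internal error: blacklist violated by learned structure")
  dag
}
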