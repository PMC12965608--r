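#' Double cross-consensus ensemble configuration
#'
#' The ensemble runs every algorithm on every transformed view (the 4 x 4
#' grid, `K = 16` cells), averages structures over `B` bootstrap resamples
#' per cell, thresholds each cell's averaged network (arc retained at
#' bootstrap strength `>= strength_min` and a strict orientation majority of
#' `>= direction_min_count` of the `B` bootstraps), and finally keeps only
#' arcs retained under all algorithms within at least `min_transformations`
#' transformations.
#'
#' @param B bootstraps per cell (the reference analysis uses 10,000).
#' @param strength_min retention threshold in `(0, 1]` (default 0.85).
#' @param direction_min_count minimal orientation count; defaults to the
#'   strict majority `floor(B/2) + 1` (5,001 of 10,000).
#' @param algorithms ordered algorithm tags.
#' @param transformations ordered view kinds.
#' @param min_transformations transformations required for consensus.
#' @param seed master seed; per-cell seeds are derived from it and the cell
#'   labels, so results do not depend on grid order.
#' @param alpha CI-test level for the hybrid learners' restrict phase.
#' @param tabu_length,max_worsening_moves tabu-search controls.
#' @param max_iter search move budget.
#' @return object of class `consnet_ensemble_config` (field `K` = grid size).
#' @export
ensemble_config <- function(B = 10000L, strength_min = 0.85,
                            direction_min_count = NULL,
                            algorithms = c("hc", "tabu", "mmhc", "h2pc"),
                            transformations = c("disc3", "disc5", "npn", "int"),
                            min_transformations = 3L, seed = 1L, alpha = 0.05,
                            tabu_length = 10L, max_worsening_moves = 10L,
                            max_iter = 500L) {
  B <- as.integer(B)
  if (is.null(direction_min_count)) direction_min_count <- direction_majority_count(B)
  stopifnot(strength_min > 0, strength_min <= 1, direction_min_count > B / 2,
            min_transformations >= 1,
            min_transformations <= length(transformations))
  structure(list(B = B, strength_min = strength_min,
                 direction_min_count = as.integer(direction_min_count),
                 algorithms = algorithms, transformations = transformations,
                 K = length(algorithms) * length(transformations),
                 min_transformations = as.integer(min_transformations),
                 seed = as.integer(seed), alpha = alpha,
                 tabu_length = as.integer(tabu_length),
                 max_worsening_moves = as.integer(max_worsening_moves),
                 max_iter = as.integer(max_iter)),
            class = "consnet_ensemble_config")
}

#' Retention count implied by the strength threshold
#' @param strength_min retention threshold.
#' @param B bootstraps.
#' @return smallest count of `B` meeting the threshold (e.g. 8,500 of 10,000
#'   at 0.85).
#' @export
retention_count <- function(strength_min, B) as.integer(ceiling(strength_min * B))

#' Strict-majority orientation count
#' @param B bootstraps.
#' @return `floor(B/2) + 1` (5,001 for B = 10,000); ties at exactly `B/2`
#'   fail.
#' @export
direction_majority_count <- function(B) as.integer(floor(B / 2) + 1L)

# label-based per-cell seed: independent of grid order, stable across runs
cell_seed <- function(master_seed, algorithm, transformation) {
  s <- paste0(algorithm, ":", transformation)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(master_seed) + h) %% 2147483629 + 1)
}

# one learner call on a prepared matrix (used inside the bootstrap loop)
learn_on_prepared <- function(pd, algorithm, blm, config, skeleton = NULL) {
  if (algorithm %in% c("hc", "tabu")) {
    res <- cc_search(pd$M, pd$type, pd$nlev, blm, NULL,
                     if (algorithm == "hc") 0L else 1L,
                     config$tabu_length, config$max_worsening_moves,
                     config$max_iter)
  } else {
    if (is.null(skeleton)) {
      skeleton <- cc_skeleton(pd$M, pd$type, pd$nlev,
                              if (algorithm == "mmhc") 0L else 1L, config$alpha)
      both <- blm & t(blm)
      skeleton[both] <- FALSE
    }
    res <- cc_search(pd$M, pd$type, pd$nlev, blm, skeleton, 0L, 0L, 0L,
                     config$max_iter)
  }
  res$arcs
}

#' Bootstrap arc-strength table for one (algorithm, transformation) cell
#'
#' Runs the learner on `B` row resamples with replacement and tabulates, per
#' ordered node pair, the number of learned structures containing the arc.
#' Strength of an unordered pair is the fraction of structures containing it
#' in either orientation; direction is the oriented fraction among those
#' (undirected occurrences, possible only for learners emitting
#' equivalence-class representatives, would count half to each side). A
#' failing resample is redrawn once, then counted structure-absent with a
#' warning.
#'
#' @param view a `consnet_view`.
#' @param algorithm one of `"hc"`, `"tabu"`, `"mmhc"`, `"h2pc"`.
#' @param config an [ensemble_config()].
#' @param bl optional [blacklist()].
#' @param seed RNG seed for the resampling (defaults to the cell seed
#'   derived from the config master seed).
#' @param B number of resamples (defaults to `config$B`).
#' @return object of class `consnet_arcstrength`: `counts` (p x p directed
#'   containment counts), `nodes`, `B`, `algorithm`, `transformation`,
#'   `failures`.
#' @export
bootstrap_arc_strength <- function(view, algorithm, config = ensemble_config(),
                                   bl = NULL, seed = NULL, B = NULL) {
  stopifnot(algorithm %in% c("hc", "tabu", "mmhc", "h2pc"))
  pd <- prep_learn_data(view)
  n <- nrow(pd$M)
  p <- length(pd$nodes)
  blm <- blacklist_matrix(bl, pd$nodes)
  if (is.null(B)) B <- config$B
  if (is.null(seed))
    seed <- cell_seed(config$seed, algorithm,
                      if (inherits(view, "consnet_view")) view$kind else "raw")
  set.seed(seed)
  counts <- matrix(0L, p, p, dimnames = list(pd$nodes, pd$nodes))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- pd
    sub$M <- pd$M[idx, , drop = FALSE]
    arcs <- tryCatch(learn_on_prepared(sub, algorithm, blm, config),
                     error = function(e) NULL)
    if (is.null(arcs)) {  # redraw once, then count as structure-absent
      idx <- sample.int(n, n, replace = TRUE)
      sub$M <- pd$M[idx, , drop = FALSE]
      arcs <- tryCatch(learn_on_prepared(sub, algorithm, blm, config),
                       error = function(e) NULL)
      if (is.null(arcs)) {
        failures <- failures + 1L
        warning("resample failed twice for ", algorithm, "; counted absent")
        next
      }
    }
    if (nrow(arcs)) counts[arcs] <- counts[arcs] + 1L
  }
  structure(list(counts = counts, nodes = pd$nodes, B = B,
                 algorithm = algorithm,
                 transformation = if (inherits(view, "consnet_view")) view$kind else "raw",
                 failures = failures),
            class = "consnet_arcstrength")
}

#' Strength/direction table of an arc-strength object
#' @param ast a `consnet_arcstrength`.
#' @return data.frame per unordered pair with positive strength: `from`,
#'   `to` (the majority orientation), `strength` (fraction of `B`),
#'   `direction` (oriented fraction among containing bootstraps),
#'   `count_fwd`, `count_rev`.
#' @export
arc_strength_table <- function(ast) {
  cnt <- ast$counts
  p <- length(ast$nodes)
  out <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      cf <- cnt[i, j]; cr <- cnt[j, i]
      if (cf + cr == 0L) next
      fwd <- cf >= cr
      out[[length(out) + 1L]] <- data.frame(
        from = ast$nodes[if (fwd) i else j],
        to = ast$nodes[if (fwd) j else i],
        strength = (cf + cr) / ast$B,
        direction = max(cf, cr) / (cf + cr),
        count_fwd = max(cf, cr), count_rev = min(cf, cr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(from = character(), to = character(), strength = numeric(),
                      direction = numeric(), count_fwd = integer(),
                      count_rev = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Construct a subnetwork DAG directly (for synthetic grids and testing)
#'
#' @param algorithm,transformation cell labels.
#' @param arcs data.frame with `from`, `to`, `strength`, `direction` (and
#'   optionally counts).
#' @param nodes node set (defaults to names present in `arcs`).
#' @return object of class `consnet_subnet`.
#' @export
subnetwork_dag <- function(algorithm, transformation, arcs,
                           nodes = union(arcs$from, arcs$to)) {
  stopifnot(all(c("from", "to", "strength", "direction") %in% names(arcs)))
  structure(list(algorithm = algorithm, transformation = transformation,
                 arcs = arcs, nodes = nodes,
                 dropped = data.frame(), acyclic = TRUE),
            class = "consnet_subnet")
}

#' @export
print.consnet_subnet <- function(x, ...) {
  cat("<consnet_subnet ", x$algorithm, ".", x$transformation, "> ",
      nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Ad-hoc thresholding of a bootstrap-averaged network
#'
#' Retains unordered pairs with bootstrap strength `>= strength_min` and
#' orients each toward the direction whose oriented count reaches
#' `direction_min_count` of the `B` bootstraps; pairs meeting strength but
#' lacking a strict orientation majority are dropped and logged. The result
#' is audited for acyclicity (an error names the offending cycle — it should
#' be unreachable when every bootstrap structure was itself acyclic).
#'
#' @param ast a `consnet_arcstrength`.
#' @param config an [ensemble_config()]; `direction_min_count` is rescaled
#'   to the table's own `B` when they differ.
#' @return object of class `consnet_subnet`: retained `arcs`
#'   (`from, to, strength, direction`), `dropped` log, cell labels.
#' @export
adhoc_threshold <- function(ast, config = ensemble_config()) {
  tab <- arc_strength_table(ast)
  dmin <- if (config$B == ast$B) config$direction_min_count
          else direction_majority_count(ast$B)
  keep <- tab$strength >= config$strength_min
  tab <- tab[keep, , drop = FALSE]
  resolved <- tab$count_fwd >= dmin
  dropped <- tab[!resolved, , drop = FALSE]
  arcs <- tab[resolved, , drop = FALSE]
  rownames(arcs) <- rownames(dropped) <- NULL
  sn <- structure(list(algorithm = ast$algorithm,
                       transformation = ast$transformation,
                       arcs = arcs, nodes = ast$nodes, dropped = dropped,
                       acyclic = TRUE),
                  class = "consnet_subnet")
  ord <- topological_order(ast$nodes, arcs[, c("from", "to"), drop = FALSE])
  if (is.null(ord)) stop("thresholded subnetwork for cell ", ast$algorithm, ".",
                         ast$transformation, " contains a cycle")
  sn
}

#' Run the full algorithm-by-transformation ensemble
#'
#' One thresholded subnetwork per grid cell; per-cell seeds are derived from
#' the master seed and the cell labels, so cells are independent and the
#' result does not depend on the order of the algorithm or transformation
#' lists.
#'
#' @param suite named list of views (from [make_transform_suite()]).
#' @param config an [ensemble_config()].
#' @param bl optional [blacklist()].
#' @param B optional bootstrap count override (reduced runs).
#' @return named list (`"algorithm.transformation"`) of `consnet_subnet`s.
#' @export
run_ensemble <- function(suite, config = ensemble_config(), bl = NULL, B = NULL) {
  stopifnot(all(config$transformations %in% names(suite)))
  out <- list()
  for (tr in config$transformations) {
    for (al in config$algorithms) {
      key <- paste(al, tr, sep = ".")
      sn <- tryCatch({
        ast <- bootstrap_arc_strength(suite[[tr]], al, config, bl,
                                      seed = cell_seed(config$seed, al, tr),
                                      B = B)
        adhoc_threshold(ast, config)
      }, error = function(e) stop("ensemble cell ", key, " failed: ",
                                  conditionMessage(e), call. = FALSE))
      out[[key]] <- sn
    }
  }
  out
}

# per-cell (strength, oriented fraction for a -> b) lookup, NA when absent
cell_pair_stats <- function(sn, a, b) {
  arcs <- sn$arcs
  hit <- (arcs$from == a & arcs$to == b) | (arcs$from == b & arcs$to == a)
  if (!any(hit)) return(NULL)
  r <- arcs[which(hit)[1], ]
  d_ab <- if (r$from == a) r$direction else 1 - r$direction
  list(s = r$strength, d_ab = d_ab)
}

#' Learned and grand statistics for one consensus arc
#'
#' `learned` statistics average over only the `k` subnetworks containing the
#' (unordered) arc; `grand` statistics average over all `K` grid cells with
#' absent cells contributing zero, so `grand = learned * k/K` exactly. The
#' grand values are computed both ways and cross-checked to 1e-12.
#' Orientation is set by the learned-direction majority.
#'
#' @param subnets list of `consnet_subnet`s (the grid).
#' @param pair character vector of the two node names.
#' @param K grid size (defaults to `length(subnets)`).
#' @return object of class `consnet_consensus_arc`: `from`, `to`, `k`,
#'   `learned_strength`, `grand_strength`, `learned_direction`,
#'   `grand_direction`, `cells` (qualifying cell labels).
#' @export
arc_statistics <- function(subnets, pair, K = length(subnets)) {
  a <- pair[1]; b <- pair[2]
  s_all <- d_all <- numeric(0)
  cells <- character(0)
  for (key in names(subnets)) {
    st <- cell_pair_stats(subnets[[key]], a, b)
    if (is.null(st)) next
    s_all <- c(s_all, st$s)
    d_all <- c(d_all, st$d_ab)
    cells <- c(cells, key)
  }
  k <- length(cells)
  if (k == 0L) stop("pair {", a, ", ", b, "} contained in no subnetwork")
  learned_s <- mean(s_all)
  learned_d_ab <- mean(d_all)
  # orientation by learned-direction majority (lexicographic on exact tie)
  if (learned_d_ab >= 0.5) { from <- a; to <- b; learned_d <- learned_d_ab }
  else { from <- b; to <- a; learned_d <- 1 - learned_d_ab }
  grand_s <- sum(s_all) / K          # absent cells contribute zero
  grand_d <- sum(if (from == a) d_all else 1 - d_all) / K
  stopifnot(abs(grand_s - learned_s * k / K) <= 1e-12,
            abs(grand_d - learned_d * k / K) <= 1e-12)
  structure(list(from = from, to = to, k = k,
                 learned_strength = learned_s, grand_strength = grand_s,
                 learned_direction = learned_d, grand_direction = grand_d,
                 cells = cells),
            class = "consnet_consensus_arc")
}

# does the pair satisfy "all algorithms within >= min_transformations
# transformations"?
consensus_qualifies <- function(cells, algorithms, transformations,
                                min_transformations) {
  full <- 0L
  for (tr in transformations) {
    have <- paste(algorithms, tr, sep = ".")
    if (all(have %in% cells)) full <- full + 1L
  }
  full >= min_transformations
}

#' Double cross-consensus graph
#'
#' An unordered pair qualifies when it is retained under all algorithms
#' within at least `min_transformations` transformations (minimum presence
#' `4 x 3 = 12` of 16 cells on the standard grid). Qualifying arcs carry
#' learned/grand strength and direction statistics; arcs whose grand
#' direction falls below 0.5 are flagged. The final graph's acyclicity is
#' audited and reported (a cycle is listed, not silently repaired).
#'
#' @param subnets the grid of `consnet_subnet`s from [run_ensemble()].
#' @param config the [ensemble_config()] used.
#' @return object of class `consnet_consensus`: `arcs` data.frame
#'   (`from, to, networks, learned_strength, grand_strength,
#'   learned_direction, grand_direction, direction_flag`), `nodes`,
#'   `acyclic` status, `cycle` (when failed).
#' @export
consensus_2xcons <- function(subnets, config = ensemble_config()) {
  expect <- as.vector(outer(config$algorithms, config$transformations, paste,
                            sep = "."))
  if (!all(expect %in% names(subnets)))
    stop("subnets do not cover the configured grid")
  nodes <- subnets[[1]]$nodes
  # collect containing cells per unordered pair
  pairs <- list()
  for (key in names(subnets)) {
    arcs <- subnets[[key]]$arcs
    if (!nrow(arcs)) next
    for (r in seq_len(nrow(arcs))) {
      pk <- paste(sort(c(arcs$from[r], arcs$to[r])), collapse = "\r")
      pairs[[pk]] <- c(pairs[[pk]], key)
    }
  }
  rows <- list()
  for (pk in names(pairs)) {
    cells <- pairs[[pk]]
    if (!consensus_qualifies(cells, config$algorithms, config$transformations,
                             config$min_transformations)) next
    pr <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    st <- arc_statistics(subnets, pr, K = config$K)
    rows[[length(rows) + 1L]] <- data.frame(
      from = st$from, to = st$to, networks = st$k,
      learned_strength = st$learned_strength,
      grand_strength = st$grand_strength,
      learned_direction = st$learned_direction,
      grand_direction = st$grand_direction,
      direction_flag = st$grand_direction < 0.5,
      stringsAsFactors = FALSE)
  }
  arcs <- if (length(rows)) do.call(rbind, rows)
          else data.frame(from = character(), to = character(),
                          networks = integer(), learned_strength = numeric(),
                          grand_strength = numeric(),
                          learned_direction = numeric(),
                          grand_direction = numeric(),
                          direction_flag = logical(), stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  ord <- topological_order(nodes, arcs[, c("from", "to"), drop = FALSE])
  structure(list(arcs = arcs, nodes = nodes,
                 acyclic = !is.null(ord),
                 cycle = if (is.null(ord)) find_cycle(nodes, arcs) else NULL,
                 config = config),
            class = "consnet_consensus")
}

#' @export
print.consnet_consensus <- function(x, ...) {
  cat("<consnet_consensus> ", nrow(x$arcs), " arcs over ", length(x$nodes),
      " nodes; acyclic: ", x$acyclic, "\n", sep = "")
  invisible(x)
}

# one directed cycle for the failure report
find_cycle <- function(nodes, arcs) {
  adj <- split(arcs$to, arcs$from)
  state <- setNames(rep(0L, length(nodes)), nodes)
  path <- character(0)
  res <- NULL
  dfs <- function(u) {
    if (!is.null(res)) return()
    state[[u]] <<- 1L
    path <<- c(path, u)
    for (v in adj[[u]] %||% character(0)) {
      if (state[[v]] == 1L) {
        res <<- c(path[which(path == v):length(path)], v)
        return()
      }
      if (state[[v]] == 0L) dfs(v)
      if (!is.null(res)) return()
    }
    state[[u]] <<- 2L
    path <<- path[-length(path)]
  }
  for (u in nodes) if (state[[u]] == 0L) dfs(u)
  res
}

#' Minimum qualifying cell count of the consensus rule
#'
#' Enumerates presence patterns over the algorithm-by-transformation grid,
#' applies the implemented consensus predicate, and returns the smallest
#' number of occupied cells among qualifying patterns (12 on the standard
#' 4 x 4 grid with a 3-of-4 transformation requirement).
#'
#' @param n_algorithms,n_transformations grid dimensions.
#' @param min_transformations transformations required.
#' @return integer minimum cell count.
#' @export
consensus_min_cells <- function(n_algorithms = 4L, n_transformations = 4L,
                                min_transformations = 3L) {
  algorithms <- paste0("a", seq_len(n_algorithms))
  transformations <- paste0("t", seq_len(n_transformations))
  grid <- as.vector(outer(algorithms, transformations, paste, sep = "."))
  ncell <- length(grid)
  best <- NA_integer_
  for (mask in 0:(2^ncell - 1)) {
    cells <- grid[bitwAnd(bitwShiftR(mask, seq_len(ncell) - 1L), 1L) == 1L]
    if (consensus_qualifies(cells, algorithms, transformations,
                            min_transformations)) {
      if (is.na(best) || length(cells) < best) best <- length(cells)
    }
  }
  best
}

#' Average bootstrap instances implied by a mean grand strength
#'
#' Bookkeeping identity: a mean grand strength `g` over a grid of `K` cells
#' of `B` bootstraps each corresponds to an average presence in `g * K * B`
#' of the `K * B` bootstrapped instances.
#'
#' @param mean_grand_strength mean grand strength as a proportion.
#' @param K grid size.
#' @param B bootstraps per cell.
#' @return expected number of bootstrap instances.
#' @export
expected_bootstrap_instances <- function(mean_grand_strength, K = 16L, B = 10000L) {
  mean_grand_strength * K * B
}

#' Overlap between the RPCN and the consensus DAG
#'
#' A consensus arc matches an RPCN edge when their unordered node pairs
#' coincide. Reports the shared-edge count, the shared percentage of RPCN
#' edges, and a Welch two-sample t comparison of absolute RPCN edge weights
#' for shared versus non-shared edges.
#'
#' @param rpcn a `consnet_rpcn`.
#' @param consensus a `consnet_consensus`.
#' @return list with `n_rpcn`, `n_dag`, `shared`, `shared_pct`, and `welch`
#'   (statistic, df, CI, p, group means; `NULL` when either group is too
#'   small).
#' @export
dual_network_overlap <- function(rpcn, consensus) {
  stopifnot(setequal(rpcn$nodes, consensus$nodes))
  W <- rpcn$weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  rpcn_pairs <- apply(ut, 1, function(ix)
    paste(sort(c(rownames(W)[ix[1]], colnames(W)[ix[2]])), collapse = "\r"))
  wts <- abs(W[ut])
  dag_pairs <- if (nrow(consensus$arcs))
    apply(consensus$arcs[, c("from", "to")], 1, function(r)
      paste(sort(r), collapse = "\r")) else character(0)
  shared <- rpcn_pairs %in% dag_pairs
  n_rpcn <- length(rpcn_pairs)
  res <- list(n_rpcn = n_rpcn, n_dag = length(dag_pairs),
              shared = sum(shared),
              shared_pct = overlap_percentage(sum(shared), n_rpcn),
              welch = NULL)
  if (sum(shared) >= 2 && sum(!shared) >= 2) {
    tt <- stats::t.test(wts[shared], wts[!shared], var.equal = FALSE)
    res$welch <- list(statistic = unname(tt$statistic),
                      df = unname(tt$parameter),
                      ci = as.numeric(tt$conf.int), p = tt$p.value,
                      mean_shared = mean(wts[shared]),
                      mean_unique = mean(wts[!shared]))
  }
  res
}

#' Shared percentage of RPCN edges
#' @param shared,total edge counts.
#' @return percentage rounded to two decimals (0 when `total` is 0).
#' @export
overlap_percentage <- function(shared, total) {
  if (total == 0) return(0)
  round(100 * shared / total, 2)
}
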