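#' RPCN estimation settings
#'
#' `ebic_gamma` is the extended-BIC hyperparameter controlling sparsity of
#' the selected graphical-lasso model (0.5 is the conservative default,
#' biasing toward false negatives). The penalty path has `n_lambda`
#' log-spaced values from the smallest penalty that empties the graph down to
#' that value times `lambda_min_ratio`.
#'
#' @param ebic_gamma EBIC hyperparameter, `>= 0`.
#' @param n_lambda penalty path length.
#' @param lambda_min_ratio smallest/largest penalty ratio in `(0, 1)`.
#' @param correlation_method `"rank_latent"` (Spearman mapped to the latent
#'   Gaussian scale by `2*sin(pi*rho/6)`) or `"pearson"`.
#' @return object of class `consnet_rpcn_config`.
#' @export
rpcn_config <- function(ebic_gamma = 0.5, n_lambda = 100L, lambda_min_ratio = 0.01,
                        correlation_method = c("rank_latent", "pearson")) {
  correlation_method <- match.arg(correlation_method)
  stopifnot(ebic_gamma >= 0, lambda_min_ratio > 0, lambda_min_ratio < 1,
            n_lambda >= 2)
  structure(list(ebic_gamma = ebic_gamma, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 correlation_method = correlation_method),
            class = "consnet_rpcn_config")
}

#' Correlation matrix for network input
#'
#' `rank_latent` computes Spearman rank correlations and maps them to the
#' latent-Gaussian scale via `2*sin(pi*rho/6)` (a rank-based stand-in for
#' polychoric/polyserial estimation, invariant to monotone transforms);
#' `pearson` computes product-moment correlations. A nearest-PSD repair
#' (eigenvalue clipping followed by rescaling to unit diagonal) is applied
#' and flagged if the matrix has eigenvalues below `-1e-8`.
#'
#' @param dataset a `consnet_view`, `consnet_cohort`, data.frame or matrix
#'   with no missing cells.
#' @param method correlation method tag.
#' @return object of class `consnet_corr`: list with `R`, `method`, `n`,
#'   `repaired`.
#' @export
correlation_auto <- function(dataset, method = c("rank_latent", "pearson")) {
  method <- match.arg(method)
  df <- view_data(dataset)
  if (anyNA(df)) stop("missing cells in correlation input")
  M <- as.matrix(df)
  const <- apply(M, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) stop("constant column: ", colnames(M)[which(const)[1]])
  if (method == "rank_latent") {
    rho <- stats::cor(M, method = "spearman")
    R <- 2 * sin(pi * rho / 6)
  } else {
    R <- stats::cor(M)
  }
  diag(R) <- 1
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    repaired <- TRUE
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
  }
  # clip perfect dependence away from +/-1 for downstream numerical stability
  off <- row(R) != col(R)
  R[off] <- pmin(pmax(R[off], -(1 - 1e-12)), 1 - 1e-12)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(list(R = R, method = method, n = nrow(M), repaired = repaired),
            class = "consnet_corr")
}

#' EBIC-selected graphical lasso network
#'
#' Fits the graphical lasso along a log-spaced penalty path from
#' `lambda_max` (the smallest penalty yielding an empty graph, i.e. the
#' largest absolute off-diagonal correlation) down to
#' `lambda_max * lambda_min_ratio`, and selects the fit minimizing
#' `EBIC = -2*l + E*log(n) + 4*gamma*E*log(p)`, where `E` counts nonzero
#' upper-triangle precision entries and `l` is the Gaussian log-likelihood at
#' the sample correlation. The selected precision matrix is converted to
#' partial correlations `r_ij = -theta_ij / sqrt(theta_ii * theta_jj)`.
#'
#' @param corr a `consnet_corr` (or plain correlation matrix).
#' @param n sample size (taken from `corr` when available).
#' @param config an [rpcn_config()].
#' @return object of class `consnet_rpcn`: `weights` (symmetric partial
#'   correlation matrix, zero diagonal), `selected_lambda`, `edge_count`,
#'   `nodes`, and the EBIC `path` table.
#' @export
ebic_glasso <- function(corr, n = NULL, config = rpcn_config()) {
  if (inherits(corr, "consnet_corr")) {
    R <- corr$R
    if (is.null(n)) n <- corr$n
  } else {
    R <- as.matrix(corr)
  }
  stopifnot(!is.null(n), n > 1)
  p <- ncol(R)
  nodes <- colnames(R) %||% paste0("V", seq_len(p))
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop("correlation matrix is not positive semi-definite")
  lmax <- max(abs(R[row(R) != col(R)]))
  empty <- function(lambda) {
    W <- matrix(0, p, p, dimnames = list(nodes, nodes))
    structure(list(weights = W, selected_lambda = lambda, edge_count = 0L,
                   nodes = nodes,
                   path = data.frame(lambda = lambda, edges = 0L, ebic = NA_real_)),
              class = "consnet_rpcn")
  }
  if (lmax < 1e-10) return(empty(0))
  lambdas <- exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
                     length.out = config$n_lambda))
  fit <- cc_glasso_path(R, lambdas)
  conv <- fit$converged
  if (!all(conv)) stop("graphical lasso failed to converge at lambda = ",
                       signif(lambdas[which(!conv)[1]], 4))
  ut <- upper.tri(R)
  ebic <- edges <- numeric(length(lambdas))
  for (l in seq_along(lambdas)) {
    Th <- fit$Theta[[l]]
    E <- sum(abs(Th[ut]) > 1e-10)
    ld <- determinant(Th, logarithm = TRUE)
    if (ld$sign <= 0) { ebic[l] <- Inf; edges[l] <- E; next }
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(R * Th))
    ebic[l] <- -2 * ll + E * log(n) + 4 * config$ebic_gamma * E * log(p)
    edges[l] <- E
  }
  best <- which.min(ebic)  # ties -> sparser model (earlier on the path)
  Th <- fit$Theta[[best]]
  d <- sqrt(diag(Th))
  W <- -Th / tcrossprod(d)
  diag(W) <- 0
  W[abs(W) < 1e-10] <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- list(nodes, nodes)
  structure(list(weights = W, selected_lambda = lambdas[best],
                 edge_count = sum(W[ut] != 0), nodes = nodes,
                 path = data.frame(lambda = lambdas, edges = edges, ebic = ebic)),
            class = "consnet_rpcn")
}

#' @export
print.consnet_rpcn <- function(x, ...) {
  cat("<consnet_rpcn> ", length(x$nodes), " nodes, ", x$edge_count,
      " edges (lambda = ", signif(x$selected_lambda, 4), ")\n", sep = "")
  invisible(x)
}

rpcn_igraph <- function(net) {
  W <- net$weights
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$dist <- 1 / igraph::E(g)$weight
  g
}

#' Node centrality indices of an RPCN
#'
#' Strength is the sum of absolute edge weights, expected influence the sum
#' of signed weights. Shortest-path indices use distances `1/|w|`:
#' closeness is harmonic (sum of inverse distances over all other nodes,
#' unreachable contributing 0) and betweenness counts weighted shortest
#' paths through the node.
#'
#' @param net a `consnet_rpcn` (or symmetric weight matrix).
#' @return data.frame with one row per node: `node`, `strength`,
#'   `expected_influence`, `closeness`, `betweenness`.
#' @export
centrality <- function(net) {
  if (!inherits(net, "consnet_rpcn")) {
    W <- as.matrix(net)
    net <- list(weights = W, nodes = colnames(W) %||% paste0("V", seq_len(ncol(W))))
    class(net) <- "consnet_rpcn"
  }
  W <- net$weights
  stopifnot(nrow(W) >= 1)
  g <- rpcn_igraph(net)
  if (igraph::ecount(g) > 0) {
    clo <- igraph::harmonic_centrality(g, weights = igraph::E(g)$dist,
                                       normalized = FALSE)
    btw <- igraph::betweenness(g, weights = igraph::E(g)$dist)
  } else {
    clo <- btw <- rep(0, nrow(W))
  }
  data.frame(node = net$nodes,
             strength = rowSums(abs(W)),
             expected_influence = rowSums(W),
             closeness = as.numeric(clo),
             betweenness = as.numeric(btw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-node predictability
#'
#' Each node is regressed (unpenalized least squares) on its RPCN neighbors.
#' Numeric nodes report R-squared; nodes whose schema role is categorical
#' report normalized accuracy above the marginal mode:
#' `(acc - acc_mode) / (1 - acc_mode)`, floored at 0, with predictions taken
#' as the nearest observed code. Isolated nodes score 0.
#'
#' @param dataset the `consnet_view` the network was fitted on.
#' @param net the fitted `consnet_rpcn`.
#' @return data.frame with `node`, `predictability`, and attribute
#'   `mean_predictability`.
#' @export
predictability <- function(dataset, net) {
  df <- view_data(dataset)
  sch <- view_schema(dataset)
  W <- net$weights
  stopifnot(identical(colnames(W), names(df)))
  out <- numeric(ncol(df))
  for (k in seq_len(ncol(df))) {
    nb <- which(W[, k] != 0)
    if (!length(nb)) { out[k] <- 0; next }
    y <- df[[k]]
    X <- as.matrix(df[, nb, drop = FALSE])
    fit <- stats::lm.fit(cbind(1, X), y)
    yhat <- y - fit$residuals
    role <- if (!is.null(sch)) sch[[names(df)[k]]]$role else "continuous"
    if (role == "categorical") {
      lev <- sort(unique(y))
      pred <- lev[pmax(1, pmin(length(lev), round(approx_code(yhat, lev))))]
      acc <- mean(pred == y)
      acc0 <- max(tabulate(match(y, lev))) / length(y)
      out[k] <- if (acc0 >= 1) 0 else max(0, (acc - acc0) / (1 - acc0))
    } else {
      tss <- sum((y - mean(y))^2)
      out[k] <- if (tss <= 0) 0 else max(0, 1 - sum(fit$residuals^2) / tss)
    }
  }
  res <- data.frame(node = names(df), predictability = out,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "mean_predictability") <- mean(out)
  res
}

# nearest observed code index for a continuous prediction
approx_code <- function(yhat, lev) {
  vapply(yhat, function(v) which.min(abs(lev - v)), numeric(1))
}

#' Non-parametric edge bootstrap
#'
#' Refits the full correlation + EBIC-glasso pipeline on `B` row resamples
#' with replacement and summarizes each edge by its bootstrap mean,
#' percentile 2.5/97.5 interval, the conditional mean over resamples where
#' the edge is nonzero, and the inclusion proportion. Resamples that fail to
#' fit are skipped (error if more than 10 percent fail).
#'
#' @param dataset a `consnet_view` (or cohort).
#' @param B number of bootstrap resamples (`>= 2`).
#' @param config an [rpcn_config()].
#' @param seed RNG seed.
#' @return object of class `consnet_edgeboot`: matrices `mean`, `ci_lo`,
#'   `ci_hi`, `mean_nonzero`, `prop_nonzero`, plus `B_effective`.
#' @export
bootstrap_edges <- function(dataset, B, config = rpcn_config(), seed = 1L) {
  stopifnot(B >= 2)
  df <- view_data(dataset)
  n <- nrow(df)
  p <- ncol(df)
  set.seed(seed)
  acc <- array(NA_real_, c(p, p, B))
  fails <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    W <- tryCatch({
      co <- correlation_auto(df[idx, , drop = FALSE], config$correlation_method)
      ebic_glasso(co, n = n, config = config)$weights
    }, error = function(e) NULL)
    if (is.null(W)) { fails <- fails + 1L; next }
    acc[, , b] <- W
  }
  if (fails > 0.1 * B) stop("more than 10% of bootstrap resamples failed (",
                            fails, "/", B, ")")
  ok <- which(!is.na(acc[1, 1, ]))
  acc <- acc[, , ok, drop = FALSE]
  mn <- apply(acc, c(1, 2), mean)
  lo <- apply(acc, c(1, 2), stats::quantile, probs = 0.025)
  hi <- apply(acc, c(1, 2), stats::quantile, probs = 0.975)
  nzmean <- apply(acc, c(1, 2), function(v) {
    nz <- v[v != 0]
    if (length(nz)) mean(nz) else 0
  })
  prop <- apply(acc, c(1, 2), function(v) mean(v != 0))
  nms <- names(df)
  dimnames(mn) <- dimnames(lo) <- dimnames(hi) <- dimnames(nzmean) <-
    dimnames(prop) <- list(nms, nms)
  structure(list(mean = mn, ci_lo = lo, ci_hi = hi, mean_nonzero = nzmean,
                 prop_nonzero = prop, B_effective = length(ok), failures = fails),
            class = "consnet_edgeboot")
}

#' CS-coefficient from a case-drop correlation cache
#'
#' The CS-coefficient is the largest drop proportion `q` on the grid such
#' that at least `prob` of subsample centralities correlate at least
#' `cor_threshold` with the full-sample values at every grid point up to and
#' including `q` (0 if the criterion already fails at the smallest drop).
#'
#' @param cors numeric matrix of correlations, rows = grid points (ordered by
#'   increasing drop proportion), columns = resamples; `NA` counts as failing.
#' @param grid drop-proportion grid matching the rows.
#' @param cor_threshold correlation criterion (default 0.70).
#' @param prob required fraction of resamples meeting it (default 0.95).
#' @return a single CS value on the grid, or 0.
#' @export
cs_coefficient <- function(cors, grid, cor_threshold = 0.70, prob = 0.95) {
  stopifnot(nrow(cors) == length(grid))
  meets <- apply(cors, 1, function(v) mean(!is.na(v) & v >= cor_threshold) >= prob)
  cs <- 0
  for (i in order(grid)) {
    if (isTRUE(meets[i])) cs <- grid[i] else break
  }
  cs
}

#' Case-dropping centrality stability
#'
#' For each drop proportion `q` on the grid, draws `B` subsamples retaining
#' `round((1-q)*n)` rows, refits the network, and records the Spearman
#' correlation of each centrality index with its full-sample values. The
#' CS-coefficient per index is the largest `q` with correlation `>= 0.70` in
#' `>= 95` percent of subsamples (grid points with too few rows to fit are
#' marked infeasible). Reports flag indices as interpretable at CS `>= 0.25`
#' and good at CS `>= 0.50`.
#'
#' @param dataset a `consnet_view` (or cohort).
#' @param B subsamples per drop level (`>= 50` recommended).
#' @param config an [rpcn_config()].
#' @param seed RNG seed.
#' @param drop_grid drop-proportion grid.
#' @param cor_threshold,prob CS criterion.
#' @return object of class `consnet_stability`: `cs` table (with
#'   interpretability flags), `grid`, raw correlation caches per index, and
#'   the conventions used.
#' @export
case_drop_stability <- function(dataset, B, config = rpcn_config(), seed = 1L,
                                drop_grid = seq(0.05, 0.75, by = 0.05),
                                cor_threshold = 0.70, prob = 0.95) {
  df <- view_data(dataset)
  n <- nrow(df)
  p <- ncol(df)
  full <- centrality(ebic_glasso(correlation_auto(df, config$correlation_method),
                                 n = n, config = config))
  idxnames <- c("strength", "expected_influence", "closeness", "betweenness")
  set.seed(seed)
  cors <- lapply(idxnames, function(i) matrix(NA_real_, length(drop_grid), B))
  names(cors) <- idxnames
  feasible <- rep(TRUE, length(drop_grid))
  for (qi in seq_along(drop_grid)) {
    keep_n <- round((1 - drop_grid[qi]) * n)
    if (keep_n <= p + 1) { feasible[qi] <- FALSE; next }
    for (b in seq_len(B)) {
      idx <- sample.int(n, keep_n, replace = FALSE)
      cen <- tryCatch(
        centrality(ebic_glasso(correlation_auto(df[idx, , drop = FALSE],
                                                config$correlation_method),
                               n = keep_n, config = config)),
        error = function(e) NULL)
      if (is.null(cen)) next
      for (i in idxnames) {
        cors[[i]][qi, b] <- suppressWarnings(
          stats::cor(full[[i]], cen[[i]], method = "spearman"))
      }
    }
  }
  fgrid <- drop_grid[feasible]
  cs <- vapply(idxnames, function(i)
    cs_coefficient(cors[[i]][feasible, , drop = FALSE], fgrid,
                   cor_threshold, prob), numeric(1))
  tab <- data.frame(index = idxnames, cs = cs,
                    interpretable = cs >= 0.25, good = cs >= 0.50,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cs = tab, grid = drop_grid, feasible = feasible,
                 correlations = cors, cor_threshold = cor_threshold,
                 prob = prob, B = B,
                 conventions = paste("Spearman correlation of subsample vs",
                                     "full-sample centralities; harmonic",
                                     "closeness over all nodes")),
            class = "consnet_stability")
}
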