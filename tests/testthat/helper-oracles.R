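# Independent oracles used across test files. These deliberately avoid the
# package's own code paths wherever they check one.

# every DAG over the given nodes, as a list of (from, to) character matrices
all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- t(utils::combn(p, 2))
  arcs_all <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  na <- nrow(arcs_all)
  out <- list()
  for (mask in 0:(2^na - 1)) {
    sel <- which(bitwAnd(bitwShiftR(mask, 0:(na - 1)), 1L) == 1L)
    if (!length(sel)) {
      out[[length(out) + 1]] <- matrix(character(), 0, 2)
      next
    }
    a <- arcs_all[sel, , drop = FALSE]
    key <- paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
    if (anyDuplicated(key)) next
    am <- cbind(nodes[a[, 1]], nodes[a[, 2]])
    if (is.null(consnet::topological_order(nodes, am))) next
    out[[length(out) + 1]] <- am
  }
  out
}

# brute-force betweenness on a symmetric weight matrix with distances 1/|w|:
# enumerate every simple path between each ordered pair, find the shortest,
# and credit its interior nodes
brute_betweenness <- function(W) {
  p <- nrow(W)
  D <- 1 / abs(W)
  D[W == 0] <- Inf
  btw <- numeric(p)
  paths_between <- function(s, t) {
    res <- list()
    grow <- function(path) {
      u <- path[length(path)]
      if (u == t) {
        res[[length(res) + 1]] <<- path
        return()
      }
      for (v in seq_len(p)) {
        if (!is.infinite(D[u, v]) && !(v %in% path)) grow(c(path, v))
      }
    }
    grow(s)
    res
  }
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- paths_between(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(pp)
        sum(D[cbind(pp[-length(pp)], pp[-1])]), numeric(1))
      best <- min(lens)
      shortest <- paths[abs(lens - best) < 1e-12]
      # count of shortest paths through each interior node, averaged over
      # equally short paths (standard betweenness with path multiplicity)
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        frac <- mean(vapply(shortest, function(pp) v %in% pp, logical(1)))
        btw[v] <- btw[v] + frac
      }
    }
  }
  btw
}

# textbook Welch t-test pieces
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df)
}

# plug-in mutual information of two code vectors via explicit double loop
mi_oracle <- function(x, y) {
  n <- length(x)
  tot <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- mean(x == a & y == b)
    if (pab > 0) tot <- tot + pab * log(pab / (mean(x == a) * mean(y == b)))
  }
  tot
}

# minimal edit count (insert/delete/reorient per unordered pair) between arc sets
shd_oracle <- function(a1, a2) {
  key <- function(a) if (nrow(a)) paste(a[, 1], a[, 2]) else character(0)
  uk <- function(a) if (nrow(a)) paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
                    else character(0)
  u1 <- uk(a1); u2 <- uk(a2); d1 <- key(a1); d2 <- key(a2)
  only1 <- sum(!(u1 %in% u2)); only2 <- sum(!(u2 %in% u1))
  shared <- intersect(u1, u2)
  reor <- 0
  for (s in shared) {
    nn <- strsplit(s, " ")[[1]]
    if ((paste(nn[1], nn[2]) %in% d1) != (paste(nn[1], nn[2]) %in% d2))
      reor <- reor + 1
  }
  only1 + only2 + reor
}

# simulated chain data with strong dependence (shared by several files)
make_chain_data <- function(n, seed, beta = 0.8, sigma = 0.6) {
  set.seed(seed)
  x <- rnorm(n)
  y <- beta * x + sigma * rnorm(n)
  z <- beta * y + sigma * rnorm(n)
  data.frame(a = x, b = y, c = z)
}

# small cohort schema used by IO tests
toy_schema <- function() {
  cohort_schema(
    variable_schema("bmi", "continuous", range = c(13, 90)),
    variable_schema("mets", "continuous"),
    variable_schema("alcohol", "continuous"),
    variable_schema("grade", "ordinal", levels = c("low", "mid", "high"),
                    discretization_exempt = TRUE, blacklist = TRUE)
  )
}

toy_csv <- function(path, rows) {
  writeLines(c("bmi,mets,alcohol,grade", rows), path)
  path
}
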