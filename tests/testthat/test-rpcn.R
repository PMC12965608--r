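test_that("correlation_auto handles perfect dependence, nulls, and known rho", {
  # two identical columns -> off-diagonal clipped just below 1
  df <- data.frame(a = 1:20, b = 1:20, c = rnorm(20))
  co <- correlation_auto(df)
  expect_lt(co$R[1, 2], 1)
  expect_gt(co$R[1, 2], 1 - 1e-10)
  expect_error(correlation_auto(data.frame(a = rep(1, 5), b = 1:5)), "constant")
  # Monte-Carlo null: independent columns stay near zero
  set.seed(21)
  dfn <- as.data.frame(matrix(rnorm(5000 * 4), 5000, 4))
  con <- correlation_auto(dfn)
  expect_lt(max(abs(con$R[upper.tri(con$R)])), 0.05)
  # sin-transform consistency at rho = 0.6
  set.seed(22)
  n <- 10000
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  cr <- correlation_auto(data.frame(x = x, y = y), "rank_latent")
  expect_lt(abs(cr$R[1, 2] - 0.6), 0.03)
})

test_that("rank_latent correlation is invariant to monotone transforms", {
  set.seed(23)
  df <- data.frame(x = rnorm(200), y = rexp(200), z = runif(200))
  df2 <- data.frame(x = exp(df$x), y = df$y^2, z = qlogis(df$z))
  expect_equal(correlation_auto(df)$R, correlation_auto(df2)$R,
               tolerance = 1e-12)
})

test_that("ebic_glasso: empty at identity, inversion limit, gamma monotonicity", {
  R <- diag(4)
  dimnames(R) <- list(letters[1:4], letters[1:4])
  for (g in c(0, 0.5)) {
    net <- ebic_glasso(R, n = 100, rpcn_config(ebic_gamma = g))
    expect_identical(net$edge_count, 0L)
  }
  # penalty -> 0 limit equals direct precision inversion (3-variable chain)
  Th_true <- matrix(c(2, -0.8, 0, -0.8, 2, -0.8, 0, -0.8, 2), 3, 3)
  S <- cov2cor(solve(Th_true))
  Th_hat <- consnet:::cc_glasso(S, 1e-9)$Theta
  pc_hat <- -Th_hat / sqrt(tcrossprod(diag(Th_hat)))
  Th_inv <- solve(S)
  pc_inv <- -Th_inv / sqrt(tcrossprod(diag(Th_inv)))
  expect_lt(max(abs(pc_hat - pc_inv)), 1e-4)
  # edge count non-increasing in gamma on a noisy fit
  set.seed(25)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[, 2] <- X[, 1] + 0.5 * rnorm(60)
  co <- correlation_auto(as.data.frame(X))
  ec <- sapply(c(0, 0.25, 0.5), function(g)
    ebic_glasso(co, config = rpcn_config(ebic_gamma = g))$edge_count)
  expect_true(all(diff(ec) <= 0))
})

test_that("selected model minimizes EBIC along the path; output is symmetric", {
  set.seed(26)
  X <- matrix(rnorm(200 * 6), 200, 6)
  X[, 2] <- 0.7 * X[, 1] + 0.5 * rnorm(200)
  X[, 3] <- 0.7 * X[, 2] + 0.5 * rnorm(200)
  net <- ebic_glasso(correlation_auto(as.data.frame(X)))
  sel <- net$path$ebic[net$path$lambda == net$selected_lambda]
  expect_true(all(sel <= net$path$ebic + 1e-9))
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(abs(net$weights) < 1))
  expect_identical(net$edge_count,
                   sum(net$weights[upper.tri(net$weights)] != 0))
})

test_that("centrality definitions and label equivariance", {
  # 3-node line: middle node bridges
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.5
  cen <- centrality(W)
  expect_equal(cen$betweenness, c(0, 1, 0))
  expect_equal(cen$strength, c(0.5, 1.0, 0.5))
  # signed weights: strength vs expected influence
  W2 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W2["a", "b"] <- W2["b", "a"] <- 0.3
  W2["a", "c"] <- W2["c", "a"] <- -0.2
  cen2 <- centrality(W2)
  expect_equal(cen2$strength[1], 0.5)
  expect_equal(cen2$expected_influence[1], 0.1)
  expect_true(all(cen2$strength >= abs(cen2$expected_influence) - 1e-12))
  # 5-node toy vs exhaustive path-enumeration oracle
  set.seed(27)
  W5 <- matrix(0, 5, 5)
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 3), c(2, 5))
  for (k in seq_len(nrow(pairs))) {
    w <- round(runif(1, 0.1, 0.6), 2)
    W5[pairs[k, 1], pairs[k, 2]] <- W5[pairs[k, 2], pairs[k, 1]] <- w
  }
  dimnames(W5) <- list(paste0("n", 1:5), paste0("n", 1:5))
  expect_equal(centrality(W5)$betweenness, brute_betweenness(W5),
               tolerance = 1e-9)
  # label equivariance under node permutation
  perm <- c(3, 1, 4, 5, 2)
  Wp <- W5[perm, perm]
  cen_p <- centrality(Wp)
  cen_o <- centrality(W5)
  expect_equal(cen_p$strength, cen_o$strength[perm])
  expect_equal(cen_p$betweenness, cen_o$betweenness[perm])
  expect_equal(cen_p$closeness, cen_o$closeness[perm])
})

test_that("predictability: isolated nodes, closed-form R2, mean attached", {
  set.seed(28)
  n <- 20000
  x <- rnorm(n)
  y <- 0.8 * x + 0.6 * rnorm(n)   # population R2 = 0.64
  z <- rnorm(n)
  df <- data.frame(x = x, y = y, z = z)
  W <- matrix(0, 3, 3, dimnames = list(names(df), names(df)))
  W["x", "y"] <- W["y", "x"] <- 0.5
  net <- structure(list(weights = W, nodes = names(df)), class = "consnet_rpcn")
  pr <- predictability(df, net)
  expect_equal(pr$predictability[pr$node == "z"], 0)
  expect_lt(abs(pr$predictability[pr$node == "y"] - 0.64), 0.02)
  expect_equal(attr(pr, "mean_predictability"), mean(pr$predictability))
})

test_that("bootstrap_edges: planted edge excluded from zero, null edges near zero", {
  set.seed(29)
  n <- 600
  x <- rnorm(n)
  y <- 0.6 * x + 0.8 * rnorm(n)
  df <- data.frame(x = x, y = y, u = rnorm(n), v = rnorm(n))
  eb <- bootstrap_edges(df, B = 60, seed = 31)
  expect_gt(eb$ci_lo["x", "y"], 0)
  # null pairs: bootstrap means stay small
  null_pairs <- rbind(c("u", "v"), c("x", "u"), c("y", "v"))
  expect_lt(max(abs(eb$mean[null_pairs])), 0.05)
  expect_true(all(eb$ci_lo <= eb$mean + 1e-12) &&
              all(eb$mean <= eb$ci_hi + 1e-12))
})

test_that("CS-coefficient semantics and monotonicity in the criterion", {
  grid <- seq(0.05, 0.25, by = 0.05)
  cors <- matrix(1, length(grid), 40)
  expect_equal(cs_coefficient(cors, grid), 0.25)
  cors2 <- cors
  cors2[3, ] <- 0.5  # fails at 0.15 -> CS stops at 0.10 despite later passes
  expect_equal(cs_coefficient(cors2, grid), 0.10)
  expect_equal(cs_coefficient(matrix(0.2, 2, 10), c(0.05, 0.1)), 0)
  # raising the correlation criterion never raises CS on fixed resamples
  set.seed(32)
  cors3 <- matrix(runif(5 * 50, 0.5, 1), 5, 50)
  cs70 <- cs_coefficient(cors3, grid, 0.70)
  cs90 <- cs_coefficient(cors3, grid, 0.90)
  expect_lte(cs90, cs70)
})

test_that("case_drop_stability saturates on strong structure and flags thresholds", {
  set.seed(33)
  n <- 1500
  # three planted pairs with well-separated dependence, so the node-strength
  # ranking survives even 75% case dropping
  a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
  df <- data.frame(a1 = a, a2 = a + 0.10 * rnorm(n),
                   b1 = b, b2 = b + 0.60 * rnorm(n),
                   c1 = c, c2 = c + 1.20 * rnorm(n))
  st <- case_drop_stability(df, B = 12, seed = 34,
                            drop_grid = c(0.1, 0.4, 0.75))
  expect_s3_class(st, "consnet_stability")
  row <- st$cs[st$cs$index == "strength", ]
  expect_equal(row$cs, 0.75)   # saturation at the grid maximum
  expect_true(row$interpretable && row$good)
  expect_identical(st$cs$interpretable, st$cs$cs >= 0.25)
  expect_identical(st$cs$good, st$cs$cs >= 0.50)
})
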