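test_that("discrete BIC matches a hand-computed closed form on a 4-row table", {
  # two binary columns, empty DAG: per-node multinomial log-likelihood minus
  # (log n / 2) * (r - 1)
  df <- data.frame(x = c(1, 1, 2, 2), y = c(1, 2, 1, 1))
  d <- dag_structure(c("x", "y"))
  sc <- score_dag(d, df, score_spec("bic_discrete"))
  ll_x <- 2 * log(2 / 4) + 2 * log(2 / 4)
  ll_y <- 3 * log(3 / 4) + 1 * log(1 / 4)
  expect_equal(unname(sc$by_node["x"]), ll_x - log(4) / 2 * 1)
  expect_equal(unname(sc$by_node["y"]), ll_y - log(4) / 2 * 1)
  expect_equal(sc$total, sum(sc$by_node))
})

test_that("BIC is score-equivalent across Markov equivalence classes", {
  set.seed(41)
  df <- make_chain_data(400, 41)
  nodes <- c("a", "b", "c")
  # the chain's equivalence class: a->b->c, a<-b->c, a<-b<-c
  cls <- list(rbind(c("a", "b"), c("b", "c")),
              rbind(c("b", "a"), c("b", "c")),
              rbind(c("c", "b"), c("b", "a")))
  sc <- vapply(cls, function(a)
    score_dag(dag_structure(nodes, a), df, score_spec("bic_gaussian"))$total,
    numeric(1))
  expect_equal(max(sc) - min(sc), 0, tolerance = 1e-8)
  # the collider a->b<-c is in a different class and must score lower here
  col <- score_dag(dag_structure(nodes, rbind(c("a", "b"), c("c", "b"))),
                   df, score_spec("bic_gaussian"))$total
  expect_lt(col, min(sc))
})

test_that("adding an arc between independent variables lowers BIC at large n", {
  set.seed(42)
  df <- data.frame(x = rnorm(2000), y = rnorm(2000))
  s0 <- score_dag(dag_structure(c("x", "y")), df, score_spec("bic_gaussian"))$total
  s1 <- score_dag(dag_structure(c("x", "y"), rbind(c("x", "y"))), df,
                  score_spec("bic_gaussian"))$total
  expect_lt(s1, s0)
})

test_that("hill climbing: independence, exhaustive optimum, blacklist", {
  set.seed(3)
  ind <- as.data.frame(matrix(rnorm(2000 * 3), 2000, 3))
  names(ind) <- c("a", "b", "c")
  expect_identical(nrow(hill_climb(ind)$arcs), 0L)

  df <- make_chain_data(2000, 44)
  hc <- hill_climb(df)
  best <- max(vapply(all_dags(c("a", "b", "c")), function(a)
    score_dag(dag_structure(c("a", "b", "c"), a), df,
              score_spec("bic_gaussian"))$total, numeric(1)))
  expect_equal(attr(hc, "score"), best, tolerance = 1e-9)

  bl <- blacklist(sink_forbidden = "a")
  hcb <- hill_climb(df, bl = bl)
  expect_false(any(hcb$arcs[, "to"] == "a"))
})

test_that("hill climbing and tabu attain the 543-DAG exhaustive optimum (p = 4)", {
  nodes <- c("a", "b", "c", "d")
  dags4 <- all_dags(nodes)
  expect_identical(length(dags4), 543L)
  # greedy-friendly high-signal structures (chains/trees); colliders whose
  # parents are themselves strongly linked can trap plain hill climbing in a
  # score-equivalent local optimum, which tabu escapes but HC legitimately
  # reports
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 1500
    a <- rnorm(n); b <- 0.8 * a + 0.6 * rnorm(n)
    c <- 0.8 * b + 0.6 * rnorm(n); d <- 0.8 * b + 0.6 * rnorm(n)
    df <- data.frame(a = a, b = b, c = c, d = d)
    best <- max(vapply(dags4, function(ar)
      score_dag(dag_structure(nodes, ar), df,
                score_spec("bic_gaussian"))$total, numeric(1)))
    expect_equal(attr(hill_climb(df), "score"), best, tolerance = 1e-9)
    expect_equal(attr(tabu_search(df), "score"), best, tolerance = 1e-9)
  }
})

test_that("tabu degenerates to HC at zero memory and never scores worse", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 400
    X <- matrix(rnorm(n * 4), n, 4)
    X[, 2] <- 0.6 * X[, 1] + 0.8 * rnorm(n)
    X[, 4] <- 0.6 * X[, 3] + 0.5 * X[, 2] + 0.6 * rnorm(n)
    df <- as.data.frame(X)
    names(df) <- letters[1:4]
    hc <- hill_climb(df)
    t0 <- tabu_search(df, tabu_length = 0, max_worsening_moves = 0)
    expect_identical(t0$arcs, hc$arcs)
    expect_equal(attr(t0, "score"), attr(hc, "score"))
    tt <- tabu_search(df)
    expect_gte(attr(tt, "score"), attr(hc, "score") - 1e-9)
  }
})

test_that("skeletons: independence, chain d-separation, 3-clique", {
  set.seed(3)
  ind <- as.data.frame(matrix(rnorm(1500 * 4), 1500, 4))
  names(ind) <- letters[1:4]
  for (m in c("mmpc", "hpc"))
    expect_false(any(learn_skeleton(ind, m)))

  df <- make_chain_data(2000, 46)
  for (m in c("mmpc", "hpc")) {
    sk <- learn_skeleton(df, m)
    expect_true(sk["a", "b"] && sk["b", "c"])
    expect_false(sk["a", "c"])   # d-separated given b
  }

  set.seed(47)
  n <- 2000
  u <- rnorm(n)
  cl <- data.frame(x = u + 0.6 * rnorm(n), y = u + 0.6 * rnorm(n),
                   z = u + 0.6 * rnorm(n))
  cl$y <- cl$y + 0.4 * cl$x
  cl$z <- cl$z + 0.4 * cl$y + 0.4 * cl$x
  for (m in c("mmpc", "hpc")) {
    sk <- learn_skeleton(cl, m)
    expect_true(all(sk[upper.tri(sk)]))
  }
})

test_that("hybrid learners: degeneration, restriction contract, recovery", {
  df <- make_chain_data(1500, 48)
  # full skeleton -> identical to plain hill climbing
  full <- matrix(TRUE, 3, 3)
  diag(full) <- FALSE
  dimnames(full) <- list(names(df), names(df))
  h <- hybrid_learn(df, "mmhc", skeleton = full)
  expect_identical(h$arcs, hill_climb(df)$arcs)
  # excluded pair can never appear in either orientation
  excl <- full
  excl["a", "b"] <- excl["b", "a"] <- FALSE
  h2 <- hybrid_learn(df, "mmhc", skeleton = excl)
  pairs <- paste(h2$arcs[, 1], h2$arcs[, 2])
  expect_false(any(pairs %in% c("a b", "b a")))
  # 5-node planted DAG: skeleton recovered in most seeded replicates
  hits <- 0L
  reps <- 10L
  for (seed in seq_len(reps)) {
    set.seed(100 + seed)
    n <- 1000
    a <- rnorm(n); b <- 0.7 * a + 0.7 * rnorm(n); c <- 0.7 * a + 0.7 * rnorm(n)
    d <- 0.5 * b + 0.5 * c + 0.6 * rnorm(n); e <- 0.7 * d + 0.7 * rnorm(n)
    df5 <- data.frame(a = a, b = b, c = c, d = d, e = e)
    truth <- dag_structure(letters[1:5],
                           rbind(c("a", "b"), c("a", "c"), c("b", "d"),
                                 c("c", "d"), c("d", "e")))
    for (m in c("mmhc", "h2pc")) {
      est <- hybrid_learn(df5, m)
      r <- score_recovery(est, truth)
      if (r$precision == 1 && r$recall == 1) hits <- hits + 1L
    }
  }
  expect_gte(hits, 0.9 * 2 * reps)
})

test_that("learned structures always pass acyclicity and blacklist audits", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    X <- matrix(rnorm(n * 5), n, 5)
    for (j in 2:5) X[, j] <- X[, j] + 0.5 * X[, j - 1]
    df <- as.data.frame(X)
    names(df) <- letters[1:5]
    bl <- blacklist(forbidden = rbind(c("a", "e")), sink_forbidden = "b")
    for (fit in list(hill_climb(df, bl = bl), tabu_search(df, bl = bl),
                     hybrid_learn(df, "mmhc", bl = bl))) {
      expect_true(is_acyclic(fit))
      expect_false(any(fit$arcs[, "to"] == "b"))
      expect_false(any(fit$arcs[, 1] == "a" & fit$arcs[, 2] == "e"))
    }
  }
})

test_that("discrete learners work on coded data and respect the blacklist", {
  set.seed(49)
  n <- 1500
  x <- sample(1:3, n, replace = TRUE)
  y <- pmin(3, pmax(1, x + sample(c(-1, 0, 0, 1), n, replace = TRUE)))
  z <- sample(1:3, n, replace = TRUE)
  df <- data.frame(x = x, y = y, z = z)
  hc <- hill_climb(df, score_spec("bic_discrete"))
  pairs <- paste(pmin(hc$arcs[, 1], hc$arcs[, 2]), pmax(hc$arcs[, 1], hc$arcs[, 2]))
  expect_true("x y" %in% pairs)
  expect_false(any(grepl("z", pairs)))
  sk <- learn_skeleton(df, "mmpc", family = "bic_discrete")
  expect_true(sk["x", "y"])
  expect_false(sk["x", "z"] || sk["y", "z"])
})
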