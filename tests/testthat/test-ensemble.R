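# synthetic subnetwork grids --------------------------------------------------

grid_cells <- function(algorithms = c("hc", "tabu", "mmhc", "h2pc"),
                       transformations = c("disc3", "disc5", "npn", "int")) {
  as.vector(outer(algorithms, transformations, paste, sep = "."))
}

# build a full 16-cell grid where `pair_cells` name the cells containing the
# arc a -> b with given strength/direction
toy_grid <- function(pair_cells, s = 1, d = 1, from = "a", to = "b",
                     nodes = c("a", "b", "c")) {
  cells <- grid_cells()
  out <- list()
  for (key in cells) {
    al_tr <- strsplit(key, ".", fixed = TRUE)[[1]]
    arcs <- if (key %in% pair_cells)
      data.frame(from = from, to = to, strength = s, direction = d,
                 stringsAsFactors = FALSE)
    else
      data.frame(from = character(), to = character(), strength = numeric(),
                 direction = numeric(), stringsAsFactors = FALSE)
    out[[key]] <- subnetwork_dag(al_tr[1], al_tr[2], arcs, nodes = nodes)
  }
  out
}

test_that("ensemble_config exposes the grid arithmetic and threshold counts", {
  cfg <- ensemble_config(B = 10000)
  expect_identical(cfg$K, 16L)
  expect_identical(cfg$direction_min_count, 5001L)
  expect_identical(retention_count(0.85, 10000), 8500L)
  expect_identical(direction_majority_count(10000), 5001L)
  cfg2 <- ensemble_config(B = 200, algorithms = c("hc", "tabu"),
                          transformations = c("npn", "int"),
                          min_transformations = 2)
  expect_identical(cfg2$K, 4L)
  expect_identical(cfg2$direction_min_count, 101L)
})

test_that("bootstrap arc strengths: counting identities and planted arc", {
  set.seed(51)
  n <- 800
  x <- rnorm(n)
  y <- 0.8 * x + 0.6 * rnorm(n)
  z <- rnorm(n)
  df <- data.frame(x = x, y = y, z = z)
  sch <- cohort_schema(lapply(names(df), variable_schema, role = "continuous"))
  view <- npn_shrinkage(cohort_table(df, sch))
  cfg <- ensemble_config(B = 100, seed = 5)
  ast <- bootstrap_arc_strength(view, "hc", cfg, B = 100)
  tab <- arc_strength_table(ast)
  # s and d are multiples of 1/B; d_fwd + d_rev = 1 on every present pair
  expect_true(all(abs(tab$strength * 100 - round(tab$strength * 100)) < 1e-9))
  expect_true(all(abs((tab$count_fwd + tab$count_rev) / 100 - tab$strength) < 1e-9))
  xy <- tab[(tab$from == "x" & tab$to == "y") | (tab$from == "y" & tab$to == "x"), ]
  expect_identical(nrow(xy), 1L)
  expect_gte(xy$strength, 0.95)
  expect_gte(xy$direction, 0.5)
  # determinism given the seed
  ast2 <- bootstrap_arc_strength(view, "hc", cfg, B = 100)
  expect_identical(ast$counts, ast2$counts)
})

test_that("ad-hoc thresholding implements the strength and direction rules", {
  nodes <- c("a", "b")
  mk <- function(cf, cr, B) {
    counts <- matrix(0L, 2, 2, dimnames = list(nodes, nodes))
    counts["a", "b"] <- cf
    counts["b", "a"] <- cr
    structure(list(counts = counts, nodes = nodes, B = B, algorithm = "hc",
                   transformation = "npn", failures = 0L),
              class = "consnet_arcstrength")
  }
  cfg <- ensemble_config(B = 10000)
  # boundary: s = 0.85 with orientation exactly at 5,001 -> retained
  sn <- adhoc_threshold(mk(5001L, 3499L, 10000L), cfg)
  expect_identical(nrow(sn$arcs), 1L)
  expect_identical(sn$arcs$from, "a")
  # s = 0.8499 -> dropped
  expect_identical(nrow(adhoc_threshold(mk(5000L, 3499L, 10000L), cfg)$arcs), 0L)
  # direction-unresolved 5,000/5,000 despite s = 1 -> dropped and logged
  sn3 <- adhoc_threshold(mk(5000L, 5000L, 10000L), cfg)
  expect_identical(nrow(sn3$arcs), 0L)
  expect_identical(nrow(sn3$dropped), 1L)
  # exhaustive rule-table oracle over count combinations at B = 20
  cfg20 <- ensemble_config(B = 20)
  for (cf in 0:20) for (cr in 0:(20 - cf)) {
    sn <- adhoc_threshold(mk(cf, cr, 20L), cfg20)
    keep_oracle <- (cf + cr) / 20 >= 0.85 && max(cf, cr) >= 11
    expect_identical(nrow(sn$arcs) == 1L, keep_oracle)
  }
})

test_that("raising strength_min never adds arcs (monotone pruning)", {
  set.seed(52)
  nodes <- letters[1:4]
  counts <- matrix(0L, 4, 4, dimnames = list(nodes, nodes))
  counts["a", "b"] <- 95L; counts["b", "a"] <- 3L
  counts["b", "c"] <- 60L; counts["c", "b"] <- 28L
  counts["c", "d"] <- 80L; counts["d", "c"] <- 10L
  ast <- structure(list(counts = counts, nodes = nodes, B = 100L,
                        algorithm = "hc", transformation = "npn",
                        failures = 0L), class = "consnet_arcstrength")
  prev <- NULL
  for (smin in c(0.5, 0.7, 0.85, 0.95)) {
    cfg <- ensemble_config(B = 100, strength_min = smin)
    arcs <- adhoc_threshold(ast, cfg)$arcs
    keys <- paste(arcs$from, arcs$to)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("arc_statistics reproduces the worked grand/learned arithmetic", {
  # learned 1.0 in 12 of 16 -> grand 0.75
  g <- toy_grid(grid_cells()[1:12], s = 1, d = 1)
  st <- arc_statistics(g, c("a", "b"))
  expect_identical(st$k, 12L)
  expect_equal(st$learned_strength, 1)
  expect_equal(st$grand_strength, 0.75)
  expect_equal(st$grand_direction, 0.75)
  # learned strength 90.91% in 12 cells -> grand 68.18% (to 2 dp)
  g2 <- toy_grid(grid_cells()[1:12], s = 0.9091, d = 0.5868)
  st2 <- arc_statistics(g2, c("a", "b"))
  expect_equal(round(100 * st2$grand_strength, 2), 68.18)
  expect_equal(round(100 * st2$grand_direction, 2), 44.01)
  expect_true(st2$grand_direction < 0.5)   # direction-flagged case
  # full-grid identity: learned == grand
  g3 <- toy_grid(grid_cells(), s = 1, d = 1)
  st3 <- arc_statistics(g3, c("a", "b"))
  expect_equal(st3$learned_strength, st3$grand_strength)
  expect_equal(st3$learned_direction, st3$grand_direction)
  expect_error(arc_statistics(g3, c("a", "c")), "no subnetwork")
})

test_that("grand = learned * k/K holds on random ensembles (property)", {
  set.seed(53)
  for (rep in 1:20) {
    k <- sample(1:16, 1)
    cells <- sample(grid_cells(), k)
    s <- runif(1, 0.85, 1)
    d <- runif(1)
    g <- toy_grid(cells, s = s, d = d)
    st <- arc_statistics(g, c("a", "b"))
    expect_lte(abs(st$grand_strength - st$learned_strength * st$k / 16), 1e-12)
    expect_lte(abs(st$grand_direction - st$learned_direction * st$k / 16), 1e-12)
    expect_gte(st$learned_direction, 0.5)  # majority orientation chosen
  }
})

test_that("consensus rule: all algorithms within >= 3 transformations", {
  cfg <- ensemble_config(B = 100)
  # all four algorithms in 3 transformations (12 cells) -> included
  cells12 <- grid_cells(transformations = c("disc3", "disc5", "npn"))
  cons <- consensus_2xcons(toy_grid(cells12), cfg)
  expect_identical(nrow(cons$arcs), 1L)
  expect_identical(cons$arcs$networks, 12L)
  # three algorithms in every transformation (12 cells too) -> excluded
  cells_marg <- grid_cells(algorithms = c("hc", "tabu", "mmhc"))
  cons2 <- consensus_2xcons(toy_grid(cells_marg), cfg)
  expect_identical(nrow(cons2$arcs), 0L)
  # sampled brute-force evaluation of the predicate over presence patterns
  set.seed(54)
  algorithms <- c("hc", "tabu", "mmhc", "h2pc")
  transformations <- c("disc3", "disc5", "npn", "int")
  for (rep in 1:60) {
    cells <- sample(grid_cells(), sample(0:16, 1))
    got <- consnet:::consensus_qualifies(cells, algorithms, transformations, 3L)
    full_tr <- sum(vapply(transformations, function(tr)
      all(paste(algorithms, tr, sep = ".") %in% cells), logical(1)))
    expect_identical(got, full_tr >= 3)
  }
  # arcs are never invented: consensus is a subset of the union of subnets
  cons3 <- consensus_2xcons(toy_grid(grid_cells()[1:13]), cfg)
  expect_true(all(paste(cons3$arcs$from, cons3$arcs$to) %in% c("a b")))
  expect_true(cons3$acyclic)
})

test_that("consensus orientation pools per-cell directions, flags < 0.5 grand", {
  # 12 cells orient a->b weakly (0.55), arc qualifies; learned direction
  # pools to 0.55 and grand falls to 0.4125 -> flagged
  g <- toy_grid(grid_cells()[1:12], s = 0.9, d = 0.55)
  cons <- consensus_2xcons(g, ensemble_config(B = 100))
  expect_identical(cons$arcs$from, "a")
  expect_equal(cons$arcs$learned_direction, 0.55)
  expect_equal(cons$arcs$grand_direction, 0.55 * 12 / 16)
  expect_true(cons$arcs$direction_flag)
})

test_that("consensus_min_cells enumerates the implemented rule", {
  expect_identical(consensus_min_cells(4, 4, 3), 12L)
  expect_identical(consensus_min_cells(4, 4, 4), 16L)
  expect_identical(consensus_min_cells(2, 2, 1), 2L)
})

test_that("cell seeds are label-based so grid order cannot matter", {
  s1 <- consnet:::cell_seed(7, "hc", "npn")
  s2 <- consnet:::cell_seed(7, "hc", "npn")
  expect_identical(s1, s2)
  expect_false(s1 == consnet:::cell_seed(7, "tabu", "npn"))
  expect_false(s1 == consnet:::cell_seed(8, "hc", "npn"))
})

test_that("run_ensemble covers the grid and is order-independent", {
  set.seed(55)
  n <- 300
  x <- rnorm(n); y <- 0.8 * x + 0.6 * rnorm(n); z <- 0.7 * y + 0.7 * rnorm(n)
  df <- data.frame(x = x, y = y, z = z)
  sch <- cohort_schema(lapply(names(df), variable_schema, role = "continuous"))
  tab <- cohort_table(df, sch)
  suite <- make_transform_suite(tab)
  cfg <- ensemble_config(B = 30, seed = 9, algorithms = c("hc", "tabu"),
                         transformations = c("npn", "int"),
                         min_transformations = 2)
  sn <- run_ensemble(suite, cfg, B = 30)
  expect_identical(length(sn), 4L)
  cfg_perm <- ensemble_config(B = 30, seed = 9, algorithms = c("tabu", "hc"),
                              transformations = c("int", "npn"),
                              min_transformations = 2)
  sn2 <- run_ensemble(suite, cfg_perm, B = 30)
  for (key in names(sn))
    expect_identical(sn[[key]]$arcs, sn2[[key]]$arcs)
  cons <- consensus_2xcons(sn, cfg)
  expect_true(cons$acyclic)
  expect_true(all(paste(cons$arcs$from, cons$arcs$to) %in%
                  c("x y", "y x", "y z", "z y")))
})

test_that("expected_bootstrap_instances is the stated bookkeeping identity", {
  expect_equal(expected_bootstrap_instances(0.9844, 16, 10000), 157504)
  expect_equal(expected_bootstrap_instances(1, 16, 10000), 160000)
})

test_that("dual_network_overlap counts shared pairs and runs Welch correctly", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.3
  W["b", "c"] <- W["c", "b"] <- -0.2
  W["c", "d"] <- W["d", "c"] <- 0.15
  net <- structure(list(weights = W, nodes = letters[1:4]),
                   class = "consnet_rpcn")
  cons <- structure(list(
    arcs = data.frame(from = c("b", "c"), to = c("a", "d"),
                      stringsAsFactors = FALSE),
    nodes = letters[1:4]), class = "consnet_consensus")
  ov <- dual_network_overlap(net, cons)
  expect_identical(ov$shared, 2L)
  expect_equal(ov$shared_pct, round(100 * 2 / 3, 2))
  # disjoint sets
  cons0 <- structure(list(arcs = data.frame(from = "a", to = "d",
                                            stringsAsFactors = FALSE),
                          nodes = letters[1:4]), class = "consnet_consensus")
  ov0 <- dual_network_overlap(net, cons0)
  expect_identical(ov0$shared, 0L)
  expect_equal(ov0$shared_pct, 0)
  # Welch statistic against the textbook closed form (4 + 4 weights)
  W8 <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  shared_w <- c(0.31, 0.25, 0.22, 0.18)
  unique_w <- c(0.08, 0.05, 0.04, 0.06)
  pr <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3), c(2, 4), c(2, 5), c(2, 6))
  for (k in 1:8) {
    w <- c(shared_w, unique_w)[k]
    W8[pr[k, 1], pr[k, 2]] <- W8[pr[k, 2], pr[k, 1]] <- w
  }
  net8 <- structure(list(weights = W8, nodes = letters[1:6]),
                    class = "consnet_rpcn")
  cons8 <- structure(list(
    arcs = data.frame(from = letters[pr[1:4, 1]], to = letters[pr[1:4, 2]],
                      stringsAsFactors = FALSE),
    nodes = letters[1:6]), class = "consnet_consensus")
  ov8 <- dual_network_overlap(net8, cons8)
  oracle <- welch_oracle(shared_w, unique_w)
  expect_equal(ov8$welch$statistic, oracle$t, tolerance = 1e-9)
  expect_equal(ov8$welch$df, oracle$df, tolerance = 1e-9)
  expect_equal(ov8$welch$mean_shared, mean(shared_w))
})
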