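#' Export a network in a standard graph format
#'
#' GraphML and DOT encode node names and edge weights (RPCN) or the
#' learned/grand arc statistics (consensus DAG) as attributes; `csv` mirrors
#' the consensus arc-table column order
#' `(from, to, networks, learned_strength, grand_strength,
#' learned_direction, grand_direction)` or the RPCN edge list; `json` is a
#' round-trippable serialization. Arcs are written in stable
#' `(from, to)` order so exports are deterministic.
#'
#' @param graph a `consnet_rpcn`, `consnet_consensus`, or `consnet_dag`.
#' @param format one of `"graphml"`, `"dot"`, `"csv"`, `"json"`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
export_graph <- function(graph, format = c("graphml", "dot", "csv", "json"),
                         file) {
  format <- match.arg(format)
  if (inherits(graph, "consnet_rpcn")) {
    el <- rpcn_edge_list(graph)
    nodes <- graph$nodes
    directed <- FALSE
  } else if (inherits(graph, "consnet_consensus")) {
    el <- graph$arcs
    nodes <- graph$nodes
    directed <- TRUE
  } else if (inherits(graph, "consnet_dag")) {
    el <- as.data.frame(graph$arcs, stringsAsFactors = FALSE)
    nodes <- graph$nodes
    directed <- TRUE
  } else stop("unsupported graph object")
  if (nrow(el)) el <- el[order(el$from, el$to), , drop = FALSE]
  rownames(el) <- NULL
  switch(format,
    csv = utils::write.csv(el, file, row.names = FALSE),
    json = jsonlite::write_json(list(nodes = nodes, directed = directed,
                                     edges = el),
                                file, auto_unbox = TRUE, digits = NA),
    dot = {
      lines <- c(paste0(if (directed) "digraph" else "graph", " consnet {"),
                 paste0("  \"", nodes, "\";"))
      if (nrow(el)) {
        op <- if (directed) " -> " else " -- "
        lab <- if ("weight" %in% names(el)) sprintf(" [weight=%g]", el$weight)
               else if ("grand_strength" %in% names(el))
                 sprintf(" [label=\"%0.4f\"]", el$grand_strength)
               else ""
        lines <- c(lines, paste0("  \"", el$from, "\"", op, "\"", el$to, "\"",
                                 lab, ";"))
      }
      writeLines(c(lines, "}"), file)
    },
    graphml = {
      g <- igraph::make_empty_graph(n = length(nodes), directed = directed)
      igraph::V(g)$name <- nodes
      if (nrow(el)) {
        g <- igraph::add_edges(g, rbind(match(el$from, nodes),
                                        match(el$to, nodes)))
        for (cn in setdiff(names(el), c("from", "to")))
          g <- igraph::set_edge_attr(g, cn, value = el[[cn]])
      }
      igraph::write_graph(g, file, format = "graphml")
    })
  invisible(file)
}

#' Edge list of an RPCN
#' @param net a `consnet_rpcn`.
#' @return data.frame `from, to, weight` over nonzero upper-triangle edges.
#' @export
rpcn_edge_list <- function(net) {
  W <- net$weights
  ix <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(from = rownames(W)[ix[, 1]], to = colnames(W)[ix[, 2]],
             weight = W[ix], stringsAsFactors = FALSE)
}

#' Parse a graph exported as JSON
#' @param file path written by [export_graph()] with `format = "json"`.
#' @return list with `nodes`, `directed`, `edges`.
#' @export
import_graph_json <- function(file) {
  x <- jsonlite::fromJSON(file)
  if (length(x$edges) == 0) {
    x$edges <- data.frame(from = character(), to = character(),
                          stringsAsFactors = FALSE)
  }
  x
}

#' End-to-end pipeline configuration
#'
#' @param rpcn an [rpcn_config()].
#' @param ensemble an [ensemble_config()].
#' @param screens list of [screening_rule()]s applied before complete-case
#'   filtering.
#' @param rpcn_view which transformed view feeds the RPCN (the reference
#'   analysis uses the five-level discretized view).
#' @param boot_edges,boot_cases bootstrap counts for the RPCN accuracy and
#'   stability stages (0 skips the stage).
#' @param B ensemble bootstraps per cell (overrides `ensemble$B` when set).
#' @param seed master seed.
#' @return object of class `consnet_pipeline_config`.
#' @export
pipeline_config <- function(rpcn = rpcn_config(), ensemble = ensemble_config(),
                            screens = list(), rpcn_view = "disc5",
                            boot_edges = 0L, boot_cases = 0L, B = NULL,
                            seed = 1L) {
  ensemble$seed <- as.integer(seed)
  structure(list(rpcn = rpcn, ensemble = ensemble, screens = screens,
                 rpcn_view = rpcn_view, boot_edges = as.integer(boot_edges),
                 boot_cases = as.integer(boot_cases), B = B,
                 seed = as.integer(seed)),
            class = "consnet_pipeline_config")
}

#' Run the full dual-network pipeline
#'
#' Value screens -> complete-case filter -> four-view transform suite ->
#' RPCN on the configured view (with optional edge/stability bootstraps) ->
#' 16-cell ensemble -> 2X-Cons consensus -> RPCN/DAG overlap report. All
#' tables and graphs are written under `out_dir` together with a JSON run
#' manifest (configuration snapshot, seeds, input hash, versions, per-stage
#' timing, warnings); re-running with the same inputs and manifest settings
#' reproduces the consensus arc table byte-identically.
#'
#' @param cohort a `consnet_cohort` or path to a cohort CSV.
#' @param schema a `consnet_schema` (required when `cohort` is a path).
#' @param bl optional [blacklist()]; defaults to the schema's flags.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return list with all stage objects (`cohort`, `log`, `suite`, `rpcn`,
#'   `centrality`, `predictability`, `edge_boot`, `stability`, `subnets`,
#'   `consensus`, `overlap`, `manifest`), invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(cohort, schema = NULL, bl = NULL,
                         config = pipeline_config(), out_dir) {
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  warn <- character(0)
  wcatch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_hash <- NULL
  if (is.character(cohort)) {
    input_hash <- unname(tools::md5sum(cohort))
    stopifnot(!is.null(schema))
    cohort <- load_cohort(cohort, schema)
  } else {
    input_hash <- object_hash(cohort$data)
  }
  if (is.null(bl)) bl <- blacklist_from_schema(cohort$schema)

  sc <- apply_screens(cohort, config$screens)
  cc <- complete_cases(sc$table, sc$log)
  tab <- cc$table
  exclusion_log_to_json(cc$log, file.path(out_dir, "exclusion_log.json"))
  write_cohort_csv(tab, file.path(out_dir, "cohort_clean.csv"))
  timing["exclusions"] <- proc.time()[["elapsed"]] - t0

  suite <- wcatch(make_transform_suite(tab))
  for (k in names(suite))
    write_cohort_csv(suite[[k]]$table, file.path(out_dir, paste0("view_", k, ".csv")))
  timing["transforms"] <- proc.time()[["elapsed"]] - sum(timing) - t0

  rview <- suite[[config$rpcn_view]]
  co <- correlation_auto(rview, config$rpcn$correlation_method)
  net <- ebic_glasso(co, config = config$rpcn)
  cen <- centrality(net)
  prd <- predictability(rview, net)
  eb <- NULL
  if (config$boot_edges > 0)
    eb <- wcatch(bootstrap_edges(rview, config$boot_edges, config$rpcn,
                                 seed = config$seed + 101L))
  stab <- NULL
  if (config$boot_cases > 0)
    stab <- wcatch(case_drop_stability(rview, config$boot_cases, config$rpcn,
                                       seed = config$seed + 202L))
  el <- rpcn_edge_list(net)
  if (!is.null(eb) && nrow(el)) {
    ij <- cbind(match(el$from, net$nodes), match(el$to, net$nodes))
    el$boot_mean <- eb$mean[ij]
    el$ci_lo <- eb$ci_lo[ij]
    el$ci_hi <- eb$ci_hi[ij]
  }
  utils::write.csv(el, file.path(out_dir, "rpcn_edges.csv"), row.names = FALSE)
  utils::write.csv(merge(cen, prd, by = "node"),
                   file.path(out_dir, "rpcn_centrality.csv"), row.names = FALSE)
  if (!is.null(stab))
    jsonlite::write_json(list(cs = stab$cs, grid = stab$grid,
                              conventions = stab$conventions),
                         file.path(out_dir, "rpcn_stability.json"),
                         auto_unbox = TRUE, digits = NA)
  export_graph(net, "graphml", file.path(out_dir, "rpcn.graphml"))
  timing["rpcn"] <- proc.time()[["elapsed"]] - sum(timing) - t0

  subnets <- wcatch(run_ensemble(suite, config$ensemble, bl, B = config$B))
  for (key in names(subnets)) {
    utils::write.csv(subnets[[key]]$arcs,
                     file.path(out_dir, paste0("cell_", key, ".csv")),
                     row.names = FALSE)
  }
  cons <- consensus_2xcons(subnets, config$ensemble)
  export_graph(cons, "csv", file.path(out_dir, "consensus_arcs.csv"))
  export_graph(cons, "graphml", file.path(out_dir, "consensus.graphml"))
  export_graph(cons, "dot", file.path(out_dir, "consensus.dot"))
  timing["ensemble"] <- proc.time()[["elapsed"]] - sum(timing) - t0

  ov <- dual_network_overlap(net, cons)
  jsonlite::write_json(ov, file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("consnet")),
    r_version = R.version.string,
    input_hash = input_hash,
    seed = config$seed,
    cell_seeds = {
      cs <- list()
      for (tr in config$ensemble$transformations)
        for (al in config$ensemble$algorithms)
          cs[[paste(al, tr, sep = ".")]] <- cell_seed(config$seed, al, tr)
      cs
    },
    config = list(
      rpcn = unclass(config$rpcn),
      ensemble = unclass(config$ensemble),
      rpcn_view = config$rpcn_view,
      boot_edges = config$boot_edges, boot_cases = config$boot_cases,
      B = config$B %||% config$ensemble$B,
      screens = lapply(config$screens, unclass)),
    category_maps = tab$codes,
    consensus_acyclic = cons$acyclic,
    timing_seconds = as.list(round(timing, 3)),
    warnings = warn)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(cohort = tab, log = cc$log, suite = suite, rpcn = net,
                 centrality = cen, predictability = prd, edge_boot = eb,
                 stability = stab, subnets = subnets, consensus = cons,
                 overlap = ov, manifest = manifest))
}

#' Consensus arc table formatted for reporting
#'
#' Percentages to two decimals, mirroring the human-readable convention of
#' the consensus arc table; machine outputs keep full precision.
#'
#' @param consensus a `consnet_consensus`.
#' @return data.frame with percent-scaled statistic columns.
#' @export
format_consensus_table <- function(consensus) {
  a <- consensus$arcs
  data.frame(from = a$from, to = a$to, networks = a$networks,
             learned_strength_pct = round(100 * a$learned_strength, 2),
             grand_strength_pct = round(100 * a$grand_strength, 2),
             learned_direction_pct = round(100 * a$learned_direction, 2),
             grand_direction_pct = round(100 * a$grand_direction, 2),
             stringsAsFactors = FALSE)
}
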