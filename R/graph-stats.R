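# frozen catalog layout: group -> metric names; 108 entries total.
# Changing names or order is a breaking change (golden-file tested).
metric_catalog_names <- function() {
  g9_feats <- c("path_length_bp", "path_step_count", "path_unique_node_count",
                "path_inverted_step_frac", "path_jump_total",
                "path_mean_degree", "path_mean_similarity")
  c(
    # G1 size & composition
    "node_count", "edge_count", "path_count", "sample_count",
    "graph_length_bp", "total_path_length_bp", "compression_ratio",
    "edges_per_node", "graph_density", "connected_components",
    "largest_component_nodes", "isolated_node_count",
    # G2 orientation & loops
    "self_loop_count", "links_ff_count", "links_rr_count",
    "links_inverted_count", "links_inverted_frac", "nodes_both_orientations",
    # G3 node length
    paste0("node_len_", c("mean", "median", "min", "max", "sd")),
    "node_len_n50", "node_len_n90",
    # G4 degree
    paste0(rep(c("degree", "in_degree", "out_degree"), each = 5), "_",
           c("mean", "median", "min", "max", "sd")),
    # G5 depth
    paste0("depth_", c("mean", "median", "min", "max", "sd")),
    "zero_depth_node_count",
    # G6 node similarity
    paste0("similarity_", c("mean", "median", "min", "max", "sd")),
    # G7 pan-classification
    "private_node_count", "private_bp", "shell_node_count", "shell_bp",
    "core_node_count", "core_bp", "core_bp_frac", "private_bp_frac",
    "softcore_node_count",
    # G8 jumps
    "jump_total", "jump_mean", "jump_median", "jump_max", "jump_sd",
    "jumps_above_threshold", "jump_above_threshold_frac", "id_sortedness",
    # G9 path distributions
    paste0(rep(g9_feats, each = 5), "_",
           c("mean", "median", "min", "max", "sd")),
    # G10 edge depth
    paste0("edge_depth_", c("mean", "median", "min", "max", "sd"))
  )
}

# metric names whose values read node ids directly (set NA without numeric ids)
jump_metric_names <- function() {
  c("jump_total", "jump_mean", "jump_median", "jump_max", "jump_sd",
    "jumps_above_threshold", "jump_above_threshold_frac", "id_sortedness",
    paste0("path_jump_total_", c("mean", "median", "min", "max", "sd")))
}

#' The 108-metric graph-level report
#'
#' Computes the package's normative catalog of 108 graph-level metrics in a
#' frozen order: size and composition, orientation and loops, node length,
#' degree, depth, node similarity, pan-classification, jumps, per-path
#' distributions, and edge depth. Definitions: compression_ratio =
#' total_path_length_bp / graph_length_bp; graph_density = non-loop edges over
#' N(N-1)/2; id_sortedness = fraction of adjacent step pairs with increasing
#' ids. Jump metrics need numeric node ids and are reported `NA` (with a
#' warning) otherwise; all other groups are still computed.
#'
#' @param graph A [variation_graph()].
#' @param jump_threshold Jump cutoff in id units (default 1000).
#' @param softcore_frac Softcore occupancy fraction (default 0.95).
#' @return data.table with columns `metric`, `value`: exactly 108 rows.
#' @examples
#' rep <- graph_stats_report(parse_gfa(toy_graphs()$TOY1))
#' nrow(rep)  # 108
#' @export
graph_stats_report <- function(graph, jump_threshold = 1000,
                               softcore_frac = 0.95) {
  stopifnot(inherits(graph, "variation_graph"))
  seg <- graph$segments; L <- graph$links; p <- graph$paths
  N <- nrow(seg); E <- nrow(L); P <- nrow(p)
  S <- length(graph_samples(graph))
  v <- c()
  add <- function(names, values) {
    v[names] <<- as.numeric(values)
  }

  glen <- sum(as.numeric(seg$length))
  st <- steps_table(graph)
  if (nrow(st)) st[, len := seg$length[match(id, seg$id)]]
  plen_total <- if (nrow(st)) sum(as.numeric(st$len)) else 0

  cc <- connected_components(graph)
  dp <- degree_profile(graph)
  dep <- depth_profile(graph)
  self_loops <- if (E) sum(L$from_id == L$to_id) else 0L

  add(c("node_count", "edge_count", "path_count", "sample_count",
        "graph_length_bp", "total_path_length_bp"),
      c(N, E, P, S, glen, plen_total))
  add("compression_ratio", if (glen > 0) plen_total / glen else NA)
  add("edges_per_node", if (N > 0) E / N else NA)
  add("graph_density",
      if (N > 1) (E - self_loops) / (N * (N - 1) / 2) else NA)
  add(c("connected_components", "largest_component_nodes",
        "isolated_node_count"),
      c(cc$count, cc$largest, sum(dp$degree == 0L)))

  ff <- if (E) sum(L$from_orient == "+" & L$to_orient == "+") else 0L
  rr <- if (E) sum(L$from_orient == "-" & L$to_orient == "-") else 0L
  inv <- E - ff - rr
  add(c("self_loop_count", "links_ff_count", "links_rr_count",
        "links_inverted_count"),
      c(self_loops, ff, rr, inv))
  add("links_inverted_frac", if (E > 0) inv / E else NA)
  add("nodes_both_orientations", sum(dep$both_orientations))

  nl <- summary5(seg$length)
  add(paste0("node_len_", names(nl)), nl)
  add(c("node_len_n50", "node_len_n90"),
      c(nX(seg$length, 50), nX(seg$length, 90)))

  for (col in c("degree", "in_degree", "out_degree")) {
    s5 <- summary5(dp[[col]])
    add(paste0(col, "_", names(s5)), s5)
  }

  d5 <- summary5(dep$depth)
  add(paste0("depth_", names(d5)), d5)
  add("zero_depth_node_count", sum(dep$depth == 0L))

  # similarity over visited nodes only: unvisited nodes belong to no sample
  s5 <- summary5(dep$similarity[dep$depth > 0L])
  add(paste0("similarity_", names(s5)), s5)

  cls <- classify_nodes(graph, softcore_frac)
  bp_of <- function(k) sum(as.numeric(cls$length[cls$class == k]))
  n_of <- function(k) sum(cls$class == k)
  add(c("private_node_count", "private_bp", "shell_node_count", "shell_bp",
        "core_node_count", "core_bp"),
      c(n_of("private"), bp_of("private"), n_of("shell"), bp_of("shell"),
        n_of("core"), bp_of("core")))
  add("core_bp_frac", if (glen > 0) bp_of("core") / glen else NA)
  add("private_bp_frac", if (glen > 0) bp_of("private") / glen else NA)
  add("softcore_node_count", sum(cls$softcore))

  pst <- if (graph$id_numeric) {
    path_stats_table(graph, jump_threshold, softcore_frac)
  } else {
    # the table's own non-numeric-id warning is folded into the one below
    suppressWarnings(path_stats_table(graph, jump_threshold, softcore_frac))
  }
  if (graph$id_numeric) {
    jp <- jump_profile(graph, jump_threshold)
    j5 <- summary5(jp$jumps$jump)
    add("jump_total", jp$total)
    add(c("jump_mean", "jump_median", "jump_max", "jump_sd"),
        j5[c("mean", "median", "max", "sd")])
    add("jumps_above_threshold", jp$above_threshold)
    add("jump_above_threshold_frac",
        if (jp$n_pairs > 0) jp$above_threshold / jp$n_pairs else NA)
    add("id_sortedness",
        if (jp$n_pairs > 0) jp$monotone_pairs / jp$n_pairs else NA)
    if (jp$n_pairs == 0) add(c("jump_total", "jumps_above_threshold"), c(0, 0))
  } else {
    warning("non-numeric node ids: jump metrics reported as NA; ",
            "run node2int() to enable them", call. = FALSE)
    add(c("jump_total", "jump_mean", "jump_median", "jump_max", "jump_sd",
          "jumps_above_threshold", "jump_above_threshold_frac",
          "id_sortedness"), rep(NA, 8))
  }

  g9 <- c(path_length_bp = "length_bp", path_step_count = "step_count",
          path_unique_node_count = "unique_node_count",
          path_inverted_step_frac = "inverted_step_frac",
          path_jump_total = "jump_total", path_mean_degree = "mean_degree",
          path_mean_similarity = "mean_similarity")
  for (k in names(g9)) {
    s5 <- summary5(pst[[g9[[k]]]])
    add(paste0(k, "_", names(s5)), s5)
  }

  ed <- edge_depth_profile(graph)
  e5 <- summary5(ed$edge_depth)
  add(paste0("edge_depth_", names(e5)), e5)

  nm <- metric_catalog_names()
  stopifnot(all(nm %in% names(v)))
  data.table(metric = nm, value = unname(v[nm]))
}

#' Per-path statistics table
#'
#' One row per path in input order: sequence length, step and unique-node
#' counts, inversion fraction, jump summaries, step-weighted means of depth,
#' degree and node similarity, and bp on private and core nodes (step
#' multiplicity counted). Jump columns are `NA` (with a warning) when node
#' ids are not numeric.
#'
#' @inheritParams graph_stats_report
#' @return data.table with 16 columns: `path_name`, `sample`, `length_bp`,
#'   `step_count`, `unique_node_count`, `inverted_step_count`,
#'   `inverted_step_frac`, `jump_total`, `jump_max`, `jumps_above_threshold`,
#'   `mean_depth`, `mean_degree`, `mean_similarity`, `private_bp`, `core_bp`,
#'   `mean_node_length`.
#' @export
path_stats_table <- function(graph, jump_threshold = 1000,
                             softcore_frac = 0.95) {
  p <- graph$paths
  cols <- c("path_name", "sample", "length_bp", "step_count",
            "unique_node_count", "inverted_step_count", "inverted_step_frac",
            "jump_total", "jump_max", "jumps_above_threshold", "mean_depth",
            "mean_degree", "mean_similarity", "private_bp", "core_bp",
            "mean_node_length")
  if (!nrow(p)) {
    out <- data.table(path_name = character(), sample = character())
    for (cl in cols[-(1:2)]) out[, (cl) := numeric()]
    return(out)
  }
  st <- steps_table(graph)
  dp <- degree_profile(graph)
  dep <- depth_profile(graph)
  cls <- classify_nodes(graph, softcore_frac)
  seg <- graph$segments
  st[, len := seg$length[match(id, seg$id)]]
  st[, deg := dp$degree[match(id, dp$id)]]
  st[, dth := dep$depth[match(id, dep$id)]]
  st[, sim := dep$similarity[match(id, dep$id)]]
  st[, kls := cls$class[match(id, cls$id)]]
  agg <- st[, .(
    length_bp = sum(as.numeric(len)),
    step_count = .N,
    unique_node_count = uniqueN(id),
    inverted_step_count = sum(orient == "-"),
    inverted_step_frac = mean(orient == "-"),
    mean_depth = mean(dth),
    mean_degree = mean(deg),
    mean_similarity = mean(sim),
    private_bp = sum(as.numeric(len[kls == "private"])),
    core_bp = sum(as.numeric(len[kls == "core"])),
    mean_node_length = mean(len)
  ), by = path]
  agg <- agg[match(p$name, path)]
  if (graph$id_numeric) {
    jp <- jump_profile(graph, jump_threshold)$per_path
    agg[, `:=`(jump_total = jp$jump_total,
               jump_max = jp$jump_max,
               jumps_above_threshold = as.numeric(jp$above_threshold))]
  } else {
    warning("non-numeric node ids: per-path jump columns reported as NA",
            call. = FALSE)
    agg[, `:=`(jump_total = NA_real_, jump_max = NA_real_,
               jumps_above_threshold = NA_real_)]
  }
  out <- data.table(path_name = p$name, sample = p$sample)
  out <- cbind(out, agg[, !"path"])
  setcolorder(out, cols)
  out[]
}
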