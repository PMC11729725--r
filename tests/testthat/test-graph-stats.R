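# hand-evaluated golden values for the toy double-bubble graph
toy1_golden <- c(
  node_count = 4, edge_count = 4, path_count = 2, sample_count = 2,
  graph_length_bp = 8, total_path_length_bp = 14, compression_ratio = 1.75,
  edges_per_node = 1, graph_density = 4 / 6, connected_components = 1,
  largest_component_nodes = 4, isolated_node_count = 0,
  self_loop_count = 0, links_ff_count = 4, links_rr_count = 0,
  links_inverted_count = 0, links_inverted_frac = 0,
  nodes_both_orientations = 0,
  node_len_mean = 2, node_len_median = 1.5, node_len_min = 1,
  node_len_max = 4, node_len_sd = sqrt(mean((c(4, 1, 1, 2) - 2)^2)),
  node_len_n50 = 4, node_len_n90 = 1,
  degree_mean = 2, degree_median = 2, degree_min = 2, degree_max = 2,
  degree_sd = 0,
  in_degree_mean = 1, out_degree_mean = 1,
  depth_mean = 1.5, depth_median = 1.5, depth_min = 1, depth_max = 2,
  depth_sd = 0.5, zero_depth_node_count = 0,
  similarity_mean = 1.5, similarity_median = 1.5, similarity_min = 1,
  similarity_max = 2, similarity_sd = 0.5,
  private_node_count = 2, private_bp = 2, shell_node_count = 0,
  shell_bp = 0, core_node_count = 2, core_bp = 6, core_bp_frac = 0.75,
  private_bp_frac = 0.25, softcore_node_count = 2,
  jump_total = 6, jump_mean = 1.5, jump_median = 1.5, jump_max = 2,
  jump_sd = 0.5, jumps_above_threshold = 0, jump_above_threshold_frac = 0,
  id_sortedness = 1,
  path_length_bp_mean = 7, path_length_bp_sd = 0,
  path_step_count_mean = 3, path_unique_node_count_mean = 3,
  path_inverted_step_frac_max = 0, path_jump_total_mean = 3,
  path_mean_degree_mean = 2, path_mean_similarity_mean = 5 / 3,
  edge_depth_mean = 1, edge_depth_median = 1, edge_depth_min = 1,
  edge_depth_max = 1, edge_depth_sd = 0
)

test_that("the toy graph report matches the hand-computed golden values", {
  rep <- graph_stats_report(toy1())
  for (nm in names(toy1_golden)) {
    expect_equal(metric_value(rep, nm), unname(toy1_golden[nm]),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("the catalog always has exactly 108 uniquely named rows in frozen order", {
  nm <- vgstats:::metric_catalog_names()
  expect_length(nm, 108L)
  expect_false(anyDuplicated(nm) > 0)
  # frozen anchor points of the catalog order
  expect_equal(nm[1], "node_count")
  expect_equal(nm[13], "self_loop_count")
  expect_equal(nm[19], "node_len_mean")
  expect_equal(nm[26], "degree_mean")
  expect_equal(nm[47], "similarity_mean")
  expect_equal(nm[61], "jump_total")
  expect_equal(nm[108], "edge_depth_sd")
  for (txt in toy_graphs()) {
    rep <- suppressWarnings(graph_stats_report(parse_gfa(txt)))
    expect_equal(rep$metric, nm)
    expect_equal(nrow(rep), 108L)
  }
  for (seed in 1:3) {
    rep <- graph_stats_report(sim_graph(rand_config(seed)))
    expect_equal(rep$metric, nm)
  }
})

test_that("degenerate graphs produce NA-safe reports", {
  rep0 <- graph_stats_report(parse_gfa("H\tVN:Z:1.0"))
  expect_equal(nrow(rep0), 108L)
  expect_equal(metric_value(rep0, "node_count"), 0)
  expect_true(is.na(metric_value(rep0, "node_len_mean")))
  repi <- graph_stats_report(parse_gfa(toy_graphs()$inversion))
  expect_gte(metric_value(repi, "links_inverted_count"), 1)
  # single path: every G9 sd is zero
  rep1 <- graph_stats_report(parse_gfa(toy_graphs()$single_sample))
  g9sd <- grep("^path_.*_sd$", rep1$metric)
  expect_true(all(rep1$value[g9sd] == 0))
})

test_that("non-numeric ids blank only the jump metrics, with a warning", {
  g <- parse_gfa(c("H\tVN:Z:1.0", "S\ta\tACG", "S\tb\tT",
                   "L\ta\t+\tb\t+\t0M", "P\tp\ta+,b+\t*"))
  expect_warning(rep <- graph_stats_report(g), "node2int")
  jumps <- rep$metric %in% vgstats:::jump_metric_names()
  expect_true(all(is.na(rep$value[jumps])))
  expect_true(all(!is.na(rep$value[rep$metric %in%
    c("node_count", "edge_count", "depth_mean", "core_node_count")])))
})

test_that("per-path statistics match the hand evaluation of the toy paths", {
  pst <- path_stats_table(toy1())
  expect_equal(names(pst),
               c("path_name", "sample", "length_bp", "step_count",
                 "unique_node_count", "inverted_step_count",
                 "inverted_step_frac", "jump_total", "jump_max",
                 "jumps_above_threshold", "mean_depth", "mean_degree",
                 "mean_similarity", "private_bp", "core_bp",
                 "mean_node_length"))
  x <- pst[pst$path_name == "x"]
  expect_equal(x$length_bp, 7)
  expect_equal(x$step_count, 3L)
  expect_equal(x$unique_node_count, 3L)
  expect_equal(x$inverted_step_frac, 0)
  expect_equal(x$jump_total, 3)
  expect_equal(x$mean_depth, 5 / 3, tolerance = 1e-12)
  expect_equal(x$private_bp, 1)
  expect_equal(x$core_bp, 6)
  y <- pst[pst$path_name == "y"]
  expect_equal(y$length_bp, 7)
  expect_equal(y$jump_total, 3)
  # single-step path on a private node of length 5
  g <- parse_gfa(c("H\tVN:Z:1.0", "S\t1\tAAAAA", "S\t2\tC",
                   "P\tp\t1+\t*", "P\tq\t2+\t*"))
  row <- path_stats_table(g)[1]
  expect_equal(row$private_bp, 5)
  expect_equal(row$jump_total, 0)
  expect_equal(row$step_count, 1L)
  # same node visited by two paths of one sample stays core for that sample
  g2 <- parse_gfa(c("H\tVN:Z:1.0", "S\t1\tAAAAA", "P\tp#1\t1+\t*",
                    "P\tp#2\t1-\t*"))
  expect_equal(path_stats_table(g2)$core_bp, c(5, 5))
  # inversion fixture: one of three steps reversed
  pin <- path_stats_table(parse_gfa(toy_graphs()$inversion))
  expect_equal(pin$inverted_step_frac, 1 / 3, tolerance = 1e-12)
})

test_that("pan-class partition and path totals reconcile with the report", {
  for (seed in 1:5) {
    g <- sim_graph(rand_config(seed))
    rep <- graph_stats_report(g)
    expect_equal(
      metric_value(rep, "private_node_count") +
        metric_value(rep, "shell_node_count") +
        metric_value(rep, "core_node_count") +
        metric_value(rep, "zero_depth_node_count"),
      metric_value(rep, "node_count"))
    pst <- path_stats_table(g)
    expect_equal(sum(pst$length_bp),
                 metric_value(rep, "total_path_length_bp"))
    cls <- classify_nodes(g)
    expect_equal(sum(cls$class == "core"),
                 metric_value(rep, "core_node_count"))
    expect_equal(sum(cls$length[cls$class == "private"]),
                 metric_value(rep, "private_bp"))
  }
})
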