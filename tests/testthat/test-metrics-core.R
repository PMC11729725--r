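test_that("degree profile counts link attachments per node end", {
  dp <- degree_profile(toy1())
  expect_equal(dp$degree, c(2L, 2L, 2L, 2L))
  expect_equal(dp$out_degree[dp$id == "1"], 2L)
  expect_equal(dp$in_degree[dp$id == "4"], 2L)
  # single node, no links
  dp0 <- degree_profile(parse_gfa(toy_graphs()$single_node))
  expect_equal(dp0$degree, 0L)
  # self-loop contributes both ends to one node
  dps <- degree_profile(parse_gfa(toy_graphs()$self_loop))
  expect_equal(dps$degree, 2L)
})

test_that("depth counts step multiplicity, similarity distinct samples", {
  dep <- depth_profile(toy1())
  expect_equal(dep$depth, c(2L, 1L, 1L, 2L))
  expect_equal(dep$similarity, c(2L, 1L, 1L, 2L))
  expect_false(any(dep$both_orientations))

  # a path looping over one node: depth 2, similarity 1
  g <- parse_gfa(c("H\tVN:Z:1.0", "S\t7\tAC", "L\t7\t+\t7\t+\t0M",
                   "P\tp\t7+,7+\t*"))
  dl <- depth_profile(g)
  expect_equal(dl$depth, 2L)
  expect_equal(dl$similarity, 1L)

  # unvisited node has depth 0
  di <- depth_profile(parse_gfa(toy_graphs()$isolated))
  expect_equal(di[di$id == "9"]$depth, 0L)
  expect_equal(di[di$id == "9"]$similarity, 0L)

  # inversion fixture: node 2 seen only reversed, not both orientations
  gi <- parse_gfa(toy_graphs()$inversion)
  expect_false(any(depth_profile(gi)$both_orientations))
  g2 <- parse_gfa(c(toy_graphs()$inversion, "P\ty\t1+,2+,3+\t*"))
  expect_true(depth_profile(g2)[id == "2"]$both_orientations)
})

test_that("edge depth counts traversals direction-agnostically", {
  ed <- edge_depth_profile(toy1())
  expect_equal(ed$edge_depth, rep(1L, 4))
  # additivity under an extra path
  g <- parse_gfa(c(toy_graphs()$TOY1, "P\tz\t1+,2+,4+\t*"))
  ed2 <- edge_depth_profile(g)
  expect_equal(ed2[from_id == "1" & to_id == "2"]$edge_depth, 2L)
  # a reverse-direction traversal hits the same canonical link
  g3 <- parse_gfa(c(toy_graphs()$TOY1, "P\tw\t4-,2-,1-\t*"))
  ed3 <- edge_depth_profile(g3)
  expect_equal(ed3[from_id == "1" & to_id == "2"]$edge_depth, 2L)
  # missing backing link is a validation error naming the path
  bad <- parse_gfa(c("H\tVN:Z:1.0", "S\t1\tA", "S\t2\tC", "P\tp\t1+,2+\t*"))
  expect_error(edge_depth_profile(bad), "path p at step 1")
})

test_that("jump profile computes |delta id| per adjacent pair", {
  jp <- jump_profile(toy1(), threshold = 1000)
  expect_equal(jp$jumps[path == "x"]$jump, c(1, 2))
  expect_equal(jp$jumps[path == "y"]$jump, c(2, 1))
  expect_equal(jp$total, 6)
  expect_equal(jp$above_threshold, 0L)
  expect_equal(jp$monotone_pairs, 4L)
  expect_equal(jp$n_pairs, 4L)

  g <- parse_gfa(c("H\tVN:Z:1.0", "S\t1\tA", "S\t1000000\tC",
                   "L\t1\t+\t1000000\t+\t0M", "P\tp\t1+,1000000+\t*"))
  jb <- jump_profile(g, 1000)
  expect_equal(jb$jumps$jump, 999999)
  expect_equal(jb$above_threshold, 1L)

  # single-step path: empty jump list
  g1 <- parse_gfa(c("H\tVN:Z:1.0", "S\t3\tAC", "P\tp\t3+\t*"))
  j1 <- jump_profile(g1)
  expect_equal(nrow(j1$jumps), 0L)
  expect_equal(j1$per_path$jump_total, 0)

  # non-numeric ids refuse with a pointer to node2int
  gs <- parse_gfa(c("H\tVN:Z:1.0", "S\ta\tA", "P\tp\ta+\t*"))
  expect_error(jump_profile(gs), "node2int")
})

test_that("jump profile is invariant under path reversal", {
  for (seed in 1:5) {
    g <- sim_graph(rand_config(seed))
    p <- g$paths
    rp <- data.table::copy(p)
    rp[, ids := lapply(ids, rev)]
    rp[, orients := lapply(orients, function(o) rev(ifelse(o == "+", "-", "+")))]
    gr <- variation_graph(g$segments, g$links, rp)
    jf <- jump_profile(g); jr <- jump_profile(gr)
    expect_equal(jr$total, jf$total)
    expect_equal(sort(jr$jumps$jump), sort(jf$jumps$jump))
  }
})

test_that("connected components ignore orientation and count isolates", {
  cc <- connected_components(toy1())
  expect_equal(cc$count, 1L)
  expect_equal(cc$largest, 4L)
  cci <- connected_components(parse_gfa(toy_graphs()$isolated))
  expect_equal(cci$count, 2L)
  expect_equal(cci$largest, 4L)
  cc0 <- connected_components(parse_gfa("H\tVN:Z:1.0"))
  expect_equal(cc0$count, 0L)
  expect_equal(cc0$largest, 0L)
})

test_that("Nx matches the cumulative-length definition", {
  expect_equal(nX(c(4, 2, 1, 1), 50), 4)
  expect_equal(nX(c(4, 2, 1, 1), 90), 1)
  expect_equal(nX(5, 10), 5)
  expect_equal(nX(numeric(), 50), 0)
  # brute-force check against direct scan on random inputs
  set.seed(99)
  for (i in 1:20) {
    lens <- sample(1:50, sample(1:12, 1), replace = TRUE)
    X <- sample(c(10, 50, 90), 1)
    s <- sort(lens, decreasing = TRUE)
    expected <- s[min(which(cumsum(s) >= X / 100 * sum(s)))]
    expect_equal(nX(lens, X), expected)
  }
})

test_that("conservation invariants hold on random simulated graphs", {
  for (seed in 1:10) {
    g <- sim_graph(rand_config(seed))
    total_steps <- sum(lengths(g$paths$ids))
    dep <- depth_profile(g)
    expect_equal(sum(dep$depth), total_steps)
    ed <- edge_depth_profile(g)
    expect_equal(sum(ed$edge_depth),
                 sum(pmax(lengths(g$paths$ids) - 1L, 0L)))
    dp <- degree_profile(g)
    expect_equal(sum(dp$degree), 2L * nrow(g$links))
    expect_true(all(dep$similarity <= length(unique(g$paths$sample))))
    expect_true(all(dep$similarity[dep$depth > 0] >= 1))
  }
})
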