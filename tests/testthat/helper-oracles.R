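# shared fixtures and independent brute-force oracles

toy1 <- function() parse_gfa(toy_graphs()$TOY1)

# structural equality of two graphs: segments (id-sorted), canonical link set,
# and paths with their oriented steps
graphs_equal <- function(g1, g2) {
  s1 <- data.table::as.data.table(g1$segments)[order(id)]
  s2 <- data.table::as.data.table(g2$segments)[order(id)]
  key <- c("from_id", "from_orient", "to_id", "to_orient")
  l1 <- data.table::as.data.table(g1$links)[, key, with = FALSE]
  l2 <- data.table::as.data.table(g2$links)[, key, with = FALSE]
  data.table::setorderv(l1, key); data.table::setorderv(l2, key)
  isTRUE(all.equal(s1, s2, check.attributes = FALSE)) &&
    isTRUE(all.equal(l1, l2, check.attributes = FALSE)) &&
    identical(g1$paths$name, g2$paths$name) &&
    identical(g1$paths$ids, g2$paths$ids) &&
    identical(g1$paths$orients, g2$paths$orients)
}

# sample -> distinct node-id set, straight from the path records
sample_node_sets <- function(g) {
  df <- data.frame(
    id = unlist(g$paths$ids, use.names = FALSE),
    sample = rep(g$paths$sample, lengths(g$paths$ids)),
    stringsAsFactors = FALSE
  )
  lapply(split(df$id, df$sample), unique)
}

# growth-curve oracle: explicit enumeration of every k-subset of samples
brute_growth <- function(g) {
  sets <- sample_node_sets(g)
  samples <- unique(g$paths$sample)
  sets <- sets[samples]
  lens <- stats::setNames(as.numeric(g$segments$length), g$segments$id)
  S <- length(samples)
  out <- data.frame(k = seq_len(S), pan_nodes = 0, pan_bp = 0,
                    core_nodes = 0, core_bp = 0)
  for (k in seq_len(S)) {
    combos <- utils::combn(S, k, simplify = FALSE)
    pn <- pb <- cn <- cb <- 0
    for (cc in combos) {
      un <- unique(unlist(sets[cc], use.names = FALSE))
      int <- Reduce(intersect, sets[cc])
      pn <- pn + length(un); pb <- pb + sum(lens[un])
      cn <- cn + length(int); cb <- cb + sum(lens[int])
    }
    m <- length(combos)
    out[k, -1] <- c(pn, pb, cn, cb) / m
  }
  out
}

# random small simulator configuration, deterministic in `seed`
rand_config <- function(seed, max_samples = 6L, max_bubbles = 20L) {
  set.seed(seed)
  sim_config(
    n_samples = sample(2:max_samples, 1),
    n_bubbles = sample(3:max_bubbles, 1),
    backbone_len = c(2L, 8L),
    allele_freq = runif(1, 0.2, 0.8),
    seed = seed
  )
}

sim_graph <- function(config) parse_gfa(simulate_graph(config)$gfa)

metric_value <- function(report, name) report$value[report$metric == name]
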