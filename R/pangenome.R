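# shared pan-class rule; core takes precedence over private when S == 1
pan_class <- function(occupancy, n_samples) {
  ifelse(occupancy == 0L, "absent",
         ifelse(occupancy == n_samples & n_samples >= 1L, "core",
                ifelse(occupancy == 1L, "private", "shell")))
}

#' Core/shell/private classification of nodes
#'
#' Occupancy of a node is the number of distinct samples with at least one
#' path step on it. Classes: `core` (all S samples), `private` (exactly one),
#' `shell` (2..S-1), `absent` (unvisited). The softcore flag marks nodes with
#' occupancy >= ceiling(softcore_frac * S); core nodes are always softcore.
#' With a single sample, a visited node is core (core precedes private).
#'
#' @param graph A [variation_graph()].
#' @param softcore_frac Softcore occupancy fraction in (0, 1]; default 0.95.
#' @param by_haplotype Treat PanSN `sample#haplotype` units as samples.
#' @return data.table per segment (segment order): `id`, `length`,
#'   `occupancy`, `class`, `softcore`.
#' @examples
#' classify_nodes(parse_gfa(toy_graphs()$TOY1))
#' @export
classify_nodes <- function(graph, softcore_frac = 0.95, by_haplotype = FALSE) {
  stopifnot(softcore_frac > 0, softcore_frac <= 1)
  S <- length(graph_samples(graph, by_haplotype))
  dp <- depth_profile(graph, by_haplotype)
  out <- data.table(id = graph$segments$id, length = graph$segments$length,
                    occupancy = dp$similarity)
  out[, class := pan_class(occupancy, S)]
  cut <- ceiling(softcore_frac * S)
  out[, softcore := occupancy > 0L & occupancy >= cut]
  out
}

# occupancy aggregated by level with node and bp counts (visited nodes only)
occupancy_spectrum <- function(graph, by_haplotype = FALSE) {
  cls <- classify_nodes(graph, by_haplotype = by_haplotype)
  cls[occupancy > 0L, .(n = .N, bp = sum(as.numeric(length))), by = occupancy]
}

#' Exact pangenome growth curve
#'
#' Closed-form hypergeometric rarefaction over all k-subsets of samples: for a
#' node present in s of S samples, the probability of being in the union of a
#' random k-subset is 1 - C(S-s,k)/C(S,k), and in the intersection
#' C(s,k)/C(S,k). Summing over nodes (optionally weighted by node length)
#' yields the expected pan and core content for every k without enumeration.
#'
#' @param graph A [variation_graph()] with at least one sample.
#' @param by_haplotype Treat PanSN `sample#haplotype` units as samples.
#' @return data.table with columns `k`, `pan_nodes`, `pan_bp`, `core_nodes`,
#'   `core_bp` for k = 1..S; attribute `mode` = "exact".
#' @examples
#' growth_exact(parse_gfa(toy_graphs()$TOY1))
#' @export
growth_exact <- function(graph, by_haplotype = FALSE) {
  S <- length(graph_samples(graph, by_haplotype))
  if (S < 1L) stop("growth curves need at least one sample", call. = FALSE)
  sp <- occupancy_spectrum(graph, by_haplotype)
  ks <- seq_len(S)
  pan_n <- pan_b <- core_n <- core_b <- numeric(S)
  for (k in ks) {
    # exp(lchoose) handles C(n,k)=0 for k>n via -Inf
    p_pan <- 1 - exp(lchoose(S - sp$occupancy, k) - lchoose(S, k))
    p_core <- exp(lchoose(sp$occupancy, k) - lchoose(S, k))
    pan_n[k] <- sum(sp$n * p_pan); pan_b[k] <- sum(sp$bp * p_pan)
    core_n[k] <- sum(sp$n * p_core); core_b[k] <- sum(sp$bp * p_core)
  }
  out <- data.table(k = ks, pan_nodes = pan_n, pan_bp = pan_b,
                    core_nodes = core_n, core_bp = core_b)
  setattr(out, "mode", "exact")
  out
}

# logical occupancy matrix (visited nodes x samples) and node lengths
occupancy_matrix <- function(graph, by_haplotype = FALSE) {
  st <- steps_table(graph, by_haplotype)
  samples <- graph_samples(graph, by_haplotype)
  pairs <- unique(st[, .(id, sample_id)])
  ids <- unique(pairs$id)
  M <- matrix(FALSE, length(ids), length(samples),
              dimnames = list(ids, samples))
  M[cbind(match(pairs$id, ids), match(pairs$sample_id, samples))] <- TRUE
  w <- graph$segments$length[match(ids, graph$segments$id)]
  list(M = M, lengths = as.numeric(w), samples = samples)
}

#' Permutation pangenome growth curve
#'
#' For each replicate, samples are shuffled with the seeded generator and the
#' cumulative union (pan) and running intersection (core) of their node sets
#' are accumulated at every prefix length k; per-k means over replicates are
#' reported. The same seed gives identical output.
#'
#' @param graph A [variation_graph()] with at least one sample.
#' @param replicates Number of sample-order permutations (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param by_haplotype Treat PanSN `sample#haplotype` units as samples.
#' @return data.table as [growth_exact()]; attributes `mode` = "permutation",
#'   `replicates`, `seed`.
#' @export
growth_permutation <- function(graph, replicates = 100, seed = NULL,
                               by_haplotype = FALSE) {
  stopifnot(replicates >= 1)
  om <- occupancy_matrix(graph, by_haplotype)
  S <- length(om$samples)
  if (S < 1L) stop("growth curves need at least one sample", call. = FALSE)
  n <- nrow(om$M)
  pan_n <- pan_b <- core_n <- core_b <- numeric(S)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      perm <- sample.int(S)
      pan <- logical(n); core <- rep(TRUE, n)
      for (k in seq_len(S)) {
        col <- om$M[, perm[k]]
        pan <- pan | col
        core <- core & col
        pan_n[k] <- pan_n[k] + sum(pan)
        pan_b[k] <- pan_b[k] + sum(om$lengths[pan])
        core_n[k] <- core_n[k] + sum(core)
        core_b[k] <- core_b[k] + sum(om$lengths[core])
      }
    }
  })
  out <- data.table(k = seq_len(S),
                    pan_nodes = pan_n / replicates,
                    pan_bp = pan_b / replicates,
                    core_nodes = core_n / replicates,
                    core_bp = core_b / replicates)
  setattr(out, "mode", "permutation")
  setattr(out, "replicates", replicates)
  setattr(out, "seed", seed)
  out
}

#' Per-path pangenome profile
#'
#' For each path, the bp of its steps falling on nodes of each occupancy level
#' 1..S (step multiplicity counted). Row sums equal path lengths.
#'
#' @param graph A [variation_graph()].
#' @param by_haplotype Treat PanSN `sample#haplotype` units as samples.
#' @return Numeric matrix paths x occupancy levels (dimnames set).
#' @export
path_pangenome_profile <- function(graph, by_haplotype = FALSE) {
  S <- length(graph_samples(graph, by_haplotype))
  p <- graph$paths
  out <- matrix(0, nrow(p), S,
                dimnames = list(p$name, as.character(seq_len(S))))
  if (!nrow(p)) return(out)
  cls <- classify_nodes(graph, by_haplotype = by_haplotype)
  st <- steps_table(graph, by_haplotype)
  st[cls, `:=`(occ = i.occupancy, len = i.length), on = "id"]
  agg <- st[, .(bp = sum(as.numeric(len))), by = .(path, occ)]
  out[cbind(match(agg$path, p$name), agg$occ)] <- agg$bp
  out
}

#' Length-weighted Jaccard similarity between samples
#'
#' For samples i and j with distinct node sets N_i, N_j, the similarity is the
#' total length of the shared nodes divided by the total length of the union.
#' The diagonal is 1 by definition.
#'
#' @param graph A [variation_graph()] with at least one sample.
#' @param by_haplotype Treat PanSN `sample#haplotype` units as samples.
#' @return Symmetric numeric matrix with sample labels.
#' @examples
#' sample_similarity_matrix(parse_gfa(toy_graphs()$TOY1))  # off-diagonal 0.75
#' @export
sample_similarity_matrix <- function(graph, by_haplotype = FALSE) {
  om <- occupancy_matrix(graph, by_haplotype)
  S <- length(om$samples)
  if (S < 1L) stop("similarity needs at least one sample", call. = FALSE)
  Mw <- om$M * om$lengths
  shared <- crossprod(om$M, Mw)          # bp of N_i intersect N_j
  tot <- diag(shared)
  if (any(tot == 0))
    warning("sample(s) with an empty node set: ",
            paste(om$samples[tot == 0], collapse = ", "), call. = FALSE)
  un <- outer(tot, tot, `+`) - shared
  sim <- ifelse(un > 0, shared / un, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(om$samples, om$samples)
  sim
}
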