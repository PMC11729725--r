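#' Configuration for the synthetic variation-graph simulator
#'
#' Describes a bubble-chain graph: S samples, B bubbles separated by backbone
#' nodes, bubble types drawn from {snp, insertion, deletion, inversion}, and a
#' per-bubble alternative-allele frequency (fixed, or drawn from a Beta).
#'
#' @param n_samples Number of samples S (>= 2); one path per sample.
#' @param n_bubbles Number of bubbles B (>= 1).
#' @param backbone_len Integer range `c(min, max)` of backbone (and indel /
#'   inversion) node lengths in bp.
#' @param type_probs Named probabilities over `snp`, `insertion`, `deletion`,
#'   `inversion`; must sum to 1.
#' @param allele_freq Fixed alternative-allele frequency f in (0, 1).
#' @param allele_freq_beta Optional `c(shape1, shape2)`: draw f per bubble
#'   from Beta(shape1, shape2) instead of using the fixed value.
#' @param shuffle_ids Permute node-id labels (keeping record order) to create
#'   high-jump test graphs; by default ids run 1..N along the chain so jumps
#'   are small by construction.
#' @param seed Integer seed; the same config reproduces the graph and truth
#'   byte for byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_bubbles, backbone_len = c(5L, 10L),
                       type_probs = c(snp = 0.4, insertion = 0.2,
                                      deletion = 0.2, inversion = 0.2),
                       allele_freq = 0.5, allele_freq_beta = NULL,
                       shuffle_ids = FALSE, seed = 1L) {
  stopifnot(n_samples >= 2, n_bubbles >= 1,
            length(backbone_len) == 2, backbone_len[1] >= 1,
            backbone_len[2] >= backbone_len[1],
            allele_freq > 0, allele_freq < 1)
  types <- c("snp", "insertion", "deletion", "inversion")
  if (!all(names(type_probs) %in% types) ||
      abs(sum(type_probs) - 1) > 1e-8)
    stop("type_probs must be named over snp/insertion/deletion/inversion ",
         "and sum to 1", call. = FALSE)
  if (!is.null(allele_freq_beta))
    stopifnot(length(allele_freq_beta) == 2, all(allele_freq_beta > 0))
  structure(list(n_samples = as.integer(n_samples),
                 n_bubbles = as.integer(n_bubbles),
                 backbone_len = as.integer(backbone_len),
                 type_probs = type_probs[types[types %in% names(type_probs)]],
                 allele_freq = allele_freq,
                 allele_freq_beta = allele_freq_beta,
                 shuffle_ids = isTRUE(shuffle_ids),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a variation graph with known ground truth
#'
#' Builds an alternating chain backbone node, bubble, backbone node, ... .
#' Bubble realizations: `snp` puts two alternative 1-bp nodes between the
#' flanking backbones; `insertion` puts an optional node that allele carriers
#' traverse while non-carriers take a skip link; `deletion` is the mirror (the
#' node belongs to the reference allele and carriers skip it); `inversion`
#' puts a node all samples traverse, carriers with `-` orientation. Each
#' sample's path picks the alternative allele of each bubble independently
#' with the bubble's frequency f. Node ids are assigned 1..N in left-to-right
#' chain order (so jumps are small by construction) unless `shuffle_ids`.
#' The returned truth sheet records every node's realized sample occupancy and
#' the expected summary counts as constructed.
#'
#' @param config A [sim_config()].
#' @return List with `gfa` (GFAv1 text lines) and `truth`, a list holding
#'   `nodes` (data.table `id`, `length`, `role`, `occupancy`, `class`,
#'   `softcore`), scalar counts (`node_count`, `edge_count`,
#'   `private_node_count`, `shell_node_count`, `core_node_count`,
#'   `absent_node_count`), `path_lengths` (data.table `sample`, `length_bp`)
#'   and the `config`.
#' @examples
#' sim <- simulate_graph(sim_config(n_samples = 4, n_bubbles = 10, seed = 7))
#' g <- parse_gfa(sim$gfa)
#' @export
simulate_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    B <- config$n_bubbles; S <- config$n_samples
    type <- sample(names(config$type_probs), B, replace = TRUE,
                   prob = config$type_probs)
    midc <- ifelse(type == "snp", 2L, 1L)
    rng <- config$backbone_len
    bb_len <- sample(rng[1]:rng[2], B + 1L, replace = TRUE)
    mid_len <- sample(rng[1]:rng[2], B, replace = TRUE)
    mid_len[type == "snp"] <- 1L

    bb_id <- 1L + cumsum(c(0L, 1L + midc))   # length B+1
    mid1 <- bb_id[seq_len(B)] + 1L
    mid2 <- ifelse(type == "snp", mid1 + 1L, NA_integer_)
    n_total <- bb_id[B + 1L]

    f <- if (!is.null(config$allele_freq_beta)) {
      rbeta(B, config$allele_freq_beta[1], config$allele_freq_beta[2])
    } else rep(config$allele_freq, B)
    carrier <- matrix(runif(B * S) < f, nrow = B)  # f recycles per row

    ## node table in chain (id) order
    len <- integer(n_total)
    role <- character(n_total)
    len[bb_id] <- bb_len; role[bb_id] <- "backbone"
    len[mid1] <- ifelse(type == "snp", 1L, mid_len)
    role[mid1] <- ifelse(type == "snp", "snp_ref", type)
    snp <- which(type == "snp")
    len[mid2[snp]] <- 1L; role[mid2[snp]] <- "snp_alt"

    ## realized occupancy per node (number of samples traversing it)
    n_car <- as.integer(rowSums(carrier))
    occ <- integer(n_total)
    occ[bb_id] <- S
    occ[mid1] <- ifelse(type == "snp", S - n_car,
                 ifelse(type == "insertion", n_car,
                 ifelse(type == "deletion", S - n_car, S)))
    occ[mid2[snp]] <- n_car[snp]
    occ <- as.integer(occ)

    samples <- sprintf("sample%02d", seq_len(S))

    ## paths: interleave backbones and per-sample middle choices
    path_ids <- vector("list", S)
    path_or <- vector("list", S)
    for (s in seq_len(S)) {
      car <- carrier[, s]
      mid_s <- ifelse(type == "snp", ifelse(car, mid2, mid1),
               ifelse(type == "insertion", ifelse(car, mid1, NA_integer_),
               ifelse(type == "deletion", ifelse(car, NA_integer_, mid1),
                      mid1)))
      or_s <- ifelse(type == "inversion" & car, "-", "+")
      idm <- rbind(bb_id[seq_len(B)], mid_s)
      orm <- rbind(rep("+", B), or_s)
      keep <- !is.na(idm)
      ids <- c(idm[keep], bb_id[B + 1L])
      if (!length(ids)) stop("simulated sample has an empty path",
                             call. = FALSE)
      path_ids[[s]] <- as.character(ids)
      path_or[[s]] <- c(orm[keep], "+")
    }

    ## links from realized adjacent pairs, canonical + deduplicated
    prs <- rbindlist(lapply(seq_len(S), function(s) {
      ids <- as.integer(path_ids[[s]]); ors <- path_or[[s]]
      m <- length(ids)
      data.table(from_id = ids[-m], from_orient = ors[-m],
                 to_id = ids[-1L], to_orient = ors[-1L])
    }))
    prs[, `:=`(from_id = as.character(from_id), to_id = as.character(to_id),
               overlap = "0M")]
    links <- canonicalize_links(prs, numeric_ids = TRUE)

    ## random DNA sequences
    total_bp <- sum(len)
    big <- paste(sample(c("A", "C", "G", "T"), total_bp, replace = TRUE),
                 collapse = "")
    ends <- cumsum(len); starts <- ends - len + 1L
    seqs <- substring(big, starts, ends)

    node_ids <- seq_len(n_total)
    if (config$shuffle_ids) {
      perm <- sample.int(n_total)   # label of node i becomes perm[i]
      relab <- as.character(perm)
      node_ids <- perm
      path_ids <- lapply(path_ids, function(v) relab[as.integer(v)])
      links[, `:=`(from_id = relab[as.integer(from_id)],
                   to_id = relab[as.integer(to_id)])]
      links <- canonicalize_links(links, numeric_ids = TRUE)
    }

    ## GFA text (S records stay in chain order)
    num_sort <- function(dt) {
      dt[order(as.numeric(from_id), from_orient, as.numeric(to_id),
               to_orient)]
    }
    links <- num_sort(links)
    gfa <- c(
      "H\tVN:Z:1.0",
      sprintf("S\t%d\t%s", node_ids, seqs),
      sprintf("L\t%s\t%s\t%s\t%s\t0M", links$from_id, links$from_orient,
              links$to_id, links$to_orient),
      sprintf("P\t%s\t%s\t*", samples,
              vapply(seq_len(S), function(s)
                paste0(path_ids[[s]], path_or[[s]], collapse = ","), ""))
    )

    cls <- pan_class(occ, S)
    truth_nodes <- data.table(id = node_ids, length = len, role = role,
                              occupancy = occ, class = cls,
                              softcore = occ > 0L & occ >= ceiling(0.95 * S))
    # lengths are indexed by chain position; map labels back when shuffled
    if (config$shuffle_ids) {
      pos <- match(seq_len(n_total), node_ids)  # label -> chain position
      path_bp <- vapply(path_ids, function(v) sum(len[pos[as.integer(v)]]), 0)
    } else {
      path_bp <- vapply(path_ids, function(v) sum(len[as.integer(v)]), 0)
    }
    truth <- list(
      nodes = truth_nodes,
      node_count = n_total,
      edge_count = nrow(links),
      private_node_count = sum(cls == "private"),
      shell_node_count = sum(cls == "shell"),
      core_node_count = sum(cls == "core"),
      absent_node_count = sum(cls == "absent"),
      path_lengths = data.table(sample = samples, length_bp = path_bp),
      config = config
    )
    list(gfa = gfa, truth = truth)
  })
}

#' Small named fixture graphs
#'
#' A collection of hand-checkable GFA texts used throughout the tests and
#' examples: `TOY1` (4 nodes, 4 links, 2 single-sample paths through a double
#' bubble), plus degenerate cases (`empty`, `single_node`, `self_loop`,
#' `isolated` = TOY1 plus an unvisited segment, `single_sample`, and
#' `inversion`, whose path traverses its middle node reversed).
#'
#' @return Named list of character vectors of GFA lines; feed to
#'   [parse_gfa()].
#' @export
toy_graphs <- function() {
  list(
    TOY1 = c(
      "H\tVN:Z:1.0",
      "S\t1\tACGT",
      "S\t2\tA",
      "S\t3\tC",
      "S\t4\tGG",
      "L\t1\t+\t2\t+\t0M",
      "L\t1\t+\t3\t+\t0M",
      "L\t2\t+\t4\t+\t0M",
      "L\t3\t+\t4\t+\t0M",
      "P\tx\t1+,2+,4+\t*",
      "P\ty\t1+,3+,4+\t*"
    ),
    empty = "H\tVN:Z:1.0",
    single_node = c("H\tVN:Z:1.0", "S\t1\tACGT"),
    self_loop = c("H\tVN:Z:1.0", "S\t5\tACG", "L\t5\t+\t5\t+\t0M"),
    isolated = c(
      "H\tVN:Z:1.0",
      "S\t1\tACGT", "S\t2\tA", "S\t3\tC", "S\t4\tGG", "S\t9\tT",
      "L\t1\t+\t2\t+\t0M", "L\t1\t+\t3\t+\t0M",
      "L\t2\t+\t4\t+\t0M", "L\t3\t+\t4\t+\t0M",
      "P\tx\t1+,2+,4+\t*", "P\ty\t1+,3+,4+\t*"
    ),
    single_sample = c(
      "H\tVN:Z:1.0",
      "S\t1\tAC", "S\t2\tGT", "S\t3\tTT",
      "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
      "P\ts\t1+,2+,3+\t*"
    ),
    inversion = c(
      "H\tVN:Z:1.0",
      "S\t1\tA", "S\t2\tCC", "S\t3\tG",
      "L\t1\t+\t2\t-\t0M", "L\t2\t-\t3\t+\t0M",
      "P\tx\t1+,2-,3+\t*"
    )
  )
}
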