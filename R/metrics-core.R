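#' Node degree profile
#'
#' Counts canonical-link attachments per node end. For a canonical link
#' (a,oa,b,ob), the attachment at a's outgoing end increments `out_degree(a)`
#' when oa is `+` (else `in_degree(a)`), and the attachment at b's incoming
#' end increments `in_degree(b)` when ob is `+` (else `out_degree(b)`). A
#' self-loop contributes both attachments to the same node, so the handshake
#' sum(degree) == 2 * edge_count always holds.
#'
#' @param graph A [variation_graph()].
#' @return data.table with one row per segment (in segment order): `id`,
#'   `degree`, `in_degree`, `out_degree`.
#' @export
degree_profile <- function(graph) {
  seg <- graph$segments
  L <- graph$links
  out <- data.table(id = seg$id, degree = 0L, in_degree = 0L, out_degree = 0L)
  if (!nrow(L) || !nrow(seg)) return(out)
  att <- data.table(
    id = c(L$from_id, L$to_id),
    kind = c(ifelse(L$from_orient == "+", "out", "in"),
             ifelse(L$to_orient == "+", "in", "out"))
  )
  cnt <- att[, .N, by = .(id, kind)]
  ins <- cnt[kind == "in"]
  outs <- cnt[kind == "out"]
  out[ins, in_degree := i.N, on = "id"]
  out[outs, out_degree := i.N, on = "id"]
  out[, degree := in_degree + out_degree]
  out
}

#' Node depth, sample occupancy and orientation profile
#'
#' Depth counts path steps on a node with multiplicity; similarity counts
#' distinct samples (not paths or haplotypes) with at least one step on it;
#' `both_orientations` flags nodes traversed in both `+` and `-` orientation
#' across all paths. Unvisited nodes have depth 0 and similarity 0.
#'
#' @param graph A [variation_graph()].
#' @param by_haplotype Count PanSN `sample#haplotype` units instead of samples.
#' @return data.table per segment: `id`, `depth`, `similarity`,
#'   `both_orientations`.
#' @export
depth_profile <- function(graph, by_haplotype = FALSE) {
  seg <- graph$segments
  out <- data.table(id = seg$id, depth = 0L, similarity = 0L,
                    both_orientations = FALSE)
  st <- steps_table(graph, by_haplotype)
  if (!nrow(st) || !nrow(seg)) return(out)
  dep <- st[, .(depth = .N,
                both_orientations = uniqueN(orient) > 1L), by = id]
  sim <- unique(st[, .(id, sample_id)])[, .(similarity = .N), by = id]
  out[dep, `:=`(depth = i.depth, both_orientations = i.both_orientations),
      on = "id"]
  out[sim, similarity := i.similarity, on = "id"]
  out
}

#' Edge traversal depth
#'
#' Counts, per canonical link, the consecutive step pairs (in any path, either
#' direction) that realize it. Every adjacent pair must be backed by a link.
#'
#' @param graph A [variation_graph()].
#' @return data.table: the canonical link columns plus `edge_depth`.
#' @export
edge_depth_profile <- function(graph) {
  L <- copy(graph$links)
  L[, edge_depth := 0L]
  pr <- step_pairs(graph)
  if (!nrow(pr)) return(L)
  cp <- canonicalize_pairs(pr, graph$id_numeric)
  key <- c("from_id", "from_orient", "to_id", "to_orient")
  hit <- L[cp, on = key, which = TRUE]
  if (anyNA(hit)) {
    j <- which(is.na(hit))[1]
    stop("adjacent steps not backed by a link in path ", cp$path[j],
         " at step ", cp$step[j], " (", cp$from_id[j], cp$from_orient[j],
         " -> ", cp$to_id[j], cp$to_orient[j], ")", call. = FALSE)
  }
  tab <- tabulate(hit, nbins = nrow(L))
  L[, edge_depth := tab]
  L
}

# canonicalize adjacent step pairs, keeping path/step provenance
canonicalize_pairs <- function(pr, numeric_ids) {
  cn <- canonicalize_links_keep(pr, numeric_ids)
  cn
}

canonicalize_links_keep <- function(pr, numeric_ids) {
  f <- pr$a; fo <- pr$ao; t_ <- pr$b; to <- pr$bo
  fa <- if (numeric_ids) as.numeric(f) else f
  ta <- if (numeric_ids) as.numeric(t_) else t_
  rfo <- flip_orient(to); rto <- flip_orient(fo)
  o_lt <- function(x, y) x == "+" & y == "-"
  take_rev <- (ta < fa) |
    (ta == fa & o_lt(rfo, fo)) |
    (ta == fa & rfo == fo & o_lt(rto, to))
  data.table(
    path = pr$path, step = pr$step,
    from_id = ifelse(take_rev, t_, f),
    from_orient = ifelse(take_rev, rfo, fo),
    to_id = ifelse(take_rev, f, t_),
    to_orient = ifelse(take_rev, rto, to)
  )
}

#' Per-path jump profile
#'
#' The jump of an adjacent step pair is the absolute difference of the numeric
#' node ids, `|id(b) - id(a)|`. Jumps above the threshold (strict `>`) flag
#' long-range links or an unsorted id space; the monotone-increase count
#' (pairs with id(b) > id(a)) measures how sorted the id space is along paths.
#'
#' @param graph A [variation_graph()] with numeric ids (else an error
#'   instructs to run [node2int()] first).
#' @param threshold Positive integer jump cutoff (default 1000 ids).
#' @return List with `jumps` (data.table `path`, `step`, `jump`, `up`),
#'   `per_path` (data.table `path`, `n_jumps`, `jump_total`, `jump_max`,
#'   `above_threshold`, `monotone_pairs`), `threshold`, and scalar fields
#'   `total`, `above_threshold`, `monotone_pairs`, `n_pairs`.
#' @export
jump_profile <- function(graph, threshold = 1000) {
  if (!graph$id_numeric)
    stop("jump statistics require numeric node ids; run node2int() first",
         call. = FALSE)
  stopifnot(threshold > 0)
  st <- steps_table(graph)
  p <- graph$paths
  if (nrow(st)) st[, iid := as.numeric(id)]
  jd <- if (nrow(st)) {
    st[, if (.N > 1L) .(step = seq_len(.N - 1L),
                        jump = abs(diff(iid)),
                        up = diff(iid) > 0), by = path]
  }
  if (is.null(jd) || !nrow(jd) || !"jump" %in% names(jd)) {
    jd <- data.table(path = character(), step = integer(),
                     jump = numeric(), up = logical())
  }
  per <- jd[, .(n_jumps = .N, jump_total = sum(jump),
                jump_max = max(jump, -Inf),  # -Inf only on the empty template
                above_threshold = sum(jump > threshold),
                monotone_pairs = sum(up)), by = path]
  # paths with a single step have an empty jump list
  missing <- setdiff(p$name, per$path)
  if (length(missing)) {
    per <- rbind(per, data.table(path = missing, n_jumps = 0L, jump_total = 0,
                                 jump_max = 0, above_threshold = 0L,
                                 monotone_pairs = 0L))
  }
  per <- per[match(p$name, path)]
  list(jumps = jd, per_path = per, threshold = threshold,
       total = sum(jd$jump), above_threshold = sum(jd$jump > threshold),
       monotone_pairs = sum(jd$up), n_pairs = nrow(jd))
}

#' Connected components of the node adjacency
#'
#' Components of the undirected node graph induced by canonical links,
#' ignoring orientation. Isolated segments form their own components.
#'
#' @param graph A [variation_graph()].
#' @return List with `membership` (named integer vector over node ids),
#'   `count`, and `largest` (size of the largest component; 0 for an empty
#'   graph).
#' @export
connected_components <- function(graph) {
  seg <- graph$segments
  if (!nrow(seg)) {
    return(list(membership = integer(), count = 0L, largest = 0L))
  }
  ig <- igraph::graph_from_data_frame(
    graph$links[, .(from_id, to_id)],
    directed = FALSE,
    vertices = data.frame(name = seg$id)
  )
  cmp <- igraph::components(ig)
  list(membership = cmp$membership[seg$id],
       count = cmp$no,
       largest = if (cmp$no) max(cmp$csize) else 0L)
}

#' Nx length statistic
#'
#' The length at which the descending cumulative length sum first reaches
#' X percent of the total (N50, N90, ...).
#'
#' @param lengths Vector of positive lengths (bp).
#' @param X Percentage in (0, 100].
#' @return The Nx length; 0 for an empty vector.
#' @examples
#' nX(c(4, 2, 1, 1), 50)  # 4
#' nX(c(4, 2, 1, 1), 90)  # 1
#' @export
nX <- function(lengths, X) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= X / 100 * cs[length(cs)])[1]]
}
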