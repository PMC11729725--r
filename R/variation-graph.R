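#' In-memory bidirected variation graph
#'
#' A `variation_graph` holds the three record classes of a GFAv1 pangenome
#' graph: segments (nodes with DNA sequence or at least a length), canonical
#' links (bidirected edges; a link and its reverse complement are stored once),
#' and named paths of oriented node traversals. Path names following the PanSN
#' convention `sample#haplotype#contig` are split so that the text before the
#' first `#` identifies the sample; names without `#` are their own sample.
#'
#' @param segments data.table with columns `id` (character), `length`
#'   (integer bp) and `sequence` (character, `NA` when the GFA stored `*`).
#' @param links data.table with columns `from_id`, `from_orient`, `to_id`,
#'   `to_orient`, `overlap`; canonicalized and deduplicated on construction.
#' @param paths data.table with columns `name`, `sample` and list columns
#'   `ids`, `orients` (one character vector per path, equal lengths).
#' @return An object of class `variation_graph` with fields `segments`,
#'   `links`, `paths` and the flag `id_numeric` (TRUE iff every segment id is
#'   a positive integer literal).
#' @seealso [parse_gfa()], [write_gfa()], [node2int()]
#' @export
variation_graph <- function(segments, links, paths) {
  segments <- as.data.table(segments)
  links <- as.data.table(links)
  paths <- as.data.table(paths)
  segments[, id := as.character(id)]
  numeric_ids <- ids_numeric(segments$id)
  links <- canonicalize_links(links, numeric_ids)
  g <- structure(
    list(segments = segments, links = links, paths = paths,
         id_numeric = numeric_ids),
    class = "variation_graph"
  )
  validate_variation_graph(g)
  g
}

ids_numeric <- function(ids) {
  length(ids) == 0L || all(grepl("^[1-9][0-9]*$", ids))
}

empty_segments <- function() {
  data.table(id = character(), length = integer(), sequence = character())
}

empty_links <- function() {
  data.table(from_id = character(), from_orient = character(),
             to_id = character(), to_orient = character(),
             overlap = character())
}

empty_paths <- function() {
  data.table(name = character(), sample = character(),
             ids = list(), orients = list())
}

validate_variation_graph <- function(g) {
  seg <- g$segments
  if (anyDuplicated(seg$id))
    stop("duplicate segment id: ",
         paste(unique(seg$id[duplicated(seg$id)]), collapse = ", "),
         call. = FALSE)
  if (nrow(seg) && any(seg$length <= 0L))
    stop("segment length must be positive (id ",
         seg$id[which(seg$length <= 0L)[1]], ")", call. = FALSE)
  p <- g$paths
  if (anyDuplicated(p$name))
    stop("duplicate path name: ",
         paste(unique(p$name[duplicated(p$name)]), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(p))) {
    ids <- p$ids[[i]]
    if (!length(ids))
      stop("path '", p$name[i], "' has no steps", call. = FALSE)
    miss <- setdiff(ids, seg$id)
    if (length(miss))
      stop("unknown segment in path ", p$name[i], ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (length(ids) != length(p$orients[[i]]))
      stop("path '", p$name[i], "' has mismatched ids/orients", call. = FALSE)
  }
  L <- g$links
  if (nrow(L)) {
    known <- c(L$from_id, L$to_id) %in% seg$id
    if (!all(known)) {
      bad <- unique(c(L$from_id, L$to_id)[!known])
      stop("link references unknown segment: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(c(L$from_orient, L$to_orient) %in% c("+", "-")))
      stop("link orientation must be '+' or '-'", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.variation_graph <- function(x, ...) {
  cat("variation_graph:",
      nrow(x$segments), "segments,",
      nrow(x$links), "links,",
      nrow(x$paths), "paths,",
      length(unique(x$paths$sample)), "samples;",
      sum(x$segments$length), "bp;",
      if (x$id_numeric) "numeric ids" else "non-numeric ids", "\n")
  invisible(x)
}

# PanSN sample derivation: text before the first '#', or the full name
pansn_sample <- function(name, by_haplotype = FALSE) {
  if (by_haplotype) {
    two <- grepl("#.*#", name)
    out <- name
    out[two] <- sub("^([^#]*#[^#]*)#.*$", "\\1", name[two])
    out
  } else {
    sub("#.*$", "", name)
  }
}

# one row per path step: path name, sample, node id, orientation, step index
steps_table <- function(g, by_haplotype = FALSE) {
  p <- g$paths
  if (!nrow(p)) {
    return(data.table(path = character(), sample_id = character(),
                      id = character(), orient = character(),
                      step = integer()))
  }
  nst <- lengths(p$ids)
  smp <- if (by_haplotype) pansn_sample(p$name, by_haplotype = TRUE) else p$sample
  data.table(
    path = rep(p$name, nst),
    sample_id = rep(smp, nst),
    id = unlist(p$ids, use.names = FALSE),
    orient = unlist(p$orients, use.names = FALSE),
    step = sequence(nst)
  )
}

graph_samples <- function(g, by_haplotype = FALSE) {
  if (!nrow(g$paths)) return(character())
  unique(if (by_haplotype) pansn_sample(g$paths$name, TRUE) else g$paths$sample)
}

# consecutive oriented step pairs of every path, with step index of the left
# member; empty for single-step paths
step_pairs <- function(g) {
  st <- steps_table(g)
  if (!nrow(st)) {
    return(data.table(path = character(), step = integer(),
                      a = character(), ao = character(),
                      b = character(), bo = character()))
  }
  st[, if (.N > 1L) .(step = seq_len(.N - 1L),
                      a = id[-.N], ao = orient[-.N],
                      b = id[-1L], bo = orient[-1L]),
     by = path]
}
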