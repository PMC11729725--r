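#' Per-base node projection of a path
#'
#' Maps every base of a path (0-based, half-open path coordinates) to the node
#' id of the step covering it, in step order with multiplicity.
#'
#' @param graph A [variation_graph()].
#' @param path_name Name of an existing path.
#' @return Character vector of node ids, one per base (length = path bp).
#' @export
project_path_coordinates <- function(graph, path_name) {
  i <- match(path_name, graph$paths$name)
  if (is.na(i)) stop("unknown path: ", path_name, call. = FALSE)
  ids <- graph$paths$ids[[i]]
  lens <- graph$segments$length[match(ids, graph$segments$id)]
  rep(ids, lens)
}

window_statistics <- c("depth", "similarity", "degree", "node_length",
                       "private_frac", "jump")

#' Sliding-window profiles along paths
#'
#' Computes a node-level statistic in sliding windows along each path, on the
#' step level or the sequence (bp) level. In `steps` mode the window value is
#' the unweighted mean of the statistic over the steps in the window; for
#' `jump`, the mean of the jumps whose left step lies in the window. In `bp`
#' mode every base inherits its step's statistic and the window value is the
#' mean over bases (for `jump`, bases of the final step carry no jump and are
#' excluded from the mean). `private_frac` is the fraction of steps (or bases)
#' on occupancy-1 nodes. Trailing partial windows are dropped unless
#' `keep_tail` is set, in which case the final short window is emitted with a
#' `partial` flag column. Windows use 0-based half-open coordinates.
#'
#' @param graph A [variation_graph()]; numeric ids required for `jump`.
#' @param statistic One of `depth`, `similarity`, `degree`, `node_length`,
#'   `private_frac`, `jump`.
#' @param size Window length (steps or bp), >= 1.
#' @param step Stride in the same unit, between 1 and `size`; default `size`
#'   (tiling windows).
#' @param mode `"steps"` or `"bp"`.
#' @param paths Optional character vector restricting to these path names.
#' @param keep_tail Also emit the trailing partial window, flagged in an extra
#'   `partial` column.
#' @return data.table with columns `path`, `start`, `end`, `value` (and
#'   `partial` when `keep_tail`). Paths shorter than one window contribute no
#'   rows (with a warning).
#' @examples
#' g <- parse_gfa(toy_graphs()$TOY1)
#' sliding_windows(g, "depth", size = 2, step = 1)
#' @export
sliding_windows <- function(graph, statistic, size, step = size,
                            mode = c("steps", "bp"), paths = NULL,
                            keep_tail = FALSE) {
  mode <- match.arg(mode)
  if (!statistic %in% window_statistics)
    stop("unknown statistic '", statistic, "'; choose one of: ",
         paste(window_statistics, collapse = ", "), call. = FALSE)
  stopifnot(size >= 1, step >= 1, step <= size)
  if (statistic == "jump" && !graph$id_numeric)
    stop("statistic 'jump' requires numeric node ids; run node2int() first",
         call. = FALSE)
  p <- graph$paths
  if (!is.null(paths)) {
    miss <- setdiff(paths, p$name)
    if (length(miss))
      stop("unknown path: ", paste(miss, collapse = ", "), call. = FALSE)
    p <- p[name %in% paths]
  }
  seg <- graph$segments
  node_stat <- switch(statistic,
    depth = , similarity = {
      dep <- depth_profile(graph)
      setNames(as.numeric(dep[[statistic]]), dep$id)
    },
    degree = {
      dp <- degree_profile(graph)
      setNames(as.numeric(dp$degree), dp$id)
    },
    node_length = setNames(as.numeric(seg$length), seg$id),
    private_frac = {
      cls <- classify_nodes(graph)
      setNames(as.numeric(cls$occupancy == 1L), cls$id)
    },
    jump = NULL
  )
  res <- vector("list", nrow(p))
  short <- character()
  for (i in seq_len(nrow(p))) {
    ids <- p$ids[[i]]
    m <- length(ids)
    if (statistic == "jump") {
      x <- if (m > 1) abs(diff(as.numeric(ids))) else numeric()
      # per-step value: jump of the pair whose left member is this step
      xs <- c(x, NA_real_)
    } else {
      xs <- unname(node_stat[ids])
    }
    if (mode == "bp") {
      lens <- seg$length[match(ids, seg$id)]
      xv <- rep(xs, lens)
    } else {
      xv <- xs
    }
    n <- length(xv)
    if (n < size) { short <- c(short, p$name[i]); next }
    starts <- seq.int(1L, n - size + 1L, by = step)
    cs <- cumsum(ifelse(is.na(xv), 0, xv))
    cn <- cumsum(!is.na(xv))
    wsum <- cs[starts + size - 1L] - c(0, cs)[starts]
    wn <- cn[starts + size - 1L] - c(0, cn)[starts]
    vals <- ifelse(wn > 0, wsum / wn, NA_real_)
    out <- data.table(path = p$name[i], start = starts - 1L,
                      end = starts - 1L + as.integer(size), value = vals)
    if (keep_tail) {
      out[, partial := FALSE]
      nxt <- starts[length(starts)] + step
      if (nxt <= n) {
        tsum <- cs[n] - cs[nxt - 1L]
        tn <- cn[n] - cn[nxt - 1L]
        out <- rbind(out, data.table(
          path = p$name[i], start = nxt - 1L, end = n,
          value = if (tn > 0) tsum / tn else NA_real_, partial = TRUE))
      }
    }
    res[[i]] <- out
  }
  if (length(short))
    warning("path(s) shorter than one window, no windows emitted: ",
            paste(short, collapse = ", "), call. = FALSE)
  out <- rbindlist(res[!vapply(res, is.null, TRUE)])
  if (!nrow(out)) {
    out <- data.table(path = character(), start = integer(),
                      end = integer(), value = numeric())
    if (keep_tail) out[, partial := logical()]
  }
  out
}
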