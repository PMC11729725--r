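#' Parse a GFAv1 file into a variation graph
#'
#' Reads H, S, L, P and W records. Walk (W) records are converted to paths
#' named `sample#haplotype#seqid`. C and unknown record types are skipped with
#' a warning. Links are stored in canonical bidirected form and deduplicated;
#' a one-time warning is raised when link overlaps other than `*`/`0M` occur,
#' since all bp statistics treat the graph as blunt-ended.
#'
#' @param source Path to a GFA file, or GFA text (a single string containing
#'   newlines, or a character vector of lines).
#' @return A [variation_graph()].
#' @examples
#' g <- parse_gfa(toy_graphs()$TOY1)
#' g
#' @export
parse_gfa <- function(source) {
  lines <- if (length(source) == 1L && !grepl("[\n\t]", source)) {
    if (!file.exists(source)) stop("cannot open GFA file: ", source, call. = FALSE)
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  type <- substr(lines, 1L, 1L)

  unknown <- !type %in% c("H", "S", "L", "P", "W", "C")
  if (any(unknown))
    warning("skipping ", sum(unknown), " record(s) of unknown type: ",
            paste(unique(type[unknown]), collapse = ", "), call. = FALSE)
  if (any(type == "C"))
    warning("skipping ", sum(type == "C"), " containment (C) record(s)",
            call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  ## segments -----------------------------------------------------------
  si <- which(type == "S")
  if (any(nf[si] < 3L))
    stop("malformed S record at line ", lineno[si[which(nf[si] < 3L)[1]]],
         call. = FALSE)
  seg_id <- vapply(fields[si], `[[`, "", 2L)
  seg_seq <- vapply(fields[si], `[[`, "", 3L)
  seg_len <- integer(length(si))
  has_seq <- seg_seq != "*"
  seg_len[has_seq] <- nchar(seg_seq[has_seq])
  if (any(!has_seq)) {
    for (j in which(!has_seq)) {
      tags <- fields[[si[j]]][-(1:3)]
      ln <- grep("^LN:i:", tags, value = TRUE)
      if (!length(ln))
        stop("segment ", seg_id[j], " (line ", lineno[si[j]],
             ") has sequence '*' and no LN:i: tag", call. = FALSE)
      seg_len[j] <- as.integer(sub("^LN:i:", "", ln[1]))
    }
  }
  seg_seq[!has_seq] <- NA_character_
  segments <- if (length(si)) {
    data.table(id = seg_id, length = seg_len, sequence = seg_seq)
  } else empty_segments()

  ## links --------------------------------------------------------------
  li <- which(type == "L")
  if (any(nf[li] < 6L))
    stop("malformed L record at line ", lineno[li[which(nf[li] < 6L)[1]]],
         call. = FALSE)
  links <- if (length(li)) {
    data.table(
      from_id = vapply(fields[li], `[[`, "", 2L),
      from_orient = vapply(fields[li], `[[`, "", 3L),
      to_id = vapply(fields[li], `[[`, "", 4L),
      to_orient = vapply(fields[li], `[[`, "", 5L),
      overlap = vapply(fields[li], `[[`, "", 6L)
    )
  } else empty_links()
  if (nrow(links) && !all(links$overlap %in% c("*", "0M")))
    warning("links with non-trivial overlaps found; bp statistics treat the ",
            "graph as blunt-ended (no overlap subtraction)", call. = FALSE)

  ## paths --------------------------------------------------------------
  pi_ <- which(type == "P")
  if (any(nf[pi_] < 3L))
    stop("malformed P record at line ", lineno[pi_[which(nf[pi_] < 3L)[1]]],
         call. = FALSE)
  p_name <- vapply(fields[pi_], `[[`, "", 2L)
  p_ids <- vector("list", length(pi_))
  p_or <- vector("list", length(pi_))
  for (j in seq_along(pi_)) {
    toks <- strsplit(fields[[pi_[j]]][[3L]], ",", fixed = TRUE)[[1]]
    ors <- substr(toks, nchar(toks), nchar(toks))
    if (!length(toks) || !all(ors %in% c("+", "-")))
      stop("malformed path steps at line ", lineno[pi_[j]], call. = FALSE)
    p_ids[[j]] <- substr(toks, 1L, nchar(toks) - 1L)
    p_or[[j]] <- ors
  }

  ## walks --------------------------------------------------------------
  wi <- which(type == "W")
  if (any(nf[wi] < 7L))
    stop("malformed W record at line ", lineno[wi[which(nf[wi] < 7L)[1]]],
         call. = FALSE)
  w_name <- character(length(wi))
  w_ids <- vector("list", length(wi))
  w_or <- vector("list", length(wi))
  for (j in seq_along(wi)) {
    f <- fields[[wi[j]]]
    w_name[j] <- paste(f[[2L]], f[[3L]], f[[4L]], sep = "#")
    m <- regmatches(f[[7L]], gregexpr("[><][^><]+", f[[7L]]))[[1]]
    if (!length(m))
      stop("malformed walk at line ", lineno[wi[j]], call. = FALSE)
    w_ids[[j]] <- substr(m, 2L, nchar(m))
    w_or[[j]] <- ifelse(substr(m, 1L, 1L) == ">", "+", "-")
  }

  paths <- if (length(pi_) + length(wi)) {
    nm <- c(p_name, w_name)
    data.table(name = nm, sample = pansn_sample(nm),
               ids = c(p_ids, w_ids), orients = c(p_or, w_or))
  } else empty_paths()

  variation_graph(segments, links, paths)
}

#' Write a variation graph as GFAv1 text
#'
#' Emits the header, then S records in ascending id order (with an `LN:i:` tag
#' when the sequence is absent), then canonical L records in sorted order, then
#' P records in path order. `parse_gfa(write_gfa(g))` reproduces `g`.
#'
#' @param graph A [variation_graph()].
#' @param path Optional output file; when `NULL` the GFA text is returned as a
#'   character vector of lines.
#' @return Invisibly (or visibly when `path` is `NULL`), the GFA lines.
#' @export
write_gfa <- function(graph, path = NULL) {
  seg <- copy(graph$segments)
  ord <- if (graph$id_numeric) order(as.numeric(seg$id)) else order(seg$id)
  seg <- seg[ord]
  s_lines <- ifelse(
    is.na(seg$sequence),
    sprintf("S\t%s\t*\tLN:i:%d", seg$id, seg$length),
    sprintf("S\t%s\t%s", seg$id, seg$sequence)
  )
  L <- copy(graph$links)
  if (nrow(L)) {
    if (graph$id_numeric) {
      setorderv(L[, `:=`(.f = as.numeric(from_id), .t = as.numeric(to_id))],
                c(".f", "from_orient", ".t", "to_orient"))
      L[, c(".f", ".t") := NULL]
    } else {
      setorderv(L, c("from_id", "from_orient", "to_id", "to_orient"))
    }
  }
  l_lines <- if (nrow(L)) {
    sprintf("L\t%s\t%s\t%s\t%s\t%s", L$from_id, L$from_orient,
            L$to_id, L$to_orient, L$overlap)
  } else character()
  p <- graph$paths
  p_lines <- vapply(seq_len(nrow(p)), function(i) {
    sprintf("P\t%s\t%s\t*", p$name[i],
            paste0(p$ids[[i]], p$orients[[i]], collapse = ","))
  }, "")
  out <- c("H\tVN:Z:1.0", s_lines, l_lines, p_lines)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Canonical form of a bidirected link
#'
#' A GFA link and its reverse complement (swap endpoints, flip both
#' orientations) denote the same bidirected edge. The canonical representative
#' is the lexicographically smaller of the two tuples under the ordering
#' id ascending, then `+` before `-`.
#'
#' @param from_id,to_id Node ids (character or integer-like).
#' @param from_orient,to_orient Orientations, `"+"` or `"-"`.
#' @return Named character vector `c(from_id, from_orient, to_id, to_orient)`.
#' @examples
#' canonicalize_link(2, "+", 1, "+")  # -> 1 - 2 -
#' @export
canonicalize_link <- function(from_id, from_orient, to_id, to_orient) {
  dt <- data.table(from_id = as.character(from_id),
                   from_orient = from_orient,
                   to_id = as.character(to_id),
                   to_orient = to_orient,
                   overlap = "*")
  cn <- canonicalize_links(dt, ids_numeric(c(dt$from_id, dt$to_id)))
  c(from_id = cn$from_id, from_orient = cn$from_orient,
    to_id = cn$to_id, to_orient = cn$to_orient)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

# vectorized canonicalization + dedup; id comparison numeric when all ids are
# numeric, else bytewise character
canonicalize_links <- function(links, numeric_ids) {
  links <- as.data.table(links)
  if (!nrow(links)) return(empty_links())
  f <- links$from_id; fo <- links$from_orient
  t_ <- links$to_id; to <- links$to_orient
  fa <- if (numeric_ids) as.numeric(f) else f
  ta <- if (numeric_ids) as.numeric(t_) else t_
  rfo <- flip_orient(to)   # reverse tuple: (to, flip(to_or), from, flip(from_or))
  rto <- flip_orient(fo)
  o_lt <- function(x, y) x == "+" & y == "-"
  take_rev <- (ta < fa) |
    (ta == fa & o_lt(rfo, fo)) |
    (ta == fa & rfo == fo & o_lt(rto, to))
  out <- data.table(
    from_id = ifelse(take_rev, t_, f),
    from_orient = ifelse(take_rev, rfo, fo),
    to_id = ifelse(take_rev, f, t_),
    to_orient = ifelse(take_rev, rto, to),
    overlap = links$overlap %||% "*"
  )
  unique(out, by = c("from_id", "from_orient", "to_id", "to_orient"))
}

#' Relabel nodes with consecutive numeric ids
#'
#' Assigns new ids 1..N in order of first appearance as S records, rewrites
#' links (re-canonicalizing under the numeric order) and path steps, and
#' returns the mapping. All id-independent statistics are unchanged; only
#' jump-related metrics, which read the ids themselves, can differ.
#'
#' @param graph A [variation_graph()].
#' @return List with elements `graph` (relabeled [variation_graph()]) and
#'   `map` (data.table `old_id`, `new_id`).
#' @export
node2int <- function(graph) {
  seg <- copy(graph$segments)
  map <- data.table(old_id = seg$id, new_id = seq_len(nrow(seg)))
  lut <- setNames(as.character(map$new_id), map$old_id)
  seg[, id := unname(lut[id])]
  L <- copy(graph$links)
  if (nrow(L)) {
    L[, `:=`(from_id = unname(lut[from_id]), to_id = unname(lut[to_id]))]
  }
  p <- copy(graph$paths)
  if (nrow(p)) p[, ids := lapply(ids, function(v) unname(lut[v]))]
  list(graph = variation_graph(seg, L, p), map = map)
}

#' Write a node-id mapping as TSV
#'
#' @param map data.table with columns `old_id`, `new_id` (as from [node2int()]).
#' @param path Output file.
#' @export
write_id_map <- function(map, path) {
  writeLines(c("old_id\tnew_id",
               sprintf("%s\t%s", map$old_id, map$new_id)), path)
  invisible(path)
}
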