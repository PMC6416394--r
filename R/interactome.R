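#' Protein-protein interactome
#'
#' An `interactome` wraps an undirected, simple [igraph][igraph::igraph] graph
#' whose vertices are protein identifiers (official gene symbols or string-typed
#' numeric gene ids). Self-loops and duplicate edges are dropped at load time
#' and the drop counts retained, since all downstream distance measures assume
#' a simple graph.
#'
#' @param edges two-column matrix or data.frame of edge endpoints, or a
#'   character vector of node names for an edgeless graph.
#' @param nodes optional character vector of isolated nodes to include in
#'   addition to edge endpoints.
#' @return An object of class `interactome` with elements `graph` (the igraph
#'   object), `n_dropped_self` and `n_dropped_dup` (counts removed during
#'   simplification).
#' @examples
#' g <- as_interactome(data.frame(a = c("A", "B"), b = c("B", "C")))
#' g
#' @export
as_interactome <- function(edges, nodes = NULL) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    el <- matrix(character(0), ncol = 2)
  } else if (is.data.frame(edges) || is.matrix(edges)) {
    if (ncol(edges) < 2) stop("edge table must have at least two columns")
    el <- cbind(trimws(as.character(edges[[1]])), trimws(as.character(edges[[2]])))
    if (is.matrix(edges)) el <- cbind(trimws(edges[, 1]), trimws(edges[, 2]))
  } else {
    stop("edges must be a two-column data.frame or matrix")
  }
  if (any(el == "")) stop("empty node identifier in edge table")
  self <- el[, 1] == el[, 2]
  n_self <- sum(self)
  el <- el[!self, , drop = FALSE]
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  el <- el[!dup, , drop = FALSE]
  all_nodes <- unique(c(as.vector(t(el)), trimws(as.character(nodes))))
  all_nodes <- all_nodes[!is.na(all_nodes) & all_nodes != ""]
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = all_nodes
  )
  structure(
    list(graph = g, n_dropped_self = n_self, n_dropped_dup = n_dup,
         .cache = new.env(parent = emptyenv())),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("Interactome:", igraph::vcount(x$graph), "proteins,",
      igraph::ecount(x$graph), "interactions\n")
  if (x$n_dropped_self + x$n_dropped_dup > 0) {
    cat("  dropped at load:", x$n_dropped_self, "self-loops,",
        x$n_dropped_dup, "duplicate edges\n")
  }
  invisible(x)
}

#' @rdname as_interactome
#' @export
interactome_nodes <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::V(g$graph)$name
}

#' Load an interactome from a delimited edge list
#'
#' Reads a plain-text edge list (tab-delimited by default), drops self-loops
#' and duplicate edges with a message, and returns an [as_interactome()]
#' object. Lines starting with `#` are skipped.
#'
#' @param path path to the edge-list file.
#' @param sep field separator (default tab).
#' @param header logical; does the file carry a header row?
#' @param columns length-2 vector selecting the two identifier columns, by
#'   index or (when `header = TRUE`) by name.
#' @param quiet suppress the load summary message.
#' @return An `interactome` object.
#' @export
load_interactome <- function(path, sep = "\t", header = FALSE,
                             columns = c(1L, 2L), quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  tab <- utils::read.table(path, sep = sep, header = header,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("edge list must have at least two columns: ", path)
  if (is.character(columns)) {
    missing_cols <- setdiff(columns, names(tab))
    if (length(missing_cols)) stop("columns not found: ",
                                   paste(missing_cols, collapse = ", "))
  }
  ia <- as_interactome(tab[, columns])
  if (!quiet) {
    message("loaded interactome: ", igraph::vcount(ia$graph), " nodes, ",
            igraph::ecount(ia$graph), " edges (dropped ",
            ia$n_dropped_self, " self-loops, ", ia$n_dropped_dup,
            " duplicates)")
  }
  ia
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; ties between equal-size
#' components are broken by the lexicographically smallest member node.
#'
#' @param g an `interactome`.
#' @return An `interactome` restricted to the largest component.
#' @export
largest_connected_component <- function(g) {
  stopifnot(inherits(g, "interactome"))
  if (igraph::vcount(g$graph) == 0) stop("empty graph")
  comp <- igraph::components(g$graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # smallest member name decides the tie
    mins <- vapply(best, function(k) {
      min(igraph::V(g$graph)$name[comp$membership == k])
    }, character(1))
    best <- best[order(mins)[1]]
  }
  keep <- igraph::V(g$graph)$name[comp$membership == best]
  sub <- igraph::induced_subgraph(g$graph, keep)
  out <- g
  out$graph <- sub
  out$.cache <- new.env(parent = emptyenv())
  out
}

#' Multi-source shortest path lengths
#'
#' Unweighted breadth-first distances from a set of source nodes: for each node
#' the minimum hop count to any source. Nodes unreachable from every source are
#' omitted from the result.
#'
#' @param g an `interactome`.
#' @param sources character vector of source node ids (must be in the graph).
#' @return Named numeric vector of finite distances.
#' @export
shortest_path_lengths_from <- function(g, sources) {
  stopifnot(inherits(g, "interactome"))
  sources <- unique(as.character(sources))
  unknown <- setdiff(sources, interactome_nodes(g))
  if (length(unknown)) stop("unknown source node(s): ",
                            paste(unknown, collapse = ", "))
  d <- dist_rows(g, sources)
  dmin <- apply(d, 2, min)
  dmin[is.finite(dmin)]
}

# Cached per-source BFS rows: matrix |from| x |V| of hop counts, Inf where
# unreachable. Cache lives in the interactome's environment so repeated
# separation / proximity calls on the same object reuse traversals.
dist_rows <- function(g, from) {
  from <- unique(as.character(from))
  cache <- g$.cache
  if (is.null(cache$rows)) cache$rows <- new.env(parent = emptyenv())
  need <- from[!vapply(from, function(v) !is.null(cache$rows[[v]]), logical(1))]
  if (length(need)) {
    m <- igraph::distances(g$graph, v = need, algorithm = "unweighted")
    for (i in seq_along(need)) cache$rows[[need[i]]] <- m[i, ]
  }
  out <- do.call(rbind, lapply(from, function(v) cache$rows[[v]]))
  rownames(out) <- from
  out
}

# distance submatrix |from| x |to|
dist_between <- function(g, from, to) {
  dist_rows(g, from)[, unique(as.character(to)), drop = FALSE]
}

#' Degree-preserving bins
#'
#' Partitions the node set into bins of similar degree for degree-matched
#' randomization. Nodes are first grouped by exact degree; starting from the
#' sparse high-degree tail, adjacent degree groups are merged downward until
#' every bin holds at least `min_bin_size` nodes.
#'
#' @param g an `interactome`.
#' @param min_bin_size minimum bin occupancy (default 100, the convention for
#'   this family of proximity methods; use small values on small graphs).
#' @return An object of class `degree_binning`: list with `bins` (list of
#'   character vectors), `bin_of` (named integer lookup), `min_bin_size`.
#' @export
build_degree_bins <- function(g, min_bin_size = 100L) {
  stopifnot(inherits(g, "interactome"))
  n <- igraph::vcount(g$graph)
  if (min_bin_size < 1 || min_bin_size > n) {
    stop("min_bin_size must be in [1, number of nodes]")
  }
  deg <- igraph::degree(g$graph)
  groups <- split(names(deg), deg) # sorted by increasing degree
  degs <- as.integer(names(groups))
  ord <- order(degs) # ascending
  groups <- groups[ord]
  bins <- list()
  acc <- character(0)
  # sweep from the high-degree end, closing a bin once it is big enough
  for (i in rev(seq_along(groups))) {
    acc <- c(groups[[i]], acc)
    if (length(acc) >= min_bin_size) {
      bins <- c(list(acc), bins)
      acc <- character(0)
    }
  }
  if (length(acc)) {
    if (length(bins)) {
      bins[[1]] <- c(acc, bins[[1]])
    } else {
      bins <- list(acc)
    }
  }
  bin_of <- integer(0)
  for (b in seq_along(bins)) {
    bin_of[bins[[b]]] <- b
  }
  structure(list(bins = bins, bin_of = bin_of,
                 min_bin_size = as.integer(min_bin_size)),
            class = "degree_binning")
}

#' @export
print.degree_binning <- function(x, ...) {
  cat("Degree binning:", length(x$bins), "bins over", length(x$bin_of),
      "nodes (min bin size", x$min_bin_size, ")\n")
  invisible(x)
}

#' Degree-matched random node set
#'
#' Draws a random node set with the same size and bin (degree) profile as a
#' template set: one node per template member, uniformly without replacement
#' from that member's degree bin. If a bin holds fewer members than the
#' template requires, sampling within that bin falls back to with-replacement.
#'
#' @param g an `interactome`.
#' @param binning a `degree_binning` built on `g`.
#' @param template character vector of template node ids.
#' @param seed optional integer seed; the draw is reproducible given the seed.
#' @return Character vector of sampled node ids, same length as `template`.
#' @export
sample_degree_matched <- function(g, binning, template, seed = NULL) {
  stopifnot(inherits(g, "interactome"), inherits(binning, "degree_binning"))
  template <- as.character(template)
  unknown <- template[is.na(binning$bin_of[template])]
  if (length(unknown)) stop("template node(s) not in binning: ",
                            paste(unique(unknown), collapse = ", "))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  counts <- table(binning$bin_of[template])
  out <- character(0)
  for (b in names(counts)) {
    members <- binning$bins[[as.integer(b)]]
    k <- counts[[b]]
    replace <- k > length(members)
    out <- c(out, sample(members, k, replace = replace))
  }
  out
}

# RNG bookkeeping so seeded helpers never disturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
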