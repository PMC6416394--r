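# Independent brute-force oracles used to cross-check the network measures.
# Everything here works on a plain edge matrix + Floyd-Warshall distance
# matrix and never calls the package's distance code.

# all-pairs shortest paths by Floyd-Warshall on an explicit matrix
oracle_dist_matrix <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges[i, 1], edges[i, 2]] <- 1
    d[edges[i, 2], edges[i, 1]] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

finite_mean_oracle <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) NA_real_ else mean(x)
}

oracle_closest <- function(d, A, B) {
  finite_mean_oracle(c(vapply(A, function(a) min(d[a, B]), numeric(1)),
                       vapply(B, function(b) min(d[A, b]), numeric(1))))
}

oracle_shortest <- function(d, A, B) {
  vals <- as.vector(d[A, B, drop = FALSE])
  finite_mean_oracle(vals)
}

oracle_kernel <- function(d, A, B) {
  terms <- c(
    vapply(A, function(a) {
      v <- d[a, B]; v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else -log(sum(exp(-(v + 1))) / length(B))
    }, numeric(1)),
    vapply(B, function(b) {
      v <- d[A, b]; v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else -log(sum(exp(-(v + 1))) / length(A))
    }, numeric(1))
  )
  if (all(is.na(terms))) NA_real_ else mean(terms, na.rm = TRUE)
}

oracle_centre_nodes <- function(d, A) {
  if (length(A) == 1) return(A)
  tot <- vapply(A, function(a) {
    v <- d[a, A]; sum(v[is.finite(v)])
  }, numeric(1))
  A[tot == min(tot)]
}

oracle_centre <- function(d, A, B) {
  ca <- oracle_centre_nodes(d, A)
  cb <- oracle_centre_nodes(d, B)
  finite_mean_oracle(as.vector(d[ca, cb, drop = FALSE]))
}

oracle_within_nearest <- function(d, A) {
  if (length(A) == 1) return(0)
  finite_mean_oracle(vapply(A, function(a) min(d[a, setdiff(A, a)]), numeric(1)))
}

oracle_separation <- function(d, A, B) {
  oracle_closest(d, A, B) -
    (oracle_within_nearest(d, A) + oracle_within_nearest(d, B)) / 2
}

# exhaustive flood fill for connected components
oracle_components <- function(edges, nodes) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  k <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    frontier <- v
    while (length(frontier)) {
      comp[frontier] <- k
      frontier <- unique(unlist(adj[frontier]))
      frontier <- frontier[is.na(comp[frontier])]
    }
  }
  comp
}

# random simple graph on letter-named nodes; returns edges, interactome and
# the oracle distance matrix
random_graph_fixture <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(all_pairs)) < p
  if (!any(keep)) keep[sample(nrow(all_pairs), 1)] <- TRUE
  edges <- all_pairs[keep, , drop = FALSE]
  list(nodes = nodes, edges = edges,
       ia = as_interactome(edges, nodes = nodes),
       d = oracle_dist_matrix(edges, nodes))
}

random_subset <- function(nodes, min_size = 1) {
  k <- sample(min_size:max(min_size, min(4, length(nodes))), 1)
  sample(nodes, k)
}

# small planted fixture reused by several test files (faster than default)
small_fixture_spec <- function(seed = 1) {
  fixture_spec(module_sizes = c(20, 20, 20, 20), n_background = 220,
               seed = seed)
}
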