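#' Closest-distance proximity between drug targets and disease proteins
#'
#' The drug-disease distance d(X, Y): for every disease protein y the shortest
#' path length to the nearest drug target x is taken, and these minima are
#' averaged over the disease set Y. A disease protein that is itself a target
#' contributes zero. Disease proteins unreachable from every target are skipped
#' from the average and counted.
#'
#' @param g an `interactome`.
#' @param targets character vector X of drug target nodes (in the graph).
#' @param disease character vector Y of disease protein nodes (in the graph).
#' @return The mean closest distance (numeric scalar, `NA` if every disease
#'   protein is unreachable) with attribute `n_skipped`.
#' @export
closest_distance_drug_disease <- function(g, targets, disease) {
  stopifnot(inherits(g, "interactome"))
  targets <- unique(as.character(targets))
  disease <- unique(as.character(disease))
  if (!length(targets) || !length(disease)) stop("empty node set")
  check_in_graph(g, c(targets, disease))
  d <- dist_between(g, targets, disease)
  mins <- apply(d, 2, min)
  reachable <- is.finite(mins)
  val <- if (any(reachable)) mean(mins[reachable]) else NA_real_
  attr(val, "n_skipped") <- sum(!reachable)
  val
}

check_in_graph <- function(g, nodes) {
  missing <- setdiff(nodes, interactome_nodes(g))
  if (length(missing)) {
    stop("node(s) not in interactome: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  invisible(TRUE)
}

#' Network proximity z-score
#'
#' Standardizes the observed closest distance between drug targets X and
#' disease proteins Y against a reference distribution of distances between
#' random node sets of matching size and degree profile: z = (d - mu) / sigma.
#' Both the target set and the disease set are resampled degree-matched each
#' iteration by default (`randomize = "drug"` resamples only the targets).
#' Negative z means the drug's targets sit inside the disease module.
#'
#' @inheritParams closest_distance_drug_disease
#' @param binning a `degree_binning` built on `g`.
#' @param n_random number of degree-matched randomizations (default 1000).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param randomize `"both"` (default) or `"drug"`.
#' @return Object of class `proximity_result`: list with `observed_d`, `mu`,
#'   `sigma`, `z` (`NA` when `sigma` is 0, with a `note`), `n_random`, `seed`,
#'   `n_skipped`.
#' @export
proximity_z <- function(g, binning, targets, disease, n_random = 1000,
                        seed = NULL, randomize = c("both", "drug")) {
  randomize <- match.arg(randomize)
  if (n_random < 2) stop("n_random must be >= 2")
  targets <- unique(as.character(targets))
  disease <- unique(as.character(disease))
  obs <- closest_distance_drug_disease(g, targets, disease)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  ref <- vapply(seq_len(n_random), function(i) {
    x <- sample_degree_matched(g, binning, targets)
    y <- if (randomize == "both") sample_degree_matched(g, binning, disease) else disease
    as.numeric(closest_distance_drug_disease(g, x, y))
  }, numeric(1))
  ref <- ref[is.finite(ref)]
  mu <- mean(ref)
  sigma <- stats::sd(ref)
  z <- if (is.na(sigma) || sigma == 0) NA_real_ else (as.numeric(obs) - mu) / sigma
  structure(list(observed_d = as.numeric(obs), mu = mu, sigma = sigma, z = z,
                 n_random = n_random, seed = seed,
                 n_skipped = attr(obs, "n_skipped"),
                 note = if (is.na(z)) "undefined z: zero reference s.d." else NULL),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Network proximity: d = %.4f, mu = %.4f, sigma = %.4f, z = %s (n_random = %d)\n",
              x$observed_d, x$mu, x$sigma,
              if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z),
              x$n_random))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

# internal: per-node minimum distance to the *other* members of its own set;
# singleton sets have no other member and contribute 0 by convention.
within_set_nearest <- function(g, A) {
  if (length(A) == 1) return(structure(0, n_skipped = 0L))
  d <- dist_between(g, A, A)
  diag(d[A, A]) <- Inf
  mins <- apply(d[A, A, drop = FALSE], 1, min)
  reachable <- is.finite(mins)
  val <- if (any(reachable)) mean(mins[reachable]) else NA_real_
  attr(val, "n_skipped") <- sum(!reachable)
  val
}

#' Topological separation of two target modules
#'
#' The separation score s_AB = <d_AB> - (<d_AA> + <d_BB>)/2, where <d_AB> is
#' the symmetric mean nearest-neighbour distance between the two target sets
#' (shared targets contribute zero) and <d_AA>, <d_BB> are the mean distances
#' of each target to the nearest *other* target of the same drug (0 for a
#' singleton set). s_AB < 0 means the two drugs' target modules occupy the same
#' network neighbourhood; s_AB >= 0 means they are topologically separated.
#'
#' @param g an `interactome`.
#' @param A,B character vectors of target nodes for the two drugs.
#' @return Object of class `separation_result`: `s_ab`, `mean_d_aa`,
#'   `mean_d_bb`, `mean_d_ab`, `n_skipped`.
#' @export
separation <- function(g, A, B) {
  stopifnot(inherits(g, "interactome"))
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (!length(A) || !length(B)) stop("empty node set")
  check_in_graph(g, c(A, B))
  daa <- within_set_nearest(g, A)
  dbb <- within_set_nearest(g, B)
  dab <- distance_closest(g, A, B)
  s <- as.numeric(dab) - (as.numeric(daa) + as.numeric(dbb)) / 2
  structure(list(s_ab = s,
                 mean_d_aa = as.numeric(daa), mean_d_bb = as.numeric(dbb),
                 mean_d_ab = as.numeric(dab),
                 n_skipped = attr(daa, "n_skipped") + attr(dbb, "n_skipped") +
                   attr(dab, "n_skipped")),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("Separation s_AB = %.4f  (<d_AB> = %.4f, <d_AA> = %.4f, <d_BB> = %.4f)\n",
              x$s_ab, x$mean_d_ab, x$mean_d_aa, x$mean_d_bb))
  invisible(x)
}

#' Alternative set-to-set network distances
#'
#' Four distance measures between two target sets on the interactome:
#' \describe{
#'   \item{`distance_closest`}{symmetric mean nearest-neighbour distance:
#'     each member of A to its nearest member of B and vice versa, averaged
#'     over |A| + |B| terms.}
#'   \item{`distance_shortest`}{plain mean over all |A| x |B| pairwise
#'     distances.}
#'   \item{`distance_kernel`}{log-average of exponentially down-weighted
#'     distances, penalizing long paths: for singletons at distance d the
#'     value is d + 1.}
#'   \item{`distance_centre`}{distance between the topological centres of the
#'     two sets (the member minimizing total within-set distance); ties are
#'     resolved by averaging over all minimizer pairs.}
#' }
#' Unreachable pairs are skipped from averages and counted in the `n_skipped`
#' attribute; a value with no reachable contribution is `NA`.
#'
#' @param g an `interactome`.
#' @param A,B character vectors of target nodes.
#' @return Numeric scalar with attribute `n_skipped`.
#' @export
distance_closest <- function(g, A, B) {
  ab <- set_dist_matrix(g, A, B)
  mins <- c(apply(ab, 1, min), apply(ab, 2, min))
  finite_mean(mins)
}

#' @rdname distance_closest
#' @export
distance_shortest <- function(g, A, B) {
  ab <- set_dist_matrix(g, A, B)
  finite_mean(as.vector(ab))
}

#' @rdname distance_closest
#' @export
distance_kernel <- function(g, A, B) {
  ab <- set_dist_matrix(g, A, B)
  # -ln of the mean exponential kernel from each node to the opposite set
  row_terms <- apply(ab, 1, function(d) {
    d <- d[is.finite(d)]
    if (!length(d)) return(NA_real_)
    -log(sum(exp(-(d + 1))) / ncol(ab))
  })
  col_terms <- apply(ab, 2, function(d) {
    d <- d[is.finite(d)]
    if (!length(d)) return(NA_real_)
    -log(sum(exp(-(d + 1))) / nrow(ab))
  })
  terms <- c(row_terms, col_terms)
  val <- if (all(is.na(terms))) NA_real_ else mean(terms, na.rm = TRUE)
  attr(val, "n_skipped") <- sum(is.na(terms))
  val
}

#' @rdname distance_closest
#' @export
distance_centre <- function(g, A, B) {
  ca <- set_centre(g, A)
  cb <- set_centre(g, B)
  d <- dist_between(g, ca, cb)
  finite_mean(as.vector(d))
}

# topological centre(s): argmin over set members of total distance to the set;
# all tied minimizers are returned
set_centre <- function(g, A) {
  A <- unique(as.character(A))
  if (length(A) == 1) return(A)
  d <- dist_between(g, A, A)[A, A]
  tot <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  A[tot == min(tot)]
}

set_dist_matrix <- function(g, A, B) {
  stopifnot(inherits(g, "interactome"))
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (!length(A) || !length(B)) stop("empty node set")
  check_in_graph(g, c(A, B))
  dist_between(g, A, B)[A, B, drop = FALSE]
}

finite_mean <- function(x) {
  ok <- is.finite(x)
  val <- if (any(ok)) mean(x[ok]) else NA_real_
  attr(val, "n_skipped") <- sum(!ok)
  val
}

#' Separation scores for many drug pairs
#'
#' Computes [separation()] for every requested pair of drugs in a mapped
#' drug-target map. BFS traversals are cached on the interactome, so the cost
#' is one multi-source traversal per distinct target rather than per pair.
#'
#' @param g an `interactome`.
#' @param m a `drug_target_map` already mapped to `g`
#'   (see [map_targets_to_network()]).
#' @param pairs data.frame with columns `drug_a`, `drug_b`; default all pairs.
#' @return data.frame with columns `drug_a`, `drug_b`, `s_ab`, `d_aa`, `d_bb`,
#'   `d_ab`, `n_skipped`; pairs naming unknown drugs are returned in the
#'   `exclusions` attribute.
#' @export
separation_matrix <- function(g, m, pairs = NULL) {
  stopifnot(inherits(g, "interactome"), inherits(m, "drug_target_map"))
  if (is.null(pairs)) pairs <- drug_pair_universe(m)
  known <- pairs$drug_a %in% names(m$targets) & pairs$drug_b %in% names(m$targets)
  excl <- pairs[!known, , drop = FALSE]
  pairs <- pairs[known, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- separation(g, m$targets[[pairs$drug_a[i]]], m$targets[[pairs$drug_b[i]]])
    data.frame(drug_a = pairs$drug_a[i], drug_b = pairs$drug_b[i],
               s_ab = s$s_ab, d_aa = s$mean_d_aa, d_bb = s$mean_d_bb,
               d_ab = s$mean_d_ab, n_skipped = s$n_skipped,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(drug_a = character(0), drug_b = character(0), s_ab = numeric(0),
               d_aa = numeric(0), d_bb = numeric(0), d_ab = numeric(0),
               n_skipped = integer(0))
  attr(out, "exclusions") <- excl
  out
}
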