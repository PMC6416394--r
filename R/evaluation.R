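#' Balanced-resampling ROC AUC
#'
#' Discrimination of known positive pairs from unknown pairs under class
#' balance: each repeat draws as many unknown pairs as there are positives
#' (uniformly, without replacement), computes the ROC AUC of the score over
#' positives vs sampled negatives, and the mean and s.d. over repeats are
#' reported. Ties are handled by the midrank convention. For separation-style
#' scores where smaller means more combination-like, use
#' `direction = "lower"` (the default).
#'
#' @param scores named numeric vector of scores keyed by pair id
#'   (see [pair_id()] convention `"a|b"`).
#' @param positives character vector of positive pair ids (must be scored).
#' @param universe character vector of all candidate pair ids (must be scored);
#'   unknowns are `setdiff(universe, positives)`.
#' @param n_repeats number of balanced resamples (default 100).
#' @param seed integer seed.
#' @param direction `"lower"` if smaller scores indicate positives, else
#'   `"higher"`.
#' @return Object of class `auc_result`: `mean_auc`, `sd_auc`, `n_repeats`,
#'   `n_pos`, `n_neg_sampled`, `seed`.
#' @export
auc_balanced <- function(scores, positives, universe, n_repeats = 100,
                         seed = NULL, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  positives <- unique(positives)
  universe <- unique(universe)
  if (!length(positives)) stop("no positive pairs")
  if (!all(positives %in% universe)) stop("positives must be in the universe")
  unknown <- setdiff(universe, positives)
  if (length(universe) < 2 * length(positives)) {
    stop("universe too small for balanced sampling")
  }
  missing <- setdiff(universe, names(scores))
  if (length(missing)) stop("unscored pair(s), e.g. ", missing[1])
  s <- scores[universe]
  if (direction == "lower") s <- -s
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_pos <- length(positives)
  aucs <- vapply(seq_len(n_repeats), function(i) {
    neg <- sample(unknown, n_pos)
    rank_auc(s[positives], s[neg])
  }, numeric(1))
  structure(list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 n_repeats = n_repeats, n_pos = n_pos, n_neg_sampled = n_pos,
                 seed = seed, aucs = aucs),
            class = "auc_result")
}

# midrank (Mann-Whitney) AUC: probability a positive outranks a negative
rank_auc <- function(pos_scores, neg_scores) {
  r <- rank(c(pos_scores, neg_scores))
  n1 <- length(pos_scores); n0 <- length(neg_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("Balanced AUC = %.3f +/- %.3f (%d repeats, %d positives)\n",
              x$mean_auc, x$sd_auc, x$n_repeats, x$n_pos))
  invisible(x)
}

#' Permutation test for exposure-class enrichment
#'
#' Tests whether labeled drug pairs (e.g. approved combinations, or adverse
#' interactions) fall into a target exposure class more often than randomly
#' drawn pairs. The statistic is the fraction of labeled pairs in the class;
#' the null draws the same number of pairs uniformly from the classified
#' universe, `n_perm` times. The one-sided enrichment p-value uses the add-one
#' estimator p = (1 + #\{null >= observed\}) / (1 + n_perm), so p is never
#' reported as zero and is floored at 1/(n_perm + 1).
#'
#' @param records classified records from [classify_all()].
#' @param labeled_pairs data.frame `drug_a`, `drug_b` (canonical or not) of
#'   labeled pairs; only those present in `records` are used.
#' @param target_class one of `"P1"`..`"P6"`.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return Object of class `permutation_test_result`: `observed_statistic`,
#'   `null_mean`, `null_sd`, `p_value`, `n_perm`, `n_labeled`.
#' @export
permutation_test_class_counts <- function(records, labeled_pairs, target_class,
                                          n_perm = 10000, seed = NULL) {
  stopifnot(target_class %in% exposure_levels())
  rec_ids <- pair_id(records$drug_a, records$drug_b)
  lab_ids <- unique(pair_id(labeled_pairs$drug_a, labeled_pairs$drug_b))
  lab_ids <- intersect(lab_ids, rec_ids)
  if (!length(lab_ids)) stop("no labeled pair is classifiable")
  if (length(rec_ids) < length(lab_ids)) stop("universe smaller than label set")
  in_class <- stats::setNames(records$class == target_class, rec_ids)
  obs <- mean(in_class[lab_ids])
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  k <- length(lab_ids)
  null <- vapply(seq_len(n_perm), function(i) {
    mean(in_class[sample(rec_ids, k)])
  }, numeric(1))
  structure(list(observed_statistic = obs,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 p_value = (1 + sum(null >= obs)) / (1 + n_perm),
                 n_perm = n_perm, n_labeled = k),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("Class enrichment: observed = %.4f, null = %.4f +/- %.4f, P = %.4g (%d permutations)\n",
              x$observed_statistic, x$null_mean, x$null_sd, x$p_value, x$n_perm))
  invisible(x)
}

#' Bootstrap control sets of adverse interactions
#'
#' Draws `n_boot` control sets of `n_needed` adverse drug-drug interaction
#' pairs from a pool, matching the size of a combination benchmark so class
#' counts can be compared on equal footing. Sampling is without replacement
#' within each draw by default.
#'
#' @param adverse_pairs character vector (pair ids) or data.frame
#'   `drug_a`, `drug_b` of the adverse-interaction pool.
#' @param n_needed pairs per control set.
#' @param n_boot number of control sets (default 100).
#' @param seed integer seed.
#' @param replace sample with replacement within a draw.
#' @return List of `n_boot` character vectors of pair ids.
#' @export
bootstrap_adverse_control <- function(adverse_pairs, n_needed, n_boot = 100,
                                      seed = NULL, replace = FALSE) {
  pool <- if (is.data.frame(adverse_pairs)) {
    unique(pair_id(adverse_pairs$drug_a, adverse_pairs$drug_b))
  } else unique(as.character(adverse_pairs))
  if (!replace && n_needed > length(pool)) {
    stop("n_needed exceeds the adverse pool for without-replacement sampling")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  lapply(seq_len(n_boot), function(i) sample(pool, n_needed, replace = replace))
}
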