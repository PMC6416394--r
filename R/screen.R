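#' Network-based exposure screen of drug pairs against a disease module
#'
#' The package's main entry point. Given an interactome, a drug-target map and
#' a disease gene set, it (i) maps targets onto the network, (ii) computes the
#' topological separation s_AB for every requested drug pair, (iii) computes
#' each drug's proximity z-score to the disease module against degree-matched
#' random expectation, and (iv) classifies every pair into one of the six
#' exposure classes. Complementary-Exposure pairs (both drugs inside the
#' disease module, target modules separated) are the predicted efficacious
#' combinations; Overlapping-Exposure pairs are candidate adverse interactions.
#'
#' @param network an `interactome` (see [load_interactome()]).
#' @param drug_targets a `drug_target_map` (see [load_drug_targets()]).
#' @param disease_genes character vector of disease-associated proteins.
#' @param pairs optional data.frame `drug_a`, `drug_b`; default all pairs of
#'   mapped drugs.
#' @param n_random randomizations per proximity z-score (default 1000).
#' @param min_bin_size degree-bin occupancy for the randomization (default
#'   100; lower it on small networks).
#' @param seed master seed; per-drug randomization seeds are derived from it.
#' @param restrict_lcc restrict all computations to the largest connected
#'   component before measuring (default `FALSE`: distances are computed on
#'   the full graph and unreachable pairs skipped).
#' @param randomize passed to [proximity_z()].
#' @param disease_id label for the disease column of the output.
#' @return Object of class `exposure_screen` with elements `records`
#'   (classified pair table), `z_table` (per-drug proximity), `excluded`
#'   (unclassifiable pairs), `drug_targets` (the mapped map), `params`, `call`.
#' @seealso [predict.exposure_screen()] for the ranked predictions,
#'   [summary.exposure_screen()] for class counts.
#' @examples
#' fx <- generate_planted_fixture(fixture_spec(seed = 7))
#' scr <- exposure_screen(fx$interactome, fx$drug_targets, fx$disease_genes,
#'                        n_random = 100, min_bin_size = 25, seed = 7)
#' summary(scr)
#' predict(scr, top_k = 3)
#' @export
exposure_screen <- function(network, drug_targets, disease_genes, pairs = NULL,
                            n_random = 1000, min_bin_size = 100L, seed = 1L,
                            restrict_lcc = FALSE, randomize = "both",
                            disease_id = "disease") {
  stopifnot(inherits(network, "interactome"),
            inherits(drug_targets, "drug_target_map"))
  cl <- match.call()
  if (restrict_lcc) network <- largest_connected_component(network)
  mapped <- map_targets_to_network(drug_targets, network, quiet = TRUE)
  if (!length(mapped$targets)) stop("no drug has an in-network target")
  disease <- intersect(unique(as.character(disease_genes)),
                       interactome_nodes(network))
  if (!length(disease)) stop("disease gene set has no in-network member")
  binning <- build_degree_bins(network, min_bin_size)
  records <- classify_all(network, mapped, disease, pairs = pairs,
                          binning = binning, n_random = n_random, seed = seed,
                          randomize = randomize, disease_id = disease_id)
  structure(list(records = records,
                 z_table = attr(records, "z_table"),
                 excluded = attr(records, "excluded"),
                 drug_targets = mapped,
                 params = list(n_random = n_random,
                               min_bin_size = min_bin_size, seed = seed,
                               restrict_lcc = restrict_lcc,
                               randomize = randomize,
                               disease_id = disease_id,
                               n_disease_genes = length(disease)),
                 call = cl),
            class = "exposure_screen")
}

#' @export
print.exposure_screen <- function(x, ...) {
  cat(sprintf("Exposure screen: %d classified drug pairs, %d drugs vs disease '%s' (%d in-network genes)\n",
              nrow(x$records), nrow(x$z_table), x$params$disease_id,
              x$params$n_disease_genes))
  tab <- table(x$records$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat("  unclassifiable pairs:", nrow(x$excluded), "\n")
  }
  invisible(x)
}

#' Summarize an exposure screen
#'
#' @param object an `exposure_screen`.
#' @param ... unused.
#' @return Object of class `summary.exposure_screen`: class counts and names,
#'   separation and z summaries, parameters.
#' @export
summary.exposure_screen <- function(object, ...) {
  counts <- table(object$records$class)
  structure(list(class_counts = counts,
                 class_names = exposure_class_names(),
                 s_ab = summary(object$records$s_ab),
                 z = summary(object$z_table$z),
                 n_pairs = nrow(object$records),
                 n_excluded = nrow(object$excluded),
                 params = object$params),
            class = "summary.exposure_screen")
}

#' @export
print.summary.exposure_screen <- function(x, ...) {
  cat("Exposure screen of", x$n_pairs, "drug pairs",
      sprintf("(n_random = %d, min_bin_size = %d, seed = %d)\n",
              x$params$n_random, x$params$min_bin_size, x$params$seed))
  for (cls in names(x$class_counts)) {
    cat(sprintf("  %s %-22s %d\n", cls, x$class_names[[cls]],
                x$class_counts[[cls]]))
  }
  cat("separation s_AB: "); print(x$s_ab)
  cat("proximity z:     "); print(x$z)
  if (x$n_excluded) cat("unclassifiable pairs:", x$n_excluded, "\n")
  invisible(x)
}

#' Predicted combinations or adverse flags from an exposure screen
#'
#' `type = "combinations"` returns Complementary-Exposure (P2) pairs ranked by
#' increasing separation score; `type = "adverse"` returns
#' Overlapping-Exposure (P1) pairs, likewise sorted.
#'
#' @param object an `exposure_screen`.
#' @param type `"combinations"` (default) or `"adverse"`.
#' @param focal optional drug id restriction.
#' @param top_k optional truncation.
#' @param ... unused.
#' @return data.frame of ranked records.
#' @export
predict.exposure_screen <- function(object, type = c("combinations", "adverse"),
                                    focal = NULL, top_k = NULL, ...) {
  type <- match.arg(type)
  if (type == "combinations") {
    rank_complementary(object$records, restrict_to_drug = focal, top_k = top_k)
  } else {
    out <- adverse_flag_overlapping(object$records)
    if (!is.null(focal)) {
      out <- out[out$drug_a == focal | out$drug_b == focal, , drop = FALSE]
    }
    if (!is.null(top_k)) out <- utils::head(out, top_k)
    out
  }
}

#' Plot an exposure screen
#'
#' Symmetric heatmap of pairwise separation scores with the exposure class
#' printed in each cell (base graphics). Intended for screens of modest size,
#' such as one disease's candidate drugs.
#'
#' @param x an `exposure_screen`.
#' @param max_drugs cap on the number of drugs drawn.
#' @param ... passed to [graphics::image()].
#' @export
plot.exposure_screen <- function(x, max_drugs = 40, ...) {
  drugs <- sort(unique(c(x$records$drug_a, x$records$drug_b)))
  if (length(drugs) > max_drugs) drugs <- drugs[seq_len(max_drugs)]
  n <- length(drugs)
  m <- matrix(NA_real_, n, n, dimnames = list(drugs, drugs))
  cls <- matrix("", n, n, dimnames = list(drugs, drugs))
  keep <- x$records$drug_a %in% drugs & x$records$drug_b %in% drugs
  r <- x$records[keep, ]
  m[cbind(r$drug_a, r$drug_b)] <- r$s_ab
  m[cbind(r$drug_b, r$drug_a)] <- r$s_ab
  cls[cbind(r$drug_a, r$drug_b)] <- as.character(r$class)
  cls[cbind(r$drug_b, r$drug_a)] <- as.character(r$class)
  pal <- grDevices::hcl.colors(25, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Pairwise separation s_AB", ...)
  graphics::axis(1, at = seq_len(n), labels = drugs, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(drugs), las = 2,
                 cex.axis = 0.7)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (nzchar(cls[n + 1 - i, j])) {
      graphics::text(j, i, cls[n + 1 - i, j], cex = 0.6)
    }
  }
  invisible(x)
}
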