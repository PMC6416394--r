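#' Exposure classes of a drug-drug-disease triple
#'
#' The six topological classes of a drug pair relative to a disease module,
#' determined entirely by the signs of the pair separation s_AB and the two
#' drug-disease proximity z-scores. The boundary values s_AB = 0 and z = 0
#' belong to the "separated" branches.
#'
#' \tabular{llll}{
#'   class \tab s_AB \tab z_A, z_B \tab name \cr
#'   P1 \tab < 0 \tab both < 0 \tab Overlapping Exposure \cr
#'   P2 \tab >= 0 \tab both < 0 \tab Complementary Exposure \cr
#'   P3 \tab < 0 \tab exactly one < 0 \tab Indirect Exposure \cr
#'   P4 \tab >= 0 \tab exactly one < 0 \tab Single Exposure \cr
#'   P5 \tab < 0 \tab both >= 0 \tab Non-exposure \cr
#'   P6 \tab >= 0 \tab both >= 0 \tab Independent Action \cr
#' }
#'
#' @param s_ab separation score of the pair.
#' @param z_a,z_b proximity z-scores of the two drugs to the disease.
#' @return Factor level in `c("P1", ..., "P6")`; the classification is
#'   invariant under swapping `z_a` and `z_b`.
#' @export
classify_exposure <- function(s_ab, z_a, z_b) {
  if (any(!is.finite(c(s_ab, z_a, z_b)))) {
    stop("classification requires finite s_ab, z_a, z_b")
  }
  n_in <- (z_a < 0) + (z_b < 0)
  overlapping <- s_ab < 0
  cls <- if (n_in == 2) {
    if (overlapping) "P1" else "P2"
  } else if (n_in == 1) {
    if (overlapping) "P3" else "P4"
  } else {
    if (overlapping) "P5" else "P6"
  }
  factor(cls, levels = exposure_levels())
}

exposure_levels <- function() c("P1", "P2", "P3", "P4", "P5", "P6")

#' @rdname classify_exposure
#' @export
exposure_class_names <- function() {
  c(P1 = "Overlapping Exposure", P2 = "Complementary Exposure",
    P3 = "Indirect Exposure", P4 = "Single Exposure",
    P5 = "Non-exposure", P6 = "Independent Action")
}

#' Classify all drug pairs against a disease module
#'
#' For each drug, the proximity z-score to the disease module is computed once
#' (with a per-drug seed derived from `seed`, so results do not depend on pair
#' order) and reused across all pairs involving the drug. Each pair is then
#' classified by [classify_exposure()]. Pairs with undefined separation or
#' z-score are excluded and reported, never silently classified.
#'
#' @param g an `interactome`.
#' @param m a `drug_target_map` mapped to `g`.
#' @param disease character vector of disease proteins (must intersect the
#'   network nodes).
#' @param pairs data.frame `drug_a`, `drug_b`; default the full pair universe.
#' @param binning optional `degree_binning`; built with `min_bin_size` if
#'   missing.
#' @param n_random,seed,randomize passed to [proximity_z()].
#' @param min_bin_size bin occupancy when `binning` is not supplied.
#' @param disease_id label carried into the output table.
#' @return data.frame with columns `drug_a`, `drug_b`, `disease`, `s_ab`,
#'   `z_a`, `z_b`, `class`; attributes `z_table` (per-drug proximity results)
#'   and `excluded` (pairs that could not be classified).
#' @export
classify_all <- function(g, m, disease, pairs = NULL, binning = NULL,
                         n_random = 1000, seed = 1L, min_bin_size = 100L,
                         randomize = "both", disease_id = "disease") {
  stopifnot(inherits(g, "interactome"), inherits(m, "drug_target_map"))
  disease <- intersect(unique(as.character(disease)), interactome_nodes(g))
  if (!length(disease)) stop("disease gene set has no in-network member")
  if (is.null(pairs)) pairs <- drug_pair_universe(m)
  if (is.null(binning)) binning <- build_degree_bins(g, min_bin_size)
  drugs <- sort(unique(c(pairs$drug_a, pairs$drug_b)))
  drugs <- intersect(drugs, names(m$targets))
  z_list <- lapply(seq_along(drugs), function(i) {
    proximity_z(g, binning, m$targets[[drugs[i]]], disease,
                n_random = n_random, seed = seed + i, randomize = randomize)
  })
  names(z_list) <- drugs
  z_table <- data.frame(
    drug = drugs,
    d = vapply(z_list, `[[`, numeric(1), "observed_d"),
    mu = vapply(z_list, `[[`, numeric(1), "mu"),
    sigma = vapply(z_list, `[[`, numeric(1), "sigma"),
    z = vapply(z_list, `[[`, numeric(1), "z"),
    n_random = n_random,
    seed = seed + seq_along(drugs),
    stringsAsFactors = FALSE, row.names = NULL
  )
  sep <- separation_matrix(g, m, pairs)
  z_of <- stats::setNames(z_table$z, z_table$drug)
  recs <- data.frame(
    drug_a = sep$drug_a, drug_b = sep$drug_b, disease = disease_id,
    s_ab = sep$s_ab, z_a = unname(z_of[sep$drug_a]),
    z_b = unname(z_of[sep$drug_b]), stringsAsFactors = FALSE
  )
  ok <- is.finite(recs$s_ab) & is.finite(recs$z_a) & is.finite(recs$z_b)
  excluded <- recs[!ok, , drop = FALSE]
  recs <- recs[ok, , drop = FALSE]
  recs$class <- factor(
    mapply(function(s, za, zb) as.character(classify_exposure(s, za, zb)),
           recs$s_ab, recs$z_a, recs$z_b),
    levels = exposure_levels()
  )
  rownames(recs) <- NULL
  attr(recs, "z_table") <- z_table
  attr(recs, "excluded") <- excluded
  recs
}

#' Rank Complementary-Exposure pairs as predicted combinations
#'
#' Filters classified records to Complementary Exposure (P2) and sorts them by
#' increasing separation score; smaller s_AB ranks first. Ties are broken by
#' the canonical pair id so the ranking is stable across runs.
#'
#' @param records classified records from [classify_all()].
#' @param restrict_to_drug optional focal drug id; keep only pairs containing
#'   it.
#' @param top_k optional truncation of the ranked list.
#' @return data.frame of P2 records with a `rank` column, sorted ascending in
#'   `s_ab`.
#' @export
rank_complementary <- function(records, restrict_to_drug = NULL, top_k = NULL) {
  out <- records[records$class == "P2", , drop = FALSE]
  if (!is.null(restrict_to_drug)) {
    out <- out[out$drug_a == restrict_to_drug | out$drug_b == restrict_to_drug, ,
               drop = FALSE]
  }
  out <- out[order(out$s_ab, pair_id(out$drug_a, out$drug_b)), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  else out$rank <- integer(0)
  rownames(out) <- NULL
  out
}

#' Flag Overlapping-Exposure pairs as candidate adverse interactions
#'
#' Overlapping Exposure (P1) pairs - both drugs inside the disease module with
#' overlapping target modules - carry statistically significant adverse-effect
#' signal rather than added efficacy; this returns them sorted by increasing
#' s_AB as candidate adverse interactions.
#'
#' @param records classified records from [classify_all()].
#' @return data.frame of P1 records sorted ascending in `s_ab`.
#' @export
adverse_flag_overlapping <- function(records) {
  out <- records[records$class == "P1", , drop = FALSE]
  out <- out[order(out$s_ab, pair_id(out$drug_a, out$drug_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
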