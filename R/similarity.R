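#' Tanimoto coefficient of two bit fingerprints
#'
#' T = c / (a + b - c) where a and b are the numbers of set bits in each
#' fingerprint and c the number of bits set in both. Two all-zero fingerprints
#' give 0 (no evidence of similarity).
#'
#' @param fp_a,fp_b fingerprints as 0/1 numeric or logical vectors, or strings
#'   of "0"/"1" characters; lengths must match.
#' @return Numeric in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  fp_a <- as_bits(fp_a); fp_b <- as_bits(fp_b)
  if (length(fp_a) != length(fp_b)) stop("fingerprint length mismatch")
  a <- sum(fp_a); b <- sum(fp_b); c <- sum(fp_a & fp_b)
  if (a + b - c == 0) return(0)
  c / (a + b - c)
}

as_bits <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  }
  x <- as.integer(as.logical(as.numeric(x)))
  if (anyNA(x)) stop("fingerprint must be 0/1 bits")
  x
}

#' Read a fingerprint table
#'
#' Two-column table (`drug`, `bits`) where `bits` is a 0/1 string; all
#' fingerprints in a collection must share one length.
#'
#' @param path file path or data.frame.
#' @param sep separator.
#' @return Named list of integer bit vectors.
#' @export
read_fingerprints <- function(path, sep = "\t") {
  tab <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = sep, header = TRUE, quote = "",
                      stringsAsFactors = FALSE, colClasses = "character")
  fps <- lapply(tab[[2]], as_bits)
  names(fps) <- trimws(tab[[1]])
  if (length(unique(lengths(fps))) > 1) stop("fingerprints differ in length")
  fps
}

# admissible cross pairs a in A, b in B with a != b (shared targets are never
# compared to themselves)
cross_pairs <- function(A, B) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  grid <- expand.grid(a = A, b = B, stringsAsFactors = FALSE)
  grid[grid$a != grid$b, , drop = FALSE]
}

#' Target protein sequence similarity of a drug pair
#'
#' Mean pairwise local-alignment similarity of the two drugs' target proteins:
#' every cross pair (a in A, b in B, a != b) is aligned with the
#' Smith-Waterman algorithm and scored as the number of identical aligned
#' positions divided by the length of the longer sequence, so that identical
#' sequences score 1 while a short spurious local match between unrelated
#' sequences scores near 0. Identical target ids are never compared to
#' themselves. Defaults: BLOSUM62, gap open 10, gap extend 0.5.
#'
#' @param targets_a,targets_b character vectors of target ids.
#' @param sequences named character vector or `AAStringSet` of protein
#'   sequences keyed by target id.
#' @param substitution_matrix,gap_opening,gap_extension alignment parameters.
#' @return Mean identity in [0, 1]; `NA` when no admissible pair exists, with
#'   attribute `n_pairs`.
#' @export
sequence_similarity <- function(targets_a, targets_b, sequences,
                                substitution_matrix = "BLOSUM62",
                                gap_opening = 10, gap_extension = 0.5) {
  pairs <- cross_pairs(targets_a, targets_b)
  if (!nrow(pairs)) {
    return(structure(NA_real_, n_pairs = 0L))
  }
  seqs <- if (inherits(sequences, "XStringSet")) as.character(sequences) else sequences
  missing <- setdiff(unique(c(pairs$a, pairs$b)), names(seqs))
  if (length(missing)) stop("no sequence for target(s): ",
                            paste(missing, collapse = ", "))
  sims <- mapply(function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[a]]), Biostrings::AAString(seqs[[b]]),
      type = "local", substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    Biostrings::nmatch(aln) / max(nchar(seqs[[a]]), nchar(seqs[[b]]))
  }, pairs$a, pairs$b)
  structure(mean(sims), n_pairs = nrow(pairs))
}

#' Co-expression similarity of a drug pair's target genes
#'
#' Mean absolute Pearson correlation across tissues over all cross pairs of
#' target-coding genes (a != b). When an interactome is supplied, the average
#' is restricted to gene pairs that are network edges, reducing correlation
#' noise from unrelated genes. Pairs with a constant expression vector are
#' skipped and counted.
#'
#' @param targets_a,targets_b character vectors of target gene ids.
#' @param expr numeric gene x tissue matrix with gene row names.
#' @param network optional `interactome`; keep only gene pairs that are edges.
#' @return Mean |PCC| in [0, 1]; `NA` when no scorable pair remains, with
#'   attributes `n_pairs` and `n_skipped`.
#' @export
coexpression_similarity <- function(targets_a, targets_b, expr, network = NULL) {
  stopifnot(is.matrix(expr) || is.data.frame(expr))
  expr <- as.matrix(expr)
  pairs <- cross_pairs(targets_a, targets_b)
  pairs <- pairs[pairs$a %in% rownames(expr) & pairs$b %in% rownames(expr), ,
                 drop = FALSE]
  if (!is.null(network)) {
    stopifnot(inherits(network, "interactome"))
    el <- igraph::as_edgelist(network$graph)
    edge_keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
    pair_keys <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "\r")
    pairs <- pairs[pair_keys %in% edge_keys, , drop = FALSE]
  }
  if (!nrow(pairs)) return(structure(NA_real_, n_pairs = 0L, n_skipped = 0L))
  vals <- mapply(function(a, b) {
    x <- expr[a, ]; y <- expr[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    abs(stats::cor(x, y))
  }, pairs$a, pairs$b)
  n_skipped <- sum(is.na(vals))
  val <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  structure(val, n_pairs = sum(!is.na(vals)), n_skipped = n_skipped)
}

# ---- Gene Ontology semantic similarity (Wang's graph-based measure) --------

# S-values of a term's ancestor closure: the semantic contribution of each
# ancestor decays along the DAG by the edge weight (is_a 0.8, part_of 0.6)
wang_svalues <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  s <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    rows <- dag[dag$child %in% frontier, , drop = FALSE]
    if (!nrow(rows)) break
    w <- weights[rows$relation]
    w[is.na(w)] <- min(weights)
    cand <- w * s[rows$child]
    upd <- tapply(cand, rows$parent, max)
    new_s <- pmax(upd, s[names(upd)], na.rm = TRUE)
    changed <- names(new_s)[is.na(s[names(new_s)]) | new_s > s[names(new_s)]]
    s[names(new_s)] <- new_s
    frontier <- changed
  }
  s
}

# Wang similarity of two GO terms on a parent-relation DAG
wang_term_sim <- function(t1, t2, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- wang_svalues(t1, dag, weights)
  s2 <- wang_svalues(t2, dag, weights)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# best-match average over two term sets
wang_gene_sim <- function(terms1, terms2, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  m <- outer(terms1, terms2,
             Vectorize(function(a, b) wang_term_sim(a, b, dag, weights)))
  m <- matrix(m, nrow = length(terms1))
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
    (length(terms1) + length(terms2))
}

#' Gene Ontology similarity of a drug pair's target genes
#'
#' Per gene pair, semantic similarity of the genes' annotation term sets under
#' Wang's DAG-based measure: each term's semantic value decays along is_a
#' (weight 0.8) / part_of (weight 0.6) edges toward the root, term-term
#' similarity is the shared ancestral semantic mass, and term sets are combined
#' by best-match averaging. The drug-level value averages all cross gene pairs
#' (a != b); unannotated genes are skipped and counted.
#'
#' @param genes_a,genes_b character vectors of target-coding gene ids.
#' @param annotations data.frame with columns `gene`, `term` and optionally
#'   `branch` (`BP`, `MF`, `CC`).
#' @param dag data.frame with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`); must be acyclic.
#' @param branch optional branch filter applied to `annotations`.
#' @param weights named decay weights per relation type.
#' @return Mean similarity in [0, 1]; `NA` if no scorable pair, with
#'   attributes `n_pairs`, `n_skipped`.
#' @export
go_similarity <- function(genes_a, genes_b, annotations, dag, branch = NULL,
                          weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(c("gene", "term") %in% names(annotations)),
            all(c("child", "parent") %in% names(dag)))
  if (!"relation" %in% names(dag)) dag$relation <- "is_a"
  if (!is.null(branch) && "branch" %in% names(annotations)) {
    annotations <- annotations[annotations$branch == branch, , drop = FALSE]
  }
  ann <- split(annotations$term, annotations$gene)
  pairs <- cross_pairs(genes_a, genes_b)
  if (!nrow(pairs)) return(structure(NA_real_, n_pairs = 0L, n_skipped = 0L))
  vals <- mapply(function(a, b) {
    ta <- ann[[a]]; tb <- ann[[b]]
    if (is.null(ta) || is.null(tb)) return(NA_real_)
    wang_gene_sim(unique(ta), unique(tb), dag, weights)
  }, pairs$a, pairs$b)
  n_skipped <- sum(is.na(vals))
  val <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  structure(val, n_pairs = sum(!is.na(vals)), n_skipped = n_skipped)
}

# ---- ATC clinical similarity ------------------------------------------------

atc_valid <- function(code) {
  grepl("^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$", code)
}

atc_level_prefix <- function(code, k) {
  substr(code, 1, c(1, 3, 4, 5, 7)[k])
}

# mean over the 5 levels of the level-prefix Jaccard for one code pair
atc_code_pair_sim <- function(code_a, code_b) {
  mean(vapply(1:5, function(k) {
    as.numeric(atc_level_prefix(code_a, k) == atc_level_prefix(code_b, k))
  }, numeric(1)))
}

#' Clinical (ATC) similarity of two drugs
#'
#' Per ATC code pair, the fraction of the five hierarchy levels at which the
#' codes agree (level-k Jaccard of singleton prefix sets); drugs with multiple
#' ATC codes are scored for every code pair and the scores averaged.
#'
#' @param codes_a,codes_b character vectors of 7-character ATC codes
#'   (letter, 2 digits, 2 letters, 2 digits).
#' @return Mean similarity in [0, 1].
#' @export
atc_similarity <- function(codes_a, codes_b) {
  codes_a <- unique(toupper(trimws(codes_a)))
  codes_b <- unique(toupper(trimws(codes_b)))
  if (!length(codes_a) || !length(codes_b)) stop("each drug needs >= 1 ATC code")
  bad <- c(codes_a[!atc_valid(codes_a)], codes_b[!atc_valid(codes_b)])
  if (length(bad)) stop("malformed ATC code(s): ", paste(bad, collapse = ", "))
  grid <- expand.grid(a = codes_a, b = codes_b, stringsAsFactors = FALSE)
  mean(mapply(atc_code_pair_sim, grid$a, grid$b))
}

#' Target-set overlap statistics of a drug pair
#'
#' Set-based overlap measures that ignore the network: the observed shared
#' target count, its expectation under random placement of targets among the N
#' interactome proteins, the fold change observed/expected, exact
#' hypergeometric enrichment and depletion tails, the overlap coefficient
#' C = |A \eqn{\cap}{n}B| / min(|A|, |B|) and the Jaccard index
#' J = |A \eqn{\cap}{n} B| / |A \eqn{\cup}{u} B|.
#'
#' @param A,B character vectors of target ids.
#' @param N number of proteins in the sampling universe (e.g. the interactome
#'   node count); must be at least |A union B|.
#' @return Object of class `overlap_stats`: `c_obs`, `c_rand`, `fold_change`,
#'   `p_enrich`, `p_deplete`, `overlap_coef`, `jaccard`.
#' @export
overlap_stats <- function(A, B, N) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (!length(A) || !length(B)) stop("empty target set")
  if (N < length(union(A, B))) stop("N smaller than |A union B|")
  c_obs <- length(intersect(A, B))
  c_rand <- length(A) * length(B) / N
  structure(list(
    c_obs = c_obs,
    c_rand = c_rand,
    fold_change = c_obs / c_rand,
    p_enrich = stats::phyper(c_obs - 1, length(A), N - length(A), length(B),
                             lower.tail = FALSE),
    p_deplete = stats::phyper(c_obs, length(A), N - length(A), length(B)),
    overlap_coef = c_obs / min(length(A), length(B)),
    jaccard = c_obs / length(union(A, B))
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("Target overlap: c_obs = %d, c_rand = %.3f, fc = %.2f, J = %.3f, C = %.3f\n",
              x$c_obs, x$c_rand, x$fold_change, x$jaccard, x$overlap_coef))
  cat(sprintf("  P(enrich) = %.3g, P(deplete) = %.3g\n", x$p_enrich, x$p_deplete))
  invisible(x)
}

#' All available similarity metrics for one drug pair
#'
#' Computes every metric whose inputs are supplied; metrics lacking inputs are
#' reported as `NA` so the caller can tell "not computed" from "zero
#' similarity".
#'
#' @param drug_a,drug_b drug ids.
#' @param targets named list of target sets per drug.
#' @param fingerprints optional named list of bit vectors.
#' @param sequences optional named sequences keyed by target id.
#' @param expr optional gene x tissue matrix.
#' @param annotations,dag optional GO inputs (see [go_similarity()]).
#' @param atc optional named list of ATC code vectors per drug.
#' @param network optional `interactome` (used for the co-expression edge
#'   filter and the overlap universe size).
#' @param N overlap universe size; defaults to the network node count when a
#'   network is given.
#' @return One-row data.frame with columns `drug_a`, `drug_b`, `tanimoto`,
#'   `sequence`, `coexpression`, `go_bp`, `go_mf`, `go_cc`, `atc`, `jaccard`,
#'   `overlap_coef`.
#' @export
similarity_profile <- function(drug_a, drug_b, targets,
                               fingerprints = NULL, sequences = NULL,
                               expr = NULL, annotations = NULL, dag = NULL,
                               atc = NULL, network = NULL, N = NULL) {
  A <- targets[[drug_a]]; B <- targets[[drug_b]]
  out <- data.frame(drug_a = drug_a, drug_b = drug_b,
                    tanimoto = NA_real_, sequence = NA_real_,
                    coexpression = NA_real_, go_bp = NA_real_,
                    go_mf = NA_real_, go_cc = NA_real_, atc = NA_real_,
                    jaccard = NA_real_, overlap_coef = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(fingerprints) && !is.null(fingerprints[[drug_a]]) &&
      !is.null(fingerprints[[drug_b]])) {
    out$tanimoto <- tanimoto(fingerprints[[drug_a]], fingerprints[[drug_b]])
  }
  if (!is.null(sequences)) {
    out$sequence <- as.numeric(sequence_similarity(A, B, sequences))
  }
  if (!is.null(expr)) {
    out$coexpression <- as.numeric(
      coexpression_similarity(A, B, expr, network = network))
  }
  if (!is.null(annotations) && !is.null(dag)) {
    branches <- if ("branch" %in% names(annotations))
      intersect(c("BP", "MF", "CC"), unique(annotations$branch)) else "BP"
    for (br in branches) {
      v <- as.numeric(go_similarity(A, B, annotations, dag,
                                    branch = if ("branch" %in% names(annotations)) br else NULL))
      out[[paste0("go_", tolower(br))]] <- v
    }
  }
  if (!is.null(atc) && !is.null(atc[[drug_a]]) && !is.null(atc[[drug_b]])) {
    out$atc <- atc_similarity(atc[[drug_a]], atc[[drug_b]])
  }
  if (!is.null(N) || !is.null(network)) {
    if (is.null(N)) N <- length(interactome_nodes(network))
    ov <- overlap_stats(A, B, N)
    out$jaccard <- ov$jaccard
    out$overlap_coef <- ov$overlap_coef
  }
  out
}
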