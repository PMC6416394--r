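#' Load and filter a drug-target map
#'
#' Builds the drug -> target-set map from a long-format table of physical
#' drug-target interactions. A row is retained when its binding affinity
#' (Ki, Kd, IC50 or EC50, in micromolar) is at or below `affinity_threshold_uM`;
#' rows with no numeric affinity (curated pharmacological targets) are kept
#' unless `require_affinity = TRUE`. Drugs are kept only if at least
#' `min_targets` distinct targets survive, mirroring the inclusion rule used to
#' assemble drug-target networks for proximity analysis.
#'
#' @param table a data.frame with columns `drug`, `target` and optionally
#'   `affinity_type`, `affinity_value_uM`; or a path to a delimited file with
#'   those columns.
#' @param affinity_threshold_uM maximum affinity in micromolar (default 10).
#' @param min_targets minimum number of distinct surviving targets per drug
#'   (default 2).
#' @param require_affinity drop rows lacking a numeric affinity value.
#' @param sep separator when `table` is a path.
#' @param quiet suppress the filter summary message.
#' @return An object of class `drug_target_map`: list with `targets` (named
#'   list of character target sets), `provenance` (the retained rows) and
#'   `log` (per-step filter counts).
#' @export
load_drug_targets <- function(table, affinity_threshold_uM = 10,
                              min_targets = 2, require_affinity = FALSE,
                              sep = "\t", quiet = FALSE) {
  if (is.character(table) && length(table) == 1) {
    if (!file.exists(table)) stop("cannot read drug-target table: ", table)
    table <- utils::read.table(table, sep = sep, header = TRUE,
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "#")
  }
  stopifnot(is.data.frame(table))
  if (!all(c("drug", "target") %in% names(table))) {
    stop("drug-target table needs columns 'drug' and 'target'")
  }
  tab <- table
  tab$drug <- trimws(as.character(tab$drug))
  tab$target <- trimws(as.character(tab$target))
  n_input <- nrow(tab)
  has_affinity <- "affinity_value_uM" %in% names(tab)
  if (has_affinity) {
    aff <- suppressWarnings(as.numeric(tab$affinity_value_uM))
    keep <- ifelse(is.na(aff), !require_affinity, aff <= affinity_threshold_uM)
  } else {
    keep <- rep(!require_affinity, nrow(tab))
  }
  tab <- tab[keep, , drop = FALSE]
  n_affinity <- nrow(tab)
  # a (drug, target) pair survives if any of its records passes the threshold
  tab <- tab[!duplicated(tab[c("drug", "target")]), , drop = FALSE]
  sets <- split(tab$target, tab$drug)
  sets <- lapply(sets, unique)
  sets <- sets[vapply(sets, length, integer(1)) >= min_targets]
  tab <- tab[tab$drug %in% names(sets), , drop = FALSE]
  log <- list(n_input_rows = n_input,
              n_after_affinity = n_affinity,
              n_drugs = length(sets),
              n_dropped_min_targets = length(unique(table$drug)) - length(sets))
  if (!quiet) {
    message("drug-target map: ", length(sets), " drugs with >= ", min_targets,
            " targets (", n_input - n_affinity,
            " rows failed the affinity filter)")
  }
  if (!length(sets)) warning("no drugs survive the filters; empty map")
  structure(list(targets = sets, provenance = tab, log = log),
            class = "drug_target_map")
}

#' @export
print.drug_target_map <- function(x, ...) {
  nt <- vapply(x$targets, length, integer(1))
  cat("Drug-target map:", length(x$targets), "drugs,",
      length(unique(unlist(x$targets))), "unique targets",
      if (length(nt)) sprintf("(median %d targets/drug)", as.integer(stats::median(nt))),
      "\n")
  invisible(x)
}

#' @rdname load_drug_targets
#' @param m a `drug_target_map`.
#' @param path output file path.
#' @export
write_drug_targets <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "drug_target_map"))
  df <- data.frame(
    drug = rep(names(m$targets), lengths(m$targets)),
    target = unlist(m$targets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Canonical unordered pair id
#'
#' Unordered drug pairs are keyed as `"smaller|larger"` (lexicographic order);
#' this id is the join key between separation tables, benchmarks and scores.
#'
#' @param a,b character vectors of drug ids (recycled).
#' @return Character vector of canonical pair ids.
#' @export
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

canonical_pairs <- function(a, b) {
  data.frame(drug_a = pmin(a, b), drug_b = pmax(a, b),
             stringsAsFactors = FALSE)
}

#' All unordered drug pairs
#'
#' The complete pair universe over the drugs of a map: n(n-1)/2 unordered
#' pairs, canonicalized as (smaller id, larger id), no self-pairs.
#'
#' @param m a `drug_target_map`, or a character vector of drug ids.
#' @return A data.frame with columns `drug_a`, `drug_b`.
#' @export
drug_pair_universe <- function(m) {
  drugs <- if (inherits(m, "drug_target_map")) names(m$targets) else as.character(m)
  drugs <- sort(unique(drugs))
  n <- length(drugs)
  if (n < 2) return(data.frame(drug_a = character(0), drug_b = character(0)))
  idx <- utils::combn(n, 2)
  data.frame(drug_a = drugs[idx[1, ]], drug_b = drugs[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Restrict a drug-target map to in-network targets
#'
#' Removes targets absent from the interactome; drugs left with no in-network
#' target are excluded and listed, since no network distance can be computed
#' for them.
#'
#' @param m a `drug_target_map`.
#' @param g an `interactome`.
#' @param quiet suppress the removal summary.
#' @return A `drug_target_map` whose `log$excluded_drugs` lists drugs dropped
#'   for having zero in-network targets.
#' @export
map_targets_to_network <- function(m, g, quiet = FALSE) {
  stopifnot(inherits(m, "drug_target_map"), inherits(g, "interactome"))
  nodes <- interactome_nodes(g)
  before <- sum(lengths(m$targets))
  sets <- lapply(m$targets, function(t) intersect(t, nodes))
  excluded <- names(sets)[lengths(sets) == 0]
  sets <- sets[lengths(sets) > 0]
  out <- m
  out$targets <- sets
  out$log$n_targets_removed <- before - sum(lengths(sets))
  out$log$excluded_drugs <- excluded
  if (!quiet && (length(excluded) || out$log$n_targets_removed > 0)) {
    message("network mapping: removed ", out$log$n_targets_removed,
            " off-network targets; excluded ", length(excluded),
            " drugs with no in-network target")
  }
  out
}

#' Read disease gene sets
#'
#' `read_gmt()` reads GMT-style files (one set per line: name, description,
#' members); `read_gene_list()` reads one gene per line. Members are trimmed
#' and deduplicated.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character vectors; `read_gene_list()`:
#'   a character vector.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read gene sets: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sets <- lapply(lines, function(l) {
    f <- trimws(strsplit(l, "\t", fixed = TRUE)[[1]])
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) {
    trimws(strsplit(l, "\t", fixed = TRUE)[[1]][1])
  }, character(1))
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  sets
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("cannot read gene list: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Read a labeled drug-pair list
#'
#' Reads a delimited table with two drug-id columns; pairs are canonicalized
#' and deduplicated. Pairs referencing drugs outside `restrict_to` are dropped
#' with a logged count (benchmarks may cite drugs absent from the target map).
#'
#' @param path file path (or data.frame with two id columns).
#' @param restrict_to optional character vector of admissible drug ids.
#' @param sep separator; `header` whether a header row is present.
#' @param header logical.
#' @return data.frame `drug_a`, `drug_b` (canonical order) with attribute
#'   `n_dropped` counting pairs removed by the restriction.
#' @export
read_pair_list <- function(path, restrict_to = NULL, sep = "\t", header = TRUE) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("cannot read pair list: ", path)
    utils::read.table(path, sep = sep, header = header, quote = "",
                      stringsAsFactors = FALSE, comment.char = "#")
  }
  if (ncol(tab) < 2) stop("pair list needs two drug-id columns")
  pr <- canonical_pairs(trimws(as.character(tab[[1]])),
                        trimws(as.character(tab[[2]])))
  pr <- pr[pr$drug_a != pr$drug_b, , drop = FALSE]
  pr <- pr[!duplicated(pair_id(pr$drug_a, pr$drug_b)), , drop = FALSE]
  n0 <- nrow(pr)
  if (!is.null(restrict_to)) {
    keep <- pr$drug_a %in% restrict_to & pr$drug_b %in% restrict_to
    pr <- pr[keep, , drop = FALSE]
  }
  rownames(pr) <- NULL
  attr(pr, "n_dropped") <- n0 - nrow(pr)
  pr
}
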