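#' Specification of a planted-module synthetic fixture
#'
#' Describes a stochastic-block-model interactome with dense protein modules on
#' a sparse background, a disease module spanning a chosen subset of the
#' blocks, and a drug placement plan. The defaults emulate the qualitative
#' structure the method relies on - localized disease neighbourhoods on a
#' large, degree-comparable background, drugs whose few targets sit inside or
#' outside those neighbourhoods - at a desk scale: four 20-node modules over a
#' 220-node background. The two disease modules are adjacent neighbourhoods of
#' one disease module (linked at `p_inter_disease`), while non-disease modules
#' reach the rest of the graph only through the background. The background
#' density is chosen so background degrees match module degrees: degree-matched
#' random sets then scatter over the whole graph rather than being confined to
#' the planted modules, which is what makes the proximity z-score informative.
#'
#' @param module_sizes integer vector of module (block) sizes.
#' @param n_background number of background nodes.
#' @param disease_modules indices of the modules whose nodes form the disease
#'   gene set.
#' @param p_intra within-module edge probability.
#' @param p_inter edge probability between module pairs that are not both
#'   disease modules.
#' @param p_inter_disease edge probability between two disease modules (the
#'   neighbourhoods of one disease module are adjacent).
#' @param p_module_bg module-background edge probability.
#' @param p_bg background-background edge probability.
#' @param drug_plan data.frame with columns `drug`, `module` (module index or
#'   0 for background), `n_targets`, `overlap_with` (drug id or `NA`),
#'   `overlap_frac`.
#' @param seed integer master seed; the fixture is a pure function of the spec.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(module_sizes = c(20, 20, 20, 20),
                         n_background = 220,
                         disease_modules = c(1, 2),
                         p_intra = 0.4, p_inter = 0.002,
                         p_inter_disease = 0.06,
                         p_module_bg = 0.005, p_bg = 0.033,
                         drug_plan = default_drug_plan(),
                         seed = 1L) {
  probs <- c(p_intra, p_inter, p_inter_disease, p_module_bg, p_bg)
  if (any(probs < 0 | probs > 1)) stop("edge probabilities must be in [0, 1]")
  stopifnot(all(disease_modules %in% seq_along(module_sizes)),
            all(c("drug", "module", "n_targets") %in% names(drug_plan)))
  if (!"overlap_with" %in% names(drug_plan)) drug_plan$overlap_with <- NA_character_
  if (!"overlap_frac" %in% names(drug_plan)) drug_plan$overlap_frac <- 0
  structure(list(module_sizes = module_sizes, n_background = n_background,
                 disease_modules = disease_modules,
                 p_intra = p_intra, p_inter = p_inter,
                 p_inter_disease = p_inter_disease,
                 p_module_bg = p_module_bg, p_bg = p_bg,
                 drug_plan = drug_plan, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
default_drug_plan <- function() {
  data.frame(
    drug = c("DA", "DB", "DD", "DC", "DE", "DH"),
    module = c(1, 2, 1, 3, 3, 4),
    n_targets = 6,
    overlap_with = c(NA, NA, "DA", NA, "DC", NA),
    overlap_frac = c(0, 0, 2 / 3, 0, 2 / 3, 0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Fixture spec:", length(x$module_sizes), "modules (",
      paste(x$module_sizes, collapse = ", "), ") +", x$n_background,
      "background nodes;", nrow(x$drug_plan), "planted drugs; seed", x$seed, "\n")
  invisible(x)
}

# deterministic sub-seeds per fixture component so adding components never
# shifts existing draws
sub_seed <- function(seed, component) {
  offsets <- c(graph = 11L, drugs = 23L, fingerprints = 37L, sequences = 41L,
               expression = 53L, go = 67L, atc = 79L)
  seed * 101L + offsets[[component]]
}

#' Generate a planted-module fixture
#'
#' Draws the stochastic-block-model interactome, restricts to the largest
#' connected component (regenerating with an incremented sub-seed, up to 50
#' attempts, if the component covers less than 90% of nodes or loses a module
#' node needed by the plan), plants the disease gene set and the drug target
#' sets, and records the intended ground truth: each drug's expected proximity
#' z sign and each plannable pair's expected separation sign and exposure
#' class. Pairs whose sign is not determined by the plan (same module, no
#' planted overlap) carry `NA` truth.
#'
#' @param spec a [fixture_spec()].
#' @return Object of class `planted_fixture`: list with `interactome`,
#'   `disease_genes`, `drug_targets` (a `drug_target_map`), `truth_drugs`,
#'   `truth_pairs`, `spec`, `n_regenerated`.
#' @export
generate_planted_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  k <- length(spec$module_sizes)
  sizes <- c(spec$module_sizes, spec$n_background)
  pref <- matrix(spec$p_inter, k + 1, k + 1)
  dm <- spec$disease_modules
  pref[dm, dm] <- spec$p_inter_disease
  diag(pref) <- c(rep(spec$p_intra, k), spec$p_bg)
  pref[k + 1, seq_len(k)] <- spec$p_module_bg
  pref[seq_len(k), k + 1] <- spec$p_module_bg
  block <- rep(c(seq_len(k), 0L), sizes)
  names_all <- unlist(lapply(seq_len(k + 1), function(b) {
    lab <- if (b <= k) paste0("M", b) else "BG"
    sprintf("%s_%02d", lab, seq_len(sizes[b]))
  }))

  attempt <- 0
  repeat {
    set.seed(sub_seed(spec$seed, "graph") + attempt)
    g_raw <- igraph::sample_sbm(sum(sizes), pref.matrix = pref,
                                block.sizes = sizes)
    igraph::V(g_raw)$name <- names_all
    comp <- igraph::components(g_raw)
    keep <- comp$membership == which.max(comp$csize)
    big_enough <- sum(keep) >= 0.9 * sum(sizes)
    # every module must keep enough nodes to host its planted targets
    per_module_ok <- all(vapply(seq_len(k), function(b) {
      need <- spec$drug_plan$n_targets[spec$drug_plan$module == b]
      sum(keep & block == b) >= max(0, need, 2)
    }, logical(1)))
    if (big_enough && per_module_ok) break
    attempt <- attempt + 1
    if (attempt > 50) stop("could not generate a sufficiently connected fixture")
  }
  lcc_nodes <- names_all[keep]
  block_of <- stats::setNames(block, names_all)[lcc_nodes]
  ia <- as_interactome(igraph::as_edgelist(
    igraph::induced_subgraph(g_raw, lcc_nodes)))

  disease <- lcc_nodes[block_of %in% spec$disease_modules]

  set.seed(sub_seed(spec$seed, "drugs") + attempt)
  plan <- spec$drug_plan
  targets <- list()
  for (i in seq_len(nrow(plan))) {
    pool <- lcc_nodes[block_of == plan$module[i]]
    shared <- character(0)
    if (!is.na(plan$overlap_with[i])) {
      partner <- targets[[plan$overlap_with[i]]]
      if (is.null(partner)) stop("overlap_with refers to a later drug: ",
                                 plan$overlap_with[i])
      shared <- sample(partner, round(plan$overlap_frac[i] * plan$n_targets[i]))
    }
    fresh <- sample(setdiff(pool, shared), plan$n_targets[i] - length(shared))
    targets[[plan$drug[i]]] <- c(shared, fresh)
  }
  dtm <- structure(list(targets = targets,
                        provenance = data.frame(
                          drug = rep(names(targets), lengths(targets)),
                          target = unlist(targets, use.names = FALSE),
                          stringsAsFactors = FALSE),
                        log = list(planted = TRUE)),
                   class = "drug_target_map")

  in_disease <- plan$module %in% spec$disease_modules
  truth_drugs <- data.frame(drug = plan$drug, module = plan$module,
                            expected_z_sign = ifelse(in_disease, "neg", "pos"),
                            stringsAsFactors = FALSE)
  pairs <- drug_pair_universe(plan$drug)
  mod_of <- stats::setNames(plan$module, plan$drug)
  ov_of <- stats::setNames(plan$overlap_with, plan$drug)
  truth_pairs <- pairs
  truth_pairs$expected_s_sign <- mapply(function(a, b) {
    if (mod_of[a] != mod_of[b]) return("pos")
    planted_overlap <- identical(ov_of[[a]], b) || identical(ov_of[[b]], a)
    if (planted_overlap) "neg" else NA_character_
  }, pairs$drug_a, pairs$drug_b)
  zsgn <- stats::setNames(truth_drugs$expected_z_sign, truth_drugs$drug)
  truth_pairs$expected_class <- mapply(function(a, b, s) {
    if (is.na(s)) return(NA_character_)
    n_in <- sum(c(zsgn[a], zsgn[b]) == "neg")
    if (n_in == 2) { if (s == "neg") "P1" else "P2" }
    else if (n_in == 1) { if (s == "neg") "P3" else "P4" }
    else { if (s == "neg") "P5" else "P6" }
  }, pairs$drug_a, pairs$drug_b, truth_pairs$expected_s_sign)

  structure(list(interactome = ia, disease_genes = disease,
                 drug_targets = dtm, truth_drugs = truth_drugs,
                 truth_pairs = truth_pairs, spec = spec,
                 block_of = block_of, n_regenerated = attempt),
            class = "planted_fixture")
}

#' @export
print.planted_fixture <- function(x, ...) {
  cat("Planted fixture:", igraph::vcount(x$interactome$graph), "nodes,",
      igraph::ecount(x$interactome$graph), "edges;",
      length(x$disease_genes), "disease genes;",
      length(x$drug_targets$targets), "drugs\n")
  invisible(x)
}

random_aa <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_seq <- function(s, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(aa, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate matched similarity inputs for a fixture
#'
#' Produces fingerprints, target protein sequences, a gene-by-tissue expression
#' matrix, a toy GO DAG with annotations, and ATC codes for the fixture's
#' drugs, with a tunable planted effect: at `effect = 1` drug pairs whose
#' target modules overlap receive strongly correlated profiles (shared
#' fingerprint bits, homologous sequences, co-expressed targets, shared GO
#' terms and ATC prefixes); at `effect = 0` all profiles are independent of
#' the network structure.
#'
#' @param fixture a `planted_fixture`.
#' @param effect effect size in [0, 1].
#' @param n_tissues number of expression columns (default 32).
#' @param fp_len fingerprint length in bits (default 166, the keyed structural
#'   fingerprint length).
#' @param seq_len target sequence length (default 60 residues).
#' @return List with `fingerprints` (named bit vectors), `sequences` (named
#'   character), `expr` (matrix), `annotations` and `dag` (data.frames),
#'   `atc` (named list of code vectors).
#' @export
generate_similarity_inputs <- function(fixture, effect = 1, n_tissues = 32,
                                       fp_len = 166, seq_len = 60) {
  stopifnot(inherits(fixture, "planted_fixture"), effect >= 0, effect <= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  spec <- fixture$spec
  plan <- spec$drug_plan
  drugs <- plan$drug
  targets <- fixture$drug_targets$targets

  # fingerprints: partners of planted-overlap pairs copy bits, mutated at a
  # rate that interpolates from independent (0.5) to near-identical (0.1)
  set.seed(sub_seed(spec$seed, "fingerprints"))
  flip_rate <- 0.5 - 0.4 * effect
  fps <- list()
  for (i in seq_len(nrow(plan))) {
    if (!is.na(plan$overlap_with[i]) && effect > 0) {
      base <- fps[[plan$overlap_with[i]]]
      flip <- stats::runif(fp_len) < flip_rate
      fps[[plan$drug[i]]] <- as.integer(xor(base, flip))
    } else {
      fps[[plan$drug[i]]] <- as.integer(stats::runif(fp_len) < 0.3)
    }
  }

  # sequences: one per target id; non-shared targets of overlapping drugs are
  # mutated copies of the partner's sequences
  set.seed(sub_seed(spec$seed, "sequences"))
  all_targets <- unique(unlist(targets))
  seqs <- stats::setNames(random_aa(length(all_targets), seq_len), all_targets)
  if (effect > 0) {
    mut_rate <- 0.6 - 0.55 * effect
    for (i in seq_len(nrow(plan))) {
      if (is.na(plan$overlap_with[i])) next
      partner_t <- targets[[plan$overlap_with[i]]]
      own_new <- setdiff(targets[[plan$drug[i]]], partner_t)
      for (j in seq_along(own_new)) {
        template <- seqs[[partner_t[1 + (j - 1) %% length(partner_t)]]]
        seqs[[own_new[j]]] <- mutate_seq(template, mut_rate)
      }
    }
  }

  # expression: per-module latent factor with loading = effect
  set.seed(sub_seed(spec$seed, "expression"))
  genes <- names(fixture$block_of)
  factors <- matrix(stats::rnorm((length(spec$module_sizes) + 1) * n_tissues),
                    ncol = n_tissues)
  expr <- t(vapply(genes, function(gn) {
    b <- fixture$block_of[[gn]] + 1L # background block 0 -> row 1
    effect * factors[b, ] + stats::rnorm(n_tissues)
  }, numeric(n_tissues)))
  rownames(expr) <- genes

  # toy GO DAG: a root, one family of three terms per module plus a background
  # family; genes annotate to their module's terms with probability `effect`,
  # otherwise to random terms
  set.seed(sub_seed(spec$seed, "go"))
  kmod <- length(spec$module_sizes)
  fam <- function(b) paste0("GO:F", b, c("a", "b", "c"))
  dag <- do.call(rbind, lapply(0:kmod, function(b) {
    t <- fam(b)
    data.frame(child = c(t[2], t[3], t[1]),
               parent = c(t[1], t[1], "GO:ROOT"),
               relation = c("is_a", "is_a", "is_a"),
               stringsAsFactors = FALSE)
  }))
  annotations <- do.call(rbind, lapply(genes, function(gn) {
    b <- fixture$block_of[[gn]]
    use_module <- stats::runif(1) < effect
    terms <- if (use_module) sample(fam(b), 2) else
      sample(setdiff(unique(dag$child), "GO:ROOT"), 2)
    data.frame(gene = gn, term = terms, branch = "BP",
               stringsAsFactors = FALSE)
  }))

  # ATC codes: same-module drugs share a level-4 prefix when effect is planted
  set.seed(sub_seed(spec$seed, "atc"))
  letters1 <- c("C", "N", "A", "J", "L", "B", "D", "G")
  atc <- list()
  for (i in seq_len(nrow(plan))) {
    if (!is.na(plan$overlap_with[i]) && effect > 0 &&
        stats::runif(1) < effect) {
      base <- atc[[plan$overlap_with[i]]][1]
      atc[[plan$drug[i]]] <- paste0(substr(base, 1, 5),
                                    sprintf("%02d", sample(2:99, 1)))
    } else {
      atc[[plan$drug[i]]] <- sprintf("%s%02d%s%s%02d",
                                     letters1[1 + (plan$module[i] %% length(letters1))],
                                     sample(1:16, 1),
                                     sample(LETTERS, 1), sample(LETTERS, 1),
                                     sample(1:99, 1))
    }
  }

  list(fingerprints = fps, sequences = seqs, expr = expr,
       annotations = annotations, dag = dag, atc = atc)
}

#' Write a fixture bundle to disk
#'
#' Serializes a planted fixture (and optionally its similarity inputs) in the
#' exact plain-text formats the package readers consume: tab-delimited edge
#' list, drug-target table, GMT disease set, fingerprint table, FASTA
#' sequences, expression TSV, GO term tables, ATC table, and the ground-truth
#' tables. A `manifest.json` lists every file with its md5 checksum.
#'
#' @param fixture a `planted_fixture`.
#' @param dir output directory (created if missing).
#' @param similarity optional result of [generate_similarity_inputs()].
#' @return Invisibly, the manifest as a data.frame.
#' @export
write_fixture <- function(fixture, dir, similarity = NULL) {
  stopifnot(inherits(fixture, "planted_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  el <- igraph::as_edgelist(fixture$interactome$graph)
  utils::write.table(data.frame(a = el[, 1], b = el[, 2]), p("edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_drug_targets(fixture$drug_targets, p("drug_targets.tsv"))
  writeLines(paste(c("disease", "planted disease module",
                     fixture$disease_genes), collapse = "\t"),
             p("disease.gmt"))
  utils::write.table(fixture$truth_drugs, p("truth_drugs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth_pairs, p("truth_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(similarity)) {
    utils::write.table(
      data.frame(drug = names(similarity$fingerprints),
                 bits = vapply(similarity$fingerprints, paste,
                               character(1), collapse = "")),
      p("fingerprints.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(similarity$sequences), p("sequences.fasta"))
    utils::write.table(similarity$expr, p("expression.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(similarity$annotations, p("go_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(similarity$dag, p("go_dag.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(drug = rep(names(similarity$atc), lengths(similarity$atc)),
                 code = unlist(similarity$atc, use.names = FALSE)),
      p("atc_codes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- list.files(dir, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, p("manifest.json"), pretty = TRUE)
  invisible(manifest)
}
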