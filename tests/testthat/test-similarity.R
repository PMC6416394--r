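test_that("tanimoto matches the bit formula and its set-arithmetic oracle", {
  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  # a = 3, b = 4, c = 2 -> 2/5
  expect_equal(tanimoto(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 1, 1, 0)), 0.4)
  expect_equal(tanimoto(rep(0, 8), rep(0, 8)), 0) # all-zero convention
  expect_equal(tanimoto("1100", "1010"), 1 / 3)   # string form
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
  set.seed(41)
  for (i in 1:50) {
    fa <- as.integer(runif(166) < 0.3)
    fb <- as.integer(runif(166) < 0.3)
    sa <- which(fa == 1); sb <- which(fb == 1)
    want <- if (!length(union(sa, sb))) 0 else
      length(intersect(sa, sb)) /
        (length(sa) + length(sb) - length(intersect(sa, sb)))
    expect_equal(tanimoto(fa, fb), want)
  }
})

test_that("sequence similarity scores cross pairs and excludes self-pairs", {
  seqs <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            p2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            p3 = "WWGGHHPPLLMMCCAAEEDDKKRRNNQQSSTT")
  # identical sequences under distinct ids -> identity 1
  expect_equal(as.numeric(sequence_similarity("p1", "p2", seqs)), 1)
  # self-pair exclusion: A = {p1, p2}, B = {p1, p3} scores exactly
  # (p1,p3), (p2,p1), (p2,p3)
  v <- sequence_similarity(c("p1", "p2"), c("p1", "p3"), seqs)
  expect_equal(attr(v, "n_pairs"), 3L)
  # both drugs share the single same target -> no admissible pair
  expect_true(is.na(sequence_similarity("p1", "p1", seqs)))
})

test_that("unrelated random sequences score low local identity", {
  set.seed(43)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vals <- replicate(10, {
    s <- vapply(1:2, function(i) paste(sample(aa, 50, TRUE), collapse = ""),
                character(1))
    as.numeric(sequence_similarity("a", "b", c(a = s[1], b = s[2])))
  })
  expect_lt(mean(vals), 0.3)
})

test_that("co-expression similarity follows the absolute-correlation rules", {
  set.seed(47)
  base <- rnorm(32)
  expr <- rbind(g1 = base, g2 = base, g3 = -base, g4 = rnorm(32),
                g5 = rep(1, 32))
  # exact copy under a different id -> |PCC| = 1
  expect_equal(as.numeric(coexpression_similarity("g1", "g2", expr)), 1)
  # anti-correlated pair -> 1 by the absolute-value rule
  expect_equal(as.numeric(coexpression_similarity("g1", "g3", expr)), 1)
  # constant vector is skipped with a count
  v <- coexpression_similarity(c("g1", "g5"), "g4", expr)
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(attr(v, "n_pairs"), 1L)
})

test_that("mean |PCC| of independent expression matches its null expectation", {
  # Monte-Carlo oracle: for white noise at n = 32 tissues, E|PCC| ~ 0.14
  set.seed(53)
  vals <- replicate(1000, {
    abs(cor(rnorm(32), rnorm(32)))
  })
  expect_equal(mean(vals), 0.14, tolerance = 0.02 / 0.14)
  # and the drug-level function reproduces it on independent genes
  expr <- matrix(rnorm(60 * 32), 60,
                 dimnames = list(sprintf("g%02d", 1:60), NULL))
  v <- coexpression_similarity(sprintf("g%02d", 1:30),
                               sprintf("g%02d", 31:60), expr)
  expect_equal(as.numeric(v), 0.14, tolerance = 0.25)
})

test_that("network restriction keeps only interactome-edge gene pairs", {
  expr <- matrix(rnorm(4 * 32), 4, dimnames = list(c("a", "b", "c", "d"), NULL))
  net <- as_interactome(rbind(c("a", "c")))
  v <- coexpression_similarity(c("a", "b"), c("c", "d"), expr, network = net)
  expect_equal(attr(v, "n_pairs"), 1L) # only (a, c) is an edge
})

# toy DAG: root R, A is_a R, B is_a R, C is_a A, D is_a A (all weight 0.8)
toy_dag <- data.frame(child = c("A", "B", "C", "D"),
                      parent = c("R", "R", "A", "A"),
                      relation = "is_a", stringsAsFactors = FALSE)

test_that("Wang term similarity equals the hand-worked semantic table", {
  # S-values for C: C=1, A=0.8, R=0.64; SV = 2.44 (same for D)
  # sim(C,D) = (2*0.8 + 2*0.64) / (2.44 + 2.44)
  expect_equal(netcombo:::wang_term_sim("C", "D", toy_dag),
               2.88 / 4.88, tolerance = 1e-12)
  # sim(C,B): SV(B) = 1.8, shared {R}: (0.64 + 0.8) / (2.44 + 1.8)
  expect_equal(netcombo:::wang_term_sim("C", "B", toy_dag),
               1.44 / 4.24, tolerance = 1e-12)
  # sim(C,A): shared {A, R}: (0.8 + 1 + 0.64 + 0.8) / (2.44 + 1.8)
  expect_equal(netcombo:::wang_term_sim("C", "A", toy_dag),
               3.24 / 4.24, tolerance = 1e-12)
  expect_equal(netcombo:::wang_term_sim("C", "C", toy_dag), 1)
})

test_that("GO similarity handles identical, disjoint and unannotated genes", {
  dag2 <- rbind(toy_dag,
                data.frame(child = c("X", "Y"), parent = c("Q", "Q"),
                           relation = "is_a"))
  ann <- data.frame(gene = c("g1", "g1", "g2", "g2", "g3"),
                    term = c("C", "D", "C", "D", "X"),
                    branch = "BP", stringsAsFactors = FALSE)
  expect_equal(as.numeric(go_similarity("g1", "g2", ann, dag2)), 1)
  # disjoint DAG components -> 0
  expect_equal(as.numeric(go_similarity("g1", "g3", ann, dag2)), 0)
  v <- go_similarity(c("g1", "gX"), "g2", ann, dag2)
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("ATC similarity follows level arithmetic and multi-code averaging", {
  expect_equal(atc_similarity("C03AA01", "C03AA01"), 1)
  # share only the level-1 letter -> 1/5
  expect_equal(atc_similarity("C03AA01", "C09XX99"), 0.2)
  expect_error(atc_similarity("C03AA01", "BAD"), "malformed")
  # multi-code drug equals the exhaustive code-pair loop
  nicotine <- c("N07BA01", "A11HA01", "C04AC01", "C10AD02")
  other <- "C03AA01"
  brute <- mean(vapply(nicotine, function(cd) {
    mean(vapply(1:5, function(k) {
      pre <- function(x) substr(x, 1, c(1, 3, 4, 5, 7)[k])
      as.numeric(pre(cd) == pre(other))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(atc_similarity(nicotine, other), brute)
  expect_equal(atc_similarity(nicotine, other), atc_similarity(other, nicotine))
})

test_that("overlap statistics match their closed forms", {
  # |A| = 5, |B| = 4, shared 2, N = 100
  A <- sprintf("t%d", 1:5); B <- c("t1", "t2", "x1", "x2")
  ov <- overlap_stats(A, B, 100)
  expect_equal(ov$c_obs, 2)
  expect_equal(ov$c_rand, 0.2)
  expect_equal(ov$fold_change, 10)
  expect_equal(ov$jaccard, 2 / 7)
  expect_equal(ov$overlap_coef, 2 / 4)
  # complete subset -> C = 1
  expect_equal(overlap_stats(c("a", "b"), c("a", "b", "c"), 50)$overlap_coef, 1)
  expect_error(overlap_stats(A, B, 5), "smaller")
})

test_that("hypergeometric tails equal the combinatorial enumeration oracle", {
  # N = 20, |A| = 5, |B| = 7: P(X = k) = C(5,k) C(15,7-k) / C(20,7)
  N <- 20; nA <- 5; nB <- 7
  pk <- vapply(0:5, function(k) {
    choose(nA, k) * choose(N - nA, nB - k) / choose(N, nB)
  }, numeric(1))
  A <- sprintf("s%d", 1:nA)
  for (c_obs in 0:5) {
    B <- c(A[seq_len(c_obs)], sprintf("u%d", seq_len(nB - c_obs)))
    ov <- overlap_stats(A, B, N)
    expect_equal(ov$p_enrich, sum(pk[(c_obs:5) + 1]), tolerance = 1e-12)
    expect_equal(ov$p_deplete, sum(pk[(0:c_obs) + 1]), tolerance = 1e-12)
  }
})

test_that("jaccard never exceeds the overlap coefficient on random sets", {
  set.seed(59)
  pool <- sprintf("t%02d", 1:40)
  for (i in 1:100) {
    A <- sample(pool, sample(1:10, 1)); B <- sample(pool, sample(1:10, 1))
    ov <- overlap_stats(A, B, 100)
    expect_lte(ov$jaccard, ov$overlap_coef)
    expect_gte(ov$jaccard, 0)
    expect_lte(ov$overlap_coef, 1)
    expect_equal(ov$jaccard, overlap_stats(B, A, 100)$jaccard)
  }
})

test_that("similarity profile computes what it is given and marks the rest", {
  fps <- list(d1 = c(1, 0, 1), d2 = c(1, 1, 1))
  targets <- list(d1 = c("p1", "p2"), d2 = c("p2", "p3"))
  prof <- similarity_profile("d1", "d2", targets, fingerprints = fps)
  expect_equal(prof$tanimoto, 2 / 3)
  expect_true(is.na(prof$sequence))
  expect_true(is.na(prof$atc))
  prof2 <- similarity_profile("d1", "d2", targets, fingerprints = fps,
                              atc = list(d1 = "C03AA01", d2 = "C03AB02"),
                              N = 100)
  expect_false(is.na(prof2$atc))
  expect_equal(prof2$jaccard, 1 / 3)
})
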