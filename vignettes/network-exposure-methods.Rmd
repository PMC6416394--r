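---
title: "Methods: network-based exposure screening of drug combinations"
author: "netcombo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based exposure screening of drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcombo)
```

## The model

`netcombo` treats the interactome as an unweighted, undirected simple graph
of physical protein–protein interactions. Three network quantities are
computed on it.

**Separation of two target modules.** For drugs with target sets $A$ and $B$,

$$s_{AB} = \langle d_{AB} \rangle - \frac{\langle d_{AA} \rangle + \langle d_{BB} \rangle}{2},$$

where $\langle d_{AB}\rangle$ is the symmetric mean nearest-neighbour
shortest-path distance (each $a \in A$ to its nearest $b \in B$ and vice
versa, averaged over $|A| + |B|$ terms; a target shared by both drugs
contributes $0$), and $\langle d_{AA}\rangle$ averages, over each
$a \in A$, the distance to the nearest *other* member of $A$. A singleton set
has no other member and its within-distance is defined as $0$; this makes
$s_{AB} = d(a, b)$ for two distinct singleton drugs, the measure's natural
degenerate case. Negative $s_{AB}$ means the two target modules occupy the
same network neighbourhood.

**Proximity of a drug to a disease.** The closest distance from target set
$X$ to disease protein set $Y$ is

$$d(X, Y) = \frac{1}{\lVert Y\rVert} \sum_{y \in Y} \min_{x \in X} d(x, y),$$

deliberately asymmetric (averaged over disease proteins only), while the
drug–drug *closest* measure is two-sided; the two definitions are kept
exactly as published and not harmonized. The observed $d$ is standardized
against a reference distribution obtained by resampling both $X$ and $Y$ as
random node sets of matching size and degree profile:
$z = (d - \mu)/\sigma$. A flag (`randomize = "drug"`) restricts
randomization to the target set. Degree matching uses exact-degree bins
merged upward from the sparse high-degree tail until each bin holds at least
`min_bin_size` nodes; one node is drawn per template node, without
replacement within a bin (falling back to with-replacement only when a bin
is exhausted, which is logged).

**Exposure classes.** Each (drug A, drug B, disease) triple is classified by
the sign pattern of $(s_{AB}, z_A, z_B)$:

| class | $s_{AB}$ | $z_A, z_B$ | name |
|---|---|---|---|
| P1 | $<0$ | both $<0$ | Overlapping Exposure |
| P2 | $\ge 0$ | both $<0$ | Complementary Exposure |
| P3 | $<0$ | exactly one $<0$ | Indirect Exposure |
| P4 | $\ge 0$ | exactly one $<0$ | Single Exposure |
| P5 | $<0$ | both $\ge 0$ | Non-exposure |
| P6 | $\ge 0$ | both $\ge 0$ | Independent Action |

Boundary zeros belong to the separated branches, matching the published
inequalities ($s_{AB} \ge 0$, $z \ge 0$). Complementary-Exposure pairs are
ranked by increasing $s_{AB}$ (ties broken by canonical pair id, so rankings
are stable) as the predicted efficacious combinations; Overlapping-Exposure
pairs are flagged, likewise sorted, as candidate adverse interactions. The
ranking uses $s_{AB}$ alone; no combined score with $z$ is applied by
default because the two scales are not commensurate.

## Parameters that matter

* `affinity_threshold_uM = 10` (µM): a drug–target interaction is physical
  evidence only if its Ki, Kd, IC50 or EC50 is at or below this; rows with no
  numeric affinity (curated pharmacological targets) are kept unless
  `require_affinity = TRUE`, since curated and affinity-based sources are
  pooled without precedence. A (drug, target) pair survives if *any* record
  passes.
* `min_targets = 2`: drugs need at least two surviving targets, applied after
  the affinity filter and before network mapping.
* `n_random = 1000`: randomizations behind each z-score. Tests and the
  acceptance script use 100–200, which is enough to fix the sign on the
  fixture scale; corpus-scale runs should keep the default.
* `min_bin_size = 100`: the degree-binning convention for interactome-scale
  networks. On the few-hundred-node fixtures the package uses 50 so that more
  than one bin exists; below ~25 the bins stop constraining degree at all.
* `seed`: every stochastic routine takes one; per-drug z-seeds are derived as
  `seed + rank of the drug id in sorted order`, so results are independent of
  the order in which pairs are submitted and each drug's z is computed once
  and shared across its pairs.

## Numerical and degenerate-input choices

* Distances are unweighted hop counts; duplicate targets collapse to sets.
* Unreachable contributions are *omitted* from every average and counted in
  an `n_skipped` attribute; a quantity with no reachable contribution is `NA`
  and propagates to classification as "unclassifiable", reported rather than
  silently classified. No arbitrary finite cap is substituted for missing
  paths. Computation is on the full graph by default; `restrict_lcc = TRUE`
  confines it to the largest connected component (ties between equal
  components break by the lexicographically smallest member).
* $\sigma = 0$ in the randomization yields an `NA` z with a diagnostic note,
  never $\pm\infty$.
* The kernel distance uses the exponential penalty $e^{-(d+1)}$ with
  unreachable terms contributing $e^{-\infty} = 0$; for singleton sets at
  distance $d$ it reduces to $d + 1$. The centre distance resolves
  non-unique topological centres by averaging the pairwise distances over
  all minimizers.
* Sequence similarity is the number of identical aligned positions in the
  optimal Smith–Waterman local alignment (BLOSUM62, gap open 10, extend 0.5,
  all configurable) divided by the length of the longer sequence. Identity
  over the local region alone was rejected: a spurious 8-residue perfect
  match between unrelated proteins would score near 1, and unrelated
  length-50 sequences should score low. Shared targets are never aligned
  against themselves ($a \ne b$); a pair of drugs sharing a single identical
  target has no admissible pair and returns `NA`.
* Co-expression similarity is the mean $|PCC|$ across tissues over cross
  pairs; when an interactome is supplied the average is restricted to gene
  pairs that are network edges (the published noise-reduction mapping, read
  as an edge filter). Constant expression vectors are skipped and counted.
* GO similarity is Wang's semantic-contribution measure (decay 0.8 for
  `is_a`, 0.6 for `part_of`) with best-match averaging over term sets;
  evidence-code filtering is left to the data preparer.
* ATC similarity averages the five-level prefix agreement over all code
  pairs of multi-code drugs, following the per-code-then-average rule.
* Tanimoto of two all-zero fingerprints is 0 ("no evidence of similarity"
  rather than 0/0).
* Balanced AUC uses midrank tie handling; each repeat samples as many
  unknown pairs as positives, without replacement. Permutation p-values use
  the add-one estimator $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$, so
  $p$ is never 0 and is floored at $1/(n_{perm}+1)$. The classified records
  table passed to the permutation test *is* the null universe, leaving the
  all-pairs vs disease-drugs choice to the caller; the bootstrap control of
  adverse interactions samples without replacement within draws by default.

## What the synthetic fixtures emulate

`generate_planted_fixture()` draws a stochastic block model: four dense
20-node modules on a 220-node background, with the two disease modules
adjacent (`p_inter_disease = 0.06`) and the non-disease modules reaching the
rest of the graph only through the background. Two properties were deliberate:

* The background density (`p_bg = 0.033`) is set so background degrees match
  module degrees. Degree-matched random sets then scatter over the whole
  graph; if the background were much sparser, the degree bins would confine
  every random draw to the planted modules and the reference distribution
  would reproduce the observed distance, making z-signs unrecoverable by
  construction rather than by any fault of the estimator.
* The disease gene set spans two adjacent neighbourhoods, so two drugs can
  both sit inside the disease module (negative z) while their target modules
  remain separated (positive $s_{AB}$) — the Complementary-Exposure geometry.

Drugs are planted six targets each: inside the two disease neighbourhoods,
inside a non-disease module, and in pairs with a planted two-thirds target
overlap. The generator records each drug's intended z-sign and each pair's
intended separation sign and class; same-module pairs without planted overlap
get `NA` truth because their sign is genuinely ambiguous. Sub-seeds for the
graph, drug placement and each similarity input are derived deterministically
from the master seed, so adding components never shifts existing draws and
the whole bundle is byte-stable (the CLI `simulate` manifest checksums are
reproducible).

What the fixtures do **not** emulate: scale-free degree heterogeneity, the
size of the real interactome (~16,677 proteins), incomplete and biased
curation of targets and disease genes, or literature-driven correlation
between target overlap and trial data. Passing the recovery tests therefore
shows the estimators read planted topology correctly at realistic
module/background densities — not that the method's corpus-scale accuracy
(e.g. the hypertension benchmark AUC) is reproduced; that requires the
original supplementary tables, which cannot be shipped here.

`generate_similarity_inputs()` plants a tunable effect: at `effect = 1`
overlapping drug pairs receive correlated fingerprints, homologous
sequences, co-expressed targets (shared latent tissue factor), shared GO
annotations and ATC prefixes; at `effect = 0` all profiles are independent
of the network. This supports the direction tests — topologically
overlapping pairs score higher on every profile than separated pairs — as a
qualitative, not quantitative, reproduction of the published correlation.

## Problem sizes used by the tests and acceptance script

Oracle-equivalence tests enumerate 1,000 random graphs of 4–12 nodes against
brute-force Floyd–Warshall implementations (tolerance $10^{-12}$); parameter
recovery runs 20 independently seeded fixtures at `n_random = 100`;
calibration uses 10 null datasets of 2,000 pairs for the AUC and 200 null
runs at 400 permutations for the type-I rate. These sizes keep the full
suite under a minute while leaving each check's statistical resolution well
inside the asserted bands.

## Known limitations

* Distances are topological only: no edge confidence weights, no
  directionality, no diffusion-based proximity.
* The z-score's Gaussian-reference assumption degrades for very small target
  sets; the screen's pair-level decisions deliberately rest on $s_{AB}$
  (ranking) with z used only for the in/out sign.
* Identifier spaces are the caller's responsibility: matching is
  case-preserving exact string equality after trimming.
* Only pairwise combinations are modelled; higher-order combinations and
  dosage are out of scope.
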