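---
title: "enterocag: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enterocag: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enterocag)
```

This vignette is the package's own account of its methods: what each
stage assumes, which parameters matter and why their defaults are what
they are, what the synthetic-cohort generator does and does not emulate,
and where genuinely open design questions were settled by a package
convention. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The analysis model

The unit of analysis is a genus-level abundance table: samples × genera,
either read counts or relative abundances (rows summing to 1). All
inference is rank-based or count-based; no parametric abundance model is
fitted.

### Enterotype classification

A sample's enterotype depends only on two coordinates of its
composition, the relative abundances of *Bacteroides* (`RA_B`) and
*Prevotella* (`RA_P`):

* **I** — `RA_B >= 0.40` and `RA_B > RA_P`;
* **II** — `RA_P >= 0.30` and `RA_P >= RA_B`;
* **III** — otherwise (an *Escherichia*-mixed residual class).

The two positive rules are mutually exclusive by construction (I needs
`RA_B > RA_P`, II needs `RA_P >= RA_B`), so the three branches are
exhaustive and deterministic. Two conventions are worth making explicit:

* The boundary inequalities are taken literally: `RA_B = 0.40` with
  `RA_B > RA_P` is enterotype I; `RA_P = 0.30` with a tie
  `RA_P = RA_B` is enterotype II. Published descriptions of such rules
  sometimes paraphrase "≥ 30 %" as "over 30 %"; the inequality form is
  the one implemented.
* Classification never depends on ordination or clustering. The PCoA
  (`pcoa_ordination()`, Bray–Curtis by default, Jensen–Shannon as an
  alternative; square-rooted JSD so the quantity is a metric) is
  descriptive. "Weighted" ordination here means an abundance-weighted
  dissimilarity rather than a presence/absence one; no phylogenetic
  weighting is attempted because the pipeline starts at a genus table.

### Alpha diversity

Richness is the count of detected genera (value > 0); when a count table
is available, detection is any mapped read. Shannon diversity is
computed in nats (`H = -sum(p log p)`); the log base is irrelevant to
every comparison the package makes (rank tests are invariant to the
base), and a binary-logarithm display transform for richness
(`log2_transform()`) is provided because that is the conventional
figure scale. Zeros under the log2 transform follow the standard
compositional pseudocount: half the smallest positive value of the
vector; a `drop` policy is available.

### Rank-based differential abundance

`mann_whitney_two_sided()` implements the two-sided Mann–Whitney test
with a documented exact/approximate switch:

* **exact** when `min(n1, n2) <= 8` and the pooled data are untied: the
  full null distribution of U is built by the standard counting
  recursion (equivalent to enumerating all `choose(n1+n2, n1)` rank
  assignments), and the two-sided p is `2 * min(P(U <= u), P(U >= u))`
  capped at 1;
* **normal approximation** otherwise, with the tie-corrected variance
  and a 0.5 continuity correction.

The switch point is a compromise: exactness where it is cheap and most
consequential (small strata), the standard approximation elsewhere. If
every pooled value is identical the test is vacuous and returns p = 1
with a message rather than an error, because prevalence-filtered genus
tables can legitimately produce constant slices in small strata.

Genus-level testing applies a **prevalence filter first**: only genera
detected in strictly more than 50 % of the cancer group's samples are
tested. The filter is applied to both the per-genus tests and CAG
construction (a flag disables it), the threshold is configurable, and
the strict inequality means exactly-half prevalence is excluded.
Significance is a raw two-sided p < 0.01 with **no multiple-testing
correction by default**, reproducing the convention of the analysis this
package implements; a Benjamini–Hochberg mode (`bh = TRUE`) is provided
but off by default. Direction is read from group medians.

The stage-transition analysis tests only consecutive pairs of an
ordered pathology sequence (default advanced adenoma → carcinoma in
situ → early carcinoma), with the prevalence filter referenced to the
pooled cancer stages.

### Co-abundance groups

CAGs are clusters of a genus–genus correlation matrix (Spearman by
default — rank correlation is depth-robust; Pearson is exposed because
correlation-network figures in this literature often use it), built by
agglomerative clustering on the distance `d = 1 - r` with average
linkage. Neither the distance nor the linkage is canonical in the
heat-map-driven CAG literature; both are arguments, and every output
records what was used. The cluster count is either fixed (`k`) or chosen
by a mean-silhouette scan over K = 2..12. Degenerate matrices (all
off-diagonal correlations equal) make the silhouette uninformative; the
implementation returns K = 2 with a warning rather than failing.

Two conventions here are package decisions worth knowing:

* **Enterotype drivers are excluded from clustering by default.** In a
  composition, the dominant genus is most of the denominator, so its
  relative abundance anti-correlates with every other genus purely
  through closure (distances near 2 on the `1 - r` scale). Left in, the
  silhouette scan reliably collapses to a two-cluster
  driver-versus-everything split and the co-abundance structure is never
  examined. `exclude_genera = character(0)` restores the full panel —
  appropriate when the cohort is not strongly driver-dominated, and
  necessary if one wants an *Escherichia*-containing anchor cluster.
* **CAG abundance is the plain sum** of member relative abundances, so
  mass is conserved exactly and CAG profiles of a full partition sum to
  the clustered fraction of each sample.

For choosing which disease groups' samples should build the CAGs,
`select_training_combination()` scores each candidate combination by
leave-one-out nearest-centroid accuracy at separating a target pair
(default adenoma vs cancer) in CAG-abundance space. The scorer was
chosen for determinism and zero tuning; ties are broken toward fewer
source groups, then lexicographically. Because the score saturates on
well-separated data, tied combinations are common, and the tie-break —
not the score — then decides; the ranking table always reports both.

### Anchor network

Per-group Pearson networks keep edges with `|r|` at or above 0.5 — a
conventional "high correlation" bar, configurable and recorded in the
output. The stable anchor is the largest cluster whose member set is
*identical* in every supplied partition (strictest reading of a cluster
"staying the same" across groups); a relaxed Jaccard ≥ 0.8 mode exists
but is off by default. A genus's anchor profile is its mean Pearson
correlation with anchor members per group; the variability score is the
range across groups, flagged at ≥ 0.4. Both 0.5 and 0.4 quantify terms
("high", "substantially different") that the underlying analysis style
leaves unquantified; they are package conventions.

### Cohort covariate statistics

`chi_square_test()` is the plain Pearson statistic without continuity
correction, `df = (r-1)(c-1)`. Two conventions reproduce the published
p-values of the packaged cohort table: adenoma and cancer sub-columns
are first summed to the three-group layout, and the literal `"Unknown"`
level is **included** as a category (excluding it does not reproduce the
printed values); `include_unknown = FALSE` is available for sensitivity
analysis. The packaged fixture (`table1_metadata()`) is a
subject-per-row reconstruction from published per-stage marginal counts;
within a stage, the joint distribution across covariates is arbitrary
(only marginals were published), which leaves every single-covariate
table exact. Its age and BMI columns are synthetic values matching the
published per-stage means and SDs and are not used by any test. Two
published per-stage gender splits contradict the stage totals by one
subject; the fixture moves one female subject from late to early stage,
preserving the three-group margins the tests use.

## The synthetic cohort: a stated world

`generate_cohort()` draws, per sample *i* with enterotype *e*, group *g*
and stage *s*:

```
log w_ig = mu[e, g'] + lambda_b * F_ib          (if genus g' in block b)
         + ln(2) * (group_effect[g', g] + stage_effect[g', s])
         + Normal(0, noise_sd)
counts_i ~ Multinomial(depth, softmax(log w_i))
```

with one standard-normal factor `F_ib` per block per sample. The
log-normal latent-factor form (rather than a Dirichlet) is deliberate:
planted blocks must survive closure and rank correlation so that the CAG
stage has recoverable ground truth.

Defaults and their reasons:

* **Panel**: 60 genera — the three drivers plus seven blocks
  (10/5/6/9/9/9/9) covering all 57 non-drivers: a 10-genus anchor, a
  pathogen-like block (+1.5 log2 in cancer), a butyrate-producer-like
  block (−1.5 log2 in cancer), four neutral blocks. Oscillospira
  additionally loses 2 log2 from carcinoma in situ onward and
  Haemophilus from early carcinoma onward, exercising the transition
  analysis. Block loading λ = 0.8, residual sd 1.0, depth 50,000 reads.
* **Every non-driver genus belongs to a block.** Unstructured filler
  genera acquire a mutual baseline correlation through closure (the
  dominant driver's noise is a shared denominator term, worth r ≈ 0.2–
  0.3 in pooled samples), drift into block clusters under average
  linkage, and turn exact cluster recovery into a coin flip. The
  generator exists to provide ground truth, so the default world does
  not contain them; custom configs can add them.
* **Driver log-means are margin-anchored, not fraction-anchored.** The
  dominant driver of each regime is placed at its classification
  threshold plus two residual standard deviations (computed
  analytically from the expected mass of the rest of the panel), so a
  generated sample clears its threshold with ~98 % probability. The
  cost is realism: the resulting mean dominant fractions (~0.75–0.78)
  are higher than typical cohort means (~0.5). Anchoring the *fraction*
  at 0.5 instead would misclassify ~1/3 of samples at noise sd 1.0 and
  make intended-enterotype ground truth meaningless. Escherichia, whose
  regime has no threshold, is placed at a median fraction of ~25 %.
* **n_per_cell = 45** (135 samples per group, 405 total): the smallest
  round cell count at which the planted block structure is reliably
  recovered from *per-group* correlation matrices. Recovery, not cohort
  mimicry, is the generator's job; tests that need a specific smaller
  size (e.g. 60 per group for power measurements) pass it explicitly.
* `block_groups` optionally restricts a block's factor loading to named
  disease groups, for experiments where co-abundance structure exists
  only in some groups.

What the generator does **not** emulate — and hence what a green test
does not establish: real per-genus dispersion (one shared noise sd);
taxonomic assignment error; variable sequencing depth and its
zero-inflation (depth is fixed, so low-abundance prevalence patterns are
mild); phylogenetic relatedness; and any real-data cohort's effect
sizes. Green synthetic tests establish that the *machinery* — rule
application, test calibration, cluster recovery, anchor detection — is
correct on a world with known truth, not that the biological findings of
any particular cohort would replicate.

## Numerical conventions and degenerate inputs

* Relative rows must sum to 1 within 1e-9; kind inference on file read
  accepts row sums within 0.01 of 1 (exported tables are often rounded)
  and refuses ambiguous tables rather than guessing.
* All-zero samples are rejected at normalisation with the sample named;
  all-zero vectors are rejected by the diversity metrics.
* OTU→genus merging routes unmapped OTUs to an explicit
  `"unclassified"` genus — totals are conserved exactly, nothing is
  silently dropped; the bucket is excluded from differential/CAG stages
  by the prevalence filter mechanics unless it genuinely passes.
* Constant genera: correlation matrices refuse them by name (callers
  prefilter); networks exclude them with a warning; anchor profiles
  report the affected group as undefined and exclude it from the
  variability range.
* `cutree` cluster ids are relabelled to first-appearance order, making
  partitions deterministic under genus reordering up to relabelling.
* Negative PCoA eigenvalues (non-Euclidean dissimilarities) are clipped
  to zero for variance fractions and reported in full in `eig`.
* All pipeline randomness flows from the single `seed`; identical
  config + seed reproduces every output byte-for-byte.

## Known limitations

* The threshold rule is this package's single enterotyping method;
  Dirichlet-multinomial or PAM-based enterotype discovery is out of
  scope by design.
* Compositional differential-abundance methods (ANCOM, ALDEx2) are
  deliberately absent: the implemented analysis style is the raw rank
  test with a prevalence filter, and mixing paradigms would blur what a
  result means.
* Cluster-count selection by silhouette is a reconstruction of a
  heat-map-reading practice; with weak or nested block structure the
  selected K is unstable at small n, which is precisely why the
  synthetic defaults are sized for reliable recovery.
* The combination-selection score saturates easily; its ranking is most
  informative when training sets differ in whether they contain the
  structure at all, and the documented tie-break decides otherwise.
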