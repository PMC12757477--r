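---
title: "Differential phosphorylation and multi-omics concordance: methods and design"
author: "phosphoDiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential phosphorylation and multi-omics concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoDiff)
```

# The analysis problem

phosphoDiff implements the statistical pipeline for a study design in which
the same biological material — here, *Drosophila* ovarian follicle cells from
fly lines expressing wild-type (WT) or hyperactive mutant AKT1, plus a
landing-pad (LP) control line carrying no transgene — is profiled three ways:

* a label-free MS **total-proteome** table (4 WT replicates, 3 per other
  condition),
* **phosphopeptide** abundances quantified in the same MS runs (no
  enrichment step), each peptide tied to a parent protein and a ptmRS
  localization score,
* an **RNA-Seq transcriptome** table (3 replicates per condition), usually
  entering as a differential-expression result table from a dedicated tool.

The questions the pipeline answers, stage by stage: which proteins and genes
are differentially expressed; which phosphopeptides change their
phosphorylation *independently of their parent protein's abundance*
(DPhospho peptides); how well protein and mRNA fold changes agree; whether
the genes shared by every mutant-versus-WT comparison behave as a
gain-of-function (GoF) or loss-of-function (LoF) transcriptional program;
which transcription-factor (TF) target sets are overrepresented and how the
TF-target incidence matrix clusters; and which nodes dominate the
protein-protein interaction (PPI) neighbourhood of the significant players.

# Differential expression

DEPs and DEGs are defined by two published filters applied in sequence:
Benjamini-Hochberg adjusted p below `alphaAdj` (0.05) and |log2FC| at or
above `log2fcMin` (0.585, i.e. fold change 1.5). `applyThresholds()` keeps
both counts because both are scientifically meaningful (features significant
by p but below the fold-change bound are reported, not dropped).

Real studies produce the DE table upstream (e.g. DESeq2 for RNA-Seq;
Progenesis ANOVA for proteins); those tables are accepted directly via
`readContrastResult()`. For synthetic end-to-end runs the package provides
`standinTest()`: log2 fold changes of group means (with a pseudocount of
half the smallest positive value) and a per-feature test on log2
abundances. The default test is limma's empirical-Bayes moderated t, because
at 3-4 replicates a per-feature variance estimate is so unstable that a
per-gene t-test loses roughly a third of truly changed features at the
BH-effective cutoff — and dedicated DE tools all share variance information
across features for exactly this reason. The classical Welch t is available
as `method = "welch"`. Both are calibrated under the null (type-I error
close to nominal; checked by the test suite).

# Differential phosphorylation

Both strategies formalize the same idea: a phosphopeptide is differentially
phosphorylated when its abundance change is *not explained* by its parent
protein's expression change. Peptides first pass the strict ptmRS
localization filter (score > 50). `normalizePhospho()` provides the
per-sample ratio peptide/parent (used for inspection and export); the
calling strategies work on fold changes, where the protein correction enters
as a subtraction on the log scale.

## Strategy 1 — normalized-difference outliers

Per mutant condition and per peptide, let A be the parent protein's log2FC
(mutant vs WT) and B the phosphopeptide's log2FC. An OLS trend line of B on
A is fitted and its intercept subtracted from B, so the refitted line passes
through the origin (peptides that follow their protein then sit on the
diagonal B = A). The normalized difference

$$D = \frac{\max(A,B) - \min(A,B)}{A + B}$$

is computed per peptide, and peptides whose Iglewicz-Hoaglin modified
Z-score of D reaches `zDphospho` (default 1, exactly the published setting)
in magnitude are flagged. Two numerical choices matter:

* D is undefined near A + B = 0; peptides with |A + B| below `delta`
  (default 1e-6) are excluded and reported, never clamped — clamping would
  manufacture outliers.
* The modified Z is $0.6745\,(x_i - \tilde x)/\mathrm{MAD}$; when the MAD is
  zero the recommended fallback $\,(x_i-\tilde x)/(1.253314\cdot
  \mathrm{meanAD})$ is used, and an all-equal vector scores all zeros.
  The outlier rule is two-sided (|z|), since the test is defined on the
  magnitude of the score and both phosphorylation gains and losses are real
  calls.

B is computed from the *raw* (run-normalized) phosphopeptide abundances, not
from the peptide/protein ratio: the trend-line step and the diagonal null
population only exist on that scale (a protein-normalized B would sit at ~0
for every null peptide regardless of A, making D degenerate). A robust
Theil-Sen line is available via `robust_fit = TRUE`; log2FCs use replicate
means by default with medians available in `contrastLog2fc()`.

A threshold of |z| >= 1 is deliberately permissive — for roughly Gaussian
null D it flags on the order of 10-30% of null peptides in each condition
(the modified Z is affine-invariant, so no noise scale avoids this). This is
why the pipeline's final call set intersects the two strategies; see
"Calibration caveats" below.

## Strategy 2 — all-pairs ratio test

Per peptide and mutant condition, every ratio of a mutant replicate over a
WT replicate is formed (n_mut x n_WT ratios, e.g. 3 x 4 = 12), both for the
phosphopeptide and for its parent protein. After adding a pseudocount of 1
to each ratio ("+1 to each value", applied at the ratio level) and taking
log2, the means of the two sets give log2FC_phospho and log2FC_tot; the
reported effect is their difference — the protein-level normalization at
the fold-change scale, so a peptide that merely follows its parent has
effect near 0. A classical equal-variance Student t between the two
transformed sets gives the raw p (Welch available by flag), with degenerate
zero-variance inputs resolved exactly (equal means give p = 1, different
means p = 0). Bonferroni correction is applied over the widest family — all
peptide-by-condition tests in the run — as the conservative default when no
family is stated.

## Consensus

`dphosphoConsensus()` combines the per-condition calls: a peptide detected
by **both** strategies and in at least **two** mutant conditions (union of
the two strategies' per-condition detections) is tier "high"; any other
flagged peptide is a "candidate". On the synthetic benchmark the consensus
tier is what controls the false-discovery proportion (~0.06 observed) while
retaining full sensitivity.

## Calibration caveats

Two properties of the published procedure deserve explicit statement; both
are quantified by the test suite and the acceptance script rather than
hidden:

* **The all-pairs t-test is anticonservative by construction.** The 12
  ratios per side are built from only 3 + 4 measurements; the t-test's
  standard error underestimates the true sampling error of the mean
  log-ratio difference by a factor of about $\sqrt{3.5}$, independently of
  the noise scale. Consequently the family-wise error of
  Bonferroni-corrected strategy 2 under a null simulation is far above the
  nominal 0.05 (measured ~0.9 across 200 null datasets). No noise model
  changes this; it is intrinsic to treating pseudo-replicated ratios as
  independent observations.
* **|z| >= 1 is permissive**, as noted above, so the union of the two
  strategies has a high false-discovery proportion (~0.5 observed at the
  default conditions) while the intersection is well behaved. Treat
  strategy-level calls as screens and the consensus tiers as results.

# Proteome-transcriptome concordance

`matchFeatures()` joins DEPs to transcripts strictly through an explicit
two-column protein-to-gene mapping (ambiguous mappings are an error, never
silently resolved; unmapped and unmeasured proteins are counted).
`removeOutliersAndCorrelate()` computes modified Z-scores separately on the
protein-FC and RNA-FC vectors, flags a pair when either score reaches
`zConcordance` (3.5) in magnitude — the literal reading of removing outliers
"in the RNA-Seq or protein data" — and reports the Pearson correlation of
the survivors, in a single pass. A pair with either fold change exactly zero
is not "same direction" (zero has no sign).

# Metagene GoF/LoF classification

For the DEGs shared by every mutant-versus-WT comparison
(`intersectDegs()`), the per-gene mutant log2FCs are averaged (unweighted
arithmetic mean) and compared with the LP-versus-WT log2FC:

* **LoF**: down in mutants vs WT *and* down in LP vs WT — the gene is
  activated by WT AKT1 and the activation disappears in the mutants;
* **GoF**: up in mutants vs WT while LP sits at the WT level;
* everything else is unclassified.

"At the WT level" needs a band, which the source analysis does not state.
The default band is the pipeline's own not-differentially-expressed bound
(|log2FC| < `log2fcMin` = 0.585): a gene is "not affected" exactly when it
would not be called DE. A narrower band (e.g. 0.2) sits inside the sampling
noise of a single 3-vs-3 fold change at 20% CV (sd ~0.24) and would
misclassify ~40% of genuine GoF genes on noise alone. The band is an
explicit argument. For the down- and up-regulated subsets separately,
two-sided one-sample t-tests compare the per-gene mutant means and the
per-gene LP fold changes against 0; zero-variance input yields p = 1, and
subsets smaller than 3 are reported as not computable rather than crashing.

# ORA, TF matrix and clustering

`ora()` is the standard hypergeometric upper tail
$P[X \ge k],\,X \sim \mathrm{Hypergeometric}(N, K, n)$ over a configurable
universe, BH-adjusted across tested sets; sets with zero overlap are not
reported. `selectBubbleTerms()` applies the published bubble-plot rules:
sort by adjusted p; deduplicate same-named terms across source databases
keeping the smallest adjusted p; collapse terms whose overlap members have
Jaccard similarity at or above 0.75 (the stated intent "related terms
involving similar gene subsets", quantified here) keeping the most general
(largest-K) term; and apply an explicit, user-supplied exclusion list for
tissue-irrelevant terms — relevance is never inferred automatically.

`buildTfMatrix()` encodes regulation binarily (gene i targeted by TF j), with
TFs restricted to an expressed-feature filter (present in the MS or RNA
tables) and genes restricted to DEGs with at least one retained regulator.
`twoWayCluster()` performs two-way average-linkage hierarchical clustering
with 1 - Pearson correlation as the distance on rows and on columns, cutting
the gene tree into k (default 2) clusters. Rows and columns are pre-sorted
lexicographically so that merge ties break deterministically; constant
rows/columns, where Pearson is undefined, are assigned maximal distance and
reported.

# PPI network

`buildNetwork()` induces the subgraph of a PPI edge list on the union of the
supplied role sets (DEP, DPhospho parent, kinase, TF, ...), canonicalizing
undirected edges, collapsing duplicates, dropping self-loops, and keeping
isolated nodes at degree 0. Edge confidence scores can gate inclusion
(`min_score`) but are never weighted into degree, because the reported
statistic is plain node degree. `rankHubs()` orders by degree with
lexicographic tie-breaks.

# The synthetic-data generator

`simulateDataset()` emulates the study's structure so every stage is
testable without downloads: seven conditions (LP, WT, T1, T5, T12, T15,
Q79K-W80R), 3 replicates each with a 4th WT replicate in the MS tables,
log-normal baselines (log2 mean 20, sd 2) and multiplicative log-normal
replicate noise at 20% CV. Planted signals, all recorded in a
`GroundTruth` ledger:

* 10% of proteins and transcripts differentially expressed in all mutants;
  20% of planted DEPs have their mapped transcript planted in the same
  direction with the same magnitude (mRNA-protein concordance);
* 25% of phosphopeptides shifted in mutants while their parent protein is
  not (the independence both strategies exploit); all other peptides equal
  parent abundance times a site-stoichiometry factor, up to noise, so
  protein normalization is exactly the right inverse;
* 40 LoF genes (up in WT only) and 40 GoF genes (up in mutants only);
* a TF-target graph whose two planted modules target the down- and
  up-regulated gene groups (edge probability 0.9 inside a module, sparse
  background elsewhere), and a PPI graph with one designated hub of maximal
  degree.

Choices that depart from the obvious caricature, and why:

* **Effect magnitudes are drawn as effect_log2 x Unif(0.6, 1.4)** per
  feature (shared across mutant conditions and between a DEP and its
  concordant transcript) rather than planted at exactly ±effect_log2. Real
  fold-change distributions are continuous; a point mass makes the robust
  outlier statistics degenerate (with any up/down imbalance the MAD of the
  FC vector collapses and the modified Z deletes the entire minority
  direction).
* **Non-planted phosphopeptides take their parents preferentially from the
  planted DEPs.** Detected phosphopeptides in such experiments come largely
  from abundant, differentially expressed proteins, and the
  expression/phosphorylation scatter needs spread in A for the
  normalized-difference statistic to be defined; with every null peptide at
  the origin, D = |A-B|/(A+B) is 0/0.
* **ptmRS scores are drawn Uniform(55, 95)**, so the default dataset passes
  the >50 filter intact and planted counts are preserved; the strict
  threshold behaviour of the filter is exercised by unit tests with crafted
  records.
* Missingness is optional, completely at random (default 0); intensity-
  dependent missingness is deliberately out of scope to keep planted truth
  recoverable and tests sharp.

Everything is keyed to a single integer seed with a fixed draw order, so an
identical configuration is bit-identical, including written files.

What passing on this generator does *not* show: the noise is exactly
log-normal with equal variance everywhere (no heavy tails, no
intensity-dependent variance, no missing-not-at-random), fold-change
distributions for null transcripts are tighter than real RNA-Seq biological
spread (one consequence: at the default 20% concordance the RNA-axis
modified-Z step flags the concordant minority itself, so the default-config
concordance r is near 0 — the fully-concordant configuration is the
recovery benchmark), identifier mapping is one-to-one by construction, and
peptide identification error does not exist. Results on real data depend on
upstream quantification quality in ways the generator cannot probe.

# Problem sizes and runtime

The test suite runs most recovery experiments on the full default
configuration (2000 proteins, 5000 transcripts, 60 phosphopeptides, 20
seeds) and uses a reduced configuration (300 proteins, 800 transcripts, 40
peptides) for the quicker per-module checks; the null-calibration
experiment uses 200 simulated datasets. These sizes give binomial
uncertainties comfortably inside the asserted margins while keeping the
whole suite around a minute on one CPU.

# Known limitations

* The two calling strategies inherit the published procedure's calibration
  problems (see "Calibration caveats"); the package reports them instead of
  silently "fixing" the method, and the consensus tier is the recommended
  result set.
* The concordance outlier step assumes the two FC axes have comparable,
  unimodal spread; strongly clustered or near-constant FC vectors can lose a
  whole direction (this is a property of median/MAD statistics, not of the
  implementation).
* `standinTest()` is a stand-in: it exists so synthetic runs need no
  external DE tool. For real data, use the dedicated tool's result table.
* No graph layout, community detection, kinase-substrate prediction or
  live database queries: exports of those tools are file inputs.
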