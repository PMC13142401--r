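---
title: "Gene cluster family dereplication, novelty scoring and depth-conditioned community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene cluster family dereplication, novelty scoring and depth-conditioned community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoGCF)
```

## The analysis problem

Metagenomic surveys of geothermal environments predict thousands of
biosynthetic gene clusters (BGCs) — genomic loci encoding secondary
metabolite pathways — across samples spanning wide gradients of
temperature, pH, conductivity and tectonic context. Three questions
structure the analysis this package implements:

1. **Dereplication.** Fragmented and redundant BGC predictions from many
   assemblies must be collapsed into gene cluster families (GCFs) so that
   presence–absence profiles are comparable across samples.
2. **Novelty.** How much of the predicted biosynthetic repertoire
   resembles experimentally characterized reference clusters
   (MIBiG-style accessions), and how does novelty vary with geodynamic
   context such as crustal thickness?
3. **Composition.** Do environmental and tectonic covariates structure
   GCF composition once the purely technical gradient of sequencing
   depth is removed, and how much of that structure is attributable to
   taxonomic community composition rather than environment?

The inputs are the standard artifacts of a BiG-SCAPE-style workflow: a
pairwise BGC distance network per biosynthetic class (tab-separated,
two node columns and a raw distance in [0, 1]; only pairs within the
clustering cutoff appear in the file), a per-sample BGC inventory, a
sample metadata table, and a CAT-style contig classification table for
taxonomy.

## Dereplication and novelty model

Within each biosynthetic class (NRPS, PKS, RiPP, terpene, hybrid,
other) a similarity network retains edges with **distance ≤ 0.5** — the
cutoff is inclusive — and GCFs are the connected components of that
network. Isolated BGCs form singleton families. Family labels are the
lexicographically smallest member id (C collation), which makes labels
reproducible without a global counter. A family is *putatively known*
when it contains at least one reference accession (id matching
`^BGC\d{7}` by default, configurable) and *putatively novel* otherwise.
Novelty analyses always run on the complete BGC set; the sparsity
filter below applies only to the composition analyses.

Per-BGC novelty is the minimum distance over **direct retained edges**
to any reference node. A BGC with no such edge receives the sentinel
**0.51**, one step above the cutoff. Graph-path distances are
deliberately not used: a pair absent from a BiG-SCAPE network file has
unknown distance above the cutoff, and the sentinel expresses exactly
that. A consequence worth knowing is that a BGC can belong to a known
family yet carry the sentinel score, when only an intermediate member
links it to the reference. Per-sample minimum novelty for a class is
the smallest score among that sample's BGCs of the class; samples
without BGCs of the class are absent from the result, never
zero-filled. Louvain-style communities (greedy modularity) are computed
for display parity only and never define families.

## Feature construction

A GCF is present in a sample when at least one member BGC was detected
there. The presence–absence matrix keeps all metadata samples as rows
(all-zero rows included). Sparsity filtering removes GCFs detected in
*fewer than* 5% of samples — a strict inequality on the count, so with
100 samples a GCF present in 4 is removed and one present in 5 is
retained. Profiles are Hellinger-transformed
(\(y'_{ij} = \sqrt{y_{ij} / \sum_j y_{ij}}\)) so that Euclidean
distances between rows are ecologically meaningful for sparse
presence data; all-zero rows map to all-zero rows.

Taxonomy features follow the same discipline: genus assignments are
retained when CAT support **strictly exceeds 0.70** (an assignment at
exactly 0.70 is discarded), contig lengths are aggregated by genus and
sample, converted to proportions of classified base pairs, genera
present in fewer than 20% of samples are removed, and the
Hellinger-transformed profile is summarized by PCA. PCA is a centred
(not scaled) eigendecomposition of the covariance matrix — Hellinger
output is already bounded and commensurable, so unit-variance scaling
would only inflate rare genera. Component signs follow the convention
that the largest-magnitude loading is positive. Ten components are
retained by default for variation partitioning.

## Multivariate inference

All multivariate machinery is implemented from first principles with
explicit permutation schemes, and cross-checked in the test suite
against vegan as an independent oracle.

* **Partial RDA.** Response and constraints are residualized on the
  conditioning block (always including an intercept) by least squares;
  the residualized response is regressed on the residualized
  constraints and site scores come from the SVD of the fitted values.
  Because the response is Hellinger-transformed, this is equivalent to
  distance-based RDA (capscale) on Hellinger–Euclidean distances.
  Reported site scores are of the weighted-average type (residualized
  response projected on constrained axes), which deliberately retain
  residual variation — this is what lets a technical gradient such as
  sequencing depth reveal itself on the axes when it is *not*
  conditioned out.
* **PERMANOVA.** McArdle–Anderson partitioning of the Gower-centred
  inner-product matrix. Marginal term sums of squares are each term's
  contribution given all other terms, so duplicated or collinear terms
  carry zero marginal SS rather than an error. With conditioning
  variables, inference permutes reduced-model residual structure
  (Freedman–Lane); otherwise rows are permuted freely.
* **ANOSIM** uses mid-ranked tied distances and the statistic
  \(R = (\bar r_{between} - \bar r_{within}) / (M/2)\), \(M = n(n-1)/2\).
* **Dispersion homogeneity** embeds the distance matrix by principal
  coordinates, corrects negative eigenvalues by subtracting squared
  distances along imaginary axes, measures each sample's distance to
  its group centroid (centroids, not spatial medians — the choice is
  documented here because either is defensible), and permutes those
  distances across groups for the F null.
* **Variation partitioning** decomposes explained variation into unique
  and shared adjusted-\(R^2\) fractions (Ezekiel correction
  \(1-(1-R^2)(n-1)/(n-p-1)\)) of two explanatory blocks after removing
  the conditioning block from response and predictors. The identities
  \([a]+[c] = \mathrm{adj}R^2(X_1)\) and \([b]+[c] = \mathrm{adj}R^2(X_2)\)
  hold to machine precision by construction; unique fractions are
  tested by Freedman–Lane permutation.

Every permutation p-value is \((1 + \#\{F^* \ge F\})/(1 + B)\) with
\(B = 999\) permutations by default, so the smallest attainable p is
\(1/(1+B)\), and every permutation stream is seeded.

### Cluster number selection

k-means runs on the site scores of all constrained axes with positive
eigenvalue, with 20 seeded restarts per k over k in [2, 8]. Two
criteria are always reported: mean silhouette width and an *elbow*
operationalized as the k maximizing the second difference of the
within-cluster sum of squares. A deterministic artifact needs a
mechanical rule where the original analysis applied judgment between
the two criteria; the elbow k is the one acted upon, and both are
logged so the judgment remains auditable. Identical input points are
reported as a degenerate case (WSS zero everywhere, silhouette
undefined) rather than an arbitrary k.

### The sequencing-depth contrast

Detection of gene cluster families improves with sequencing effort, so
an unconditioned ordination of presence profiles carries a technical
depth gradient on its leading axis. The package's canonical check runs
Spearman correlations (tie-corrected, t-approximation) of ordination
axes against log1p depth twice: on the unconditioned PCA of the
Hellinger matrix, and on the site scores of the partial RDA conditioned
on log1p depth. Conditioning should collapse the axis-1 correlation
toward zero; the test suite requires at least a 50% drop under the
default synthetic conditions, where the observed drop is about 90%.

## Univariate statistics

Shannon diversity (natural log) is computed on per-sample GCF class
count vectors. The index could equally be taken over GCF presences or
taxa; the class-count choice is the documented default because the
downstream comparisons are about class repertoires. Group comparisons
use Kruskal–Wallis with tie correction (degenerate all-equal input is
reported as such, not an error), Dunn's post hoc z-tests with either
Holm or Benjamini–Hochberg adjustment, and the two-sided Wilcoxon
rank-sum test — exact by enumeration up to a pooled size of 20 when no
ties are present, otherwise normal approximation with tie and
continuity corrections. BH adjustment of omnibus p-values is applied
over the family of omnibus tests run in one invocation, and the family
size is logged, since nothing larger can be reconstructed from a single
run. Minimum-novelty regressions are ordinary least squares with the
overall F-test p and a 95% confidence band exported for plotting.

## What the synthetic generator emulates

`sim_config()` / `simulate_study()` generate studies with known ground
truth at every stage:

* **Planted families.** Each class holds `n_families_per_class`
  families; within-family edges are drawn uniformly from
  `within_family_distance` (default [0.05, 0.45], below the cutoff)
  along a random spanning tree, so connected components recover the
  planted partition exactly. Cross-family pairs all lie above the
  cutoff and are therefore omitted from the edge lists, exactly as
  BiG-SCAPE network files omit them.
* **Reference contamination.** A fraction `ref_fraction` (default 0.1,
  echoing the high novelty levels reported for geothermal systems) of
  families contains exactly one reference accession; members of such
  families get direct reference edges with probability 0.7.
* **Setting effects.** Detection log-odds are tilted per tectonic
  setting by `effect_size` along three fixed, pairwise-equidistant
  directions in class space (volcanic arcs gain NRPS and lose terpenes,
  backarcs the reverse, mid-ocean ridges gain RiPPs). The tilt is a
  deterministic exponential reweighting of a base simplex vector rather
  than a random Dirichlet draw: this keeps compositions valid, makes
  `effect_size` directly interpretable, and — importantly — makes
  `effect_size = 0` an exact null in which settings differ only by
  sampling noise. The default `effect_size = 2` is deliberately well
  above the family-level noise (`noise_sd = 0.3`) so that parameter
  recovery is a property of the method, not of luck.
* **Depth bias.** Sequencing depths are log-normal
  (`depth_meanlog = 16`, `depth_sdlog = 0.8`, i.e. a few million to a
  few hundred million reads) and detection log-odds increase by
  `depth_bias` (default 1.5) per unit of centred log1p depth. The
  default makes the technical gradient comparable in magnitude to the
  biological signal, reproducing the situation in which the leading
  unconditioned ordination axis is dominated by depth.
* **Novelty geology.** `ct_known_bias` (default 1) raises detection of
  reference-containing families with crustal thickness, planting the
  negative crustal-thickness–novelty association as a recoverable
  effect.
* **Coupled taxonomy.** Genus log-abundances share the setting labels
  with strength `taxonomy_coupling` (default `effect_size`), giving
  variation partitioning a recoverable shared fraction; a CAT-style
  contig table realises the profile with Beta(8, 2) support values so
  roughly a quarter of assignments fall at or below the 0.70 retention
  threshold.

What the generator does **not** emulate: sequence content, assembly
fragmentation, within-family distance structure beyond uniform draws,
geochemistry beyond the named covariates, phylogenetic correlation
among genera, or abundance (the pipeline is presence–absence by
design). Passing tests therefore demonstrate correctness of the
statistical machinery under the planted model, not robustness to every
pathology of real metagenomes.

## Numerical choices and reproducibility

* Constraint columns whose norm collapses under residualization on the
  conditioning block (relative tolerance 1e-8) are dropped as collinear
  with a warning; marginal tests report them with zero df rather than
  failing.
* All textual orderings (family labels, matrix columns, file lists) use
  C-collation radix sorting, so artifacts are byte-identical across
  locales; numeric matrices are serialized with 17 significant digits
  so writer/reader pairs round-trip exactly.
* Every random stream flows from a single seed through explicit child
  seeds; `run_all()` twice with the same config and seed produces
  byte-identical artifacts, and the manifest records the config hash,
  seeds, thresholds and content hash of every artifact.
* Default problem sizes were chosen to keep a laptop-scale run
  comfortable: 60 samples across three settings, 200 planted families,
  999 permutations (about half a minute end to end); the validation
  suite uses 500 null replicates at n = 40 for type-I calibration and
  100 replicate studies for power-style checks.

## Known limitations

* The per-sample novelty statistic is the *minimum* distance to a
  reference; the maximum-novelty reading of the same data is not
  implemented, only noted.
* Distance metrics other than Euclidean-on-Hellinger are accepted by
  the distance-based tests but untested.
* Greedy modularity is a stand-in for Louvain sweeps; since communities
  are reporting-only, exact Louvain parity is out of scope.
* Variation partitioning assumes linear (RDA-style) relationships
  between predictors and the Hellinger profile; strongly unimodal
  responses would call for CCA, which is out of scope.
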