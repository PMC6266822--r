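---
title: "Within-individual time-series co-expression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-individual time-series co-expression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcenet)
```

# The problem

Short human time-series expression studies — a handful of time points per
participant, two intervention arms, strong inter-individual variability —
defeat the standard co-expression recipe of correlating group-average
profiles: averaging across heterogeneous individuals dampens exactly the
expression dynamics one wants to correlate. `dcenet` implements the
alternative: compute gene–gene Pearson correlations *within* each
individual's time series first, then aggregate across the group with a
support rule. An individual with an idiosyncratic trajectory contributes
one (possibly dissenting) correlation rather than distorting a group mean,
which is what makes the approach usable on small dietary-intervention-style
cohorts with repeated biopsies.

The package covers the full workflow: background filtering, paired
differential expression, per-group network construction, a sign-consistent
overlap network between two groups, per-individual variability
diagnostics, community clustering, and gene-set over-representation
analysis, plus a synthetic study generator that plants known co-expression
modules so that every stage can be validated against ground truth.

# Models and procedures

## Background filter

Y-chromosome genes are transcriptionally silent in female samples, so
their measured signal in females is a biological negative control for the
platform noise floor. `y_background_threshold()` pools every
(Y gene, female sample) value and takes the median; `filter_background()`
then removes every gene whose median expression across *all* samples is
equal to or below that threshold (the boundary gene is removed, not kept).
The pooled median is the default because it is a single order statistic of
the full noise sample and is insensitive to how values are grouped by
gene; the median-of-per-gene-medians reading is available as
`method = "per_gene"`. Gene medians are taken over all samples of all
groups jointly, so the two arms are filtered identically.

## Paired differential expression

Contrasts are within-individual: for gene $g$ and individual $i$,
$d_{gi} = x_g(t_B, i) - x_g(t_A, i)$ on the log2 scale. The effect
estimate is $\overline{d_g}$ (the log2 fold change), reported alongside a
signed linear fold change ($2^{\overline{d}}$ up, $-2^{-\overline{d}}$
down) so the gate $|FC| \ge 1.2$ reads symmetrically in both directions.

Two tests are provided. `paired_t` is the one-sample t on the $d_{gi}$.
The default `moderated_paired_t` shrinks each gene's variance toward a
common prior: with $s_g^2$ the sample variance on $df = n - 1$ degrees of
freedom, the posterior variance is
$\tilde{s}_g^2 = (d_0 s_0^2 + df\, s_g^2) / (d_0 + df)$ and the moderated
t is referred to $df + d_0$ degrees of freedom. The prior $(d_0, s_0^2)$
is fitted by method of moments on $\log s_g^2$, matching the mean and
variance of the log-variances through digamma/trigamma identities — the
classical empirical-Bayes treatment for small-$n$ expression studies. With
$d_0 = 0$ the moderated test reduces exactly to the plain paired t (a
contract the test suite asserts to machine precision), and the suite also
cross-checks the full fit against an independent empirical-Bayes
implementation.

Genes with zero-variance differences are flagged (`zero_var`), receive an
undefined p-value under the plain t, and can never be called significant.

Significance uses the raw p-value gate `p < 0.05` together with the
fold-change gate `|FC| >= 1.2`; the fold-change boundary is inclusive and
the p boundary exclusive. Storey q-values are reported alongside for FDR
interpretation: $q_{(i)} = \min_{j \ge i} \hat\pi_0 \, m \, p_{(j)}/j$,
with $\hat\pi_0$ from the smoother method (natural cubic spline through
$\hat\pi_0(\lambda)$ over $\lambda = 0.05, \dots, 0.95$, evaluated at the
largest $\lambda$). With $\hat\pi_0 = 1$ the procedure is exactly
Benjamini–Hochberg, which is how the implementation is validated. For
fewer than 20 p-values the smoother is too unstable to be meaningful and
the estimator conservatively returns $\hat\pi_0 = 1$.

## The network edge rule

For a group with $n$ individuals, `individual_correlations()` computes one
correlation matrix per individual across that individual's $T \ge 3$
time-ordered values. A pair correlation is undefined (NA) whenever either
gene is constant within the individual. `build_network()` then applies the
edge rule: individual $i$ *supports* the pair $(g, h)$ when
$|r_i(g,h)| \ge c$ (default $c = 0.6$); the pair becomes an edge when at
least a fraction $f$ (default $0.25$) of the group's individuals support
it *and* all supporting correlations share one sign.

Decisions worth spelling out:

* **"25% of the samples" means 25% of individuals.** Correlations exist
  per individual (each contributes one series), so the support unit is the
  individual, not the microarray.
* **Weight over supporting individuals.** The edge weight is the mean
  correlation over supporting individuals only, which guarantees
  $|w| \ge c$ and a stable sign; averaging over all individuals with a
  defined correlation is available via `weight_over = "all"`.
* **Sign consistency.** Strong correlations of conflicting sign indicate
  no coherent shared pattern, and the downstream overlap intersection
  needs one well-defined sign per edge, so conflicted pairs are rejected.
  A consequence: the edge set is *not* monotone in the cutoff — raising
  $c$ can drop a dissenting qualifier and thereby legitimise a pair. The
  edge set is monotone in $f$.
* **NA handling is conservative.** Undefined correlations are excluded
  from the support count and the weight mean, but the denominator stays
  $n$, so missing information can only lose edges, never create them.

## Overlap network

`overlap_network()` keeps the canonical gene pairs present in both group
networks with equal sign; weight is the mean of the parent weights and
support the minimum of the parent supports. The intersection depends only
on edge identity and sign, not on the exact correlation values, so it
commutes, is idempotent, and always yields a subgraph of each parent.

## Individual variability diagnostic

`frobenius_distance()` implements
$\lVert A - B \rVert_F = \sqrt{\sum_i \sum_j |a_{ij} - b_{ij}|^2}$ over
the full matrix — both triangles and the diagonal, following the
definition's double sum; the symmetric off-diagonal entries therefore
count twice, consistently for every comparison.
`individual_distance_profile()` reports, per individual, the distance
between that individual's correlation matrix and the group mean matrix
(entry-wise NA-aware mean, unit diagonal), sorted descending. Large values
flag individuals whose co-expression structure departs most from the
group — the in-package analogue of manual outlier screening. Undefined
entries are excluded pairwise by default (`na_action = "error"` turns
them into a hard failure).

## Community clustering

Clusters are communities in the unweighted overlap graph. Connected
components smaller than `min_cluster_size` (default 3) are labelled
`"unclustered"` — isolated correlated pairs stay pairs rather than being
forced into clusters — and the remaining graph is partitioned by greedy
modularity maximisation (fast-greedy agglomeration via igraph). The merge
dendrogram is cut at maximal modularity after rounding the modularity
trace to 10 decimal places, so a whole-component community whose true
modularity is zero (e.g. a clique) is not lost to floating-point noise in
favour of a strictly negative cut. Any community that still ends up
smaller than `min_cluster_size` is relabelled unclustered, so every
numbered cluster honours the minimum. Cluster ids are dense from 1,
ordered by decreasing size with ties broken by the lexicographically
first member gene, making the labelling deterministic; the `seed`
argument exists for interface stability with stochastic algorithms that
could be plugged in behind the same surface. The original
visualisation-coupled community-layout tooling is not reproduced; greedy
modularity is the deterministic, scriptable stand-in for the same
topological notion of "cluster".

## Over-representation analysis

`ora()` tests each gene set with the hypergeometric upper tail
$P(X \ge k)$ where $N$ is the universe size, $K$ the set size within the
universe, $n$ the query size and $k$ the overlap. Reported rows must pass
`min_overlap` (default 2), the number-or-percentage gate
(`k >= min_genes` *or* `k/K >= min_fraction`), and `p <= 0.01`;
Benjamini–Hochberg adjustment is computed over all tested sets before any
filtering. The universe defaults (in `run_pipeline()`) to the
background-filtered gene list rather than the whole genome — enrichment
against genes that could never have been detected would inflate
significance. Gene-set hierarchies are not modelled; GMT files carry
whatever granularity the user supplies.

# The synthetic study generator

`generate_study()` emulates the design the workflow targets: two diet-style
groups, three time points per individual, complete series, both sexes with
Y-chromosome genes expressed only in males, planted co-expression modules
(shared and group-specific, with a fraction of mirrored members), and
background genes at the noise floor.

Each module in each individual follows a latent trajectory
$z_i(1) = 0$, $z_i(t+1) = z_i(t) + \delta_t + \varepsilon_{it}$ with
$\varepsilon_{it} \sim N(0, 1)$, where the group-level shift $\delta_1$
(default $-1$ log2 unit) acts between the first two time points and is 0
afterwards — the design concentrates the systematic change in the first
interval, with the later interval dominated by individual variation.
A member gene reads
$x_g(t, i) = \beta_g + s_g \cdot \ell \cdot z_i(t) + N(0, \sigma)$, with
per-gene baseline $\beta_g \sim N(7, 0.5^2)$, loading $\ell = 1$, sign
$s_g \in \{+1, -1\}$ (a quarter of members mirrored by default), and
measurement noise $\sigma = 0.25$ log2 units. Background genes sit at a
noise floor of 4 log2 units in every sample; Y genes behave like expressed
genes in males and like background in females. The baseline (7), spread
(0.5) and floor (4) are chosen once as realistic log2 microarray levels —
expressed genes a few log2 units above an aggregated optical noise floor —
and the default cohort (12 individuals per group, five 8-gene modules of
which three are shared and one is unique to each group, 200 background and
20 Y genes, equal sex split) mirrors a small two-arm intervention study.
One RNG stream seeded from `spec$seed` is consumed in a documented order,
so studies are exactly reproducible; sexes are assigned deterministically.

What the generator does *not* emulate: probe-level and batch effects,
missing time points, dropout, and — importantly — background genes with
correlated structure. Passing the planted-recovery tests therefore shows
the pipeline recovers block-structured latent-factor signal under
realistic noise; it does not certify behaviour under array artefacts or
confounded designs.

A structural property of this generator worth knowing when interpreting
recovery metrics: because every module shares the same group-level shift,
genes of *different* modules are correlated within an individual through
the common deterministic trend $(0, -1, -1)$, at a strength set by the
ratio of shift to per-step individual deviation (here $1 : 1$). With only
three time points this produces a non-trivial rate of strong cross-module
correlations, so edge precision against the within-module truth is
intrinsically limited at these settings — an honest reflection of what a
shared intervention trend does to short-series co-expression analysis, and
the reason differential trajectories (or more time points) are needed for
clean module separation. `truth_edge_metrics()` and
`adjusted_rand_index()` quantify exactly this on any generated study, and
`scripts/acceptance.R` recomputes the numbers end to end.

# Numerical and interface choices

* Tabular I/O is TSV (UTF-8, unquoted); reals are serialised with
  `%.17g`, so write/read round-trips are bit-exact for expression
  matrices, edge lists and GraphML (the SIF format structurally carries
  only topology and sign). GraphML is written from a fixed template for
  the same full-precision reason.
* Edges are canonicalised with `gene_a < gene_b` lexicographically and
  stored once, making edge-set comparisons and intersections
  deterministic.
* Gene identifiers are opaque strings; no identifier mapping happens
  in-package.
* The trigamma inverse needed by the variance-prior fit uses the standard
  Newton iteration on $1/\text{trigamma}$ with asymptotic endpoints
  ($1/x$ for small $x$, $1/\sqrt{x}$ for large).
* Degenerate inputs fail loudly: samples without annotation, duplicated
  (individual, time point) pairs, missing expression cells, incomplete
  time series, empty groups, a background threshold that removes every
  gene, and q-value inputs outside $[0, 1]$ are all errors rather than
  silent repairs.

# Validation scales

The test suite and `scripts/acceptance.R` validate the implementation at
sizes chosen to exercise every code path while keeping a full run in the
tens of seconds: the default synthetic study (260 genes × 72 samples, two
groups of 12), 100 random correlation stacks of up to 20 genes × 10
individuals checked against a brute-force edge-rule reference, 1,000
random symmetric-matrix triples for the Frobenius metric axioms and
double-loop agreement, 1,000 random p-vectors for exact equality between
the $\pi_0 = 1$ q-value and independent step-up FDR, a 2,000-gene null
study for the type-I error of the DE gate, and exhaustive
modularity enumeration on an 8-node two-clique graph for the clustering
cut.

# Known limitations

* With $T = 3$ time points a single individual's Pearson correlation is
  extremely coarse (|r| ≥ 0.6 is likely even for unrelated series);
  inferential strength comes entirely from the support-across-individuals
  rule, not from any one correlation.
* The DE stage supports exactly the paired two-time-point contrast — no
  covariates, batch terms, or general design matrices.
* The significance gate is on raw p (with q-values reported), matching
  common practice for this workflow rather than controlling FDR at the
  gate.
* `ora()` treats gene sets as flat; ontology structure, term levels and
  parent–child redundancy are out of scope.
* The overlap stage is defined for exactly two groups.
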