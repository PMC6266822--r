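# dcenet — within-individual time-series co-expression networks

`dcenet` builds signed gene co-expression networks from short time-series
expression studies with repeated measures per individual — the design of
human intervention studies (e.g. two diet arms, a biopsy before and after
intervention and after follow-up). Standard co-expression methods
correlate group-average profiles and are washed out by the high
inter-individual variability of such cohorts. `dcenet` instead computes
Pearson correlations **within each individual's time series first** and
aggregates them across the group with a support rule, so each participant
contributes one correlation per gene pair and heterogeneity is preserved
rather than averaged away.

It is aimed at transcriptomics analysts working with small repeated-
measures cohorts who want networks, per-individual diagnostics and
cluster-level enrichment from a single scriptable toolchain.

## The method

For a group of $n$ individuals measured at $T \ge 3$ time points:

1. **Background filter.** Genes whose median expression (all samples) is
   equal to or below the median of Y-chromosome gene expression in female
   samples — a biological negative control for the noise floor — are
   removed.
2. **Paired differential expression.** Per gene, within-individual log2
   differences $d_i = x(t_B, i) - x(t_A, i)$ are tested with a plain or
   empirical-Bayes moderated paired t (posterior variance
   $(d_0 s_0^2 + df\,s^2)/(d_0 + df)$, prior fitted by method of moments
   on log variances). Significance gate: $|FC| \ge 1.2$ and $p < 0.05$;
   Storey q-values ($\pi_0$ by the smoother method) reported alongside.
   The per-group analysis gene list is the union of significant genes
   over the chosen contrasts.
3. **Network edge rule.** For each gene pair, individual $i$ supports the
   edge when $|r_i| \ge 0.6$; the pair becomes an edge when at least 25%
   of the group's individuals support it and all supporting correlations
   share one sign. Weight = mean supporting correlation; support =
   supporting fraction.
4. **Overlap network.** The edge-wise intersection of the two group
   networks keeping pairs correlated in the same direction — the
   co-expression behaviour shared by both conditions.
5. **Diagnostics and downstream.** Per-individual Frobenius distances
   $\lVert A_i - \bar{A} \rVert_F$ between each individual's correlation
   matrix and the group mean quantify who deviates most; greedy-modularity
   community clustering (components below 3 genes stay unclustered)
   partitions the overlap network; hypergeometric over-representation
   analysis (min overlap 2, $p \le 0.01$, Benjamini–Hochberg adjusted)
   annotates each cluster against user-supplied GMT gene sets.

A synthetic study generator (`generate_study()`) plants known shared and
group-specific co-expression modules (with mirrored members), background
genes and sex-specific Y genes, and returns the ground truth, so the whole
pipeline is testable without any external data.

## Worked example

```r
library(dcenet)

study <- generate_study(study_spec())   # default two-group synthetic study
res <- run_pipeline(study$expr, study$chrom)
print(res)
```

```
dcen_pipeline
  filtered genes: 151 (background threshold 4.003) 
  [LCD] DE union: 34; network: 32 nodes / 167 edges
  [VLCD] DE union: 33; network: 33 nodes / 195 edges
  overlap: 24 nodes / 71 edges (27 negative)
  clusters: 8, 8, 8 | unclustered: 0 
```

Reading: of 260 simulated genes, 151 clear the Y-chromosome noise-floor
threshold (4.003 log2 units). Each diet-style group yields ~33
differentially expressed genes whose within-individual correlation
network has ~30 nodes; the sign-consistent intersection of the two
networks keeps 71 edges among 24 genes, and community clustering
partitions them into three 8-gene clusters — exactly the three planted
modules shared by both groups:

```r
m <- truth_edge_metrics(res$networks$LCD, study$truth, "group")
str(m)
#> List of 2
#>  $ recall         : num 0.973
#>  $ false_edge_rate: num 0.347

roles <- setNames(study$truth$genes$role, study$truth$genes$gene_id)
adjusted_rand_index(res$clusters$cluster, roles[res$clusters$gene])
#> [1] 1
```

Per-individual variability diagnostic (largest Frobenius distances first):

```r
head(res$distance_profiles$LCD, 3)
#>  LCD_I11  LCD_I09  LCD_I05 
#> 25.99832 24.33988 22.62759
```

The same stages are available from the shell via the thin CLI:

```sh
Rscript inst/cli/dcenet.R simulate --out-dir sim --seed 42
Rscript inst/cli/dcenet.R filter-background --expr sim/expression.tsv \
    --samples sim/samples.tsv --chrom sim/chromosomes.tsv --out filtered.tsv
Rscript inst/cli/dcenet.R run-all --config pipeline.yaml
```

Networks export as edge-list TSV, SIF or GraphML for Cytoscape.

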