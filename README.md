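# cascadepath

Measuring the biological gap between genetically engineered organoids and
matched tumor samples, and prioritizing the *gene cascading paths* —
ordered driver-to-candidate gene sequences — most likely to shrink it.

Engineered intestinal organoids carrying cumulative driver mutations
(*APC* → +*KRAS* → +*SMAD4* → +*TP53* → +*PIK3CA*; types A, AK, AS, AKST,
AKSTP) approximate colorectal tumors increasingly well, but a measurable
functional gap to real tumor tissue remains.  `cascadepath` implements an
integrative strategy for systems-biology analyses of that gap:

1. **Rank-based integration.**  Per sample, the gene of expression rank
   *i* among *N* common genes scores `W_s(g_i) = exp(-i/N)`, making
   profiles from different platforms jointly analyzable.
2. **Dysregulated functions.**  A pathway's activity is the
   normalized-centroid shift `FAS = mean(in-set score) − mean(out-set
   score)`; the gap statistic `DFAS = |mean_S FAS − mean_T FAS|` between
   organoid group S and tumor group T is tested against a gene-relabeling
   permutation null (1,000 permutations, add-one p-values,
   Benjamini–Hochberg, FDR 0.01).
3. **Signature dynamics.**  Stepwise organoid-vs-organoid comparisons with
   the weighted Kolmogorov–Smirnov running-sum enrichment score and the
   same permutation machinery (FDR 0.05), plus single-sample activity and
   group activity correlations.
4. **Subsequent key genes.**  Random walk with restart
   (`P_{t+1} = (1−r) W P_t + r P_0`, r = 0.7, tolerance 1e-8) from each
   dysregulated pathway's top-10%-degree hub genes on a protein
   interaction network; per-gene empirical significance against 1,000
   equal-size pseudo-seed sets; Fisher's method
   `χ² = −2 Σ ln P_jk ~ χ²(2K)` across the K dysregulated functions;
   FDR 0.05 defines key genes.
5. **Cascade paths.**  A functional-coherence network (cosine over shared
   functional annotation, edges ≥ 0.4) sparsified to each gene's top-2
   neighbors; the path runs from the organoid's mutant genes to the
   candidate key gene at maximum shortest distance.

A synthetic-data generator (`synthetic_config()`, `simulate_bundle()`)
emulates the required inputs — scale-free interaction network, connected
pathway subgraphs, two sample groups with planted expression shifts,
driver-mutation labels — with recorded ground truth, so the whole pipeline
is testable without downloads.  `run_all()` orchestrates every stage from
one YAML config with deterministic per-stage seeds.

## Worked example

Plant three dysregulated pathways and five key genes, then recover them:

```r
library(cascadepath)

cfg <- synthetic_config(n_genes = 1000, n_samples = 8, n_pathways = 20,
                        pathway_size = c(8, 15), frac_dysregulated = 0.15,
                        n_key_genes = 5, seed = 7)
net <- generate_network(cfg)
pws <- generate_pathways(net, cfg)
sim <- generate_expression(net, pws, cfg)

rs_org <- rank_transform(sim$organoid)
rs_tum <- rank_transform(sim$tumor)
sets   <- lapply(pws, function(p) igraph::V(p)$name)
dys <- dysregulation_test(rs_org, rs_tum, sets, n_perm = 1000,
                          fdr = 0.01, seed = 8)
head(dys[order(dys$q), ], 5)
#>    function_name n_genes_used fas_S_mean fas_T_mean   dfas        p       q dysregulated
#> 10          pw10            8    0.06745     0.3316 0.2642 0.000999 0.00666         TRUE
#> 11          pw11           10    0.00514     0.3158 0.3107 0.000999 0.00666         TRUE
#> 12          pw12           10    0.01204     0.3049 0.2929 0.000999 0.00666         TRUE
#> 5           pw05           11   -0.00109     0.0553 0.0563 0.022977 0.11489        FALSE
#> 3           pw03           13   -0.01746     0.0111 0.0285 0.182817 0.73127        FALSE

sim$truth$dysregulated
#> [1] "pw10" "pw11" "pw12"
```

The three planted pathways (`pw10`–`pw12`) are exactly the three calls at
FDR 0.01: their tumor-side activity (`fas_T_mean` ≈ 0.26–0.31 above the
organoid side) reflects the +3σ expression shift planted in the tumor
group.  Key-gene inference then propagates from those pathways' hubs:

```r
kg <- infer_key_genes(net, pws[sim$truth$dysregulated],
                      n_random = 1000, seed = 9)
head(kg$table, 3)
#>      gene K chi2 df p_combined      q is_key excluded_reason
#> 782 g0782 3 28.7  6   7.06e-05 0.0706  FALSE
#> 913 g0913 3 24.4  6   4.40e-04 0.1636  FALSE
#> 148 g0148 3 23.6  6   6.25e-04 0.1636  FALSE

median(match(sim$truth$key_genes, kg$table$gene))
#> [1] 47
```

The five planted key genes sit at median rank 47 of 1,000 network genes —
far above background (a rank-sum test against the remaining genes is part
of the acceptance checks).  `extract_cascade_path()` then turns drivers
plus candidates into an ordered path on the sparsified coherence network;
`run_all()` chains all stages and writes one TSV per stage plus a
`manifest.json`.

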