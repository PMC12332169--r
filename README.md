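# netmediator

Sample-specific network analysis of two-group transcriptomic cohorts:
finds **central genes** — genes that mediate a transcriptomic shift
through the interactome even when their own differential expression is
negligible — and contrasts them with the classical top-DEG list.

## Who this is for

Computational biologists comparing two tumour (or any case/control)
subtypes with a gene×sample expression matrix and a protein–protein
interaction network, who suspect that hub-like mediators with small fold
changes are being missed by `limma`-style rankings.

## The method in brief

For each case sample $j$:

1. **Node weights.** Signed per-gene log2 fold change against the control
   median; a loess fit of $|\mathrm{lfc}|$ on control expression gives the
   expected magnitude, and the weight is the positive residual
   $w_g=\max(|\mathrm{lfc}_g|-\widehat{E}|\mathrm{lfc}|,0)+\varepsilon$,
   gated on the fold-change sign ("activated" mode).
2. **Differentially active paths.** With $\hat w = w/\max w$, an edge
   $(u,v)$ costs $1/\sqrt{\hat w_u\hat w_v}$; minimum-cost paths between
   the top-weight terminal genes are scored against a null that shuffles
   node weights over the network (200 permutations,
   $p=(1+\#\{C_\mathrm{perm}\le C_\mathrm{obs}\})/201$), BH-adjusted at
   $\alpha=0.05$. Significant paths union into the sample's **TopNet**.
3. **Ripple centrality.**
   $r(v)=\sqrt{R_\mathrm{out}(v)R_\mathrm{in}(v)}/(n-1)$ on the TopNet;
   per-sample top-100 by $r$, then frequency-ranked across samples into
   the cohort's top-100 **central genes**.

Companion modules: differential expression (Welch / moderated-t, BH FDR),
hypergeometric over-representation on GMT collections, Fisher's-exact
gene-list overlap with odds ratios (default 20,000-gene universe),
single-cell cell-type specificity (ANOVA, z-scores, log2 observed/expected
expressed fractions), classifier evaluation (5-fold CV, AUROC/AUPRC/F1,
bootstrap CIs, DeLong's test), degree-based hub selection with drug-target
annotation, and a synthetic-cohort generator with planted mediators.

## Worked example

```r
library(netmediator)

spec <- synthetic_spec(n_genes = 200, n_case = 8, n_control = 16,
                       mediator_count = 3, seed = 42)
coh  <- generate_cohort(spec)
net  <- generate_network(coh$truth$gene,
                         mediator_ids = subset(coh$truth, role == "mediator")$gene,
                         deg_ids      = subset(coh$truth, role == "deg")$gene,
                         seed = 43)
coh$expr
#> ExpressionMatrix: 200 genes x 24 samples (8 case, 16 control)
net
#> InteractionNetwork: 456 undirected edges over 200 genes

res <- central_genes(coh$expr, net, n_perm = 100, seed = 42)
head(res$central, 5)
#>    gene frequency freq_fraction mean_centrality
#> 1 G0061         4          1.00               1
#> 2 G0092         4          1.00               1
#> 3 G0098         4          1.00               1
#> 4 G0107         4          1.00               1
#> 5 G0005         3          0.75               1
```

Four of the eight case samples have a significantly altered network;
`freq_fraction` is the share of those significant samples in which a gene
ranked in the per-sample top-100 by ripple centrality. On this small
world, 2 of the 3 planted mediators land in the central-gene table while
none appear in the top-100 DEG list (at the full default scale, 16/48
samples and 500 genes, recovery is 5/5 vs 0/5).

Benchmark overlap of a top-100 list against, say, a 1665-gene
transcription-factor catalogue in a 20,000-gene universe:

```r
fisher_overlap_counts(17, 100, 1665, 20000)
#>    a  b    c     d odds_ratio     p_value
#> 1 17 83 1648 18252   2.268423 0.005207622
```

An odds ratio above 1 means the list is enriched for the reference
catalogue; the p-value is the two-sided Fisher exact test.

## Pipeline and CLI

`run_all(pipeline_config(expr = ..., groups = ..., network = ...), out_dir)`
executes every stage with provenance headers and a `run.log`; re-running
the same config is bit-identical. A thin CLI wraps it:

```sh
exec/netmediator simulate --spec spec.yaml --out sim/
exec/netmediator run-all  --config config.yaml --out results/
exec/netmediator overlap  --genes central.txt --ref tfs.txt --background 20000
```

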