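# mirnet

Mutual-information regulatory networks from paired miRNA and mRNA
expression.

## The problem

MicroRNAs repress their target mRNAs post-transcriptionally, and in
tumours this layer of regulation is extensively rewired. Given paired
tumour/adjacent-control expression profiles (miRNA-Seq counts and
RNA-Seq abundances for the same patients), `mirnet` reconstructs, per
condition, an undirected co-expression network over miRs and mRNAs and
asks the questions a regulatory study asks of it: which miR families hub
the network, what happens to its cohesion when the miRs are removed,
which associations survive in both tumour and control, whether the
network's miRs concentrate in a genomic cluster, which gene sets its
mRNAs over-represent, and how far each tumour sample has drifted from
normal pathway behaviour.

It is aimed at computational biologists who want the whole chain —
normalization, inference, topology, enrichment, deregulation scoring —
as composable, tested R functions returning tibbles, plus a
synthetic-data generator with planted ground truth to validate the chain
end to end.

## The method

Dependence is measured by mutual information estimated with a Gaussian
kernel on fractional ranks $r_i = \mathrm{rank}_i/(n+1)$:

$$\hat I(X;Y) = \frac{1}{n}\sum_{i=1}^{n}
  \log\frac{\hat f_2(x_i,y_i)}{\hat f_1(x_i)\hat f_1(y_i)},$$

with boundary-reflected kernels, a blended full-sample/leave-one-out
log-density that cancels the plug-in bias, and bandwidth
$h = c\,n^{-1/6}$ calibrated per sample size on an independence null
(for bivariate Gaussians the estimate reproduces
$-\tfrac12\ln(1-\rho^2)$; the rank transform makes it invariant to any
monotone normalization). Edges are kept per class above empirical
percentile cutoffs (mRNA-mRNA 99.987%; miR-miR and miR-mRNA pooled at
99.741%), annotated with class-pooled permutation p-values
(Bonferroni-corrected), and pruned by the data processing inequality:
the weakest edge of a triangle is removed unless within 10% of the
weaker of the other two.

Around the network: TMM and upper-quartile normalization with the
standard count/abundance filters; paired differential expression
(median-of-ratios size factors, Wilcoxon signed-rank, BH) flagged at
twofold and FDR < 0.01; hypergeometric gene-set and genomic-cluster
enrichment; and Pathifier-style pathway deregulation scores (PDS): per
pathway, standardized expression is reduced by PCA, a principal curve is
fitted by projection/local-averaging iterations anchored at the control
centroid, and each sample is scored by its normalized arc-length
position in [0, 1].

See `vignette("mirnet-methods")` for assumptions, parameter defaults and
numerical choices.

## Worked example

```r
library(mirnet)

# paired tumour/control benchmark with planted hubs, a genomic miR
# cluster, a conserved miR-mRNA core, and two-fold differential expression
synth <- synthetic_dataset(synthetic_config(seed = 1))
run   <- run_study(synth, seed = 1)
print(run)
```

```
<mirnet_run>
  tumour network: 194 nodes, 217 edges
  control network: 274 nodes, 309 edges
  intersection: 19 edges; DE flagged: 80; pathways scored: 11
<mirnet_scorecard>
  hub recovered: tumour TRUE, control TRUE (top-10 degree)
  conserved core: precision 0.947, recall 0.900
  cluster positional p: 3.59e-08
  DE sensitivity 0.976, empirical FDR 0.000
  planted pathway separation p: 9.04e-07
```

Reading the scorecard: both planted hub miR families rank inside the
top-10 degree nodes of their condition's network; 18 of the 20 planted
conserved miR-mRNA pairs are recovered by the tumour∩control edge
intersection, with one false edge; the planted 12-miR genomic cluster is
strongly over-represented among the tumour network's miR nodes
(hypergeometric p = 3.6e-08); 98% of the planted expression shifts are
flagged with the correct sign at twofold/FDR < 0.01 with no false flags;
and the planted deregulated pathway's PDS separates tumour from control
samples (rank-sum p = 9.0e-07).

Every intermediate is a first-class object:

```r
glance(run$networks$tumour)      # node/edge counts per class
run$degrees$tumour$families      # miR-family degree ranking
tidy(run$pds)                    # pathway x sample scores, long form
autoplot(run$de)                 # volcano plot
plot_mi_histogram(tumour = run$networks$tumour,
                  control = run$networks$control)
```

A thin command-line front end over the same functions ships in
`inst/cli/mirnet.R` (`synth`, `preprocess`, `infer`, `run-all`, `score`).

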