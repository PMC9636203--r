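# cagegrn

Gene regulatory networks and key-transcription-factor prediction from
CAGE-seq alone.

## The problem

CAGE-seq captures 5'-capped RNA ends, so it measures transcription
initiation per base and per strand. Two initiation patterns carry distinct
regulatory meaning: *unidirectional* tag clusters mark gene TSSs and
quantify gene expression, while balanced *bidirectional* (divergent)
initiation — minus-strand signal upstream, plus-strand signal downstream of
a midpoint — is the transcriptional signature of active enhancers. This
package exploits that signature so that a single CAGE-seq experiment per
cell state is enough to (1) call enhancers, (2) predict which transcription
factors (TFs) bind them, (3) build TF→gene regulatory networks, and
(4) rank TFs by how well they explain the transition between two cell
states. It is aimed at regulatory genomicists who have CTSS BED files and
want candidate drivers of a differentiation, reprogramming or disease
transition without ATAC- or ChIP-seq.

## The model

**Enhancer calling.** CTSSs are TPM-normalized per sample, pooled, and
sliced into same-strand tag clusters (gap ≤ 20 bp). At every candidate
midpoint *m*, a 201-bp window (100 + 1 + 100) is scored with a balance
statistic over pooled signal: with *D* the minus-strand TPM in the upstream
arm, *U* the plus-strand TPM in the downstream arm and *T* the total TPM in
the window,

```
B = sqrt(0.5 * D/T) + sqrt(0.5 * U/T)
```

the Bhattacharyya coefficient against the ideal (0.5, 0.5) divergent
pattern. B = 1 for perfectly balanced divergent initiation and
B = √0.5 ≈ 0.707 for purely unidirectional signal, so the threshold
B ≥ 0.95 rejects ordinary TSS clusters. Qualifying midpoints ≤ 20 bp apart
merge into one region, kept if supported by ≥ 2 samples, then normalized to
200 bp around the midpoint.

**TF binding.** For TF *f* at enhancer *l*, a logistic model

```
logit(p_fl) = b1 * S_fl + b2 * E_CAGE_l + b3 * E_ChIP_l + intercept
```

combines the TF's best motif z-score (PFM best hits standardized against a
seeded, composition-matched background), the log-transformed
quantile-normalized bidirectional TPM, and the log1p of averaged curated
ChIP-seq coverage. Models are L2-regularized on standardized features and
evaluated by cross-validated PR AUC (held-out chromosomes for per-TF
models, held-out cell types for the pooled "general" model).

**Networks and influence.** A TF→gene edge score is the mean of four
rank-scaled components: TF expression, target expression, distance-weighted
binding `sum_l p_fl * w(d_l)` (full weight within 5 kb, exponential decay
to 100 kb) and genome-wide motif activity (ridge regression of enhancer
intensities on motif z-scores). For a source→target comparison, edges are
differenced (`max(0, target − source)`, top 500 k kept) and each TF's
influence sums, over genes reachable within two steps, a depth-discounted
best-path score times the gene's positive log2 fold change — activation
only. Influence-per-timepoint matrices can be clustered with seeded k-means
plus an elbow rule.

A deterministic fixture generator builds miniature genomes with planted TSS
clusters, enhancers, motifs, binding labels and a two-cell-state design, so
the whole pipeline is testable offline with exact ground truth.

## Worked example

Two synthetic cell states; TF1 and TF2 are planted drivers of state B
(their genes are silent in A, and B switches on motif-bearing enhancers
near their targets):

```r
library(cagegrn)
spec <- fixture_spec(seed = 1)
tw   <- make_two_state(spec)
w    <- tw$world

resA <- process_ctss(tw$ctss_a, annotation = w$annotation)
resB <- process_ctss(tw$ctss_b, annotation = w$annotation)
regA <- find_enhancers(resA$pooled, chrom_lengths = w$genome$lengths)
regB <- find_enhancers(resB$pooled, chrom_lengths = w$genome$lengths)
regB[1:3, .(region_id, chrom, mid, balance, tpm, support)]
#>    region_id  chrom   mid   balance      tpm support
#> 1:   BR00001   chr1 11037 0.9998268 5007.459       3
#> 2:   BR00002   chr1 27633 0.9999947 5374.398       3
#> 3:   BR00003   chr1 44305 1.0000000 4873.639       3
```

State A yields the 40 baseline enhancers, state B additionally the 12
planted state-B enhancers (52 regions). Each row is a called enhancer: a
balance score near 1 (balanced divergent initiation), its pooled TPM over
the signal window and 3-of-3 replicate support.

```r
truth <- make_binding_truth(spec, w, regB)   # labels + coverage track
feats <- merge(truth$features_true, truth$labels, by = c("tf", "region_id"))
model <- train_general_model(feats, feats$label)
model
#> BindingModel [general]: logit(p) = 0.6969 + 2.804*S + 0.4933*E_CAGE + 1.229*E_ChIP
pr_auc(predict_binding(model, feats), feats$label)  # 0.934, prevalence 0.522
```

All three coefficients are positive: motif match, enhancer intensity and
curated ChIP coverage each raise the predicted binding probability.

```r
write_coverage_track(truth$coverage, "remap_like.bedGraph")
trk  <- read_coverage_track("remap_like.bedGraph")
grnA <- network_from_state(regA, resA$expression$genes, w$genome, w$motifs,
                           w$motif2tf, trk, model, annotation = w$annotation)
grnB <- network_from_state(regB, resB$expression$genes, w$genome, w$motifs,
                           w$motif2tf, trk, model, annotation = w$annotation)
inf  <- influence_scores(differential_grn(grnA, grnB), tw$de)
rank_and_plot_data(inf, tw$de)
#>    rank_     tf influence   log2fc out_degree
#> 1:     1    TF1 1.0000000  9.91669         54
#> 2:     2    TF2 0.9836968 10.22471         54
#> 3:     3    TF4 0.8843720  0.00000         54
#> ...
```

The two planted drivers rank first and second for the A→B transition; in
the reverse B→A comparison they acquire no differential edges and are
unranked. `timecourse_cluster()` groups per-timepoint influence profiles
(k-means + elbow) for time-course designs.

A command-line interface mirrors the R API
(`inst/cli/cagegrn validate|fixtures|ctss|enhancers|network|influence|timecourse`).

## Documentation

See the methods vignette (`vignettes/cagegrn-methods.Rmd`) for the model
assumptions, parameter defaults, numerical choices and known limitations.
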