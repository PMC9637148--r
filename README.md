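# chromattn

Gene expression prediction from histone-modification ChIP-seq signals with
a three-level attention architecture that integrates distal cis-regulatory
elements contacted through 3D chromatin folding — together with the full
feature pipeline, chromosome-disjoint training protocol, attention/PCRI
interpretation statistics, and a self-contained synthetic-epigenome
simulator. It is written for computational epigenomics groups who want a
transparent, fully testable implementation of interaction-aware histone-code
modeling: every forward *and* backward pass is plain R matrix code,
hand-differentiated and verified against numerical gradients in the test
suite.

## The model

For each gene, seven histone marks (H3K4me1, H3K4me3, H3K9me3, H3K27me3,
H3K36me3, H3K27ac, H3K9ac) are binned over the 40 kbp window around the TSS
at 100 bp / 500 bp / 2 kbp resolutions (400/80/20 bins) as log2 mean depth.
Putative cis-regulatory elements (pCREs) in contact with the promoter —
from promoter-capture Hi-C, kept when the normalized interaction frequency
exceeds 1.5, at most the 8 strongest — are binned the same way and
center-aligned with zero padding.

Each resolution runs an independent stack of three attention modules
(defaults: width d = 128):

1. **Promoter encoder** — sinusoidal positional encoding, one encoder layer
   of 2-head self-attention, `softmax(QKᵀ/√64)V`, residual + layer norm,
   position-wise FFN. Output `X_emb`.
2. **Pairwise interaction module** — two encoder-decoder attention layers
   per pCRE: queries from `X_emb`, bias-free keys/values from the pCRE
   matrix. Output `X_pair` per pCRE.
3. **Regulation module** — the TSS-bin rows of `X_emb` and all `X_pair`s
   form a 9 × 128 composite; six layers of gated self-attention
   `softmax(QKᵀ/√32 + γB) V ∘ σ(G)`, where `B` carries the interaction
   frequency vector in its first row and `γ` is learnable. Its first output
   row is the regulatory embedding.

The three regulatory embeddings are concatenated into a 384-dim vector and
a 128-wide ReLU head predicts the binary expression state (`clf`, 2
logits), log2 RPKM (`reg`), or — with a Siamese shared backbone over two
cell types plus auxiliary absolute-level heads — the log2 fold-change
(`diff`). Training: AdamW, lr 3e-5 decayed ×0.87 per epoch, 10 epochs,
batch 64, last-epoch weights, 4-fold chromosome-disjoint cross-validation.

The **predicted cis-regulatory impact (PCRI)** of a gene is the Euclidean
distance between its standardized multi-resolution promoter embedding and
regulatory embedding — how far the interaction modules moved the
promoter's latent state — computed on validation genes under their own
fold's model, z-scored within cell type for cross-context comparison.

## Worked example

```r
library(chromattn)
dir <- file.path(tempdir(), "demo")
write_fixture("tiny", dir, seed = 7)       # 40 genes, 2 chromosomes

genes  <- read_genes(file.path(dir, "genes.bed"))
tracks <- sapply(list.files(file.path(dir, "tracks"), full.names = TRUE),
                 read_bedgraph, simplify = FALSE)
names(tracks) <- sub(".bedGraph", "", basename(names(tracks)), fixed = TRUE)
ints   <- read_interactions(file.path(dir, "interactions.tsv"))
expr   <- read_expression(file.path(dir, "expression.tsv"))

labels   <- derive_labels(expr, task = "clf")   # above-median split
examples <- featurize_dataset(genes, tracks, ints, labels,
                              resolutions = c(100, 500, 2000))
e <- examples[["chrS1_g003"]]
sapply(e$promoter, dim)
#>      100 500 2000
#> [1,] 400  80   20
#> [2,]   7   7    7
e$n_pcres
#> [1] 6
round(e$freq, 2)
#> [1] 3.42 3.29 2.68 2.38 2.15 1.80 0.00 0.00
```

The promoter is represented at three resolutions over the 40 kbp window;
this gene has six retained pCREs, ranked by normalized interaction
frequency (all above the 1.5 filter), zero-filled to the length-8
frequency vector the regulation module consumes.

```r
mcfg <- model_config(resolutions = 2000, d_model = 16, n_heads_emb = 2,
                     d_ffn_emb = 16, n_layers_pair = 1, d_head_pair = 8,
                     d_ffn_pair = 32, n_layers_reg = 2, d_head_reg = 4,
                     d_ffn_reg = 16, head_hidden = 16, task = "clf")
tcfg <- train_config(epochs = 4, lr = 3e-3, batch_size = 16, seed = 1)
cv <- run_cv(examples, mcfg, tcfg, k = 2, seed = 1)
sapply(cv$reports, function(r) round(unlist(r), 3))
#>                    [,1]  [,2]
#> auc               0.680 0.800
#> accuracy          0.550 0.700
#> average_precision 0.641 0.877
```

A width-16 model trained for four epochs on 20 genes per fold already
separates expression classes on held-out chromosomes (AUC 0.68/0.80 for
the two folds); the package defaults reproduce the full-scale
configuration. Validation-gene embeddings collected during CV feed the
interpretation layer:

```r
pcri <- normalize_pcri(pcri_table(cv$bundles))
head(pcri[order(-pcri$pcri), c("gene_id", "pcri", "normalized_pcri")], 3)
#>       gene_id     pcri normalized_pcri
#> 23 chrS2_g003 1.887446        2.005050
#> 15 chrS1_g015 1.859541        1.662825
#> 26 chrS2_g006 1.849232        1.536401
```

Genes with high PCRI are those whose latent promoter state the interaction
modules moved farthest — the model's prediction of strong distal
cis-regulation.

A thin command-line wrapper over these functions is installed at
`inst/scripts/chromattn-cli.R`
(`simulate` / `featurize` / `train` / `pcri` subcommands).

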