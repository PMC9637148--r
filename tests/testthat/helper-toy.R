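# shared fixtures, built in code

# small model configuration for unit tests (structure intact, widths tiny)
toy_config <- function(...) {
  defaults <- list(channels = paste0("M", 1:3), window = 240L,
                   resolutions = c(40L, 120L), d_model = 8L,
                   n_heads_emb = 2L, d_ffn_emb = 8L, n_layers_pair = 2L,
                   d_head_pair = 4L, d_ffn_pair = 12L, n_layers_reg = 3L,
                   d_head_reg = 2L, d_ffn_reg = 8L, i_max = 3L,
                   head_hidden = 6L, task = "clf")
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# random featurized example matching a config
toy_example <- function(cfg, n_pcres = 2L, seed = 42L, freq = NULL) {
  set.seed(seed)
  C <- length(cfg$channels)
  prom <- list(); pcres <- list()
  for (r in cfg$resolutions) {
    n_r <- cfg$window %/% r
    prom[[as.character(r)]] <-
      matrix(stats::rnorm(n_r * C), n_r, C,
             dimnames = list(NULL, cfg$channels))
    pcres[[as.character(r)]] <- lapply(seq_len(n_pcres), function(i)
      matrix(stats::rnorm(n_r * C), n_r, C,
             dimnames = list(NULL, cfg$channels)))
  }
  f <- numeric(cfg$i_max)
  if (is.null(freq) && n_pcres > 0)
    freq <- sort(stats::runif(n_pcres, 1.6, 4), decreasing = TRUE)
  f[seq_len(n_pcres)] <- freq
  list(gene_id = "toy", chrom = "chr1", label = 1,
       promoter = prom, pcres = pcres, freq = f,
       n_pcres = as.integer(n_pcres),
       pad_mask = c(TRUE, seq_len(cfg$i_max) <= n_pcres),
       channels = cfg$channels)
}

# tiny synthetic epigenome, simulated once per test run
.fixture_env <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_epigenome(sim_preset("tiny", seed = 7))
  .fixture_env$sim
}

tiny_examples <- function(resolutions = c(100, 500, 2000)) {
  key <- paste0("ex", paste(resolutions, collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    sim <- tiny_sim()
    labels <- derive_labels(sim$expression, "clf")
    .fixture_env[[key]] <- featurize_dataset(
      sim$genes, sim$tracks, sim$interactions, labels,
      resolutions = resolutions)
  }
  .fixture_env[[key]]
}

# the shared scaled-down evaluation run used by the behavioural checks
get_benchmark <- function() {
  if (is.null(.fixture_env$bm))
    .fixture_env$bm <- run_synthetic_benchmark(seed = 1, preset = "medium",
                                               epochs = 6)
  .fixture_env$bm
}

# brute-force ROC-AUC by concordant-pair counting (independent oracle)
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
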