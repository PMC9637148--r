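#' Model configuration
#'
#' Assembles and validates the hyperparameters of the three-level attention
#' architecture. Defaults are the full-scale dimensions: model width 128
#' with two 64-wide heads in the promoter (Embedding) encoder, two
#' encoder-decoder (Pairwise) layers with 64-wide heads and a 256-wide
#' feed-forward hidden layer, six gated set-attention (Regulation) layers
#' with 32-wide heads, at most 8 pCREs per promoter, and a 128-wide
#' fully-connected prediction head. Head counts for the Pairwise (2) and
#' Regulation (4) modules follow from `d_model / d_head`; configurations
#' where the per-head widths do not tile the model width are rejected.
#'
#' @param channels Character vector of signal channel names (7 histone marks
#'   by default; extensible with extra channels such as CTCF).
#' @param window Feature window around the TSS in bp.
#' @param resolutions Bin sizes (bp) of the independent single-resolution
#'   stacks; each must divide `window` into an even number of bins.
#' @param d_model Embedding width shared by all submodules.
#' @param n_heads_emb Attention heads in the promoter encoder.
#' @param d_ffn_emb,d_ffn_pair,d_ffn_reg Feed-forward hidden widths.
#' @param n_layers_pair,n_layers_reg Stacked layers in the Pairwise and
#'   Regulation modules.
#' @param d_head_pair,d_head_reg Per-head widths; head counts are
#'   `d_model / d_head`.
#' @param i_max Maximum number of pCREs entering the model per promoter.
#' @param head_hidden Hidden width of the fully-connected prediction head.
#' @param task One of `"clf"` (binary expression state, 2 logits), `"reg"`
#'   (log2 expression, scalar) or `"diff"` (log2 fold-change between two
#'   cell types, Siamese backbone).
#' @param embedding_only If `TRUE`, bypass the Pairwise and Regulation
#'   modules and feed the concatenated TSS-bin promoter embeddings straight
#'   to the head (the interaction-free ablation).
#' @param gamma_init Initial value of the learnable scalar weighting the
#'   interaction-frequency bias, one per Regulation layer.
#' @param use_pad_mask Mask dummy (zero-padded) pCRE rows out of the
#'   Regulation softmax; disable for literal zero-vector padding.
#' @param bias_all_layers Inject the frequency bias matrix at every
#'   Regulation layer (the bias encodes a static prior); if `FALSE`, only at
#'   the first layer.
#' @return A list of class `chromattn_config`.
#' @export
model_config <- function(channels = c("H3K4me1", "H3K4me3", "H3K9me3",
                                      "H3K27me3", "H3K36me3", "H3K27ac",
                                      "H3K9ac"),
                         window = 40000L,
                         resolutions = c(100L, 500L, 2000L),
                         d_model = 128L, n_heads_emb = 2L, d_ffn_emb = 128L,
                         n_layers_pair = 2L, d_head_pair = 64L,
                         d_ffn_pair = 256L,
                         n_layers_reg = 6L, d_head_reg = 32L,
                         d_ffn_reg = 128L,
                         i_max = 8L, head_hidden = 128L,
                         task = c("clf", "reg", "diff"),
                         embedding_only = FALSE,
                         gamma_init = 1.0,
                         use_pad_mask = TRUE,
                         bias_all_layers = TRUE) {
  task <- match.arg(task)
  if (length(channels) < 1L) stop("at least one signal channel is required")
  if (d_model %% n_heads_emb != 0L)
    stop("d_model must be divisible by n_heads_emb")
  if (d_model %% d_head_pair != 0L)
    stop("d_model must be divisible by d_head_pair")
  if (d_model %% d_head_reg != 0L)
    stop("d_model must be divisible by d_head_reg")
  if (d_model %% 2L != 0L) stop("d_model must be even (positional encoding)")
  for (r in resolutions) {
    if (window %% r != 0L) stop("window must be divisible by every resolution")
    if ((window / r) %% 2L != 0L)
      stop("each resolution must give an even bin count (TSS midpoint bin)")
  }
  if (i_max < 1L) stop("i_max must be >= 1")
  cfg <- list(channels = channels, window = as.integer(window),
              resolutions = as.integer(resolutions),
              d_model = as.integer(d_model),
              n_heads_emb = as.integer(n_heads_emb),
              d_head_emb = as.integer(d_model / n_heads_emb),
              d_ffn_emb = as.integer(d_ffn_emb),
              n_layers_pair = as.integer(n_layers_pair),
              d_head_pair = as.integer(d_head_pair),
              n_heads_pair = as.integer(d_model / d_head_pair),
              d_ffn_pair = as.integer(d_ffn_pair),
              n_layers_reg = as.integer(n_layers_reg),
              d_head_reg = as.integer(d_head_reg),
              n_heads_reg = as.integer(d_model / d_head_reg),
              d_ffn_reg = as.integer(d_ffn_reg),
              i_max = as.integer(i_max),
              head_hidden = as.integer(head_hidden),
              task = task,
              embedding_only = isTRUE(embedding_only),
              gamma_init = gamma_init,
              use_pad_mask = isTRUE(use_pad_mask),
              bias_all_layers = isTRUE(bias_all_layers))
  class(cfg) <- "chromattn_config"
  cfg
}

res_key <- function(r) paste0("r", r)

#' Build a model with freshly initialised weights
#'
#' @param config A [model_config()] object.
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `chromattn_model` with elements `params` (flat
#'   named list of weight arrays), `config`, and cached positional encodings.
#' @export
build_chromoformer <- function(config, seed = 1L) {
  stopifnot(inherits(config, "chromattn_config"))
  set.seed(seed)
  C <- length(config$channels)
  d <- config$d_model
  p <- list()
  pe <- list()
  for (r in config$resolutions) {
    rk <- res_key(r)
    n_r <- config$window %/% r
    pe[[rk]] <- positional_encoding(n_r, d)
    p[[paste0(rk, ".emb.proj.W")]] <- init_mat(C, d)
    p[[paste0(rk, ".emb.proj.b")]] <- init_vec(C, d)
    p <- init_enc_layer(p, paste0(rk, ".emb.enc"), d, config$d_ffn_emb,
                        proj_bias = TRUE)
    if (!config$embedding_only) {
      p[[paste0(rk, ".pair.proj.W")]] <- init_mat(C, d)
      p[[paste0(rk, ".pair.proj.b")]] <- init_vec(C, d)
      for (l in seq_len(config$n_layers_pair)) {
        p <- init_enc_layer(p, paste0(rk, ".pair.l", l), d,
                            config$d_ffn_pair, proj_bias = FALSE)
      }
      for (l in seq_len(config$n_layers_reg)) {
        p <- init_enc_layer(p, paste0(rk, ".reg.l", l), d, config$d_ffn_reg,
                            proj_bias = FALSE, gated = TRUE,
                            gamma_init = config$gamma_init)
      }
    }
  }
  in_head <- length(config$resolutions) * d
  out_dim <- if (config$task == "clf") 2L else 1L
  if (config$task == "diff") {
    p[["head.W1"]] <- init_mat(2L * in_head, config$head_hidden)
    p[["head.b1"]] <- init_vec(2L * in_head, config$head_hidden)
    p[["head.W2"]] <- init_mat(config$head_hidden, 1L)
    p[["head.b2"]] <- init_vec(config$head_hidden, 1L)
    # single auxiliary head applied to each cell type's embedding, so the
    # Siamese symmetry (swap inputs <=> swap auxiliary outputs) holds exactly
    p[["aux.W1"]] <- init_mat(in_head, config$head_hidden)
    p[["aux.b1"]] <- init_vec(in_head, config$head_hidden)
    p[["aux.W2"]] <- init_mat(config$head_hidden, 1L)
    p[["aux.b2"]] <- init_vec(config$head_hidden, 1L)
  } else {
    p[["head.W1"]] <- init_mat(in_head, config$head_hidden)
    p[["head.b1"]] <- init_vec(in_head, config$head_hidden)
    p[["head.W2"]] <- init_mat(config$head_hidden, out_dim)
    p[["head.b2"]] <- init_vec(config$head_hidden, out_dim)
  }
  model <- list(params = p, config = config, pe = pe)
  class(model) <- "chromattn_model"
  model
}

#' @export
print.chromattn_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<chromattn_model> task=%s d=%d resolutions=%s channels=%d params=%d%s\n",
    cfg$task, cfg$d_model, paste(cfg$resolutions, collapse = "/"),
    length(cfg$channels), n_par,
    if (cfg$embedding_only) " (embedding-only)" else ""))
  invisible(x)
}

# example accessor checks
check_example <- function(example, config) {
  C <- length(config$channels)
  for (r in config$resolutions) {
    rk <- as.character(r)
    n_r <- config$window %/% r
    X <- example$promoter[[rk]]
    if (is.null(X)) stop("example lacks promoter features at resolution ", r)
    if (nrow(X) != n_r || ncol(X) != C)
      stop(sprintf("promoter matrix at %d bp must be %d x %d, got %d x %d",
                   r, n_r, C, nrow(X), ncol(X)))
  }
  if (example$n_pcres > 0 && !config$embedding_only) {
    for (r in config$resolutions) {
      rk <- as.character(r)
      for (M in example$pcres[[rk]]) {
        if (nrow(M) != config$window %/% r || ncol(M) != C)
          stop("pCRE matrix shape mismatch at resolution ", r)
      }
    }
  }
  invisible(TRUE)
}

# ---- backbone forward for one example ----
# Returns per-resolution regulatory vector (or TSS-bin embedding vector if
# embedding_only), caches for the backward pass, and an embedding bundle.
backbone_fwd <- function(model, example, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  i_max <- cfg$i_max
  n_act <- min(example$n_pcres, i_max)
  f <- example$freq
  if (length(f) != i_max) {
    f <- c(f, numeric(i_max))[seq_len(i_max)]
  }
  if (any(f < 0)) stop("interaction frequencies must be non-negative")
  vecs <- list()
  prom_vecs <- list()
  caches <- list()
  attn <- list()
  for (r in cfg$resolutions) {
    rk <- res_key(r)
    erk <- as.character(r)
    n_r <- cfg$window %/% r
    mid <- n_r %/% 2L + 1L # row holding the TSS (0-based bin n_r/2)
    P <- model$pe[[rk]]
    Xp <- example$promoter[[erk]]
    Xin <- lin_fwd(Xp, p[[paste0(rk, ".emb.proj.W")]],
                   p[[paste0(rk, ".emb.proj.b")]]) + P
    emb <- enc_layer_fwd(Xin, Xin, p, paste0(rk, ".emb.enc"),
                         cfg$n_heads_emb, proj_bias = TRUE)
    X_emb <- emb$out
    attn[[rk]] <- list(embedding = emb$attn_weights)
    prom_vecs[[rk]] <- X_emb[mid, ]
    rc <- list(Xp = Xp, Xin = Xin, emb = emb$cache, mid = mid, n_r = n_r)
    if (cfg$embedding_only) {
      vecs[[rk]] <- X_emb[mid, ]
    } else {
      Xcomp <- matrix(0, i_max + 1L, cfg$d_model)
      Xcomp[1L, ] <- X_emb[mid, ]
      pair_caches <- vector("list", n_act)
      pair_attn <- vector("list", n_act)
      for (i in seq_len(n_act)) {
        Mi <- example$pcres[[erk]][[i]]
        XHM <- lin_fwd(Mi, p[[paste0(rk, ".pair.proj.W")]],
                       p[[paste0(rk, ".pair.proj.b")]]) + P
        xq <- X_emb
        lcs <- vector("list", cfg$n_layers_pair)
        lattn <- vector("list", cfg$n_layers_pair)
        for (l in seq_len(cfg$n_layers_pair)) {
          lay <- enc_layer_fwd(xq, XHM, p, paste0(rk, ".pair.l", l),
                               cfg$n_heads_pair, proj_bias = FALSE)
          lcs[[l]] <- lay$cache
          lattn[[l]] <- lay$attn_weights
          xq <- lay$out
        }
        pair_caches[[i]] <- list(Mi = Mi, XHM = XHM, layers = lcs)
        pair_attn[[i]] <- lattn
        Xcomp[1L + i, ] <- xq[mid, ]
      }
      attn[[rk]]$pairwise <- pair_attn
      B <- matrix(0, i_max + 1L, i_max + 1L)
      B[1L, seq_len(i_max) + 1L] <- f
      key_mask <- if (cfg$use_pad_mask) {
        c(TRUE, seq_len(i_max) <= n_act)
      } else NULL
      xr <- Xcomp
      reg_caches <- vector("list", cfg$n_layers_reg)
      reg_attn <- vector("list", cfg$n_layers_reg)
      for (l in seq_len(cfg$n_layers_reg)) {
        bl <- if (cfg$bias_all_layers || l == 1L) B else NULL
        lay <- enc_layer_fwd(xr, xr, p, paste0(rk, ".reg.l", l),
                             cfg$n_heads_reg, proj_bias = FALSE,
                             bias_mat = bl, key_mask = key_mask,
                             gated = TRUE)
        reg_caches[[l]] <- lay$cache
        reg_attn[[l]] <- lay$attn_weights
        xr <- lay$out
      }
      attn[[rk]]$regulation <- reg_attn
      vecs[[rk]] <- xr[1L, ]
      rc$pairs <- pair_caches
      rc$reg <- reg_caches
      rc$Xcomp <- Xcomp
      rc$B <- B
      rc$key_mask <- key_mask
      rc$n_act <- n_act
    }
    caches[[rk]] <- rc
  }
  list(vec = unlist(vecs, use.names = FALSE),
       prom_vec = unlist(prom_vecs, use.names = FALSE),
       caches = if (keep_cache) caches else NULL,
       attn = attn,
       n_act = n_act)
}

# Backward through the backbone given d(vec); accumulates grads into `gr`.
backbone_bwd <- function(model, caches, dvec, gr) {
  cfg <- model$config
  p <- model$params
  d <- cfg$d_model
  off <- 0L
  for (r in cfg$resolutions) {
    rk <- res_key(r)
    rc <- caches[[rk]]
    dv <- dvec[(off + 1L):(off + d)]
    off <- off + d
    dX_emb <- matrix(0, rc$n_r, d)
    if (cfg$embedding_only) {
      dX_emb[rc$mid, ] <- dv
    } else {
      dXr <- matrix(0, cfg$i_max + 1L, d)
      dXr[1L, ] <- dv
      for (l in rev(seq_len(cfg$n_layers_reg))) {
        bk <- enc_layer_bwd(dXr, rc$reg[[l]], p, paste0(rk, ".reg.l", l), gr)
        dXr <- bk$dXq + bk$dXkv # self-attention: same input on both sides
      }
      dXcomp <- dXr
      dX_emb[rc$mid, ] <- dX_emb[rc$mid, ] + dXcomp[1L, ]
      for (i in seq_len(rc$n_act)) {
        pc <- rc$pairs[[i]]
        dxq <- matrix(0, rc$n_r, d)
        dxq[rc$mid, ] <- dXcomp[1L + i, ]
        dXHM <- matrix(0, rc$n_r, d)
        for (l in rev(seq_len(cfg$n_layers_pair))) {
          bk <- enc_layer_bwd(dxq, pc$layers[[l]], p,
                              paste0(rk, ".pair.l", l), gr)
          dxq <- bk$dXq
          dXHM <- dXHM + bk$dXkv
        }
        dX_emb <- dX_emb + dxq
        lin_bwd(dXHM, pc$Mi, p[[paste0(rk, ".pair.proj.W")]], gr,
                paste0(rk, ".pair.proj.W"), paste0(rk, ".pair.proj.b"))
      }
    }
    bk <- enc_layer_bwd(dX_emb, rc$emb, p, paste0(rk, ".emb.enc"), gr)
    dXin <- bk$dXq + bk$dXkv
    lin_bwd(dXin, rc$Xp, p[[paste0(rk, ".emb.proj.W")]], gr,
            paste0(rk, ".emb.proj.W"), paste0(rk, ".emb.proj.b"))
  }
  invisible(NULL)
}

head_fwd <- function(p, vec, prefix = "head") {
  z1 <- drop(vec %*% p[[paste0(prefix, ".W1")]]) + p[[paste0(prefix, ".b1")]]
  a1 <- relu(z1)
  out <- drop(a1 %*% p[[paste0(prefix, ".W2")]]) + p[[paste0(prefix, ".b2")]]
  list(out = out, z1 = z1, a1 = a1, vec = vec)
}

head_bwd <- function(p, cache, dout, gr, prefix = "head") {
  da1 <- drop(p[[paste0(prefix, ".W2")]] %*% dout)
  acc_grad(gr, paste0(prefix, ".W2"), cache$a1 %o% dout)
  acc_grad(gr, paste0(prefix, ".b2"), dout)
  dz1 <- da1 * (cache$z1 > 0)
  acc_grad(gr, paste0(prefix, ".W1"), cache$vec %o% dz1)
  acc_grad(gr, paste0(prefix, ".b1"), dz1)
  drop(p[[paste0(prefix, ".W1")]] %*% dz1)
}

#' Forward pass for one featurized gene
#'
#' Runs the three independent single-resolution stacks, concatenates their
#' regulatory vectors (TSS-bin embedding vectors for an embedding-only
#' model), and applies the fully-connected head. For the `"clf"` task the
#' output is two logits; for `"reg"` a single scalar.
#'
#' @param model A `chromattn_model` (task `"clf"` or `"reg"`).
#' @param example A featurized training example (see [featurize_dataset()]).
#' @param bundle If `TRUE`, also return the embedding bundle (concatenated
#'   multi-resolution promoter and regulatory vectors plus attention maps)
#'   used for interpretation.
#' @return `list(output = , bundle = )`; `bundle` is `NULL` unless requested.
#' @export
chromoformer_forward <- function(model, example, bundle = FALSE) {
  cfg <- model$config
  if (cfg$task == "diff")
    stop("use chromoformer_diff_forward() for the fold-change model")
  check_example(example, cfg)
  bb <- backbone_fwd(model, example)
  hd <- head_fwd(model$params, bb$vec)
  out <- list(output = hd$out, bundle = NULL)
  if (bundle) {
    out$bundle <- list(gene_id = example$gene_id,
                       promoter = bb$prom_vec,
                       regulatory = bb$vec,
                       attention = bb$attn,
                       n_pcres = example$n_pcres)
  }
  out
}

#' Siamese forward pass for fold-change prediction
#'
#' One shared backbone embeds the same gene featurized in two cell types;
#' the head consumes the concatenated embeddings and predicts the log2
#' fold-change, while a shared auxiliary regression head predicts each cell
#' type's absolute log2 expression. Swapping the two inputs therefore swaps
#' the two auxiliary outputs.
#'
#' @param model A `chromattn_model` with `task = "diff"`.
#' @param example_a,example_b The gene featurized in cell types A and B.
#' @return `list(fold_change = , aux_a = , aux_b = )`, three scalars.
#' @export
chromoformer_diff_forward <- function(model, example_a, example_b) {
  cfg <- model$config
  if (cfg$task != "diff") stop("model task must be 'diff'")
  check_example(example_a, cfg)
  check_example(example_b, cfg)
  ba <- backbone_fwd(model, example_a)
  bb <- backbone_fwd(model, example_b)
  main <- head_fwd(model$params, c(ba$vec, bb$vec), "head")
  aa <- head_fwd(model$params, ba$vec, "aux")
  ab <- head_fwd(model$params, bb$vec, "aux")
  list(fold_change = unname(main$out), aux_a = unname(aa$out),
       aux_b = unname(ab$out))
}

#' Drop signal channels from a featurized example
#'
#' Removes the named channels from the promoter and pCRE feature matrices
#' (the model input projection is sized to the remaining channels at build
#' time). Used for feature-ablation experiments such as removing the
#' elongation mark H3K36me3.
#'
#' @param example A featurized example carrying a `channels` attribute.
#' @param channels_to_drop Character vector, subset of the example's
#'   channels. Dropping every channel is an error.
#' @return The example restricted to the remaining channels.
#' @export
ablate_channels <- function(example, channels_to_drop) {
  ch <- example$channels
  if (is.null(ch)) stop("example does not carry channel names")
  if (!all(channels_to_drop %in% ch))
    stop("unknown channel(s): ",
         paste(setdiff(channels_to_drop, ch), collapse = ", "))
  keep <- !(ch %in% channels_to_drop)
  if (!any(keep)) stop("cannot drop every channel")
  example$promoter <- lapply(example$promoter,
                             function(M) M[, keep, drop = FALSE])
  example$pcres <- lapply(example$pcres, function(ml)
    lapply(ml, function(M) M[, keep, drop = FALSE]))
  example$channels <- ch[keep]
  example
}

#' Save / load a self-describing model checkpoint
#'
#' A checkpoint is a single file holding the weights, the full model
#' configuration, and optional featurization provenance (window, frequency
#' threshold, channel list, ...), so it can be reloaded and applied without
#' external context.
#'
#' @param model A `chromattn_model`.
#' @param path File path for the checkpoint.
#' @param provenance Optional named list recorded alongside the model.
#' @return `save_chromoformer()` returns `path` invisibly;
#'   `load_chromoformer()` returns the model.
#' @export
save_chromoformer <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "chromattn_model"))
  model$provenance <- provenance
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_chromoformer
#' @export
load_chromoformer <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "chromattn_model"))
    stop("not a chromattn model checkpoint: ", path)
  model
}

# ---- loss ----

# returns list(loss, dout) for one example's raw model output
loss_and_grad <- function(output, label, task) {
  if (task == "clf") {
    z <- output - max(output)
    p <- exp(z) / sum(exp(z))
    loss <- -log(max(p[label + 1L], 1e-12))
    dout <- p
    dout[label + 1L] <- dout[label + 1L] - 1
    list(loss = loss, dout = dout)
  } else {
    e <- unname(output - label)
    list(loss = e^2, dout = 2 * e)
  }
}

# full per-example gradient (used by the training loop and gradient checks)
example_loss_grad <- function(model, example, label, gr) {
  bb <- backbone_fwd(model, example, keep_cache = TRUE)
  hd <- head_fwd(model$params, bb$vec)
  lg <- loss_and_grad(hd$out, label, model$config$task)
  dvec <- head_bwd(model$params, hd, lg$dout, gr)
  backbone_bwd(model, bb$caches, dvec, gr)
  lg$loss
}

diff_loss_grad <- function(model, example_a, example_b, labels, gr) {
  # labels: c(fold_change, log2_expr_a, log2_expr_b); equal loss weights
  ba <- backbone_fwd(model, example_a, keep_cache = TRUE)
  bb <- backbone_fwd(model, example_b, keep_cache = TRUE)
  main <- head_fwd(model$params, c(ba$vec, bb$vec), "head")
  aa <- head_fwd(model$params, ba$vec, "aux")
  ab <- head_fwd(model$params, bb$vec, "aux")
  d <- length(ba$vec)
  l_main <- loss_and_grad(main$out, labels[1L], "reg")
  l_a <- loss_and_grad(aa$out, labels[2L], "reg")
  l_b <- loss_and_grad(ab$out, labels[3L], "reg")
  dcat <- head_bwd(model$params, main, l_main$dout, gr, "head")
  dva <- dcat[seq_len(d)] + head_bwd(model$params, aa, l_a$dout, gr, "aux")
  dvb <- dcat[d + seq_len(d)] + head_bwd(model$params, ab, l_b$dout, gr, "aux")
  backbone_bwd(model, ba$caches, dva, gr)
  backbone_bwd(model, bb$caches, dvb, gr)
  l_main$loss + l_a$loss + l_b$loss
}
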