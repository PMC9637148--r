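#' Sinusoidal positional encoding
#'
#' Builds the standard sinusoidal positional-encoding matrix added to binned
#' signal features before self-attention. Entry `P[i, 2k] = sin(i / 10000^(2k/d))`
#' and `P[i, 2k+1] = cos(i / 10000^(2k/d))` (0-based indices), so the inner
#' product of any two rows depends only on their positional distance, which is
#' what lets attention reason about relative genomic distance.
#'
#' @param n Number of positions (genomic bins).
#' @param d Embedding width; must be even.
#' @return An `n x d` numeric matrix.
#' @export
positional_encoding <- function(n, d) {
  if (d %% 2L != 0L) stop("positional encoding width `d` must be even")
  i <- 0:(n - 1L)
  k <- 0:(d / 2L - 1L)
  ang <- outer(i, 1 / 10000^(2 * k / d)) # n x d/2
  P <- matrix(0, n, d)
  P[, 2L * k + 1L] <- sin(ang)
  P[, 2L * k + 2L] <- cos(ang)
  P
}

# ---- elementwise helpers ----

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) (x > 0) * x

# fast row-wise addition of a length-ncol vector (column-major recycling)
add_rvec <- function(Y, b) Y + rep(b, each = nrow(Y))

# Row-wise softmax with optional key mask (FALSE columns excluded).
# Rows whose keys are all masked fall back to self-only attention when the
# matrix is square, otherwise to uniform weights (degenerate-softmax rule).
softmax_rows <- function(Z, key_mask = NULL) {
  if (!is.null(key_mask) && !all(key_mask)) {
    Z[, !key_mask] <- -Inf
  }
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  bad <- !is.finite(m)
  if (any(bad)) m[bad] <- 0
  E <- exp(Z - m)
  E[!is.finite(E)] <- 0
  s <- rowSums(E)
  zero <- s <= 0
  if (any(zero)) {
    for (r in which(zero)) {
      if (ncol(Z) == nrow(Z)) E[r, r] <- 1 else E[r, ] <- 1
    }
    s <- rowSums(E)
  }
  E / s
}

# d/dZ of softmax given A = softmax(Z) and upstream dA
softmax_rows_bwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(scale_dim) + gamma * bias) V`, optionally
#' gated elementwise by `sigmoid(gate)`. Masked key columns receive zero
#' weight; a query row with every key masked degenerates to self-only
#' attention (square case) rather than NaN.
#'
#' @param Q,K,V Query (`n_q x d`), key and value (`n_k x d`) matrices.
#' @param scale_dim Scalar used as `sqrt(scale_dim)` denominator (the per-head
#'   width).
#' @param bias Optional `n_q x n_k` additive bias (e.g. interaction
#'   frequencies), scaled by `gamma`.
#' @param gamma Scalar coefficient on `bias`.
#' @param gate Optional `n_q x d` pre-activation gate; the output is
#'   multiplied elementwise by `sigmoid(gate)`.
#' @param key_mask Optional logical vector of length `n_k`; `FALSE` keys are
#'   excluded from the softmax.
#' @return `list(output = , weights = )` where every unmasked weight row sums
#'   to 1.
#' @export
scaled_dot_attention <- function(Q, K, V, scale_dim, bias = NULL, gamma = 1,
                                 gate = NULL, key_mask = NULL) {
  Z <- tcrossprod(Q, K) / sqrt(scale_dim)
  if (!is.null(bias)) Z <- Z + gamma * bias
  A <- softmax_rows(Z, key_mask)
  out <- A %*% V
  if (!is.null(gate)) out <- out * sigmoid(gate)
  list(output = out, weights = A)
}

# ---- parameter initialisation ----

# torch-style uniform fan-in initialisation
init_mat <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
}

init_vec <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  stats::runif(d_out, -lim, lim)
}

# ---- gradient accumulation ----

new_grad_store <- function() new.env(parent = emptyenv())

acc_grad <- function(gr, name, g) {
  prev <- gr[[name]]
  gr[[name]] <- if (is.null(prev)) g else prev + g
  invisible(NULL)
}

grads_as_list <- function(gr) as.list(gr)

# ---- linear ----

lin_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- add_rvec(Y, b)
  Y
}

# returns dX and accumulates dW (and db) into `gr` under the given names
lin_bwd <- function(dY, X, W, gr, wname, bname = NULL) {
  acc_grad(gr, wname, crossprod(X, dY))
  if (!is.null(bname)) acc_grad(gr, bname, colSums(dY))
  tcrossprod(dY, W)
}

# ---- layer norm (per row, over features) ----

LN_EPS <- 1e-5

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- Xc * inv
  out <- add_rvec(xhat * rep(g, each = nrow(X)), b)
  list(out = out, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g, gr, prefix) {
  xhat <- cache$xhat
  acc_grad(gr, paste0(prefix, ".g"), colSums(dY * xhat))
  acc_grad(gr, paste0(prefix, ".b"), colSums(dY))
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  (dxhat - m1 - xhat * m2) * cache$inv
}

# ---- multi-head attention (heads concatenated; no output projection) ----
# Projections live in params as <prefix>.Wq/.Wk/.Wv (and .bq/.bk/.bv when
# proj_bias), plus <prefix>.Wg and <prefix>.gamma for the gated variant.

mha_fwd <- function(Xq, Xkv, params, prefix, n_heads, proj_bias = TRUE,
                    bias_mat = NULL, key_mask = NULL, gated = FALSE) {
  Wq <- params[[paste0(prefix, ".Wq")]]
  Wk <- params[[paste0(prefix, ".Wk")]]
  Wv <- params[[paste0(prefix, ".Wv")]]
  d_total <- ncol(Wq)
  dh <- d_total / n_heads
  Q <- Xq %*% Wq
  K <- Xkv %*% Wk
  V <- Xkv %*% Wv
  if (proj_bias) {
    Q <- add_rvec(Q, params[[paste0(prefix, ".bq")]])
    K <- add_rvec(K, params[[paste0(prefix, ".bk")]])
    V <- add_rvec(V, params[[paste0(prefix, ".bv")]])
  }
  G <- NULL
  gamma <- NULL
  if (gated) G <- Xq %*% params[[paste0(prefix, ".Wg")]]
  if (!is.null(bias_mat)) gamma <- params[[paste0(prefix, ".gamma")]]
  out <- matrix(0, nrow(Xq), d_total)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Z <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(bias_mat)) Z <- Z + gamma * bias_mat
    A <- softmax_rows(Z, key_mask)
    O <- A %*% V[, idx, drop = FALSE]
    if (gated) {
      sg <- sigmoid(G[, idx, drop = FALSE])
      heads[[h]] <- list(A = A, O_raw = O, sg = sg)
      O <- O * sg
    } else {
      heads[[h]] <- list(A = A)
    }
    out[, idx] <- O
  }
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, G = G,
                    heads = heads, dh = dh, n_heads = n_heads,
                    bias_mat = bias_mat, gamma = gamma, key_mask = key_mask,
                    proj_bias = proj_bias, gated = gated))
}

# returns list(dXq, dXkv); accumulates parameter grads
mha_bwd <- function(dOut, cache, params, prefix, gr) {
  dh <- cache$dh
  n_heads <- cache$n_heads
  Q <- cache$Q; K <- cache$K; V <- cache$V
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- matrix(0, nrow(K), ncol(K))
  dV <- matrix(0, nrow(V), ncol(V))
  dG <- if (cache$gated) matrix(0, nrow(Q), ncol(Q)) else NULL
  dgamma <- 0
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    hd <- cache$heads[[h]]
    dOh <- dOut[, idx, drop = FALSE]
    if (cache$gated) {
      sg <- hd$sg
      dG[, idx] <- dOh * hd$O_raw * sg * (1 - sg)
      dOh <- dOh * sg
    }
    A <- hd$A
    dA <- tcrossprod(dOh, V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dZ <- softmax_rows_bwd(dA, A)
    if (!is.null(cache$bias_mat)) dgamma <- dgamma + sum(dZ * cache$bias_mat)
    dQ[, idx] <- dZ %*% K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dZ, Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  if (!is.null(cache$bias_mat)) acc_grad(gr, paste0(prefix, ".gamma"), dgamma)
  dXq <- lin_bwd(dQ, cache$Xq, params[[paste0(prefix, ".Wq")]], gr,
                 paste0(prefix, ".Wq"))
  dXkv <- lin_bwd(dK, cache$Xkv, params[[paste0(prefix, ".Wk")]], gr,
                  paste0(prefix, ".Wk")) +
    lin_bwd(dV, cache$Xkv, params[[paste0(prefix, ".Wv")]], gr,
            paste0(prefix, ".Wv"))
  if (cache$proj_bias) {
    acc_grad(gr, paste0(prefix, ".bq"), colSums(dQ))
    acc_grad(gr, paste0(prefix, ".bk"), colSums(dK))
    acc_grad(gr, paste0(prefix, ".bv"), colSums(dV))
  }
  if (cache$gated) {
    dXq <- dXq + tcrossprod(dG, params[[paste0(prefix, ".Wg")]])
    acc_grad(gr, paste0(prefix, ".Wg"), crossprod(cache$Xq, dG))
  }
  list(dXq = dXq, dXkv = dXkv)
}

# ---- transformer encoder layer ----
# attn -> residual + LN -> position-wise FFN -> residual + LN
# params: <prefix>.attn.*, <prefix>.ln1.g/b, <prefix>.ffn.W1/b1/W2/b2,
#         <prefix>.ln2.g/b

enc_layer_fwd <- function(Xq, Xkv, params, prefix, n_heads, proj_bias = TRUE,
                          bias_mat = NULL, key_mask = NULL, gated = FALSE) {
  at <- mha_fwd(Xq, Xkv, params, paste0(prefix, ".attn"), n_heads,
                proj_bias = proj_bias, bias_mat = bias_mat,
                key_mask = key_mask, gated = gated)
  l1 <- ln_fwd(Xq + at$out, params[[paste0(prefix, ".ln1.g")]],
               params[[paste0(prefix, ".ln1.b")]])
  h1 <- l1$out
  z1 <- lin_fwd(h1, params[[paste0(prefix, ".ffn.W1")]],
                params[[paste0(prefix, ".ffn.b1")]])
  a1 <- relu(z1)
  f <- lin_fwd(a1, params[[paste0(prefix, ".ffn.W2")]],
               params[[paste0(prefix, ".ffn.b2")]])
  l2 <- ln_fwd(h1 + f, params[[paste0(prefix, ".ln2.g")]],
               params[[paste0(prefix, ".ln2.b")]])
  list(out = l2$out,
       cache = list(attn = at$cache, l1 = l1, l2 = l2, h1 = h1, z1 = z1,
                    a1 = a1),
       attn_weights = lapply(at$cache$heads, `[[`, "A"))
}

enc_layer_bwd <- function(dOut, cache, params, prefix, gr) {
  d2 <- ln_bwd(dOut, cache$l2, params[[paste0(prefix, ".ln2.g")]], gr,
               paste0(prefix, ".ln2"))
  # FFN branch
  da1 <- lin_bwd(d2, cache$a1, params[[paste0(prefix, ".ffn.W2")]], gr,
                 paste0(prefix, ".ffn.W2"), paste0(prefix, ".ffn.b2"))
  dz1 <- da1 * (cache$z1 > 0)
  dh1_ffn <- lin_bwd(dz1, cache$h1, params[[paste0(prefix, ".ffn.W1")]], gr,
                     paste0(prefix, ".ffn.W1"), paste0(prefix, ".ffn.b1"))
  dh1 <- d2 + dh1_ffn
  d1 <- ln_bwd(dh1, cache$l1, params[[paste0(prefix, ".ln1.g")]], gr,
               paste0(prefix, ".ln1"))
  at <- mha_bwd(d1, cache$attn, params, paste0(prefix, ".attn"), gr)
  list(dXq = d1 + at$dXq, dXkv = at$dXkv)
}

# parameter initialisation for one encoder layer
init_enc_layer <- function(params, prefix, d, d_ffn, proj_bias = TRUE,
                           gated = FALSE, gamma_init = NULL) {
  params[[paste0(prefix, ".attn.Wq")]] <- init_mat(d, d)
  params[[paste0(prefix, ".attn.Wk")]] <- init_mat(d, d)
  params[[paste0(prefix, ".attn.Wv")]] <- init_mat(d, d)
  if (proj_bias) {
    params[[paste0(prefix, ".attn.bq")]] <- init_vec(d, d)
    params[[paste0(prefix, ".attn.bk")]] <- init_vec(d, d)
    params[[paste0(prefix, ".attn.bv")]] <- init_vec(d, d)
  }
  if (gated) params[[paste0(prefix, ".attn.Wg")]] <- init_mat(d, d)
  if (!is.null(gamma_init)) params[[paste0(prefix, ".attn.gamma")]] <- gamma_init
  params[[paste0(prefix, ".ln1.g")]] <- rep(1, d)
  params[[paste0(prefix, ".ln1.b")]] <- rep(0, d)
  params[[paste0(prefix, ".ffn.W1")]] <- init_mat(d, d_ffn)
  params[[paste0(prefix, ".ffn.b1")]] <- init_vec(d, d_ffn)
  params[[paste0(prefix, ".ffn.W2")]] <- init_mat(d_ffn, d)
  params[[paste0(prefix, ".ffn.b2")]] <- init_vec(d_ffn, d)
  params[[paste0(prefix, ".ln2.g")]] <- rep(1, d)
  params[[paste0(prefix, ".ln2.b")]] <- rep(0, d)
  params
}
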