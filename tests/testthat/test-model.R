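test_that("analytic gradients match central differences", {
  cfg <- toy_config()
  model <- build_chromoformer(cfg, seed = 9)
  ex <- toy_example(cfg, n_pcres = 2)
  gr <- chromattn:::new_grad_store()
  loss0 <- chromattn:::example_loss_grad(model, ex, 1L, gr)
  grads <- chromattn:::grads_as_list(gr)
  expect_true(is.finite(loss0))
  # every parameter tensor received a gradient, and nothing else did
  expect_setequal(names(grads), names(model$params))
  eps <- 1e-6
  set.seed(4)
  check <- sample(names(model$params), 25)
  # always include the pieces with bespoke backward rules
  check <- union(check, grep("gamma|Wg|ln1\\.g|proj\\.W",
                             names(model$params), value = TRUE)[1:8])
  for (nm in check) {
    v <- model$params[[nm]]
    i <- sample(length(v), 1)
    mp <- model; mp$params[[nm]][i] <- v[i] + eps
    mm <- model; mm$params[[nm]][i] <- v[i] - eps
    lp <- chromattn:::example_loss_grad(mp, ex, 1L,
                                        chromattn:::new_grad_store())
    lm <- chromattn:::example_loss_grad(mm, ex, 1L,
                                        chromattn:::new_grad_store())
    num <- (lp - lm) / (2 * eps)
    # relative error with an absolute floor (tiny gradients hit the
    # precision limit of central differences)
    err <- abs(grads[[nm]][i] - num) / max(1e-3, abs(num))
    expect_lt(err, 1e-5, label = paste("grad", nm))
  }
})

test_that("forward pass has the task-specific output arity", {
  cfg <- toy_config(task = "clf")
  model <- build_chromoformer(cfg, 1)
  ex <- toy_example(cfg, 1)
  expect_length(chromoformer_forward(model, ex)$output, 2L)
  cfg_r <- toy_config(task = "reg")
  expect_length(
    chromoformer_forward(build_chromoformer(cfg_r, 1), ex)$output, 1L)
})

test_that("forward pass is deterministic and promoter-only without pCREs", {
  cfg <- toy_config()
  model <- build_chromoformer(cfg, 5)
  ex0 <- toy_example(cfg, n_pcres = 0)
  o1 <- chromoformer_forward(model, ex0)$output
  o2 <- chromoformer_forward(model, ex0)$output
  expect_identical(o1, o2)
  # with zero interactions the prediction depends on promoter features only
  ex0b <- ex0
  ex0b$freq <- numeric(cfg$i_max)
  expect_identical(chromoformer_forward(model, ex0b)$output, o1)
})

test_that("regulation module is permutation-invariant over pCRE rows", {
  cfg <- toy_config(i_max = 3L)
  model <- build_chromoformer(cfg, 11)
  ex <- toy_example(cfg, n_pcres = 3, freq = c(3.1, 2.4, 1.8))
  base <- chromoformer_forward(model, ex, bundle = TRUE)$bundle$regulatory
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) {
    exp_ <- ex
    for (r in names(ex$pcres)) exp_$pcres[[r]] <- ex$pcres[[r]][pm]
    exp_$freq <- ex$freq[pm]
    out <- chromoformer_forward(model, exp_, bundle = TRUE)$bundle$regulatory
    expect_lt(max(abs(out - base)), 1e-5)
  }
})

test_that("freezing gamma at zero removes all dependence on frequencies", {
  cfg <- toy_config()
  model <- build_chromoformer(cfg, 3)
  for (nm in grep("gamma", names(model$params), value = TRUE))
    model$params[[nm]] <- 0
  ex1 <- toy_example(cfg, 2, freq = c(3.5, 2.0))
  ex2 <- ex1
  ex2$freq <- c(9.9, 5.5, 0)
  expect_equal(chromoformer_forward(model, ex1)$output,
               chromoformer_forward(model, ex2)$output, tolerance = 1e-12)
})

test_that("with gamma > 0 raising f_j raises the row-0 weight on column j", {
  set.seed(8)
  n <- 4; d <- 6
  Q <- matrix(rnorm(n * d), n, d); K <- matrix(rnorm(n * d), n, d)
  V <- matrix(rnorm(n * d), n, d)
  mk_bias <- function(f) {
    B <- matrix(0, n, n); B[1, 2:n] <- f; B
  }
  f <- c(1, 2, 3)
  w_lo <- scaled_dot_attention(Q, K, V, d, bias = mk_bias(f), gamma = 0.8)
  f_hi <- f; f_hi[2] <- f[2] + 1
  w_hi <- scaled_dot_attention(Q, K, V, d, bias = mk_bias(f_hi), gamma = 0.8)
  expect_gt(w_hi$weights[1, 3], w_lo$weights[1, 3])
  # other row-0 weights must shrink (softmax mass conservation)
  expect_lt(w_hi$weights[1, 2], w_lo$weights[1, 2])
})

test_that("embedding-only and intact models share the promoter encoder", {
  cfg <- toy_config()
  cfg_e <- toy_config(embedding_only = TRUE)
  m_full <- build_chromoformer(cfg, seed = 21)
  m_emb <- build_chromoformer(cfg_e, seed = 22)
  # copy the promoter-encoder weights: the two variants run the same code
  emb_names <- grep("\\.emb\\.", names(m_emb$params), value = TRUE)
  for (nm in emb_names) m_emb$params[[nm]] <- m_full$params[[nm]]
  ex <- toy_example(cfg, 2)
  b_full <- chromoformer_forward(m_full, ex, bundle = TRUE)$bundle
  b_emb <- chromoformer_forward(m_emb, ex, bundle = TRUE)$bundle
  expect_equal(b_full$promoter, b_emb$promoter, tolerance = 1e-12)
  # for the embedding-only variant that vector IS the regulatory input
  expect_equal(b_emb$regulatory, b_emb$promoter, tolerance = 1e-12)
})

test_that("invalid configurations are rejected at build time", {
  expect_error(toy_config(d_model = 10L, n_heads_emb = 4L), "divisible")
  expect_error(toy_config(d_head_reg = 3L), "divisible")
  expect_error(toy_config(resolutions = c(48L)), "even bin count")
  expect_error(toy_config(window = 250L), "divisible by every resolution")
})

test_that("channel ablation shrinks the input width and preserves content", {
  cfg <- toy_config()
  ex <- toy_example(cfg, 1)
  ex1 <- ablate_channels(ex, "M2")
  expect_equal(ex1$channels, c("M1", "M3"))
  expect_equal(ncol(ex1$promoter[[1]]), 2L)
  expect_equal(ex1$promoter[[1]][, "M1"], ex$promoter[[1]][, "M1"])
  ex2 <- ablate_channels(ex, c("M1", "M3"))
  expect_equal(ncol(ex2$promoter[[1]]), 1L)
  expect_error(ablate_channels(ex, paste0("M", 1:3)), "every channel")
  expect_error(ablate_channels(ex, "H3K4me9"), "unknown")
  # dropping nothing is the identity
  expect_equal(ablate_channels(ex, character(0)), ex)
})

test_that("checkpoints round-trip with configuration and provenance", {
  cfg <- toy_config()
  model <- build_chromoformer(cfg, 5)
  path <- tempfile(fileext = ".rds")
  save_chromoformer(model, path,
                    provenance = list(window = 240L, threshold = 1.5))
  back <- load_chromoformer(path)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
  expect_equal(back$provenance$threshold, 1.5)
  ex <- toy_example(cfg, 1)
  expect_identical(chromoformer_forward(back, ex)$output,
                   chromoformer_forward(model, ex)$output)
  bad <- tempfile(); saveRDS(1:3, bad)
  expect_error(load_chromoformer(bad), "checkpoint")
})

test_that("Siamese fold-change model is symmetric in its auxiliary heads", {
  cfg <- toy_config(task = "diff")
  model <- build_chromoformer(cfg, 13)
  exa <- toy_example(cfg, 2, seed = 31)
  exb <- toy_example(cfg, 1, seed = 32)
  o_ab <- chromoformer_diff_forward(model, exa, exb)
  o_ba <- chromoformer_diff_forward(model, exb, exa)
  expect_length(unlist(o_ab), 3L)
  expect_equal(o_ab$aux_a, o_ba$aux_b, tolerance = 1e-12)
  expect_equal(o_ab$aux_b, o_ba$aux_a, tolerance = 1e-12)
  # identical inputs give identical auxiliary outputs
  o_aa <- chromoformer_diff_forward(model, exa, exa)
  expect_equal(o_aa$aux_a, o_aa$aux_b, tolerance = 1e-12)
  # gradients of the Siamese loss check out numerically
  gr <- chromattn:::new_grad_store()
  l0 <- chromattn:::diff_loss_grad(model, exa, exb, c(0.7, 1.2, 0.5), gr)
  grads <- chromattn:::grads_as_list(gr)
  eps <- 1e-6
  set.seed(6)
  for (nm in sample(names(model$params), 8)) {
    i <- sample(length(model$params[[nm]]), 1)
    mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    lp <- chromattn:::diff_loss_grad(mp, exa, exb, c(0.7, 1.2, 0.5),
                                     chromattn:::new_grad_store())
    lm <- chromattn:::diff_loss_grad(mm, exa, exb, c(0.7, 1.2, 0.5),
                                     chromattn:::new_grad_store())
    num <- (lp - lm) / (2 * eps)
    err <- abs(grads[[nm]][i] - num) / max(1e-3, abs(num))
    expect_lt(err, 1e-5, label = paste("diff grad", nm))
  }
})
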