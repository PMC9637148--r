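test_that("attention extraction yields six promoter maps per gene", {
  # three resolutions x two heads, mirroring the full-scale setup
  cfg <- model_config(channels = paste0("M", 1:3), window = 240L,
                      resolutions = c(40L, 60L, 120L), d_model = 8L,
                      n_heads_emb = 2L, d_ffn_emb = 8L, n_layers_pair = 1L,
                      d_head_pair = 4L, d_ffn_pair = 8L, n_layers_reg = 2L,
                      d_head_reg = 2L, d_ffn_reg = 8L, i_max = 3L,
                      head_hidden = 6L)
  model <- build_chromoformer(cfg, 2)
  ex <- toy_example(cfg, 2)
  rec <- extract_attention(model, ex, modules = "embedding")
  expect_length(rec, 6L)
  all_rec <- extract_attention(model, ex)
  for (r in all_rec) {
    if (r$module == "regulation") {
      # rows over unmasked keys sum to 1; masked keys carry no weight
      mask <- c(TRUE, TRUE, TRUE, FALSE)
      expect_true(all(abs(rowSums(r$weights) - 1) < 1e-5))
      expect_true(all(r$weights[, !mask] == 0))
    } else {
      expect_true(all(abs(rowSums(r$weights) - 1) < 1e-5))
    }
  }
  # TSS-row profile is the row of the TSS bin
  r1 <- rec[[1]]
  mid <- nrow(r1$weights) / 2 + 1
  expect_equal(r1$tss_profile, r1$weights[mid, ])
})

test_that("PCRI is zero for identical embeddings and matches hand toys", {
  expect_equal(compute_pcri(list(promoter = c(1, 2, 3),
                                 regulatory = c(1, 2, 3)))$pcri, 0)
  # 2-dim toy: u = (1,-1), v = (-1,1); sample sd = sqrt(2), so the
  # standardized vectors are +/- (1,-1)/sqrt(2) and the distance is 2
  p <- compute_pcri(list(promoter = c(1, -1), regulatory = c(-1, 1)))
  expect_equal(p$pcri, 2, tolerance = 1e-12)
  expect_false(p$degenerate)
  # zero-variance embedding is flagged, not an error
  dg <- compute_pcri(list(promoter = c(1, 1), regulatory = c(0, 2)))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$pcri))
})

test_that("PCRI is invariant to per-vector affine transforms", {
  set.seed(21)
  u <- rnorm(24); v <- rnorm(24)
  base <- compute_pcri(list(promoter = u, regulatory = v))$pcri
  for (i in 1:5) {
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    c_ <- runif(1, 0.1, 5); d_ <- rnorm(1, 0, 10)
    p <- compute_pcri(list(promoter = a * u + b,
                           regulatory = c_ * v + d_))$pcri
    expect_equal(p, base, tolerance = 1e-9)
  }
})

test_that("PCRI normalization z-scores within cell type and is idempotent", {
  tab <- data.frame(gene_id = c("g1", "g2"), cell_type = "A",
                    pcri = c(1, 3))
  n1 <- normalize_pcri(tab)
  expect_equal(n1$normalized_pcri, c(-1, 1))
  # per-cell-type mean 0 / unit population sd on random tables, idempotence
  set.seed(31)
  tab2 <- data.frame(gene_id = rep(paste0("g", 1:20), 2),
                     cell_type = rep(c("A", "B"), each = 20),
                     pcri = rgamma(40, 2))
  n2 <- normalize_pcri(tab2)
  for (ct in c("A", "B")) {
    x <- n2$normalized_pcri[n2$cell_type == ct]
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-12)
  }
  n3 <- normalize_pcri(transform(n2, pcri = normalized_pcri))
  expect_equal(n3$normalized_pcri, n2$normalized_pcri, tolerance = 1e-12)
  tabc <- data.frame(gene_id = c("g1", "g2"), cell_type = "A",
                     pcri = c(2, 2))
  expect_warning(nc <- normalize_pcri(tabc), "constant")
  expect_equal(nc$normalized_pcri, c(0, 0))
})

test_that("variance ranking orders genes by cross-cell-type variability", {
  tab <- data.frame(
    gene_id = rep(c("flat", "mid", "wild"), each = 3),
    cell_type = rep(c("A", "B", "C"), 3),
    normalized_pcri = c(0.5, 0.5, 0.5, 0, 1, 0, -2, 2, 0))
  r <- rank_variable_genes(tab, top_n = 10)
  expect_equal(r, c("wild", "mid", "flat"))
  expect_equal(rank_variable_genes(tab, top_n = 2), c("wild", "mid"))
  tab_miss <- tab[-1, ]
  expect_warning(r2 <- rank_variable_genes(tab_miss, 10), "missing")
  expect_false("flat" %in% r2)
})

test_that("PCRI clustering is average-linkage on correlation distance", {
  set.seed(41)
  base <- rnorm(30)
  mat <- cbind(A = base + rnorm(30, 0, 0.01),
               B = base + rnorm(30, 0, 0.01),
               C = -base + rnorm(30, 0, 0.01),
               D = rnorm(30))
  rownames(mat) <- paste0("g", 1:30)
  cl <- cluster_pcri(mat)
  # the two nearly identical cell types merge first, at height ~0
  m1 <- cl$cell_types$merge[1, ]
  expect_setequal(abs(m1), c(1, 2)) # A and B are leaves 1 and 2
  expect_lt(cl$cell_types$height[1], 0.01)
  # anti-correlated columns sit at distance ~2
  expect_equal(max(1 - cor(mat)[1, 3], 1 - cor(mat)[2, 3]), 2,
               tolerance = 0.01)
  # brute-force average-linkage oracle on a 4-item toy
  d <- stats::as.dist(1 - cor(mat))
  D <- as.matrix(d)
  # first merge by the oracle: the closest pair
  idx <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  expect_setequal(abs(cl$cell_types$merge[1, ]), sort(idx))
  # its height equals the pair distance
  expect_equal(cl$cell_types$height[1], min(D[D > 0]), tolerance = 1e-12)
  # second merge height equals the average distance to the formed cluster
  rest <- setdiff(1:4, idx)
  avg <- vapply(rest, function(i) mean(D[i, idx]), numeric(1))
  h2 <- sort(c(avg, D[rest[1], rest[2]]))[1]
  expect_equal(cl$cell_types$height[2], h2, tolerance = 1e-12)
  # zero-variance column excluded with a warning
  mat2 <- cbind(mat, E = rep(1, 30))
  expect_warning(cluster_pcri(mat2), "zero-variance")
  expect_error(cluster_pcri(cbind(mat[, 1], NA)), "missing")
})

test_that("dose-response summarises PCRI by annotated-pCRE count", {
  pcri <- data.frame(gene_id = paste0("g", 1:6),
                     pcri = c(1, 1.2, 2, 2.4, 3, 3.3))
  ann <- data.frame(gene_id = c("g2", "g3", "g3", "g5", "g5", "g5",
                                "g6", "g6", "g6"),
                    annotated = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                  TRUE, TRUE, FALSE))
  expr <- setNames(c(1, 2, 3, 4, 5, 6), pcri$gene_id)
  dr <- pcre_dose_response(pcri, ann, expression = expr,
                           all_genes = pcri$gene_id)
  # zero-count group present (g1, g4 have no annotated pCRE)
  expect_true(0 %in% dr$table$count)
  expect_equal(dr$table$n_genes[dr$table$count == 0], 2L)
  # counts follow the annotation sums
  expect_equal(dr$table$count, c(0, 1, 2, 3))
  expect_gt(dr$spearman_pcri, 0)
  # empty annotation on an empty universe gives an empty table
  dr0 <- pcre_dose_response(pcri[0, ], data.frame(gene_id = character(),
                                                  annotated = logical()),
                            all_genes = character())
  expect_equal(nrow(dr0$table), 0L)
})
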