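test_that("binned signals follow the log2 mean-depth definition", {
  # constant depth 1 everywhere: log2(1 + 1) = 1 in every bin
  trk <- coverage_track(data.frame(chrom = "c1", start = 0, end = 100000,
                                   depth = 1))
  v <- bin_signals(trk, "c1", center = 50000, window = 40000,
                   bin_size = 2000)
  expect_length(v, 20L)
  expect_equal(v, rep(1, 20), tolerance = 1e-12)
  expect_length(bin_signals(trk, "c1", 50000, 40000, 100), 400L)
  expect_length(bin_signals(trk, "c1", 50000, 40000, 500), 80L)
  # depth 3 over exactly half a bin, 1 over the other half: mean 2,
  # log2(2 + 1) = log2(3)
  trk2 <- coverage_track(data.frame(chrom = "c1",
                                    start = c(0, 1000),
                                    end = c(1000, 2000),
                                    depth = c(3, 1)))
  v2 <- bin_signals(trk2, "c1", center = 1000, window = 2000,
                    bin_size = 2000)
  expect_equal(v2, log2(3), tolerance = 1e-12)
  # off-chromosome positions read as depth 0
  v3 <- bin_signals(trk2, "c1", center = 0, window = 2000, bin_size = 1000)
  expect_equal(v3[1], 0)
  expect_error(bin_signals(trk, "c1", 0, 1000, 300), "divisible")
})

test_that("overlapping depth segments add up", {
  trk <- coverage_track(data.frame(chrom = "c1", start = c(0, 50),
                                   end = c(100, 150), depth = c(1, 2)))
  # [50,100) has depth 3
  v <- bin_signals(trk, "c1", center = 75, window = 50, bin_size = 50,
                   pseudocount = 0)
  expect_equal(v, log2(3), tolerance = 1e-12)
})

test_that("promoter features localise a spike and mirror on minus strand", {
  # single spike 5 kbp right of the TSS (in genomic coordinates)
  tss <- 100000
  spike <- coverage_track(data.frame(chrom = "c1", start = tss + 5000,
                                     end = tss + 5100, depth = 40))
  flat <- coverage_track(data.frame(chrom = "c1", start = 0, end = 3e5,
                                    depth = 0))
  tracks <- list(A = spike, B = flat)
  plus <- build_promoter_features(list(chrom = "c1", tss = tss,
                                       strand = "+"),
                                  tracks, resolutions = 2000)
  M <- plus[["2000"]]
  # TSS bin is 0-based index 10; +5 kbp lands in 0-based bin 12
  expect_equal(which.max(M[, "A"]), 13L) # 1-based
  minus <- build_promoter_features(list(chrom = "c1", tss = tss,
                                        strand = "-"),
                                   tracks, resolutions = 2000)
  # reversal: genomically-right spike appears mirrored at 0-based bin 7
  expect_equal(which.max(minus[["2000"]][, "A"]), 8L)
  # all-zero tracks give all-zero matrices (log2(0 + 1) = 0)
  expect_true(all(minus[["2000"]][, "B"] == 0))
  expect_error(
    build_promoter_features(list(chrom = "c1", tss = tss, strand = "+"),
                            tracks, channels = c("A", "C")),
    "C")
})

test_that("strand reversal equals mirroring the track around the TSS", {
  set.seed(10)
  tss <- 50000
  segs <- data.frame(chrom = "c1",
                     start = seq(tss - 20000, tss + 19900, by = 100),
                     end = seq(tss - 19900, tss + 20000, by = 100),
                     depth = rpois(400, 3))
  mirrored <- data.frame(chrom = "c1",
                         start = 2 * tss - segs$end,
                         end = 2 * tss - segs$start,
                         depth = segs$depth)
  tr <- list(A = coverage_track(segs))
  tr_m <- list(A = coverage_track(mirrored))
  plus <- build_promoter_features(list(chrom = "c1", tss = tss,
                                       strand = "+"), tr,
                                  resolutions = c(100, 500, 2000))
  minus <- build_promoter_features(list(chrom = "c1", tss = tss,
                                        strand = "-"), tr_m,
                                   resolutions = c(100, 500, 2000))
  for (r in names(plus)) expect_equal(minus[[r]], plus[[r]])
})

test_that("pCRE matrices are center-aligned, zero-padded and truncated", {
  trk <- list(A = coverage_track(data.frame(chrom = "c1", start = 0,
                                            end = 2e5, depth = 3)))
  # 4 kbp fragment at 2 kbp resolution in a 20-bin target:
  # 2 signal bins at 0-based indices 9-10
  M <- build_pcre_features(list(chrom = "c1", start = 100000, end = 104000),
                           trk, resolution = 2000, target_bins = 20)
  expect_equal(dim(M), c(20L, 1L))
  expect_true(all(M[10:11, ] == 2)) # log2(3 + 1)
  expect_true(all(M[-(10:11), ] == 0))
  # fragment wider than the window: exactly 20 centered bins retained
  M2 <- build_pcre_features(list(chrom = "c1", start = 50000, end = 98000),
                            trk, resolution = 2000, target_bins = 20)
  expect_equal(dim(M2), c(20L, 1L))
  expect_true(all(M2 == 2))
  # fragment exactly the window width: no padding columns
  M3 <- build_pcre_features(list(chrom = "c1", start = 60000, end = 100000),
                            trk, resolution = 2000, target_bins = 20)
  expect_true(all(M3 == 2))
  expect_error(
    build_pcre_features(list(chrom = "c1", start = 5, end = 5), trk,
                        resolution = 2000, target_bins = 20),
    "degenerate")
})

test_that("interaction selection filters, ranks and truncates", {
  cand <- data.frame(chrom = "c1", start = c(10, 20, 30),
                     end = c(15, 25, 35), norm_freq = c(2.0, 1.4, 3.1))
  s <- select_interactions(cand, threshold = 1.5, i_max = 8)
  expect_equal(s$pcres$norm_freq, c(3.1, 2.0))
  expect_equal(s$freq, c(3.1, 2.0, rep(0, 6)))
  # exactly at the threshold is excluded (strictly greater than)
  expect_equal(nrow(select_interactions(
    data.frame(chrom = "c", start = 1, end = 2, norm_freq = 1.5))$pcres), 0L)
  # ten passing candidates: the eight strongest are kept
  cand10 <- data.frame(chrom = "c1", start = 1:10 * 100,
                       end = 1:10 * 100 + 50, norm_freq = 2 + (1:10) / 10)
  s10 <- select_interactions(cand10, 1.5, 8)
  expect_equal(nrow(s10$pcres), 8L)
  expect_equal(s10$pcres$norm_freq, sort(cand10$norm_freq,
                                         decreasing = TRUE)[1:8])
  # empty input is valid
  s0 <- select_interactions(NULL, 1.5, 8)
  expect_equal(s0$freq, numeric(8))
  expect_error(select_interactions(
    data.frame(chrom = "c", start = 1, end = 2, norm_freq = NaN)), "finite")
})

test_that("interaction selection is stable under input permutation", {
  set.seed(12)
  cand <- data.frame(chrom = "c1", start = sample(1000, 12),
                     end = sample(1000, 12) + 2000,
                     norm_freq = round(runif(12, 1, 4), 1)) # forced ties
  ref <- select_interactions(cand, 1.5, 8)
  for (i in 1:5) {
    s <- select_interactions(cand[sample(nrow(cand)), ], 1.5, 8)
    expect_equal(s$pcres, ref$pcres)
  }
  # idempotence: re-selecting the retained set returns it unchanged
  again <- select_interactions(ref$pcres, 1.5, 8)
  expect_equal(again$pcres$norm_freq, ref$pcres$norm_freq)
})

test_that("labels follow the median-split, log2 and fold-change rules", {
  tab <- data.frame(gene_id = letters[1:4], cellA = c(0, 1, 2, 3))
  expect_equal(unname(derive_labels(tab, "clf")), c(0, 0, 1, 1))
  # ties: nothing strictly above the median gets label 1
  tab2 <- data.frame(gene_id = letters[1:3], cellA = c(5, 5, 5))
  expect_equal(unname(derive_labels(tab2, "clf")), c(0, 0, 0))
  expect_equal(unname(derive_labels(tab, "reg")), log2(c(0, 1, 2, 3) + 1))
  tabd <- data.frame(gene_id = "g", cellA = 4, cellB = 1)
  expect_equal(unname(derive_labels(tabd, "diff",
                                    cell_pair = c("cellA", "cellB"),
                                    pseudocount = 0)), 2)
  expect_error(derive_labels(tabd, "diff"), "cell_pair")
  # balance: with all-distinct values the split is within one gene
  set.seed(3)
  tab3 <- data.frame(gene_id = paste0("g", 1:101), cellA = runif(101))
  l <- derive_labels(tab3, "clf")
  expect_lte(abs(sum(l == 1) - sum(l == 0)), 1)
})

test_that("cross-validation folds are chromosome-disjoint and balanced", {
  g4 <- data.frame(gene_id = paste0("g", 1:40),
                   chrom = rep(paste0("chr", 1:4), each = 10))
  f <- make_cv_folds(g4, k = 4, seed = 1)
  sizes <- lengths(f$folds)
  expect_equal(sort(sizes), rep(10L, 4)) # one chromosome per fold
  # partition: pairwise disjoint and exhaustive
  all_ids <- unlist(f$folds)
  expect_setequal(all_ids, g4$gene_id)
  expect_equal(anyDuplicated(all_ids), 0L)
  # chromosome-disjointness on a ragged layout
  set.seed(5)
  g <- data.frame(gene_id = paste0("g", 1:60),
                  chrom = sample(paste0("chr", 1:7), 60, replace = TRUE))
  f2 <- make_cv_folds(g, k = 3, seed = 2)
  for (ch in unique(g$chrom)) {
    in_fold <- vapply(f2$folds, function(ids)
      any(g$gene_id[g$chrom == ch] %in% ids), logical(1))
    expect_equal(sum(in_fold), 1L)
  }
  # greedy balance: counts 10/10/1/1 over two folds -> {11, 11}
  g3 <- data.frame(gene_id = paste0("g", 1:22),
                   chrom = rep(c("c1", "c2", "c3", "c4"),
                               times = c(10, 10, 1, 1)))
  for (sd in 1:5) {
    f3 <- make_cv_folds(g3, k = 2, seed = sd)
    expect_equal(sort(lengths(f3$folds)), c(11L, 11L))
  }
  expect_error(make_cv_folds(g4, k = 5), "chromosomes")
  expect_error(make_cv_folds(g4, k = 1), "k must be")
  # reproducibility under a fixed seed
  expect_identical(make_cv_folds(g, k = 3, seed = 9),
                   make_cv_folds(g, k = 3, seed = 9))
})
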