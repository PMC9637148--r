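#' Read gene annotation (BED6 or GTF)
#'
#' Returns one record per gene with its TSS as a 0-based coordinate. For
#' BED6 the TSS is `chromStart` for `+` genes and `chromEnd` for `-` genes;
#' GTF records are converted from 1-based closed to 0-based half-open on
#' read and follow the same rule (TSS = start for `+`, end for `-`).
#'
#' @param path Path to a BED6 or GTF file.
#' @param format `"bed"` or `"gtf"`; guessed from the file extension by
#'   default.
#' @return A data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("every gene must have strand '+' or '-'")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  tss <- ifelse(strand == "+", start0, end0)
  ids <- if (!is.null(gr$name)) gr$name else gr$gene_id
  if (is.null(ids)) stop("gene identifiers not found (BED name / GTF gene_id)")
  df <- data.frame(gene_id = as.character(ids), chrom = chrom,
                   tss = as.integer(tss), strand = strand,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) {
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
  }
  df
}

#' Read a promoter-pCRE interaction table
#'
#' @param path TSV with header `gene_id chrom start end norm_freq`
#'   (0-based half-open intervals, normalized pcHi-C frequencies).
#' @return A data.frame.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "norm_freq")
  if (!all(need %in% names(df)))
    stop("interaction table must have columns: ", paste(need, collapse = " "))
  df
}

#' Read a gene expression table
#'
#' @param path TSV with a `gene_id` column and one RPKM column per cell
#'   type.
#' @return A data.frame.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression table needs a gene_id column")
  df
}

#' Multi-resolution promoter feature matrices
#'
#' Bins each signal channel over the window around the TSS at every
#' resolution and stacks channels as columns, giving one `n_r x C`
#' log2-signal matrix per resolution (400 x C, 80 x C and 20 x C for the
#' default 40 kbp window). For minus-strand genes the bin order is reversed
#' so that increasing bin index always points downstream of transcription
#' (set `strand_aware = FALSE` for strand-agnostic windows).
#'
#' @param gene A list or one-row data.frame with `chrom`, `tss`, `strand`.
#' @param tracks Named list of [coverage_track()]s, one per channel.
#' @param channels Channel names to use (all tracks by default); each must
#'   be present in `tracks`.
#' @param window,resolutions,pseudocount See [model_config()] and
#'   [bin_signals()].
#' @param strand_aware Reverse minus-strand matrices (default `TRUE`).
#' @return Named list of matrices, one per resolution (names are the bin
#'   sizes).
#' @export
build_promoter_features <- function(gene, tracks, channels = names(tracks),
                                    window = 40000,
                                    resolutions = c(100, 500, 2000),
                                    pseudocount = 1, strand_aware = TRUE) {
  missing_ch <- setdiff(channels, names(tracks))
  if (length(missing_ch) > 0)
    stop("missing coverage track for channel(s): ",
         paste(missing_ch, collapse = ", "))
  out <- list()
  for (r in resolutions) {
    M <- vapply(channels, function(ch)
      bin_signals(tracks[[ch]], gene$chrom, gene$tss, window, r, pseudocount),
      numeric(window / r))
    if (strand_aware && gene$strand == "-") M <- M[rev(seq_len(nrow(M))), ,
                                                   drop = FALSE]
    colnames(M) <- channels
    out[[as.character(r)]] <- M
  }
  out
}

#' Zero-padded pCRE feature matrix
#'
#' Bins the pCRE interval with its own non-overlapping bins, then
#' center-aligns the resulting matrix within `target_bins` rows, appending
#' zero rows on both sides so the shape matches the promoter matrix at the
#' same resolution. Intervals wider than the window are center-truncated.
#'
#' @param interval List or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param tracks,channels,pseudocount As in [build_promoter_features()].
#' @param resolution Bin size in bp.
#' @param target_bins Promoter bin count at this resolution.
#' @return A `target_bins x C` matrix; padded rows are exactly zero.
#' @export
build_pcre_features <- function(interval, tracks, channels = names(tracks),
                                resolution, target_bins, pseudocount = 1) {
  if (interval$end <= interval$start)
    stop("degenerate interval: end must exceed start")
  M <- vapply(channels, function(ch)
    bin_signals_interval(tracks[[ch]], interval$chrom, interval$start,
                         interval$end, resolution, pseudocount),
    numeric(ceiling((interval$end - interval$start) / resolution)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L,
                                   dimnames = list(NULL, channels))
  n <- nrow(M)
  if (n > target_bins) { # center-truncate oversized fragments
    lead <- (n - target_bins) %/% 2L
    M <- M[(lead + 1L):(lead + target_bins), , drop = FALSE]
    n <- target_bins
  }
  pad_left <- (target_bins - n) %/% 2L
  pad_right <- target_bins - n - pad_left
  out <- rbind(matrix(0, pad_left, ncol(M)), M,
               matrix(0, pad_right, ncol(M)))
  colnames(out) <- channels
  out
}

#' Filter and rank candidate interactions
#'
#' Keeps candidates with normalized frequency strictly above `threshold`,
#' orders them by decreasing frequency (ties broken by ascending genomic
#' start for determinism) and truncates to the `i_max` strongest.
#'
#' @param candidates data.frame with columns `chrom`, `start`, `end`,
#'   `norm_freq` (an empty data.frame is valid).
#' @param threshold Inclusion threshold on the normalized frequency
#'   (default 1.5, i.e. interaction/background ratio above 1.5).
#' @param i_max Maximum number of retained pCREs (default 8).
#' @return `list(pcres = data.frame of retained intervals in rank order,
#'   freq = numeric(i_max) zero-filled beyond the retained count)`.
#' @export
select_interactions <- function(candidates, threshold = 1.5, i_max = 8L) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(pcres = data.frame(chrom = character(), start = integer(),
                                   end = integer(), norm_freq = numeric()),
                freq = numeric(i_max)))
  }
  if (any(!is.finite(candidates$norm_freq)))
    stop("interaction frequencies must be finite")
  keep <- candidates[candidates$norm_freq > threshold, , drop = FALSE]
  keep <- keep[order(-keep$norm_freq, keep$start), , drop = FALSE]
  if (nrow(keep) > i_max) keep <- keep[seq_len(i_max), , drop = FALSE]
  f <- numeric(i_max)
  f[seq_len(nrow(keep))] <- keep$norm_freq
  rownames(keep) <- NULL
  list(pcres = keep, freq = f)
}

#' Derive task labels from an expression table
#'
#' `clf`: 1 if a gene's RPKM is strictly above the median over all genes in
#' the cell type, else 0. `reg`: `log2(RPKM + pseudocount)`. `diff`: log2
#' ratio of pseudocounted RPKMs between the two cell types in `cell_pair`.
#'
#' @param expression data.frame with `gene_id` and one RPKM column per cell
#'   type.
#' @param task `"clf"`, `"reg"` or `"diff"`.
#' @param cell_type Column used for `clf`/`reg` (first cell type column by
#'   default).
#' @param cell_pair Length-2 character vector of columns for `diff`.
#' @param pseudocount Added to RPKM before log2 (default 1).
#' @return Named numeric vector of labels (names are gene ids).
#' @export
derive_labels <- function(expression, task = c("clf", "reg", "diff"),
                          cell_type = NULL, cell_pair = NULL,
                          pseudocount = 1) {
  task <- match.arg(task)
  cols <- setdiff(names(expression), "gene_id")
  if (task == "diff") {
    if (is.null(cell_pair) || length(cell_pair) != 2L)
      stop("the diff task needs cell_pair = c(cell_a, cell_b)")
    a <- expression[[cell_pair[1L]]]
    b <- expression[[cell_pair[2L]]]
    if (any(a < 0) || any(b < 0)) stop("RPKM values must be non-negative")
    lab <- log2((a + pseudocount) / (b + pseudocount))
  } else {
    if (is.null(cell_type)) cell_type <- cols[1L]
    x <- expression[[cell_type]]
    if (is.null(x)) stop("cell type column not found: ", cell_type)
    if (any(x < 0)) stop("RPKM values must be non-negative")
    lab <- if (task == "clf") as.numeric(x > stats::median(x))
    else log2(x + pseudocount)
  }
  stats::setNames(lab, expression$gene_id)
}

#' Chromosome-disjoint cross-validation folds
#'
#' Assigns whole chromosomes to folds so that no two genes on the same
#' chromosome ever fall into different folds (ruling out information
#' leakage through promoter-promoter interactions). Chromosomes are
#' shuffled with the seed to randomize ties, ordered by decreasing gene
#' count and greedily assigned to the currently smallest fold, keeping the
#' fold sizes as balanced as the chromosome partition allows.
#'
#' @param genes data.frame with `gene_id` and `chrom`.
#' @param k Number of folds (>= 2; at most the number of chromosomes).
#' @param seed Integer seed for the shuffle.
#' @return `list(folds = list of k gene-id vectors, chrom_fold = named
#'   integer vector mapping chromosome to fold)`.
#' @export
make_cv_folds <- function(genes, k = 4L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  chroms <- unique(genes$chrom)
  if (length(chroms) < k)
    stop("need at least k distinct chromosomes, got ", length(chroms))
  counts <- table(genes$chrom)
  set.seed(seed)
  chroms <- sample(chroms)
  chroms <- chroms[order(-as.integer(counts[chroms]))] # stable within ties
  fold_sizes <- integer(k)
  chrom_fold <- integer(0)
  for (ch in chroms) {
    f <- which.min(fold_sizes)
    chrom_fold[ch] <- f
    fold_sizes[f] <- fold_sizes[f] + as.integer(counts[[ch]])
  }
  folds <- lapply(seq_len(k), function(f)
    genes$gene_id[genes$chrom %in% names(chrom_fold)[chrom_fold == f]])
  list(folds = folds, chrom_fold = chrom_fold)
}

#' Featurize a full dataset
#'
#' Runs the whole feature pipeline: promoter matrices at every resolution,
#' interaction filtering and ranking, zero-padded pCRE matrices, and task
#' labels, yielding one training example per gene.
#'
#' @param genes data.frame from [read_genes()] (columns `gene_id`, `chrom`,
#'   `tss`, `strand`).
#' @param tracks Named list of [coverage_track()]s, one per channel.
#' @param interactions data.frame from [read_interactions()] (may be empty).
#' @param labels Named numeric vector from [derive_labels()].
#' @param channels Channels to featurize (all tracks by default).
#' @param window,resolutions,pseudocount,strand_aware See
#'   [build_promoter_features()].
#' @param threshold,i_max See [select_interactions()].
#' @param progress Print a dot every 200 genes.
#' @return A list of examples; each has `gene_id`, `chrom`, `label`,
#'   `promoter` (matrices per resolution), `pcres` (matrix lists per
#'   resolution), `freq` (length `i_max`), `n_pcres`, `pad_mask`
#'   (length `i_max + 1`, first entry always `TRUE`), and `channels`.
#' @export
featurize_dataset <- function(genes, tracks, interactions, labels,
                              channels = names(tracks), window = 40000,
                              resolutions = c(100, 500, 2000),
                              threshold = 1.5, i_max = 8L,
                              pseudocount = 1, strand_aware = TRUE,
                              progress = FALSE) {
  ints_by_gene <- if (nrow(interactions) > 0L)
    split(interactions, interactions$gene_id) else list()
  examples <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    prom <- build_promoter_features(gene, tracks, channels, window,
                                    resolutions, pseudocount, strand_aware)
    sel <- select_interactions(ints_by_gene[[gene$gene_id]], threshold, i_max)
    n_act <- nrow(sel$pcres)
    pcres <- list()
    for (r in resolutions) {
      target <- window / r
      pcres[[as.character(r)]] <- lapply(seq_len(n_act), function(i)
        build_pcre_features(sel$pcres[i, ], tracks, channels, r, target,
                            pseudocount))
    }
    if (!gene$gene_id %in% names(labels))
      stop("no label for gene ", gene$gene_id)
    lab <- labels[[gene$gene_id]]
    examples[[g]] <- list(gene_id = gene$gene_id, chrom = gene$chrom,
                          label = unname(lab), promoter = prom,
                          pcres = pcres, freq = sel$freq,
                          n_pcres = n_act,
                          pad_mask = c(TRUE, seq_len(i_max) <= n_act),
                          pcre_intervals = sel$pcres,
                          channels = channels)
    if (progress && g %% 200L == 0L) cat(".")
  }
  if (progress) cat("\n")
  names(examples) <- genes$gene_id
  examples
}

#' Write featurized examples to a directory
#'
#' One serialized tensor file per gene plus a `manifest.tsv` with `gene_id`,
#' `fold`, `label` and `n_interactions`.
#'
#' @param examples List from [featurize_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param folds Optional [make_cv_folds()] result for the manifest's fold
#'   column.
#' @return The manifest data.frame, invisibly.
#' @export
write_features <- function(examples, out_dir, folds = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fold_of <- rep(NA_integer_, length(examples))
  if (!is.null(folds)) {
    for (f in seq_along(folds$folds))
      fold_of[names(examples) %in% folds$folds[[f]]] <- f
  }
  for (ex in examples)
    saveRDS(ex, file.path(out_dir, paste0(ex$gene_id, ".rds")))
  manifest <- data.frame(
    gene_id = vapply(examples, `[[`, character(1), "gene_id"),
    fold = fold_of,
    label = vapply(examples, `[[`, numeric(1), "label"),
    n_interactions = vapply(examples, `[[`, integer(1), "n_pcres"))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read featurized examples back from a directory
#'
#' @param dir Directory written by [write_features()].
#' @return Named list of examples.
#' @export
read_features <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  ex <- lapply(manifest$gene_id, function(g)
    readRDS(file.path(dir, paste0(g, ".rds"))))
  names(ex) <- manifest$gene_id
  ex
}
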