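#' Extract attention maps for one gene
#'
#' Runs the model in inference mode and returns the softmax-normalized
#' attention weight matrices. The promoter (embedding) encoder yields one
#' map per resolution and head — six with the default three resolutions and
#' two heads; pairwise and regulation maps are included on request. Every
#' returned row sums to 1 over unmasked keys. The TSS-row attention profile
#' (the weights the TSS bin places on every other bin) is attached for each
#' embedding map.
#'
#' @param model Trained `chromattn_model`.
#' @param example Featurized example.
#' @param modules Character subset of
#'   `c("embedding", "pairwise", "regulation")`.
#' @return A list of records, each with `gene_id`, `module`, `resolution`,
#'   `layer`, `head`, `weights`, and (embedding only) `tss_profile`.
#' @export
extract_attention <- function(model, example,
                              modules = c("embedding", "pairwise",
                                          "regulation")) {
  modules <- match.arg(modules, several.ok = TRUE)
  check_example(example, model$config)
  bb <- backbone_fwd(model, example)
  cfg <- model$config
  records <- list()
  add <- function(rec) records[[length(records) + 1L]] <<- rec
  for (r in cfg$resolutions) {
    rk <- res_key(r)
    a <- bb$attn[[rk]]
    mid <- (cfg$window %/% r) %/% 2L + 1L
    if ("embedding" %in% modules) {
      for (h in seq_along(a$embedding)) {
        W <- a$embedding[[h]]
        add(list(gene_id = example$gene_id, module = "embedding",
                 resolution = r, layer = 1L, head = h, weights = W,
                 tss_profile = W[mid, ]))
      }
    }
    if ("pairwise" %in% modules && !cfg$embedding_only) {
      for (i in seq_along(a$pairwise)) {
        for (l in seq_along(a$pairwise[[i]])) {
          for (h in seq_along(a$pairwise[[i]][[l]])) {
            add(list(gene_id = example$gene_id, module = "pairwise",
                     resolution = r, pcre = i, layer = l, head = h,
                     weights = a$pairwise[[i]][[l]][[h]]))
          }
        }
      }
    }
    if ("regulation" %in% modules && !cfg$embedding_only) {
      for (l in seq_along(a$regulation)) {
        for (h in seq_along(a$regulation[[l]])) {
          add(list(gene_id = example$gene_id, module = "regulation",
                   resolution = r, layer = l, head = h,
                   weights = a$regulation[[l]][[h]]))
        }
      }
    }
  }
  records
}

standardize_vec <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(NULL)
  (v - mean(v)) / s
}

#' Predicted cis-regulatory impact (PCRI)
#'
#' The Euclidean distance between a gene's multi-resolution core-promoter
#' embedding (concatenated TSS-bin rows of the promoter encoder output) and
#' its multi-resolution regulatory embedding (concatenated first rows of
#' the Regulation-transformer output), after standardizing each vector to
#' mean 0 / sd 1 across its components (sample sd) to remove the global
#' shift introduced by the transformation itself. Large values mean the
#' interaction modules moved the promoter's latent state far — a strongly
#' predicted distal cis-regulatory effect.
#'
#' @param bundle An embedding bundle from
#'   `chromoformer_forward(..., bundle = TRUE)` with elements `promoter`
#'   and `regulatory`.
#' @return `list(pcri = non-negative scalar (NA when degenerate),
#'   degenerate = flag for zero-variance embeddings)`.
#' @export
compute_pcri <- function(bundle) {
  u <- standardize_vec(bundle$promoter)
  v <- standardize_vec(bundle$regulatory)
  if (is.null(u) || is.null(v))
    return(list(pcri = NA_real_, degenerate = TRUE))
  list(pcri = sqrt(sum((u - v)^2)), degenerate = FALSE)
}

#' PCRI table for a set of bundles
#'
#' @param bundles Named list of embedding bundles (e.g. `run_cv()$bundles`).
#' @param cell_type Cell type annotation added to every row.
#' @return data.frame with `gene_id`, `cell_type`, `pcri`, `degenerate`,
#'   `n_pcres`.
#' @export
pcri_table <- function(bundles, cell_type = "cell") {
  rows <- lapply(bundles, function(b) {
    p <- compute_pcri(b)
    data.frame(gene_id = b$gene_id, cell_type = cell_type, pcri = p$pcri,
               degenerate = p$degenerate,
               n_pcres = if (is.null(b$n_pcres)) NA_integer_ else b$n_pcres)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-score PCRI within each cell type
#'
#' Adds a `normalized_pcri` column with per-cell-type mean 0 and unit
#' population sd (`sqrt(mean((x - mean(x))^2))`, so two genes with PCRI 1
#' and 3 normalize to exactly -1 and +1); a cell type with constant PCRI
#' gets all zeros with a warning. The operation is idempotent.
#'
#' @param table data.frame with `cell_type` and `pcri` columns.
#' @return The table with `normalized_pcri` added.
#' @export
normalize_pcri <- function(table) {
  stopifnot(all(c("cell_type", "pcri") %in% names(table)))
  table$normalized_pcri <- NA_real_
  for (ct in unique(table$cell_type)) {
    i <- table$cell_type == ct
    x <- table$pcri[i]
    if (sum(i) < 2L) stop("need >= 2 genes per cell type, got ", sum(i))
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s == 0) {
      warning("constant PCRI within cell type ", ct, "; normalized to 0")
      table$normalized_pcri[i] <- 0
    } else {
      table$normalized_pcri[i] <- (x - mean(x)) / s
    }
  }
  table
}

#' Rank genes by cross-cell-type PCRI variance
#'
#' @param table data.frame with `gene_id`, `cell_type`, `normalized_pcri`.
#' @param top_n Number of genes to return (full ranking if larger than the
#'   gene count).
#' @return Character vector of gene ids, most variable first. Genes missing
#'   in some cell type are excluded with a warning.
#' @export
rank_variable_genes <- function(table, top_n = 1000L) {
  stopifnot("normalized_pcri" %in% names(table))
  n_ct <- length(unique(table$cell_type))
  cnt <- table(table$gene_id)
  incomplete <- names(cnt)[cnt < n_ct]
  if (length(incomplete) > 0L) {
    warning(length(incomplete), " gene(s) missing in some cell type; excluded")
    table <- table[!(table$gene_id %in% incomplete), , drop = FALSE]
  }
  v <- tapply(table$normalized_pcri, table$gene_id, stats::var)
  ranked <- names(sort(v, decreasing = TRUE))
  utils::head(ranked, top_n)
}

#' Cluster genes and cell types by PCRI profile
#'
#' Average-linkage hierarchical clustering on distance
#' `1 - Pearson correlation`, applied to both axes of a genes-by-cell-types
#' matrix of normalized PCRI. Zero-variance rows or columns have undefined
#' correlation and are excluded with a warning.
#'
#' @param mat Numeric matrix, genes in rows, cell types in columns, no
#'   missing values.
#' @return `list(genes = hclust, cell_types = hclust)`.
#' @export
cluster_pcri <- function(mat) {
  if (anyNA(mat)) stop("PCRI matrix must not contain missing values")
  drop_const <- function(M, margin) {
    v <- apply(M, margin, stats::var)
    bad <- v == 0 | !is.finite(v)
    if (any(bad)) {
      warning(sum(bad), " zero-variance ",
              if (margin == 1L) "gene(s)" else "cell type(s)", " excluded")
      M <- if (margin == 1L) M[!bad, , drop = FALSE]
      else M[, !bad, drop = FALSE]
    }
    M
  }
  mat <- drop_const(drop_const(mat, 1L), 2L)
  d_genes <- stats::as.dist(1 - stats::cor(t(mat)))
  d_cells <- stats::as.dist(1 - stats::cor(mat))
  list(genes = stats::hclust(d_genes, method = "average"),
       cell_types = stats::hclust(d_cells, method = "average"))
}

#' Dose-response of PCRI on annotated pCRE counts
#'
#' Groups genes by the number of their pCREs carrying a binary annotation
#' (e.g. transcriptionally active, or silencer-bound) and reports the
#' median PCRI and median expression per count bin, plus gene-level
#' Spearman rank correlations of the count with PCRI and with expression —
#' the additive (enhancer) versus switch-like (silencer) readout.
#'
#' @param pcri data.frame with `gene_id` and `pcri` (e.g. from
#'   [pcri_table()]).
#' @param annotations data.frame with one row per pCRE: `gene_id` and a
#'   logical `annotated` column. Genes absent from `annotations` are
#'   treated as zero-count only if listed in `all_genes`.
#' @param expression Optional named vector of per-gene expression values.
#' @param all_genes Optional character vector fixing the gene universe so
#'   the zero-count group is present whenever such genes exist.
#' @return `list(table = per-count summary, spearman_pcri = , spearman_expr
#'   = )`; empty annotation yields an empty table.
#' @export
pcre_dose_response <- function(pcri, annotations, expression = NULL,
                               all_genes = NULL) {
  if (is.null(all_genes)) all_genes <- pcri$gene_id
  if (nrow(annotations) == 0L && length(all_genes) == 0L) {
    return(list(table = data.frame(), spearman_pcri = NA_real_,
                spearman_expr = NA_real_))
  }
  counts <- stats::setNames(integer(length(all_genes)), all_genes)
  if (nrow(annotations) > 0L) {
    tab <- tapply(annotations$annotated, annotations$gene_id, sum)
    counts[names(tab)] <- as.integer(tab)
  }
  df <- data.frame(gene_id = names(counts), count = unname(counts))
  df <- merge(df, pcri[, c("gene_id", "pcri")], by = "gene_id")
  df$expr <- if (!is.null(expression)) unname(expression[df$gene_id])
  else NA_real_
  agg <- do.call(rbind, lapply(sort(unique(df$count)), function(k) {
    s <- df[df$count == k, ]
    data.frame(count = k, n_genes = nrow(s),
               median_pcri = stats::median(s$pcri, na.rm = TRUE),
               median_expr = stats::median(s$expr, na.rm = TRUE))
  }))
  sp_p <- if (nrow(df) > 2L && stats::sd(df$count) > 0)
    stats::cor(df$count, df$pcri, method = "spearman",
               use = "complete.obs") else NA_real_
  sp_e <- if (!is.null(expression) && nrow(df) > 2L &&
              stats::sd(df$count) > 0)
    stats::cor(df$count, df$expr, method = "spearman",
               use = "complete.obs") else NA_real_
  list(table = agg, spearman_pcri = sp_p, spearman_expr = sp_e)
}
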