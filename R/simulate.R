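#' Simulation configuration
#'
#' Parameters of the synthetic epigenome generator. Genes carry two
#' independent latent variables: an initiation strength `s ~ N(0, 1)` and an
#' elongation propensity `e ~ N(0, 1)`. Promoter-activation marks (H3K4me3,
#' H3K9ac, H3K27ac and a weaker H3K4me1 component) scale with
#' `plogis(1.5 s)`, repressive marks (H3K27me3, H3K9me3) with
#' `plogis(-1.5 s)`, while the elongation mark H3K36me3 forms a bump peaking
#' `body_offset` bp downstream of the TSS (strand-oriented) whose amplitude
#' scales with `plogis(1.5 e)` — steady-state mRNA depends on transcriptional
#' elongation, and only the gene-body mark traces it, so the 4-6 kbp
#' downstream region carries signal no promoter-proximal mark duplicates.
#' Enhancer pCREs carry H3K4me1/H3K27ac peaks, silencer pCREs carry H3K27me3
#' peaks. Expression on the log2 scale is `baseline + strength_effect * s +
#' elongation_effect * e + enhancer_effect * n_enhancers - silencer_effect *
#' 1[n_silencers >= silencer_threshold] + N(0, noise_sd)`: additive
#' activation by enhancers, switch-like suppression above the silencer-count
#' threshold. Interaction frequencies
#' decay with distance as `freq_base * (d / freq_ref_dist)^(-freq_decay)`
#' with lognormal noise, so nearly all planted pCREs clear the 1.5 filter
#' while per-gene decoy candidates fall below it.
#'
#' @param n_chromosomes,genes_per_chromosome Genome layout.
#' @param gene_spacing Distance between consecutive TSSs in bp.
#' @param window Feature window (kept clear of chromosome edges).
#' @param frac_no_interaction Fraction of genes with no pCRE candidates at
#'   all (the interaction-free stratum).
#' @param baseline_log2,strength_effect,elongation_effect,enhancer_effect,silencer_threshold,silencer_effect,noise_sd
#'   Expression-rule parameters (log2 RPKM scale).
#' @param enhancer_max,enhancer_prob,silencer_max,silencer_prob Planted
#'   enhancer/silencer counts are Binomial(max, prob) per gene.
#' @param promoter_amp,promoter_sd,repressive_amp,repressive_sd,body_amp,body_offset,body_sd,enhancer_amp,enhancer_sd,silencer_amp,silencer_sd
#'   Gaussian bump amplitudes (read-depth units over background) and sds
#'   (bp).
#' @param amp_jitter_sd Lognormal sd of multiplicative amplitude jitter.
#' @param pcre_dist_range,pcre_width_range pCRE placement (bp from TSS) and
#'   fragment widths.
#' @param freq_base,freq_decay,freq_ref_dist,freq_noise_sd Interaction
#'   frequency model.
#' @param decoys_per_gene,decoy_freq_range Below-threshold candidate
#'   interactions exercising the frequency filter.
#' @param background_depth Flat background read depth.
#' @param signal_step Discretization step (bp) for writing bumps as depth
#'   segments.
#' @param n_cell_types Number of cell types (shared gene/pCRE layout;
#'   strengths, noise and tracks are redrawn per cell type).
#' @param seed Seed controlling the whole simulation.
#' @return A list of class `chromattn_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4L, genes_per_chromosome = 100L,
                       gene_spacing = 60000L, window = 40000L,
                       frac_no_interaction = 0.25,
                       baseline_log2 = 2, strength_effect = 1.5,
                       elongation_effect = 1.0,
                       enhancer_effect = 0.5,
                       enhancer_max = 5L, enhancer_prob = 0.45,
                       silencer_max = 4L, silencer_prob = 0.35,
                       silencer_threshold = 3L, silencer_effect = 3,
                       noise_sd = 0.5,
                       promoter_amp = 6, promoter_sd = 300,
                       repressive_amp = 4, repressive_sd = 2000,
                       body_amp = 5, body_offset = 5000L, body_sd = 1000,
                       enhancer_amp = 5, enhancer_sd = 500,
                       silencer_amp = 5, silencer_sd = 800,
                       amp_jitter_sd = 0.3,
                       pcre_dist_range = c(25000L, 150000L),
                       pcre_width_range = c(2000L, 6000L),
                       freq_base = 4, freq_decay = 0.35,
                       freq_ref_dist = 20000L, freq_noise_sd = 0.25,
                       decoys_per_gene = 1L,
                       decoy_freq_range = c(0.5, 1.4),
                       background_depth = 1, signal_step = 50L,
                       n_cell_types = 1L, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$frac_no_interaction < 0 || cfg$frac_no_interaction > 1)
    stop("frac_no_interaction must be in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$amp_jitter_sd < 0 || cfg$freq_noise_sd < 0)
    stop("noise sds must be non-negative")
  if (cfg$gene_spacing < cfg$window %/% 2L)
    stop("genes too dense for the feature window")
  class(cfg) <- "chromattn_sim_config"
  cfg
}

sim_marks <- c("H3K4me1", "H3K4me3", "H3K9me3", "H3K27me3", "H3K36me3",
               "H3K27ac", "H3K9ac")

# discretize a Gaussian bump into depth segments
bump_segments <- function(chrom, center, sd, amp, step) {
  lo <- floor((center - 3 * sd) / step) * step
  hi <- ceiling((center + 3 * sd) / step) * step
  starts <- seq(lo, hi - step, by = step)
  mids <- starts + step / 2
  data.frame(chrom = chrom, start = starts, end = starts + step,
             depth = amp * exp(-(mids - center)^2 / (2 * sd^2)))
}

jitter_amp <- function(amp, n, sd) amp * exp(stats::rnorm(n, 0, sd))

#' Simulate a synthetic epigenome
#'
#' Generates genes, seven-channel coverage tracks, promoter-pCRE candidate
#' interactions with distance-decayed normalized frequencies, RPKM
#' expression produced by the known generative rules, and a ground-truth
#' table — everything the feature pipeline consumes, with the answers
#' recorded.
#'
#' @param config A [sim_config()].
#' @return A list of class `chromattn_sim` with `genes`, `tracks` (per cell
#'   type when `n_cell_types > 1`), `interactions`, `expression`, `truth`,
#'   `pcre_truth` and `chrom_lengths`.
#' @export
simulate_epigenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "chromattn_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  margin <- 50000L + cfg$pcre_dist_range[2L]
  chrom_len <- 2L * margin + cfg$genes_per_chromosome * cfg$gene_spacing
  chroms <- sprintf("chrS%d", seq_len(cfg$n_chromosomes))

  # ---- shared layout: genes ----
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    n <- cfg$genes_per_chromosome
    data.frame(gene_id = sprintf("%s_g%03d", ch, seq_len(n)), chrom = ch,
               tss = as.integer(margin + (seq_len(n) - 1L) * cfg$gene_spacing +
                                  sample(-5000:5000, n, replace = TRUE)),
               strand = sample(c("+", "-"), n, replace = TRUE))
  }))
  rownames(genes) <- NULL
  n_genes <- nrow(genes)
  no_int <- stats::runif(n_genes) < cfg$frac_no_interaction
  n_enh <- ifelse(no_int, 0L,
                  stats::rbinom(n_genes, cfg$enhancer_max, cfg$enhancer_prob))
  n_sil <- ifelse(no_int, 0L,
                  stats::rbinom(n_genes, cfg$silencer_max, cfg$silencer_prob))

  # ---- shared layout: pCREs and interaction frequencies ----
  pcre_rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_real <- n_enh[g] + n_sil[g]
    n_dec <- if (no_int[g]) 0L else cfg$decoys_per_gene
    n_tot <- n_real + n_dec
    if (n_tot == 0L) next
    dist <- round(stats::runif(n_tot, cfg$pcre_dist_range[1L],
                               cfg$pcre_dist_range[2L]))
    side <- sample(c(-1L, 1L), n_tot, replace = TRUE)
    w <- round(stats::runif(n_tot, cfg$pcre_width_range[1L],
                            cfg$pcre_width_range[2L]))
    center <- genes$tss[g] + side * dist
    freq_real <- cfg$freq_base * (dist / cfg$freq_ref_dist)^(-cfg$freq_decay) *
      exp(stats::rnorm(n_tot, 0, cfg$freq_noise_sd))
    freq <- freq_real
    role <- c(rep("enhancer", n_enh[g]), rep("silencer", n_sil[g]),
              rep("decoy", n_dec))
    if (n_dec > 0L) {
      di <- n_real + seq_len(n_dec)
      freq[di] <- stats::runif(n_dec, cfg$decoy_freq_range[1L],
                               cfg$decoy_freq_range[2L])
    }
    pcre_rows[[g]] <- data.frame(
      gene_id = genes$gene_id[g], chrom = genes$chrom[g],
      start = as.integer(center - w %/% 2L),
      end = as.integer(center + w %/% 2L),
      norm_freq = freq, role = role)
  }
  pcre_truth <- do.call(rbind, pcre_rows)
  if (is.null(pcre_truth))
    pcre_truth <- data.frame(gene_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             norm_freq = numeric(), role = character())
  interactions <- pcre_truth[, c("gene_id", "chrom", "start", "end",
                                 "norm_freq")]

  passes <- pcre_truth$norm_freq > 1.5
  pass_count <- function(role) {
    tab <- tapply(passes & pcre_truth$role == role, pcre_truth$gene_id, sum)
    out <- integer(n_genes)
    out[match(names(tab), genes$gene_id)] <- as.integer(tab)
    out
  }
  n_enh_pass <- pass_count("enhancer")
  n_sil_pass <- pass_count("silencer")

  # ---- per cell type: strengths, expression, tracks ----
  cells <- if (cfg$n_cell_types == 1L) "cell" else
    sprintf("cell%s", LETTERS[seq_len(cfg$n_cell_types)])
  expression <- data.frame(gene_id = genes$gene_id)
  truth <- list()
  tracks_all <- list()
  for (ct in cells) {
    s <- stats::rnorm(n_genes)
    e <- stats::rnorm(n_genes) # elongation propensity, independent of s
    act <- stats::plogis(1.5 * s)
    elo <- stats::plogis(1.5 * e)
    rep_ <- stats::plogis(-1.5 * s)
    log2_clean <- cfg$baseline_log2 + cfg$strength_effect * s +
      cfg$elongation_effect * e +
      cfg$enhancer_effect * n_enh -
      cfg$silencer_effect * (n_sil >= cfg$silencer_threshold)
    log2_expr <- log2_clean + stats::rnorm(n_genes, 0, cfg$noise_sd)
    expression[[ct]] <- 2^log2_expr
    truth[[ct]] <- data.frame(
      gene_id = genes$gene_id, cell_type = ct, strength = s,
      elongation = e,
      active = s > 0, n_enhancers = n_enh, n_silencers = n_sil,
      n_enhancers_passing = n_enh_pass, n_silencers_passing = n_sil_pass,
      has_interactions = !no_int, log2_noiseless = log2_clean,
      log2_expression = log2_expr)

    segs <- stats::setNames(vector("list", length(sim_marks)), sim_marks)
    addseg <- function(mark, df) segs[[mark]][[length(segs[[mark]]) + 1L]] <<- df
    strand_sign <- ifelse(genes$strand == "+", 1L, -1L)
    for (g in seq_len(n_genes)) {
      ch <- genes$chrom[g]; tss <- genes$tss[g]
      st <- cfg$signal_step
      for (mk in c("H3K4me3", "H3K9ac", "H3K27ac"))
        addseg(mk, bump_segments(ch, tss,
                                 cfg$promoter_sd,
                                 jitter_amp(cfg$promoter_amp * act[g], 1,
                                            cfg$amp_jitter_sd), st))
      addseg("H3K4me1", bump_segments(ch, tss, cfg$promoter_sd,
                                      jitter_amp(0.3 * cfg$promoter_amp *
                                                   act[g], 1,
                                                 cfg$amp_jitter_sd), st))
      for (mk in c("H3K27me3", "H3K9me3"))
        addseg(mk, bump_segments(ch, tss, cfg$repressive_sd,
                                 jitter_amp(cfg$repressive_amp * rep_[g], 1,
                                            cfg$amp_jitter_sd), st))
      addseg("H3K36me3",
             bump_segments(ch, tss + strand_sign[g] * cfg$body_offset,
                           cfg$body_sd,
                           jitter_amp(cfg$body_amp * elo[g], 1,
                                      cfg$amp_jitter_sd), st))
    }
    if (nrow(pcre_truth) > 0L) {
      for (j in seq_len(nrow(pcre_truth))) {
        ctr <- (pcre_truth$start[j] + pcre_truth$end[j]) / 2
        ch <- pcre_truth$chrom[j]
        if (pcre_truth$role[j] == "enhancer") {
          for (mk in c("H3K4me1", "H3K27ac"))
            addseg(mk, bump_segments(ch, ctr, cfg$enhancer_sd,
                                     jitter_amp(cfg$enhancer_amp, 1,
                                                cfg$amp_jitter_sd),
                                     cfg$signal_step))
        } else if (pcre_truth$role[j] == "silencer") {
          addseg("H3K27me3", bump_segments(ch, ctr, cfg$silencer_sd,
                                           jitter_amp(cfg$silencer_amp, 1,
                                                      cfg$amp_jitter_sd),
                                           cfg$signal_step))
        }
      }
    }
    bg <- data.frame(chrom = rep(chroms, each = 1L), start = 0L,
                     end = chrom_len, depth = cfg$background_depth)
    tracks_all[[ct]] <- lapply(segs, function(lst)
      coverage_track(rbind(bg, do.call(rbind, lst))))
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(config = cfg, genes = genes,
              tracks = if (cfg$n_cell_types == 1L) tracks_all[[1L]]
              else tracks_all,
              interactions = interactions, expression = expression,
              truth = truth, pcre_truth = pcre_truth,
              chrom_lengths = stats::setNames(rep(chrom_len,
                                                  length(chroms)), chroms))
  class(out) <- "chromattn_sim"
  out
}

#' @export
print.chromattn_sim <- function(x, ...) {
  cat(sprintf("<chromattn_sim> %d genes on %d chromosome(s), %d pCRE candidate(s), %d cell type(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom)),
              nrow(x$interactions), x$config$n_cell_types))
  invisible(x)
}

sim_presets <- list(
  tiny = list(n_chromosomes = 2L, genes_per_chromosome = 20L),
  small = list(n_chromosomes = 4L, genes_per_chromosome = 100L),
  medium = list(n_chromosomes = 20L, genes_per_chromosome = 100L)
)

#' Preset simulation configuration
#'
#' `tiny` (40 genes, 2 chromosomes) for unit tests, `small` (400 genes, 4
#' chromosomes) for cross-validation integration, `medium` (2000 genes, 20
#' chromosomes) for full evaluation runs.
#'
#' @param size One of `"tiny"`, `"small"`, `"medium"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_preset <- function(size = c("tiny", "small", "medium"), ...) {
  size <- match.arg(size)
  do.call(sim_config, utils::modifyList(sim_presets[[size]], list(...)))
}

#' Write a simulated dataset to disk as standard text formats
#'
#' Emits exactly what the feature pipeline consumes — `genes.bed` (BED6),
#' one bedGraph per mark under `tracks/`, `interactions.tsv`,
#' `expression.tsv` — plus `truth.tsv` / `pcre_truth.tsv` (ground truth)
#' and a `manifest.tsv` listing every file with its md5 checksum.
#'
#' @param size Preset name passed to [sim_preset()], or a
#'   [sim_config()]/[simulate_epigenome()] result.
#' @param out_dir Output directory.
#' @param seed Seed (ignored when a simulated object is supplied).
#' @return The manifest data.frame, invisibly.
#' @export
write_fixture <- function(size = "tiny", out_dir, seed = 7L) {
  sim <- if (inherits(size, "chromattn_sim")) size
  else if (inherits(size, "chromattn_sim_config")) simulate_epigenome(size)
  else simulate_epigenome(sim_preset(size, seed = seed))
  if (sim$config$n_cell_types != 1L)
    stop("write_fixture() writes single-cell-type datasets")
  dir.create(file.path(out_dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  g <- sim$genes
  bed <- data.frame(chrom = g$chrom,
                    start = ifelse(g$strand == "+", g$tss, g$tss - 500L),
                    end = ifelse(g$strand == "+", g$tss + 500L, g$tss),
                    name = g$gene_id, score = 0L, strand = g$strand)
  files <- character()
  wt <- function(df, path, col.names = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
    files <<- c(files, path)
  }
  wt(bed, file.path(out_dir, "genes.bed"), col.names = FALSE)
  for (mk in names(sim$tracks)) {
    p <- file.path(out_dir, "tracks", paste0(mk, ".bedGraph"))
    write_bedgraph(sim$tracks[[mk]], p)
    files <- c(files, p)
  }
  wt(sim$interactions, file.path(out_dir, "interactions.tsv"))
  wt(sim$expression, file.path(out_dir, "expression.tsv"))
  wt(sim$truth, file.path(out_dir, "truth.tsv"))
  wt(sim$pcre_truth, file.path(out_dir, "pcre_truth.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
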