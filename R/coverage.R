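#' Coverage track from depth segments
#'
#' Builds a genome-wide piecewise-constant read-depth track from possibly
#' overlapping depth segments (0-based, half-open intervals). Overlapping
#' segments add up; positions not covered by any segment have depth 0. The
#' track stores, per chromosome, the breakpoints of the step function and a
#' cumulative depth integral, so binned mean depths over arbitrary windows
#' are exact and O(bins) to query.
#'
#' @param segments A data.frame with columns `chrom`, `start`, `end`,
#'   `depth` (0-based half-open; depths non-negative).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(segments)))
  if (any(segments$end <= segments$start))
    stop("degenerate segment: end must exceed start")
  out <- list()
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    # event-based overlay: +depth at start, -depth at end
    ev_pos <- c(s$start, s$end)
    ev_d <- c(s$depth, -s$depth)
    o <- order(ev_pos)
    ev_pos <- ev_pos[o]
    ev_d <- ev_d[o]
    pos <- unique(ev_pos)
    depth_at <- cumsum(ev_d)
    # depth on [pos[j], pos[j+1]) is the running sum after all events at pos[j]
    last_idx <- cumsum(tabulate(match(ev_pos, pos), length(pos)))
    depth <- depth_at[last_idx]
    depth <- depth[-length(depth)] # last break closes the track
    width <- diff(pos)
    cum <- c(0, cumsum(depth * width))
    out[[ch]] <- list(pos = pos, depth = depth, cum = cum)
  }
  structure(out, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s): %s\n", length(x),
              paste(utils::head(names(x), 5), collapse = ", ")))
  invisible(x)
}

# cumulative depth integral at arbitrary positions (0 depth off-track)
track_cum_at <- function(trk_chr, x) {
  if (is.null(trk_chr)) return(numeric(length(x)))
  pos <- trk_chr$pos
  cum <- trk_chr$cum
  i <- findInterval(x, pos)
  res <- numeric(length(x))
  inside <- i >= 1L & i < length(pos)
  res[inside] <- cum[i[inside]] +
    trk_chr$depth[i[inside]] * (x[inside] - pos[i[inside]])
  res[i >= length(pos)] <- cum[length(cum)]
  res
}

#' Read a bedGraph file into a coverage track
#'
#' @param path Path to a bedGraph file (`chrom start end depth`, 0-based
#'   half-open).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # back to 0-based half-open
    end = GenomicRanges::end(gr),
    depth = gr$score))
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted, matching common bedGraph practice.
#'
#' @param track A [coverage_track()].
#' @param path Output file path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    t <- track[[ch]]
    keep <- t$depth != 0
    if (!any(keep)) next
    df <- data.frame(
      chrom = ch,
      start = format(t$pos[-length(t$pos)][keep], trim = TRUE,
                     scientific = FALSE),
      end = format(t$pos[-1L][keep], trim = TRUE, scientific = FALSE),
      depth = format(t$depth[keep], trim = TRUE, scientific = FALSE))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Binned log2 mean depth over a window
#'
#' Tiles the half-open window `[center - window/2, center + window/2)` with
#' non-overlapping bins of `bin_size` bp, left to right in genomic
#' orientation, and returns `log2(mean depth + pseudocount)` per bin.
#' Positions beyond the covered part of the chromosome contribute depth 0.
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name.
#' @param center Window center (bp, 0-based).
#' @param window Window width in bp; must be divisible by `bin_size`.
#' @param bin_size Bin width in bp.
#' @param pseudocount Added to the mean depth before log2 (default 1, so
#'   zero depth maps to 0).
#' @return Numeric vector of length `window / bin_size`.
#' @export
bin_signals <- function(track, chrom, center, window = 40000,
                        bin_size, pseudocount = 1) {
  if (window %% bin_size != 0)
    stop("window must be divisible by bin_size")
  edges <- (center - window / 2) + bin_size * (0:(window / bin_size))
  Fv <- track_cum_at(track[[chrom]], edges)
  log2(diff(Fv) / bin_size + pseudocount)
}

#' Binned log2 mean depth over an explicit interval
#'
#' Like [bin_signals()] but tiles `[start, end)` with `ceiling((end - start)
#' / bin_size)` bins anchored at `start` (the last bin may extend past
#' `end`), as used for variable-width pCRE fragments.
#' @noRd
bin_signals_interval <- function(track, chrom, start, end, bin_size,
                                 pseudocount = 1) {
  if (end <= start) stop("degenerate interval: end must exceed start")
  n_bins <- ceiling((end - start) / bin_size)
  edges <- start + bin_size * (0:n_bins)
  Fv <- track_cum_at(track[[chrom]], edges)
  log2(diff(Fv) / bin_size + pseudocount)
}
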