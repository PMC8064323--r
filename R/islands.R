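#' Bin tags into fixed-width genomic bins
#'
#' Each fragment is assigned to exactly one bin by its midpoint
#' (floor((start+end)/2), integer division by the bin size). The trailing
#' partial bin of each chromosome is retained.
#'
#' @param tags a `tag_set`.
#' @param layout `genome_layout`.
#' @param bin_size bin width in bp (>= 1). 32 bp is the density-track
#'   convention; island calling uses a wider scoring window (200 bp default).
#' @return object of class `binned_coverage`: list with `bin_size`, `counts`
#'   (named list of integer vectors per chromosome), `total_tags`,
#'   `chrom_lengths`.
#' @export
bin_tags <- function(tags, layout, bin_size = 32) {
  stop_if_not_layout(layout)
  stopifnot(bin_size >= 1)
  fr <- tags$fragments
  bad <- !(fr$chrom %in% names(layout))
  if (any(bad))
    stop("fragment on unknown chromosome: ", fr$chrom[which(bad)[1]])
  lens <- unclass(layout)
  out_of_bounds <- fr$start < 0 | fr$end > lens[fr$chrom]
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    stop(sprintf("fragment outside chromosome bounds: %s:%d-%d",
                 fr$chrom[i], fr$start[i], fr$end[i]))
  }
  mids <- fragment_midpoints(fr)
  counts <- lapply(names(lens), function(chrom) {
    nb <- as.integer(ceiling(lens[[chrom]] / bin_size))
    m <- mids[fr$chrom == chrom]
    if (!length(m)) return(integer(nb))
    tabulate(m %/% bin_size + 1L, nbins = nb)
  })
  names(counts) <- names(lens)
  structure(list(bin_size = bin_size, counts = counts,
                 total_tags = nrow(fr), chrom_lengths = lens),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("binned_coverage: %d bp bins, %d tags, %d chromosome(s)\n",
              x$bin_size, x$total_tags, length(x$counts)))
  invisible(x)
}

#' Call enrichment islands from binned coverage
#'
#' SICER-style two-tier procedure. The scoring window is the bin size of
#' `cov` (bin tags at the scoring window, 200 bp by convention, before
#' calling). Steps:
#' (1) background rate lambda = total_tags x window / effective genome
#' length (sum of chromosome lengths; synthetic genomes are fully
#' mappable);
#' (2) a window with count k is *eligible* if the Poisson upper tail
#' P(X >= k; lambda) < `window_p`;
#' (3) eligible windows whose gap is at most `gap` bp are chained into one
#' island spanning from the first to the last eligible window;
#' (4) island significance is the Poisson upper tail of the island tag count
#' against lambda x (island span / window), counting all tags in the span;
#' (5) Benjamini-Hochberg correction across the islands of the sample;
#' islands with fdr below `fdr_cutoff` are kept, sorted by (chrom, start).
#'
#' When an input (control) coverage is supplied, the island expectation is
#' the larger of the global lambda-based expectation and the input tag count
#' in the span scaled to the treatment library size, a conservative local
#' background.
#'
#' @param cov `binned_coverage` binned at the scoring window.
#' @param gap maximum bp between eligible windows merged into one island;
#'   rounded up to a multiple of the window if needed.
#' @param window_p Poisson tail probability for window eligibility
#'   (permissive by design; stringency comes from the island FDR).
#' @param fdr_cutoff island-level BH FDR cutoff.
#' @param input_cov optional `binned_coverage` of an input library, binned
#'   at the same window.
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   tag_count, score (-log10 Poisson tail), p, fdr.
#' @export
call_islands <- function(cov, gap = 600, window_p = 0.2,
                         fdr_cutoff = 1e-10, input_cov = NULL) {
  stopifnot(inherits(cov, "binned_coverage"))
  window <- cov$bin_size
  L <- sum(cov$chrom_lengths)
  if (L <= 0) stop("zero-length genome")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), tag_count = integer(0),
                      score = numeric(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
  if (cov$total_tags == 0) return(empty)
  if (gap %% window != 0) {
    gap <- ceiling(gap / window) * window
    message("gap rounded up to a multiple of the window: ", gap, " bp")
  }
  max_gap_windows <- gap %/% window
  lambda <- cov$total_tags * window / L
  if (!is.null(input_cov)) {
    stopifnot(inherits(input_cov, "binned_coverage"),
              input_cov$bin_size == window)
    if (input_cov$total_tags == 0) input_cov <- NULL
  }

  rows <- list()
  for (chrom in names(cov$counts)) {
    k <- cov$counts[[chrom]]
    eligible <- which(stats::ppois(k - 1, lambda, lower.tail = FALSE) <
                        window_p)
    if (!length(eligible)) next
    # chain eligible windows separated by <= max_gap_windows ineligible ones
    brk <- c(0, which(diff(eligible) - 1 > max_gap_windows), length(eligible))
    for (j in seq_len(length(brk) - 1)) {
      first <- eligible[brk[j] + 1]
      last <- eligible[brk[j + 1]]
      span_windows <- last - first + 1
      tag_count <- sum(k[first:last])
      expect <- lambda * span_windows
      if (!is.null(input_cov)) {
        inp <- sum(input_cov$counts[[chrom]][first:last])
        expect <- max(expect,
                      inp * cov$total_tags / input_cov$total_tags)
      }
      p <- stats::ppois(tag_count - 1, expect, lower.tail = FALSE)
      st <- (first - 1) * window
      en <- min(last * window, cov$chrom_lengths[[chrom]])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = st, end = en, tag_count = tag_count,
        score = -log10(pmax(p, .Machine$double.xmin)), p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  isl <- do.call(rbind, rows)
  isl$fdr <- stats::p.adjust(isl$p, method = "BH")
  isl <- isl[isl$fdr < fdr_cutoff, ]
  isl <- isl[order(isl$chrom, isl$start), ]
  rownames(isl) <- NULL
  isl
}

#' Write islands as BED6 plus a statistics TSV
#'
#' BED score column is min(1000, round(10 x score)).
#'
#' @param islands island data.frame from [call_islands()].
#' @param path BED path; a `.stats.tsv` sibling carries tag_count, p, fdr.
#' @param name interval name prefix.
#' @export
write_islands_bed <- function(islands, path, name = "island") {
  score <- pmin(1000, round(10 * islands$score))
  utils::write.table(
    data.frame(islands$chrom, islands$start, islands$end,
               paste0(name, seq_len(nrow(islands))), score, "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    islands[, c("chrom", "start", "end", "tag_count", "p", "fdr")],
    sub("\\.bed$", ".stats.tsv", path), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Write binned coverage as bedGraph
#'
#' Zero bins are omitted, the bedGraph convention for sparse tracks.
#'
#' @param cov `binned_coverage` (32-nt bins for browser tracks).
#' @param path output path.
#' @param track_name track line name; `NULL` suppresses the track line.
#' @export
write_bedgraph <- function(cov, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  for (chrom in names(cov$counts)) {
    k <- cov$counts[[chrom]]
    nz <- which(k > 0)
    if (!length(nz)) next
    st <- (nz - 1) * cov$bin_size
    en <- pmin(nz * cov$bin_size, cov$chrom_lengths[[chrom]])
    utils::write.table(data.frame(chrom, st, en, k[nz]), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
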