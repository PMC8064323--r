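#' Read position frequency matrices in JASPAR text format
#'
#' Parses one or more motifs of the form
#' ```
#' >MA0079.5 SP1 ZFC2H2
#' A [ 10  2  0 ... ]
#' C [  1  8 12 ... ]
#' G [ ... ]
#' T [ ... ]
#' ```
#' (brackets optional; an optional third header token is kept as the
#' factor-family classification). Log-odds weights are derived with a
#' pseudocount mass of 1 distributed by the background:
#' `log2((count + p*bg) / (colsum + p)) - log2(bg)` with p = 1.
#'
#' @param path file path, or `text =` a character scalar of the content.
#' @param text literal content, overrides `path`.
#' @param background length-4 base probabilities (A, C, G, T), summing to 1.
#' @param pseudocount total pseudocount mass p.
#' @return list of `pw_motif` objects: motif_id, factor_name,
#'   classification, counts (4 x L, rows A/C/G/T), background, log_odds.
#' @export
read_jaspar_pfm <- function(path = NULL, text = NULL,
                            background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(abs(sum(background) - 1) < 1e-9)
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR header ('>') found")
  bounds <- c(heads, length(lines) + 1)
  motifs <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    if (length(block) != 4)
      stop("motif ", hdr[1], ": expected 4 count rows, got ", length(block))
    rows <- lapply(seq_along(block), function(r) {
      ln <- gsub("^[ACGTacgt]\\s*", "", block[r])
      ln <- gsub("\\[|\\]", " ", ln)
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(v)) stop("motif ", hdr[1], ": unparseable counts in row ", r)
      v
    })
    L <- unique(lengths(rows))
    if (length(L) != 1)
      stop("motif ", hdr[1], ": ragged matrix (row lengths ",
           paste(lengths(rows), collapse = "/"), ")")
    counts <- do.call(rbind, rows)
    if (any(counts < 0)) {
      bad <- which(counts < 0, arr.ind = TRUE)[1, ]
      stop("motif ", hdr[1], ": negative count at row ", bad[1],
           ", column ", bad[2])
    }
    rownames(counts) <- c("A", "C", "G", "T")
    motifs[[i]] <- pw_motif(motif_id = hdr[1],
                            factor_name = if (length(hdr) >= 2) hdr[2]
                            else NA_character_,
                            classification = if (length(hdr) >= 3) hdr[3]
                            else NA_character_,
                            counts = counts, background = background,
                            pseudocount = pseudocount)
  }
  motifs
}

#' Construct a position weight motif from a count matrix
#'
#' @param motif_id identifier.
#' @param counts 4 x L non-negative matrix, rows A/C/G/T, L >= 4.
#' @param factor_name,classification optional annotation.
#' @param background length-4 base probabilities.
#' @param pseudocount total pseudocount mass distributed by background.
#' @return object of class `pw_motif`.
#' @export
pw_motif <- function(motif_id, counts, factor_name = NA_character_,
                     classification = NA_character_,
                     background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(nrow(counts) == 4, ncol(counts) >= 4, all(counts >= 0))
  rownames(counts) <- c("A", "C", "G", "T")
  colsum <- colSums(counts)
  lo <- log2(sweep(counts + pseudocount * background, 2,
                   colsum + pseudocount, "/")) - log2(background)
  structure(list(motif_id = motif_id, factor_name = factor_name,
                 classification = classification, counts = counts,
                 background = background, log_odds = lo),
            class = "pw_motif")
}

#' @export
print.pw_motif <- function(x, ...) {
  cat(sprintf("pw_motif %s (%s): %d bp, consensus %s\n", x$motif_id,
              x$factor_name, ncol(x$counts), motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence (column-max base) of a motif
#' @param motif a `pw_motif`.
#' @return character scalar.
#' @export
motif_consensus <- function(motif) {
  paste0(rownames(motif$counts)[apply(motif$counts, 2, which.max)],
         collapse = "")
}

# reverse-complemented log-odds: complement rows (A<->T, C<->G) and reverse
# the columns, so scoring at an offset equals scoring the reverse
# complement of the window with the forward matrix
revcomp_log_odds <- function(lo) lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]

#' Scan a sequence with a motif
#'
#' At every offset and on both strands the window score is the sum of
#' log-odds weights; it is min-max normalized,
#' `(S - S_min) / (S_max - S_min)`, where S_min/S_max are the worst/best
#' attainable scores, and offsets with normalized score >= `cutoff` are
#' reported. Windows containing N are skipped. Overlapping hits are all
#' reported.
#'
#' @param seq nucleotide string over A/C/G/T/N (or a
#'   [Biostrings::DNAString]).
#' @param motif a `pw_motif`.
#' @param cutoff normalized score cutoff in `[0, 1]` (default 0.85).
#' @return data.frame: offset (0-based window start), strand, score
#'   (normalized). Empty if the sequence is shorter than the motif.
#' @export
scan_sequence <- function(seq, motif, cutoff = 0.85) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  lo <- motif$log_odds
  L <- ncol(lo)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  s_min <- sum(apply(lo, 2, min))
  s_max <- sum(apply(lo, 2, max))
  denom <- s_max - s_min
  if (denom <= 0) stop("degenerate motif: constant score")
  n_off <- n - L + 1
  score_with <- function(w) {
    s <- numeric(n_off)
    for (j in seq_len(L)) s <- s + w[cbind(code[j:(j + n_off - 1)], j)]
    (s - s_min) / denom  # NA propagates from N-containing windows
  }
  fwd <- score_with(lo)
  rev <- score_with(revcomp_log_odds(lo))
  fi <- which(!is.na(fwd) & fwd >= cutoff)
  ri <- which(!is.na(rev) & rev >= cutoff)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi], stringsAsFactors = FALSE),
    data.frame(offset = ri - 1L, strand = rep("-", length(ri)),
               score = rev[ri], stringsAsFactors = FALSE))
  hits <- hits[order(hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Motif frequency over flanked intervals: average sites per interval
#'
#' Extracts each interval sequence with `flank` bp added on both sides
#' (clipped at chromosome ends), scans every motif on both strands, and
#' reports the total hit count divided by the number of intervals, ranked
#' descending (ties by motif id) - the "average number of binding sites per
#' interval sequence" statistic.
#'
#' @param intervals data.frame chrom/start/end (0-based half-open), or a
#'   `merged_regions` object.
#' @param genome named [Biostrings::DNAStringSet] covering the intervals.
#' @param motifs list of `pw_motif`.
#' @param flank bp added on each side (default 200).
#' @param cutoff normalized score cutoff (default 0.85).
#' @return data.frame: motif_id, factor_name, classification,
#'   n_intervals_scanned, total_sites, avg_sites_per_interval.
#' @export
motif_frequency_table <- function(intervals, genome, motifs, flank = 200,
                                  cutoff = 0.85) {
  if (inherits(intervals, "merged_regions")) intervals <- intervals$regions
  if (!nrow(intervals))
    stop("no intervals: average sites per interval undefined")
  missing_chrom <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome missing from genome sequence: ", missing_chrom[1])
  seq_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  lo <- pmax(0, intervals$start - flank)
  hi <- pmin(seq_lens[intervals$chrom], intervals$end + flank)
  seqs <- vapply(seq_len(nrow(intervals)), function(i)
    as.character(Biostrings::subseq(genome[[intervals$chrom[i]]],
                                    lo[i] + 1, hi[i])), character(1))
  rows <- lapply(motifs, function(m) {
    total <- sum(vapply(seqs, function(s)
      nrow(scan_sequence(s, m, cutoff)), numeric(1)))
    data.frame(motif_id = m$motif_id, factor_name = m$factor_name,
               classification = m$classification,
               n_intervals_scanned = nrow(intervals), total_sites = total,
               avg_sites_per_interval = total / nrow(intervals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$avg_sites_per_interval, out$motif_id), ]
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6 and the frequency summary as TSV
#'
#' BED scores are 1000 x normalized score.
#'
#' @param hits data.frame from [scan_sequence()] with added chrom and
#'   absolute coordinates, or assembled by the caller.
#' @param freq data.frame from [motif_frequency_table()].
#' @param hits_path,freq_path output paths.
#' @export
write_motif_outputs <- function(hits, freq, hits_path, freq_path) {
  if (!is.null(hits) && nrow(hits))
    utils::write.table(
      data.frame(hits$chrom, hits$start, hits$end, hits$motif_id,
                 round(1000 * hits$score), hits$strand),
      hits_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  utils::write.table(freq, freq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(freq_path)
}
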