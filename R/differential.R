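#' Quantify per-target H3K4me3 signal for one sample
#'
#' Counts fragment midpoints in a strand-aware window per gene and converts
#' to a length-corrected density (tags per kb). The promoter window is
#' TSS +/- `promoter_flank` (2 kb total by default); the gene body runs from
#' TSS to TES. Tags are expected to be downsample-normalized first.
#'
#' @param tags a `tag_set` (normalized).
#' @param genes gene model data.frame.
#' @param window "promoter" or "gene_body".
#' @param promoter_flank bp either side of the TSS.
#' @return data.frame: target_id, sample_id, raw_count, length_bp,
#'   tag_density (tags/kb).
#' @export
quantify_signal <- function(tags, genes, window = c("promoter", "gene_body"),
                            promoter_flank = 1000) {
  window <- match.arg(window)
  if (window == "promoter") {
    lo <- genes$tss - promoter_flank
    hi <- genes$tss + promoter_flank
  } else {
    lo <- genes$start
    hi <- genes$end
  }
  if (any(hi <= lo)) stop("zero-length quantification window")
  fr <- tags$fragments
  mids <- fragment_midpoints(fr)
  counts <- integer(nrow(genes))
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    m <- sort(mids[fr$chrom == chrom])
    if (!length(m)) next
    # half-open [lo, hi): tags with lo <= mid < hi
    counts[gi] <- findInterval(hi[gi] - 1, m) - findInterval(lo[gi] - 1, m)
  }
  len <- hi - lo
  data.frame(target_id = genes$gene_id, sample_id = tags$sample_id,
             raw_count = counts, length_bp = len,
             tag_density = counts / (len / 1000),
             stringsAsFactors = FALSE)
}

#' Call differential activity between two groups
#'
#' Group means are taken on the density scale; the ratio is
#' (mean_B + pseudo) / (mean_A + pseudo) on pseudocounted densities and the
#' p-value comes from a two-sided t test on log2(density + pseudo)
#' (Welch by default; `pooled = TRUE` gives the pooled-variance test). A
#' record passes the filter when the fold change reaches `fc_cutoff` in
#' either direction and p < `alpha`. A BH-adjusted column is emitted for
#' transparency but does not enter the filter. With fewer than two samples
#' in a group, p is NA and the filter uses the fold change alone (with a
#' warning).
#'
#' @param signals data.frame of per-sample signals (rbind of
#'   [quantify_signal()] outputs, all samples).
#' @param groups named character vector sample_id -> group; exactly two
#'   groups, the first sorted level is "A" (denominator).
#' @param fc_cutoff fold-change cutoff (default 1.5).
#' @param alpha raw p-value cutoff (default 0.05).
#' @param pseudo pseudocount in tags/kb (default 0.5).
#' @param pooled use pooled-variance t instead of Welch.
#' @return data.frame sorted by p then |log2fc|: target_id, mean_A, mean_B,
#'   ratio, log2fc, p, bh_q, present_A, present_B, passes_filter.
#'   Presence means a nonzero group mean density.
#' @export
differential_call <- function(signals, groups, fc_cutoff = 1.5,
                              alpha = 0.05, pseudo = 0.5, pooled = FALSE) {
  stopifnot(all(signals$sample_id %in% names(groups)))
  gl <- sort(unique(as.character(groups[unique(signals$sample_id)])))
  if (length(gl) != 2) stop("differential_call expects exactly two groups")
  g <- as.character(groups[signals$sample_id])
  targets <- unique(signals$target_id)
  wide <- matrix(NA_real_, length(targets), length(unique(signals$sample_id)),
                 dimnames = list(targets, unique(signals$sample_id)))
  wide[cbind(match(signals$target_id, targets),
             match(signals$sample_id, colnames(wide)))] <- signals$tag_density
  cols_a <- colnames(wide)[groups[colnames(wide)] == gl[1]]
  cols_b <- colnames(wide)[groups[colnames(wide)] == gl[2]]
  if (length(cols_a) < 2 || length(cols_b) < 2)
    warning("a group has < 2 samples: p-values undefined, ",
            "filter uses fold change only")
  mean_a <- rowMeans(wide[, cols_a, drop = FALSE])
  mean_b <- rowMeans(wide[, cols_b, drop = FALSE])
  ratio <- (mean_b + pseudo) / (mean_a + pseudo)
  la <- log2(wide[, cols_a, drop = FALSE] + pseudo)
  lb <- log2(wide[, cols_b, drop = FALSE] + pseudo)
  p <- rep(NA_real_, length(targets))
  if (length(cols_a) >= 2 && length(cols_b) >= 2) {
    for (i in seq_along(targets)) {
      x <- la[i, ]
      y <- lb[i, ]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        p[i] <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      } else {
        p[i] <- stats::t.test(y, x, var.equal = pooled)$p.value
      }
    }
  }
  fold_ok <- ratio >= fc_cutoff | ratio <= 1 / fc_cutoff
  passes <- if (all(is.na(p))) fold_ok else fold_ok & !is.na(p) & p < alpha
  out <- data.frame(target_id = targets, mean_A = mean_a, mean_B = mean_b,
                    ratio = ratio, log2fc = log2(ratio), p = p,
                    bh_q = stats::p.adjust(p, method = "BH"),
                    present_A = mean_a > 0, present_B = mean_b > 0,
                    passes_filter = passes, stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_A"] <- paste0("mean_", gl[1])
  names(out)[names(out) == "mean_B"] <- paste0("mean_", gl[2])
  names(out)[names(out) == "present_A"] <- paste0("present_", gl[1])
  names(out)[names(out) == "present_B"] <- paste0("present_", gl[2])
  o <- order(out$p, -abs(out$log2fc), na.last = TRUE)
  out <- out[o, ]
  rownames(out) <- NULL
  out
}

#' Present/absent matrix of merged regions
#'
#' @param merged `merged_regions`.
#' @return integer 0/1 matrix, regions x samples.
#' @export
presence_matrix <- function(merged) {
  m <- merged$presence + 0L
  rownames(m) <- paste0("region", seq_len(nrow(m)))
  m
}
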