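#' Genomic feature categories used by the annotation module
#' @keywords internal
FEATURE_CATEGORIES <- c("proximal_promoter", "distal_promoter",
                        "five_prime_utr", "exon", "intron",
                        "three_prime_utr", "proximal_downstream",
                        "distal_downstream", "distal_intergenic")

# strand-aware position of a midpoint relative to a gene's TSS:
# negative = upstream of the TSS, 0.. = at/inside/downstream.
rel_to_tss <- function(mid, gene) {
  if (gene$strand == "+") mid - gene$tss else gene$tss - mid
}

# classify one midpoint against one gene; NA if the gene does not claim it
classify_against_gene <- function(mid, gene, proximal, distal, utr_frac) {
  len <- gene$end - gene$start
  rel <- rel_to_tss(mid, gene)
  inside <- mid >= gene$start && mid < gene$end
  if (inside) {
    from5 <- if (gene$strand == "+") mid - gene$start else gene$end - 1 - mid
    utr_len <- utr_frac * len
    if (from5 < utr_len) return(list(cat = "five_prime_utr", rel = rel))
    if (from5 >= len - utr_len) return(list(cat = "three_prime_utr",
                                            rel = rel))
    es <- gene$exon_starts[[1]]
    ee <- gene$exon_ends[[1]]
    in_exon <- any(mid >= es & mid < ee)
    return(list(cat = if (in_exon) "exon" else "intron", rel = rel))
  }
  if (rel <= 0) {  # upstream (rel == 0 only at the half-open TSS boundary)
    if (rel >= -proximal) return(list(cat = "proximal_promoter", rel = rel))
    if (rel >= -distal) return(list(cat = "distal_promoter", rel = rel))
    return(NULL)
  }
  dd <- rel - len  # bp past the TES; >= 0 for all non-upstream outside hits
  if (dd < proximal) return(list(cat = "proximal_downstream", rel = rel))
  if (dd < distal) return(list(cat = "distal_downstream", rel = rel))
  NULL
}

#' Annotate regions against gene models
#'
#' Each region is classified by its midpoint against the nearest claiming
#' gene, strand-aware, into one of nine categories: proximal (0-1 kb) and
#' distal (1-3 kb) promoters upstream of the TSS, 5'UTR / exon / intron /
#' 3'UTR inside genes (UTRs are the first/last `utr_frac` of the gene span,
#' a convention for synthetic models, with precedence 5'UTR > 3'UTR > exon >
#' intron), proximal (0-1 kb) and distal (1-3 kb) downstream past the TES,
#' and distal_intergenic otherwise. When several genes claim a midpoint the
#' gene with the smallest absolute distance to its TSS wins, ties broken by
#' gene id. Gene-to-region association over a wider margin (10 kb) is a
#' separate operation, [genes_near_peaks()].
#'
#' @param regions data.frame with chrom/start/end (0-based half-open).
#' @param genes gene model data.frame.
#' @param proximal proximal band width, bp (default 1000).
#' @param distal distal band outer edge, bp (default 3000).
#' @param utr_frac fraction of the gene span treated as UTR at each end.
#' @return data.frame: region index, chrom, start, end, category, gene_id
#'   (NA iff distal_intergenic), dist_tss (signed bp, negative upstream,
#'   NA iff distal_intergenic).
#' @export
annotate_regions <- function(regions, genes, proximal = 1000,
                             distal = 3000, utr_frac = 0.1) {
  n <- nrow(regions)
  category <- rep("distal_intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist_tss <- rep(NA_real_, n)
  if (n && nrow(genes)) {
    mids <- floor((regions$start + regions$end) / 2)
    for (i in seq_len(n)) {
      cand <- genes[genes$chrom == regions$chrom[i] &
                      genes$start - distal <= mids[i] &
                      genes$end + distal > mids[i], , drop = FALSE]
      if (!nrow(cand)) next
      best <- NULL
      for (j in seq_len(nrow(cand))) {
        hit <- classify_against_gene(mids[i], cand[j, ], proximal, distal,
                                     utr_frac)
        if (is.null(hit)) next
        hit$gene_id <- cand$gene_id[j]
        if (is.null(best) || abs(hit$rel) < abs(best$rel) ||
            (abs(hit$rel) == abs(best$rel) && hit$gene_id < best$gene_id))
          best <- hit
      }
      if (!is.null(best)) {
        category[i] <- best$cat
        gene_id[i] <- best$gene_id
        dist_tss[i] <- best$rel
      }
    }
  }
  data.frame(region = seq_len(n), chrom = regions$chrom,
             start = regions$start, end = regions$end,
             category = factor(category, levels = FEATURE_CATEGORIES),
             gene_id = gene_id, dist_tss = dist_tss,
             stringsAsFactors = FALSE)
}

#' Associate genes with peaks within a margin
#'
#' A gene maps to every region whose span intersects
#' `[gene_start - margin, gene_end + margin)` (half-open; a region starting
#' exactly at the margin boundary is excluded).
#'
#' @param regions data.frame chrom/start/end.
#' @param genes gene model data.frame.
#' @param margin bp margin around the gene span (default 10 kb).
#' @return named list gene_id -> integer vector of region row indices
#'   (genes with no region omitted).
#' @export
genes_near_peaks <- function(regions, genes, margin = 10000) {
  out <- list()
  for (j in seq_len(nrow(genes))) {
    lo <- genes$start[j] - margin
    hi <- genes$end[j] + margin
    idx <- which(regions$chrom == genes$chrom[j] &
                   regions$start < hi & regions$end > lo)
    if (length(idx)) out[[genes$gene_id[j]]] <- idx
  }
  out
}

#' Feature-category fractions for pie charts
#'
#' @param annotations data.frame from [annotate_regions()].
#' @return named numeric fractions over all nine categories, summing to 1.
#' @export
feature_pie <- function(annotations) {
  if (!nrow(annotations)) stop("no annotations: pie fractions undefined")
  tab <- table(factor(annotations$category, levels = FEATURE_CATEGORIES))
  stats::setNames(as.numeric(tab) / nrow(annotations), FEATURE_CATEGORIES)
}

#' Matched random control peaks
#'
#' Draws intervals with the same length multiset as the input regions,
#' placed uniformly on the genome (chromosome chosen proportional to
#' length), the random control of the feature-distribution comparison.
#'
#' @param regions data.frame chrom/start/end whose lengths are reused.
#' @param layout `genome_layout`.
#' @param seed integer seed.
#' @return data.frame chrom/start/end.
#' @export
random_control_peaks <- function(regions, layout, seed = 1L) {
  stop_if_not_layout(layout)
  set.seed(as.integer(seed))
  lens <- regions$end - regions$start
  n <- length(lens)
  cl <- unclass(layout)
  chrom <- character(n)
  start <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      ci <- sample.int(length(cl), 1, prob = cl)
      if (cl[ci] >= lens[i]) break
    }
    chrom[i] <- names(cl)[ci]
    start[i] <- floor(stats::runif(1, 0, cl[ci] - lens[i] + 1))
  }
  data.frame(chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}
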