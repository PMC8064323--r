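#' Build a tag-density profile matrix around anchors
#'
#' Rows are anchors, columns are bins, values are fragment-midpoint counts
#' per bin; upstream is always on the left (strand-aware).
#' Anchor conventions:
#' * `promoter`: anchored at the TSS, window TSS +/- `flank`; column offsets
#'   run from -flank to +flank and a fragment exactly at the TSS falls in
#'   the bin containing offset 0.
#' * `merged_region`: anchored at the region midpoint, window +/- `flank`,
#'   unstranded.
#' * `gene_body`: meta-gene rows; the body (TSS to TES) is length-scaled to
#'   `meta_length` pseudo-bp, flanked by `flank` bp at true scale on both
#'   sides.
#'
#' Anchors whose window runs off the genome keep their row; out-of-genome
#' positions simply contribute zero counts.
#'
#' @param tags a `tag_set` (normalized).
#' @param anchors gene model data.frame (promoter/gene_body) or region
#'   data.frame with chrom/start/end (merged_region).
#' @param anchor_set one of "promoter", "merged_region", "gene_body".
#' @param flank bp of flanking sequence (defaults: 1500 promoter, 5000
#'   merged region, 2000 gene body).
#' @param bin bin width in bp (default 32).
#' @param meta_length pseudo-length of the scaled gene body (default 2000).
#' @return object of class `profile_matrix`: list with `matrix` (anchors x
#'   bins), `offsets` (left edge of each column in profile coordinates),
#'   `anchor_set`, `flank`, `bin`, `cluster_labels` (NULL until
#'   [cluster_profiles()]).
#' @export
build_profile <- function(tags, anchors,
                          anchor_set = c("promoter", "merged_region",
                                         "gene_body"),
                          flank = NULL, bin = 32, meta_length = 2000) {
  anchor_set <- match.arg(anchor_set)
  if (is.null(flank))
    flank <- switch(anchor_set, promoter = 1500, merged_region = 5000,
                    gene_body = 2000)
  if (!nrow(anchors)) stop("anchors must be non-empty")
  span <- switch(anchor_set,
                 promoter = 2 * flank,
                 merged_region = 2 * flank,
                 gene_body = meta_length + 2 * flank)
  ncol <- as.integer(ceiling(span / bin))
  left <- if (anchor_set == "gene_body") -flank else -flank
  offsets <- left + (seq_len(ncol) - 1) * bin
  fr <- tags$fragments
  mids <- fragment_midpoints(fr)
  mat <- matrix(0, nrow(anchors), ncol)
  rn <- if (!is.null(anchors$gene_id)) anchors$gene_id else
    paste0("region", seq_len(nrow(anchors)))
  rownames(mat) <- rn

  by_chrom <- split(mids, fr$chrom)
  by_chrom <- lapply(by_chrom, sort)

  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]
    m <- by_chrom[[chrom]]
    if (is.null(m) || !length(m)) next
    if (anchor_set == "promoter") {
      tss <- anchors$tss[i]
      lo <- tss - flank
      hi <- tss + flank
      sel <- m[m >= lo & m < hi]
      if (!length(sel)) next
      x <- if (anchors$strand[i] == "+") sel - tss else tss - sel - 1
    } else if (anchor_set == "merged_region") {
      ctr <- floor((anchors$start[i] + anchors$end[i]) / 2)
      lo <- ctr - flank
      hi <- ctr + flank
      sel <- m[m >= lo & m < hi]
      if (!length(sel)) next
      x <- sel - ctr
    } else {
      gs <- anchors$start[i]
      ge <- anchors$end[i]
      len <- ge - gs
      plus <- anchors$strand[i] == "+"
      lo <- gs - flank
      hi <- ge + flank
      sel <- m[m >= lo & m < hi]
      if (!length(sel)) next
      rel <- if (plus) sel - gs else ge - 1 - sel
      x <- ifelse(rel < 0, rel,
                  ifelse(rel < len, floor(rel / len * meta_length),
                         meta_length + (rel - len)))
    }
    col <- floor((x - left) / bin) + 1
    col <- col[col >= 1 & col <= ncol]
    if (length(col))
      mat[i, ] <- mat[i, ] + tabulate(col, nbins = ncol)
  }
  structure(list(matrix = mat, offsets = offsets, anchor_set = anchor_set,
                 flank = flank, bin = bin, cluster_labels = NULL),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix (%s): %d anchors x %d bins of %d bp\n",
              x$anchor_set, nrow(x$matrix), ncol(x$matrix), x$bin))
  invisible(x)
}

#' Cluster profile rows by shape
#'
#' k-means on row-normalized profiles (each row divided by its sum; all-zero
#' rows stay zero and fall in one cluster). Cluster labels are renumbered by
#' descending mean raw signal so C1 is always the strongest, making labels
#' reproducible across runs with the same seed. Empty-cluster failures are
#' retried with derived seeds up to 10 times.
#'
#' @param pm `profile_matrix` (or a plain matrix).
#' @param k number of clusters (default 5).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return integer labels 1..k, named by row; also stored in the returned
#'   attribute when given a `profile_matrix` (use the return value).
#' @export
cluster_profiles <- function(pm, k = 5, seed = 1L, nstart = 10) {
  mat <- if (inherits(pm, "profile_matrix")) pm$matrix else pm
  if (k == 1)
    return(stats::setNames(rep(1L, nrow(mat)), rownames(mat)))
  rs <- rowSums(mat)
  norm <- mat / ifelse(rs == 0, 1, rs)
  km <- NULL
  for (try in 0:9) {
    set.seed(as.integer(seed) + try)
    km <- tryCatch(stats::kmeans(norm, centers = k, nstart = nstart),
                   error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed after bounded retries")
  strength <- tapply(rs, km$cluster, mean)
  relabel <- match(km$cluster, as.integer(names(sort(strength,
                                                     decreasing = TRUE))))
  stats::setNames(as.integer(relabel), rownames(mat))
}

#' Average profile (column means)
#'
#' @param pm `profile_matrix` or plain matrix.
#' @return numeric vector of per-bin means.
#' @export
average_plot <- function(pm) {
  mat <- if (inherits(pm, "profile_matrix")) pm$matrix else pm
  colMeans(mat)
}

#' Cross-group scatter QC: Pearson r and OLS slope
#'
#' Pearson correlation and ordinary-least-squares slope (with intercept) of
#' the group-B region means regressed on group A, the consistency check of
#' the pipeline's between-group comparison.
#'
#' @param region_means_a,region_means_b equal-length paired numeric vectors
#'   (>= 3 points).
#' @return named numeric: pearson_r, ols_slope.
#' @export
group_scatter_qc <- function(region_means_a, region_means_b) {
  stopifnot(length(region_means_a) == length(region_means_b),
            length(region_means_a) >= 3)
  fit <- stats::lm(region_means_b ~ region_means_a)
  c(pearson_r = stats::cor(region_means_a, region_means_b),
    ols_slope = unname(stats::coef(fit)[2]))
}

#' Write a profile matrix (and optional cluster labels) as TSV
#'
#' @param pm `profile_matrix`.
#' @param path output TSV path.
#' @param labels optional cluster labels from [cluster_profiles()]; rows are
#'   ordered by cluster so clusters are contiguous.
#' @export
write_profile_matrix <- function(pm, path, labels = NULL) {
  mat <- pm$matrix
  df <- data.frame(anchor = rownames(mat), mat, check.names = FALSE)
  colnames(df)[-1] <- pm$offsets
  if (!is.null(labels)) {
    df$cluster <- labels[rownames(mat)]
    df <- df[order(df$cluster), ]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
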