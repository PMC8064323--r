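#' Normalize libraries by downsampling to the smallest sample
#'
#' Every tag set is reduced by random sampling without replacement to the
#' tag count of the smallest input sample; the smallest sample is returned
#' intact. Deterministic given the seed (per-sample substreams keyed by
#' sample id, so the result does not depend on list order).
#'
#' @param samples list of `tag_set`, all with total_count > 0.
#' @param seed integer seed.
#' @return list of `tag_set` with equal total_count.
#' @export
downsample_tags <- function(samples, seed = 1L) {
  stopifnot(length(samples) >= 1)
  totals <- vapply(samples, `[[`, numeric(1), "total_count")
  if (any(totals == 0)) stop("all samples must have tags")
  m <- min(totals)
  lapply(samples, function(s) {
    if (s$total_count == m) return(s)
    set.seed(substream_seed(seed, s$sample_id))
    keep <- sort(sample.int(s$total_count, m))
    fr <- s$fragments[keep, ]
    rownames(fr) <- NULL
    tag_set(s$sample_id, s$group, fr)
  })
}

#' Build cross-sample merged regions
#'
#' The transitive closure of interval overlap across all samples: two
#' islands overlap iff they share at least 1 bp under half-open semantics
#' (book-ended intervals do not overlap). Each merged region runs from the
#' start of its most upstream member island to the end of its most
#' downstream member; a region contributed by a single sample is that
#' island itself.
#'
#' @param per_sample_islands named list (sample id -> island data.frame with
#'   chrom/start/end, internally disjoint).
#' @param groups named character vector sample id -> group label.
#' @return object of class `merged_regions`: list with `regions`
#'   (data.frame chrom/start/end sorted and disjoint), `presence` (logical
#'   region x sample matrix), `groups`.
#' @export
merge_regions <- function(per_sample_islands, groups) {
  stopifnot(length(per_sample_islands) >= 1,
            !is.null(names(per_sample_islands)))
  samples <- names(per_sample_islands)
  if (!all(samples %in% names(groups)))
    stop("groups must cover every sample")
  dfs <- lapply(samples, function(s) {
    df <- per_sample_islands[[s]]
    if (!nrow(df)) return(NULL)
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               sample = s, stringsAsFactors = FALSE)
  })
  all_isl <- do.call(rbind, dfs)
  if (is.null(all_isl) || !nrow(all_isl)) {
    return(structure(list(
      regions = data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), stringsAsFactors = FALSE),
      presence = matrix(FALSE, 0, length(samples),
                        dimnames = list(NULL, samples)),
      groups = groups[samples]), class = "merged_regions"))
  }
  gr <- df_to_granges(all_isl)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- GenomicRanges::sort(red)
  hit <- GenomicRanges::findOverlaps(gr, red)
  reg_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  presence <- matrix(FALSE, length(red), length(samples),
                     dimnames = list(NULL, samples))
  presence[cbind(reg_of, match(all_isl$sample, samples))] <- TRUE
  structure(list(regions = granges_to_df(red), presence = presence,
                 groups = groups[samples]),
            class = "merged_regions")
}

#' @export
print.merged_regions <- function(x, ...) {
  cat(sprintf("merged_regions: %d regions across %d samples (%s)\n",
              nrow(x$regions), ncol(x$presence),
              paste(unique(x$groups), collapse = "/")))
  invisible(x)
}

#' Group presence of merged regions
#'
#' A region is group-present if at least one sample of the group
#' contributes an island (a stricter all-samples rule is available via
#' `require_all`).
#'
#' @param merged `merged_regions`.
#' @param require_all require every sample of a group rather than any.
#' @return logical region x group matrix.
#' @export
group_presence <- function(merged, require_all = FALSE) {
  gl <- unique(merged$groups)
  out <- matrix(FALSE, nrow(merged$regions), length(gl),
                dimnames = list(NULL, gl))
  for (g in gl) {
    cols <- merged$presence[, merged$groups == g, drop = FALSE]
    out[, g] <- if (require_all) apply(cols, 1, all) else apply(cols, 1, any)
  }
  out
}

#' Venn partition of merged regions by group
#'
#' Counts the regions exclusive to each of two groups and those shared;
#' the three counts always partition the region set.
#'
#' @param merged `merged_regions` with exactly two groups.
#' @param require_all see [group_presence()].
#' @return named numeric: exclusive_<A>, exclusive_<B>, shared.
#' @export
group_venn <- function(merged, require_all = FALSE) {
  gp <- group_presence(merged, require_all = require_all)
  if (ncol(gp) != 2) stop("group_venn expects exactly two groups")
  a <- gp[, 1]
  b <- gp[, 2]
  out <- c(sum(a & !b), sum(!a & b), sum(a & b))
  names(out) <- c(paste0("exclusive_", colnames(gp)[1]),
                  paste0("exclusive_", colnames(gp)[2]), "shared")
  if (sum(out) != nrow(merged$regions) - sum(!a & !b))
    stop("internal error: Venn counts do not partition the regions")
  out
}

#' Count regions per chromosome
#'
#' @param regions data.frame with a chrom column (e.g. `merged$regions`).
#' @return data.frame chrom, n; counts sum to the number of regions.
#' @export
per_chromosome_counts <- function(regions) {
  if (!nrow(regions))
    return(data.frame(chrom = character(0), n = integer(0)))
  tab <- table(regions$chrom)
  data.frame(chrom = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Fraction of one sample's islands overlapping another's
#'
#' Asymmetric pairwise QC: the fraction of `islands_a` sharing >= 1 bp with
#' any interval of `islands_b` (half-open semantics).
#'
#' @param islands_a,islands_b island data.frames (chrom/start/end), each
#'   internally disjoint.
#' @return fraction in `[0, 1]`.
#' @export
pairwise_overlap_fraction <- function(islands_a, islands_b) {
  if (!nrow(islands_a)) return(NaN)
  if (!nrow(islands_b)) return(0)
  ga <- df_to_granges(islands_a)
  gb <- df_to_granges(islands_b)
  # disjoint chromosome sets between the two lists are legitimate input
  suppressWarnings(mean(GenomicRanges::countOverlaps(ga, gb) > 0))
}

#' Write merged regions, presence matrix, Venn and per-chromosome tables
#'
#' @param merged `merged_regions`.
#' @param prefix output path prefix; writes `<prefix>.bed`,
#'   `<prefix>.presence.tsv`, `<prefix>.venn.tsv`, `<prefix>.per_chrom.tsv`.
#' @export
write_merged_regions <- function(merged, prefix) {
  reg <- merged$regions
  utils::write.table(
    data.frame(reg$chrom, reg$start, reg$end,
               paste0("region", seq_len(nrow(reg))), 0L, "."),
    paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  pres <- data.frame(region = paste0("region", seq_len(nrow(reg))),
                     reg[, c("chrom", "start", "end")],
                     merged$presence + 0L, check.names = FALSE)
  utils::write.table(pres, paste0(prefix, ".presence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  venn <- group_venn(merged)
  utils::write.table(data.frame(set = names(venn), n = as.numeric(venn)),
                     paste0(prefix, ".venn.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(per_chromosome_counts(reg),
                     paste0(prefix, ".per_chrom.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
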