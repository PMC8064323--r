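# Independent oracle implementations used to cross-check the package.
# These deliberately use naive algorithms (union-find, quadratic scans,
# direct summation) so they share no code path with the implementation.

# --- union-find merge of intervals across samples ---------------------------
# islands: data.frame chrom/start/end/sample; returns regions sorted by
# (chrom, start) with a list of contributing samples per region.
oracle_merge <- function(islands) {
  n <- nrow(islands)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (islands$chrom[i] == islands$chrom[j] &&
          islands$start[i] < islands$end[j] &&
          islands$end[i] > islands$start[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  regs <- lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = islands$chrom[idx[1]],
               start = min(islands$start[idx]),
               end = max(islands$end[idx]),
               samples = I(list(sort(unique(islands$sample[idx])))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regs)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# --- Poisson upper tail by direct summation ---------------------------------
oracle_poisson_tail <- function(k, lambda, nmax = 500) {
  # P(X >= k) summed upward from the k-th term so tiny tails keep full
  # relative precision (no 1 - cdf cancellation)
  term <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  total <- 0
  for (i in k:(k + nmax)) {
    total <- total + term
    term <- term * lambda / (i + 1)
  }
  total
}

# --- rule-by-rule midpoint classification -----------------------------------
# Literal re-statement of the annotation rules, one gene at a time, with
# explicit strand branches.
oracle_annotate_one <- function(mid, genes, proximal = 1000, distal = 3000,
                                utr_frac = 0.1) {
  best_cat <- "distal_intergenic"
  best_rel <- NA_real_
  best_gene <- NA_character_
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    len <- g$end - g$start
    if (g$strand == "+") rel <- mid - g$start else rel <- g$end - mid
    cat <- NULL
    if (mid >= g$start && mid < g$end) {
      from5 <- if (g$strand == "+") mid - g$start else g$end - 1 - mid
      if (from5 < utr_frac * len) {
        cat <- "five_prime_utr"
      } else if (from5 >= len - utr_frac * len) {
        cat <- "three_prime_utr"
      } else {
        es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
        hit <- FALSE
        for (e in seq_along(es)) if (mid >= es[e] && mid < ee[e]) hit <- TRUE
        cat <- if (hit) "exon" else "intron"
      }
    } else if (rel <= 0) {
      if (rel >= -proximal) cat <- "proximal_promoter"
      else if (rel >= -distal) cat <- "distal_promoter"
    } else if (rel - len >= 0) {
      if (rel - len < proximal) cat <- "proximal_downstream"
      else if (rel - len < distal) cat <- "distal_downstream"
    }
    if (!is.null(cat)) {
      if (is.na(best_rel) || abs(rel) < abs(best_rel) ||
          (abs(rel) == abs(best_rel) && g$gene_id < best_gene)) {
        best_cat <- cat; best_rel <- rel; best_gene <- g$gene_id
      }
    }
  }
  list(category = best_cat, gene_id = best_gene, rel = best_rel)
}

# restrict a gene table to one chromosome for the oracle above
oracle_annotate <- function(regions, genes, ...) {
  out <- character(nrow(regions))
  gid <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    r <- oracle_annotate_one(mid, g, ...)
    out[i] <- r$category
    gid[i] <- r$gene_id
  }
  list(category = out, gene_id = gid)
}

# --- Welch t-test, straight-line --------------------------------------------
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# --- adjusted Rand index ----------------------------------------------------
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# --- fixtures ---------------------------------------------------------------
# random internally-disjoint islands on one chromosome
random_islands <- function(n, chrom_len = 1e6, min_len = 200,
                           max_len = 2000, chrom = "chr1") {
  start <- sort(sample.int(chrom_len - max_len, n))
  len <- sample(min_len:max_len, n, replace = TRUE)
  end <- start + len
  # enforce within-sample disjointness by dropping overlaps greedily
  keep <- rep(TRUE, n)
  last_end <- -1
  for (i in seq_len(n)) {
    if (start[i] < last_end) keep[i] <- FALSE else last_end <- end[i]
  }
  data.frame(chrom = chrom, start = start[keep], end = end[keep],
             stringsAsFactors = FALSE)
}

# tag_set with given midpoints on one chromosome (length-2 fragments so the
# midpoint is exactly floor of the planted position)
tags_at <- function(mids, sample_id = "s1", group = "A", chrom = "chr1") {
  tag_set(sample_id, group,
          data.frame(chrom = chrom, start = mids - 1, end = mids + 1,
                     stringsAsFactors = FALSE))
}

# default dominant sequence is deliberately non-palindromic so forward and
# reverse-complement hits are distinguishable
toy_motif <- function(dominant = c("G", "C", "A", "C", "G", "T", "T", "C"),
                      strong = 17, weak = 1, id = "TOY0001") {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(weak, 4, length(dominant), dimnames = list(bases, NULL))
  counts[cbind(match(dominant, bases), seq_along(dominant))] <- strong
  pw_motif(id, counts, factor_name = "toy")
}
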