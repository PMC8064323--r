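#' Simulate a genome with non-overlapping gene models
#'
#' Builds a synthetic genome: uniformly random nucleotide sequence, and
#' `n_genes` gene models placed uniformly on both strands without gene-span
#' overlap. Gene lengths are uniform in `gene_length`, exon/intron structure
#' is random with 1-5 exons covering the span ends. This is artifact
#' plumbing standing in for a reference assembly; it makes no attempt to
#' model isochores, repeats or real gene architecture.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp); recycled.
#' @param n_genes number of genes to place across the genome.
#' @param seed integer seed; the whole genome is deterministic given it.
#' @param gene_length length-2 range of gene lengths.
#' @param max_tries placement retries before giving up.
#' @return list with `layout` (genome_layout), `genes` (gene model
#'   data.frame), `sequence` (named [Biostrings::DNAStringSet]).
#' @export
simulate_genome <- function(n_chroms, chrom_length, n_genes, seed,
                            gene_length = c(2000, 20000),
                            max_tries = 200L) {
  set.seed(as.integer(seed))
  chrom_length <- rep_len(as.numeric(chrom_length), n_chroms)
  layout <- genome_layout(paste0("chr", seq_len(n_chroms)), chrom_length)

  seqs <- Biostrings::DNAStringSet(vapply(chrom_length, function(L)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- names(layout)

  placed <- vector("list", n_genes)
  occ <- lapply(names(layout), function(x) list(start = numeric(0),
                                                end = numeric(0)))
  names(occ) <- names(layout)
  if (n_genes > 0) {
    for (i in seq_len(n_genes)) {
      len <- sample(seq(gene_length[1], gene_length[2]), 1)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(n_chroms, 1, prob = chrom_length)
        chrom <- names(layout)[ci]
        if (chrom_length[ci] <= len) next
        st <- sample.int(chrom_length[ci] - len, 1) - 1
        en <- st + len
        if (!any(st < occ[[chrom]]$end & en > occ[[chrom]]$start)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place gene ", i, " without overlap after ",
             max_tries, " tries; reduce n_genes or gene_length")
      occ[[chrom]]$start <- c(occ[[chrom]]$start, st)
      occ[[chrom]]$end <- c(occ[[chrom]]$end, en)
      placed[[i]] <- list(chrom = chrom, start = st, end = en,
                          strand = sample(c("+", "-"), 1))
    }
  }
  if (n_genes > 0) {
    st <- vapply(placed, `[[`, numeric(1), "start")
    en <- vapply(placed, `[[`, numeric(1), "end")
    ch <- vapply(placed, `[[`, character(1), "chrom")
    sd <- vapply(placed, `[[`, character(1), "strand")
    ex <- lapply(seq_len(n_genes), function(i)
      random_exons(st[i], en[i]))
    genes <- gene_models(sprintf("gene%04d", seq_len(n_genes)), ch, sd,
                         st, en,
                         exon_starts = lapply(ex, `[[`, "starts"),
                         exon_ends = lapply(ex, `[[`, "ends"))
    o <- order(genes$chrom, genes$start)
    genes <- genes[o, ]
    rownames(genes) <- NULL
  } else {
    genes <- gene_models(character(0), character(0), character(0),
                         numeric(0), numeric(0),
                         exon_starts = list(), exon_ends = list())
  }
  list(layout = layout, genes = genes, sequence = seqs)
}

# random exon/intron structure: n exons, first starting at gene start and
# last ending at gene end, separated by introns of >= 1 bp
random_exons <- function(start, end) {
  len <- end - start
  n_ex <- sample.int(min(5, max(1, len %/% 400)), 1)
  if (n_ex == 1) return(list(starts = start, ends = end))
  n_seg <- 2 * n_ex - 1
  cuts <- sort(sample.int(len - 1, n_seg - 1))
  bounds <- c(0, cuts, len) + start
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  keep <- seq(1, n_seg, by = 2)
  list(starts = seg_start[keep], ends = seg_end[keep])
}

#' Construct a simulation ground-truth record
#'
#' Picks the genes that carry promoter H3K4me3 enrichment and, among them,
#' the genes with a planted between-group fold change. Non-differential
#' enriched genes get the same factor in both groups; differential genes
#' have the group-B factor multiplied or divided by `differential_fold`
#' (direction random, at least one in each direction when possible).
#'
#' @param genes gene model data.frame.
#' @param n_enriched number of promoter-enriched genes.
#' @param n_differential number of enriched genes with a planted
#'   between-group fold change (subset of the enriched genes).
#' @param enrichment_factor promoter density over background for enriched
#'   genes (>= 1).
#' @param differential_fold planted fold change between groups (> 1).
#' @param seed integer seed.
#' @return object of class `simulation_truth`: list with `enriched_genes`
#'   (data.frame gene_id, factor_A, factor_B), `differential_genes`
#'   (character), `planted_motif_sites` (data.frame, empty until
#'   [plant_motif_sites()] is used), `background_rate` (filled by
#'   [simulate_tags()]), `seed`.
#' @export
simulate_truth <- function(genes, n_enriched, n_differential,
                           enrichment_factor = 10, differential_fold = 3,
                           seed = 1L) {
  stopifnot(n_differential <= n_enriched, n_enriched <= nrow(genes),
            enrichment_factor >= 1, differential_fold > 0)
  set.seed(as.integer(seed))
  ids <- sample(genes$gene_id, n_enriched)
  fa <- rep(enrichment_factor, n_enriched)
  fb <- fa
  diff_ids <- character(0)
  if (n_differential > 0) {
    diff_ids <- sample(ids, n_differential)
    up <- sample(c(TRUE, FALSE), n_differential, replace = TRUE)
    if (n_differential >= 2) {
      up[1] <- TRUE
      up[2] <- FALSE
    }
    j <- match(diff_ids, ids)
    fb[j] <- ifelse(up, fa[j] * differential_fold,
                    pmax(1, fa[j] / differential_fold))
  }
  structure(list(
    enriched_genes = data.frame(gene_id = ids, factor_A = fa, factor_B = fb,
                                stringsAsFactors = FALSE),
    differential_genes = diff_ids,
    planted_motif_sites = data.frame(chrom = character(0), pos = numeric(0),
                                     motif_id = character(0),
                                     strand = character(0),
                                     stringsAsFactors = FALSE),
    background_rate = NA_real_,
    seed = as.integer(seed)), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation_truth: %d enriched genes (%d differential), %d motif sites, seed %d\n",
    nrow(x$enriched_genes), length(x$differential_genes),
    nrow(x$planted_motif_sites), x$seed))
  invisible(x)
}

#' Simulate per-sample extended-fragment tag sets
#'
#' Fragment midpoints are drawn from a mixture of a uniform genomic
#' background and, for each enriched gene, a Gaussian component centered on
#' its TSS (sd `sigma`) whose mass scales the promoter density to
#' (approximately) `factor` times background. Fragment lengths are uniform
#' in `frag_len` and fragments are clipped inside chromosome bounds.
#' Per-sample totals are Poisson around `depth`. Each sample uses a
#' substream seeded by a stable hash of its id, so results do not depend on
#' sample order.
#'
#' @param layout `genome_layout`.
#' @param genes gene model data.frame.
#' @param truth `simulation_truth` (its seed drives all sampling).
#' @param n_samples_per_group samples per group (groups "A" and "B").
#' @param depth expected tags per sample.
#' @param frag_len length-2 fragment length range (bp).
#' @param sigma Gaussian sd of the promoter enrichment component (bp).
#' @return list of `tag_set` (samples A1..An then B1..Bn). `truth` is
#'   returned updated (background_rate filled) as attribute "truth".
#' @export
simulate_tags <- function(layout, genes, truth, n_samples_per_group = 3,
                          depth = 2e5, frag_len = c(150, 250), sigma = 500) {
  stop_if_not_layout(layout)
  stopifnot(inherits(truth, "simulation_truth"), depth > 0)
  enr <- truth$enriched_genes
  if (nrow(enr) && any(c(enr$factor_A, enr$factor_B) < 1))
    stop("enrichment factors must be >= 1")
  gidx <- match(enr$gene_id, genes$gene_id)
  if (anyNA(gidx)) stop("truth references unknown genes")
  L <- genome_size(layout)
  lens <- unclass(layout)
  samples <- c(paste0("A", seq_len(n_samples_per_group)),
               paste0("B", seq_len(n_samples_per_group)))
  groups <- rep(c("A", "B"), each = n_samples_per_group)
  # component mass: (factor - 1) x 2 kb promoter window per enriched gene
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    set.seed(substream_seed(truth$seed, samples[i]))
    f <- if (groups[i] == "A") enr$factor_A else enr$factor_B
    gmass <- if (nrow(enr)) (f - 1) * 2000 else numeric(0)
    mass <- c(L, gmass)
    n <- stats::rpois(1, depth)
    comp <- if (length(mass) > 1)
      sample.int(length(mass), n, replace = TRUE, prob = mass)
    else rep(1L, n)
    mid <- numeric(n)
    chrom <- character(n)
    bg <- comp == 1L
    if (any(bg)) {
      ci <- sample.int(length(lens), sum(bg), replace = TRUE, prob = lens)
      chrom[bg] <- names(lens)[ci]
      mid[bg] <- floor(stats::runif(sum(bg), 0, lens[ci]))
    }
    if (any(!bg)) {
      gi <- gidx[comp[!bg] - 1L]
      chrom[!bg] <- genes$chrom[gi]
      mid[!bg] <- round(stats::rnorm(sum(!bg), genes$tss[gi], sigma))
    }
    len <- sample(seq(frag_len[1], frag_len[2]), n, replace = TRUE)
    st <- round(mid - len / 2)
    cl <- lens[chrom]
    st <- pmax(0, pmin(st, cl - len))
    fr <- data.frame(chrom = chrom, start = st, end = st + len,
                     stringsAsFactors = FALSE)
    fr <- fr[order(fr$chrom, fr$start), ]
    rownames(fr) <- NULL
    out[[i]] <- tag_set(samples[i], groups[i], fr, layout)
  }
  truth$background_rate <- depth / L
  attr(out, "truth") <- truth
  out
}

#' Plant motif occurrences into a genome sequence
#'
#' Overwrites the sequence at randomly chosen positions inside the given
#' intervals with the motif consensus (or its reverse complement for minus
#' strand placements). The number of sites per interval is Poisson with the
#' given mean; sites are non-overlapping within an interval.
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param intervals data.frame chrom/start/end (0-based half-open).
#' @param motifs list of `pw_motif` (see [read_jaspar_pfm()]).
#' @param mean_sites_per_interval Poisson mean of planted sites per interval.
#' @param seed integer seed.
#' @return list with `sequence` (modified DNAStringSet) and `sites`
#'   (data.frame chrom, pos, motif_id, strand).
#' @export
plant_motif_sites <- function(seqs, intervals, motifs,
                              mean_sites_per_interval = 2.5, seed = 1L) {
  set.seed(as.integer(seed))
  stopifnot(length(motifs) >= 1)
  rec <- list()
  for (r in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[r]
    lo <- intervals$start[r]
    hi <- intervals$end[r]
    k <- stats::rpois(1, mean_sites_per_interval)
    if (k == 0) next
    used_s <- numeric(0)
    used_e <- numeric(0)
    for (j in seq_len(k)) {
      m <- motifs[[sample.int(length(motifs), 1)]]
      w <- ncol(m$counts)
      if (hi - lo < w) next
      for (try in 1:50) {
        pos <- lo + sample.int(hi - lo - w + 1, 1) - 1
        if (!any(pos < used_e & pos + w > used_s)) break
        pos <- NA
      }
      if (is.na(pos)) next
      strand <- sample(c("+", "-"), 1)
      cons <- motif_consensus(m)
      if (strand == "-")
        cons <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(cons)))
      Biostrings::subseq(seqs[[chrom]], pos + 1, pos + w) <-
        Biostrings::DNAString(cons)
      used_s <- c(used_s, pos)
      used_e <- c(used_e, pos + w)
      rec[[length(rec) + 1]] <- data.frame(
        chrom = chrom, pos = pos, motif_id = m$motif_id, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rec)) do.call(rbind, rec) else
    data.frame(chrom = character(0), pos = numeric(0),
               motif_id = character(0), strand = character(0),
               stringsAsFactors = FALSE)
  list(sequence = seqs, sites = sites)
}

#' Simulate a ChIP-qPCR Ct table across postmortem intervals
#'
#' Enrichment of positive targets (percent input) decays exponentially with
#' postmortem time with an antibody-specific half-life; the negative-control
#' gene-desert region is flat. Ct values are back-computed from the planted
#' percent input with Gaussian cycle noise, mirroring standard
#' percent-input chemistry: percent_input = 100 x 2^(ct_input_adj - ct_ip).
#'
#' @param timepoints postmortem intervals in hours.
#' @param antibodies character; one enrichment decay half-life each.
#' @param halflife named numeric, hours per antibody; `Inf` means no decay.
#' @param base_percent named numeric, percent input of positive targets at
#'   0 h per antibody.
#' @param targets positive target names; a negative control "Untr6" is
#'   always added.
#' @param negative_percent flat percent input of the negative region.
#' @param replicates technical replicates per condition (>= 2).
#' @param ct_noise_sd Gaussian sd of Ct noise (cycles).
#' @param input_fraction fraction of chromatin kept as input (dilution
#'   adjustment); 1 means undiluted.
#' @param seed integer seed.
#' @return data.frame with columns target, antibody, timepoint_h, replicate,
#'   ct_ip, ct_input.
#' @export
simulate_qpcr <- function(timepoints = c(0, 6, 24, 48, 72, 96),
                          antibodies = c("H3K4me3", "H3K27Ac", "RNAPol"),
                          halflife = c(H3K4me3 = 72, H3K27Ac = 48,
                                       RNAPol = 12),
                          base_percent = c(H3K4me3 = 20, H3K27Ac = 8,
                                           RNAPol = 2),
                          targets = c("ACTB", "GAPDH"),
                          negative_percent = 0.1,
                          replicates = 3, ct_noise_sd = 0.15,
                          input_fraction = 1, seed = 1L) {
  stopifnot(replicates >= 2)
  set.seed(as.integer(seed))
  all_targets <- c(targets, "Untr6")
  grid <- expand.grid(target = all_targets, antibody = antibodies,
                      timepoint_h = timepoints,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  hl <- halflife[grid$antibody]
  pct <- ifelse(grid$target == "Untr6", negative_percent,
                base_percent[grid$antibody] *
                  2^(-grid$timepoint_h / hl))
  ct_input <- stats::rnorm(nrow(grid), 20, 0.1)
  ct_input_adj <- ct_input - log2(1 / input_fraction)
  ct_ip <- ct_input_adj - log2(pct / 100) +
    stats::rnorm(nrow(grid), 0, ct_noise_sd)
  out <- grid
  out$ct_ip <- ct_ip
  out$ct_input <- ct_input
  out <- out[order(out$antibody, out$target, out$timepoint_h,
                   out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Write / read the qPCR Ct table and the simulation truth record
#'
#' Plain TSV; truth additionally as JSON for machine reading.
#'
#' @param qpcr data.frame from [simulate_qpcr()].
#' @param truth `simulation_truth`.
#' @param path file path (for truth JSON, `.json` is appended to `path`).
#' @return read functions return the parsed object.
#' @export
write_qpcr_table <- function(qpcr, path) {
  utils::write.table(qpcr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname write_qpcr_table
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$enriched_genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(enriched_genes = truth$enriched_genes,
         differential_genes = truth$differential_genes,
         planted_motif_sites = truth$planted_motif_sites,
         background_rate = truth$background_rate,
         seed = truth$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
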