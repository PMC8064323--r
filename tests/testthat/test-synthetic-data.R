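test_that("simulate_genome handles the degenerate no-gene case", {
  gen <- simulate_genome(1, 1e6, 0, seed = 7)
  expect_s3_class(gen$layout, "genome_layout")
  expect_equal(unname(unclass(gen$layout)), 1e6)
  expect_equal(nrow(gen$genes), 0)
  expect_equal(Biostrings::width(gen$sequence), 1e6)
})

test_that("simulate_genome is deterministic and genes never overlap", {
  g1 <- simulate_genome(2, 1e6, 40, seed = 1)
  g2 <- simulate_genome(2, 1e6, 40, seed = 1)
  expect_identical(g1$genes[, 1:7], g2$genes[, 1:7])
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))

  gen <- simulate_genome(1, 1e6, 50, seed = 3)
  g <- gen$genes
  # brute-force O(n^2) pairwise overlap check
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(g))) {
      if (i >= j || g$chrom[i] != g$chrom[j]) next
      expect_true(g$end[i] <= g$start[j] || g$end[j] <= g$start[i],
                  label = sprintf("genes %d/%d disjoint", i, j))
    }
  }
  # exon invariants: inside span, sorted, non-overlapping
  for (i in seq_len(nrow(g))) {
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    expect_true(all(es >= g$start[i]) && all(ee <= g$end[i]))
    expect_true(all(ee > es))
    if (length(es) > 1) expect_true(all(es[-1] >= ee[-length(ee)]))
  }
})

test_that("strand convention: tss/tes follow the strand", {
  gen <- simulate_genome(1, 1e6, 30, seed = 5)
  plus <- gen$genes$strand == "+"
  expect_true(all(gen$genes$tss[plus] < gen$genes$tes[plus]))
  expect_true(all(gen$genes$tss[!plus] > gen$genes$tes[!plus]))
})

test_that("null tags are homogeneous Poisson and totals are conserved", {
  gen <- simulate_genome(1, 1e7, 10, seed = 2)
  truth <- simulate_truth(gen$genes, 0, 0, seed = 2)
  tags <- simulate_tags(gen$layout, gen$genes, truth, 1, 2e5)
  ts <- tags[[1]]
  expect_equal(ts$total_count, nrow(ts$fragments))
  expect_true(all(ts$fragments$start >= 0))
  expect_true(all(ts$fragments$end <= 1e7))
  lens <- ts$fragments$end - ts$fragments$start
  expect_true(all(lens >= 150 & lens <= 250))
  cov <- bin_tags(ts, gen$layout, 1000)
  k <- cov$counts$chr1
  expect_equal(sum(k), ts$total_count)  # conservation over 10k bins
  # index-of-dispersion chi-square goodness of fit against Poisson
  disp <- sum((k - mean(k))^2) / mean(k)
  p <- stats::pchisq(disp, df = length(k) - 1, lower.tail = FALSE)
  expect_gt(min(p, 1 - p), 0.001)
})

test_that("planted promoter enrichment reaches its factor over background", {
  gen <- simulate_genome(1, 2e6, 20, seed = 11)
  truth <- simulate_truth(gen$genes, 5, 0, enrichment_factor = 10, seed = 11)
  ratios <- replicate(20, {
    truth$seed <- truth$seed + 1
    tags <- simulate_tags(gen$layout, gen$genes, truth, 1, 5e4)[[1]]
    mids <- floor((tags$fragments$start + tags$fragments$end) / 2)
    enr <- gen$genes[match(truth$enriched_genes$gene_id,
                           gen$genes$gene_id), ]
    inprom <- sum(vapply(seq_len(nrow(enr)), function(i)
      sum(mids >= enr$tss[i] - 1000 & mids < enr$tss[i] + 1000),
      numeric(1)))
    prom_density <- inprom / (2000 * nrow(enr))
    bg_density <- tags$total_count / 2e6
    prom_density / bg_density
  })
  expect_true(all(ratios >= 5))
})

test_that("planted group fold is recovered within a sampling envelope", {
  gen <- simulate_genome(1, 1e7, 10, seed = 4)
  g <- gen$genes$gene_id[1]
  truth <- simulate_truth(gen$genes, 1, 0, enrichment_factor = 1, seed = 4)
  truth$enriched_genes <- data.frame(gene_id = g, factor_A = 5,
                                     factor_B = 1)
  tssg <- gen$genes$tss[gen$genes$gene_id == g]
  ratios <- vapply(1:20, function(s) {
    truth$seed <- s
    tags <- simulate_tags(gen$layout, gen$genes, truth, 1, 2e5)
    dens <- vapply(tags, function(ts) {
      mids <- floor((ts$fragments$start + ts$fragments$end) / 2)
      sum(ts$fragments$chrom == gen$genes$chrom[1] &
            mids >= tssg - 1000 & mids < tssg + 1000)
    }, numeric(1))
    dens[1] / dens[2]  # A1 / B1
  }, numeric(1))
  expect_gt(mean(ratios), 3.5)
  expect_lt(mean(ratios), 6.5)
})

test_that("simulate_tags substreams make samples order-independent", {
  gen <- simulate_genome(1, 1e6, 10, seed = 6)
  truth <- simulate_truth(gen$genes, 5, 2, seed = 6)
  t1 <- simulate_tags(gen$layout, gen$genes, truth, 2, 1e4)
  t2 <- simulate_tags(gen$layout, gen$genes, truth, 2, 1e4)
  expect_identical(t1[[1]]$fragments, t2[[1]]$fragments)
  expect_identical(t1[[4]]$fragments, t2[[4]]$fragments)
})

test_that("qPCR table has the planted shape and decay behavior", {
  q <- simulate_qpcr(timepoints = c(0, 24, 48), replicates = 3, seed = 1)
  # 3 targets x 3 antibodies x 3 timepoints x 3 replicates
  expect_equal(nrow(q), 3 * 3 * 3 * 3)
  expect_equal(sum(q$target == "GAPDH" & q$antibody == "H3K4me3"), 9)

  # no-decay limit: infinite half-life leaves 96 h equal to 0 h within noise
  q0 <- simulate_qpcr(timepoints = c(0, 96), halflife = c(H3K4me3 = Inf),
                      antibodies = "H3K4me3", replicates = 50,
                      ct_noise_sd = 0.05, seed = 2)
  e0 <- qpcr_enrichment(q0)
  m <- tapply(e0$fold_over_negative[e0$target == "GAPDH"],
              e0$timepoint_h[e0$target == "GAPDH"], mean)
  expect_lt(abs(log2(m[["96"]] / m[["0"]])), 3 * 0.05 * sqrt(2 / 50) * 10)

  # half-life 24 h: enrichment at 48 h is one quarter of 0 h, within 2 se
  q24 <- simulate_qpcr(timepoints = c(0, 48), halflife = c(H3K4me3 = 24),
                       antibodies = "H3K4me3", replicates = 50,
                       ct_noise_sd = 0.1, seed = 3)
  e24 <- qpcr_enrichment(q24)
  g <- e24[e24$target == "GAPDH", ]
  lr <- log2(tapply(g$fold_over_negative, g$timepoint_h, mean))
  obs <- lr[["0"]] - lr[["48"]]
  se <- sqrt(2) * stats::sd(log2(g$fold_over_negative[g$timepoint_h == 0])) /
    sqrt(50)
  expect_lt(abs(obs - 2), 2 * se + 0.05)
})

test_that("plant_motif_sites writes the consensus into the sequence", {
  gen <- simulate_genome(1, 1e5, 0, seed = 8)
  m <- toy_motif(c("G", "G", "G", "G", "C", "A", "G", "G", "G", "C"))
  iv <- data.frame(chrom = "chr1", start = c(1000, 5000),
                   end = c(3000, 7000))
  pl <- plant_motif_sites(gen$sequence, iv, list(m), 3, seed = 9)
  expect_gt(nrow(pl$sites), 0)
  cons <- motif_consensus(m)
  for (i in seq_len(nrow(pl$sites))) {
    s <- as.character(Biostrings::subseq(pl$sequence[[pl$sites$chrom[i]]],
                                         pl$sites$pos[i] + 1,
                                         pl$sites$pos[i] + nchar(cons)))
    expected <- if (pl$sites$strand[i] == "+") cons else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    expect_equal(s, expected)
  }
})
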