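two_genes <- function() {
  gene_models(c("gplus", "gminus"), c("chr1", "chr1"), c("+", "-"),
              c(10000, 40000), c(20000, 50000))
}

test_that("proximal promoter classification is strand-aware", {
  genes <- two_genes()
  # + strand gene, TSS 10,000: midpoint 9,500 is 500 bp upstream
  r <- annotate_regions(data.frame(chrom = "chr1", start = 9400,
                                   end = 9600), genes)
  expect_equal(as.character(r$category), "proximal_promoter")
  expect_equal(r$gene_id, "gplus")
  expect_equal(r$dist_tss, -500)
  # - strand gene, TSS 50,000: midpoint 50,400 is 400 bp upstream
  r2 <- annotate_regions(data.frame(chrom = "chr1", start = 50300,
                                    end = 50500), genes)
  expect_equal(as.character(r2$category), "proximal_promoter")
  expect_equal(r2$gene_id, "gminus")
  expect_equal(r2$dist_tss, -400)
  # 2 kb upstream is a distal promoter; 5 kb upstream is intergenic
  r3 <- annotate_regions(data.frame(chrom = "chr1", start = c(7900, 4900),
                                    end = c(8100, 5100)), genes)
  expect_equal(as.character(r3$category),
               c("distal_promoter", "distal_intergenic"))
  expect_true(is.na(r3$gene_id[2]))
})

test_that("downstream and in-gene categories follow the rules", {
  genes <- two_genes()
  # 500 bp past the + gene TES (20,000)
  r <- annotate_regions(data.frame(chrom = "chr1", start = 20400,
                                   end = 20600), genes)
  expect_equal(as.character(r$category), "proximal_downstream")
  # 2 kb past the - gene TES (40,000, i.e. below the span)
  r2 <- annotate_regions(data.frame(chrom = "chr1", start = 37900,
                                    end = 38100), genes)
  expect_equal(as.character(r2$category), "distal_downstream")
  # midpoint in the first 10% of a + gene span is 5'UTR, last 10% is 3'UTR
  r3 <- annotate_regions(data.frame(chrom = "chr1",
                                    start = c(10400, 19400),
                                    end = c(10600, 19600)), genes)
  expect_equal(as.character(r3$category),
               c("five_prime_utr", "three_prime_utr"))
  # same fractions mirror on the - strand gene
  r4 <- annotate_regions(data.frame(chrom = "chr1",
                                    start = c(49400, 40400),
                                    end = c(49600, 40600)), genes)
  expect_equal(as.character(r4$category),
               c("five_prime_utr", "three_prime_utr"))
})

test_that("random regions classify identically to the rule-by-rule oracle", {
  gen <- simulate_genome(1, 2e6, 60, seed = 17)
  set.seed(18)
  n <- 400
  st <- sample.int(2e6 - 500, n)
  regions <- data.frame(chrom = "chr1", start = st, end = st + 500)
  got <- annotate_regions(regions, gen$genes)
  oracle <- oracle_annotate(regions, gen$genes)
  expect_equal(as.character(got$category), oracle$category)
  same_gene <- !is.na(got$gene_id)
  expect_equal(got$gene_id[same_gene], oracle$gene_id[same_gene])
  expect_true(all(is.na(got$gene_id) ==
                    (got$category == "distal_intergenic")))
})

test_that("strand mirroring leaves categories unchanged", {
  gen <- simulate_genome(1, 1e6, 40, seed = 19)
  set.seed(20)
  st <- sample.int(1e6 - 400, 300)
  regions <- data.frame(chrom = "chr1", start = st, end = st + 400)
  fwd <- annotate_regions(regions, gen$genes)
  L <- 1e6
  g <- gen$genes
  mirrored <- gene_models(
    g$gene_id, g$chrom, ifelse(g$strand == "+", "-", "+"),
    L - g$end, L - g$start,
    exon_starts = lapply(seq_len(nrow(g)), function(i)
      rev(L - g$exon_ends[[i]])),
    exon_ends = lapply(seq_len(nrow(g)), function(i)
      rev(L - g$exon_starts[[i]])))
  # mirror the regions so even-length midpoints map exactly to L - 1 - mid
  mreg <- data.frame(chrom = regions$chrom, start = L - 1 - regions$end,
                     end = L - 1 - regions$start)
  rev_ann <- annotate_regions(mreg, mirrored)
  expect_equal(as.character(rev_ann$category), as.character(fwd$category))
})

test_that("genes_near_peaks respects the 10-kb half-open margin", {
  genes <- two_genes()
  regions <- data.frame(chrom = "chr1",
                        start = c(35000, 30000, 25000, 0),
                        end = c(36000, 30100, 25500, 100))
  hits <- genes_near_peaks(regions, genes, margin = 10000)
  # gplus margin window is [0, 30000): regions 3 and 4 only; region 2
  # starts exactly at the boundary and is excluded (half-open)
  expect_equal(hits$gplus, c(3, 4))
  # gminus window is [30000, 60000): regions 1 and 2
  expect_equal(hits$gminus, c(1, 2))
  exact <- data.frame(chrom = "chr1", start = 60000, end = 60100)
  expect_null(genes_near_peaks(exact, genes, 10000)$gminus)
  far <- data.frame(chrom = "chr1", start = 65000, end = 66000)
  expect_length(genes_near_peaks(far, genes, 10000), 0)
  # random data match a quadratic scan
  set.seed(23)
  gen <- simulate_genome(1, 1e6, 30, seed = 23)
  st <- sample.int(1e6 - 300, 200)
  reg <- data.frame(chrom = "chr1", start = st, end = st + 300)
  got <- genes_near_peaks(reg, gen$genes, 10000)
  for (j in seq_len(nrow(gen$genes))) {
    manual <- which(reg$start < gen$genes$end[j] + 10000 &
                      reg$end > gen$genes$start[j] - 10000)
    if (length(manual))
      expect_equal(got[[gen$genes$gene_id[j]]], manual)
    else expect_null(got[[gen$genes$gene_id[j]]])
  }
})

test_that("feature pie fractions partition the annotation set", {
  gen <- simulate_genome(1, 1e6, 30, seed = 29)
  set.seed(30)
  st <- sample.int(1e6 - 300, 250)
  ann <- annotate_regions(data.frame(chrom = "chr1", start = st,
                                     end = st + 300), gen$genes)
  pie <- feature_pie(ann)
  expect_equal(sum(pie), 1, tolerance = 1e-9)
  expect_equal(unname(pie["intron"]),
               mean(ann$category == "intron"))
  expect_error(feature_pie(ann[0, ]), "undefined")
})

test_that("random control peaks preserve lengths and spread uniformly", {
  layout <- genome_layout(c("chr1", "chr2"), c(5e5, 5e5))
  set.seed(33)
  st <- sample.int(4e5, 100)
  regions <- data.frame(chrom = "chr1", start = st,
                        end = st + sample(200:2000, 100, replace = TRUE))
  ctrl <- random_control_peaks(regions, layout, seed = 3)
  expect_equal(sort(ctrl$end - ctrl$start),
               sort(regions$end - regions$start))
  expect_true(all(ctrl$start >= 0))
  expect_true(all(ctrl$end <= unclass(layout)[ctrl$chrom]))
  expect_identical(ctrl, random_control_peaks(regions, layout, seed = 3))

  # uniformity: chi-square over 10 genome slices across 50 draws
  mids <- unlist(lapply(1:50, function(s) {
    d <- random_control_peaks(regions, layout, seed = s)
    (match(d$chrom, names(layout)) - 1) * 5e5 + (d$start + d$end) / 2
  }))
  counts <- tabulate(findInterval(mids, seq(0, 1e6, length.out = 11),
                                  rightmost.closed = TRUE), nbins = 10)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)

  # on a gene-free genome every control peak is intergenic
  empty_genes <- gene_models(character(0), character(0), character(0),
                             numeric(0), numeric(0), list(), list())
  ann <- annotate_regions(ctrl, empty_genes)
  expect_true(all(ann$category == "distal_intergenic"))
})
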