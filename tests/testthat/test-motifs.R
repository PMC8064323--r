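test_that("JASPAR parsing and log-odds derivation follow the pinned rule", {
  uniform <- read_jaspar_pfm(text = paste(
    ">M0001 TEST",
    "A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]", "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]",
    sep = "\n"))[[1]]
  expect_equal(uniform$motif_id, "M0001")
  expect_equal(uniform$factor_name, "TEST")
  expect_true(all(abs(uniform$log_odds) < 1e-12))

  single <- read_jaspar_pfm(text = paste(
    ">M0002 X",
    "A [ 10 10 10 10 ]", "C [ 0 0 0 0 ]", "G [ 0 0 0 0 ]", "T [ 0 0 0 0 ]",
    sep = "\n"))[[1]]
  # weight for A with pseudocount mass 1, uniform background:
  # log2((10.25/11)/0.25)
  expect_equal(unname(single$log_odds["A", 1]), log2((10.25 / 11) / 0.25),
               tolerance = 1e-12)

  hdr <- read_jaspar_pfm(text = paste(
    "> MA0079.5 SP1",
    "A [ 1 2 3 4 ]", "C [ 1 1 1 1 ]", "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]",
    sep = "\n"))[[1]]
  expect_equal(hdr$motif_id, "MA0079.5")
  expect_equal(hdr$factor_name, "SP1")

  expect_error(read_jaspar_pfm(text = paste(
    ">BAD", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]", sep = "\n")),
    "ragged")
  expect_error(pw_motif("NEG", matrix(c(-1, rep(1, 15)), 4, 4)))
})

test_that("the consensus scores exactly 1.0 on both strands", {
  m <- toy_motif()
  cons <- motif_consensus(m)
  hit <- scan_sequence(cons, m, cutoff = 1)
  expect_equal(hit$offset[hit$strand == "+"], 0)
  expect_equal(hit$score[hit$strand == "+"], 1.0)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  hit_rc <- scan_sequence(rc, m, cutoff = 1)
  expect_equal(hit_rc$strand, "-")
  expect_equal(hit_rc$score, 1.0)
})

test_that("scanning equals exhaustive per-offset scoring on random sequence", {
  m <- toy_motif()
  set.seed(61)
  seq <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  got <- scan_sequence(seq, m, cutoff = 0.85)
  # independent oracle: per-offset double loop over positions and strands
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- m$counts
  w <- log2((counts + 0.25) / matrix(colSums(counts) + 1, 4,
                                     ncol(counts), byrow = TRUE)) -
    log2(0.25)
  smin <- sum(apply(w, 2, min))
  smax <- sum(apply(w, 2, max))
  chars <- strsplit(seq, "")[[1]]
  L <- ncol(counts)
  exp_hits <- list()
  for (off in 0:(200 - L)) {
    win <- chars[(off + 1):(off + L)]
    s_f <- 0
    s_r <- 0
    for (j in seq_len(L)) {
      s_f <- s_f + w[win[j], j]
      s_r <- s_r + w[comp[[win[L + 1 - j]]], j]
    }
    for (sc in list(c((s_f - smin) / (smax - smin), "+"),
                    c((s_r - smin) / (smax - smin), "-"))) {
      if (as.numeric(sc[1]) >= 0.85)
        exp_hits[[length(exp_hits) + 1]] <-
          data.frame(offset = off, strand = sc[2],
                     score = as.numeric(sc[1]))
    }
  }
  expected <- if (length(exp_hits)) do.call(rbind, exp_hits) else
    data.frame(offset = integer(0), strand = character(0),
               score = numeric(0))
  expected <- expected[order(expected$offset, expected$strand), ]
  rownames(expected) <- NULL
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("strand symmetry: reverse complement mirrors the hit set", {
  m <- toy_motif()
  set.seed(62)
  seq <- paste0(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  # plant one consensus so the hit set is non-empty
  substr(seq, 101, 100 + ncol(m$counts)) <- motif_consensus(m)
  fwd <- scan_sequence(seq, m, cutoff = 0.8)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  rev_hits <- scan_sequence(rc, m, cutoff = 0.8)
  expect_gt(nrow(fwd), 0)
  expect_equal(nrow(fwd), nrow(rev_hits))
  mapped <- data.frame(offset = 300 - ncol(m$counts) - rev_hits$offset,
                       strand = ifelse(rev_hits$strand == "+", "-", "+"),
                       score = rev_hits$score)
  mapped <- mapped[order(mapped$offset, mapped$strand), ]
  rownames(mapped) <- NULL
  expect_equal(fwd, mapped, tolerance = 1e-12)
})

test_that("N-containing windows are skipped and cutoff is monotone", {
  m <- toy_motif()
  seqN <- paste0(motif_consensus(m), "N", motif_consensus(m))
  hits <- scan_sequence(seqN, m, cutoff = 0.9)
  # windows crossing the N are absent
  expect_true(all(hits$offset %in% c(0, ncol(m$counts) + 1)))
  set.seed(63)
  seq <- paste0(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  n_low <- nrow(scan_sequence(seq, m, cutoff = 0.6))
  n_high <- nrow(scan_sequence(seq, m, cutoff = 0.8))
  expect_gte(n_low, n_high)
  expect_equal(nrow(scan_sequence("ACG", m, 0.5)), 0)
})

test_that("motif frequency table recovers planted sites per interval", {
  m <- bundled_motifs()[[1]]  # 10-bp GC-box, low random-match rate
  avgs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    gen <- simulate_genome(1, 3e5, 0, seed = 100 + s)
    st <- seq(2000, 290000, length.out = 50)
    iv <- data.frame(chrom = "chr1", start = st, end = st + 2000)
    pl <- plant_motif_sites(gen$sequence, iv, list(m), 2.5,
                            seed = 200 + s)
    ft <- motif_frequency_table(iv, pl$sequence, list(m), flank = 200,
                                cutoff = 0.85)
    ft$avg_sites_per_interval
  }, numeric(1))
  expect_gt(mean(avgs), 2.0)
  expect_lt(mean(avgs), 3.0)
})

test_that("frequency table orders by average and validates inputs", {
  gen <- simulate_genome(1, 5e4, 0, seed = 71)
  m1 <- toy_motif(strsplit("GGCACGTCAG", "")[[1]], id = "AAA1")
  iv <- data.frame(chrom = "chr1", start = c(1000, 3000),
                   end = c(2000, 4000))
  # plant three non-overlapping consensus copies of m1 in interval 1
  seqs <- gen$sequence
  cons <- motif_consensus(m1)
  for (pos in c(1100, 1300, 1500))
    Biostrings::subseq(seqs[["chr1"]], pos + 1, pos + nchar(cons)) <-
      Biostrings::DNAString(cons)
  ft <- motif_frequency_table(iv, seqs, list(m1), flank = 0, cutoff = 0.95)
  expect_equal(ft$total_sites, 3)
  expect_equal(ft$avg_sites_per_interval, 1.5)
  expect_error(motif_frequency_table(iv[0, ], seqs, list(m1)),
               "no intervals")
  bad <- data.frame(chrom = "chrX", start = 0, end = 100)
  expect_error(motif_frequency_table(bad, seqs, list(m1)), "chrX")
})
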