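#' Default pipeline configuration
#'
#' A nested list of every tunable stage parameter, with the analysis
#' settings at their field defaults (200 bp scoring window, 600 bp gap,
#' island FDR 1e-10, 10 kb gene margin, promoter TSS +/- 1 kb, 1.5-fold and
#' p < 0.05 differential filter, 2/5/1.5 kb profile flanks with 32 bp bins
#' and 5 clusters, 200 bp motif flanks) and a synthetic study sized for a
#' desk-scale run: a 10 Mb genome, 400 genes, 3 samples per group at an
#' expected depth of 2e5 tags.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(n_chroms = 2L, chrom_length = 5e6, n_genes = 400L,
                  gene_length = c(2000, 20000)),
    truth = list(n_enriched = 200L, n_differential = 40L,
                 enrichment_factor = 10, differential_fold = 3),
    tags = list(n_samples_per_group = 3L, depth = 2e5,
                frag_len = c(150, 250), sigma = 500),
    islands = list(window = 200L, gap = 600L, window_p = 0.2,
                   fdr_cutoff = 1e-10, track_bin = 32L),
    annotation = list(proximal = 1000L, distal = 3000L, margin = 10000L,
                      utr_frac = 0.1),
    differential = list(fc_cutoff = 1.5, alpha = 0.05, pseudo = 0.5),
    profiles = list(flank_gene = 2000L, flank_region = 5000L,
                    flank_promoter = 1500L, bin = 32L, k = 5L),
    motifs = list(flank = 200L, cutoff = 0.85,
                  mean_planted_sites = 2.5),
    qpcr = list(timepoints = c(0, 6, 24, 48, 72, 96), replicates = 3L,
                halflife = list(H3K4me3 = 72, H3K27Ac = 48, RNAPol = 12),
                base_percent = list(H3K4me3 = 20, H3K27Ac = 8, RNAPol = 2),
                negative_percent = 0.1, ct_noise_sd = 0.15,
                input_fraction = 1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  stopifnot(cfg$islands$window > 0, cfg$islands$gap > 0,
            cfg$annotation$proximal > 0, cfg$annotation$distal > 0,
            cfg$differential$fc_cutoff > 0, cfg$motifs$flank >= 0)
  cfg
}

#' Bundled synthetic motif library
#'
#' Three synthetic position frequency matrices shipped with the package
#' (GC-box, CRE and E-box-like consensi); they are stand-ins for a real
#' motif database, used to plant and recover motif occurrences in the
#' synthetic genome.
#'
#' @return list of `pw_motif`.
#' @export
bundled_motifs <- function() {
  read_jaspar_pfm(system.file("extdata", "synthetic_motifs.jaspar",
                              package = "chipislands", mustWork = TRUE))
}

# midpoint counts of a tag set inside each region (half-open)
count_in_regions <- function(tags, regions) {
  fr <- tags$fragments
  mids <- fragment_midpoints(fr)
  counts <- integer(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    ri <- which(regions$chrom == chrom)
    m <- sort(mids[fr$chrom == chrom])
    if (!length(m)) next
    counts[ri] <- findInterval(regions$end[ri] - 1, m) -
      findInterval(regions$start[ri] - 1, m)
  }
  counts
}

stage_log <- function(con, stage, t0, quiet) {
  msg <- sprintf("[%s] %s done in %.1f s", format(Sys.time(), "%H:%M:%S"),
                 stage, as.numeric(Sys.time()) - t0)
  writeLines(msg, con)
  if (!quiet) message(msg)
}

#' Run the full synthetic study end to end
#'
#' simulate -> density tracks -> downsample normalization -> island calling
#' -> merged regions / Venn -> annotation -> differential -> profiles ->
#' motif scan -> qPCR statistics. Every output is a plain-text file under
#' `outdir`; `manifest.tsv` lists each file with its row count and MD5
#' checksum, and `summary.json` carries the headline numbers of the run.
#' The whole run is deterministic given `config$seed`.
#'
#' @param config nested configuration list (see [default_config()]).
#' @param outdir output directory (created; must be empty or absent).
#' @param quiet suppress console stage messages.
#' @return invisibly, a list with `outdir`, `manifest` (data.frame),
#'   `summary` (list of computed headline numbers) and `truth`.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)))
    stop("outdir exists and is not empty: ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  logcon <- file(logfile, "w")
  on.exit(close(logcon))
  seed <- as.integer(config$seed)
  path <- function(...) file.path(outdir, ...)

  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_log(logcon, stage, t0, quiet)
    res
  }

  # -- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", function() {
    gen <- simulate_genome(config$genome$n_chroms,
                           config$genome$chrom_length,
                           config$genome$n_genes, seed = seed,
                           gene_length = config$genome$gene_length)
    truth <- simulate_truth(gen$genes, config$truth$n_enriched,
                            config$truth$n_differential,
                            config$truth$enrichment_factor,
                            config$truth$differential_fold,
                            seed = seed)
    motifs <- bundled_motifs()
    enr_genes <- gen$genes[match(truth$enriched_genes$gene_id,
                                 gen$genes$gene_id), ]
    promoters <- data.frame(chrom = enr_genes$chrom,
                            start = pmax(0, enr_genes$tss - 1000),
                            end = enr_genes$tss + 1000)
    planted <- plant_motif_sites(gen$sequence, promoters, motifs,
                                 config$motifs$mean_planted_sites,
                                 seed = substream_seed(seed, "motifs"))
    gen$sequence <- planted$sequence
    truth$planted_motif_sites <- planted$sites
    tags <- simulate_tags(gen$layout, gen$genes, truth,
                          config$tags$n_samples_per_group,
                          config$tags$depth, config$tags$frag_len,
                          config$tags$sigma)
    truth <- attr(tags, "truth")
    qpcr <- simulate_qpcr(
      timepoints = config$qpcr$timepoints,
      halflife = unlist(config$qpcr$halflife),
      base_percent = unlist(config$qpcr$base_percent),
      negative_percent = config$qpcr$negative_percent,
      replicates = config$qpcr$replicates,
      ct_noise_sd = config$qpcr$ct_noise_sd,
      input_fraction = config$qpcr$input_fraction,
      seed = substream_seed(seed, "qpcr"))
    Biostrings::writeXStringSet(gen$sequence, path("genome.fa"))
    write_chrom_sizes(gen$layout, path("chrom.sizes"))
    write_genes_bed12(gen$genes, path("genes.bed12"))
    for (ts in tags)
      write_tags_bed(ts, path(sprintf("tags_%s.bed", ts$sample_id)))
    write_truth(truth, path("truth.tsv"))
    write_qpcr_table(qpcr, path("qpcr.tsv"))
    list(gen = gen, truth = truth, tags = tags, qpcr = qpcr,
         motifs = motifs)
  })
  layout <- sim$gen$layout
  genes <- sim$gen$genes

  # -- density tracks ---------------------------------------------------
  run_stage("tracks", function() {
    for (ts in sim$tags) {
      cov <- bin_tags(ts, layout, config$islands$track_bin)
      write_bedgraph(cov, path(sprintf("coverage_%s.bedgraph",
                                       ts$sample_id)), ts$sample_id)
    }
  })

  # -- normalization ----------------------------------------------------
  norm_tags <- run_stage("downsample", function() {
    nt <- downsample_tags(sim$tags, seed = substream_seed(seed, "downsample"))
    for (ts in nt)
      write_tags_bed(ts, path(sprintf("tags_norm_%s.bed", ts$sample_id)))
    nt
  })
  groups <- vapply(norm_tags, `[[`, character(1), "group")
  names(groups) <- vapply(norm_tags, `[[`, character(1), "sample_id")

  # -- island calling ---------------------------------------------------
  islands <- run_stage("callpeaks", function() {
    isl <- lapply(norm_tags, function(ts) {
      cov <- bin_tags(ts, layout, config$islands$window)
      call_islands(cov, gap = config$islands$gap,
                   window_p = config$islands$window_p,
                   fdr_cutoff = config$islands$fdr_cutoff)
    })
    names(isl) <- names(groups)
    for (s in names(isl))
      write_islands_bed(isl[[s]], path(sprintf("islands_%s.bed", s)), s)
    isl
  })

  # -- merged regions ---------------------------------------------------
  merged <- run_stage("merge", function() {
    mg <- merge_regions(islands, groups)
    write_merged_regions(mg, path("merged"))
    samples <- names(islands)
    ov <- outer(samples, samples, Vectorize(function(a, b)
      pairwise_overlap_fraction(islands[[a]], islands[[b]])))
    dimnames(ov) <- list(samples, samples)
    utils::write.table(data.frame(sample = samples, round(ov, 4),
                                  check.names = FALSE),
                       path("pairwise_overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    attr(mg, "overlap") <- ov
    mg
  })

  # -- annotation -------------------------------------------------------
  ann <- run_stage("annotate", function() {
    a <- annotate_regions(merged$regions, genes,
                          config$annotation$proximal,
                          config$annotation$distal,
                          config$annotation$utr_frac)
    utils::write.table(a, path("annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pie <- feature_pie(a)
    ctrl <- random_control_peaks(merged$regions, layout,
                                 seed = substream_seed(seed, "control"))
    ctrl_pie <- feature_pie(annotate_regions(ctrl, genes,
                                             config$annotation$proximal,
                                             config$annotation$distal,
                                             config$annotation$utr_frac))
    utils::write.table(
      data.frame(category = names(pie), fraction = as.numeric(pie),
                 random_control = as.numeric(ctrl_pie)),
      path("feature_pie.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(annotations = a, pie = pie, control_pie = ctrl_pie)
  })

  # -- differential -----------------------------------------------------
  diff <- run_stage("diff", function() {
    prom <- do.call(rbind, lapply(norm_tags, quantify_signal, genes,
                                  "promoter"))
    body <- do.call(rbind, lapply(norm_tags, quantify_signal, genes,
                                  "gene_body"))
    dprom <- differential_call(prom, groups, config$differential$fc_cutoff,
                               config$differential$alpha,
                               config$differential$pseudo)
    dbody <- differential_call(body, groups, config$differential$fc_cutoff,
                               config$differential$alpha,
                               config$differential$pseudo)
    utils::write.table(dprom, path("differential_promoter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dbody, path("differential_genebody.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(presence_matrix(merged), path("presence_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    list(promoter = dprom, genebody = dbody)
  })

  # -- profiles ---------------------------------------------------------
  prof <- run_stage("profile", function() {
    pooled <- lapply(c("A", "B"), function(g) {
      fr <- do.call(rbind, lapply(norm_tags[groups == g],
                                  function(ts) ts$fragments))
      tag_set(paste0("pooled_", g), g, fr)
    })
    names(pooled) <- c("A", "B")
    out <- list()
    for (g in c("A", "B")) {
      pm_prom <- build_profile(pooled[[g]], genes, "promoter",
                               config$profiles$flank_promoter,
                               config$profiles$bin)
      pm_body <- build_profile(pooled[[g]], genes, "gene_body",
                               config$profiles$flank_gene,
                               config$profiles$bin)
      pm_reg <- if (nrow(merged$regions))
        build_profile(pooled[[g]], merged$regions, "merged_region",
                      config$profiles$flank_region, config$profiles$bin)
      else NULL
      lab <- cluster_profiles(pm_prom, config$profiles$k,
                              seed = substream_seed(seed, "cluster"))
      write_profile_matrix(pm_prom,
                           path(sprintf("profile_promoter_%s.tsv", g)), lab)
      write_profile_matrix(pm_body,
                           path(sprintf("profile_genebody_%s.tsv", g)))
      if (!is.null(pm_reg))
        write_profile_matrix(pm_reg,
                             path(sprintf("profile_region_%s.tsv", g)))
      utils::write.table(
        data.frame(offset = pm_prom$offsets, mean = average_plot(pm_prom)),
        path(sprintf("avgplot_promoter_%s.tsv", g)), sep = "\t",
        quote = FALSE, row.names = FALSE)
      out[[g]] <- list(promoter = pm_prom)
    }
    # scatter QC: per-region mean tag counts, group B on group A
    qc <- c(pearson_r = NA_real_, ols_slope = NA_real_)
    if (nrow(merged$regions) >= 3) {
      per_sample <- vapply(norm_tags,
                           function(ts) count_in_regions(ts, merged$regions),
                           numeric(nrow(merged$regions)))
      mean_a <- rowMeans(per_sample[, groups == "A", drop = FALSE])
      mean_b <- rowMeans(per_sample[, groups == "B", drop = FALSE])
      qc <- group_scatter_qc(mean_a, mean_b)
      utils::write.table(data.frame(region = seq_along(mean_a),
                                    mean_A = mean_a, mean_B = mean_b),
                         path("region_means.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(qc = qc)
  })

  # -- motif scan -------------------------------------------------------
  motif <- run_stage("motifscan", function() {
    if (!nrow(merged$regions)) return(NULL)
    ft <- motif_frequency_table(merged$regions, sim$gen$sequence,
                                sim$motifs, config$motifs$flank,
                                config$motifs$cutoff)
    utils::write.table(ft, path("motif_frequency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ft
  })

  # -- qPCR statistics --------------------------------------------------
  qstats <- run_stage("qpcr", function() {
    enr <- qpcr_enrichment(sim$qpcr, config$qpcr$input_fraction)
    utils::write.table(enr, path("qpcr_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rows <- list()
    for (ab in unique(enr$antibody)) {
      for (tg in setdiff(unique(enr$target), "Untr6")) {
        d <- enr[enr$antibody == ab & enr$target == tg, ]
        an <- stability_anova(d$fold_over_negative, d$timepoint_h)
        rows[[length(rows) + 1]] <- data.frame(
          antibody = ab, target = tg, F = an$F, p = an$p,
          n_significant_pairs = sum(an$pairwise$significant),
          stringsAsFactors = FALSE)
      }
    }
    anova_tab <- do.call(rbind, rows)
    slopes <- decay_slope(enr)
    utils::write.table(anova_tab, path("qpcr_anova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(slopes, path("qpcr_decay_slopes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(anova = anova_tab, slopes = slopes, enrichment = enr)
  })

  # -- summary + manifest ----------------------------------------------
  truth <- sim$truth
  diff_ids <- truth$differential_genes
  dp <- diff$promoter
  sens <- if (length(diff_ids))
    mean(dp$passes_filter[match(diff_ids, dp$target_id)]) else NA_real_
  nondiff <- setdiff(dp$target_id, diff_ids)
  null_rate <- mean(dp$passes_filter[match(nondiff, dp$target_id)])
  venn <- group_venn(merged)
  summary <- list(
    n_islands_per_sample = vapply(islands, nrow, numeric(1)),
    n_merged_regions = nrow(merged$regions),
    venn = as.list(venn),
    mean_pairwise_overlap = mean(attr(merged, "overlap")[
      upper.tri(attr(merged, "overlap"))]),
    modal_feature_category = names(which.max(ann$pie)),
    proximal_promoter_fraction = unname(ann$pie["proximal_promoter"]),
    differential_sensitivity = sens,
    differential_null_rate = null_rate,
    n_passing_filter = sum(dp$passes_filter),
    scatter_pearson_r = unname(prof$qc["pearson_r"]),
    scatter_ols_slope = unname(prof$qc["ols_slope"]),
    top_motif = if (!is.null(motif)) motif$motif_id[1] else NA,
    top_motif_avg_sites = if (!is.null(motif))
      motif$avg_sites_per_interval[1] else NA,
    qpcr_slopes = stats::setNames(as.list(qstats$slopes$slope),
                                  qstats$slopes$antibody))
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(config, path("config_echo.yaml"))

  files <- sort(setdiff(list.files(outdir), c("manifest.tsv",
                                              "pipeline.log")))
  manifest <- data.frame(
    file = files,
    rows = vapply(files, function(f)
      length(readLines(path(f), warn = FALSE)), numeric(1)),
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(outdir = outdir, manifest = manifest, summary = summary,
                 truth = truth))
}
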