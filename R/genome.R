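#' Genome layout
#'
#' A minimal description of a genome as a set of named chromosomes with
#' lengths, the coordinate frame for every interval in the package.
#' All interval coordinates in this package are 0-based half-open
#' (BED convention); conversion to 1-based happens only at FASTA and
#' GRanges boundaries.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of chromosome lengths in bp, > 0.
#' @return An object of class `genome_layout`: a named numeric vector of
#'   chromosome lengths.
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(stats::setNames(chrom_lengths, chrom_names),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(unclass(x))
  invisible(x)
}

genome_size <- function(layout) sum(unclass(layout))

stop_if_not_layout <- function(layout) {
  if (!inherits(layout, "genome_layout"))
    stop("expected a genome_layout object")
  invisible(layout)
}

#' Write / read chromosome sizes
#'
#' Plain two-column (chrom, length) tab-separated files, the UCSC
#' "chrom.sizes" convention.
#'
#' @param layout a `genome_layout`.
#' @param path file path.
#' @return `read_chrom_sizes` returns a `genome_layout`.
#' @export
write_chrom_sizes <- function(layout, path) {
  stop_if_not_layout(layout)
  utils::write.table(
    data.frame(chrom = names(layout), length = as.numeric(layout)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene model table
#'
#' Genes are strand-aware intervals with exon structure. `start`/`end` are
#' genomic (0-based half-open, start < end); `tss`/`tes` are derived from
#' strand: on "+" the TSS is `start` and the TES is `end`, on "-" the TSS is
#' `end` and the TES is `start`, so that on "-" genes tss > tes in genomic
#' coordinates.
#'
#' @param gene_id character ids, unique.
#' @param chrom chromosome per gene.
#' @param strand "+" or "-".
#' @param start,end genomic span, 0-based half-open.
#' @param exon_starts,exon_ends lists of integer vectors, exons within the
#'   gene span, sorted and non-overlapping.
#' @return data.frame with columns gene_id, chrom, strand, start, end, tss,
#'   tes and list-columns exon_starts, exon_ends.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(end <= start)) stop("gene end must exceed start")
  if (is.null(exon_starts)) exon_starts <- as.list(start)
  if (is.null(exon_ends)) exon_ends <- as.list(end)
  for (i in seq_len(n)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es))
      stop("malformed exons for gene ", gene_id[i])
    if (any(es < start[i]) || any(ee > end[i]))
      stop("exons outside gene span for gene ", gene_id[i])
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop("exons must be sorted and non-overlapping for gene ", gene_id[i])
  }
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tes <- ifelse(df$strand == "+", df$end, df$start)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  df
}

#' Write / read gene models as BED12
#'
#' Standard BED12 with exon blocks; scores are 0 and thick coordinates equal
#' the gene span. Coordinates stay 0-based half-open on disk.
#'
#' @param genes gene model data.frame from [gene_models()].
#' @param path file path.
#' @return `read_genes_bed12` returns a gene model data.frame.
#' @export
write_genes_bed12 <- function(genes, path) {
  n <- nrow(genes)
  sizes <- vapply(seq_len(n), function(i)
    paste0(genes$exon_ends[[i]] - genes$exon_starts[[i]], collapse = ","),
    character(1))
  offs <- vapply(seq_len(n), function(i)
    paste0(genes$exon_starts[[i]] - genes$start[i], collapse = ","),
    character(1))
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                    genes$strand, genes$start, genes$end, "0",
                    lengths(genes$exon_starts), sizes, offs)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed12
#' @export
read_genes_bed12 <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 12) stop("expected BED12: ", path)
  starts <- lapply(seq_len(nrow(bed)), function(i) {
    off <- as.numeric(strsplit(as.character(bed[[12]][i]), ",")[[1]])
    bed[[2]][i] + off
  })
  ends <- lapply(seq_len(nrow(bed)), function(i) {
    sz <- as.numeric(strsplit(as.character(bed[[11]][i]), ",")[[1]])
    starts[[i]] + sz
  })
  gene_models(bed[[4]], bed[[1]], bed[[6]], bed[[2]], bed[[3]],
              exon_starts = starts, exon_ends = ends)
}

# ---- GRanges bridge --------------------------------------------------------

# 0-based half-open data.frame (chrom,start,end) -> GRanges (1-based closed)
df_to_granges <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
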