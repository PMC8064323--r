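#' Tag sets: one sample's extended ChIP fragments
#'
#' A tag is an in-silico 3'-extended immunoprecipitated fragment (150-250 bp).
#' The tag set is the unit of library normalization.
#'
#' @param sample_id sample identifier.
#' @param group group label (e.g. "A"/"B").
#' @param fragments data.frame with columns chrom, start, end
#'   (0-based half-open).
#' @param layout optional `genome_layout`; when given, fragments are checked
#'   against chromosome bounds.
#' @return object of class `tag_set` with elements sample_id, group,
#'   fragments, total_count.
#' @export
tag_set <- function(sample_id, group, fragments, layout = NULL) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$end <= fragments$start))
    stop("fragment end must exceed start")
  if (!is.null(layout)) {
    stop_if_not_layout(layout)
    bad <- !(fragments$chrom %in% names(layout))
    if (any(bad))
      stop("fragment on unknown chromosome: ", fragments$chrom[which(bad)[1]])
    lens <- unclass(layout)[fragments$chrom]
    out <- fragments$start < 0 | fragments$end > lens
    if (any(out)) {
      i <- which(out)[1]
      stop(sprintf("fragment outside chromosome bounds: %s:%d-%d (%s)",
                   fragments$chrom[i], fragments$start[i], fragments$end[i],
                   sample_id))
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group),
                 fragments = fragments[, c("chrom", "start", "end")],
                 total_count = nrow(fragments)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set '%s' (group %s): %d fragments\n",
              x$sample_id, x$group, x$total_count))
  invisible(x)
}

#' Write / read tag sets as BED6
#'
#' BED6 with name = sample id, score = 0, strand = ".".
#'
#' @param tags a `tag_set`.
#' @param path file path.
#' @param group group label to attach on read.
#' @return `read_tags_bed` returns a `tag_set`.
#' @export
write_tags_bed <- function(tags, path) {
  fr <- tags$fragments
  utils::write.table(
    data.frame(fr$chrom, fr$start, fr$end, tags$sample_id, 0L, "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tags_bed
#' @export
read_tags_bed <- function(path, group = NA_character_) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  sample_id <- if (ncol(bed) >= 4) as.character(bed[[4]][1]) else
    sub("\\.bed$", "", basename(path))
  tag_set(sample_id, group,
          data.frame(chrom = as.character(bed[[1]]), start = bed[[2]],
                     end = bed[[3]], stringsAsFactors = FALSE))
}

fragment_midpoints <- function(fragments) {
  floor((fragments$start + fragments$end) / 2)
}

# Deterministic 31-bit string hash; fans a global seed out to per-sample
# substreams independent of sample order.
stable_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(as.character(x))) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

substream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 1000003 + stable_hash(key)) %% 2147483629)
}
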