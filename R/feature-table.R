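#' Build a feature table
#'
#' A feature table is a plain `data.frame` of genomic features on the
#' package's 1-based inclusive coordinate convention, serializable to and
#' from GFF3 without any coordinate change.
#'
#' @param seqid Sequence identifier (recycled).
#' @param type Feature type label (e.g. `"ORF"`, `"TRS_leader"`).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param label Optional feature name, stored as the GFF3 `Name`
#'   attribute.
#' @return A `data.frame` with class `feature_table`.
#' @export
feature_table <- function(seqid, type, start, end, strand = "+",
                          label = NA_character_) {
  n <- max(length(start), length(end))
  df <- data.frame(
    seqid = rep_len(seqid, n), type = rep_len(type, n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n), label = rep_len(label, n),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0L && any(df$start > df$end)) {
    stop("feature with start > end")
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

empty_feature_table <- function() {
  feature_table(character(), character(), integer(), integer(),
                character(), character())
}

#' Write a feature table to GFF3
#'
#' Serialization goes through [GenomicRanges::GRanges] and
#' [rtracklayer::export.gff3()]; coordinates are written unchanged
#' (GFF3 is 1-based inclusive, like the package convention).
#'
#' @param features A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", con = path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  gr$type <- features$type
  gr$source <- "nidoscan"
  if (!is.null(features$label)) gr$Name <- features$label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into a feature table
#'
#' @param path Path to a GFF3 file.
#' @return A [feature_table()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_feature_table())
  lab <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  feature_table(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    label = lab
  )
}
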