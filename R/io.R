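#' Write a GFF3 table
#'
#' `gff` is a data frame with the nine GFF3 columns
#' (`seqid, source, type, start, end, score, strand, phase, attributes`),
#' 1-based closed coordinates. A `##gff-version 3` header is emitted.
#'
#' @param gff data frame of GFF3 fields.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write single-nucleotide tags as BED6
#'
#' One record per tag, 0-based half-open single-nucleotide intervals,
#' score 1, strand in column 6.
#'
#' @param tags data frame with `chrom`, `pos` (1-based cleavage base),
#'   `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_tags <- function(tags, path) {
  bed <- data.frame(
    chrom = tags$chrom,
    start = tags$pos - 1L,
    end = tags$pos,
    name = sprintf("tag%07d", seq_len(nrow(tags))),
    score = 1L,
    strand = tags$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of mapped records
#'
#' @param path BED file (0-based half-open intervals).
#' @return Data frame with `chrom, start, end, name, score, strand` (strand
#'   `"."` preserved; see [reduce_to_tags()] for strand handling).
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character"),
                    col.names = c("chrom", "start", "end", "name", "score", "strand"),
                    fill = TRUE, stringsAsFactors = FALSE)
  bed
}

SCHEMA_TAG <- "#patseqr_schema=1"

#' Write / read tab-separated pipeline tables with a schema-version header
#'
#' Pipeline intermediates carry a one-line schema header so incompatible
#' files are rejected explicitly.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return For `write_tsv`, `path` invisibly; for `read_tsv`, a data frame.
#' @export
write_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_TAG, con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, SCHEMA_TAG))
    stop("incompatible table schema in ", path, " (expected ", SCHEMA_TAG, ")")
  read.table(path, sep = "\t", header = TRUE, skip = 1L,
             stringsAsFactors = FALSE, check.names = FALSE)
}
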