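#' Normalize Illumina read identifiers
#'
#' Strips everything after the first whitespace and a trailing \code{/1} or
#' \code{/2} mate suffix, so R1/R2 mates share one ID.
#'
#' @param ids character vector of raw FASTQ identifiers.
#' @return normalized IDs.
#' @export
normalize_read_id <- function(ids) {
  ids <- sub("[ \t].*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Read a FASTQ file into a read table
#'
#' Thin wrapper over \code{Biostrings} FASTQ parsing (gzip-transparent).
#' Read IDs are normalized via \code{\link{normalize_read_id}}.
#'
#' @param path FASTQ(.gz) file.
#' @return data.frame with columns \code{read_id}, \code{seq}, \code{qual}.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(
    read_id = normalize_read_id(names(ss)),
    seq = as.character(ss),
    qual = as.character(S4Vectors::mcols(ss)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with \code{read_id}, \code{seq}, \code{qual}.
#' @param path output file; \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
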