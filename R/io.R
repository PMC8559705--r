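# FASTQ input/output. Reads are handled in memory as lists with
# `read_id`, `sequence` and integer `qualities` (Phred).

#' Write reads to FASTQ
#'
#' Records are emitted directly (4 lines per read); the Biostrings FASTQ
#' writer in this version cannot serialise records longer than its
#' internal line buffer, which long Nanopore reads exceed.
#'
#' @param reads List of read lists (`read_id`, `sequence`, `qualities`).
#' @param path Output path (`.gz` supported).
#' @export
write_fastq <- function(reads, path) {
  lines <- unlist(lapply(reads, function(r) {
    c(
      paste0("@", r$read_id), r$sequence, "+",
      intToUtf8(pmin(pmax(r$qualities, 0L), 93L) + 33L)
    )
  }), use.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to the FASTQ (gz-aware).
#' @return Named list of reads (`read_id`, `sequence`, `qualities`).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- S4Vectors::mcols(x)$qualities
  out <- lapply(seq_along(x), function(i) {
    list(
      read_id = names(x)[i],
      sequence = as.character(x[[i]]),
      qualities = utf8ToInt(as.character(quals[[i]])) - 33L
    )
  })
  names(out) <- names(x)
  out
}
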