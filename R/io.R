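#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; RNA input is
#' accepted (U is normalized to T by [apply_transformation()] downstream).
#' Names are truncated at the first whitespace, as aligners do.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
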