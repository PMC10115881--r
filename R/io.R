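# Thin FASTA wrappers around Biostrings, so every external format used by
# the pipeline has a package-level entry point.

#' Write / read a proteome as FASTA
#'
#' @param proteome An [Biostrings::AAStringSet] (e.g. from [gen_proteome]).
#' @param path FASTA path.
#' @return `path` invisibly (write); an `AAStringSet` (read).
#' @export
write_proteome_fasta <- function(proteome, path) {
  if (!inherits(proteome, "AAStringSet")) {
    proteome <- Biostrings::AAStringSet(proteome)
  }
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  Biostrings::readAAStringSet(path)
}
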