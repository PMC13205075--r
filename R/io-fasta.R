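#' Read sequences from a FASTA file
#'
#' Parsing is delegated to Biostrings; on top of it the reader enforces the
#' package's sequence contract: unique headers, non-empty records, upper-case
#' output, and an RNA internal alphabet — `T` is accepted on input and
#' normalized to `U`, so DNA and RNA FASTA files are interchangeable.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, id -> sequence over `{A,C,G,U,N}`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_input(paste0("duplicate FASTA header(s): ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               class = "cernascreen_format_error")
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop_input(paste0("empty sequence for: ",
                      paste(ids[!nzchar(seqs)], collapse = ", ")),
               class = "cernascreen_format_error")
  }
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- regexpr("[^ACGUN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_input(sprintf("illegal character '%s' in sequence '%s' at position %d",
                       substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
               class = "cernascreen_format_error")
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_input("sequences must have unique names")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(seqs)
}
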