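#' Validate and normalise a nucleotide sequence
#'
#' Sequences are uppercased at load; characters outside `{A,C,G,T,N}` are
#' rejected with the 1-based position of the first offending character.
#' Soft-masked (lowercase) bases are uppercased, not treated as masked.
#'
#' @param seq Single character string.
#' @param id Sequence identifier used in error messages.
#' @return The validated, uppercased sequence string.
#' @export
validate_seq <- function(seq, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) {
    stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  }
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)[1]
  if (bad > 0) {
    stop(sprintf("sequence '%s' has invalid character '%s' at position %d",
                 id, substr(seq, bad, bad), bad), call. = FALSE)
  }
  seq
}

#' Construct a validated sequence record
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @return A `sequence_record`: list with elements `id` and `seq`.
#' @export
sequence_record <- function(id, seq) {
  structure(list(id = as.character(id), seq = validate_seq(seq, id)),
            class = "sequence_record")
}

## Accepts a sequence_record or a bare string + id and returns the record.
as_record <- function(x, id = "seq") {
  if (inherits(x, "sequence_record")) return(x)
  sequence_record(id, x)
}

#' Read a multi-record FASTA genome
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences (may contain N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
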