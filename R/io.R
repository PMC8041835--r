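## BED6+ motif I/O and small table writers.

#' Write motifs as BED6+
#'
#' Columns: chrom, start, end, name (`class:id`), score (`n_stems`), strand,
#' plus `motif_seq` as a 7th column. Coordinates are already 0-based
#' half-open.
#'
#' @param motifs Motif tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs_bed <- function(motifs, path) {
  d <- data.frame(motifs$chrom, motifs$start, motifs$end, motifs$motif_id,
                  motifs$n_stems, motifs$strand, motifs$motif_seq)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read motifs from BED6+ written by [write_motifs_bed()]
#'
#' @param path BED path.
#' @return Motif tibble.
#' @export
read_motifs_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  cls <- sub(":.*$", "", d[[4]])
  tibble::tibble(chrom = as.character(d[[1]]), start = as.integer(d[[2]]),
                 end = as.integer(d[[3]]), strand = as.character(d[[6]]),
                 motif_class = cls, n_stems = as.integer(d[[5]]),
                 motif_seq = if (ncol(d) >= 7) as.character(d[[7]]) else NA,
                 motif_id = as.character(d[[4]]))
}

#' Write a positional profile as TSV
#'
#' @param profile A `g4_profile`.
#' @param path Output path.
#' @param normalize Optional override of the profile's normalisation.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, normalize = NULL) {
  utils::write.table(as.data.frame(profile_values(profile, normalize)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write Circos-style histogram track
#'
#' @param bins Tibble from [bin_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circos_track <- function(bins, path) {
  utils::write.table(
    data.frame(bins$chrom, bins$bin_start, bins$bin_end, bins$count), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
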