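# FASTQ / table IO thin wrappers.

#' Read amplicon reads from FASTQ (Phred+33)
#'
#' @param path FASTQ file.
#' @return Data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = sub("\\s.*", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write amplicon reads to FASTQ (Phred+33)
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a barcode map (TSV: barcode, site)
#' @param path TSV file with columns `barcode` and `site`.
#' @return Data frame.
#' @export
read_barcode_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a sites x OTUs table as TSV
#' @param table Count matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(site = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
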