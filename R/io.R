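# Small, deterministic readers/writers for the pipeline's plain-text
# formats. All tables are tab-separated with a header line and no quoting,
# so that byte-identical reruns are possible.

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @param required_cols columns that must be present (format error if not).
#' @return data.frame.
#' @export
read_tsv <- function(path, required_cols = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss))
      stop("file ", path, " is missing required column(s): ",
           paste(miss, collapse = ", "))
  }
  df
}

#' Write named nucleotide sequences as FASTA
#' @param seqs named character vector of nucleotide strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a BED-like gene position table
#'
#' Columns: chrom, start, end, gene, strand; 0-based half-open gene-rank
#' coordinates as emitted by the simulator.
#' @param path input file.
#' @export
read_positions <- function(path) {
  read_tsv(path, required_cols = c("chrom", "start", "end", "gene", "strand"))
}
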