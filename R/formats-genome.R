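#' Read a genome FASTA file
#'
#' Loads every record of a nucleotide FASTA into memory and indexes it by the
#' first whitespace-delimited header token, giving random access to arbitrary
#' subsequences on either strand.
#'
#' @param path path to a FASTA file of nucleotide sequences.
#' @return an object of class `genome_sequence` wrapping a
#'   [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path))
    stop("genome FASTA not found: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    stop("genome FASTA '", path, "' contains no sequences", call. = FALSE)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA headers in '", path, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  # DNAStringSet already rejects non-IUPAC letters; restrict further to ACGTN
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- colnames(freq)[colSums(freq) > 0]
  if (!all(extra %in% allowed))
    stop("non-ACGTN characters in '", path, "': ",
         paste(setdiff(extra, allowed), collapse = ", "), call. = FALSE)
  structure(list(seqs = seqs), class = "genome_sequence")
}

#' Construct a genome object from in-memory sequences
#'
#' @param x named character vector or [Biostrings::DNAStringSet].
#' @return `genome_sequence` object.
#' @export
genome_from_sequences <- function(x) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must have unique names", call. = FALSE)
  structure(list(seqs = x), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$seqs), "sequence(s)\n")
  for (nm in names(x$seqs))
    cat(" ", nm, ":", length(x$seqs[[nm]]), "nt\n")
  invisible(x)
}

#' Chromosome names of a genome
#' @param genome a `genome_sequence`.
#' @return character vector.
#' @export
chrom_names <- function(genome) names(genome$seqs)

#' Chromosome length
#' @param genome a `genome_sequence`.
#' @param chrom chromosome name.
#' @return integer nucleotide count.
#' @export
chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$seqs))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  length(genome$seqs[[chrom]])
}

#' Fetch a genomic subsequence
#'
#' Coordinates are 1-based inclusive on the forward strand. For `strand ==
#' "-"` the reverse complement of the forward-strand slice is returned, so the
#' result always reads 5'→3' on the requested strand.
#'
#' @param genome a `genome_sequence`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive forward-strand coordinates, start ≤ end.
#' @param strand `"+"` or `"-"`.
#' @return character string of length `end - start + 1`.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome$seqs))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  len <- length(genome$seqs[[chrom]])
  if (start < 1L || end > len || start > end)
    stop(sprintf("coordinates %d..%d out of bounds for %s (1..%d)",
                 start, end, chrom, len), call. = FALSE)
  s <- Biostrings::subseq(genome$seqs[[chrom]], start, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Write a genome to FASTA
#' @param genome a `genome_sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path, width = 70L)
  invisible(path)
}
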