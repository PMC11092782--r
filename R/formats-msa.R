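#' Read a splice-aware isoform alignment with codon coordinates
#'
#' Loads one gene family's protein isoform MSA (aligned FASTA) together with
#' its companion mapping file, which records for every non-gap residue the
#' genomic position of the middle nucleotide of its codon. The two files
#' together define the residue matrix `M` and the coordinate matrix `P`.
#'
#' FASTA headers follow the grammar
#' `>isoform_id species=<s> chrom=<c> strand=<+|-> [score=<1-5>]`. The mapping
#' file holds one block per isoform: a line with the isoform id, then a line
#' of comma-separated integers, one per non-gap residue in row order.
#'
#' @param msa_path aligned FASTA file (all rows equal length).
#' @param map_path companion coordinate mapping file.
#' @param gene gene-family identifier; defaults to the MSA file's base name.
#' @return an object of class `isoform_alignment` with elements `gene`,
#'   `rows` (data.frame: isoform, species, chrom, strand, score), `M`
#'   (character matrix of single letters / `"-"`), and `P` (integer matrix,
#'   `NA` at gaps).
#' @export
read_isoform_alignment <- function(msa_path, map_path,
                                   gene = tools::file_path_sans_ext(basename(msa_path))) {
  if (!file.exists(msa_path)) stop("MSA file not found: ", msa_path, call. = FALSE)
  if (!file.exists(map_path)) stop("mapping file not found: ", map_path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(msa_path)
  if (length(aa) == 0L) stop("empty MSA file: ", msa_path, call. = FALSE)
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1L)
    stop("ragged alignment in '", msa_path, "': row widths ",
         paste(unique(w), collapse = ", "), call. = FALSE)
  rows <- parse_msa_headers(names(aa), msa_path)
  M <- do.call(rbind, strsplit(as.character(aa), ""))
  rownames(M) <- rows$isoform
  coords <- read_mapping_file(map_path)
  P <- matrix(NA_integer_, nrow = nrow(M), ncol = ncol(M),
              dimnames = dimnames(M))
  for (i in seq_len(nrow(M))) {
    id <- rows$isoform[i]
    if (is.null(coords[[id]]))
      stop("isoform '", id, "' missing from mapping file ", map_path,
           call. = FALSE)
    nongap <- which(M[i, ] != "-")
    ci <- coords[[id]]
    if (length(ci) != length(nongap))
      stop(sprintf("isoform '%s': %d coordinates for %d residues",
                   id, length(ci), length(nongap)), call. = FALSE)
    P[i, nongap] <- ci
  }
  aln <- structure(list(gene = gene, rows = rows, M = M, P = P),
                   class = "isoform_alignment")
  validate_isoform_alignment(aln)
  aln
}

parse_msa_headers <- function(headers, path) {
  parse_one <- function(h) {
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    kv <- grep("=", toks[-1], value = TRUE)
    keys <- sub("=.*", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys
    need <- c("species", "chrom", "strand")
    if (!all(need %in% keys))
      stop("MSA header lacks ", paste(setdiff(need, keys), collapse = "/"),
           " in '", path, "': >", h, call. = FALSE)
    if (!vals[["strand"]] %in% c("+", "-"))
      stop("bad strand '", vals[["strand"]], "' in header >", h, call. = FALSE)
    score <- if ("score" %in% keys) as.integer(vals[["score"]]) else NA_integer_
    if (!is.na(score) && (score < 1L || score > 5L))
      stop("annotation score must be 1-5, got ", score, " in >", h, call. = FALSE)
    data.frame(isoform = toks[1], species = vals[["species"]],
               chrom = vals[["chrom"]], strand = vals[["strand"]],
               score = score, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(headers, parse_one))
  if (anyDuplicated(rows$isoform))
    stop("duplicate isoform ids in '", path, "'", call. = FALSE)
  rows
}

read_mapping_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2L != 0L)
    stop("mapping file '", path, "' must have id/coordinate line pairs",
         call. = FALSE)
  ids <- sub("^>", "", trimws(lines[seq(1L, length(lines), by = 2L)]))
  vals <- lines[seq(2L, length(lines), by = 2L)]
  coords <- lapply(vals, function(v) {
    x <- suppressWarnings(as.integer(strsplit(trimws(v), ",")[[1]]))
    if (anyNA(x)) stop("non-integer coordinate in '", path, "'", call. = FALSE)
    x
  })
  names(coords) <- ids
  coords
}

#' Validate the invariants of an isoform alignment
#'
#' Checks that `M` and `P` agree in shape, gaps coincide with `NA`
#' coordinates, coordinates are strictly monotone along each row in strand
#' orientation, and all isoforms of one species share a chromosome and strand.
#'
#' @param aln an `isoform_alignment`.
#' @return `aln`, invisibly; errors on any violation.
#' @export
validate_isoform_alignment <- function(aln) {
  stopifnot(identical(dim(aln$M), dim(aln$P)))
  gap <- aln$M == "-"
  if (!identical(unname(gap), unname(is.na(aln$P))))
    stop("P must be NA exactly at gap columns of M", call. = FALSE)
  for (i in seq_len(nrow(aln$M))) {
    p <- aln$P[i, !is.na(aln$P[i, ])]
    if (length(p) > 1L) {
      d <- diff(p)
      ok <- if (aln$rows$strand[i] == "+") all(d > 0) else all(d < 0)
      if (!ok)
        stop("non-monotone coordinates for isoform '", aln$rows$isoform[i],
             "' on strand ", aln$rows$strand[i], call. = FALSE)
    }
  }
  sp <- split(aln$rows, aln$rows$species)
  for (s in sp) {
    if (length(unique(s$chrom)) > 1L || length(unique(s$strand)) > 1L)
      stop("isoforms of species '", s$species[1],
           "' disagree on chrom/strand", call. = FALSE)
  }
  invisible(aln)
}

#' Write an isoform alignment and its coordinate mapping
#'
#' Inverse of [read_isoform_alignment()]: emits the aligned FASTA with the
#' header grammar and the mapping file with one id/coordinate block per row.
#'
#' @param aln an `isoform_alignment`.
#' @param msa_path,map_path output paths.
#' @return invisibly, c(msa_path, map_path).
#' @export
write_isoform_alignment <- function(aln, msa_path, map_path) {
  hdr <- with(aln$rows, paste0(isoform, " species=", species,
                               " chrom=", chrom, " strand=", strand,
                               ifelse(is.na(score), "", paste0(" score=", score))))
  fa <- character(2L * nrow(aln$M))
  fa[c(TRUE, FALSE)] <- paste0(">", hdr)
  fa[c(FALSE, TRUE)] <- apply(aln$M, 1L, paste, collapse = "")
  writeLines(fa, msa_path)
  write_mapping_file(aln$rows$isoform,
                     lapply(seq_len(nrow(aln$P)),
                            function(i) aln$P[i, !is.na(aln$P[i, ])]),
                     map_path)
  invisible(c(msa_path, map_path))
}

write_mapping_file <- function(ids, coord_list, path) {
  out <- character(2L * length(ids))
  out[c(TRUE, FALSE)] <- ids
  out[c(FALSE, TRUE)] <- vapply(coord_list, paste, "", collapse = ",")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.isoform_alignment <- function(x, ...) {
  cat("isoform_alignment '", x$gene, "': ", nrow(x$M), " isoform(s), ",
      ncol(x$M), " columns, ", length(unique(x$rows$species)),
      " species\n", sep = "")
  invisible(x)
}
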