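#' Read CDS annotation tracks for one species
#'
#' Builds the interval stores used for novelty classification: CDS features
#' from a GTF file and, optionally, competing exon predictions from BED
#' files. Both are normalized to 1-based inclusive coordinates internally
#' (GTF already is; BED's 0-based half-open starts are shifted by +1).
#'
#' Malformed lines are skipped and counted rather than aborting the load; a
#' file in which every line is malformed is rejected.
#'
#' @param gtf_path GTF file, or `NULL` for no annotation track. Only lines
#'   with feature type `CDS` are used.
#' @param bed_paths character vector of BED files of competing predictions
#'   (may be empty).
#' @return object of class `cds_annotation`: list with [GenomicRanges::GRanges]
#'   elements `gtf` and `competing`, plus `skipped` counts per file.
#' @export
read_cds_annotations <- function(gtf_path = NULL, bed_paths = character()) {
  skipped <- integer()
  gtf <- GenomicRanges::GRanges()
  if (!is.null(gtf_path)) {
    res <- read_gtf_cds(gtf_path)
    gtf <- res$gr
    skipped[gtf_path] <- res$skipped
  }
  comp <- GenomicRanges::GRanges()
  for (bp in bed_paths) {
    res <- read_bed_intervals(bp)
    comp <- c(comp, res$gr)
    skipped[bp] <- res$skipped
  }
  structure(list(gtf = gtf, competing = comp, skipped = skipped),
            class = "cds_annotation")
}

# Line-tolerant GTF reader restricted to CDS features. Returns a GRanges and
# the count of malformed lines.
read_gtf_cds <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 8L
  n_bad <- sum(!ok)
  fields <- fields[ok]
  if (length(lines) > 0L && length(fields) == 0L)
    stop("no parseable lines in GTF '", path, "'", call. = FALSE)
  feat  <- vapply(fields, `[`, "", 3L)
  keep  <- feat == "CDS"
  if (!any(keep) && length(fields) > 0L)
    warning("GTF '", path, "' contains no CDS features", call. = FALSE)
  fields <- fields[keep]
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  chrom <- vapply(fields, `[`, "", 1L)
  strand <- vapply(fields, `[`, "", 7L)
  bad <- is.na(start) | is.na(end) | start > end | !strand %in% c("+", "-", ".")
  n_bad <- n_bad + sum(bad)
  if (n_bad > 0L)
    message("skipped ", n_bad, " malformed line(s) in GTF ", path)
  idx <- which(!bad)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[idx],
    ranges = IRanges::IRanges(start = start[idx], end = end[idx]),
    strand = ifelse(strand[idx] == ".", "*", strand[idx]))
  S4Vectors::mcols(gr)$source_tag <- rep("gtf", length(gr))
  list(gr = gr, skipped = n_bad)
}

# Line-tolerant BED reader: 0-based half-open intervals converted to 1-based
# inclusive.
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 3L
  n_bad <- sum(!ok)
  fields <- fields[ok]
  if (length(lines) > 0L && length(fields) == 0L)
    stop("no parseable lines in BED '", path, "'", call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "*", "")
  bad <- is.na(start0) | is.na(end0) | start0 >= end0
  n_bad <- n_bad + sum(bad)
  if (n_bad > 0L)
    message("skipped ", n_bad, " malformed line(s) in BED ", path)
  idx <- which(!bad)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[idx],
    ranges = IRanges::IRanges(start = start0[idx] + 1L, end = end0[idx]),
    strand = ifelse(strand[idx] %in% c("+", "-"), strand[idx], "*"))
  S4Vectors::mcols(gr)$source_tag <- rep("bed", length(gr))
  list(gr = gr, skipped = n_bad)
}

#' @export
print.cds_annotation <- function(x, ...) {
  cat("cds_annotation:", length(x$gtf), "GTF CDS interval(s),",
      length(x$competing), "competing interval(s)\n")
  invisible(x)
}
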