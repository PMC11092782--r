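# Output writers: per-species BED tracks, the ranked hits report, and
# per-gene result folders with human-readable alignment renderings plus the
# collapsed C/Q data.

#' Write predicted exons for one species as a BED file
#'
#' Six tab-separated fields: chrom, 0-based start, half-open end, name
#' `gene|query_species|e<block>`, percent identity (one decimal, penultimate
#' field), strand. Internal coordinates are 1-based inclusive and are
#' converted at this boundary.
#'
#' @param preds list of deduplicated `exon_prediction` for one target
#'   species.
#' @param species the target species (written into the header comment).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(preds, species, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# predicted exons: ", species), con)
  for (p in preds) {
    name <- sprintf("%s|%s|e%d", p$gene, p$supports[[1L]]$source_species,
                    as.integer(p$block_index))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.1f\t%s",
                       p$chrom, as.integer(p$interval[1L]) - 1L,
                       as.integer(p$interval[2L]),
                       name, p$pct_identity, p$strand), con)
  }
  invisible(path)
}

#' Write the global hit report sorted by percent identity
#'
#' One record per prediction across all species, in strictly non-increasing
#' order of alignment percent identity (ties broken by gene, target species,
#' then coordinate), with the genomic region, amino-acid length, GTF-overlap
#' flag, and novelty label.
#'
#' @param preds list of annotated `exon_prediction` (all species pooled).
#' @param path output file (TSV with a commented header line).
#' @return `path`, invisibly.
#' @export
write_hits_report <- function(preds, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("# rank", "gene", "target_species", "region", "aa_length",
                   "pct_identity", "gtf_overlap", "novelty", sep = "\t"), con)
  if (length(preds)) {
    ord <- order(-vapply(preds, `[[`, 0, "pct_identity"),
                 vapply(preds, `[[`, "", "gene"),
                 vapply(preds, `[[`, "", "target_species"),
                 vapply(preds, `[[`, "", "chrom"),
                 vapply(preds, function(p) p$interval[1L], 0))
    preds <- preds[ord]
    for (i in seq_along(preds)) {
      p <- preds[[i]]
      writeLines(sprintf("%d\t%s\t%s\t%s:%d-%d(%s)\t%d\t%.1f\t%s\t%s",
                         i, p$gene, p$target_species, p$chrom,
                         as.integer(p$interval[1L]), as.integer(p$interval[2L]),
                         p$strand, p$aa_length, p$pct_identity,
                         if (identical(p$novelty, "overlaps_gtf")) "yes" else "no",
                         p$novelty), con)
    }
  }
  invisible(path)
}

#' Render one exon alignment as plain text
#'
#' @param a an `exon_alignment` with genomic coordinates.
#' @param width characters of alignment per line.
#' @return character vector of lines.
#' @export
format_exon_alignment <- function(a, width = 60L) {
  q <- strsplit(a$aligned_query, "")[[1]]
  t <- strsplit(a$aligned_target, "")[[1]]
  mid <- ifelse(q == t & q != "-", "|", ifelse(q != "-" & t != "-", ".", " "))
  out <- c(sprintf("score %d  identity %.1f%%  coverage %.2f  frame %d",
                   a$score, a$pct_identity, a$query_coverage, a$frame),
           sprintf("target %s:%d-%d(%s)",
                   if (is.null(a$chrom)) "window" else a$chrom,
                   a$genomic[["start"]], a$genomic[["end"]],
                   if (is.null(a$strand)) "+" else a$strand),
           "")
  n <- length(q)
  for (s in seq(1L, max(n, 1L), by = width)) {
    e <- min(n, s + width - 1L)
    if (s > n) break
    out <- c(out,
             paste0("query  ", paste(q[s:e], collapse = "")),
             paste0("       ", paste(mid[s:e], collapse = "")),
             paste0("target ", paste(t[s:e], collapse = "")),
             "")
  }
  out
}

#' Write per-gene result files
#'
#' Creates `dir/<gene>/` holding one plain-text alignment rendering per
#' prediction (best supporting query first, then the other supports), plus
#' the collapsed alignment (`C` as aligned FASTA, `Q` in the mapping
#' dialect). The C/Q files round-trip through [read_all_exon()].
#'
#' @param gene gene identifier.
#' @param aln the gene's `all_exon_alignment`.
#' @param preds deduplicated predictions of the gene (any target species).
#' @param dir root results directory.
#' @return the gene directory, invisibly.
#' @export
write_gene_results <- function(gene, aln, preds, dir) {
  gdir <- file.path(dir, gene)
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  write_all_exon(aln, file.path(gdir, paste0(gene, ".C.afa")),
                 file.path(gdir, paste0(gene, ".Q.map")))
  if (length(preds)) {
    ord <- order(vapply(preds, `[[`, "", "target_species"),
                 vapply(preds, function(p) p$interval[1L], 0))
    preds <- preds[ord]
    for (i in seq_along(preds)) {
      p <- preds[[i]]
      lines <- c(sprintf("gene %s  exon predicted in %s  block e%d  novelty %s",
                         p$gene, p$target_species, p$block_index,
                         if (is.na(p$novelty)) "unclassified" else p$novelty))
      for (s in p$supports) {
        lines <- c(lines, "",
                   sprintf("query exon from %s (%s:%d-%d)  annotation score %s",
                           s$source_species,
                           s$alignment$chrom %||% "window",
                           s$source_coords[["start"]], s$source_coords[["end"]],
                           if (is.na(s$source_annotation_score)) "-" else
                             s$source_annotation_score),
                   format_exon_alignment(s$alignment))
      }
      writeLines(lines, file.path(gdir, sprintf("prediction_%02d_%s.txt",
                                                i, p$target_species)))
    }
  }
  invisible(gdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
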