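# Post-processing of accepted exon predictions: deduplication across query
# species, novelty classification against annotation tracks, transitive
# annotation scores, and exon-divergence deltas.

#' Merge predictions of the same exon found through different queries
#'
#' Predictions for one (gene, target species) whose genomic intervals share
#' at least one nucleotide describe the same exon and are merged: the merged
#' interval is the union, all supporting query alignments are retained, and
#' the reported identity is that of the best supporting query. The result is
#' independent of the input order and idempotent.
#'
#' @param preds list of `exon_prediction` for one gene/target species.
#' @return list of merged `exon_prediction`, sorted by (chrom, start, end).
#' @export
dedup_predictions <- function(preds) {
  if (length(preds) <= 1L) return(preds)
  chrom <- vapply(preds, `[[`, "", "chrom")
  start <- vapply(preds, function(p) p$interval[1L], 0)
  end <- vapply(preds, function(p) p$interval[2L], 0)
  out <- list()
  for (ch in sort(unique(chrom))) {
    idx <- which(chrom == ch)
    ir <- IRanges::IRanges(start = start[idx], end = end[idx])
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (g in seq_along(red)) {
      members <- idx[grp == g]
      merged <- preds[[members[1L]]]
      merged$interval <- c(min(start[members]), max(end[members]))
      supports <- unlist(lapply(preds[members], `[[`, "supports"),
                         recursive = FALSE)
      # canonical support order: identity desc, then species, then block
      ord <- order(-vapply(supports, `[[`, 0, "pct_identity"),
                   vapply(supports, `[[`, "", "source_species"),
                   vapply(supports, function(x) as.numeric(x$block_index), 0))
      merged$supports <- supports[ord]
      merged$pct_identity <- merged$supports[[1L]]$pct_identity
      merged$aa_length <- as.integer(
        (merged$interval[2L] - merged$interval[1L] + 1L) %/% 3L)
      merged$block_index <- merged$supports[[1L]]$block_index
      out[[length(out) + 1L]] <- merged
    }
  }
  ord <- order(vapply(out, `[[`, "", "chrom"),
               vapply(out, function(p) p$interval[1L], 0),
               vapply(out, function(p) p$interval[2L], 0))
  out[ord]
}

#' Classify a prediction against annotation tracks
#'
#' Labels a predicted exon `overlaps_gtf` when it shares at least one
#' nucleotide with an annotated CDS interval, otherwise `overlaps_competing`
#' when it overlaps a competing-prediction interval, otherwise
#' `entirely_novel`. Overlap is strand-agnostic.
#'
#' @param pred an `exon_prediction`.
#' @param tracks a `cds_annotation` for the target species.
#' @return the prediction with its `novelty` field set.
#' @export
classify_novelty <- function(pred, tracks) {
  gr <- GenomicRanges::GRanges(
    seqnames = pred$chrom,
    ranges = IRanges::IRanges(pred$interval[1L], pred$interval[2L]))
  hits_gtf <- length(tracks$gtf) > 0L &&
    sum(GenomicRanges::countOverlaps(gr, tracks$gtf,
                                     ignore.strand = TRUE)) > 0L
  hits_comp <- length(tracks$competing) > 0L &&
    sum(GenomicRanges::countOverlaps(gr, tracks$competing,
                                     ignore.strand = TRUE)) > 0L
  pred$novelty <- if (hits_gtf) "overlaps_gtf"
    else if (hits_comp) "overlaps_competing"
    else "entirely_novel"
  pred
}

#' Transitive annotation score of a predicted exon
#'
#' Among supporting query exons whose alignment covers at least `min_cov`
#' (default 85%) of the predicted exon's residues, takes the best (lowest)
#' source annotation score. Coverage counts aligned residue pairs (gap-free
#' columns) against the predicted exon's amino-acid length.
#'
#' @param pred an `exon_prediction`.
#' @param min_cov minimum coverage fraction of the predicted exon.
#' @return the prediction with `transitive_score` set (NA when no qualifying
#'   support carries a score).
#' @export
transitive_annotation_score <- function(pred, min_cov = 0.85) {
  scores <- integer()
  for (s in pred$supports) {
    aln <- s$alignment
    q <- strsplit(aln$aligned_query, "")[[1]]
    t <- strsplit(aln$aligned_target, "")[[1]]
    paired <- sum(q != "-" & t != "-")
    if (pred$aa_length > 0L && paired / pred$aa_length >= min_cov &&
        !is.na(s$source_annotation_score))
      scores <- c(scores, s$source_annotation_score)
  }
  pred$transitive_score <- if (length(scores)) min(scores) else NA_integer_
  pred
}

# gap-free-column identity of two collapsed rows restricted to an exon block;
# NA when the pair shares no gap-free column there.
block_identity <- function(aln, sp_a, sp_b, block_index) {
  b <- aln$X[block_index, "start"]; e <- aln$X[block_index, "end"]
  ra <- aln$C[match(sp_a, aln$species), b:e]
  rb <- aln$C[match(sp_b, aln$species), b:e]
  gapfree <- ra != "-" & rb != "-"
  if (!any(gapfree)) return(NA_real_)
  100 * sum(ra[gapfree] == rb[gapfree]) / sum(gapfree)
}

#' Divergence of a predicted exon relative to the rest of its gene
#'
#' For the (target, best-query) species pair, computes the gap-free-column
#' percent identity of every exon block where both collapsed rows have
#' residues, then reports how the prediction's identity differs from (i) the
#' unweighted mean over those blocks, and (ii) the nearest upstream and
#' downstream blocks with a defined identity. Values are percentage-point
#' differences; a delta is `NA` when its reference quantity does not exist.
#'
#' @param pred an `exon_prediction` (deduplicated; its best support defines
#'   the query species).
#' @param aln the `all_exon_alignment` of the gene, with `X`.
#' @return list `delta_vs_gene_mean`, `delta_vs_upstream`,
#'   `delta_vs_downstream`.
#' @export
divergence_deltas <- function(pred, aln) {
  qsp <- pred$supports[[1L]]$source_species
  tsp <- pred$target_species
  bi <- pred$block_index
  ids <- vapply(seq_len(nrow(aln$X)),
                function(j) block_identity(aln, qsp, tsp, j), 0.0)
  defined <- which(!is.na(ids))
  gene_mean <- if (length(defined)) mean(ids[defined]) else NA_real_
  up <- defined[defined < bi]
  dn <- defined[defined > bi]
  list(
    delta_vs_gene_mean = if (is.na(gene_mean)) NA_real_ else
      pred$pct_identity - gene_mean,
    delta_vs_upstream = if (length(up)) pred$pct_identity - ids[max(up)] else
      NA_real_,
    delta_vs_downstream = if (length(dn)) pred$pct_identity - ids[min(dn)] else
      NA_real_)
}
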