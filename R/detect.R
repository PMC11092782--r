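#' Find exon blocks missing from a species
#'
#' Scans every (species, exon block) pair of an all-exon alignment and flags
#' those where the species' consensus row is entirely gaps over the block
#' while at least one other species has residues there — the signature of an
#' exon observed in other species but absent from this species' isoforms.
#'
#' @param aln an `all_exon_alignment` with exon blocks `X`.
#' @param min_query_aa minimum residues for a query peptide (shorter source
#'   exons are discarded).
#' @return list of `missing_exon_candidate` objects, each with `gene`,
#'   `target_species`, `block` (columns `b..e`), `block_index`, and
#'   `queries` (see [build_query_peptides()]). Candidates whose every query
#'   fails the length filter are dropped.
#' @export
find_missing_exons <- function(aln, min_query_aa = 6L) {
  if (is.null(aln$X))
    stop("derive_exon_blocks() must be run before find_missing_exons()",
         call. = FALSE)
  out <- list()
  for (bi in seq_len(nrow(aln$X))) {
    b <- unname(aln$X[bi, "start"]); e <- unname(aln$X[bi, "end"])
    gapped <- apply(aln$C[, b:e, drop = FALSE], 1L, function(r) all(r == "-"))
    if (all(gapped) || !any(gapped)) next
    for (k in which(gapped)) {
      cand <- structure(list(
        gene = aln$gene,
        target_species = aln$species[k],
        block = c(b = b, e = e),
        block_index = bi,
        queries = list()), class = "missing_exon_candidate")
      cand$queries <- build_query_peptides(aln, cand, min_query_aa = min_query_aa)
      if (length(cand$queries)) out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Build query peptides for a missing-exon candidate
#'
#' For every other species with residues over the candidate block, extracts
#' the block residues with gaps stripped, its genomic footprint, and the best
#' annotation score among the isoforms contributing to that exon. Peptides
#' shorter than `min_query_aa` residues are discarded.
#'
#' @param aln an `all_exon_alignment`.
#' @param candidate a `missing_exon_candidate` (only its block is used).
#' @param min_query_aa minimum peptide length to keep.
#' @return list of query records: `source_species`, `peptide`,
#'   `source_chrom`, `source_strand`, `source_coords` (genomic span of the
#'   source exon's codon middles), `source_annotation_score` (or `NA`).
#' @export
build_query_peptides <- function(aln, candidate, min_query_aa = 6L) {
  b <- candidate$block[["b"]]; e <- candidate$block[["e"]]
  queries <- list()
  for (i in seq_along(aln$species)) {
    if (aln$species[i] == candidate$target_species) next
    res <- aln$C[i, b:e]
    keep <- res != "-"
    if (!any(keep)) next
    pep <- paste(res[keep], collapse = "")
    if (nchar(pep) < min_query_aa) next
    qq <- aln$Q[i, b:e][keep]
    scr <- aln$scores[i, b:e][keep]
    queries[[length(queries) + 1L]] <- list(
      source_species = aln$species[i],
      peptide = pep,
      source_chrom = aln$species_info$chrom[i],
      source_strand = aln$species_info$strand[i],
      source_coords = c(start = min(qq) - 1L, end = max(qq) + 1L),
      source_annotation_score = if (all(is.na(scr))) NA_integer_ else
        min(scr, na.rm = TRUE))
  }
  queries
}

#' Compute the genomic search window for a missing exon
#'
#' The missing exon's homolog, if present, must lie between the target
#' species' flanking exons. The window is bounded by the codon-middle
#' coordinates adjacent to the block: on the protein-upstream side the
#' coordinate at column `b-1`, downstream at `e+1` (scanning further out if
#' those columns happen to be gaps in the target row). When one flank has no
#' mapped exon at all, the window extends `window_pad` nucleotides (default
#' 25,000) from the existing flank. Coordinates are reported on the forward
#' strand with `L < R` always; on the minus strand the flanks swap roles.
#'
#' @param aln an `all_exon_alignment` with `X`.
#' @param candidate a `missing_exon_candidate`.
#' @param genome optional `genome_sequence` of the target species, used to
#'   clamp the window to chromosome bounds.
#' @param window_pad one-sided fallback width in nucleotides.
#' @return a `search_window` (list: `chrom`, `strand`, `L`, `R`) or `NULL`
#'   with a message when the target species has no mapped coordinate on
#'   either side of the block.
#' @export
compute_search_window <- function(aln, candidate, genome = NULL,
                                  window_pad = 25000L) {
  k <- match(candidate$target_species, aln$species)
  b <- candidate$block[["b"]]; e <- candidate$block[["e"]]
  q <- aln$Q[k, ]
  m <- length(q)
  strand <- aln$species_info$strand[k]
  chrom <- aln$species_info$chrom[k]
  up_idx <- if (b > 1L) rev(which(!is.na(q[seq_len(b - 1L)]))) else integer()
  dn_idx <- if (e < m) e + which(!is.na(q[seq.int(e + 1L, m)])) else integer()
  up <- if (length(up_idx)) q[up_idx[1L]] else NA_integer_
  dn <- if (length(dn_idx)) q[dn_idx[1L]] else NA_integer_
  if (is.na(up) && is.na(dn)) {
    message("candidate ", candidate$gene, "/", candidate$target_species,
            " block ", candidate$block_index,
            ": no mapped flanking coordinate; skipped")
    return(NULL)
  }
  if (!is.na(up) && !is.na(dn)) {
    L <- min(up, dn); R <- max(up, dn)
  } else {
    v <- if (is.na(up)) dn else up
    # which genomic side is unknown? protein-upstream maps left on '+',
    # right on '-'
    missing_left <- (is.na(up) && strand == "+") || (is.na(dn) && strand == "-")
    if (missing_left) { L <- v - window_pad; R <- v } else { L <- v; R <- v + window_pad }
  }
  L <- max(1L, as.integer(L))
  if (!is.null(genome)) R <- min(as.integer(R), chrom_length(genome, chrom))
  R <- as.integer(R)
  if (L >= R) {
    message("degenerate search window for ", candidate$gene, "/",
            candidate$target_species, "; skipped")
    return(NULL)
  }
  structure(list(chrom = chrom, strand = strand, L = L, R = R),
            class = "search_window")
}
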