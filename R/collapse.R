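#' Collapse all isoforms of each species into an all-exon consensus row
#'
#' Produces one row per species holding the union of all exons observed for
#' the gene, genome-ordered, in the same column space as the input alignment.
#' A column is a gap in species `k` only where no isoform of `k` has a
#' residue. Where isoforms disagree at a column (different residue or
#' different codon coordinate, as can happen when a region codes in more than
#' one frame across isoforms), a simple majority vote over the (residue,
#' coordinate) pairs decides; ties go to the value carried by the isoform
#' with the best (lowest) annotation score, then to the earliest row.
#'
#' @param aln an `isoform_alignment`.
#' @return an `all_exon_alignment` (without exon blocks `X`; see
#'   [derive_exon_blocks()]): `C` residue matrix (species x columns), `Q`
#'   codon-middle coordinate matrix (`NA` at gaps), `scores` best annotation
#'   score among contributing isoforms per cell, `species_info`, and a
#'   `conflicts` data.frame recording every outvoted cell.
#' @export
collapse_isoforms <- function(aln) {
  validate_isoform_alignment(aln)
  species <- unique(aln$rows$species)
  m <- ncol(aln$M)
  n <- length(species)
  C <- matrix("-", n, m, dimnames = list(species, NULL))
  Q <- matrix(NA_integer_, n, m, dimnames = list(species, NULL))
  A <- matrix(NA_integer_, n, m, dimnames = list(species, NULL))
  conflicts <- list()
  for (k in seq_along(species)) {
    ridx <- which(aln$rows$species == species[k])
    subM <- aln$M[ridx, , drop = FALSE]
    subP <- aln$P[ridx, , drop = FALSE]
    sc <- aln$rows$score[ridx]
    sc_rank <- ifelse(is.na(sc), Inf, sc)
    for (j in seq_len(m)) {
      hit <- which(subM[, j] != "-")
      if (length(hit) == 0L) next
      aa <- subM[hit, j]
      qq <- subP[hit, j]
      A[k, j] <- if (all(is.na(sc[hit]))) NA_integer_ else
        min(sc[hit], na.rm = TRUE)
      key <- paste(aa, qq)
      if (length(unique(key)) == 1L) {
        C[k, j] <- aa[1L]
        Q[k, j] <- qq[1L]
      } else {
        tab <- table(key)
        best_keys <- names(tab)[tab == max(tab)]
        # tie-break: best-evidenced isoform among the tied values, then order
        cand <- hit[key %in% best_keys]
        winner <- cand[order(sc_rank[cand], cand)][1L]
        C[k, j] <- subM[winner, j]
        Q[k, j] <- subP[winner, j]
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          species = species[k], column = j,
          n_entries = length(hit),
          n_outvoted = sum(key != paste(subM[winner, j], subP[winner, j])),
          stringsAsFactors = FALSE)
      }
    }
  }
  info <- unique(aln$rows[, c("species", "chrom", "strand")])
  rownames(info) <- NULL
  structure(list(
    gene = aln$gene,
    species = species,
    species_info = info[match(species, info$species), , drop = FALSE],
    C = C, Q = Q, scores = A, X = NULL,
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
      data.frame(species = character(), column = integer(),
                 n_entries = integer(), n_outvoted = integer())),
    class = "all_exon_alignment")
}

#' Partition alignment columns into exon blocks
#'
#' Places a block boundary between consecutive columns wherever any species
#' with coordinates at both columns shows a codon-coordinate jump larger than
#' `max_codon_step` nucleotides: adjacent codon middles are 3 nt apart in
#' contiguous coding sequence, so a larger jump marks an intron. Boundaries
#' from all species are unioned, so a single block list serves the family.
#'
#' @param aln an `all_exon_alignment`.
#' @param max_codon_step maximum within-exon coordinate step, in nucleotides.
#' @return `aln` with element `X`: an integer matrix with columns
#'   `start`,`end`, whose rows tile `1..m` with adjacent disjoint ranges.
#' @export
derive_exon_blocks <- function(aln, max_codon_step = 6L) {
  m <- ncol(aln$C)
  bnd <- logical(max(m - 1L, 0L))
  for (k in seq_len(nrow(aln$Q))) {
    q <- aln$Q[k, ]
    if (m > 1L) {
      both <- !is.na(q[-m]) & !is.na(q[-1L])
      jump <- abs(q[-1L] - q[-m]) > max_codon_step
      bnd <- bnd | (both & jump)
    }
  }
  cuts <- which(bnd)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, m)
  aln$X <- cbind(start = starts, end = ends)
  aln
}

#' Reinterpret an all-exon alignment as a one-isoform-per-species alignment
#'
#' Useful for idempotence checks and for feeding collapsed rows back through
#' isoform-level tooling.
#'
#' @param aln an `all_exon_alignment`.
#' @return an `isoform_alignment` with one row per species.
#' @export
as_isoform_alignment <- function(aln) {
  rows <- data.frame(isoform = aln$species,
                     species = aln$species,
                     chrom = aln$species_info$chrom,
                     strand = aln$species_info$strand,
                     score = NA_integer_,
                     stringsAsFactors = FALSE)
  M <- aln$C
  P <- aln$Q
  rownames(M) <- rownames(P) <- rows$isoform
  structure(list(gene = aln$gene, rows = rows, M = M, P = P),
            class = "isoform_alignment")
}

#' Write the collapsed alignment (C as aligned FASTA, Q in mapping dialect)
#'
#' @param aln an `all_exon_alignment`.
#' @param c_path,q_path output paths for the residue and coordinate files.
#' @return invisibly, c(c_path, q_path).
#' @export
write_all_exon <- function(aln, c_path, q_path) {
  hdr <- paste0(aln$species, " species=", aln$species,
                " chrom=", aln$species_info$chrom,
                " strand=", aln$species_info$strand)
  fa <- character(2L * nrow(aln$C))
  fa[c(TRUE, FALSE)] <- paste0(">", hdr)
  fa[c(FALSE, TRUE)] <- apply(aln$C, 1L, paste, collapse = "")
  writeLines(fa, c_path)
  write_mapping_file(aln$species,
                     lapply(seq_len(nrow(aln$Q)),
                            function(i) aln$Q[i, !is.na(aln$Q[i, ])]),
                     q_path)
  invisible(c(c_path, q_path))
}

#' Read back a collapsed alignment written by [write_all_exon()]
#'
#' Restores `C` and `Q` exactly; per-cell annotation scores and conflict logs
#' are not serialized. Exon blocks can be re-derived with
#' [derive_exon_blocks()].
#'
#' @param c_path,q_path files written by [write_all_exon()].
#' @param gene gene identifier; defaults to the C file's base name.
#' @return an `all_exon_alignment` without `X`.
#' @export
read_all_exon <- function(c_path, q_path,
                          gene = tools::file_path_sans_ext(basename(c_path))) {
  iso <- read_isoform_alignment(c_path, q_path, gene = gene)
  structure(list(
    gene = gene,
    species = iso$rows$species,
    species_info = iso$rows[, c("species", "chrom", "strand")],
    C = `rownames<-`(iso$M, iso$rows$species),
    Q = `rownames<-`(iso$P, iso$rows$species),
    scores = matrix(NA_integer_, nrow(iso$M), ncol(iso$M),
                    dimnames = list(iso$rows$species, NULL)),
    X = NULL,
    conflicts = data.frame(species = character(), column = integer(),
                           n_entries = integer(), n_outvoted = integer())),
    class = "all_exon_alignment")
}

#' @export
print.all_exon_alignment <- function(x, ...) {
  cat("all_exon_alignment '", x$gene, "': ", nrow(x$C), " species, ",
      ncol(x$C), " columns", sep = "")
  if (!is.null(x$X)) cat(", ", nrow(x$X), " exon block(s)", sep = "")
  cat("\n")
  invisible(x)
}
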