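# Construct small alignment objects directly, bypassing file I/O.

make_iso_aln <- function(seqs, coords, species, strands = NULL, chroms = NULL,
                         scores = NULL, gene = "TOY") {
  n <- length(seqs)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(chroms)) chroms <- rep("chr1", n)
  if (is.null(scores)) scores <- rep(NA_integer_, n)
  M <- do.call(rbind, strsplit(seqs, ""))
  P <- matrix(NA_integer_, nrow(M), ncol(M))
  for (i in seq_len(n)) P[i, M[i, ] != "-"] <- coords[[i]]
  ids <- sprintf("iso%d", seq_len(n))
  rownames(M) <- rownames(P) <- ids
  aln <- structure(list(
    gene = gene,
    rows = data.frame(isoform = ids, species = species, chrom = chroms,
                      strand = strands, score = as.integer(scores),
                      stringsAsFactors = FALSE),
    M = M, P = P), class = "isoform_alignment")
  validate_isoform_alignment(aln)
  aln
}

# hand-built all_exon_alignment; X given as list of c(start, end)
make_aea <- function(C_rows, Q_rows, species, strands = NULL, chroms = NULL,
                     X = NULL, gene = "TOY") {
  n <- length(C_rows)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(chroms)) chroms <- rep("chr1", n)
  C <- do.call(rbind, strsplit(C_rows, ""))
  Q <- do.call(rbind, Q_rows)
  rownames(C) <- rownames(Q) <- species
  structure(list(
    gene = gene, species = species,
    species_info = data.frame(species = species, chrom = chroms,
                              strand = strands, stringsAsFactors = FALSE),
    C = C, Q = Q,
    scores = matrix(NA_integer_, n, ncol(C), dimnames = list(species, NULL)),
    X = if (is.null(X)) NULL else
      do.call(rbind, lapply(X, function(x) c(start = x[1], end = x[2]))),
    conflicts = data.frame()), class = "all_exon_alignment")
}

# minimal exon_prediction stub for annotate-level tests
make_pred <- function(chrom = "chr1", start, end, identity,
                      target = "sp1", source = "sp2", block = 2L,
                      aligned_query = NULL, aligned_target = NULL,
                      source_score = NA_integer_, gene = "TOY",
                      strand = "+") {
  aa_len <- as.integer((end - start + 1) %/% 3)
  if (is.null(aligned_query)) aligned_query <- strrep("A", aa_len)
  if (is.null(aligned_target)) aligned_target <- aligned_query
  aln <- structure(list(
    query_peptide = gsub("-", "", aligned_query),
    aligned_query = aligned_query, aligned_target = aligned_target,
    target_peptide = gsub("-", "", aligned_target),
    score = 50L, frame = 0L,
    query_range = c(start = 1L, end = nchar(gsub("-", "", aligned_query))),
    target_nt = c(start = 1L, end = 3L * aa_len),
    query_coverage = 1, pct_identity = identity,
    chrom = chrom, strand = strand,
    genomic = c(start = start, end = end)), class = "exon_alignment")
  structure(list(
    gene = gene, target_species = target, chrom = chrom, strand = strand,
    interval = c(start, end), block_index = block,
    supports = list(list(source_species = source, alignment = aln,
                         pct_identity = identity,
                         source_annotation_score = source_score,
                         source_coords = c(start = 1L, end = 100L),
                         block_index = block)),
    pct_identity = identity, aa_length = aa_len,
    novelty = NA_character_, transitive_score = NA_integer_),
    class = "exon_prediction")
}
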