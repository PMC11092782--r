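# Translated search of a query exon peptide inside a genomic window, and the
# protein-level Smith-Waterman realignment of each seed.

aa_encode <- function(x, S = blosum62()) {
  codes <- match(strsplit(x, "")[[1]], rownames(S))
  # unknown letters (shouldn't occur) score as X
  codes[is.na(codes)] <- match("X", rownames(S))
  codes - 1L
}

# local affine-gap alignment of two peptide strings; thin R wrapper over the
# C++ kernel. mask: logical over target positions excluded from alignment.
sw_local <- function(query, target, gap_open = 11L, gap_extend = 1L,
                     mask = NULL) {
  S <- blosum62()
  a <- aa_encode(query, S)
  b <- aa_encode(target, S)
  if (is.null(mask)) mask <- rep(FALSE, length(b))
  r <- .sw_local_cpp(a, b, S, as.integer(gap_open), as.integer(gap_extend),
                     mask)
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  r$aligned_query <- paste(ifelse(r$a_idx == 0L, "-", qc[pmax(r$a_idx, 1L)]),
                           collapse = "")
  r$aligned_target <- paste(ifelse(r$b_idx == 0L, "-", tc[pmax(r$b_idx, 1L)]),
                            collapse = "")
  r
}

# Ungapped extension of a local alignment toward the ends of the query,
# wherever the target has residues to pair with. The core score is left
# untouched; only the aligned strings and bounds grow.
extend_full_length <- function(r, query, target) {
  if (r$a_start == 0L) return(r)
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  left <- min(r$a_start - 1L, r$b_start - 1L)
  right <- min(length(qc) - r$a_end, length(tc) - r$b_end)
  if (left > 0L) {
    r$a_idx <- c(seq.int(r$a_start - left, r$a_start - 1L), r$a_idx)
    r$b_idx <- c(seq.int(r$b_start - left, r$b_start - 1L), r$b_idx)
    r$a_start <- r$a_start - left
    r$b_start <- r$b_start - left
  }
  if (right > 0L) {
    r$a_idx <- c(r$a_idx, seq.int(r$a_end + 1L, r$a_end + right))
    r$b_idx <- c(r$b_idx, seq.int(r$b_end + 1L, r$b_end + right))
    r$a_end <- r$a_end + right
    r$b_end <- r$b_end + right
  }
  r$aligned_query <- paste(ifelse(r$a_idx == 0L, "-", qc[pmax(r$a_idx, 1L)]),
                           collapse = "")
  r$aligned_target <- paste(ifelse(r$b_idx == 0L, "-", tc[pmax(r$b_idx, 1L)]),
                            collapse = "")
  r
}

# Translate a window in one of the three forward frames. Codons containing N
# translate to X; trailing partial codons are dropped.
translate_frame <- function(window_dna, frame) {
  n <- nchar(window_dna)
  start <- frame + 1L
  len <- ((n - frame) %/% 3L) * 3L
  if (len < 3L) return("")
  dna <- Biostrings::DNAString(substr(window_dna, start, frame + len))
  as.character(Biostrings::translate(dna, no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Translated seed search of a peptide against a genomic window
#'
#' Scans all three forward reading frames of a (strand-oriented) window for
#' local alignments of the query peptide, returning the highest-scoring
#' mutually non-overlapping hits. The internal backend is an exhaustive
#' translated Smith-Waterman scan: the best local hit is extracted, its
#' nucleotide footprint is masked in every frame, and the scan repeats until
#' no hit reaches the seed threshold. The threshold is
#' `min(seed_min_score, 0.9 * self-score of the peptide)`, so short queries
#' near their maximum attainable score still seed while random windows stay
#' quiet.
#'
#' @param peptide query peptide (>= 6 residues).
#' @param window_dna nucleotide string, already oriented to the coding
#'   strand (reverse-complemented for minus-strand windows).
#' @param cfg a [scout_config()].
#' @param max_seeds safety cap on the number of seeds returned.
#' @return list of seed hits, each `list(start, end, frame, score)` with
#'   `start`/`end` 1-based nucleotide positions on the window and `frame`
#'   in 0..2; sorted by descending score.
#' @export
seed_search <- function(peptide, window_dna, cfg = scout_config(),
                        max_seeds = 25L) {
  if (nchar(window_dna) < 3L * 6L) {
    message("window shorter than 18 nt; no translated search possible")
    return(list())
  }
  if (identical(cfg$seed_backend, "tblastn"))
    return(seed_search_tblastn(peptide, window_dna, cfg, max_seeds))
  S <- blosum62()
  pep_codes <- aa_encode(peptide, S) + 1L
  self_score <- sum(diag(S)[pep_codes])
  thr <- min(cfg$seed_min_score, floor(0.9 * self_score))
  trans <- lapply(0:2, function(f) translate_frame(window_dna, f))
  masks <- lapply(trans, function(t) rep(FALSE, nchar(t)))
  seeds <- list()
  repeat {
    best <- NULL
    for (f in 0:2) {
      if (nchar(trans[[f + 1L]]) == 0L) next
      r <- sw_local(peptide, trans[[f + 1L]], cfg$gap_open, cfg$gap_extend,
                    mask = masks[[f + 1L]])
      if (is.null(best) || r$score > best$r$score) best <- list(f = f, r = r)
    }
    if (is.null(best) || best$r$score < thr || best$r$b_start == 0L) break
    f <- best$f
    nt_start <- f + 3L * (best$r$b_start - 1L) + 1L
    nt_end <- f + 3L * best$r$b_end
    seeds[[length(seeds) + 1L]] <- list(start = nt_start, end = nt_end,
                                        frame = f, score = best$r$score)
    # mask the seed's nucleotide footprint in every frame
    for (f2 in 0:2) {
      nt <- nchar(trans[[f2 + 1L]])
      if (nt == 0L) next
      t_lo <- max(1L, ceiling((nt_start - f2) / 3))
      t_hi <- min(nt, floor((nt_end - f2 + 2L) / 3))
      if (t_lo <= t_hi) masks[[f2 + 1L]][t_lo:t_hi] <- TRUE
    }
    if (length(seeds) >= max_seeds) break
  }
  seeds[order(vapply(seeds, `[[`, 0, "score"), decreasing = TRUE)]
}

# External seed backend: tblastn on a temporary query/subject FASTA pair,
# honoring the same contract as the internal scan (plus-frame hits only,
# since the window is already strand-oriented; highest-scoring mutually
# non-overlapping hits above the seed threshold).
seed_search_tblastn <- function(peptide, window_dna, cfg, max_seeds = 25L) {
  if (Sys.which("tblastn") == "")
    stop("tblastn not found on PATH; use seed_backend = \"internal\"",
         call. = FALSE)
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)))
  writeLines(c(">q", peptide), qf)
  writeLines(c(">w", window_dna), sf)
  out <- suppressWarnings(system2(
    "tblastn",
    c("-query", qf, "-subject", sf, "-seg", "no", "-outfmt",
      shQuote("6 sstart send sframe score")),
    stdout = TRUE, stderr = FALSE))
  if (length(out) == 0L) return(list())
  S <- blosum62()
  self_score <- sum(diag(S)[aa_encode(peptide, S) + 1L])
  thr <- min(cfg$seed_min_score, floor(0.9 * self_score))
  rows <- do.call(rbind, lapply(strsplit(out, "\t"), as.numeric))
  keep <- rows[, 3L] > 0 & rows[, 4L] >= thr   # plus-frame, above threshold
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) return(list())
  rows <- rows[order(-rows[, 4L]), , drop = FALSE]
  seeds <- list()
  for (i in seq_len(nrow(rows))) {
    s <- min(rows[i, 1:2]); e <- max(rows[i, 1:2])
    clash <- any(vapply(seeds, function(x) s <= x$end && e >= x$start, TRUE))
    if (clash) next
    seeds[[length(seeds) + 1L]] <- list(start = as.integer(s),
                                        end = as.integer(e),
                                        frame = as.integer((s - 1) %% 3),
                                        score = as.integer(rows[i, 4L]))
    if (length(seeds) >= max_seeds) break
  }
  seeds
}

#' Realign a query peptide around a seed and map the hit to the genome
#'
#' Extends the seed by `cfg$seed_margin` codons on each side (staying in the
#' seed's reading frame), translates that region, and performs protein-level
#' Smith-Waterman alignment of the query against the translation. The aligned
#' target residues are mapped back to reference coordinates through the
#' window definition, strand-aware.
#'
#' @param peptide query peptide.
#' @param window_dna strand-oriented window sequence (as passed to
#'   [seed_search()]).
#' @param seed one element of the [seed_search()] result.
#' @param window the `search_window` the DNA came from; needed to map window
#'   positions back to reference coordinates. May be `NULL` for tests, in
#'   which case genomic coordinates are reported on the window itself.
#' @param cfg a [scout_config()].
#' @return an `exon_alignment`: aligned strings, `score`, `pct_identity`,
#'   `query_coverage`, `frame`, window-relative `target_nt` span, and
#'   reference `genomic` span (+ `chrom`, `strand` when `window` is given).
#' @export
sw_align <- function(peptide, window_dna, seed, window = NULL,
                     cfg = scout_config()) {
  wlen <- nchar(window_dna)
  pad <- 3L * cfg$seed_margin
  region_start <- seed$start - pad
  # keep the region in the seed's frame
  region_start <- region_start + ((seed$start - region_start) %% 3L)
  while (region_start < 1L) region_start <- region_start + 3L
  region_end <- min(wlen, seed$end + pad)
  region <- substr(window_dna, region_start, region_end)
  tr <- translate_frame(region, 0L)
  r <- sw_local(peptide, tr, cfg$gap_open, cfg$gap_extend)
  # the exon's extent is defined by the query, not by the score optimum:
  # extend the local core ungapped to the full query where target residues
  # exist, so terminal mismatches of a diverged exon stay in the alignment
  r <- extend_full_length(r, peptide, tr)
  if (r$b_start > 0L) {
    nt_start <- region_start + 3L * (r$b_start - 1L)
    nt_end <- region_start + 3L * r$b_end - 1L
  } else {
    nt_start <- nt_end <- NA_integer_
  }
  n_query_aligned <- sum(r$a_idx > 0L)
  a <- structure(list(
    query_peptide = peptide,
    aligned_query = r$aligned_query,
    aligned_target = r$aligned_target,
    target_peptide = gsub("-", "", r$aligned_target, fixed = TRUE),
    score = r$score,
    frame = seed$frame,
    query_range = c(start = r$a_start, end = r$a_end),
    target_nt = c(start = nt_start, end = nt_end),
    query_coverage = n_query_aligned / nchar(peptide)),
    class = "exon_alignment")
  a$pct_identity <- percent_identity(a)
  if (!is.null(window) && !is.na(nt_start)) {
    if (window$strand == "+") {
      g <- c(window$L + nt_start - 1L, window$L + nt_end - 1L)
    } else {
      g <- c(window$R - nt_end + 1L, window$R - nt_start + 1L)
    }
    a$chrom <- window$chrom
    a$strand <- window$strand
    a$genomic <- c(start = g[1L], end = g[2L])
  } else if (!is.na(nt_start)) {
    a$genomic <- c(start = nt_start, end = nt_end)
  } else {
    a$genomic <- c(start = NA_integer_, end = NA_integer_)
  }
  a
}

#' Percent identity over gap-free alignment columns
#'
#' The fraction of alignment columns in which both sequences carry a residue
#' and the residues are identical, among all columns in which both carry a
#' residue, as a percentage. Columns with a gap on either side count toward
#' neither numerator nor denominator.
#'
#' @param a an `exon_alignment`, or the first of two equal-length aligned
#'   strings.
#' @param b second aligned string when `a` is a string.
#' @return percentage in \[0, 100\]. When there is no gap-free column the
#'   value is 0 with attribute `undefined = TRUE`.
#' @export
percent_identity <- function(a, b = NULL) {
  if (inherits(a, "exon_alignment")) {
    x <- a$aligned_query; y <- a$aligned_target
  } else {
    x <- a; y <- b
  }
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  if (length(cx) != length(cy))
    stop("aligned strings differ in length", call. = FALSE)
  gapfree <- cx != "-" & cy != "-"
  if (!any(gapfree)) {
    return(structure(0, undefined = TRUE))
  }
  100 * sum(cx[gapfree] == cy[gapfree]) / sum(gapfree)
}

#' Accept or reject a candidate exon alignment
#'
#' An alignment supports an exon prediction when it covers at least
#' `cfg$min_coverage` of the query peptide, reaches `cfg$min_identity`
#' percent identity over gap-free columns, and has positive score.
#'
#' @param a an `exon_alignment`.
#' @param cfg a [scout_config()].
#' @return `list(accepted = TRUE)` or `list(accepted = FALSE, reason =
#'   "score"|"coverage"|"identity")`; the first failing criterion in that
#'   order is reported.
#' @export
accept_prediction <- function(a, cfg = scout_config()) {
  if (a$score <= 0) return(list(accepted = FALSE, reason = "score"))
  if (a$query_coverage < cfg$min_coverage)
    return(list(accepted = FALSE, reason = "coverage"))
  if (a$pct_identity < cfg$min_identity)
    return(list(accepted = FALSE, reason = "identity"))
  list(accepted = TRUE)
}

#' Search one missing-exon candidate inside its genomic window
#'
#' Runs the translated seed search and realignment for every query peptide
#' of the candidate and collects the accepted alignments as raw exon
#' predictions (one per accepted query/seed pair; overlapping predictions
#' are merged later by [dedup_predictions()]).
#'
#' @param candidate a `missing_exon_candidate`.
#' @param window a `search_window` for the candidate.
#' @param genome `genome_sequence` of the target species.
#' @param cfg a [scout_config()].
#' @return list with `predictions` (list of `exon_prediction`) and
#'   `rejections` (data.frame of rejected alignments and reasons).
#' @export
search_candidate <- function(candidate, window, genome,
                             cfg = scout_config()) {
  window_dna <- fetch_sequence(genome, window$chrom, window$L, window$R,
                               window$strand)
  preds <- list()
  rej <- list()
  for (q in candidate$queries) {
    seeds <- seed_search(q$peptide, window_dna, cfg)
    for (seed in seeds) {
      a <- sw_align(q$peptide, window_dna, seed, window = window, cfg = cfg)
      verdict <- accept_prediction(a, cfg)
      if (verdict$accepted) {
        supp <- list(source_species = q$source_species,
                     alignment = a,
                     pct_identity = a$pct_identity,
                     source_annotation_score = q$source_annotation_score,
                     source_coords = q$source_coords,
                     block_index = candidate$block_index)
        preds[[length(preds) + 1L]] <- structure(list(
          gene = candidate$gene,
          target_species = candidate$target_species,
          chrom = window$chrom,
          strand = window$strand,
          interval = unname(a$genomic),
          block_index = candidate$block_index,
          supports = list(supp),
          pct_identity = a$pct_identity,
          aa_length = as.integer((a$genomic[["end"]] - a$genomic[["start"]] + 1L) %/% 3L),
          novelty = NA_character_,
          transitive_score = NA_integer_),
          class = "exon_prediction")
      } else {
        rej[[length(rej) + 1L]] <- data.frame(
          gene = candidate$gene, target_species = candidate$target_species,
          source_species = q$source_species,
          block_index = candidate$block_index,
          score = a$score, pct_identity = a$pct_identity,
          query_coverage = a$query_coverage, reason = verdict$reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(predictions = preds,
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(gene = character(), target_species = character(),
                    source_species = character(), block_index = integer(),
                    score = numeric(), pct_identity = numeric(),
                    query_coverage = numeric(), reason = character()))
}
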