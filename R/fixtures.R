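# Synthetic multi-species gene families with planted hidden exons. The
# generator emulates the evolutionary scenario the pipeline targets: a gene
# whose exons are conserved across species, where one species' known isoforms
# happen not to include a particular exon even though its homolog is present
# in the genome.

#' Specification of a synthetic gene family
#'
#' @param seed integer RNG seed; the family is a pure function of the spec.
#' @param n_species number of species.
#' @param n_exons number of exons in the ancestral gene.
#' @param exon_aa_range min/max exon length in amino acids.
#' @param intron_nt_range min/max intron length in nucleotides (introns get
#'   canonical GT..AG ends).
#' @param pairwise_identity target percent identity of each non-reference
#'   species to the reference (species 1), applied uniformly to every exon.
#' @param hidden_exons list of `list(species=, exon=, identity=)`: the exon
#'   is removed from every isoform of that species but planted in its genome
#'   at the given percent identity to the ancestral copy.
#' @param strands per-species strand of the gene on its toy chromosome.
#' @param flank_policy `"both"` leaves the hidden exon with intact flanking
#'   exons; `"no-upstream"`/`"no-downstream"` force the hidden exon to be the
#'   first/last exon so one genomic flank is undefined.
#' @param flank_nt random sequence padding each end of the gene.
#' @param gene gene-family identifier.
#' @return a `family_spec` list.
#' @export
family_spec <- function(seed,
                        n_species = 3L,
                        n_exons = 5L,
                        exon_aa_range = c(18L, 36L),
                        intron_nt_range = c(100L, 2000L),
                        pairwise_identity = 100,
                        hidden_exons = list(),
                        strands = rep("+", n_species),
                        flank_policy = c("both", "no-upstream", "no-downstream"),
                        flank_nt = 2500L,
                        gene = sprintf("FAM%05d", seed %% 100000L)) {
  flank_policy <- match.arg(flank_policy)
  stopifnot(n_species >= 2L, n_exons >= 1L,
            length(strands) == n_species, all(strands %in% c("+", "-")))
  if (flank_policy == "no-upstream")
    hidden_exons <- lapply(hidden_exons, function(h) { h$exon <- 1L; h })
  if (flank_policy == "no-downstream")
    hidden_exons <- lapply(hidden_exons, function(h) { h$exon <- n_exons; h })
  hidden_exons <- lapply(hidden_exons, function(h) {
    h$species <- as.integer(h$species); h$exon <- as.integer(h$exon)
    stopifnot(h$species >= 1L, h$species <= n_species,
              h$exon >= 1L, h$exon <= n_exons,
              h$identity >= 0, h$identity <= 100)
    h
  })
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_exons = as.integer(n_exons),
                 exon_aa_range = as.integer(exon_aa_range),
                 intron_nt_range = as.integer(intron_nt_range),
                 pairwise_identity = pairwise_identity,
                 hidden_exons = hidden_exons, strands = strands,
                 flank_policy = flank_policy, flank_nt = as.integer(flank_nt),
                 gene = gene),
            class = "family_spec")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Mutate a peptide to a target percent identity
#'
#' Substitutes `round(n * (1 - identity/100))` residues at random positions
#' with different amino acids (no indels), so the gap-free identity of the
#' result to the input equals the target up to one residue's granularity.
#'
#' @param peptide input peptide.
#' @param identity target percent identity in \[0, 100\].
#' @param aa alphabet to draw replacements from.
#' @return mutated peptide string.
#' @export
plant_divergence <- function(peptide, identity, aa = AA20) {
  stopifnot(identity >= 0, identity <= 100)
  n <- nchar(peptide)
  k <- round(n * (1 - identity / 100))
  if (k == 0L) return(peptide)
  chars <- strsplit(peptide, "")[[1]]
  pos <- sample.int(n, k)
  for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1L)
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# reverse table of the standard genetic code, built once
codon_table <- function() {
  if (is.null(.exonscout_env$REV_CODE)) {
    gc <- Biostrings::GENETIC_CODE
    .exonscout_env$REV_CODE <- split(names(gc), gc)
  }
  .exonscout_env$REV_CODE
}

back_translate <- function(peptide) {
  rev_code <- codon_table()
  chars <- strsplit(peptide, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- rev_code[[a]]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

random_intron <- function(len) {
  stopifnot(len >= 4L)
  paste0("GT", random_dna(len - 4L), "AG")
}

#' Generate a synthetic gene family with planted hidden exons
#'
#' Builds an ancestral multi-exon protein, derives each species' exon copies
#' at the spec's pairwise identity (substitutions only, so exon copies stay
#' column-aligned), back-translates them with random codon choice, embeds
#' them with random GT..AG introns and flanking sequence on a per-species toy
#' chromosome (reverse-complemented for minus-strand species), and constructs
#' the isoform MSA and codon-coordinate matrices exactly. Exons listed in
#' `hidden_exons` are present in the species' genome (mutated to the planted
#' identity) but omitted from all of its isoforms. Each species contributes
#' two isoforms (the full visible exon set, annotation score 1, and the same
#' set minus its last exon, score 3) so that collapsing is exercised.
#'
#' @param spec a [family_spec()].
#' @return list with `genomes` (named list of `genome_sequence`), `aln`
#'   (`isoform_alignment`), `truth` (data.frame: one row per hidden exon with
#'   its genomic interval, strand, true peptide and planted identity),
#'   `gtf` (data.frame of CDS intervals of the visible exons per species),
#'   and `spec`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n_sp <- spec$n_species
  species <- sprintf("sp%d", seq_len(n_sp))
  exon_len <- sample(seq(spec$exon_aa_range[1L], spec$exon_aa_range[2L]),
                     spec$n_exons, replace = TRUE)
  ancestral <- vapply(exon_len, function(l)
    paste(sample(AA20, l, TRUE), collapse = ""), "")

  hidden_key <- vapply(spec$hidden_exons,
                       function(h) paste(h$species, h$exon), "")
  hidden_of <- function(s, x) {
    i <- match(paste(s, x), hidden_key)
    if (is.na(i)) NULL else spec$hidden_exons[[i]]
  }

  # per-species exon peptides (genomic copies, hidden or not)
  peptides <- matrix("", n_sp, spec$n_exons)
  for (s in seq_len(n_sp)) {
    for (x in seq_len(spec$n_exons)) {
      h <- hidden_of(s, x)
      peptides[s, x] <- if (!is.null(h)) {
        plant_divergence(ancestral[x], h$identity)
      } else if (s == 1L || spec$pairwise_identity >= 100) {
        ancestral[x]
      } else {
        plant_divergence(ancestral[x], spec$pairwise_identity)
      }
    }
  }

  genomes <- list()
  gtf_rows <- list()
  truth_rows <- list()
  # per species/exon: chromosome-coordinate codon middles, row-ordered 5'->3'
  # in protein order
  middles <- vector("list", n_sp)
  exon_iv <- vector("list", n_sp)

  for (s in seq_len(n_sp)) {
    cds <- vapply(peptides[s, ], back_translate, "")
    introns <- if (spec$n_exons > 1L)
      vapply(sample(seq(spec$intron_nt_range[1L], spec$intron_nt_range[2L]),
                    spec$n_exons - 1L, replace = TRUE), random_intron, "")
    else character()
    parts <- character(2L * spec$n_exons - 1L)
    parts[seq(1L, length(parts), by = 2L)] <- cds
    if (spec$n_exons > 1L) parts[seq(2L, length(parts), by = 2L)] <- introns
    gene_seq <- paste0(random_dna(spec$flank_nt), paste(parts, collapse = ""),
                       random_dna(spec$flank_nt))
    # plus-orientation exon intervals on the gene sequence
    off <- spec$flank_nt
    iv <- matrix(0L, spec$n_exons, 2L)
    for (x in seq_len(spec$n_exons)) {
      len <- nchar(cds[x])
      iv[x, ] <- c(off + 1L, off + len)
      off <- off + len + if (x < spec$n_exons) nchar(introns[x]) else 0L
    }
    chrom_len <- nchar(gene_seq)
    if (spec$strands[s] == "+") {
      chrom_seq <- gene_seq
      iv_chrom <- iv
      mid <- lapply(seq_len(spec$n_exons), function(x)
        iv[x, 1L] + 3L * (seq_len(nchar(peptides[s, x])) - 1L) + 1L)
    } else {
      chrom_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seq)))
      iv_chrom <- cbind(chrom_len - iv[, 2L] + 1L, chrom_len - iv[, 1L] + 1L)
      mid <- lapply(seq_len(spec$n_exons), function(x) {
        p <- iv[x, 1L] + 3L * (seq_len(nchar(peptides[s, x])) - 1L) + 1L
        chrom_len - p + 1L
      })
    }
    genomes[[species[s]]] <- genome_from_sequences(
      stats::setNames(chrom_seq, "chr1"))
    middles[[s]] <- mid
    exon_iv[[s]] <- iv_chrom
    for (x in seq_len(spec$n_exons)) {
      h <- hidden_of(s, x)
      if (is.null(h)) {
        gtf_rows[[length(gtf_rows) + 1L]] <- data.frame(
          species = species[s], chrom = "chr1",
          start = iv_chrom[x, 1L], end = iv_chrom[x, 2L],
          strand = spec$strands[s], exon = x, stringsAsFactors = FALSE)
      } else {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene = spec$gene, species = species[s], chrom = "chr1",
          start = iv_chrom[x, 1L], end = iv_chrom[x, 2L],
          strand = spec$strands[s], exon = x,
          peptide = peptides[s, x], planted_identity = h$identity,
          stringsAsFactors = FALSE)
      }
    }
  }

  # column layout: exon x occupies a contiguous block of width |ancestral x|
  col_off <- cumsum(c(0L, exon_len))
  m <- col_off[spec$n_exons + 1L]

  rows <- list()
  Mrows <- list()
  Prows <- list()
  for (s in seq_len(n_sp)) {
    visible <- setdiff(seq_len(spec$n_exons),
                       vapply(spec$hidden_exons,
                              function(h) if (h$species == s) h$exon else 0L,
                              0L))
    iso_sets <- list(visible)
    if (length(visible) >= 2L)
      iso_sets <- c(iso_sets, list(visible[-length(visible)]))
    iso_scores <- c(1L, 3L)
    for (ii in seq_along(iso_sets)) {
      Mr <- rep("-", m)
      Pr <- rep(NA_integer_, m)
      for (x in iso_sets[[ii]]) {
        cols <- (col_off[x] + 1L):(col_off[x] + exon_len[x])
        Mr[cols] <- strsplit(peptides[s, x], "")[[1]]
        Pr[cols] <- middles[[s]][[x]]
      }
      id <- sprintf("%s_%s_iso%d", spec$gene, species[s], ii)
      rows[[length(rows) + 1L]] <- data.frame(
        isoform = id, species = species[s], chrom = "chr1",
        strand = spec$strands[s], score = iso_scores[ii],
        stringsAsFactors = FALSE)
      Mrows[[length(Mrows) + 1L]] <- Mr
      Prows[[length(Prows) + 1L]] <- Pr
    }
  }
  rows <- do.call(rbind, rows)
  M <- do.call(rbind, Mrows)
  P <- do.call(rbind, Prows)
  rownames(M) <- rownames(P) <- rows$isoform
  aln <- structure(list(gene = spec$gene, rows = rows, M = M, P = P),
                   class = "isoform_alignment")
  validate_isoform_alignment(aln)

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(gene = character(), species = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               exon = integer(), peptide = character(),
               planted_identity = numeric())
  gtf <- do.call(rbind, gtf_rows)
  list(genomes = genomes, aln = aln, truth = truth, gtf = gtf, spec = spec)
}

#' Write a synthetic family to disk in the pipeline's input formats
#'
#' Creates `genomes/<species>.fa`, `msa/<gene>.afa`, `maps/<gene>.map`,
#' `gtf/<species>.gtf` (CDS features of the visible exons only), and appends
#' the hidden-exon ground truth to `truth.tsv`.
#'
#' @param fam result of [generate_family()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(fam, dir) {
  for (d in file.path(dir, c("genomes", "msa", "maps", "gtf")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(fam$genomes)) {
    write_genome_fasta(fam$genomes[[sp]],
                       file.path(dir, "genomes", paste0(sp, ".fa")))
  }
  write_isoform_alignment(fam$aln,
                          file.path(dir, "msa", paste0(fam$aln$gene, ".afa")),
                          file.path(dir, "maps", paste0(fam$aln$gene, ".map")))
  for (sp in unique(fam$gtf$species)) {
    g <- fam$gtf[fam$gtf$species == sp, ]
    lines <- sprintf("%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\";",
                     g$chrom, g$start, g$end, g$strand, fam$spec$gene)
    gtf_path <- file.path(dir, "gtf", paste0(sp, ".gtf"))
    cat(lines, file = gtf_path, sep = "\n", append = file.exists(gtf_path))
    cat("\n", file = gtf_path, append = TRUE)
  }
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(fam$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(truth_path),
                     append = file.exists(truth_path))
  invisible(dir)
}
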