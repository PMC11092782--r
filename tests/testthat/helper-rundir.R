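# build a small on-disk input set: one planted family, one negative control
make_run_dir <- function(root = tempfile()) {
  specs <- list(
    family_spec(seed = 201, gene = "FAMA",
                hidden_exons = list(list(species = 2L, exon = 3L,
                                         identity = 85))),
    family_spec(seed = 202, gene = "FAMB")
  )
  fams <- lapply(specs, generate_family)
  # families share species labels, so merge their genomes onto one toy
  # chromosome set per species by giving each family its own chromosome name
  for (fi in seq_along(fams)) {
    fam <- fams[[fi]]
    chrom <- paste0("chr", fi)
    for (sp in names(fam$genomes)) {
      names(fam$genomes[[sp]]$seqs) <- chrom
    }
    fam$aln$rows$chrom <- chrom
    fam$gtf$chrom <- chrom
    if (nrow(fam$truth)) fam$truth$chrom <- chrom
    fams[[fi]] <- fam
  }
  dir.create(file.path(root, "msa"), recursive = TRUE)
  dir.create(file.path(root, "maps"), recursive = TRUE)
  dir.create(file.path(root, "genomes"))
  dir.create(file.path(root, "gtf"))
  species <- names(fams[[1]]$genomes)
  for (sp in species) {
    g <- Biostrings::DNAStringSet(c(
      as.character(fams[[1]]$genomes[[sp]]$seqs[[1]]),
      as.character(fams[[2]]$genomes[[sp]]$seqs[[1]])))
    names(g) <- c("chr1", "chr2")
    Biostrings::writeXStringSet(g, file.path(root, "genomes",
                                             paste0(sp, ".fa")))
    gtf_sp <- do.call(rbind, lapply(fams, function(f)
      f$gtf[f$gtf$species == sp, ]))
    writeLines(sprintf("%s\tsyn\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"x\";",
                       gtf_sp$chrom, gtf_sp$start, gtf_sp$end, gtf_sp$strand),
               file.path(root, "gtf", paste0(sp, ".gtf")))
  }
  for (fam in fams) {
    write_isoform_alignment(fam$aln,
                            file.path(root, "msa", paste0(fam$aln$gene, ".afa")),
                            file.path(root, "maps", paste0(fam$aln$gene, ".map")))
  }
  list(root = root, truth = fams[[1]]$truth, species = species)
}

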