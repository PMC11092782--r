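# End-to-end orchestration over a directory of gene families.

#' Process one gene family in memory
#'
#' Runs the full discovery chain for a single family: collapse the isoform
#' alignment, derive exon blocks, detect missing-exon candidates, compute
#' search windows, run the translated search, merge overlapping predictions,
#' classify novelty, assign transitive annotation scores, and compute
#' divergence deltas.
#'
#' @param aln an `isoform_alignment` for the family.
#' @param genomes named list of `genome_sequence`, one per species.
#' @param tracks named list of `cds_annotation` per species (optional).
#' @param cfg a [scout_config()].
#' @return list: `aln` (the collapsed alignment with blocks),
#'   `predictions` (annotated, deduplicated), `rejections` (data.frame),
#'   `n_candidates`, `n_windows`.
#' @export
process_family <- function(aln, genomes, tracks = list(),
                           cfg = scout_config()) {
  coll <- collapse_isoforms(aln)
  coll <- derive_exon_blocks(coll, max_codon_step = cfg$max_codon_step)
  cands <- find_missing_exons(coll)
  raw <- list()
  rejections <- list()
  n_windows <- 0L
  for (cand in cands) {
    genome <- genomes[[cand$target_species]]
    if (is.null(genome)) {
      message("no genome for species '", cand$target_species, "'; skipped")
      next
    }
    window <- compute_search_window(coll, cand, genome = genome,
                                    window_pad = cfg$window_pad)
    if (is.null(window)) next
    n_windows <- n_windows + 1L
    res <- search_candidate(cand, window, genome, cfg)
    raw <- c(raw, res$predictions)
    if (nrow(res$rejections)) rejections[[length(rejections) + 1L]] <- res$rejections
  }
  # merge per target species, then annotate
  preds <- list()
  targets <- unique(vapply(raw, `[[`, "", "target_species"))
  for (sp in sort(targets)) {
    sp_preds <- dedup_predictions(raw[vapply(raw, `[[`, "", "target_species") == sp])
    trk <- tracks[[sp]] %||% read_cds_annotations(NULL)
    for (p in sp_preds) {
      p <- classify_novelty(p, trk)
      p <- transitive_annotation_score(p)
      p$deltas <- divergence_deltas(p, coll)
      preds[[length(preds) + 1L]] <- p
    }
  }
  list(aln = coll, predictions = preds,
       rejections = if (length(rejections)) do.call(rbind, rejections) else
         data.frame(),
       n_candidates = length(cands), n_windows = n_windows)
}

#' Run the discovery pipeline over a directory of gene families
#'
#' Expects one aligned-FASTA MSA per family under `msa_dir` (extension
#' `.afa`) with a same-named `.map` companion under `map_dir`, per-species
#' genome FASTAs, and optional per-species GTF / competing-prediction BED
#' tracks. Families are independent units of work and are processed in
#' sorted name order, so outputs do not depend on scheduling; a failure in
#' one family is logged and does not abort the run.
#'
#' Outputs under `out_dir`: one `<species>.bed` per target species with
#' predictions, `Hits-by-Pct-ID.tsv` ranking all predictions, a
#' `Results-by-Gene/` folder with per-family alignment renderings and the
#' collapsed C/Q data, `run_config.txt`, and `summary.txt` with per-stage
#' counts.
#'
#' @param msa_dir,map_dir input directories.
#' @param genome_paths named character vector, species -> genome FASTA.
#' @param gtf_paths optional named vector, species -> GTF.
#' @param competing_paths optional named list, species -> character vector
#'   of BED files.
#' @param out_dir output directory (created).
#' @param cfg a [scout_config()]. `cfg$threads` is recorded; families are
#'   currently processed sequentially, and results are identical for any
#'   thread setting.
#' @return invisibly, a list with `predictions`, `summary`, and the output
#'   paths.
#' @export
run_pipeline <- function(msa_dir, map_dir, genome_paths, gtf_paths = NULL,
                         competing_paths = NULL, out_dir,
                         cfg = scout_config()) {
  msa_files <- sort(list.files(msa_dir, pattern = "\\.afa$", full.names = TRUE))
  if (length(msa_files) == 0L)
    stop("no .afa gene-family alignments found under ", msa_dir, call. = FALSE)
  if (!is.na(cfg$seed)) set.seed(cfg$seed)
  genomes <- lapply(genome_paths, read_genome_fasta)
  tracks <- list()
  for (sp in names(genome_paths)) {
    gtf <- if (!is.null(gtf_paths) && sp %in% names(gtf_paths))
      gtf_paths[[sp]] else NULL
    beds <- if (!is.null(competing_paths) && sp %in% names(competing_paths))
      competing_paths[[sp]] else character()
    tracks[[sp]] <- read_cds_annotations(gtf, beds)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gene_dir <- file.path(out_dir, "Results-by-Gene")
  dir.create(gene_dir, showWarnings = FALSE)

  all_preds <- list()
  n_cand <- 0L; n_win <- 0L; n_fail <- 0L
  for (mf in msa_files) {
    gene <- tools::file_path_sans_ext(basename(mf))
    mp <- file.path(map_dir, paste0(gene, ".map"))
    res <- tryCatch({
      aln <- read_isoform_alignment(mf, mp, gene = gene)
      process_family(aln, genomes, tracks, cfg)
    }, error = function(e) {
      message("family '", gene, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    n_cand <- n_cand + res$n_candidates
    n_win <- n_win + res$n_windows
    write_gene_results(gene, res$aln, res$predictions, gene_dir)
    all_preds <- c(all_preds, res$predictions)
  }

  bed_paths <- character()
  for (sp in sort(names(genome_paths))) {
    sp_preds <- all_preds[vapply(all_preds, `[[`, "", "target_species") == sp]
    bp <- file.path(out_dir, paste0(sp, ".bed"))
    write_bed(sp_preds, sp, bp)
    bed_paths[sp] <- bp
  }
  hits_path <- file.path(out_dir, "Hits-by-Pct-ID.tsv")
  write_hits_report(all_preds, hits_path)

  cfg_lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", format(cfg[[k]])), "")
  writeLines(cfg_lines, file.path(out_dir, "run_config.txt"))

  novelty <- vapply(all_preds, `[[`, "", "novelty")
  summary <- c(families = length(msa_files), failed = n_fail,
               candidates = n_cand, windows = n_win,
               accepted = length(all_preds),
               entirely_novel = sum(novelty == "entirely_novel"))
  writeLines(paste(names(summary), summary, sep = "\t"),
             file.path(out_dir, "summary.txt"))
  invisible(list(predictions = all_preds, summary = summary,
                 bed_paths = bed_paths, hits_path = hits_path,
                 gene_dir = gene_dir))
}
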