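# Simulation experiments built on the synthetic family generator. These are
# the package's own validation studies: recovery of planted hidden exons and
# the centering of exon-divergence deltas under uniform mutation.

#' Planted hidden-exon recovery experiment
#'
#' Generates `n_families` synthetic families, each hiding one exon in one
#' species at the given planted identity with intact flanking exons, runs the
#' in-memory pipeline on each, and checks whether a prediction in the right
#' species overlaps the true planted interval.
#'
#' @param n_families number of families.
#' @param planted_identity percent identity of the hidden genomic copy to
#'   the query exons.
#' @param seed base RNG seed; family `i` uses `seed + i`.
#' @param cfg a [scout_config()].
#' @param pairwise_identity identity of non-reference species to the
#'   reference for all exons (100 = identical copies).
#' @param n_species,n_exons family shape.
#' @return data.frame, one row per family: `recovered`, `pred_identity`
#'   (best identity of the overlapping prediction, NA when missed),
#'   `delta_vs_gene_mean`, `n_predictions`.
#' @export
recovery_experiment <- function(n_families, planted_identity, seed,
                                cfg = scout_config(),
                                pairwise_identity = 100,
                                n_species = 3L, n_exons = 5L) {
  rows <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    # rotate the hiding species over the non-reference lineages: species 1 is
    # the ancestral reference, so hiding there would compound two independent
    # divergences between query and planted copy
    sp_hide <- 2L + (i %% (n_species - 1L))
    x_hide <- 2L + (i %% max(n_exons - 2L, 1L)) # interior exon: intact flanks
    spec <- family_spec(
      seed = seed + i, n_species = n_species, n_exons = n_exons,
      pairwise_identity = pairwise_identity,
      hidden_exons = list(list(species = sp_hide, exon = x_hide,
                               identity = planted_identity)))
    fam <- generate_family(spec)
    res <- process_family(fam$aln, fam$genomes, cfg = cfg)
    tr <- fam$truth[1L, ]
    hit <- NULL
    for (p in res$predictions) {
      if (p$target_species == tr$species && p$chrom == tr$chrom &&
          p$interval[1L] <= tr$end && p$interval[2L] >= tr$start) {
        if (is.null(hit) || p$pct_identity > hit$pct_identity) hit <- p
      }
    }
    rows[[i]] <- data.frame(
      family = spec$gene, seed = spec$seed,
      target_species = tr$species, planted_identity = planted_identity,
      recovered = !is.null(hit),
      pred_identity = if (is.null(hit)) NA_real_ else hit$pct_identity,
      delta_vs_gene_mean = if (is.null(hit)) NA_real_ else
        hit$deltas$delta_vs_gene_mean,
      n_predictions = length(res$predictions),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
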