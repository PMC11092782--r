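# deterministic codon-exact back-translation for constructing windows
simple_codons <- c(M = "ATG", K = "AAA", V = "GTT", L = "CTG", Q = "CAA",
                   R = "CGT", S = "TCT", A = "GCT", D = "GAT", E = "GAA",
                   W = "TGG", Y = "TAT", H = "CAC", I = "ATT", G = "GGT",
                   N = "AAT", T = "ACT", F = "TTT", P = "CCT", C = "TGT")
code_peptide <- function(pep) paste(simple_codons[strsplit(pep, "")[[1]]],
                                    collapse = "")

test_that("an exact embedded match is found as a seed in the right frame", {
  set.seed(21)
  pep <- "MKVLQRSADE"
  for (offset in 0:2) {
    window <- paste0(random_dna_str(90 + offset), code_peptide(pep),
                     random_dna_str(60))
    seeds <- seed_search(pep, window)
    expect_gte(length(seeds), 1L)
    expect_equal(seeds[[1]]$frame, (90 + offset) %% 3)
    expect_equal(seeds[[1]]$start, 90 + offset + 1)
    expect_equal(seeds[[1]]$end, 90 + offset + 3 * nchar(pep))
  }
})

test_that("two disjoint embedded copies give two non-overlapping seeds", {
  set.seed(22)
  pep <- "MKVLQRSADEWY"
  window <- paste0(random_dna_str(60), code_peptide(pep),
                   random_dna_str(300), code_peptide(pep),
                   random_dna_str(60))
  seeds <- seed_search(pep, window)
  expect_equal(length(seeds), 2L)
  iv <- t(vapply(seeds, function(s) c(s$start, s$end), c(0, 0)))
  iv <- iv[order(iv[, 1]), ]
  expect_lt(iv[1, 2], iv[2, 1])
})

test_that("random windows produce no seeds at the default threshold", {
  set.seed(23)
  n_false <- 0L
  for (i in 1:20) {
    pep <- random_peptide(20)
    window <- random_dna_str(4000)
    n_false <- n_false + length(seed_search(pep, window))
  }
  expect_equal(n_false, 0L)
})

test_that("realignment of a peptide against its own coding DNA is exact", {
  pep <- "MKVLQRSADEWYH"
  window <- paste0(strrep("T", 33), code_peptide(pep), strrep("C", 33))
  seeds <- seed_search(pep, window)
  a <- sw_align(pep, window, seeds[[1]])
  expect_equal(a$pct_identity, 100)
  expect_equal(a$query_coverage, 1.0)
  expect_equal(a$aligned_query, pep)
  expect_equal(a$aligned_target, pep)
  expect_equal(unname(a$genomic), c(34, 33 + 3 * nchar(pep)))
})

test_that("alignment scores match the independent oracle on a known case", {
  # MKVL vs coding sequence of MKIL under BLOSUM62, open 11, extend 1
  window <- code_peptide("MKIL")
  seed <- list(start = 1L, end = 12L, frame = 0L, score = 0L)
  a <- sw_align("MKVL", window, seed)
  expect_equal(a$score, ref_local_score("MKVL", "MKIL"))
  expect_equal(a$score, 17)  # 5 + 5 + 3 + 4
})

test_that("the reference DP oracle agrees with exhaustive enumeration at tiny sizes", {
  set.seed(24)
  for (i in 1:25) {
    a <- random_peptide(sample(2:5, 1))
    b <- random_peptide(sample(2:5, 1))
    expect_equal(ref_local_score(a, b), enum_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("kernel scores equal the reference DP on random peptide pairs", {
  set.seed(25)
  for (i in 1:50) {
    pep <- random_peptide(sample(4:12, 1))
    dna <- random_dna_str(3 * sample(6:20, 1))
    seed <- list(start = 1L, end = nchar(dna), frame = 0L, score = 0L)
    a <- sw_align(pep, dna, seed)
    tr <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
    expect_equal(a$score, ref_local_score(pep, tr), info = paste(pep, dna))
  }
})

test_that("a wrong-frame seed yields a low-scoring alignment rejected downstream", {
  pep <- "MKVLQRSADEWYH"
  window <- paste0(strrep("T", 33), code_peptide(pep), strrep("C", 34))
  good <- seed_search(pep, window)[[1]]
  bad <- list(start = good$start + 1L, end = good$end + 1L,
              frame = (good$frame + 1L) %% 3L, score = 0L)
  a <- sw_align(pep, window, bad)
  expect_lt(a$score, good$score)
  verdict <- accept_prediction(a)
  expect_false(verdict$accepted)
})

test_that("percent identity counts only gap-free columns", {
  expect_equal(percent_identity("ACDE", "ACDE"), 100.0)
  expect_equal(percent_identity("ACDE", "ACDK"), 75.0)
  expect_equal(percent_identity("AC-E", "ACDE"), 100.0)
  expect_equal(percent_identity("ACE", "ADE"), 100 * 2 / 3)
  und <- percent_identity("--", "AA")
  expect_equal(as.numeric(und), 0)
  expect_true(attr(und, "undefined"))
})

test_that("acceptance applies coverage then identity thresholds", {
  mk <- function(cov, id, score = 50) {
    structure(list(score = score, query_coverage = cov, pct_identity = id),
              class = "exon_alignment")
  }
  expect_true(accept_prediction(mk(1.0, 81.4))$accepted)
  expect_equal(accept_prediction(mk(0.5, 90))$reason, "coverage")
  expect_equal(accept_prediction(mk(0.95, 20))$reason, "identity")
  expect_equal(accept_prediction(mk(1.0, 90, score = 0))$reason, "score")
  cfg <- scout_config(min_coverage = 0.4, min_identity = 10)
  expect_true(accept_prediction(mk(0.5, 20), cfg)$accepted)
})

test_that("short windows return no seeds", {
  expect_message(seeds <- seed_search("MKVLQR", "ACGTACGTACGT"), "shorter")
  expect_equal(length(seeds), 0L)
})

test_that("the external tblastn backend honors the seed contract", {
  set.seed(26)
  pep <- "MKVLQRSADEWYHKNI"
  offset <- 61
  window <- paste0(random_dna_str(offset), code_peptide(pep),
                   random_dna_str(80))
  cfg <- scout_config(seed_backend = "tblastn")
  seeds <- seed_search(pep, window, cfg)
  expect_gte(length(seeds), 1L)
  s <- seeds[[1]]
  expect_equal(s$frame, offset %% 3)
  expect_lte(s$start, offset + 4)       # covers the embedding (edges may trim)
  expect_gte(s$end, offset + 3 * nchar(pep) - 3)
  a <- sw_align(pep, window, s, cfg = cfg)
  expect_equal(a$pct_identity, 100)
  expect_equal(a$query_coverage, 1.0)
})
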