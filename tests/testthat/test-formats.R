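test_that("genome FASTA reading and strand-aware fetch work", {
  fa <- tempfile(fileext = ".fa")
  seq60 <- paste0("AAAATGC", paste(rep("ACGT", 13), collapse = ""), "G")
  writeLines(c(">chr1 some description", seq60), fa)
  g <- read_genome_fasta(fa)
  expect_equal(chrom_names(g), "chr1")
  expect_equal(chrom_length(g, "chr1"), 60L)
  expect_equal(fetch_sequence(g, "chr1", 1, 60, "+"), seq60)
  # minus strand returns the reverse complement of the forward slice
  expect_equal(fetch_sequence(g, "chr1", 5, 7, "-"), "GCA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    fetch_sequence(g, "chr1", 10, 30, "+"))))
  expect_equal(fetch_sequence(g, "chr1", 10, 30, "-"), rc)
  expect_error(fetch_sequence(g, "chr1", 0, 10), "out of bounds")
  expect_error(fetch_sequence(g, "chr2", 1, 10), "unknown chromosome")
})

test_that("degenerate genome FASTA inputs raise typed errors", {
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_genome_fasta(empty), empty, fixed = TRUE)
  expect_error(read_genome_fasta(tempfile()), "not found")
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "TTTT"), dup)
  expect_error(read_genome_fasta(dup), "duplicate")
})

test_that("isoform alignment loads with coordinates and validates invariants", {
  msa <- tempfile(fileext = ".afa")
  map <- tempfile(fileext = ".map")
  writeLines(c(">isoA species=human chrom=chr1 strand=+ score=1", "MKVL"), msa)
  writeLines(c("isoA", "101,104,107,110"), map)
  aln <- read_isoform_alignment(msa, map, gene = "G1")
  expect_equal(dim(aln$M), c(1L, 4L))
  expect_equal(unname(aln$P[1, ]), c(101L, 104L, 107L, 110L))
  expect_true(all(diff(aln$P[1, ]) > 0))
  expect_equal(aln$rows$score, 1L)

  # a gap in one row must produce NA in P at that cell
  writeLines(c(">isoA species=human chrom=chr1 strand=+", "MKVL",
               ">isoB species=human chrom=chr1 strand=+", "MK-L"), msa)
  writeLines(c("isoA", "101,104,107,110", "isoB", "101,104,110"), map)
  aln2 <- read_isoform_alignment(msa, map)
  expect_true(is.na(aln2$P[2, 3]))
  expect_false(anyNA(aln2$P[1, ]))

  # non-monotone coordinates on the plus strand are rejected
  writeLines(c(">isoA species=human chrom=chr1 strand=+", "MKV"), msa)
  writeLines(c("isoA", "101,104,103"), map)
  expect_error(read_isoform_alignment(msa, map), "monotone")

  # ragged alignments are rejected
  writeLines(c(">isoA species=human chrom=chr1 strand=+", "MKVL",
               ">isoB species=human chrom=chr1 strand=+", "MKV"), msa)
  writeLines(c("isoA", "101,104,107,110", "isoB", "101,104,107"), map)
  expect_error(read_isoform_alignment(msa, map), "ragged")

  # coordinate count must equal residue count
  writeLines(c(">isoA species=human chrom=chr1 strand=+", "MKVL"), msa)
  writeLines(c("isoA", "101,104,107"), map)
  expect_error(read_isoform_alignment(msa, map), "coordinates")
})

test_that("isoform alignment round-trips through write/read exactly", {
  aln <- make_iso_aln(c("MKVL-Q", "M-VLKQ"),
                      list(c(101L, 104L, 107L, 110L, 116L),
                           c(101L, 107L, 110L, 113L, 116L)),
                      species = c("human", "mouse"),
                      scores = c(1L, NA))
  msa <- tempfile(fileext = ".afa"); map <- tempfile(fileext = ".map")
  write_isoform_alignment(aln, msa, map)
  back <- read_isoform_alignment(msa, map, gene = aln$gene)
  expect_identical(unname(back$M), unname(aln$M))
  expect_identical(unname(back$P), unname(aln$P))
  expect_identical(back$rows$species, aln$rows$species)
  expect_identical(back$rows$score, aln$rows$score)
  # ungapped rows reproduce the input isoform sequences
  expect_equal(paste(back$M[1, back$M[1, ] != "-"], collapse = ""), "MKVLQ")
})

test_that("GTF and BED tracks normalize to 1-based inclusive intervals", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\tCDS\t100\t200\t.\t+\t0\tgene_id \"g\";",
               "chr1\tsrc\texon\t300\t400\t.\t+\t0\tgene_id \"g\";"), gtf)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tname\t0\t+", bed)
  ann <- read_cds_annotations(gtf, bed)
  expect_equal(GenomicRanges::start(ann$gtf), 100L)
  expect_equal(GenomicRanges::end(ann$gtf), 200L)
  # BED 0-based half-open maps onto the same interval
  expect_equal(GenomicRanges::start(ann$competing), 100L)
  expect_equal(GenomicRanges::end(ann$competing), 200L)
})

test_that("BED to internal coordinate normalization is a bijection", {
  set.seed(11)
  start1 <- sample.int(10000, 50)
  end1 <- start1 + sample.int(500, 50)
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d", start1 - 1L, end1), bed)
  ann <- read_cds_annotations(NULL, bed)
  expect_equal(GenomicRanges::start(ann$competing), start1)
  expect_equal(GenomicRanges::end(ann$competing), end1)
})

test_that("malformed annotation lines are skipped and counted", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\tCDS\t100\t200\t.\t+\t0\tx",
               "garbage line without tabs",
               "chr1\tsrc\tCDS\tnotanumber\t300\t.\t+\t0\tx"), gtf)
  expect_message(ann <- read_cds_annotations(gtf), "skipped 2")
  expect_equal(length(ann$gtf), 1L)
  expect_equal(unname(ann$skipped[gtf]), 2L)

  only_exon <- tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\texon\t100\t200\t.\t+\t0\tx", only_exon)
  expect_warning(ann2 <- read_cds_annotations(only_exon), "no CDS")
  expect_equal(length(ann2$gtf), 0L)
})
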