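# shared toy all-exon alignment: 3 species, 3 blocks of 7 columns each;
# block 2 missing (all gaps) in selected species
toy_aea <- function(gap_species = "sp2", strands = rep("+", 3)) {
  pep <- c("MKVLQRS", "ADEWYRH", "GGILKNT")
  full <- paste(pep, collapse = "")
  gapped <- paste0(pep[1], strrep("-", 7), pep[3])
  rowstr <- ifelse(c("sp1", "sp2", "sp3") == gap_species, gapped, full)
  qrow <- function(strand, base) {
    q <- integer(21)
    mids <- function(start) seq(start, by = 3L, length.out = 7L)
    if (strand == "+") {
      q[1:7] <- mids(base + 1L)
      q[8:14] <- mids(base + 1001L)
      q[15:21] <- mids(base + 2001L)
    } else {
      q[1:7] <- rev(mids(base + 2001L))
      q[8:14] <- rev(mids(base + 1001L))
      q[15:21] <- rev(mids(base + 1L))
    }
    q
  }
  Q <- lapply(seq_len(3), function(i) {
    q <- qrow(strands[i], 100L * i)
    q[strsplit(rowstr[i], "")[[1]] == "-"] <- NA_integer_
    q
  })
  make_aea(rowstr, Q, species = c("sp1", "sp2", "sp3"), strands = strands,
           X = list(c(1L, 7L), c(8L, 14L), c(15L, 21L)))
}

test_that("fully populated alignments yield no candidates", {
  aea <- toy_aea(gap_species = "none")
  expect_equal(length(find_missing_exons(aea)), 0L)
})

test_that("a block gapped in one species yields one candidate with the other species as queries", {
  aea <- toy_aea("sp2")
  cands <- find_missing_exons(aea)
  expect_equal(length(cands), 1L)
  expect_equal(cands[[1]]$target_species, "sp2")
  expect_equal(unname(cands[[1]]$block), c(8L, 14L))
  expect_equal(length(cands[[1]]$queries), 2L)
  expect_equal(vapply(cands[[1]]$queries, `[[`, "", "source_species"),
               c("sp1", "sp3"))
  expect_equal(cands[[1]]$queries[[1]]$peptide, "ADEWYRH")
})

test_that("a block gapped in two species yields one candidate per gapped species", {
  aea <- toy_aea("sp2")
  aea$C["sp3", 8:14] <- "-"
  aea$Q["sp3", 8:14] <- NA_integer_
  cands <- find_missing_exons(aea)
  expect_equal(length(cands), 2L)
  expect_equal(sort(vapply(cands, `[[`, "", "target_species")),
               c("sp2", "sp3"))
  # both candidates quote the same remaining source exon
  expect_equal(cands[[1]]$queries[[1]]$peptide,
               cands[[2]]$queries[[1]]$peptide)
})

test_that("query peptides strip gaps and drop short source exons", {
  aea <- toy_aea("sp2")
  aea$C["sp1", 10] <- "-"; aea$Q["sp1", 10] <- NA_integer_
  cand <- find_missing_exons(aea)[[1]]
  q1 <- cand$queries[[which(vapply(cand$queries, `[[`, "", "source_species") == "sp1")]]
  expect_equal(q1$peptide, "ADWYRH")  # gap stripped, 6 aa kept
  # shrink sp1 support below 6 residues: dropped from the query list
  aea$C["sp1", 9:11] <- "-"; aea$Q["sp1", 9:11] <- NA_integer_
  cand2 <- find_missing_exons(aea)[[1]]
  expect_equal(vapply(cand2$queries, `[[`, "", "source_species"), "sp3")
})

test_that("search windows are bounded by the flanking codon coordinates", {
  aea <- toy_aea("sp2")
  cand <- find_missing_exons(aea)[[1]]
  w <- compute_search_window(aea, cand)
  # L = Q(k, b-1), R = Q(k, e+1) on the plus strand
  expect_equal(w$L, unname(aea$Q["sp2", 7]))
  expect_equal(w$R, unname(aea$Q["sp2", 15]))
  expect_equal(w$strand, "+")
})

test_that("one-sided windows fall back to a fixed pad", {
  aea <- toy_aea("sp2")
  cand <- find_missing_exons(aea)[[1]]
  # no upstream exon: L = R - 25000
  aea_up <- aea
  aea_up$C["sp2", 1:7] <- "-"; aea_up$Q["sp2", 1:7] <- NA_integer_
  w <- compute_search_window(aea_up, find_missing_exons(aea_up)[[1]])
  expect_equal(w$R, unname(aea_up$Q["sp2", 15]))
  expect_equal(w$L, max(1L, w$R - 25000L))
  # no downstream exon: R = L + 25000
  aea_dn <- aea
  aea_dn$C["sp2", 15:21] <- "-"; aea_dn$Q["sp2", 15:21] <- NA_integer_
  cands <- find_missing_exons(aea_dn)
  cand_dn <- cands[[which(vapply(cands, function(c) c$block_index, 0L) == 2L &
                          vapply(cands, `[[`, "", "target_species") == "sp2")]]
  w2 <- compute_search_window(aea_dn, cand_dn, window_pad = 25000L)
  expect_equal(w2$L, unname(aea_dn$Q["sp2", 7]))
  expect_equal(w2$R, w2$L + 25000L)
  # both flanks absent: candidate skipped with a message
  aea_no <- aea
  aea_no$C["sp2", ] <- "-"; aea_no$Q["sp2", ] <- NA_integer_
  cand_no <- find_missing_exons(aea_no)[[1]]
  expect_message(w3 <- compute_search_window(aea_no, cand_no), "skipped")
  expect_null(w3)
})

test_that("minus-strand flanks swap so that L < R on the reference", {
  aea <- toy_aea("sp2", strands = c("+", "-", "+"))
  cand <- find_missing_exons(aea)[[1]]
  w <- compute_search_window(aea, cand)
  up <- unname(aea$Q["sp2", 7])    # protein-upstream, genomically right
  dn <- unname(aea$Q["sp2", 15])   # protein-downstream, genomically left
  expect_true(up > dn)
  expect_equal(w$L, dn)
  expect_equal(w$R, up)
  expect_equal(w$strand, "-")
})

test_that("windows are clamped to chromosome bounds", {
  aea <- toy_aea("sp2")
  aea_up <- aea
  aea_up$C["sp2", 1:7] <- "-"; aea_up$Q["sp2", 1:7] <- NA_integer_
  cand <- find_missing_exons(aea_up)[[1]]
  w <- compute_search_window(aea_up, cand)  # R - 25000 < 1
  expect_equal(w$L, 1L)
  genome <- genome_from_sequences(c(chr1 = strrep("A", 2300)))
  aea_dn <- aea
  aea_dn$C["sp2", 15:21] <- "-"; aea_dn$Q["sp2", 15:21] <- NA_integer_
  cands <- find_missing_exons(aea_dn)
  cand_dn <- cands[[which(vapply(cands, function(c) c$block_index, 0L) == 2L)[1]]]
  w2 <- compute_search_window(aea_dn, cand_dn, genome = genome)
  expect_equal(w2$R, 2300L)
})
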