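# Independent oracles for local alignment scores.
#
# ref_local_score: a plain, loop-based Gotoh local aligner written separately
# from the package's kernel (different state layout, no traceback).
# enum_local_score: exhaustive enumeration over all monotone sets of aligned
# column pairs, scoring the forced gap runs between consecutive pairs; only
# feasible for tiny sequences, used to validate ref_local_score itself.

ref_local_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- exonscout:::blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  if (m == 0 || n == 0) return(0)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

enum_local_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- exonscout:::blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  best <- 0
  gap_cost <- function(k) if (k > 0) gap_open + gap_extend * k else 0
  # recursively extend a matching whose last pair is (i, j)
  extend <- function(i, j, score) {
    best <<- max(best, score)
    if (i < m && j < n) {
      for (i2 in (i + 1):m) for (j2 in (j + 1):n) {
        extend(i2, j2, score + S[av[i2], bv[j2]] -
                 gap_cost(i2 - i - 1) - gap_cost(j2 - j - 1))
      }
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n))
    extend(i, j, S[av[i], bv[j]])
  best
}

random_peptide <- function(n) paste(sample(exonscout:::AA20, n, TRUE),
                                    collapse = "")

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
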