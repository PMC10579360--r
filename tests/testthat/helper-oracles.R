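# Independent alignment oracles used to cross-check the Waterman-Eggert
# implementation. Both are deliberately naive and share no code with the
# package's aligner.

# Best ungapped local alignment score: enumerate every diagonal and take the
# maximum-sum contiguous segment (Kadane) of its column scores.
ungappedOracle <- function(a, b, mat = loadMatrix("BLOSUM62")) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  m <- length(ac); n <- length(bc)
  best <- 0
  for (d in (-(m - 1)):(n - 1)) {
    i <- max(1, 1 - d); j <- i + d
    run <- 0
    while (i <= m && j <= n) {
      run <- max(0, run + mat[ac[i], bc[j]])
      best <- max(best, run)
      i <- i + 1; j <- j + 1
    }
  }
  best
}

# Best local alignment score with at most one gap run, by enumerating every
# gap placement (which sequence, position, gap length) between a diagonal
# segment ending at (i, j) and one starting after the gap. E[i,j] / B[i,j]
# are the best non-empty diagonal segment sums ending / starting at (i, j).
oneGapOracle <- function(a, b, mat = loadMatrix("BLOSUM62"),
                         gapOpen = 14, gapExtend = 4) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  m <- length(ac); n <- length(bc)
  S <- matrix(0, m, n)
  for (i in seq_len(m)) S[i, ] <- mat[ac[i], bc]
  E <- matrix(-Inf, m, n)  # segment ends at (i, j)
  B <- matrix(-Inf, m, n)  # segment starts at (i, j)
  for (i in seq_len(m)) for (j in seq_len(n))
    E[i, j] <- S[i, j] + if (i > 1 && j > 1) max(0, E[i - 1, j - 1]) else 0
  for (i in rev(seq_len(m))) for (j in rev(seq_len(n)))
    B[i, j] <- S[i, j] + if (i < m && j < n) max(0, B[i + 1, j + 1]) else 0
  best <- max(0, max(E))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (E[i, j] == -Inf) next
    for (g in seq_len(max(m, n))) {
      cost <- gapOpen + (g - 1) * gapExtend
      # gap in query: target advances by g
      if (i < m && j + g < n)
        best <- max(best, E[i, j] + B[i + 1, j + g + 1] - cost)
      # gap in target: query advances by g
      if (i + g < m && j < n)
        best <- max(best, E[i, j] + B[i + g + 1, j + 1] - cost)
    }
  }
  best
}

# Established-library oracle: best local score from Biostrings at identical
# parameters. Biostrings charges gapOpening + L*gapExtension for a length-L
# gap, so gapOpening = gapOpen - gapExtend matches this package's
# gapOpen + (L-1)*gapExtend convention.
biostringsOracle <- function(a, b, gapOpen = 14, gapExtend = 4) {
  mat <- loadMatrix("BLOSUM62")[1:20, 1:20]
  max(0, Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gapOpen - gapExtend, gapExtension = gapExtend)))
}

randomPeptide <- function(n, alphabet = rownames(loadMatrix("BLOSUM62"))[1:20])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

bestScore <- function(a, b, ...) {
  alns <- watermanEggert(a, b, ...)
  if (length(alns)) alignmentScore(alns[[1]]) else 0
}
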