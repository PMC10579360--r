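# Six aligned pairs of the worked-example table; the cytochrome c1 row's
# printed identity (8) differs from its printed strings (7 equal columns),
# so the recomputed value is checked against the strings, not the print.
tab1 <- data.frame(
  human = c("PSRGKSSSYSKQF", "SETAPAAPAAAP", "AATASPPTPSAQAP",
            "REVENVAITALE", "LKVVGMFPSRGEKRA", "AANNGALPPDLSY"),
  mtg = c("PSRMKAVIYSKHF", "NESAPAASSAGP", "APAASSAGPSFRAP",
          "REVASVMNRALE", "LCTAGFMPSAGEAAA", "AADNGAGEETKSY"),
  identity = c(8L, 7L, 7L, 7L, 7L, 7L),
  similarity = c(9L, 10L, 8L, 8L, 7L, 8L))

test_that("alignmentStats reproduces the worked-example identity/similarity", {
  for (k in seq_len(nrow(tab1))) {
    st <- alignmentStats(tab1$human[k], tab1$mtg[k])
    expect_identical(st[["length"]], nchar(tab1$human[k]))
    expect_identical(st[["nIdentity"]], tab1$identity[k])
    expect_identical(st[["nSimilarity"]], tab1$similarity[k])
    expect_identical(st[["nGaps"]], 0L)
  }
})

test_that("alignmentStats on self-alignments and its error contract", {
  st <- alignmentStats("ACDEFGHIK", "ACDEFGHIK")
  expect_identical(st[["nIdentity"]], 9L)
  expect_identical(st[["nSimilarity"]], 9L)
  expect_error(alignmentStats("AC", "ACD"), "equal length")
  expect_error(alignmentStats("A-C", "A-C"), "gap-vs-gap")
})

test_that("watermanEggert recovers the fibrinogen pair ungapped", {
  alns <- watermanEggert("PSRGKSSSYSKQF", "PSRMKAVIYSKHF")
  expect_length(alns, 1L)
  a <- alns[[1]]
  expect_identical(alignmentLength(a), 13L)
  expect_identical(nIdentity(a), 8L)
  expect_identical(nGaps(a), 0L)
})

test_that("identical sequences align full-length with identity everywhere", {
  a <- watermanEggert("ACDEFGHIK", "ACDEFGHIK")[[1]]
  expect_identical(alignmentLength(a), 9L)
  expect_identical(nIdentity(a), 9L)
  expect_identical(nSimilarity(a), 9L)
  expect_identical(a@qStart, 1L)
  expect_identical(a@tEnd, 9L)
})

test_that("with prohibitive gap penalties the score is the best ungapped window", {
  set.seed(421)
  for (k in 1:50) {
    a <- randomPeptide(20)
    b <- randomPeptide(20)
    expect_equal(bestScore(a, b, gapOpen = 1000, gapExtend = 1000),
                 ungappedOracle(a, b))
  }
})

test_that("best local score matches the one-gap enumeration and Biostrings", {
  set.seed(17)
  reduced <- c("A", "C", "D", "E")
  for (k in 1:200) {
    a <- randomPeptide(sample(3:12, 1), reduced)
    b <- randomPeptide(sample(3:12, 1), reduced)
    s <- bestScore(a, b)
    expect_equal(s, oneGapOracle(a, b))
    expect_equal(s, biostringsOracle(a, b))
  }
})

test_that("reported score always equals its recomputation from the strings", {
  set.seed(99)
  for (k in 1:40) {
    a <- randomPeptide(sample(8:25, 1))
    b <- randomPeptide(sample(8:25, 1))
    alns <- watermanEggert(a, b, gapOpen = 12, gapExtend = 2,
                           nAlternatives = 2L)
    for (al in alns)
      expect_equal(alignmentScore(al),
                   recomputeScore(al@alignedQuery, al@alignedTarget,
                                  gapOpen = 12, gapExtend = 2))
  }
})

test_that("declumped alternatives share no aligned residue pair", {
  set.seed(7)
  a <- randomPeptide(30)
  b <- paste0(a, a)  # guarantees several strong local matches
  alns <- watermanEggert(a, b, nAlternatives = 4L)
  expect_gte(length(alns), 2L)
  pairKey <- function(al) {
    qc <- strsplit(al@alignedQuery, "")[[1]]
    tc <- strsplit(al@alignedTarget, "")[[1]]
    qi <- cumsum(qc != "-") + al@qStart - 1L
    ti <- cumsum(tc != "-") + al@tStart - 1L
    res <- qc != "-" & tc != "-"
    paste(qi[res], ti[res])
  }
  keys <- lapply(alns, pairKey)
  for (i in seq_along(keys)[-1]) {
    expect_length(intersect(keys[[i]], unlist(keys[seq_len(i - 1)])), 0L)
    expect_lte(alignmentScore(alns[[i]]), alignmentScore(alns[[i - 1]]))
  }
})

test_that("raising the gap-open penalty never increases the optimal score", {
  set.seed(5)
  for (k in 1:20) {
    a <- randomPeptide(18)
    b <- randomPeptide(18)
    s <- vapply(c(8, 12, 16, 24), function(go)
      bestScore(a, b, gapOpen = go, gapExtend = 4), numeric(1))
    expect_true(all(diff(s) <= 0))
  }
})

test_that("degapped aligned strings match the claimed coordinates", {
  set.seed(31)
  for (k in 1:20) {
    q <- randomPeptide(15)
    t <- randomPeptide(40)
    alns <- watermanEggert(q, t, gapOpen = 10, gapExtend = 1)
    for (al in alns) {
      expect_identical(gsub("-", "", al@alignedQuery),
                       substr(q, al@qStart, al@qEnd))
      expect_identical(gsub("-", "", al@alignedTarget),
                       substr(t, al@tStart, al@tEnd))
    }
  }
})

test_that("degenerate and invalid alignment inputs are rejected", {
  expect_error(watermanEggert("", "ACD"), "non-empty|nonempty|residues")
  expect_error(watermanEggert("ACD", "ACD", gapOpen = Inf), "finite")
  expect_error(watermanEggert("ACD", "ACD", gapOpen = 2, gapExtend = 4),
               "gapOpen >= gapExtend")
})

test_that("recomputeScore applies the affine gap formula", {
  expect_equal(recomputeScore("PSR", "PSR"), 16)   # 7 + 4 + 5
  # one length-2 gap: residue columns PP + WW, gap cost 14 + 4
  expect_equal(recomputeScore("P--W", "PAAW"),
               7 + 11 - 18)
  expect_equal(recomputeScore("", ""), 0)
})

test_that("ambiguous residue X scores zero and never counts as similar", {
  st <- alignmentStats("AXC", "AXC")
  expect_identical(st[["nIdentity"]], 3L)
  expect_identical(st[["nSimilarity"]], 2L)  # X-X scores 0, not similar
  expect_equal(recomputeScore("AXC", "AWC"), 4 + 0 + 9)
})
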