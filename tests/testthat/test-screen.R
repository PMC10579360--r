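# Minimal LocalAlignment with the given identity and column count, built
# from an ungapped self-alignment padded with mismatching residues.
mockAlignment <- function(nId, len) {
  idPart <- strrep("A", nId)
  q <- paste0(idPart, strrep("W", len - nId))
  t <- paste0(idPart, strrep("D", len - nId))
  st <- alignmentStats(q, t)
  new("LocalAlignment", queryId = "q", targetId = "t",
      alignedQuery = q, alignedTarget = t,
      qStart = 1L, qEnd = len, tStart = 1L, tEnd = len,
      score = max(0, recomputeScore(q, t)),
      length = st[["length"]], nIdentity = st[["nIdentity"]],
      nSimilarity = st[["nSimilarity"]], nGaps = st[["nGaps"]])
}

test_that("identity/length filter honours both cutoffs and both modes", {
  inclusive <- screenConfig()
  strict <- screenConfig(lengthStrict = TRUE)
  expect_true(applyIdentityLengthFilter(mockAlignment(7L, 13L), inclusive))
  expect_false(applyIdentityLengthFilter(mockAlignment(6L, 20L), inclusive))
  ln12 <- mockAlignment(7L, 12L)
  expect_true(applyIdentityLengthFilter(ln12, inclusive))
  expect_false(applyIdentityLengthFilter(ln12, strict))
})

test_that("screenEpitopes finds an exact substring epitope at full identity", {
  set.seed(2)
  target <- proteinSequence("T1", randomPeptide(120))
  ep <- data.frame(epitope_id = "SUB", sequence = substr(residues(target), 40, 54),
                   parent_antigen = "Antigen A", accession = "",
                   diseases = "RA", stringsAsFactors = FALSE)
  hits <- screenEpitopes(ep, target)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$n_identity, 15L)
  expect_identical(hits$t_start, 40L)
  expect_identical(hits$mtg_peptide, ep$sequence)
})

test_that("screenEpitopes on an empty catalog returns an empty hit table", {
  target <- proteinSequence("T1", "ACDEFGHIKLMNPQRSTVWY")
  hits <- screenEpitopes(data.frame(), target)
  expect_identical(nrow(hits), 0L)
  expect_identical(attr(hits, "nInput"), 0L)
})

test_that("hit ordering is deterministic: identity, then score, then id", {
  set.seed(3)
  target <- proteinSequence("T1", randomPeptide(200))
  win <- function(s, l) substr(residues(target), s, s + l - 1)
  ep <- data.frame(epitope_id = c("B", "A", "C"),
                   sequence = c(win(10, 13), win(60, 14), win(120, 13)),
                   parent_antigen = "X", accession = "", diseases = "RA",
                   stringsAsFactors = FALSE)
  hits <- screenEpitopes(ep, target)
  expect_identical(hits$epitope_id[1], "A")  # highest identity (14) first
  bc <- hits[hits$epitope_id != "A", ]       # tie at identity 13 ...
  expect_identical(bc$epitope_id, bc$epitope_id[order(-bc$score,
                                                      bc$epitope_id)])
  expect_identical(hits, screenEpitopes(ep, target))  # rerun-stable
})

bindingRows <- function(peptide, ic50I, ic50II = 5000) {
  data.frame(peptide = peptide,
             allele = c("HLA-A*02:01", "HLA-DRB1*04:01"),
             hla_class = c("I", "II"), ic50_nM = c(ic50I, ic50II),
             stringsAsFactors = FALSE)
}

test_that("immunogenicity filter keeps strong binders with best-record evidence", {
  hits <- data.frame(epitope_id = c("H1", "H2", "H3"),
                     mtg_peptide = c("AAA", "CCC", "GGG"),
                     stringsAsFactors = FALSE)
  binding <- rbind(bindingRows("AAA", 30),          # strong class I
                   bindingRows("CCC", 5000, 5000))  # weak everywhere
  expect_message(out <- immunogenicityFilter(hits, binding),
                 "no prediction")                   # GGG absent
  expect_identical(out$epitope_id, "H1")
  expect_identical(out$best_ic50_hla1, 30)
  expect_true(is.na(out$best_ic50_hla2))
  expect_true(all(out$immunogenic))
})

test_that("class II threshold applies independently of class I", {
  hits <- data.frame(epitope_id = "H1", mtg_peptide = "AAA",
                     stringsAsFactors = FALSE)
  out <- immunogenicityFilter(hits, bindingRows("AAA", 5000, 400))
  expect_identical(out$best_ic50_hla2, 400)
  expect_true(is.na(out$best_ic50_hla1))
})

test_that("an empty binding table empties the hit list with a warning", {
  hits <- data.frame(epitope_id = "H1", mtg_peptide = "AAA",
                     stringsAsFactors = FALSE)
  expect_warning(out <- immunogenicityFilter(hits, hits[0, ]),
                 "empty binding table")
  expect_identical(nrow(out), 0L)
})

test_that("reactive-antigen intersection matches by synonym and accession", {
  hits <- data.frame(epitope_id = c("H1", "H2", "H3"),
                     parent_antigen = c("Fibrinogen alpha chain",
                                        "Histone H1.2", "Unrelated"),
                     accession = c("", "P16403", ""),
                     stringsAsFactors = FALSE)
  out <- intersectWithReactive(hits, c("fibrinogen"))
  expect_identical(out$epitope_id, "H1")             # synonym-map match
  expect_true(all(out$cross_reactive))
  out2 <- intersectWithReactive(hits, c("P16403"))
  expect_identical(out2$epitope_id, "H2")            # accession match
  expect_identical(nrow(intersectWithReactive(hits, character())), 0L)
})

test_that("disease summary counts distinct antigens under every tag", {
  expect_identical(
    summarizeByDisease(table1Hits())[1:3, ],
    data.frame(disease = c("RA", "T1DM", "SS"), n_antigens = c(4L, 3L, 2L)))
  expect_identical(nrow(summarizeByDisease(table1Hits()[0, ])), 0L)
  two <- data.frame(parent_antigen = "A", diseases = "RA;SS",
                    stringsAsFactors = FALSE)
  s <- summarizeByDisease(two)
  expect_setequal(s$disease, c("RA", "SS"))
  expect_true(all(s$n_antigens == 1L))
})

test_that("each screening stage returns a subset of its input", {
  study <- genSyntheticStudy(syntheticSpec(seed = 4))
  hits <- screenEpitopes(study$epitopes, study$target)
  imm <- suppressMessages(immunogenicityFilter(hits, study$binding))
  fin <- intersectWithReactive(imm, study$reactiveAntigens)
  expect_true(all(imm$epitope_id %in% hits$epitope_id))
  expect_true(all(fin$epitope_id %in% imm$epitope_id))
})
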