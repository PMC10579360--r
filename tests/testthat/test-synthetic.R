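test_that("generators are deterministic under a seed and sensitive to it", {
  sp <- syntheticSpec(seed = 42)
  expect_identical(residues(genTargetProtein(sp)),
                   residues(genTargetProtein(sp)))
  expect_identical(genElisaPanel(sp), genElisaPanel(sp))
  expect_identical(genBackgroundEpitopes(sp), genBackgroundEpitopes(sp))
  differs <- vapply(1:10, function(k)
    residues(genTargetProtein(syntheticSpec(seed = k))) !=
      residues(genTargetProtein(syntheticSpec(seed = k + 1000))),
    logical(1))
  expect_true(all(differs))
})

test_that("the synthetic target has the configured length and alphabet", {
  tg <- genTargetProtein(syntheticSpec(seed = 1))
  expect_identical(nchar(residues(tg)), 331L)
  expect_true(validObject(tg))
  expect_error(genTargetProtein(syntheticSpec(seed = 1, targetLength = 10,
                                              plantedLength = 15)))
})

test_that("planted epitopes carry the constructed identity and similarity", {
  sp <- syntheticSpec(seed = 8)
  tg <- genTargetProtein(sp)
  pl <- plantEpitopes(tg, sp)
  expect_identical(nrow(pl), 5L)
  for (k in seq_len(nrow(pl))) {
    a <- strsplit(pl$sequence[k], "")[[1]]
    b <- strsplit(pl$source_peptide[k], "")[[1]]
    expect_identical(sum(a == b), 12L)           # length 15 - 3 mutations
    st <- alignmentStats(pl$sequence[k], pl$source_peptide[k])
    expect_identical(st[["nSimilarity"]], st[["nIdentity"]])  # non-positive subs
    expect_identical(substr(residues(tg), pl$start[k], pl$start[k] + 14L),
                     pl$source_peptide[k])
  }
})

test_that("zero mutations plant exact substrings", {
  sp <- syntheticSpec(seed = 8, plantedMutations = 0)
  pl <- plantEpitopes(genTargetProtein(sp), sp)
  expect_identical(pl$sequence, pl$source_peptide)
})

test_that("planted epitopes pass the identity/length filter with recall 1", {
  study <- genSyntheticStudy(syntheticSpec(seed = 12))
  hits <- screenEpitopes(study$epitopes, study$target)
  expect_true(all(sprintf("PLANTED-%02d", 1:5) %in% hits$epitope_id))
})

test_that("binding-table strong designation agrees with the filter outcome", {
  sp <- syntheticSpec(seed = 9)
  peps <- vapply(1:12, function(k) randomPeptide(15), character(1))
  tab <- genBindingTable(peps, sp)
  strong <- attr(tab, "strong")
  for (p in peps) {
    rec <- tab[tab$peptide == p, ]
    qualifies <- any((rec$hla_class == "I" & rec$ic50_nM <= 50) |
                     (rec$hla_class == "II" & rec$ic50_nM <= 500))
    expect_identical(qualifies, unname(strong[p]))
  }
  expect_true(all(tab$ic50_nM >= 2 & tab$ic50_nM <= 50000))
})

test_that("ELISA panel: duplicate variation bounded, background tail calibrated", {
  sp <- syntheticSpec(seed = 3)
  panel <- genElisaPanel(sp)
  expect_true(all(duplicateCvCheck(panel)$cv_percent < 7))
  # with no reactive antigens the fraction above mean + 2*SD is the normal
  # upper tail (~2.3%; slightly deflated by truncation at zero)
  big <- syntheticSpec(seed = 3, nAntigens = 10000L, nReactive = 0L)
  ods <- rowMeans(genElisaPanel(big)[c("od1", "od2")])
  frac <- mean(ods > big@bgOdMean + 2 * big@bgOdSd)
  expect_lt(abs(frac - pnorm(2, lower.tail = FALSE)), 0.007)
})

test_that("written study files round-trip through the package readers", {
  dir <- tempfile()
  study <- genSyntheticStudy(syntheticSpec(seed = 6), dir = dir)
  tg <- readFasta(study$files$target)[[1]]
  expect_identical(residues(tg), residues(study$target))
  ep <- readEpitopeTable(study$files$epitopes)
  expect_identical(nrow(ep), nrow(study$epitopes))
  expect_setequal(ep$sequence, study$epitopes$sequence)
  bind <- readBindingTable(study$files$binding)
  expect_identical(nrow(bind), nrow(study$binding))
  panel <- readElisaTable(study$files$elisa)
  expect_equal(panel$od1, study$panel$od1)
})

test_that("invalid synthetic specifications are rejected", {
  expect_error(syntheticSpec(plantedMutations = 15, plantedLength = 15),
               "plantedMutations")
  expect_error(syntheticSpec(nReactive = 100, nAntigens = 77), "nReactive")
  expect_error(syntheticSpec(bindingFractionStrong = 1.5), "bindingFraction")
})
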