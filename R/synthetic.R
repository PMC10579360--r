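#' @include screen.R elisa.R
NULL

# Background amino-acid frequencies (approximate vertebrate proteome
# composition, percent) used by all sequence generators.
AA_FREQS <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
              E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
              M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
              Y = 2.92, V = 6.87)

# A small fixed allele panel for generated binding tables.
HLA1_ALLELES <- c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02")
HLA2_ALLELES <- c("HLA-DRB1*04:01", "HLA-DQB1*03:01", "HLA-DRB1*15:01")

#' SyntheticSpec: parameters of a synthetic mimicry study
#'
#' Describes one synthetic dataset: a random target protein, an epitope
#' catalog of background epitopes plus planted mutated copies of target
#' segments, a binding-prediction table, and an ELISA panel with a dominant
#' near-background cluster and a set of elevated reactive antigens.
#' Defaults mirror the motivating study's dimensions: a 331-residue target,
#' a 77-antigen panel, background ODs around mean 0.16 / SD 0.12.
#'
#' @slot seed integer seed; every generator is deterministic given it.
#' @slot targetLength residues in the synthetic target (default 331).
#' @slot nBackground background epitopes with no planted similarity.
#' @slot backgroundLengthRange min/max background epitope length.
#' @slot nPlanted planted epitopes (mutated target segments).
#' @slot plantedLength length of each planted segment.
#' @slot plantedMutations substituted positions per planted epitope; the
#'   substitutes score non-positively against the original residue, so the
#'   planted identity is exactly \code{plantedLength - plantedMutations} and
#'   the similarity count is equally controlled.
#' @slot nAntigens ELISA panel size (default 77).
#' @slot nReactive antigens with elevated ODs.
#' @slot bgOdMean,bgOdSd background OD distribution (Normal, truncated at 0).
#' @slot reactiveOdShift OD elevation of reactive antigens.
#' @slot bindingFractionStrong share of planted target peptides forced to
#'   have a strong (below-threshold) binding record.
#' @seealso [syntheticSpec()], [genSyntheticStudy()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(seed = "integer", targetLength = "integer",
                        nBackground = "integer",
                        backgroundLengthRange = "integer",
                        nPlanted = "integer", plantedLength = "integer",
                        plantedMutations = "integer",
                        nAntigens = "integer", nReactive = "integer",
                        bgOdMean = "numeric", bgOdSd = "numeric",
                        reactiveOdShift = "numeric",
                        bindingFractionStrong = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@plantedMutations >= object@plantedLength)
    msg <- c(msg, "plantedMutations must be < plantedLength")
  if (object@plantedLength > object@targetLength)
    msg <- c(msg, "plantedLength must be <= targetLength")
  if (object@nReactive > object@nAntigens)
    msg <- c(msg, "nReactive must be <= nAntigens")
  if (any(c(object@nBackground, object@nPlanted, object@nAntigens,
            object@nReactive) < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (length(object@backgroundLengthRange) != 2L ||
      object@backgroundLengthRange[1] > object@backgroundLengthRange[2])
    msg <- c(msg, "backgroundLengthRange must be (min, max)")
  if (object@bindingFractionStrong < 0 || object@bindingFractionStrong > 1)
    msg <- c(msg, "bindingFractionStrong must be in [0, 1]")
  if (object@bgOdSd < 0 || object@bgOdMean < 0)
    msg <- c(msg, "background OD parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' @param seed integer seed.
#' @param targetLength,nBackground,backgroundLengthRange,nPlanted,plantedLength,plantedMutations
#'   sequence-side parameters; see [SyntheticSpec-class].
#' @param nAntigens,nReactive,bgOdMean,bgOdSd,reactiveOdShift ELISA-side
#'   parameters.
#' @param bindingFractionStrong share of planted peptides with a strong
#'   binding record.
#' @return A [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(seed = 1L, targetLength = 331L, nBackground = 200L,
                          backgroundLengthRange = c(10L, 15L),
                          nPlanted = 5L, plantedLength = 15L,
                          plantedMutations = 3L,
                          nAntigens = 77L, nReactive = 20L,
                          bgOdMean = 0.16, bgOdSd = 0.12,
                          reactiveOdShift = 0.60,
                          bindingFractionStrong = 0.6) {
  new("SyntheticSpec", seed = as.integer(seed),
      targetLength = as.integer(targetLength),
      nBackground = as.integer(nBackground),
      backgroundLengthRange = as.integer(backgroundLengthRange),
      nPlanted = as.integer(nPlanted),
      plantedLength = as.integer(plantedLength),
      plantedMutations = as.integer(plantedMutations),
      nAntigens = as.integer(nAntigens), nReactive = as.integer(nReactive),
      bgOdMean = as.numeric(bgOdMean), bgOdSd = as.numeric(bgOdSd),
      reactiveOdShift = as.numeric(reactiveOdShift),
      bindingFractionStrong = as.numeric(bindingFractionStrong))
}

.randomPeptide <- function(n) {
  paste(sample(names(AA_FREQS), n, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

#' Generate the synthetic target protein
#'
#' Residues drawn i.i.d. from a fixed background amino-acid frequency table;
#' deterministic given the spec's seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [ProteinSequence-class] with id \code{"SYN-TARGET"}.
#' @export
genTargetProtein <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@targetLength < spec@plantedLength)
    stop("targetLength must be >= plantedLength")
  res <- withSeed(spec@seed, .randomPeptide(spec@targetLength))
  proteinSequence("SYN-TARGET", res, "synthetic target protein")
}

#' Plant mutated target segments as ground-truth epitopes
#'
#' Each planted epitope is a contiguous substring of the target with exactly
#' \code{plantedMutations} interior positions substituted by residues whose
#' substitution score against the original is non-positive. By construction
#' the ungapped identity to the source window is exactly
#' \code{plantedLength - plantedMutations}, the similarity count equals the
#' identity count, and (because the window's first and last residues are
#' never mutated) the optimal local alignment spans the whole window, so the
#' degapped target-side peptide of the best alignment equals the recorded
#' \code{source_peptide}.
#'
#' @param target the [ProteinSequence-class] the segments are copied from.
#' @param spec a [SyntheticSpec-class].
#' @param matrix substitution matrix (used to pick non-positive substitutes).
#' @return Epitope data.frame with ground-truth columns \code{planted}
#'   (\code{TRUE}), \code{start} (window start on the target) and
#'   \code{source_peptide}.
#' @export
plantEpitopes <- function(target, spec, matrix = loadMatrix("BLOSUM62")) {
  stopifnot(is(target, "ProteinSequence"), is(spec, "SyntheticSpec"))
  L <- spec@plantedLength
  if (L > length(target)) stop("plantedLength exceeds target length")
  if (spec@nPlanted == 0L) return(.emptyEpitopes(planted = TRUE))
  withSeed(spec@seed + 1L, {
    starts <- sample(seq_len(length(target) - L + 1L), spec@nPlanted,
                     replace = spec@nPlanted > length(target) - L + 1L)
    rows <- lapply(seq_len(spec@nPlanted), function(k) {
      window <- substr(residues(target), starts[k], starts[k] + L - 1L)
      orig <- strsplit(window, "")[[1]]
      # Rejection-sample the mutation set until every proper prefix and
      # suffix of the window's column scores is strictly positive: then the
      # full window is the unique optimal ungapped local alignment (trimming
      # any edge run strictly lowers the score), so the best alignment's
      # degapped target side equals the recorded source window.
      repeat {
        chars <- orig
        mutPos <- sample(2:(L - 1L), spec@plantedMutations)
        for (p in mutPos) {
          cand <- AA_STANDARD[matrix[orig[p], AA_STANDARD] <= 0L]
          chars[p] <- sample(cand, 1L)
        }
        colScores <- matrix[cbind(chars, orig)]
        pre <- cumsum(colScores)
        suf <- rev(cumsum(rev(colScores)))
        if (all(pre[-L] > 0L) && all(suf[-1] > 0L)) break
      }
      data.frame(epitope_id = sprintf("PLANTED-%02d", k),
                 sequence = paste(chars, collapse = ""),
                 parent_antigen = sprintf("SYN-ANTIGEN-%02d", k),
                 accession = "",
                 diseases = paste(sample(DISEASE_VOCAB, 2L), collapse = ";"),
                 assay_classes = "T cell",
                 planted = TRUE, start = starts[k], source_peptide = window,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

.emptyEpitopes <- function(planted = FALSE) {
  data.frame(epitope_id = character(), sequence = character(),
             parent_antigen = character(), accession = character(),
             diseases = character(), assay_classes = character(),
             planted = logical(), start = integer(),
             source_peptide = character(), stringsAsFactors = FALSE)
}

#' Generate background epitopes with no planted similarity
#'
#' Sequences drawn i.i.d. from the background amino-acid frequencies with
#' lengths uniform in \code{backgroundLengthRange}; disease tags are decoys
#' sampled from the 10-tag vocabulary.
#'
#' @param spec a [SyntheticSpec-class].
#' @return Epitope data.frame (\code{planted = FALSE}).
#' @export
genBackgroundEpitopes <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@nBackground == 0L) return(.emptyEpitopes())
  withSeed(spec@seed + 2L, {
    lens <- sample(seq(spec@backgroundLengthRange[1],
                       spec@backgroundLengthRange[2]),
                   spec@nBackground, replace = TRUE)
    nAnt <- max(spec@nAntigens - spec@nPlanted, 1L)
    rows <- lapply(seq_len(spec@nBackground), function(k) {
      data.frame(epitope_id = sprintf("BG-%04d", k),
                 sequence = .randomPeptide(lens[k]),
                 parent_antigen = sprintf("SYN-ANTIGEN-%02d",
                                          spec@nPlanted +
                                            sample.int(nAnt, 1L)),
                 accession = "",
                 diseases = paste(sample(DISEASE_VOCAB, 2L), collapse = ";"),
                 assay_classes = sample(c("B cell", "T cell"), 1L),
                 planted = FALSE, start = NA_integer_,
                 source_peptide = NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate an HLA binding-prediction table
#'
#' Four records per peptide (two alleles per HLA class) with IC50 values
#' log-uniform in [2, 50000] nM. A \code{strong} designation per peptide
#' (by default a seeded draw at \code{bindingFractionStrong}) is then
#' enforced: strong peptides get their best class-I record placed below the
#' class-I threshold, non-strong peptides have any qualifying record moved
#' above both thresholds - so the designation and the filter outcome agree
#' by construction.
#'
#' @param peptides character vector of peptides to predict for.
#' @param spec a [SyntheticSpec-class].
#' @param strong optional logical vector (length of \code{peptides})
#'   overriding the seeded designation.
#' @param hla1Max,hla2Max thresholds used when forcing records (defaults
#'   match [screenConfig()]).
#' @return Binding-record data.frame; the designation is attached as
#'   \code{attr(,"strong")}.
#' @export
genBindingTable <- function(peptides, spec, strong = NULL,
                            hla1Max = 50, hla2Max = 500) {
  stopifnot(is(spec, "SyntheticSpec"))
  withSeed(spec@seed + 3L, {
    n <- length(peptides)
    if (is.null(strong))
      strong <- runif(n) < spec@bindingFractionStrong
    rows <- lapply(seq_len(n), function(k) {
      ic50 <- 10 ^ runif(4L, log10(2), log10(50000))
      if (strong[k]) {
        ic50[1] <- 10 ^ runif(1L, log10(2), log10(hla1Max))
      } else {
        low1 <- ic50[1:2] <= hla1Max
        low2 <- ic50[3:4] <= hla2Max
        if (any(low1))
          ic50[1:2][low1] <- 10 ^ runif(sum(low1), log10(hla1Max * 20),
                                        log10(50000))
        if (any(low2))
          ic50[3:4][low2] <- 10 ^ runif(sum(low2), log10(hla2Max * 2),
                                        log10(50000))
      }
      data.frame(peptide = peptides[k],
                 allele = c(sample(HLA1_ALLELES, 2L),
                            sample(HLA2_ALLELES, 2L)),
                 hla_class = c("I", "I", "II", "II"),
                 ic50_nM = round(ic50, 2), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "strong") <- setNames(strong, peptides)
    out
  })
}

#' Generate an ELISA panel
#'
#' Non-reactive antigens draw a true OD from Normal(\code{bgOdMean},
#' \code{bgOdSd}^2) truncated at 0; reactive antigens from the same
#' distribution shifted by \code{reactiveOdShift}. Duplicate wells jitter the
#' true OD symmetrically so their variation stays below 7\%.
#'
#' @param spec a [SyntheticSpec-class].
#' @param antigens optional antigen names (defaults to
#'   \code{SYN-ANTIGEN-01..nAntigens}).
#' @param reactiveAntigens optional names of the designated reactive
#'   antigens (defaults to a seeded sample of size \code{nReactive}).
#' @param antibody \code{"polyclonal"} or \code{"monoclonal"}.
#' @return ELISA data.frame (\code{antigen}, \code{antibody}, \code{od1},
#'   \code{od2}) with the designated reactive set in
#'   \code{attr(,"reactive")}.
#' @export
genElisaPanel <- function(spec, antigens = NULL, reactiveAntigens = NULL,
                          antibody = "polyclonal") {
  stopifnot(is(spec, "SyntheticSpec"))
  if (is.null(antigens))
    antigens <- sprintf("SYN-ANTIGEN-%02d", seq_len(spec@nAntigens))
  withSeed(spec@seed + 4L, {
    if (is.null(reactiveAntigens)) {
      if (spec@nReactive > length(antigens))
        stop("nReactive exceeds the number of antigens")
      reactiveAntigens <- sample(antigens, spec@nReactive)
    }
    truncNorm <- function(n, m, s) {
      x <- rnorm(n, m, s)
      while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), m, s)
      x
    }
    isRe <- antigens %in% reactiveAntigens
    true <- numeric(length(antigens))
    true[!isRe] <- truncNorm(sum(!isRe), spec@bgOdMean, spec@bgOdSd)
    true[isRe] <- truncNorm(sum(isRe), spec@bgOdMean + spec@reactiveOdShift,
                            spec@bgOdSd)
    u <- runif(length(antigens), 0, 0.034)  # duplicate CV = 200*u < 6.8%
    out <- data.frame(antigen = antigens, antibody = antibody,
                      od1 = round(true * (1 + u), 6),
                      od2 = round(true * (1 - u), 6),
                      stringsAsFactors = FALSE)
    attr(out, "reactive") <- reactiveAntigens
    out
  })
}

#' Generate a complete synthetic mimicry study
#'
#' Builds every pipeline input with consistent ground truth: the target
#' protein, an epitope catalog (planted + background), a binding table over
#' the planted source peptides plus decoy target windows, and an ELISA panel
#' whose designated reactive set contains \code{ceil(0.6 * nPlanted)} of the
#' planted antigens (the rest of \code{nReactive} are background antigens).
#' The triple-filter ground truth - planted epitopes whose source peptide is
#' strong-binding and whose parent antigen is designated reactive - is
#' returned, and the inputs are optionally written to \code{dir} (FASTA +
#' TSVs + a ready-to-run YAML pipeline config).
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir optional output directory (created if needed).
#' @return List with \code{target}, \code{epitopes}, \code{binding},
#'   \code{panel}, \code{reactiveAntigens} (designated), \code{groundTruth}
#'   (epitope ids expected to survive the full pipeline), \code{spec}, and
#'   (when written) \code{files}.
#' @export
genSyntheticStudy <- function(spec = syntheticSpec(), dir = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  target <- suppressMessages(genTargetProtein(spec))
  planted <- plantEpitopes(target, spec)
  background <- genBackgroundEpitopes(spec)
  epitopes <- rbind(planted, background)
  epitopes$outcome <- "Positive"

  nStrong <- min(ceiling(spec@bindingFractionStrong * spec@nPlanted),
                 spec@nPlanted)
  decoys <- withSeed(spec@seed + 5L, {
    starts <- sample(seq_len(max(length(target) - spec@plantedLength, 1L)),
                     20L, replace = TRUE)
    unique(vapply(starts, function(s)
      substr(residues(target), s, s + spec@plantedLength - 1L), character(1)))
  })
  decoys <- setdiff(decoys, planted$source_peptide)
  strongFlags <- withSeed(spec@seed + 6L, {
    idx <- if (nStrong > 0L) sample(seq_len(spec@nPlanted), nStrong)
           else integer(0)
    seq_len(spec@nPlanted) %in% idx
  })
  binding <- genBindingTable(c(planted$source_peptide, decoys), spec,
                             strong = c(strongFlags,
                                        rep(FALSE, length(decoys))))

  antigens <- sprintf("SYN-ANTIGEN-%02d", seq_len(spec@nAntigens))
  nPlantedReactive <- min(ceiling(0.6 * spec@nPlanted), spec@nReactive)
  reactive <- withSeed(spec@seed + 7L, {
    plantedRe <- sample(planted$parent_antigen, nPlantedReactive)
    others <- setdiff(antigens, planted$parent_antigen)
    c(plantedRe, sample(others, spec@nReactive - length(plantedRe)))
  })
  panel <- genElisaPanel(spec, antigens = antigens,
                         reactiveAntigens = reactive)

  truth <- planted$epitope_id[strongFlags &
                                planted$parent_antigen %in% reactive]
  out <- list(target = target, epitopes = epitopes, binding = binding,
              panel = panel, reactiveAntigens = reactive,
              groundTruth = sort(truth), spec = spec)
  if (!is.null(dir)) out$files <- .writeStudy(out, dir)
  out
}

.writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    target = file.path(dir, "target.fasta"),
    epitopes = file.path(dir, "epitopes.tsv"),
    binding = file.path(dir, "binding.tsv"),
    elisa = file.path(dir, "elisa.tsv"),
    config = file.path(dir, "config.yaml"))
  writeLines(c(paste0(">", seqId(study$target), " ",
                      study$target@name),
               residues(study$target)), files$target)
  write.table(study$epitopes, files$epitopes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$binding, files$binding, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$panel, files$elisa, sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(list(
    seed = study$spec@seed,
    target_fasta = normalizePath(files$target),
    epitope_table = normalizePath(files$epitopes),
    binding_table = normalizePath(files$binding),
    elisa_table = normalizePath(files$elisa),
    antibody = "polyclonal",
    screen = list(min_identity = 7L, min_length = 12L,
                  length_strict = FALSE, gap_open = 14, gap_extend = 4,
                  matrix = "BLOSUM62", n_alternatives = 1L,
                  hla1_ic50_max = 50, hla2_ic50_max = 500),
    elisa = list(cutoff_k = 1, trim_k = 2, max_cv_percent = 7)),
    files$config)
  files
}
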