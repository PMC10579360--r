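#' @include MimicryScan-package.R
NULL

# Amino-acid alphabet: the 20 standard residues plus the ambiguity code X.
# X is accepted everywhere but scores 0 against every residue in alignments.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

# Disease-tag vocabulary used by the screen's motivating study; shipped as a
# controlled vocabulary for the generators but not enforced on user tables.
DISEASE_VOCAB <- c("RA", "AS", "AIAS", "PA", "AIT", "SS", "PBC", "T1DM",
                   "MS", "AU")

#' ProteinSequence: an identified amino-acid sequence
#'
#' Minimal container for a protein: an accession-style identifier, a free-text
#' name, and an uppercase residue string over the 20 standard amino acids
#' (plus \code{X}, accepted but flagged at construction).
#'
#' @slot id single non-empty accession string.
#' @slot name free-text description (may be empty).
#' @slot residues uppercase residue string, alphabet \code{ACDEFGHIKLMNPQRSTVWYX}.
#' @seealso [proteinSequence()], [readFasta()]
#' @exportClass ProteinSequence
setClass("ProteinSequence",
         representation(id = "character", name = "character",
                        residues = "character"))

setValidity("ProteinSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@residues) != 1L || !nzchar(object@residues))
    msg <- c(msg, "'residues' must be a single non-empty string")
  else {
    bad <- setdiff(unique(strsplit(object@residues, "")[[1]]), AA_ALPHABET)
    if (length(bad))
      msg <- c(msg, sprintf("record '%s': illegal residue character(s): %s",
                            object@id, paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinSequence
#'
#' Residues are uppercased before validation; a message is emitted when the
#' ambiguity code \code{X} is present (it is kept, and scores 0 against every
#' residue during alignment).
#'
#' @param id accession string (e.g. \code{"P81453"}).
#' @param residues amino-acid string.
#' @param name optional free-text name.
#' @return A [ProteinSequence-class] object.
#' @examples
#' proteinSequence("P81453", "DSDDRVTPPAEPLDRMPDPYRPSYGRAETVVNNYIRKWQQVYSHRDGRKQQM")
#' @export
proteinSequence <- function(id, residues, name = "") {
  residues <- toupper(as.character(residues))
  obj <- new("ProteinSequence", id = as.character(id),
             name = as.character(name), residues = residues)
  if (grepl("X", residues, fixed = TRUE))
    message("sequence '", id, "' contains ambiguous residue(s) 'X' ",
            "(scored 0 against everything)")
  obj
}

#' @describeIn ProteinSequence-class sequence identifier
#' @param x,object a \code{ProteinSequence}
#' @export
seqId <- function(x) x@id

#' @describeIn ProteinSequence-class residue string
#' @export
residues <- function(x) x@residues

setMethod("show", "ProteinSequence", function(object) {
  n <- nchar(object@residues)
  head <- substr(object@residues, 1L, 40L)
  cat("ProteinSequence ", object@id,
      if (nzchar(object@name)) paste0(" (", object@name, ")"), "\n",
      "  ", n, " aa: ", head, if (n > 40L) "...", "\n", sep = "")
})

setMethod("length", "ProteinSequence", function(x) nchar(x@residues))

#' ScreenConfig: parameters of the mimicry screen
#'
#' Bundles every tunable of the screening chain: the alignment scoring scheme,
#' the identity/length mimicry cutoff, the HLA binding-affinity thresholds,
#' and the ELISA cutoff multiplier.
#'
#' @slot minIdentity minimum identical columns in the best local alignment
#'   (default 7).
#' @slot minLength minimum alignment length in columns (default 12).
#' @slot lengthStrict if \code{TRUE} the length cutoff is strict
#'   (\code{length > minLength}); the default \code{FALSE} uses
#'   \code{length >= minLength}. See the methods vignette for why inclusive is
#'   the default.
#' @slot gapOpen,gapExtend non-negative affine gap penalties; a gap run of
#'   length L costs \code{gapOpen + (L-1)*gapExtend}. Defaults 14 / 4.
#' @slot matrixName substitution matrix name (default \code{"BLOSUM62"}).
#' @slot nAlternatives number of declumped alignments to report per pair
#'   (default 1).
#' @slot hla1Ic50Max,hla2Ic50Max IC50 strong-binder thresholds in nM for HLA
#'   class I / class II (defaults 50 / 500).
#' @slot cutoffK multiplier on the background SD in the ELISA cutoff
#'   (default 1).
#' @slot trimK multiplier used while iteratively isolating the ELISA
#'   background cluster (default 2).
#' @slot seed integer seed propagated to stochastic helpers.
#' @seealso [screenConfig()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
         representation(minIdentity = "integer", minLength = "integer",
                        lengthStrict = "logical",
                        gapOpen = "numeric", gapExtend = "numeric",
                        matrixName = "character", nAlternatives = "integer",
                        hla1Ic50Max = "numeric", hla2Ic50Max = "numeric",
                        cutoffK = "numeric", trimK = "numeric",
                        seed = "integer"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@minIdentity < 1L) msg <- c(msg, "minIdentity must be >= 1")
  if (object@minLength < object@minIdentity)
    msg <- c(msg, "minLength must be >= minIdentity")
  if (!is.finite(object@gapOpen) || !is.finite(object@gapExtend))
    msg <- c(msg, "gap penalties must be finite")
  if (object@gapExtend < 0 || object@gapOpen < object@gapExtend)
    msg <- c(msg, "need gapOpen >= gapExtend >= 0")
  if (object@nAlternatives < 1L) msg <- c(msg, "nAlternatives must be >= 1")
  if (object@hla1Ic50Max <= 0 || object@hla2Ic50Max <= 0)
    msg <- c(msg, "IC50 thresholds must be positive")
  if (object@cutoffK <= 0) msg <- c(msg, "cutoffK must be positive")
  if (object@trimK <= 0) msg <- c(msg, "trimK must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenConfig
#'
#' Defaults encode the screen's published operating point: BLOSUM62 with gap
#' open 14 / extend 4 (the EMBOSS Matcher defaults for proteins), a cutoff of
#' at least 7 identical residues over at least 12 alignment columns, and
#' strong-binder IC50 thresholds of 50 nM (HLA-I) and 500 nM (HLA-II).
#'
#' @param minIdentity,minLength,lengthStrict identity/length cutoff; see
#'   [ScreenConfig-class].
#' @param gapOpen,gapExtend affine gap penalties.
#' @param matrixName substitution matrix name understood by [loadMatrix()].
#' @param nAlternatives declumped alignments per pair.
#' @param hla1Ic50Max,hla2Ic50Max strong-binder IC50 thresholds (nM).
#' @param cutoffK,trimK ELISA cutoff and background-trimming SD multipliers.
#' @param seed integer seed.
#' @return A [ScreenConfig-class] object.
#' @examples
#' cfg <- screenConfig()
#' cfg
#' @export
screenConfig <- function(minIdentity = 7L, minLength = 12L,
                         lengthStrict = FALSE,
                         gapOpen = 14, gapExtend = 4,
                         matrixName = "BLOSUM62", nAlternatives = 1L,
                         hla1Ic50Max = 50, hla2Ic50Max = 500,
                         cutoffK = 1, trimK = 2, seed = 1L) {
  new("ScreenConfig",
      minIdentity = as.integer(minIdentity),
      minLength = as.integer(minLength),
      lengthStrict = isTRUE(lengthStrict),
      gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
      matrixName = as.character(matrixName),
      nAlternatives = as.integer(nAlternatives),
      hla1Ic50Max = as.numeric(hla1Ic50Max),
      hla2Ic50Max = as.numeric(hla2Ic50Max),
      cutoffK = as.numeric(cutoffK), trimK = as.numeric(trimK),
      seed = as.integer(seed))
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n",
      "  identity/length cutoff : identity >= ", object@minIdentity,
      ", length ", if (object@lengthStrict) "> " else ">= ",
      object@minLength, "\n",
      "  alignment              : ", object@matrixName,
      ", gap open ", object@gapOpen, " / extend ", object@gapExtend,
      ", alternatives ", object@nAlternatives, "\n",
      "  strong binder (IC50)   : HLA-I <= ", object@hla1Ic50Max,
      " nM, HLA-II <= ", object@hla2Ic50Max, " nM\n",
      "  ELISA cutoff           : mean + ", object@cutoffK,
      "*SD (background trim at ", object@trimK, "*SD)\n", sep = "")
})

#' LocalAlignment: one gapped local alignment and its column statistics
#'
#' Stores the aligned strings (over the residue alphabet plus \code{"-"}),
#' the 1-based inclusive coordinates on the ungapped sequences (EMBOSS
#' dialect), the alignment score, and the column statistics used by the
#' mimicry cutoff: \code{length} (column count, the report's "Ln"),
#' \code{nIdentity} (equal-residue columns), \code{nSimilarity} (columns with
#' strictly positive substitution score; identities included), and
#' \code{nGaps} (columns with exactly one gap).
#'
#' @slot queryId,targetId sequence identifiers.
#' @slot alignedQuery,alignedTarget equal-length aligned strings.
#' @slot qStart,qEnd,tStart,tEnd 1-based inclusive ungapped coordinates.
#' @slot score alignment score (non-negative).
#' @slot length,nIdentity,nSimilarity,nGaps integer column statistics.
#' @seealso [watermanEggert()], [alignmentStats()]
#' @exportClass LocalAlignment
setClass("LocalAlignment",
         representation(queryId = "character", targetId = "character",
                        alignedQuery = "character",
                        alignedTarget = "character",
                        qStart = "integer", qEnd = "integer",
                        tStart = "integer", tEnd = "integer",
                        score = "numeric",
                        length = "integer", nIdentity = "integer",
                        nSimilarity = "integer", nGaps = "integer"))

setValidity("LocalAlignment", function(object) {
  msg <- character()
  qa <- object@alignedQuery
  ta <- object@alignedTarget
  if (nchar(qa) != nchar(ta))
    return("aligned strings must have equal length")
  if (nchar(qa) != object@length)
    msg <- c(msg, "'length' must equal the aligned string length")
  qc <- strsplit(qa, "")[[1]]
  tc <- strsplit(ta, "")[[1]]
  if (any(qc == "-" & tc == "-"))
    msg <- c(msg, "gap-vs-gap column")
  if (nchar(gsub("-", "", qa, fixed = TRUE)) !=
      object@qEnd - object@qStart + 1L)
    msg <- c(msg, "query coordinates inconsistent with degapped length")
  if (nchar(gsub("-", "", ta, fixed = TRUE)) !=
      object@tEnd - object@tStart + 1L)
    msg <- c(msg, "target coordinates inconsistent with degapped length")
  if (object@score < 0) msg <- c(msg, "score must be non-negative")
  if (object@nIdentity < 0L || object@nIdentity > object@nSimilarity ||
      object@nSimilarity > object@length)
    msg <- c(msg, "need 0 <= nIdentity <= nSimilarity <= length")
  if (length(msg)) msg else TRUE
})

#' @describeIn LocalAlignment-class alignment score
#' @param x a \code{LocalAlignment}
#' @export
alignmentScore <- function(x) x@score

#' @describeIn LocalAlignment-class column count ("Ln")
#' @export
alignmentLength <- function(x) x@length

#' @describeIn LocalAlignment-class identical columns
#' @export
nIdentity <- function(x) x@nIdentity

#' @describeIn LocalAlignment-class positively-scoring columns
#' @export
nSimilarity <- function(x) x@nSimilarity

#' @describeIn LocalAlignment-class single-gap columns
#' @export
nGaps <- function(x) x@nGaps

setMethod("show", "LocalAlignment", function(object) {
  qc <- strsplit(object@alignedQuery, "")[[1]]
  tc <- strsplit(object@alignedTarget, "")[[1]]
  mid <- ifelse(qc == tc & qc != "-", "|",
                ifelse(qc == "-" | tc == "-", " ", "."))
  cat("LocalAlignment (coordinates 1-based inclusive)\n",
      "  score ", object@score,
      ", Ln ", object@length,
      ", identity ", object@nIdentity, "/", object@length,
      ", similarity ", object@nSimilarity, "/", object@length,
      ", gaps ", object@nGaps, "\n",
      "  ", format(object@queryId, width = 10), " ",
      object@qStart, " ", object@alignedQuery, " ", object@qEnd, "\n",
      "  ", strrep(" ", 10), " ", strrep(" ", nchar(object@qStart)), " ",
      paste(mid, collapse = ""), "\n",
      "  ", format(object@targetId, width = 10), " ",
      object@tStart, " ", object@alignedTarget, " ", object@tEnd, "\n",
      sep = "")
})

#' PipelineReport: the end-to-end screening report
#'
#' Returned by [runPipeline()]. Holds the per-stage funnel counts, the final
#' hit table in the tabular report layout, the per-disease antigen summary,
#' the ELISA-derived (or user-supplied) reactive antigen list, and an echo of
#' the configuration for reproducibility.
#'
#' @slot stageCounts named integer vector of per-stage record counts, in
#'   execution order; non-increasing across filter stages.
#' @slot hits final hit table (one row per surviving epitope).
#' @slot diseaseSummary data.frame of disease tag vs distinct antigen count.
#' @slot reactiveAntigens character vector of reactive antigens used for the
#'   intersection stage.
#' @slot config configuration echo (named list).
#' @slot version package version string.
#' @exportClass PipelineReport
setClass("PipelineReport",
         representation(stageCounts = "integer", hits = "data.frame",
                        diseaseSummary = "data.frame",
                        reactiveAntigens = "character",
                        config = "list", version = "character"))

setValidity("PipelineReport", function(object) {
  cnt <- object@stageCounts
  if (length(cnt) && is.null(names(cnt)))
    return("stageCounts must be named")
  TRUE
})

#' @describeIn PipelineReport-class per-stage funnel counts
#' @param x,object a \code{PipelineReport}
#' @export
stageCounts <- function(x) x@stageCounts

#' @describeIn PipelineReport-class final hit table
#' @export
pipelineHits <- function(x) x@hits

#' @describeIn PipelineReport-class per-disease antigen counts
#' @export
diseaseSummary <- function(x) x@diseaseSummary

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport (MimicryScan ", object@version, ")\n", sep = "")
  cnt <- object@stageCounts
  for (i in seq_along(cnt))
    cat(sprintf("  %-28s %d\n", names(cnt)[i], cnt[i]))
  if (nrow(object@diseaseSummary)) {
    cat("  antigens per disease:\n")
    s <- object@diseaseSummary
    cat(paste0("    ", s$disease, ": ", s$n_antigens, collapse = "\n"), "\n")
  }
})
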