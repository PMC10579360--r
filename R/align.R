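#' @include AllClasses.R matrix.R
NULL

.asProtein <- function(x, fallbackId) {
  if (is(x, "ProteinSequence")) return(x)
  if (is.character(x) && length(x) == 1L) {
    id <- names(x)
    if (is.null(id) || !nzchar(id)) id <- fallbackId
    return(suppressMessages(proteinSequence(id, x)))
  }
  stop("expected a ProteinSequence or a single character string")
}

.splitChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Waterman-Eggert local alignment with declumped alternatives
#'
#' Aligns \code{query} against \code{target} with the Smith-Waterman /
#' Gotoh affine-gap recurrences and reports up to \code{nAlternatives}
#' non-overlapping local alignments in non-increasing score order
#' (Waterman-Eggert declumping: each reported alignment's residue pairs are
#' excluded before the matrix is re-filled, so the k-th alignment shares no
#' aligned residue pair with alignments 1..k-1).
#'
#' A maximal gap run of length L costs \code{gapOpen + (L-1)*gapExtend}.
#' Among equal-scoring alignments the one ending earliest in the target (then
#' in the query) is reported, and diagonal moves are preferred during
#' traceback, so output is deterministic. Coordinates are 1-based inclusive.
#'
#' @param query,target [ProteinSequence-class] objects (or plain residue
#'   strings, optionally named with an identifier).
#' @param matrix substitution matrix from [loadMatrix()].
#' @param gapOpen,gapExtend affine gap penalties, \code{gapOpen >= gapExtend
#'   >= 0}.
#' @param nAlternatives maximum number of declumped alignments (>= 1).
#' @return List of [LocalAlignment-class] objects; empty iff the best local
#'   score is 0.
#' @examples
#' aln <- watermanEggert("PSRGKSSSYSKQF", "PSRMKAVIYSKHF")[[1]]
#' nIdentity(aln)   # 8
#' @export
watermanEggert <- function(query, target, matrix = loadMatrix("BLOSUM62"),
                           gapOpen = 14, gapExtend = 4, nAlternatives = 1L) {
  query <- .asProtein(query, "query")
  target <- .asProtein(target, "target")
  if (!is.finite(gapOpen) || !is.finite(gapExtend))
    stop("gap penalties must be finite")
  if (gapExtend < 0 || gapOpen < gapExtend)
    stop("need gapOpen >= gapExtend >= 0")
  nAlternatives <- as.integer(nAlternatives)
  if (nAlternatives < 1L) stop("nAlternatives must be >= 1")

  qc <- .splitChars(residues(query))
  tc <- .splitChars(residues(target))
  qi <- match(qc, rownames(matrix)) - 1L
  ti <- match(tc, rownames(matrix)) - 1L
  raw <- we_align_cpp(qi, ti, matrix, gapOpen, gapExtend, nAlternatives)

  lapply(raw, function(a) {
    qa <- a$qa
    ta <- a$ta
    alignedQ <- paste(ifelse(qa > 0L, qc[pmax(qa, 1L)], "-"), collapse = "")
    alignedT <- paste(ifelse(ta > 0L, tc[pmax(ta, 1L)], "-"), collapse = "")
    st <- alignmentStats(alignedQ, alignedT, matrix)
    new("LocalAlignment",
        queryId = seqId(query), targetId = seqId(target),
        alignedQuery = alignedQ, alignedTarget = alignedT,
        qStart = min(qa[qa > 0L]), qEnd = max(qa),
        tStart = min(ta[ta > 0L]), tEnd = max(ta),
        score = a$score,
        length = st[["length"]], nIdentity = st[["nIdentity"]],
        nSimilarity = st[["nSimilarity"]], nGaps = st[["nGaps"]])
  })
}

#' Column statistics of an aligned pair
#'
#' Counts, over the columns of an aligned string pair: the alignment length
#' ("Ln"), the identical-residue columns, the similar columns (substitution
#' score strictly positive; identities always included because diagonal
#' BLOSUM62 entries are positive), and the columns with exactly one gap.
#'
#' @param alignedQuery,alignedTarget equal-length aligned strings over the
#'   residue alphabet plus \code{"-"}; no column may be gap-vs-gap.
#' @param matrix substitution matrix from [loadMatrix()].
#' @return Named integer vector with elements \code{length}, \code{nIdentity},
#'   \code{nSimilarity}, \code{nGaps}.
#' @examples
#' alignmentStats("SETAPAAPAAAP", "NESAPAASSAGP")  # identity 7, similarity 10
#' @export
alignmentStats <- function(alignedQuery, alignedTarget,
                           matrix = loadMatrix("BLOSUM62")) {
  qc <- .splitChars(alignedQuery)
  tc <- .splitChars(alignedTarget)
  if (length(qc) != length(tc))
    stop("aligned strings must have equal length")
  qgap <- qc == "-"
  tgap <- tc == "-"
  if (any(qgap & tgap)) stop("gap-vs-gap column at position ",
                             which(qgap & tgap)[1])
  res <- !qgap & !tgap
  sc <- integer(length(qc))
  sc[res] <- matrix[cbind(qc[res], tc[res])]
  c(length = length(qc),
    nIdentity = sum(res & qc == tc),
    nSimilarity = sum(res & sc > 0L),
    nGaps = sum(xor(qgap, tgap)))
}

#' Recompute the affine-gap score of an aligned pair
#'
#' Sums substitution scores over residue columns and subtracts
#' \code{gapOpen + (L-1)*gapExtend} for each maximal gap run of length L.
#' Used as the internal consistency check on alignments produced by
#' [watermanEggert()].
#'
#' @inheritParams alignmentStats
#' @param gapOpen,gapExtend affine gap penalties.
#' @return Numeric score; 0 for an empty alignment.
#' @examples
#' recomputeScore("PSR", "PSR")  # 7 + 4 + 5 = 16
#' @export
recomputeScore <- function(alignedQuery, alignedTarget,
                           matrix = loadMatrix("BLOSUM62"),
                           gapOpen = 14, gapExtend = 4) {
  if (!nzchar(alignedQuery) && !nzchar(alignedTarget)) return(0)
  qc <- .splitChars(alignedQuery)
  tc <- .splitChars(alignedTarget)
  if (length(qc) != length(tc))
    stop("aligned strings must have equal length")
  qgap <- qc == "-"
  tgap <- tc == "-"
  if (any(qgap & tgap)) stop("gap-vs-gap column")
  res <- !qgap & !tgap
  subSum <- sum(matrix[cbind(qc[res], tc[res])])
  gapCost <- 0
  runs <- rle(ifelse(qgap, "q", ifelse(tgap, "t", "r")))
  gapRuns <- runs$lengths[runs$values != "r"]
  if (length(gapRuns))
    gapCost <- sum(gapOpen + (gapRuns - 1) * gapExtend)
  subSum - gapCost
}
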