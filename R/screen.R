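#' @include align.R io.R
NULL

#' Identity/length mimicry cutoff
#'
#' The screen's core filter: an alignment is a mimicry candidate iff it has
#' at least \code{minIdentity} identical columns and its length (column
#' count, "Ln") meets the length cutoff. In the default inclusive mode the
#' length condition is \code{length >= minLength}; in strict mode it is
#' \code{length > minLength}. The worked-example table contains two
#' 12-column alignments although the stated rule reads "length > 12", so
#' both modes are exposed and inclusive is the default (see the methods
#' vignette).
#'
#' @param alignment a [LocalAlignment-class].
#' @param config a [ScreenConfig-class].
#' @return \code{TRUE} or \code{FALSE}.
#' @export
applyIdentityLengthFilter <- function(alignment, config = screenConfig()) {
  stopifnot(is(alignment, "LocalAlignment"), is(config, "ScreenConfig"))
  lenOk <- if (config@lengthStrict) alignment@length > config@minLength
           else alignment@length >= config@minLength
  alignment@nIdentity >= config@minIdentity && lenOk
}

#' Align an epitope catalog against the target and apply the mimicry cutoff
#'
#' Aligns every epitope to the target protein with [watermanEggert()] (only
#' the top declumped alignment per epitope is filtered) and keeps epitopes
#' whose best alignment passes [applyIdentityLengthFilter()]. Output order is
#' deterministic: descending identity, then descending score, then
#' epitope_id.
#'
#' @param epitopes epitope data.frame as returned by [readEpitopeTable()]
#'   (columns \code{epitope_id}, \code{sequence}, \code{parent_antigen},
#'   \code{accession}, \code{diseases}; extra columns are carried along).
#' @param target a [ProteinSequence-class].
#' @param config a [ScreenConfig-class].
#' @return Hit data.frame, one row per passing epitope, with the alignment
#'   statistics, coordinates, the degapped target-side peptide
#'   (\code{mtg_peptide}) used by the immunogenicity filter, and the
#'   [LocalAlignment-class] objects in the \code{alignment} list-column. The
#'   number of epitopes aligned is attached as \code{attr(,"nInput")}.
#' @export
screenEpitopes <- function(epitopes, target, config = screenConfig()) {
  stopifnot(is(target, "ProteinSequence"), is(config, "ScreenConfig"))
  mat <- loadMatrix(config@matrixName)
  empty <- data.frame(epitope_id = character(), parent_antigen = character(),
                      accession = character(), diseases = character(),
                      human_seq = character(), ln = integer(),
                      n_identity = integer(), n_similarity = integer(),
                      mtg_seq = character(), n_gaps = integer(),
                      score = numeric(), q_start = integer(),
                      q_end = integer(), t_start = integer(),
                      t_end = integer(), mtg_peptide = character(),
                      stringsAsFactors = FALSE)
  empty$alignment <- list()
  if (is.null(epitopes) || nrow(epitopes) == 0L) {
    attr(empty, "nInput") <- 0L
    return(empty)
  }
  rows <- vector("list", nrow(epitopes))
  for (k in seq_len(nrow(epitopes))) {
    alns <- watermanEggert(
      setNames(epitopes$sequence[k], epitopes$epitope_id[k]), target,
      matrix = mat, gapOpen = config@gapOpen, gapExtend = config@gapExtend,
      nAlternatives = config@nAlternatives)
    if (!length(alns)) next
    best <- alns[[1]]
    if (!applyIdentityLengthFilter(best, config)) next
    row <- data.frame(
      epitope_id = epitopes$epitope_id[k],
      parent_antigen = epitopes$parent_antigen[k],
      accession = if ("accession" %in% names(epitopes))
        epitopes$accession[k] else "",
      diseases = if ("diseases" %in% names(epitopes))
        epitopes$diseases[k] else "",
      human_seq = best@alignedQuery, ln = best@length,
      n_identity = best@nIdentity, n_similarity = best@nSimilarity,
      mtg_seq = best@alignedTarget, n_gaps = best@nGaps,
      score = best@score, q_start = best@qStart, q_end = best@qEnd,
      t_start = best@tStart, t_end = best@tEnd,
      mtg_peptide = gsub("-", "", best@alignedTarget, fixed = TRUE),
      stringsAsFactors = FALSE)
    row$alignment <- list(best)
    rows[[k]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  ord <- order(-out$n_identity, -out$score, out$epitope_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nInput") <- nrow(epitopes)
  out
}

#' Immunogenicity filter on precomputed HLA binding predictions
#'
#' A hit is retained iff its degapped target-side peptide has at least one
#' binding record at or below the strong-binder IC50 threshold of its HLA
#' class (\code{hla1Ic50Max} for class I, \code{hla2Ic50Max} for class II).
#' Retained hits carry the best (lowest-IC50) supporting record per class.
#' Peptides absent from the table cannot be assessed and are dropped with a
#' message; an empty binding table yields an empty result with a warning.
#'
#' @param hits hit data.frame from [screenEpitopes()].
#' @param bindingRecords data.frame from [readBindingTable()] or
#'   [genBindingTable()].
#' @param config a [ScreenConfig-class].
#' @return Subset of \code{hits} with added columns \code{immunogenic}
#'   (\code{TRUE}), \code{best_ic50_hla1}, \code{best_allele_hla1},
#'   \code{best_ic50_hla2}, \code{best_allele_hla2} (NA where the class has
#'   no qualifying record).
#' @export
immunogenicityFilter <- function(hits, bindingRecords,
                                 config = screenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  if (is.null(bindingRecords) || nrow(bindingRecords) == 0L) {
    warning("empty binding table: every hit dropped ",
            "(no immunogenicity evidence available)")
    return(hits[0, , drop = FALSE])
  }
  thr <- c(I = config@hla1Ic50Max, II = config@hla2Ic50Max)
  keep <- logical(nrow(hits))
  b1 <- b2 <- rep(NA_real_, nrow(hits))
  a1 <- a2 <- rep(NA_character_, nrow(hits))
  for (k in seq_len(nrow(hits))) {
    rec <- bindingRecords[bindingRecords$peptide == hits$mtg_peptide[k], ,
                          drop = FALSE]
    if (!nrow(rec)) {
      message("hit '", hits$epitope_id[k],
              "': no prediction for target peptide ", hits$mtg_peptide[k],
              " - dropped")
      next
    }
    ok <- rec$ic50_nM <= thr[rec$hla_class]
    if (!any(ok)) next
    keep[k] <- TRUE
    for (cls in c("I", "II")) {
      sub <- rec[rec$hla_class == cls & ok, , drop = FALSE]
      if (nrow(sub)) {
        i <- which.min(sub$ic50_nM)
        if (cls == "I") { b1[k] <- sub$ic50_nM[i]; a1[k] <- sub$allele[i] }
        else            { b2[k] <- sub$ic50_nM[i]; a2[k] <- sub$allele[i] }
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out$immunogenic <- rep(TRUE, nrow(out))
  out$best_ic50_hla1 <- b1[keep]
  out$best_allele_hla1 <- a1[keep]
  out$best_ic50_hla2 <- b2[keep]
  out$best_allele_hla2 <- a2[keep]
  rownames(out) <- NULL
  out
}

#' Intersect hits with the cross-reactive antigen set
#'
#' Keeps hits whose parent antigen is in the reactive set. Matching is by
#' accession when both sides carry one, otherwise by case-insensitive
#' canonical name through the synonym map ([loadSynonyms()]).
#'
#' @param hits hit data.frame.
#' @param reactiveAntigens character vector of reactive antigen names and/or
#'   accessions (e.g. from [analyzeReactivity()]).
#' @param synonyms synonym map from [loadSynonyms()].
#' @return Subset of \code{hits} with \code{cross_reactive = TRUE}.
#' @export
intersectWithReactive <- function(hits, reactiveAntigens,
                                  synonyms = loadSynonyms()) {
  if (!length(reactiveAntigens)) return(hits[0, , drop = FALSE])
  reCanon <- .canonicalAntigen(reactiveAntigens, synonyms)
  reLower <- tolower(trimws(reactiveAntigens))
  acc <- if ("accession" %in% names(hits)) tolower(trimws(hits$accession))
         else rep("", nrow(hits))
  keep <- (nzchar(acc) & acc %in% reLower) |
    .canonicalAntigen(hits$parent_antigen, synonyms) %in% reCanon
  out <- hits[keep, , drop = FALSE]
  out$cross_reactive <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Count distinct antigens per disease tag
#'
#' Splits each hit's \code{diseases} field (";" or "," separated) and counts
#' the distinct parent antigens under every tag; an antigen with several
#' disease tags is counted once under each.
#'
#' @param hits hit data.frame with \code{parent_antigen} and \code{diseases}.
#' @return data.frame with columns \code{disease} and \code{n_antigens},
#'   sorted by descending count then tag.
#' @examples
#' summarizeByDisease(table1Hits())   # RA 4, T1DM 3, SS 2, ...
#' @export
summarizeByDisease <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(disease = character(), n_antigens = integer(),
                      stringsAsFactors = FALSE))
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(hits)), function(k) {
    tags <- .splitTags(hits$diseases[k])
    if (!length(tags)) return(NULL)
    data.frame(disease = tags, antigen = hits$parent_antigen[k],
               stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(disease = character(), n_antigens = integer(),
                      stringsAsFactors = FALSE))
  tab <- as.data.frame(table(pairs$disease), stringsAsFactors = FALSE)
  names(tab) <- c("disease", "n_antigens")
  tab$n_antigens <- as.integer(tab$n_antigens)
  tab <- tab[order(-tab$n_antigens, tab$disease), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
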