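#' @include align.R screen.R
NULL

#' The six published aligned pairs (worked-example fixture)
#'
#' \code{table1Pairs()} returns the six aligned human/target sequence pairs
#' of the motivating study's similarity table, with their printed length
#' ("Ln"), identity and similarity numerators, parent antigens, UniProt
#' accessions, and disease annotations. \code{table1Hits()} recomputes the
#' column statistics of every pair with [alignmentStats()] and returns them
#' as a hit data.frame usable with [summarizeByDisease()] and
#' [writeHitsReport()].
#'
#' Note: the cytochrome c1 row prints identity 8/13, but position-by-position
#' comparison of its printed strings yields 7 equal columns (the similarity
#' 8/13 does check out); the printed value is kept verbatim in
#' \code{table1Pairs()} and the recomputed one appears in
#' \code{table1Hits()}.
#'
#' @return data.frames; see above.
#' @examples
#' table1Pairs()[1, c("human", "identity", "similarity")]
#' summarizeByDisease(table1Hits())
#' @export
table1Pairs <- function() {
  .readTable(system.file("extdata", "table1_pairs.tsv",
                         package = "MimicryScan"))
}

#' @rdname table1Pairs
#' @export
table1Hits <- function() {
  tab <- table1Pairs()
  mat <- loadMatrix("BLOSUM62")
  rows <- lapply(seq_len(nrow(tab)), function(k) {
    st <- alignmentStats(tab$human[k], tab$mtg[k], mat)
    data.frame(epitope_id = sprintf("TAB1-%02d", k),
               parent_antigen = tab$antigen[k],
               accession = tab$accession[k],
               diseases = tab$diseases[k],
               human_seq = tab$human[k],
               ln = st[["length"]],
               n_identity = st[["nIdentity"]],
               n_similarity = st[["nSimilarity"]],
               mtg_seq = tab$mtg[k],
               n_gaps = st[["nGaps"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
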