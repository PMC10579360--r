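#' @include AllClasses.R
NULL

# Delimiter by extension: .csv is comma, everything else tab.
.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, sep = .sepFor(path), header = TRUE,
             stringsAsFactors = FALSE, quote = "", comment.char = "#",
             check.names = FALSE, fileEncoding = "UTF-8")
}

# Coerce a column to numeric; report the 1-based file line (header = line 1)
# of the first malformed cell.
.numericColumn <- function(x, column) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop("column '", column, "': malformed numeric value '", x[bad[1]],
         "' at line ", bad[1] + 1L)
  v
}

.checkResidues <- function(seqs, what, ids) {
  chars <- strsplit(toupper(seqs), "")
  for (k in seq_along(chars)) {
    bad <- setdiff(unique(chars[[k]]), AA_ALPHABET)
    if (length(bad))
      stop(what, " '", ids[k], "': illegal residue character(s): ",
           paste(bad, collapse = ", "))
  }
  toupper(seqs)
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file via \pkg{Biostrings} and validates every record against
#' the package's amino-acid alphabet. The record identifier is the first
#' whitespace-delimited token of the header; the remainder becomes the name.
#'
#' @param path FASTA file.
#' @return List of [ProteinSequence-class] objects, in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  nm <- trimws(sub("^\\S+\\s*", "", headers))
  seqs <- as.character(set)
  lapply(seq_along(set), function(k) {
    bad <- setdiff(unique(strsplit(toupper(seqs[k]), "")[[1]]), AA_ALPHABET)
    if (length(bad))
      stop("FASTA record '", ids[k], "': illegal residue character(s): ",
           paste(bad, collapse = ", "))
    suppressMessages(proteinSequence(ids[k], seqs[k], nm[k]))
  })
}

#' Default epitope-table column mapping
#'
#' Export dialects for epitope catalogs vary; the mapping decouples the
#' reader from any one dialect. Values name the columns of the file; the
#' \code{epitope_id}, \code{accession} and \code{assay_classes} entries are
#' optional (filled with defaults when the named column is absent).
#'
#' @return Named list of column names.
#' @export
epitopeColumnMap <- function() {
  list(epitope_id = "epitope_id", sequence = "sequence",
       parent_antigen = "parent_antigen", accession = "accession",
       diseases = "diseases", assay_classes = "assay_classes",
       outcome = "outcome")
}

.splitTags <- function(x) {
  tags <- toupper(trimws(unlist(strsplit(x, "[;,]"))))
  unique(tags[nzchar(tags)])
}

#' Read an epitope catalog
#'
#' Reads a delimited epitope table (TSV, or CSV by extension), keeps only
#' positive-outcome rows, and collapses duplicate (sequence, parent antigen)
#' rows, merging their disease tags and assay classes. Disease tags are
#' normalized to upper case.
#'
#' @param path delimited table with a header row.
#' @param columnMap column mapping, see [epitopeColumnMap()].
#' @return data.frame with columns \code{epitope_id}, \code{sequence},
#'   \code{parent_antigen}, \code{accession}, \code{diseases} (";"-joined),
#'   \code{assay_classes} (";"-joined). Never contains a non-positive-outcome
#'   epitope.
#' @export
readEpitopeTable <- function(path, columnMap = epitopeColumnMap()) {
  tab <- .readTable(path)
  need <- c("sequence", "parent_antigen", "outcome")
  for (f in need) {
    col <- columnMap[[f]]
    if (is.null(col) || !(col %in% names(tab)))
      stop("epitope table is missing mapped column '", f,
           "' (expected file column '", columnMap[[f]] %||% "?", "')")
  }
  get <- function(f, default = "") {
    col <- columnMap[[f]]
    if (!is.null(col) && col %in% names(tab)) {
      v <- as.character(tab[[col]])
      v[is.na(v)] <- default
      v
    } else rep(default, nrow(tab))
  }
  seqs <- trimws(get("sequence"))
  if (any(!nzchar(seqs)))
    stop("empty sequence cell at line ", which(!nzchar(seqs))[1] + 1L)
  outcome <- tolower(trimws(get("outcome")))
  pos <- outcome %in% c("positive", "pos", "true", "t", "1", "yes")
  df <- data.frame(
    epitope_id = get("epitope_id"),
    sequence = .checkResidues(seqs, "epitope",
                              ifelse(nzchar(get("epitope_id")),
                                     get("epitope_id"), seqs)),
    parent_antigen = trimws(get("parent_antigen")),
    accession = trimws(get("accession")),
    diseases = get("diseases"),
    assay_classes = get("assay_classes"),
    stringsAsFactors = FALSE)[pos, , drop = FALSE]
  if (!nrow(df)) {
    df$diseases <- character(0)
    return(df)
  }
  key <- paste(df$sequence, df$parent_antigen, sep = "\r")
  merged <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                   function(idx) {
    first <- idx[1]
    data.frame(
      epitope_id = if (nzchar(df$epitope_id[first])) df$epitope_id[first]
                   else paste0("EPI-", sprintf("%05d", first)),
      sequence = df$sequence[first],
      parent_antigen = df$parent_antigen[first],
      accession = df$accession[first],
      diseases = paste(.splitTags(df$diseases[idx]), collapse = ";"),
      assay_classes = paste(unique(trimws(unlist(
        strsplit(df$assay_classes[idx], "[;,]")))), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an HLA binding-prediction table
#'
#' Reads precomputed peptide/HLA IC50 predictions. Required columns:
#' \code{peptide}, \code{allele}, \code{hla_class} (\code{"I"} or
#' \code{"II"}), \code{ic50_nM}; optional \code{percentile_rank}.
#'
#' @param path delimited table with a header row.
#' @return data.frame of binding records with positive \code{ic50_nM}.
#' @export
readBindingTable <- function(path) {
  tab <- .readTable(path)
  need <- c("peptide", "allele", "hla_class", "ic50_nM")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("binding table is missing column(s): ", paste(miss, collapse = ", "))
  ic50 <- .numericColumn(as.character(tab$ic50_nM), "ic50_nM")
  if (any(is.na(ic50) | ic50 <= 0))
    stop("ic50_nM must be positive at line ",
         which(is.na(ic50) | ic50 <= 0)[1] + 1L)
  cls <- toupper(trimws(as.character(tab$hla_class)))
  if (!all(cls %in% c("I", "II")))
    stop("hla_class must be 'I' or 'II' at line ",
         which(!cls %in% c("I", "II"))[1] + 1L)
  out <- data.frame(peptide = .checkResidues(trimws(as.character(tab$peptide)),
                                             "binding peptide",
                                             as.character(tab$peptide)),
                    allele = as.character(tab$allele),
                    hla_class = cls, ic50_nM = ic50,
                    stringsAsFactors = FALSE)
  if ("percentile_rank" %in% names(tab))
    out$percentile_rank <- .numericColumn(as.character(tab$percentile_rank),
                                          "percentile_rank")
  out
}

#' Read an ELISA optical-density table
#'
#' Required columns: \code{antigen}, \code{antibody} (\code{polyclonal} or
#' \code{monoclonal}) and at least one OD column named \code{od1},
#' \code{od2}, ... All ODs must be non-negative numbers; malformed cells are
#' reported with their line number.
#'
#' @param path delimited table with a header row.
#' @return data.frame with \code{antigen}, \code{antibody} and the OD
#'   columns.
#' @export
readElisaTable <- function(path) {
  tab <- .readTable(path)
  miss <- setdiff(c("antigen", "antibody"), names(tab))
  if (length(miss))
    stop("ELISA table is missing column(s): ", paste(miss, collapse = ", "))
  odCols <- grep("^od[0-9]*$", names(tab), value = TRUE)
  if (!length(odCols)) stop("ELISA table has no OD column (od1, od2, ...)")
  for (cn in odCols) {
    v <- .numericColumn(as.character(tab[[cn]]), cn)
    if (any(v < 0, na.rm = TRUE))
      stop("negative OD in column '", cn, "' at line ",
           which(v < 0)[1] + 1L)
    tab[[cn]] <- v
  }
  ab <- tolower(trimws(as.character(tab$antibody)))
  if (!all(ab %in% c("polyclonal", "monoclonal")))
    stop("antibody must be 'polyclonal' or 'monoclonal' at line ",
         which(!ab %in% c("polyclonal", "monoclonal"))[1] + 1L)
  tab$antibody <- ab
  tab$antigen <- trimws(as.character(tab$antigen))
  tab[c("antigen", "antibody", odCols)]
}

# Columns of the tabular hit report, in the layout of the worked-example
# table: human aligned sequence, Ln, identity, similarity, target aligned
# sequence, then provenance.
.hitReportCols <- c("epitope_id", "parent_antigen", "accession", "diseases",
                    "human_seq", "ln", "n_identity", "n_similarity",
                    "mtg_seq", "n_gaps", "score",
                    "q_start", "q_end", "t_start", "t_end")

#' Write / read the tabular hit report
#'
#' \code{writeHitsReport} writes one row per hit in the report layout (human
#' aligned sequence, Ln, identity and similarity numerators, target aligned
#' sequence, disease tags, coordinates); \code{readHitsReport} reads it back
#' identically. An empty hit set yields a header-only file. Coordinates are
#' 1-based inclusive, as stated in the report header comment.
#'
#' @param hits hit data.frame as produced by [screenEpitopes()] (extra
#'   columns beyond the report layout are preserved).
#' @param path output TSV path.
#' @return \code{writeHitsReport} returns \code{path} invisibly;
#'   \code{readHitsReport} returns the hit data.frame.
#' @export
writeHitsReport <- function(hits, path) {
  keep <- c(intersect(.hitReportCols, names(hits)),
            setdiff(names(hits), c(.hitReportCols, "alignment")))
  df <- hits[, keep, drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# MimicryScan hit report; coordinates 1-based inclusive", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHitsReport
#' @export
readHitsReport <- function(path) .readTable(path)

#' Antigen synonym map
#'
#' Loads the bundled (or a user-supplied) antigen synonym table mapping
#' common aliases to a canonical lower-case antigen name, used when
#' intersecting screen hits with reactive-antigen lists whose naming differs
#' from the epitope catalog's. Matching is case-insensitive; accessions
#' always take precedence over names.
#'
#' @param path optional two-column TSV (\code{alias}, \code{canonical});
#'   defaults to the bundled map.
#' @return Named character vector: \code{alias -> canonical}, lower case.
#' @export
loadSynonyms <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "antigen_synonyms.tsv",
                        package = "MimicryScan")
  tab <- .readTable(path)
  setNames(tolower(trimws(tab$canonical)), tolower(trimws(tab$alias)))
}

# Map antigen names to canonical form through the synonym table.
.canonicalAntigen <- function(x, synonyms) {
  key <- tolower(trimws(x))
  hit <- synonyms[key]
  ifelse(is.na(hit), key, unname(hit))
}
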