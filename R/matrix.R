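#' @include AllClasses.R
NULL

.matrixCache <- new.env(parent = emptyenv())

#' Load a bundled substitution matrix
#'
#' Parses a plain-text substitution matrix in the NCBI/EMBOSS layout (a
#' \code{#}-commented header, a column-label row, then one labelled row per
#' residue) and returns the integer scoring matrix restricted to the 20
#' standard amino acids, with an extra \code{X} row/column scoring 0 against
#' everything (the package's convention for ambiguous residues). BLOSUM62 is
#' bundled.
#'
#' @param name matrix name (default \code{"BLOSUM62"}); either a bundled
#'   matrix or a path to a matrix file in the same format.
#' @return Symmetric integer matrix with residue dimnames and a
#'   \code{"name"} attribute.
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' m["A", "S"]   # 1
#' m["W", "W"]   # 11
#' @export
loadMatrix <- function(name = "BLOSUM62") {
  key <- name
  if (!is.null(.matrixCache[[key]])) return(.matrixCache[[key]])
  path <- if (file.exists(name)) name else
    system.file("extdata", name, package = "MimicryScan")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown substitution matrix: '", name, "'")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- read.table(text = lines[-1], row.names = 1,
                     col.names = c("aa", cols), check.names = FALSE)
  m <- as.matrix(body)
  colnames(m) <- cols
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("matrix '", name, "' is not symmetric")
  keep <- intersect(rownames(m), AA_STANDARD)
  if (length(keep) != 20L)
    stop("matrix '", name, "' does not cover the 20 standard residues")
  m <- m[AA_STANDARD, AA_STANDARD]
  m <- rbind(cbind(m, X = 0L), X = 0L)
  storage.mode(m) <- "integer"
  attr(m, "name") <- basename(name)
  .matrixCache[[key]] <- m
  m
}
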