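#' @include screen.R elisa.R synthetic.R
NULL

.configDefaults <- function() {
  list(seed = 1L, antibody = "polyclonal",
       screen = list(min_identity = 7L, min_length = 12L,
                     length_strict = FALSE, gap_open = 14, gap_extend = 4,
                     matrix = "BLOSUM62", n_alternatives = 1L,
                     hla1_ic50_max = 50, hla2_ic50_max = 500),
       elisa = list(cutoff_k = 1, trim_k = 2, max_cv_percent = 7))
}

.mergeConfig <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      user[[nm]] <- .mergeConfig(user[[nm]], defaults[[nm]])
  }
  user
}

.screenConfigFrom <- function(cfg) {
  s <- cfg$screen
  screenConfig(minIdentity = s$min_identity, minLength = s$min_length,
               lengthStrict = isTRUE(s$length_strict),
               gapOpen = s$gap_open, gapExtend = s$gap_extend,
               matrixName = s$matrix, nAlternatives = s$n_alternatives,
               hla1Ic50Max = s$hla1_ic50_max, hla2Ic50Max = s$hla2_ic50_max,
               cutoffK = cfg$elisa$cutoff_k, trimK = cfg$elisa$trim_k,
               seed = cfg$seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full mimicry-screening pipeline
#'
#' Orchestrates the workflow end to end: read the target and epitope catalog
#' (data aggregation), align and apply the identity/length cutoff (sequence
#' alignment), filter by HLA binding (immunogenicity), derive the reactive
#' antigen set from the ELISA panel (or take a supplied list), intersect,
#' and summarize per disease. Per-stage counts are logged with
#' \code{message()} and returned in the report; the run is deterministic
#' given identical inputs and configuration, so reports are byte-identical
#' across reruns.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognized fields: \code{target_fasta}, \code{epitope_table},
#'   \code{binding_table}, one of \code{elisa_table} / \code{reactive_list},
#'   \code{antibody}, \code{seed}, and the \code{screen} / \code{elisa}
#'   parameter blocks (defaults as in [screenConfig()]).
#' @param outDir optional directory; when given, the hit report
#'   (\code{hits.tsv}) and a machine-readable JSON report
#'   (\code{report.json}) are written there.
#' @return A [PipelineReport-class].
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  cfg <- .mergeConfig(config, .configDefaults())
  scfg <- .screenConfigFrom(cfg)

  target <- .stage("data aggregation", {
    if (is.null(cfg$target_fasta)) stop("no target_fasta configured")
    readFasta(cfg$target_fasta)[[1]]
  })
  epitopes <- .stage("data aggregation", {
    if (is.null(cfg$epitope_table)) stop("no epitope_table configured")
    readEpitopeTable(cfg$epitope_table)
  })
  message("data aggregation: ", nrow(epitopes), " positive epitopes, target ",
          seqId(target), " (", length(target), " aa)")

  aligned <- .stage("sequence alignment",
                    screenEpitopes(epitopes, target, scfg))
  message("sequence alignment: ", nrow(aligned), " of ", nrow(epitopes),
          " epitopes pass the identity/length cutoff")

  hits <- .stage("immunogenicity", {
    if (is.null(cfg$binding_table)) stop("no binding_table configured")
    immunogenicityFilter(aligned, readBindingTable(cfg$binding_table), scfg)
  })
  message("immunogenicity: ", nrow(hits), " hits with a strong HLA binder")

  reactive <- .stage("reactivity", {
    if (!is.null(cfg$elisa_table)) {
      panel <- readElisaTable(cfg$elisa_table)
      if (!is.null(cfg$antibody))
        panel <- panel[panel$antibody == cfg$antibody, , drop = FALSE]
      analyzeReactivity(panel, cutoffK = cfg$elisa$cutoff_k,
                        trimK = cfg$elisa$trim_k)$reactiveAntigens
    } else if (!is.null(cfg$reactive_list)) {
      .readTable(cfg$reactive_list)[[1]]
    } else stop("no elisa_table or reactive_list configured")
  })
  message("reactivity: ", length(reactive), " cross-reactive antigens")

  final <- .stage("cross-reactivity intersection",
                  intersectWithReactive(hits, reactive))
  message("cross-reactivity intersection: ", nrow(final), " final hits")

  report <- new("PipelineReport",
                stageCounts = c(epitopes_in = as.integer(nrow(epitopes)),
                                alignment_pass = as.integer(nrow(aligned)),
                                immunogenic = as.integer(nrow(hits)),
                                cross_reactive = as.integer(nrow(final))),
                hits = final[, setdiff(names(final), "alignment"),
                             drop = FALSE],
                diseaseSummary = summarizeByDisease(final),
                reactiveAntigens = as.character(reactive),
                config = cfg,
                version = as.character(packageVersion("MimicryScan")))
  if (!is.null(outDir)) writePipelineReport(report, outDir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes \code{hits.tsv} (via [writeHitsReport()]) and \code{report.json}
#' with the stage counts, disease summary, reactive antigens, configuration
#' echo and package version. Content depends only on the report, so reruns
#' with identical inputs produce byte-identical files.
#'
#' @param report a [PipelineReport-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writePipelineReport <- function(report, dir) {
  stopifnot(is(report, "PipelineReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hitsPath <- file.path(dir, "hits.tsv")
  jsonPath <- file.path(dir, "report.json")
  writeHitsReport(report@hits, hitsPath)
  jsonlite::write_json(
    list(stage_counts = as.list(report@stageCounts),
         disease_summary = report@diseaseSummary,
         reactive_antigens = report@reactiveAntigens,
         config = report@config,
         version = report@version),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(hits = hitsPath, report = jsonPath))
}
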