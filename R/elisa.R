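#' @include io.R
NULL

# Per-antigen summary of an ELISA measurement table: mean OD over replicate
# wells and the duplicate-well variation (percent).
.elisaSummary <- function(measurements) {
  odCols <- grep("^od[0-9]*$", names(measurements), value = TRUE)
  if (!length(odCols)) stop("no OD columns (od1, od2, ...) in measurements")
  ods <- as.matrix(measurements[odCols])
  nRep <- rowSums(!is.na(ods))
  meanOd <- rowMeans(ods, na.rm = TRUE)
  cv <- rep(NA_real_, nrow(ods))
  two <- nRep == 2L
  if (any(two)) {
    pair <- t(apply(ods[two, , drop = FALSE], 1,
                    function(r) r[!is.na(r)][1:2]))
    cv[two] <- 100 * abs(pair[, 1] - pair[, 2]) / rowMeans(pair)
  }
  data.frame(antigen = measurements$antigen,
             antibody = if ("antibody" %in% names(measurements))
               measurements$antibody else NA_character_,
             mean_od = meanOd, n_replicates = nRep, cv_percent = cv,
             stringsAsFactors = FALSE)
}

#' Isolate the ELISA background cluster
#'
#' Finds the near-background antigen cluster whose mean and SD define the
#' reactivity cutoff. Starting from all antigens' mean ODs, antigens above
#' \code{mean + trimK*SD} are dropped and the statistics recomputed until
#' membership stabilizes; membership shrinks monotonically, so convergence
#' is guaranteed (asserted at 100 iterations). Supplying \code{background}
#' bypasses the iteration and computes the statistics on the given antigens.
#'
#' The trimming multiplier is deliberately larger than the cutoff
#' multiplier: trimming at 1 SD removes the upper ~16\% tail of a Gaussian
#' cluster at every pass and collapses it, whereas 2 SD converges after
#' shaving only the few clear reactives (details in the methods vignette).
#'
#' @param measurements ELISA table from [readElisaTable()] or
#'   [genElisaPanel()].
#' @param trimK SD multiplier for the trimming threshold (default 2).
#' @param background optional explicit character vector of background
#'   antigen names.
#' @return List with \code{antigens} (background member names), \code{mean},
#'   \code{sd} (population of mean ODs, full precision), and
#'   \code{iterations}.
#' @export
determineBackground <- function(measurements, trimK = 2, background = NULL) {
  summ <- .elisaSummary(measurements)
  if (!is.null(background)) {
    sel <- summ$antigen %in% background
    if (sum(sel) < 1L) stop("explicit background set matches no antigen")
    return(list(antigens = summ$antigen[sel],
                mean = mean(summ$mean_od[sel]),
                sd = if (sum(sel) > 1L) sd(summ$mean_od[sel]) else 0,
                iterations = 0L))
  }
  if (nrow(summ) < 3L) stop("need at least 3 antigens")
  if (trimK <= 0) stop("trimK must be positive")
  member <- rep(TRUE, nrow(summ))
  for (it in seq_len(100L)) {
    od <- summ$mean_od[member]
    m <- mean(od)
    s <- if (length(od) > 1L) sd(od) else 0
    drop <- member & summ$mean_od > m + trimK * s
    if (!any(drop)) {
      return(list(antigens = summ$antigen[member], mean = m, sd = s,
                  iterations = it))
    }
    member <- member & !drop
  }
  stop("background trimming did not converge in 100 iterations")  # unreachable
}

#' Reactivity cutoff from background statistics
#'
#' \code{cutoff = mean + k*sd}; with the published polyclonal background
#' (mean 0.16, SD 0.12) and \code{k = 1} this is 0.28, and 0.24 for the
#' monoclonal background (0.15, 0.09).
#'
#' @param mean,sd background mean OD and SD (\code{sd >= 0}).
#' @param k SD multiplier (> 0, default 1).
#' @return The cutoff OD.
#' @examples
#' determineCutoff(0.16, 0.12)  # 0.28
#' determineCutoff(0.15, 0.09)  # 0.24
#' @export
determineCutoff <- function(mean, sd, k = 1) {
  if (sd < 0) stop("sd must be non-negative")
  if (k <= 0) stop("k must be positive")
  mean + k * sd
}

#' Classify antigens against the reactivity cutoff
#'
#' An antigen is reactive iff its mean OD exceeds the cutoff. The annotated
#' p-value is the one-sided upper-tail probability of the antigen's mean OD
#' under Normal(background mean, background sd^2) - a z-score stand-in that
#' reproduces the qualitative monotonicity (higher OD above the cutoff,
#' smaller p), not any particular published p-value.
#'
#' @param measurements ELISA table.
#' @param cutoff cutoff OD from [determineCutoff()].
#' @param backgroundMean,backgroundSd background statistics from
#'   [determineBackground()].
#' @param backgroundAntigens optional background member names, used to set
#'   the \code{background_member} flag.
#' @return data.frame (one row per antigen, sorted by descending mean OD)
#'   with \code{antigen}, \code{antibody}, \code{mean_od},
#'   \code{cv_percent}, \code{cutoff}, \code{reactive}, \code{p_value},
#'   \code{background_member}.
#' @export
classifyAntigens <- function(measurements, cutoff, backgroundMean,
                             backgroundSd, backgroundAntigens = character()) {
  if (backgroundSd < 0) stop("backgroundSd must be non-negative")
  summ <- .elisaSummary(measurements)
  p <- if (backgroundSd > 0)
    pnorm(summ$mean_od, mean = backgroundMean, sd = backgroundSd,
          lower.tail = FALSE)
  else as.numeric(summ$mean_od <= backgroundMean)
  out <- data.frame(antigen = summ$antigen, antibody = summ$antibody,
                    mean_od = summ$mean_od, cv_percent = summ$cv_percent,
                    cutoff = cutoff, reactive = summ$mean_od > cutoff,
                    p_value = pmax(p, .Machine$double.xmin),
                    background_member = summ$antigen %in% backgroundAntigens,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_od, out$antigen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Duplicate-well variation check
#'
#' Computes the duplicate-well variation \code{100*|od1-od2|/mean} per
#' antigen and flags whether it is below \code{maxCvPercent} (the assay's
#' stated quality bound, default 7\%). Antigens without exactly two
#' replicate wells are flagged not-assessable rather than failed.
#'
#' @param measurements ELISA table.
#' @param maxCvPercent pass threshold in percent.
#' @return data.frame with \code{antigen}, \code{cv_percent}, \code{pass},
#'   \code{assessable}.
#' @export
duplicateCvCheck <- function(measurements, maxCvPercent = 7) {
  summ <- .elisaSummary(measurements)
  data.frame(antigen = summ$antigen, cv_percent = summ$cv_percent,
             pass = !is.na(summ$cv_percent) & summ$cv_percent < maxCvPercent,
             assessable = !is.na(summ$cv_percent),
             stringsAsFactors = FALSE)
}

#' Full ELISA reactivity analysis
#'
#' Convenience chain: [determineBackground()], [determineCutoff()],
#' [classifyAntigens()], [duplicateCvCheck()]. The reactive antigen names
#' are returned in the form [intersectWithReactive()] consumes.
#'
#' @param measurements ELISA table.
#' @param cutoffK cutoff SD multiplier (default 1).
#' @param trimK background-trimming SD multiplier (default 2).
#' @param background optional explicit background antigen names.
#' @param maxCvPercent duplicate-well QC bound.
#' @return List with \code{results} (classification table), \code{cutoff},
#'   \code{background} (list from [determineBackground()]), \code{qc}, and
#'   \code{reactiveAntigens} (character).
#' @export
analyzeReactivity <- function(measurements, cutoffK = 1, trimK = 2,
                              background = NULL, maxCvPercent = 7) {
  bg <- determineBackground(measurements, trimK = trimK,
                            background = background)
  cutoff <- determineCutoff(bg$mean, bg$sd, k = cutoffK)
  res <- classifyAntigens(measurements, cutoff, bg$mean, bg$sd,
                          backgroundAntigens = bg$antigens)
  list(results = res, cutoff = cutoff, background = bg,
       qc = duplicateCvCheck(measurements, maxCvPercent),
       reactiveAntigens = res$antigen[res$reactive])
}
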