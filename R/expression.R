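#' @include AllClasses.R contexts.R motif.R
NULL

#' Read reporter measurement / plate-control tables
#'
#' Measurement TSV columns: `context_id`, `species`, `plate_id`,
#' `replicate`, `fluc_raw`. Control TSV columns: `plate_id`, `rluc_raw`.
#' Lines starting with `#` are ignored.
#'
#' @param file Path to a TSV.
#' @return A data.frame.
#' @rdname readMeasurements
#' @export
readMeasurements <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("context_id", "species", "plate_id", "replicate", "fluc_raw")
  if (!all(need %in% names(tab)))
    stop("measurement table must have columns ",
         paste(need, collapse = ", "))
  tab
}

#' @rdname readMeasurements
#' @export
readPlateControls <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("plate_id", "rluc_raw") %in% names(tab)))
    stop("control table must have columns plate_id, rluc_raw")
  tab
}

#' Standardise firefly readings to the per-plate Renilla control
#'
#' Each well's raw FLuc relative light units are divided by the mean of
#' the RLuc control readings of its plate, removing plate-to-plate scale
#' differences. Raw values are left untouched; a `normalized` column is
#' added.
#'
#' @param records Measurement data.frame (see [readMeasurements()]).
#' @param controls Control data.frame with columns `plate_id`, `rluc_raw`.
#' @return `records` with a `normalized` column.
#' @examples
#' rec <- data.frame(context_id = 1, species = "rabbit", plate_id = "p1",
#'                   replicate = 1, fluc_raw = 100)
#' ctl <- data.frame(plate_id = "p1", rluc_raw = c(40, 60))
#' normalizePlates(rec, ctl)$normalized  # 2
#' @export
normalizePlates <- function(records, controls) {
  if (any(records$fluc_raw < 0))
    stop("fluc_raw must be nonnegative")
  ctlMean <- tapply(controls$rluc_raw, controls$plate_id, mean)
  missing <- setdiff(unique(records$plate_id), names(ctlMean))
  if (length(missing))
    stop("no plate control for plate(s): ", paste(missing, collapse = ", "))
  bad <- names(ctlMean)[!is.na(ctlMean) & ctlMean <= 0]
  if (any(ctlMean[unique(records$plate_id)] <= 0))
    stop("plate control mean is not positive for plate(s): ",
         paste(bad, collapse = ", "))
  records$normalized <- records$fluc_raw /
    as.numeric(ctlMean[as.character(records$plate_id)])
  records
}

#' Per-(context, species) mean normalised activity
#'
#' Arithmetic mean of normalised replicate activities for every assayed
#' (context, species) pair, with the replicate count.
#'
#' @param records Normalised records (see [normalizePlates()]).
#' @param contexts Optional integer ids that must appear; ids with zero
#'   replicates are omitted with a warning.
#' @return data.frame with `context_id`, `species`, `n`,
#'   `mean_normalized`.
#' @export
summarizeContexts <- function(records, contexts = NULL) {
  if (is.null(records$normalized))
    stop("records are not normalised; run normalizePlates() first")
  agg <- aggregate(normalized ~ context_id + species, data = records,
                   FUN = mean)
  n <- aggregate(normalized ~ context_id + species, data = records,
                 FUN = length)
  out <- data.frame(context_id = agg$context_id, species = agg$species,
                    n = n$normalized, mean_normalized = agg$normalized,
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$context_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(contexts)) {
    missing <- setdiff(contexts, out$context_id)
    if (length(missing))
      warning("no replicates for context id(s): ",
              paste(missing, collapse = ", "), "; omitted")
  }
  out
}

checkSummary <- function(summary) {
  if (!all(c("context_id", "mean_normalized") %in% names(summary)))
    stop("summary must have columns context_id and mean_normalized")
  if (length(unique(summary$species)) > 1L)
    stop("summary spans several species; subset to one before splitting")
  invisible(summary)
}

#' Split contexts into an extreme fraction and the background
#'
#' Contexts are ranked by mean normalised activity; the top (or bottom)
#' `round(fraction * n)` (half-up) form the selected set, the remainder
#' the background. Ties at the cut are broken by ascending context id, so
#' splits are deterministic.
#'
#' @param summary Per-context summary (one species), from
#'   [summarizeContexts()].
#' @param fraction Fraction in (0, 1); default 0.2.
#' @param side `"top"` (highest activity) or `"bottom"`.
#' @return List with `selected` and `background` (integer id vectors) and
#'   `k`.
#' @export
rankAndSplit <- function(summary, fraction = 0.2,
                         side = c("top", "bottom")) {
  side <- match.arg(side)
  checkSummary(summary)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  n <- nrow(summary)
  if (n < 2L) stop("need at least two contexts to split")
  k <- roundHalfUp(fraction * n)
  if (k < 1L) stop("fraction * n is below 1; nothing to select")
  ord <- if (side == "top")
    order(-summary$mean_normalized, summary$context_id)
  else
    order(summary$mean_normalized, summary$context_id)
  ids <- summary$context_id[ord]
  list(selected = ids[seq_len(k)], background = ids[-seq_len(k)], k = k)
}

#' Ratio of top-fraction to bottom-fraction mean activity
#'
#' Mean activity of the top `fraction` of contexts divided by the mean of
#' the bottom `fraction`.
#'
#' @inheritParams rankAndSplit
#' @return Positive numeric.
#' @export
topBottomRatio <- function(summary, fraction = 0.2) {
  top <- rankAndSplit(summary, fraction, "top")$selected
  bottom <- rankAndSplit(summary, fraction, "bottom")$selected
  m <- setNames(summary$mean_normalized, summary$context_id)
  bottomMean <- mean(m[as.character(bottom)])
  if (bottomMean == 0)
    stop("bottom-fraction mean activity is zero; ratio undefined")
  mean(m[as.character(top)]) / bottomMean
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Two-sided Mann-Whitney U with midranks for ties. The p-value is the
#' exact one when the pooled size is at most 12 and there are no ties,
#' otherwise the normal approximation with tie correction and continuity
#' correction. The returned U counts pairs in which `a` exceeds `b`.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return List with `u` and `p`.
#' @examples
#' rankSumTest(1:3, 4:6)  # U = 0, exact p = 0.1
#' @export
rankSumTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  # fully tied samples have zero rank variance; U sits at its mean
  if (!is.finite(p)) p <- 1
  list(u = unname(u), p = p)
}

#' Fold change of non-matching over matching contexts
#'
#' Splits a per-context summary into contexts matching a degenerate motif
#' (or an exact 7-mer set) and all remaining contexts, and reports the
#' ratio of aggregate activities (non-matching over matching) together
#' with a two-sided rank-sum test on the two per-context activity
#' vectors.
#'
#' @param summary Per-context summary for one species
#'   ([summarizeContexts()]).
#' @param pattern A [MotifPattern-class] or pattern text (e.g.
#'   `"YCMAUGY"`); ignored when `exactSet` is given.
#' @param contexts Context panel mapping ids to sequences; default
#'   [loadTable1()].
#' @param exactSet Optional character vector of exact 7-mers defining the
#'   matching group (e.g. [bacsSequences()]).
#' @param aggregate `"mean"` (default) or `"median"` group aggregation.
#' @return A [GroupComparison-class]: group A is the matching set, group B
#'   the rest; `foldChange` = aggregate(B) / aggregate(A).
#' @export
motifFoldChange <- function(summary, pattern = NULL,
                            contexts = loadTable1(), exactSet = NULL,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  checkSummary(summary)
  seqs <- setNames(contexts$sevenmer %||% sevenMer(contexts$sequence),
                   contexts$id)
  sev <- seqs[as.character(summary$context_id)]
  if (anyNA(sev))
    stop("summary contains context ids absent from the context panel")
  hit <- if (!is.null(exactSet)) sev %in% normalizeSeq(exactSet)
         else matchesPattern(pattern, unname(sev))
  if (all(hit) || !any(hit))
    stop("pattern matches ", if (all(hit)) "all" else "no",
         " contexts; fold change undefined")
  f <- if (aggregate == "mean") mean else median
  va <- summary$mean_normalized[hit]
  vb <- summary$mean_normalized[!hit]
  rs <- rankSumTest(va, vb)
  new("GroupComparison", foldChange = f(vb) / f(va), uStatistic = rs$u,
      pValue = rs$p, nA = length(va), nB = length(vb))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a per-context summary TSV
#'
#' Adds Kozak class and BACS columns from the context panel and writes a
#' TSV with a version/parameter header comment.
#'
#' @param summary Output of [summarizeContexts()].
#' @param file Output path.
#' @param contexts Context panel; default [loadTable1()].
#' @return `file`, invisibly.
#' @export
writeSummary <- function(summary, file, contexts = loadTable1()) {
  idx <- match(summary$context_id, contexts$id)
  summary$kozak <- contexts$kozak[idx]
  summary$bacs <- contexts$bacs[idx]
  writeTsvWithHeader(summary, file, "summarize")
}

writeTsvWithHeader <- function(tab, file, what, params = character(0)) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# bacscan %s | %s%s",
                     as.character(packageVersion("bacscan")), what,
                     if (length(params))
                       paste0(" | ", paste(params, collapse = " "))
                     else ""), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
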