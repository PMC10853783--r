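#' @include AllClasses.R motif.R expression.R
NULL

positionLabel <- function(pos) ifelse(pos < 0, as.character(pos),
                                      paste0("+", pos))

#' Per-position nucleotide probabilities
#'
#' Tallies the nucleotide at each requested anchored position over a set
#' of contexts, adds `pseudocount` to every (position, nucleotide) count,
#' and normalises per position.
#'
#' @param contexts A [TISContext-class] or character TIS windows.
#' @param positions Integer positions relative to the AUG (negative or
#'   >= 4); default `c(-3, -2, -1, 4)`, the assayed window.
#' @param pseudocount Nonnegative count added per nucleotide per position
#'   before normalisation; default 0.01.
#' @return A [ProbabilityMatrix-class].
#' @examples
#' positionProbabilities(c("CCAAUGU", "UCAAUGU"), pseudocount = 0)
#' @export
positionProbabilities <- function(contexts, positions = c(-3L, -2L, -1L, 4L),
                                  pseudocount = 0.01) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  parts <- contextParts(contexts)
  if (!length(parts$upstream)) stop("context list is empty")
  probs <- matrix(0, nrow = length(positions), ncol = 4L,
                  dimnames = list(positionLabel(positions), RNA_BASES))
  for (i in seq_along(positions)) {
    base <- contextBaseAt(parts, as.integer(positions[i]))
    if (anyNA(base) || any(base == ""))
      stop("position ", positionLabel(positions[i]),
           " is not covered by every context")
    counts <- table(factor(base, levels = RNA_BASES)) + pseudocount
    probs[i, ] <- as.numeric(counts) / sum(counts)
  }
  new("ProbabilityMatrix", probs = probs)
}

#' Enrichment/depletion matrix for sequence logos
#'
#' For each nucleotide i and position k computes
#' `E[i,k] = P_set[i,k] * log2(P_set[i,k] / P_back[i,k])` — positive where
#' the subset is enriched relative to the background, negative where
#' depleted. `E` is defined as 0 where `P_set` is 0 (the limit of
#' x*log(x)).
#'
#' @param pSet Subset probabilities, a [ProbabilityMatrix-class].
#' @param pBack Background probabilities over the same positions; must be
#'   strictly positive wherever `pSet` is positive (guaranteed by a
#'   positive pseudocount).
#' @return An [EnrichmentMatrix-class].
#' @export
enrichmentMatrix <- function(pSet, pBack) {
  ps <- matrixValues(pSet)
  pb <- matrixValues(pBack)
  if (!identical(dimnames(ps), dimnames(pb)))
    stop("subset and background matrices cover different positions")
  if (any(pb == 0 & ps > 0))
    stop("background probability is 0 where the subset is positive; ",
         "use a positive pseudocount")
  e <- matrix(0, nrow = nrow(ps), ncol = ncol(ps), dimnames = dimnames(ps))
  nz <- ps > 0
  e[nz] <- ps[nz] * log2(ps[nz] / pb[nz])
  new("EnrichmentMatrix", e = e)
}

#' Percentile split plus enrichment logo in one step
#'
#' Composes [rankAndSplit()], [positionProbabilities()] on the selected
#' subset and on the complementary background, and [enrichmentMatrix()].
#' With `side = "bottom"` the lowest-activity fraction is compared with
#' the remaining contexts, the comparison behind the consensus of poorly
#' translated sequences.
#'
#' @inheritParams rankAndSplit
#' @param pseudocount Passed to [positionProbabilities()].
#' @param positions Positions for the matrices; default `c(-3,-2,-1,4)`.
#' @param contexts Context panel mapping ids to sequences; default
#'   [loadTable1()].
#' @return List with `enrichment` ([EnrichmentMatrix-class]), `pSet`,
#'   `pBack`, and the `split` id lists.
#' @export
splitAndLogo <- function(summary, fraction = 0.2,
                         side = c("top", "bottom"), pseudocount = 0.01,
                         positions = c(-3L, -2L, -1L, 4L),
                         contexts = loadTable1()) {
  side <- match.arg(side)
  split <- rankAndSplit(summary, fraction, side)
  seqs <- setNames(contexts$sevenmer, contexts$id)
  sel <- unname(seqs[as.character(split$selected)])
  bg <- unname(seqs[as.character(split$background)])
  if (anyNA(sel) || anyNA(bg))
    stop("summary contains context ids absent from the context panel")
  pSet <- positionProbabilities(sel, positions, pseudocount)
  pBack <- positionProbabilities(bg, positions, pseudocount)
  list(enrichment = enrichmentMatrix(pSet, pBack), pSet = pSet,
       pBack = pBack, split = split)
}

#' Call a degenerate consensus from a probability matrix
#'
#' Per position, nucleotides are sorted by probability (descending); the
#' smallest prefix whose cumulative probability reaches the threshold is
#' reported as the matching IUPAC code. Nucleotides tied with the last
#' included one are included as well, so the call is deterministic and
#' monotone in the threshold.
#'
#' @param pMatrix A [ProbabilityMatrix-class].
#' @param threshold Cumulative probability threshold in (0, 1]; default
#'   0.75.
#' @return A [MotifPattern-class] (print it or use [patternString()] for
#'   text such as `"YCMAUGY"`).
#' @export
callConsensus <- function(pMatrix, threshold = 0.75) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  p <- matrixValues(pMatrix)
  codes <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    ord <- order(-p[i, ], RNA_BASES)  # prob desc, alphabetical tiebreak
    probs <- p[i, ord]
    k <- which(cumsum(probs) >= threshold - 1e-12)[1L]
    if (is.na(k)) k <- 4L
    # include nucleotides tied with the last selected probability
    k <- max(which(probs >= probs[k] - 1e-12))
    codes[i] <- setToCode(RNA_BASES[ord][seq_len(k)])
  }
  pos <- rownames(p)
  new("MotifPattern",
      positions = as.integer(sub("^\\+", "", pos)), codes = codes)
}

#' Export a probability or enrichment matrix as TSV
#'
#' Rows are positions, columns A/C/G/U; a header comment records the
#' package version.
#'
#' @param x A [ProbabilityMatrix-class] or [EnrichmentMatrix-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportMatrix <- function(x, file) {
  m <- matrixValues(x)
  tab <- data.frame(position = rownames(m), m, check.names = FALSE)
  writeTsvWithHeader(tab, file, class(x))
}
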