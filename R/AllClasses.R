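#' TISContext: nucleotides flanking a start codon
#'
#' A vectorised container for translation-initiation-site contexts: the
#' upstream flank (positions -k..-1, 5'->3'), the start codon itself and the
#' downstream flank (position +4 onward). The A of the AUG is position +1;
#' there is no position 0. Input is normalised to the RNA alphabet
#' (T -> U, upper case) on construction.
#'
#' @slot upstream character, upstream flanks (length 1-6 nt each).
#' @slot codon character, start codons (3 nt each).
#' @slot downstream character, downstream flanks (>= 1 nt each).
#' @aliases TISContext-class
#' @exportClass TISContext
setClass("TISContext",
         representation(upstream = "character", codon = "character",
                        downstream = "character"))

setValidity("TISContext", function(object) {
  n <- length(object@upstream)
  if (length(object@codon) != n || length(object@downstream) != n)
    return("upstream, codon and downstream must have equal length")
  for (s in list(object@upstream, object@codon, object@downstream))
    if (any(grepl("[^ACGU]", s)))
      return("sequences must be over A/C/G/U after normalization")
  if (any(nchar(object@codon) != 3L))
    return("start codon must be exactly 3 nt")
  if (any(nchar(object@upstream) < 1L | nchar(object@upstream) > 6L))
    return("upstream flank must be 1-6 nt")
  if (any(nchar(object@downstream) < 1L))
    return("downstream flank must be >= 1 nt")
  TRUE
})

#' Construct TIS contexts
#'
#' @param upstream Character vector of upstream flanks (positions -k..-1,
#'   1-6 nt). DNA or RNA, case-insensitive.
#' @param codon Character vector of start codons (default `"AUG"`),
#'   recycled.
#' @param downstream Character vector of downstream flanks (position +4
#'   onward, >= 1 nt).
#' @return A [TISContext-class] object.
#' @examples
#' tisContext("CCA", downstream = "U")   # the 7-mer CCAAUGU
#' @export
tisContext <- function(upstream, codon = "AUG", downstream) {
  up <- normalizeSeq(upstream)
  co <- normalizeSeq(codon)
  dn <- normalizeSeq(downstream)
  n <- max(length(up), length(co), length(dn))
  new("TISContext", upstream = rep_len(up, n), codon = rep_len(co, n),
      downstream = rep_len(dn, n))
}

setMethod("length", "TISContext", function(x) length(x@upstream))

setMethod("show", "TISContext", function(object) {
  n <- length(object)
  cat("TISContext of length", n, "\n")
  k <- min(n, 6L)
  if (k > 0)
    cat(paste0(" ", object@upstream[seq_len(k)], ".", object@codon[seq_len(k)],
               ".", object@downstream[seq_len(k)]), sep = "\n")
  if (n > k) cat(" ...\n")
})

#' @export
setMethod("[", "TISContext", function(x, i, j, ..., drop = TRUE) {
  new("TISContext", upstream = x@upstream[i], codon = x@codon[i],
      downstream = x@downstream[i])
})

#' Accessors for TISContext flanks
#' @param x A [TISContext-class] object.
#' @return Character vector.
#' @rdname tisAccessors
#' @export
upstreamFlank <- function(x) x@upstream
#' @rdname tisAccessors
#' @export
startCodon <- function(x) x@codon
#' @rdname tisAccessors
#' @export
downstreamFlank <- function(x) x@downstream

#' MotifPattern: an IUPAC degenerate motif anchored to the start codon
#'
#' Positions are relative to the A (+1) of the start codon: negative
#' upstream positions, +4 onward downstream. The AUG itself is implicit
#' between -1 and +4.
#'
#' @slot positions integer, e.g. `c(-3L, -2L, -1L, 4L)`.
#' @slot codes character, one IUPAC code per position.
#' @aliases MotifPattern-class
#' @exportClass MotifPattern
setClass("MotifPattern",
         representation(positions = "integer", codes = "character"))

setValidity("MotifPattern", function(object) {
  if (length(object@positions) != length(object@codes))
    return("positions and codes must have equal length")
  if (any(object@positions == 0L) ||
      any(object@positions > 0L & object@positions < 4L))
    return("positions must be negative or >= +4 (the codon occupies +1..+3)")
  if (anyDuplicated(object@positions))
    return("duplicated positions")
  if (!all(object@codes %in% names(IUPAC_RNA)))
    return("unknown IUPAC code")
  TRUE
})

setMethod("show", "MotifPattern", function(object) {
  cat("MotifPattern:", patternString(object), "\n")
})

#' ProbabilityMatrix: per-position nucleotide probabilities
#'
#' Rows are TIS positions (e.g. "-3", "-2", "-1", "+4"), columns the four
#' RNA nucleotides; each row sums to 1.
#'
#' @slot probs numeric matrix, positions x A/C/G/U.
#' @aliases ProbabilityMatrix-class
#' @exportClass ProbabilityMatrix
setClass("ProbabilityMatrix", representation(probs = "matrix"))

setValidity("ProbabilityMatrix", function(object) {
  p <- object@probs
  if (!identical(colnames(p), RNA_BASES))
    return("columns must be A, C, G, U")
  if (any(p < 0)) return("probabilities must be >= 0")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    return("each position's probabilities must sum to 1 (within 1e-9)")
  TRUE
})

setMethod("show", "ProbabilityMatrix", function(object) {
  cat("ProbabilityMatrix (", nrow(object@probs), " positions)\n", sep = "")
  print(round(object@probs, 4))
})

#' EnrichmentMatrix: the logo statistic E = P_set * log2(P_set / P_back)
#'
#' Positive values mark nucleotides enriched in the selected subset
#' relative to the background, negative values mark depletion.
#'
#' @slot e numeric matrix, positions x A/C/G/U.
#' @aliases EnrichmentMatrix-class
#' @exportClass EnrichmentMatrix
setClass("EnrichmentMatrix", representation(e = "matrix"))

setValidity("EnrichmentMatrix", function(object) {
  if (!identical(colnames(object@e), RNA_BASES))
    return("columns must be A, C, G, U")
  if (any(!is.finite(object@e))) return("enrichment values must be finite")
  TRUE
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat("EnrichmentMatrix (", nrow(object@e), " positions)\n", sep = "")
  print(round(object@e, 4))
})

#' Extract the numeric matrix from a probability/enrichment matrix
#' @param x A [ProbabilityMatrix-class] or [EnrichmentMatrix-class].
#' @return Numeric matrix (positions x A/C/G/U).
#' @export
matrixValues <- function(x) {
  if (is(x, "ProbabilityMatrix")) return(x@probs)
  if (is(x, "EnrichmentMatrix")) return(x@e)
  stop("not a ProbabilityMatrix or EnrichmentMatrix")
}

#' GroupComparison: fold change plus rank-sum test between two groups
#'
#' @slot foldChange numeric, mean(group B) / mean(group A).
#' @slot uStatistic numeric, Mann-Whitney U for group A.
#' @slot pValue numeric in `[0, 1]`, two-sided.
#' @slot nA,nB integer group sizes.
#' @aliases GroupComparison-class
#' @exportClass GroupComparison
setClass("GroupComparison",
         representation(foldChange = "numeric", uStatistic = "numeric",
                        pValue = "numeric", nA = "integer", nB = "integer"))

setValidity("GroupComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("p-value must lie in [0, 1]")
  TRUE
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison: fold change %.4g (n=%d vs n=%d), U=%g, p=%.4g\n",
    object@foldChange, object@nA, object@nB, object@uStatistic,
    object@pValue))
})

#' @rdname GroupComparison-class
#' @param x A `GroupComparison`.
#' @export
foldChange <- function(x) x@foldChange
#' @rdname GroupComparison-class
#' @export
pValue <- function(x) x@pValue
#' @rdname GroupComparison-class
#' @export
uStatistic <- function(x) x@uStatistic
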