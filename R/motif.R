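#' @include AllClasses.R
NULL

# IUPAC degenerate nucleotide codes over the RNA alphabet
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), M = c("A", "C"), K = c("G", "U"),
  S = c("C", "G"), W = c("A", "U"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

# reverse map: sorted nucleotide set -> code
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_RNA, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(IUPAC_RNA), keys)
})

iupacSet <- function(code) IUPAC_RNA[[code]]

setToCode <- function(nucs) {
  code <- IUPAC_FROM_SET[paste(sort(unique(nucs)), collapse = "")]
  if (is.na(code)) stop("empty nucleotide set has no IUPAC code")
  unname(code)
}

#' Parse an anchored IUPAC motif pattern
#'
#' Parses text such as `"YCMAUGY"` into a [MotifPattern-class]. The text
#' must contain exactly one `AUG`/`ATG` anchor; all remaining characters
#' are IUPAC degenerate codes assigned to positions relative to the anchor
#' (-1, -2, ... upstream; +4, +5, ... downstream). Both T and U are
#' accepted; the internal canonical form is RNA.
#'
#' Bracket classes as emitted by [toSearchPattern()] (e.g. `[CT]`) are
#' folded back to their IUPAC code, so emitted patterns round-trip.
#'
#' @param text Pattern string with one AUG/ATG anchor.
#' @return A [MotifPattern-class].
#' @examples
#' parsePattern("YCMAUGY")
#' parsePattern("[CT]C[AC]ATG[CT]")
#' @export
parsePattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- normalizeSeq(text)
  # fold bracket classes back into single IUPAC codes
  while (grepl("\\[[ACGU]+\\]", txt)) {
    grp <- regmatches(txt, regexpr("\\[[ACGU]+\\]", txt))
    code <- setToCode(strsplit(gsub("[][]", "", grp), "")[[1]])
    txt <- sub("\\[[ACGU]+\\]", code, txt)
  }
  chars <- strsplit(txt, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_RNA))
  if (length(bad))
    stop("unknown IUPAC symbol(s): ", paste(bad, collapse = ", "))
  # all (possibly overlapping) literal AUG occurrences
  hits <- integer(0)
  if (nchar(txt) >= 3L)
    for (i in seq_len(nchar(txt) - 2L))
      if (substr(txt, i, i + 2L) == "AUG") hits <- c(hits, i)
  if (length(hits) != 1L)
    stop("pattern must contain exactly one AUG anchor (found ",
         length(hits), ")")
  a <- hits
  upCodes <- if (a > 1L) chars[seq_len(a - 1L)] else character(0)
  dnCodes <- if (a + 3L <= length(chars)) chars[(a + 3L):length(chars)]
             else character(0)
  positions <- c(if (length(upCodes)) -(length(upCodes):1L),
                 if (length(dnCodes)) 3L + seq_along(dnCodes))
  new("MotifPattern", positions = as.integer(positions),
      codes = c(upCodes, dnCodes))
}

#' Pattern text of a MotifPattern
#' @param pattern A [MotifPattern-class].
#' @param alphabet `"rna"` (default) or `"dna"`.
#' @return Single string, e.g. `"YCMAUGY"`.
#' @export
patternString <- function(pattern, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  up <- pattern@codes[pattern@positions < 0L][order(
    pattern@positions[pattern@positions < 0L])]
  dn <- pattern@codes[pattern@positions > 0L][order(
    pattern@positions[pattern@positions > 0L])]
  s <- paste0(paste(up, collapse = ""), "AUG", paste(dn, collapse = ""))
  if (alphabet == "dna") chartr("U", "T", s) else s
}

#' Expand a degenerate pattern into all concrete sequences
#'
#' Cartesian product of the per-position nucleotide sets, with AUG
#' inserted at the anchor.
#'
#' @param pattern A [MotifPattern-class].
#' @return Sorted character vector of concrete RNA sequences.
#' @examples
#' expandPattern(parsePattern("YCMAUGY"))  # 8 sequences
#' @export
expandPattern <- function(pattern) {
  ord <- order(pattern@positions)
  pos <- pattern@positions[ord]
  sets <- lapply(pattern@codes[ord], iupacSet)
  if (!length(sets)) return("AUG")
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(sets)), drop = FALSE]
  flanks <- apply(as.matrix(grid), 1L, function(row) {
    paste0(paste(row[pos < 0L], collapse = ""), "AUG",
           paste(row[pos > 0L], collapse = ""))
  })
  sort(unname(flanks))
}

# nucleotide of a context at an anchored position (-k or >= +4)
contextBaseAt <- function(parts, position) {
  if (position < 0L) {
    idx <- parts$nUp + position + 1L
    out <- substr(parts$upstream, idx, idx)
    out[idx < 1L] <- NA_character_
  } else {
    idx <- position - 3L
    out <- substr(parts$downstream, idx, idx)
    out[idx > parts$nDown] <- NA_character_
  }
  out
}

#' Match a pattern against TIS contexts
#'
#' TRUE where every pattern position's nucleotide lies in the code's set.
#' The context must cover every position the pattern constrains.
#'
#' @param pattern A [MotifPattern-class] or pattern text (parsed with
#'   [parsePattern()]).
#' @param contexts A [TISContext-class] or character TIS windows (see
#'   [classifyKozak()] for the window convention).
#' @return Logical vector, one element per context.
#' @examples
#' matchesPattern("YCMAUGY", c("CCAAUGU", "GCCAUGG"))
#' @export
matchesPattern <- function(pattern, contexts) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  parts <- contextParts(contexts)
  if (any(parts$codon != "AUG"))
    stop("pattern matching defined only for AUG contexts")
  n <- length(parts$upstream)
  out <- rep(TRUE, n)
  for (i in seq_along(pattern@positions)) {
    base <- contextBaseAt(parts, pattern@positions[i])
    if (anyNA(base) || any(base == ""))
      stop("context does not cover pattern position ",
           pattern@positions[i])
    out <- out & base %in% iupacSet(pattern@codes[i])
  }
  out
}

#' Emit a bracket-class search pattern
#'
#' Converts a [MotifPattern-class] to a plain-text regular-expression
#' fragment with bracket classes, e.g. `"[CT]C[AC]ATG[CT]"` for YCMAUGY on
#' the DNA alphabet. Parsing the emitted pattern back yields an equivalent
#' motif.
#'
#' @param pattern A [MotifPattern-class] or pattern text.
#' @param alphabet `"dna"` (U -> T) or `"rna"`.
#' @return Single string.
#' @examples
#' toSearchPattern("YCMAUGY", "dna")
#' @export
toSearchPattern <- function(pattern, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  ord <- order(pattern@positions)
  pos <- pattern@positions[ord]
  piece <- vapply(pattern@codes[ord], function(code) {
    s <- sort(iupacSet(code))
    if (alphabet == "dna") s <- chartr("U", "T", s)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, "")
  codon <- if (alphabet == "dna") "ATG" else "AUG"
  paste0(paste(piece[pos < 0L], collapse = ""), codon,
         paste(piece[pos > 0L], collapse = ""))
}
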