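#' @include AllClasses.R
NULL

KOZAK_LEVELS <- c("optimal", "strong", "moderate", "weak")

# md5 checksums of the bundled fixtures, fixed when they were generated
TABLE1_MD5 <- "6a255ec16d3c6a2d6e9cfb2672e05aed"
TABLE2_MD5 <- "95d80c302b6796cf7c72c98f131c631d"

# decompose context input into (minus3, minus2, minus1, plus4, codon,
# upstream length, downstream length). Character input is a TIS window
# ending at +4: <upstream>AUG<+4>, e.g. "CCAAUGU" or "GCCACCAUGG".
contextParts <- function(x) {
  if (is(x, "TISContext")) {
    up <- x@upstream; co <- x@codon; dn <- x@downstream
  } else if (is.character(x)) {
    x <- normalizeSeq(x)
    checkAlphabet(x, "context")
    if (any(nchar(x) < 7L))
      stop("character contexts must be at least 7 nt (<upstream>AUG<+4>)",
           call. = FALSE)
    n <- nchar(x)
    up <- substr(x, 1L, n - 4L)
    co <- substr(x, n - 3L, n - 1L)
    dn <- substr(x, n, n)
  } else {
    stop("contexts must be a TISContext or a character vector")
  }
  nu <- nchar(up)
  list(minus3 = substr(up, nu - 2L, nu - 2L),
       minus2 = substr(up, nu - 1L, nu - 1L),
       minus1 = substr(up, nu, nu),
       plus4 = substr(dn, 1L, 1L),
       codon = co, upstream = up, downstream = dn,
       nUp = nu, nDown = nchar(dn))
}

checkClassifiable <- function(parts) {
  if (any(parts$codon != "AUG"))
    stop("classification defined only for AUG", call. = FALSE)
  if (any(parts$nUp < 3L))
    stop("classification requires at least 3 upstream nucleotides",
         call. = FALSE)
  if (any(parts$nDown < 1L))
    stop("classification requires at least 1 downstream nucleotide",
         call. = FALSE)
  invisible(parts)
}

#' Classify a TIS context by the Kozak rules
#'
#' Applies the classical flanking-sequence rules: *strong* when -3 is a
#' purine (A/G) and +4 is G; *moderate* when exactly one of the two holds;
#' *weak* when -3 is a pyrimidine (C/U) and +4 is not G. *optimal* (the
#' full vertebrate GCCRCCAUGG context) is returned instead of strong only
#' when at least six upstream nucleotides are available and positions
#' -6..-1 read GCCRCC with R = A/G; with shorter flanks optimality cannot
#' be established and strong is reported.
#'
#' @param contexts A [TISContext-class] object, or a character vector of
#'   TIS windows ending at position +4 (`<upstream>AUG<+4>`, DNA or RNA).
#' @return Factor with levels `optimal`, `strong`, `moderate`, `weak`.
#' @examples
#' classifyKozak(c("GAAAUGG", "CAAAUGG", "CAAAUGA", "GCCACCAUGG"))
#' @export
classifyKozak <- function(contexts) {
  p <- checkClassifiable(contextParts(contexts))
  strong <- p$minus3 %in% c("A", "G") & p$plus4 == "G"
  moderate <- xor(p$minus3 %in% c("A", "G"), p$plus4 == "G")
  cls <- ifelse(strong, "strong", ifelse(moderate, "moderate", "weak"))
  canOpt <- p$nUp >= 6L
  if (any(canOpt)) {
    up6 <- substr(p$upstream, p$nUp - 5L, p$nUp)
    opt <- canOpt & strong & grepl("^GCC[AG]CC$", up6)
    cls[opt] <- "optimal"
  }
  factor(cls, levels = KOZAK_LEVELS)
}

#' Seven-nucleotide core of a TIS context
#'
#' The concatenation of positions -3..-1, the codon, and +4 — the window
#' in which the eight BACS are defined.
#'
#' @inheritParams classifyKozak
#' @return Character vector of 7-mers (RNA alphabet).
#' @export
sevenMer <- function(contexts) {
  p <- checkClassifiable(contextParts(contexts))
  paste0(p$minus3, p$minus2, p$minus1, p$codon, p$plus4)
}

#' Is a context one of the eight barren AUG context sequences?
#'
#' Exact lookup of the 7-mer (-3..-1, AUG, +4) against the eight conserved
#' translation-disfavouring sequences ([bacsSequences()]). BACS membership
#' is an exact-sequence property, not a degenerate pattern: the eight
#' sequences are not expressible as a single IUPAC word.
#'
#' @inheritParams classifyKozak
#' @return Logical vector.
#' @examples
#' isBacs(c("CCAAUGU", "GCCAUGG"))
#' @export
isBacs <- function(contexts) sevenMer(contexts) %in% BACS_SEQUENCES

readFixture <- function(file, expectedMd5, checksum) {
  if (checksum) {
    got <- unname(md5sum(file))
    if (!identical(got, expectedMd5))
      stop("fixture checksum mismatch for ", basename(file),
           " (expected ", expectedMd5, ", got ", got, ")", call. = FALSE)
  }
  read.delim(file, stringsAsFactors = FALSE)
}

#' Load the assayed TIS-context panel
#'
#' Returns the 160-row panel of assayed start-codon contexts: integer id,
#' the four variable nucleotides (-3, -2, -1, +4), the printed Kozak class
#' mark, the BACS mark, and a `tested` flag (`FALSE` for the ten rows not
#' tested). The bundled fixture is checksummed on load.
#'
#' @param file Path to a panel TSV; default the bundled fixture.
#' @return A data.frame with columns `id`, `minus3`, `minus2`, `minus1`,
#'   `plus4`, `kozak`, `bacs`, `tested` and derived `sevenmer`.
#' @examples
#' tab1 <- loadTable1()
#' subset(tab1, bacs)$sevenmer
#' @export
loadTable1 <- function(file = NULL) {
  bundled <- is.null(file)
  if (bundled)
    file <- system.file("extdata", "table1_contexts.tsv", package = "bacscan",
                        mustWork = TRUE)
  tab <- readFixture(file, TABLE1_MD5, checksum = bundled)
  need <- c("id", "minus3", "minus2", "minus1", "plus4", "kozak", "bacs",
            "tested")
  if (!all(need %in% names(tab)))
    stop("panel table must have columns ", paste(need, collapse = ", "))
  tab$sevenmer <- paste0(tab$minus3, tab$minus2, tab$minus1, "AUG", tab$plus4)
  tab
}

#' Load the per-species bottom-20% context lists
#'
#' The least efficient 20% of assayed contexts per species, ordered from
#' the best to the least efficient, twelve entries per species (rabbit,
#' fruit fly, wheat).
#'
#' @param file Path to a TSV with columns `species`, `rank`, `id`,
#'   `sequence`; default the bundled fixture (checksummed on load).
#' @return A data.frame with those columns.
#' @export
loadTable2 <- function(file = NULL) {
  bundled <- is.null(file)
  if (bundled)
    file <- system.file("extdata", "table2_bottom20.tsv", package = "bacscan",
                        mustWork = TRUE)
  tab <- readFixture(file, TABLE2_MD5, checksum = bundled)
  need <- c("species", "rank", "id")
  if (!all(need %in% names(tab)))
    stop("bottom-list table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Intersect per-species bottom lists
#'
#' Order-independent set intersection of context ids across two or more
#' bottom lists; applied to the three-species bottom-20% lists this
#' recovers the eight BACS ids.
#'
#' @param lists Either a data.frame as returned by [loadTable2()] (split
#'   by its `species` column) or a list of integer id vectors.
#' @return Sorted integer vector of ids common to every list.
#' @examples
#' intersectBottomLists(loadTable2())
#' @export
intersectBottomLists <- function(lists) {
  if (is.data.frame(lists)) {
    if (!all(c("species", "id") %in% names(lists)))
      stop("data.frame input must have columns species and id")
    lists <- split(lists$id, lists$species)
  }
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least two bottom lists to intersect")
  sort(as.integer(Reduce(intersect, lists)))
}
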