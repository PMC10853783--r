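#' @include AllClasses.R contexts.R motif.R
NULL

# reverse complement of a short DNA string (base-R, for small windows)
revcompChr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

firstChar <- function(x) vapply(strsplit(x, " ", fixed = TRUE), `[`, "", 1L)

# CDS/exon table from an imported GFF3 GRanges, one row per (segment,
# parent) pair
featureTable <- function(gr, types) {
  sel <- gr[as.character(gr$type) %in% types]
  if (!length(sel))
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      parent = character(0)))
  parents <- mcols(sel)$Parent
  np <- lengths(parents)
  idx <- rep(seq_along(sel), np)
  data.frame(seqid = as.character(seqnames(sel))[idx],
             start = start(sel)[idx], end = end(sel)[idx],
             strand = as.character(strand(sel))[idx],
             parent = unlist(parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# first `need` spliced bases of a CDS (transcript orientation);
# segs is a data.frame ordered in transcript orientation
splicedPrefix <- function(segs, contig, need = 4L) {
  out <- ""
  joined <- FALSE
  for (i in seq_len(nrow(segs))) {
    if (nchar(out) >= need) break
    if (i > 1L) joined <- TRUE
    take <- need - nchar(out)
    w <- segs$end[i] - segs$start[i] + 1L
    take <- min(take, w)
    if (segs$strand[i] == "+") {
      piece <- substr(contig, segs$start[i], segs$start[i] + take - 1L)
    } else {
      piece <- revcompChr(substr(contig, segs$end[i] - take + 1L,
                                 segs$end[i]))
    }
    out <- paste0(out, piece)
  }
  list(seq = out, joined = joined)
}

#' Extract start-codon contexts genome-wide
#'
#' Reads a genome FASTA and its GFF3 annotation and emits, per gene, the
#' start codon plus three bases upstream and one downstream, in
#' transcript orientation (minus-strand genes are reverse-complemented so
#' the upstream flank is 5' of the codon). The +4 base is the first
#' coding base after the codon and is drawn from the next CDS segment
#' when the codon abuts an intron (flag `joined_over_intron`). Genes
#' whose upstream flank runs past the contig edge are flagged
#' `truncated_upstream`, annotated non-AUG starts are flagged
#' `non_aug_start`; flagged genes carry no context and are excluded from
#' pattern counts.
#'
#' @param fastaFile Genome FASTA (plain or gzip).
#' @param gffFile GFF3 annotation with gene/mRNA/CDS features.
#' @param policy Which transcript represents a gene:
#'   `"longest_mrna"` (default; the mRNA with the longest total CDS,
#'   ties broken by transcript id), `"per_transcript"` (one record per
#'   mRNA) or `"per_unique_context"` (one record per distinct context per
#'   gene).
#' @param spliced If `TRUE`, take the upstream flank from the spliced
#'   transcript (annotated 5'UTR exons) instead of the genomic bases
#'   immediately 5' of the start codon.
#' @return data.frame with columns `gene_id`, `transcript_id`, `seq_id`,
#'   `strand`, `start_codon_coord` (1-based genomic coordinate of the A
#'   of AUG on the sense strand), `context` (RNA 7-mer, NA when flagged),
#'   `kozak`, `bacs`, `flags` (comma-separated) and `ok`.
#' @export
extractTisContexts <- function(fastaFile, gffFile,
                               policy = c("longest_mrna", "per_transcript",
                                          "per_unique_context"),
                               spliced = FALSE) {
  policy <- match.arg(policy)
  genome <- readDNAStringSet(fastaFile)
  names(genome) <- firstChar(names(genome))
  contigs <- as.character(genome)
  gff <- rtracklayer::import(gffFile, format = "gff3")

  genes <- gff[as.character(gff$type) == "gene"]
  geneIds <- as.character(mcols(genes)$ID)
  mrna <- gff[as.character(gff$type) %in% c("mRNA", "transcript")]
  mrnaIds <- as.character(mcols(mrna)$ID)
  mrnaGene <- vapply(mcols(mrna)$Parent, `[`, "", 1L)
  cdsTab <- featureTable(gff, "CDS")
  exonTab <- featureTable(gff, "exon")

  missingSeq <- setdiff(unique(cdsTab$seqid), names(contigs))
  if (length(missingSeq))
    stop("missing sequence for feature(s) on: ",
         paste(missingSeq, collapse = ", "))

  cdsByTx <- split(cdsTab, cdsTab$parent)
  exonByTx <- split(exonTab, exonTab$parent)
  cdsLen <- vapply(cdsByTx, function(d) sum(d$end - d$start + 1L), 0)

  txWithCds <- mrnaIds[mrnaIds %in% names(cdsByTx)]
  if (policy == "longest_mrna") {
    byGene <- split(txWithCds, mrnaGene[match(txWithCds, mrnaIds)])
    chosen <- vapply(byGene, function(tx) {
      len <- cdsLen[tx]
      tx[order(-len, tx)][1L]
    }, "")
  } else {
    chosen <- txWithCds
  }

  rows <- vector("list", length(chosen))
  for (j in seq_along(chosen)) {
    tx <- chosen[j]
    segs <- cdsByTx[[tx]]
    minus <- segs$strand[1L] == "-"
    segs <- segs[order(if (minus) -segs$end else segs$start), ,
                 drop = FALSE]
    contig <- contigs[[segs$seqid[1L]]]
    clen <- nchar(contig)
    flags <- character(0)

    pre <- splicedPrefix(segs, contig, 4L)
    if (nchar(pre$seq) < 4L) flags <- c(flags, "truncated_downstream")
    if (pre$joined) flags <- c(flags, "joined_over_intron")
    codonDna <- substr(pre$seq, 1L, 3L)
    plus4 <- substr(pre$seq, 4L, 4L)
    if (nchar(codonDna) == 3L && codonDna != "ATG")
      flags <- c(flags, "non_aug_start")

    coord <- if (minus) segs$end[1L] else segs$start[1L]
    upDna <- NA_character_
    if (spliced) {
      ex <- exonByTx[[tx]]
      upDna <- splicedUpstream(ex, segs, contig, minus)
      if (is.na(upDna)) flags <- c(flags, "truncated_upstream")
    } else {
      if (minus) {
        if (coord + 3L > clen) flags <- c(flags, "truncated_upstream")
        else upDna <- revcompChr(substr(contig, coord + 1L, coord + 3L))
      } else {
        if (coord - 3L < 1L) flags <- c(flags, "truncated_upstream")
        else upDna <- substr(contig, coord - 3L, coord - 1L)
      }
    }

    excluded <- any(flags %in% c("truncated_upstream",
                                 "truncated_downstream", "non_aug_start"))
    context <- if (excluded) NA_character_
               else normalizeSeq(paste0(upDna, codonDna, plus4))
    rows[[j]] <- data.frame(
      gene_id = if (policy == "longest_mrna") names(chosen)[j]
                else unname(mrnaGene[match(tx, mrnaIds)]),
      transcript_id = tx, seq_id = segs$seqid[1L],
      strand = if (minus) "-" else "+",
      start_codon_coord = coord, context = context,
      flags = paste(sort(flags), collapse = ","), ok = !excluded,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$transcript_id), , drop = FALSE]
  if (policy == "per_unique_context")
    out <- out[!duplicated(out[, c("gene_id", "context")]), , drop = FALSE]
  rownames(out) <- NULL
  out$kozak <- NA_character_
  out$bacs <- NA
  if (any(out$ok)) {
    out$kozak[out$ok] <- as.character(classifyKozak(out$context[out$ok]))
    out$bacs[out$ok] <- isBacs(out$context[out$ok])
  }
  out
}

# upstream 3 bases through the spliced transcript; NA when fewer than 3
# transcript bases precede the CDS start
splicedUpstream <- function(ex, segs, contig, minus) {
  if (is.null(ex) || !nrow(ex)) return(NA_character_)
  ex <- ex[order(if (minus) -ex$end else ex$start), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(ex)), function(i) {
    s <- substr(contig, ex$start[i], ex$end[i])
    if (minus) revcompChr(s) else s
  }, "")
  txSeq <- paste(pieces, collapse = "")
  # transcript offset of the CDS start (1-based)
  cstart <- if (minus) segs$end[1L] else segs$start[1L]
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i] + 1L
    inside <- cstart >= ex$start[i] && cstart <= ex$end[i]
    if (inside) {
      off <- off + if (minus) ex$end[i] - cstart + 1L
                   else cstart - ex$start[i] + 1L
      break
    }
    off <- off + w
    if (i == nrow(ex)) return(NA_character_)  # CDS start not in exons
  }
  if (off - 3L < 1L) return(NA_character_)
  substr(txSeq, off - 3L, off - 1L)
}

#' Scan extracted contexts for motifs and exact sequences
#'
#' Tests every non-flagged gene context against each degenerate pattern
#' and, optionally, against a set of exact 7-mers (e.g.
#' [bacsSequences()]); flagged genes are excluded from counts.
#'
#' @param records Output of [extractTisContexts()].
#' @param patterns List (or character vector) of anchored IUPAC patterns.
#' @param exactSet Optional character vector of exact 7-mers.
#' @return List with `hits` (per-gene data.frame, one logical column per
#'   pattern plus `exact` when requested) and `counts` (pattern, count).
#' @export
scanContexts <- function(records, patterns = list("YCMAUGY"),
                         exactSet = NULL) {
  if (is.character(patterns)) patterns <- as.list(patterns)
  hits <- records
  labels <- character(0)
  for (p in patterns) {
    mp <- if (is.character(p)) parsePattern(p) else p
    lab <- patternString(mp)
    labels <- c(labels, lab)
    col <- rep(NA, nrow(records))
    col[records$ok] <- matchesPattern(mp, records$context[records$ok])
    hits[[lab]] <- col
  }
  if (!is.null(exactSet)) {
    exactSet <- normalizeSeq(exactSet)
    col <- rep(NA, nrow(records))
    col[records$ok] <- records$context[records$ok] %in% exactSet
    hits[["exact"]] <- col
    labels <- c(labels, "exact")
  }
  counts <- data.frame(pattern = labels,
                       count = vapply(labels, function(l)
                         sum(hits[[l]], na.rm = TRUE), 0L),
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(hits = hits, counts = counts)
}

#' Read a gene-to-GO mapping TSV
#'
#' Two tab-separated columns, `gene_id` and `go_id`; a gene may appear on
#' several lines. A header line is optional. Malformed lines raise an
#' error naming the line number.
#'
#' @param file Path to the TSV.
#' @return data.frame with columns `gene_id`, `go_id`.
#' @export
readGene2GO <- function(file) {
  parseTwoColumnTsv(file, c("gene_id", "go_id"))
}

#' Read a GO-to-category binning map
#'
#' Two tab-separated columns, `go_id` and `category`. File order defines
#' category priority for genes annotated with several GO ids. A seed map
#' covering the usual bins (membrane component, complexes, enzymes,
#' mitochondrion, ER, cation binding, Golgi, cell movement, ADP/ATP
#' binding, DNA/RNA binding) ships in
#' `system.file("extdata", "go_category_map.tsv", package = "bacscan")`.
#'
#' @param file Path to the TSV; default the bundled seed map.
#' @return data.frame with columns `go_id`, `category`.
#' @export
readCategoryMap <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "go_category_map.tsv",
                        package = "bacscan", mustWork = TRUE)
  parseTwoColumnTsv(file, c("go_id", "category"))
}

parseTwoColumnTsv <- function(file, cols) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", basename(file),
         ": expected two tab-separated fields")
  tab <- data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- cols
  if (identical(unname(unlist(tab[1L, ])), cols))
    tab <- tab[-1L, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Bin pattern-hit genes by gene-ontology category
#'
#' Each gene hitting the chosen pattern is binned exactly once: among its
#' mapped GO ids, the category whose GO id appears earliest in the
#' category map wins; genes with no mapped annotation fall into
#' `"diverse"`. Fractions are over all hit genes and sum to 1.
#'
#' @param hits Per-gene hit table from [scanContexts()].
#' @param gene2go Mapping data.frame from [readGene2GO()].
#' @param categoryMap Binning data.frame from [readCategoryMap()].
#' @param pattern Name of the hit column to summarise; default the first
#'   pattern column.
#' @return data.frame with `category`, `gene_count`, `fraction`, sorted
#'   by count (descending).
#' @export
summarizeGO <- function(hits, gene2go, categoryMap, pattern = NULL) {
  patCols <- setdiff(names(hits),
                     c("gene_id", "transcript_id", "seq_id", "strand",
                       "start_codon_coord", "context", "flags", "ok",
                       "kozak", "bacs"))
  if (is.null(pattern)) {
    if (!length(patCols)) stop("hit table has no pattern columns")
    pattern <- patCols[1L]
  }
  if (!pattern %in% names(hits))
    stop("no hit column named ", pattern)
  genes <- hits$gene_id[which(hits[[pattern]])]
  if (!length(genes))
    return(data.frame(category = character(0), gene_count = integer(0),
                      fraction = numeric(0)))
  prio <- setNames(seq_len(nrow(categoryMap)), categoryMap$go_id)
  cat <- vapply(genes, function(g) {
    gos <- gene2go$go_id[gene2go$gene_id == g]
    ranks <- prio[gos]
    ranks <- ranks[!is.na(ranks)]
    if (!length(ranks)) "diverse"
    else categoryMap$category[min(ranks)]
  }, "", USE.NAMES = FALSE)
  counts <- sort(table(cat), decreasing = TRUE)
  data.frame(category = names(counts),
             gene_count = as.integer(counts),
             fraction = as.numeric(counts) / length(genes),
             stringsAsFactors = FALSE)
}
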