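# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
exactRankSumP <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  picks <- combn(length(pooled), na)
  us <- apply(picks, 2L, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  pl <- mean(us <= uObs)
  pg <- mean(us >= uObs)
  min(1, 2 * min(pl, pg))
}

# scalar evaluation of the enrichment statistic for one cell
scalarEnrichment <- function(pSet, pBack) {
  if (pSet == 0) return(0)
  pSet * log2(pSet / pBack)
}

# all 256 concrete -3..+4 context 7-mers
allContexts256 <- function() {
  b <- c("A", "C", "G", "U")
  g <- expand.grid(m3 = b, m2 = b, m1 = b, p4 = b,
                   stringsAsFactors = FALSE)
  paste0(g$m3, g$m2, g$m1, "AUG", g$p4)
}

# write a small genome + GFF3 by hand (1-based inclusive coordinates)
writeHandGenome <- function(contigs, features, dir = tempfile("hand")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fasta")
  writeLines(unlist(lapply(names(contigs), function(n)
    c(paste0(">", n), contigs[[n]]))), fasta)
  gff <- file.path(dir, "genome.gff3")
  lines <- "##gff-version 3"
  for (f in features) {
    attrs <- if (is.na(f$parent)) paste0("ID=", f$id)
             else paste0("ID=", f$id, ";Parent=", f$parent)
    lines <- c(lines, paste(f$seqid, "test", f$type, f$start, f$end, ".",
                            f$strand, if (f$type == "CDS") "0" else ".",
                            attrs, sep = "\t"))
  }
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff)
}

# gene/mRNA/CDS feature triple for a single-exon CDS
geneFeatures <- function(gid, seqid, start, end, strand) {
  list(list(seqid = seqid, type = "gene", start = start, end = end,
            strand = strand, id = gid, parent = NA),
       list(seqid = seqid, type = "mRNA", start = start, end = end,
            strand = strand, id = paste0(gid, ".t1"), parent = gid),
       list(seqid = seqid, type = "CDS", start = start, end = end,
            strand = strand, id = paste0(gid, ".c1"),
            parent = paste0(gid, ".t1")))
}

revcompStr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
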