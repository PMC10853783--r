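test_that("a plus-strand start codon context is read off the contig", {
  # contig AACCAATGCTTG, CDS at 6..11: upstream CCA, codon ATG, +4 C
  hg <- writeHandGenome(list(chr1 = "AACCAATGCTTG"),
                        geneFeatures("g1", "chr1", 6, 11, "+"))
  rec <- extractTisContexts(hg$fasta, hg$gff)
  expect_equal(rec$context, "CCAAUGC")
  expect_equal(rec$start_codon_coord, 6)
  expect_equal(rec$kozak, "weak")
  expect_true(rec$ok)
})

test_that("minus-strand genes give the identical context after revcomp", {
  fwd <- "AACCAATGCTTG"
  rev <- revcompStr(fwd)  # CDS 6..11 maps to 2..7 on the reverse
  hg <- writeHandGenome(list(chr1 = rev),
                        geneFeatures("g1", "chr1", 2, 7, "-"))
  rec <- extractTisContexts(hg$fasta, hg$gff)
  expect_equal(rec$context, "CCAAUGC")
  expect_equal(rec$strand, "-")
  expect_equal(rec$start_codon_coord, 7)
})

test_that("contig-edge start codons are flagged and excluded", {
  hg <- writeHandGenome(list(chr1 = "CATGCTTGAA"),
                        geneFeatures("g1", "chr1", 2, 7, "+"))
  rec <- extractTisContexts(hg$fasta, hg$gff)
  expect_match(rec$flags, "truncated_upstream")
  expect_false(rec$ok)
  expect_true(is.na(rec$context))
})

test_that("annotated non-AUG starts are flagged and excluded", {
  hg <- writeHandGenome(list(chr1 = "AACCAGTGCTTG"),
                        geneFeatures("g1", "chr1", 6, 11, "+"))
  rec <- extractTisContexts(hg$fasta, hg$gff)
  expect_match(rec$flags, "non_aug_start")
  expect_false(rec$ok)
})

test_that("the +4 base is drawn across an intron when the codon ends one", {
  # CDS1 = ATG at 4..6, intron 7..14, CDS2 from 15: +4 = base 15 (G)
  contig <- "CCCATGGTTTTTAGGAATAA"
  feats <- c(geneFeatures("g1", "chr1", 4, 6, "+")[1:2],
             list(list(seqid = "chr1", type = "CDS", start = 4, end = 6,
                       strand = "+", id = "g1.c1", parent = "g1.t1"),
                  list(seqid = "chr1", type = "CDS", start = 15, end = 20,
                       strand = "+", id = "g1.c2", parent = "g1.t1")))
  feats[[1]]$end <- 20; feats[[2]]$end <- 20
  hg <- writeHandGenome(list(chr1 = contig), feats)
  rec <- extractTisContexts(hg$fasta, hg$gff)
  expect_equal(rec$context, "CCCAUGG")
  expect_match(rec$flags, "joined_over_intron")
  expect_true(rec$ok)
})

test_that("the longest mRNA represents a gene, other policies differ", {
  contig <- "AACCAATGCTTGGGGGGGGG"
  feats <- list(
    list(seqid = "chr1", type = "gene", start = 6, end = 20, strand = "+",
         id = "g1", parent = NA),
    list(seqid = "chr1", type = "mRNA", start = 6, end = 11, strand = "+",
         id = "t1", parent = "g1"),
    list(seqid = "chr1", type = "CDS", start = 6, end = 11, strand = "+",
         id = "c1", parent = "t1"),
    list(seqid = "chr1", type = "mRNA", start = 6, end = 20, strand = "+",
         id = "t2", parent = "g1"),
    list(seqid = "chr1", type = "CDS", start = 6, end = 20, strand = "+",
         id = "c2", parent = "t2"))
  hg <- writeHandGenome(list(chr1 = contig), feats)
  rec <- extractTisContexts(hg$fasta, hg$gff)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$transcript_id, "t2")  # longer CDS wins
  perTx <- extractTisContexts(hg$fasta, hg$gff, policy = "per_transcript")
  expect_equal(nrow(perTx), 2L)
  uniq <- extractTisContexts(hg$fasta, hg$gff,
                             policy = "per_unique_context")
  expect_equal(nrow(uniq), 1L)  # both transcripts share the context
})

test_that("missing contigs are reported by name", {
  hg <- writeHandGenome(list(chr1 = "AACCAATGCTTG"),
                        geneFeatures("g1", "chrMISSING", 6, 11, "+"))
  expect_error(extractTisContexts(hg$fasta, hg$gff), "chrMISSING")
})

test_that("pattern counts equal the motif-module oracle", {
  sim <- simulateToyGenome(300, seed = 13)
  rec <- extractTisContexts(sim$fasta, sim$gff)
  scan <- scanContexts(rec, c("YCMAUGY", "RNNAUGG"),
                       exactSet = bacsSequences())
  okCtx <- rec$context[rec$ok]
  for (pat in c("YCMAUGY", "RNNAUGG")) {
    want <- sum(okCtx %in% expandPattern(parsePattern(pat)))
    expect_equal(scan$counts$count[scan$counts$pattern == pat], want)
  }
  expect_equal(scan$counts$count[scan$counts$pattern == "exact"],
               sum(okCtx %in% bacsSequences()))
  # flagged genes carry NA hits and are excluded from counts
  expect_true(all(is.na(scan$hits$YCMAUGY[!scan$hits$ok])))
  # empty pattern list gives an empty counts table
  empty <- scanContexts(rec, list())
  expect_equal(nrow(empty$counts), 0L)
})

test_that("scans are deterministic across repeated runs", {
  sim <- simulateToyGenome(60, seed = 17)
  a <- scanContexts(extractTisContexts(sim$fasta, sim$gff), "YCMAUGY")
  b <- scanContexts(extractTisContexts(sim$fasta, sim$gff), "YCMAUGY")
  expect_identical(a, b)
})

test_that("GO binning assigns each hit gene exactly one category", {
  hits <- data.frame(gene_id = sprintf("g%02d", 1:10), ok = TRUE,
                     YCMAUGY = TRUE)
  g2g <- data.frame(gene_id = c("g01", "g02", "g03"),
                    go_id = c("GO:0016021", "GO:0016021", "GO:0005739"))
  cmap <- readCategoryMap()
  go <- summarizeGO(hits, g2g, cmap, pattern = "YCMAUGY")
  expect_equal(go$gene_count[go$category == "membrane_component"], 2L)
  expect_equal(go$fraction[go$category == "membrane_component"], 0.2)
  expect_equal(go$gene_count[go$category == "diverse"], 7L)
  expect_equal(sum(go$fraction), 1.0)
  # empty hit set gives an empty summary
  none <- hits; none$YCMAUGY <- FALSE
  expect_equal(nrow(summarizeGO(none, g2g, cmap, "YCMAUGY")), 0L)
  # earlier map rows take priority for multi-GO genes
  g2g2 <- data.frame(gene_id = "g01", go_id = c("GO:0003677", "GO:0016021"))
  go2 <- summarizeGO(hits[1, ], g2g2, cmap, "YCMAUGY")
  expect_equal(go2$category[1], "membrane_component")
})

test_that("malformed annotation mappings report the line number", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tgo_id", "g1\tGO:1", "brokenline"), f)
  expect_error(readGene2GO(f), "line 3")
})

test_that("spliced upstream extraction uses annotated 5'UTR exons", {
  # exon1 1..4 (UTR), intron, exon2 9..20 containing UTR base + CDS 11..
  #            CCAG    ....    gTATGGGGGGGG
  contig <- "CCAGTTTTGTATGGGGGGGG"
  feats <- list(
    list(seqid = "chr1", type = "gene", start = 1, end = 20, strand = "+",
         id = "g1", parent = NA),
    list(seqid = "chr1", type = "mRNA", start = 1, end = 20, strand = "+",
         id = "t1", parent = "g1"),
    list(seqid = "chr1", type = "exon", start = 1, end = 4, strand = "+",
         id = "e1", parent = "t1"),
    list(seqid = "chr1", type = "exon", start = 9, end = 20, strand = "+",
         id = "e2", parent = "t1"),
    list(seqid = "chr1", type = "CDS", start = 11, end = 20, strand = "+",
         id = "c1", parent = "t1"))
  hg <- writeHandGenome(list(chr1 = contig), feats)
  genomic <- extractTisContexts(hg$fasta, hg$gff)
  expect_equal(genomic$context, "UGUAUGG")  # bases 8-10 are intronic TGT
  spliced <- extractTisContexts(hg$fasta, hg$gff, spliced = TRUE)
  # the spliced transcript CCAG|GTATG... puts GGT before the codon
  expect_equal(spliced$context, "GGUAUGG")
})
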