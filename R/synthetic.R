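#' @include AllClasses.R contexts.R expression.R
NULL

POSITION_ROWS <- c("-3", "-2", "-1", "+4")

#' SimulationParams: knobs of the synthetic dual-luciferase assay
#'
#' Per-well log10 activity is
#' `baseline(species) + sum(position effects) + bacsPenalty * [7-mer in
#' barren set] + Normal(0, noiseSd)`; raw FLuc is `10^activity` scaled by
#' the plate's realised control level, so noise is multiplicative
#' (log-normal) on the raw scale, as reporter light units are.
#'
#' @slot speciesBaseline named numeric, log10 activity offset per species.
#' @slot positionEffects numeric matrix (rows `-3`, `-2`, `-1`, `+4`;
#'   columns A/C/G/U) of additive log10 effects.
#' @slot bacsPenalty additive log10 effect applied to the barren set.
#' @slot barrenSet character 7-mers receiving the penalty.
#' @slot noiseSd standard deviation of the log10 noise (>= 0).
#' @slot replicates wells per context (>= 1; default 3, the triplicate
#'   design).
#' @slot plateControlMean,plateControlCv Renilla control level and its
#'   log-scale coefficient of variation.
#' @slot plateCapacity contexts per 96-well plate (with triplicates and
#'   control wells, 30).
#' @slot seed integer; output is fully determined by it.
#' @aliases SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
         representation(speciesBaseline = "numeric",
                        positionEffects = "matrix",
                        bacsPenalty = "numeric", barrenSet = "character",
                        noiseSd = "numeric", replicates = "integer",
                        plateControlMean = "numeric",
                        plateControlCv = "numeric",
                        plateCapacity = "integer", seed = "integer"))

setValidity("SimulationParams", function(object) {
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (is.null(names(object@speciesBaseline)))
    return("speciesBaseline must be named by species")
  pe <- object@positionEffects
  if (!identical(rownames(pe), POSITION_ROWS) ||
      !identical(colnames(pe), RNA_BASES))
    return("positionEffects must be a matrix with rows -3,-2,-1,+4 and columns A,C,G,U")
  if (object@plateControlMean <= 0) return("plateControlMean must be > 0")
  TRUE
})

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", length(object@speciesBaseline), "species,",
      object@replicates, "replicates, noiseSd =", object@noiseSd,
      ", bacsPenalty =", object@bacsPenalty, ", seed =", object@seed, "\n")
})

#' Construct simulation parameters
#'
#' @param speciesBaseline Named numeric, log10 baseline per species.
#' @param positionEffects Matrix of additive log10 effects (rows `-3`,
#'   `-2`, `-1`, `+4`; columns A/C/G/U); default all zero.
#' @param bacsPenalty Additive log10 effect for the barren set; default 0.
#' @param barrenSet Character 7-mers; default [bacsSequences()].
#' @param noiseSd Log10 noise SD; default 0.
#' @param replicates Wells per context; default 3.
#' @param plateControlMean,plateControlCv Control RLuc level (default
#'   1e5) and log-scale CV (default 0.1).
#' @param plateCapacity Contexts per plate; default 30.
#' @param seed Integer seed; default 1.
#' @return A [SimulationParams-class].
#' @export
simulationParams <- function(speciesBaseline = c(rabbit = 0),
                             positionEffects = NULL, bacsPenalty = 0,
                             barrenSet = bacsSequences(), noiseSd = 0,
                             replicates = 3L, plateControlMean = 1e5,
                             plateControlCv = 0.1, plateCapacity = 30L,
                             seed = 1L) {
  if (is.null(positionEffects))
    positionEffects <- matrix(0, 4L, 4L,
                              dimnames = list(POSITION_ROWS, RNA_BASES))
  new("SimulationParams", speciesBaseline = speciesBaseline,
      positionEffects = positionEffects, bacsPenalty = bacsPenalty,
      barrenSet = normalizeSeq(barrenSet), noiseSd = noiseSd,
      replicates = as.integer(replicates),
      plateControlMean = plateControlMean,
      plateControlCv = plateControlCv,
      plateCapacity = as.integer(plateCapacity), seed = as.integer(seed))
}

#' Preset emulating the structure of the real assay
#'
#' Position effects favour a purine at -3 (A strongest) and G at +4, the
#' eight BACS carry a log10(1/25) penalty, and wells have 0.15 log10
#' multiplicative noise. The preset produces a strong-over-weak class
#' separation of the same order as the real reporter data
#' (top-20%/bottom-20% activity ratios in the hundreds to thousands)
#' without claiming to reproduce any measured value.
#'
#' @param species Character vector of species to simulate.
#' @param seed Integer seed.
#' @return A [SimulationParams-class].
#' @export
paperlikeParams <- function(species = c("rabbit", "fruit_fly", "wheat",
                                        "yeast"), seed = 1L) {
  pe <- matrix(0, 4L, 4L, dimnames = list(POSITION_ROWS, RNA_BASES))
  pe["-3", ] <- c(A = 1.4, C = 0, G = 1.0, U = 0.1)
  pe["-2", ] <- c(A = 0.1, C = 0.2, G = 0, U = 0)
  pe["-1", ] <- c(A = 0.1, C = 0.1, G = 0, U = 0)
  pe["+4", ] <- c(A = 0.2, C = 0, G = 0.8, U = 0)
  simulationParams(speciesBaseline = setNames(rep(0, length(species)),
                                              species),
                   positionEffects = pe, bacsPenalty = log10(1 / 25),
                   noiseSd = 0.15, seed = seed)
}

# noise-free log10 activity per 7-mer
expectedLog10 <- function(sevenmers, params) {
  m3 <- substr(sevenmers, 1L, 1L)
  m2 <- substr(sevenmers, 2L, 2L)
  m1 <- substr(sevenmers, 3L, 3L)
  p4 <- substr(sevenmers, 7L, 7L)
  pe <- params@positionEffects
  pe["-3", m3] + pe["-2", m2] + pe["-1", m1] + pe["+4", p4] +
    params@bacsPenalty * (sevenmers %in% params@barrenSet)
}

#' Simulate a multi-plate dual-luciferase assay
#'
#' Generates per-well firefly measurements for every (context, species)
#' pair in `replicates` wells, laid out on plates of `plateCapacity`
#' contexts, each plate with its own Renilla control readings. Raw FLuc
#' is the context's expected activity times the plate's realised control
#' level times log-normal well noise, so [normalizePlates()] recovers
#' activities on a common scale. Output is fully determined by the seed.
#'
#' @param contexts Context panel: a data.frame with columns `id` and
#'   `sevenmer` (e.g. from [loadTable1()]), or a character vector of
#'   7-mers.
#' @param params A [SimulationParams-class].
#' @return List with `records` (well table), `controls` (plate control
#'   table) and `truth` (per-context expected normalised activity at zero
#'   noise, with the 7-mer).
#' @examples
#' p <- simulationParams(bacsPenalty = log10(1 / 25))
#' sim <- simulateAssay(loadTable1()[loadTable1()$tested, ], p)
#' head(sim$records)
#' @export
simulateAssay <- function(contexts, params) {
  if (is.character(contexts))
    contexts <- data.frame(id = seq_along(contexts),
                           sevenmer = normalizeSeq(contexts),
                           stringsAsFactors = FALSE)
  if (!nrow(contexts)) stop("context list is empty")
  if (is.null(contexts$sevenmer))
    stop("contexts must carry a sevenmer column or be 7-mer strings")
  set.seed(params@seed)
  species <- names(params@speciesBaseline)
  la0 <- expectedLog10(contexts$sevenmer, params)

  recs <- list(); ctls <- list(); truth <- list()
  for (sp in species) {
    laSp <- la0 + params@speciesBaseline[[sp]]
    nPlate <- ceiling(nrow(contexts) / params@plateCapacity)
    plateOf <- rep(seq_len(nPlate), each = params@plateCapacity,
                   length.out = nrow(contexts))
    plateIds <- sprintf("%s_p%02d", sp, seq_len(nPlate))
    rluc <- params@plateControlMean *
      exp(rnorm(3L * nPlate, 0, params@plateControlCv))
    ctl <- data.frame(plate_id = rep(plateIds, each = 3L),
                      rluc_raw = rluc, stringsAsFactors = FALSE)
    plateLevel <- tapply(ctl$rluc_raw, ctl$plate_id, mean)[plateIds]

    nWell <- nrow(contexts) * params@replicates
    noise <- if (params@noiseSd > 0) rnorm(nWell, 0, params@noiseSd)
             else numeric(nWell)
    idx <- rep(seq_len(nrow(contexts)), times = params@replicates)
    rep_no <- rep(seq_len(params@replicates),
                  each = nrow(contexts))
    recs[[sp]] <- data.frame(
      context_id = contexts$id[idx], species = sp,
      plate_id = plateIds[plateOf[idx]],
      replicate = rep_no,
      fluc_raw = 10^(laSp[idx] + noise) *
        as.numeric(plateLevel[plateOf[idx]]),
      stringsAsFactors = FALSE)
    ctls[[sp]] <- ctl
    truth[[sp]] <- data.frame(context_id = contexts$id, species = sp,
                              sevenmer = contexts$sevenmer,
                              expected = 10^laSp,
                              stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
       controls = do.call(rbind, c(ctls, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Planted (closed-form) quantities of a simulated assay
#'
#' Computed from the truth table at zero noise: the fold change a motif
#' comparison should recover, and the top/bottom percentile ratio.
#'
#' @param truth Truth table from [simulateAssay()].
#' @param pattern,exactSet Matching rule as in [motifFoldChange()].
#' @param species Species to evaluate; default the first in the table.
#' @return Numeric scalar.
#' @rdname plantedTruth
#' @export
plantedFoldChange <- function(truth, pattern = NULL, exactSet = NULL,
                              species = truth$species[1L]) {
  t <- truth[truth$species == species, ]
  hit <- if (!is.null(exactSet)) t$sevenmer %in% normalizeSeq(exactSet)
         else matchesPattern(pattern, t$sevenmer)
  mean(t$expected[!hit]) / mean(t$expected[hit])
}

#' @param fraction Percentile fraction; default 0.2.
#' @rdname plantedTruth
#' @export
plantedTopBottomRatio <- function(truth, fraction = 0.2,
                                  species = truth$species[1L]) {
  t <- truth[truth$species == species, ]
  s <- data.frame(context_id = t$context_id, species = species,
                  n = 1L, mean_normalized = t$expected)
  topBottomRatio(s, fraction)
}

#' Simulate a toy annotated genome
#'
#' Plants `nGenes` single-transcript genes with known start-codon
#' contexts on multi-gene contigs, on both strands, and writes a FASTA, a
#' GFF3 and a truth table. Edge cases are built in: the first gene of
#' every contig has only one base of upstream flank (flag
#' `truncated_upstream`), a fraction of genes have their start codon
#' split from the +4 base by an intron (flag `joined_over_intron`), and a
#' fraction carry an annotated non-AUG (GUG) start (flag
#' `non_aug_start`).
#'
#' @param nGenes Number of genes (>= 1).
#' @param contextDistribution Optional data.frame with columns `sevenmer`
#'   and `prob`; default uniform over all 256 (-3, -2, -1, +4) contexts.
#' @param intergenicLength Bases between genes; default 40.
#' @param minusStrandFraction Fraction of genes on the minus strand;
#'   default 0.5.
#' @param intronSplitFraction Fraction of genes with an intron directly
#'   after the start codon; default 0.1.
#' @param nonAugFraction Fraction of genes with a GUG start; default
#'   0.005.
#' @param genesPerContig Genes per contig; default 100.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return List with `fasta`, `gff` (file paths) and `truth` (data.frame
#'   with `gene_id`, `seq_id`, `strand`, `start_codon_coord`, `context`,
#'   `flags`, `ok`).
#' @export
simulateToyGenome <- function(nGenes, contextDistribution = NULL,
                              intergenicLength = 40L,
                              minusStrandFraction = 0.5,
                              intronSplitFraction = 0.1,
                              nonAugFraction = 0.005,
                              genesPerContig = 100L,
                              dir = tempfile("toygenome"), seed = 1L) {
  if (nGenes < 1L) stop("nGenes must be >= 1")
  set.seed(seed)
  if (is.null(contextDistribution)) {
    all7 <- expandPattern(parsePattern("NNNAUGN"))
    contextDistribution <- data.frame(sevenmer = all7,
                                      prob = rep(1 / length(all7),
                                                 length(all7)))
  }
  dnaBases <- c("A", "C", "G", "T")
  rnd <- function(n) paste(sample(dnaBases, n, replace = TRUE),
                           collapse = "")

  sevenmers <- sample(contextDistribution$sevenmer, nGenes, replace = TRUE,
                      prob = contextDistribution$prob)
  onMinus <- runif(nGenes) < minusStrandFraction
  hasIntron <- runif(nGenes) < intronSplitFraction
  nonAug <- runif(nGenes) < nonAugFraction
  contig_of <- rep(seq_len(ceiling(nGenes / genesPerContig)),
                   each = genesPerContig, length.out = nGenes)
  firstOnContig <- !duplicated(contig_of)
  onMinus[firstOnContig] <- FALSE  # edge-case genes kept on +

  contigs <- list()
  feats <- list()
  truth <- list()
  for (ci in unique(contig_of)) {
    parts <- character(0)
    pos <- 0L  # bases written so far
    for (g in which(contig_of == ci)) {
      sv <- chartr("U", "T", sevenmers[g])
      codon <- if (nonAug[g]) "GTG" else "ATG"
      p4 <- substr(sv, 7L, 7L)
      trunc <- firstOnContig[g]
      # truncated edge genes keep only one base 5' of the codon
      up3 <- if (trunc) "" else substr(sv, 1L, 3L)
      uplen <- nchar(up3)
      spacer <- if (trunc) rnd(1L) else rnd(intergenicLength)
      body <- paste0(p4, rnd(25L), "TAA")   # coding after the codon
      if (hasIntron[g]) {
        intron <- paste0("GT", rnd(16L), "AG")
        senseSegs <- rbind(c(uplen + 1L, uplen + 3L),
                           c(uplen + 3L + nchar(intron) + 1L,
                             uplen + 3L + nchar(intron) + nchar(body)))
        block <- paste0(up3, codon, intron, body)
      } else {
        senseSegs <- rbind(c(uplen + 1L, uplen + 3L + nchar(body)))
        block <- paste0(up3, codon, body)
      }
      if (onMinus[g]) block <- revcompChr(block)
      s <- pos + nchar(spacer) + 1L          # block start, 1-based
      B <- nchar(block)
      gid <- sprintf("g%05d", g)
      tid <- sprintf("t%05d", g)
      if (onMinus[g]) {
        segs <- cbind(start = s + B - senseSegs[, 2L],
                      end = s + B - senseSegs[, 1L])
        coordA <- s + B - senseSegs[1L, 1L]
        strandCh <- "-"
      } else {
        segs <- cbind(start = s + senseSegs[, 1L] - 1L,
                      end = s + senseSegs[, 2L] - 1L)
        coordA <- s + senseSegs[1L, 1L] - 1L
        strandCh <- "+"
      }
      feats[[gid]] <- data.frame(
        seqid = sprintf("contig%02d", ci),
        start = c(min(segs[, "start"]), min(segs[, "start"]),
                  segs[, "start"]),
        end = c(max(segs[, "end"]), max(segs[, "end"]), segs[, "end"]),
        strand = strandCh,
        type = c("gene", "mRNA", rep("CDS", nrow(segs))),
        ID = c(gid, tid, paste0("cds", substring(tid, 2L),
                                seq_len(nrow(segs)))),
        Parent = c(NA, gid, rep(tid, nrow(segs))),
        stringsAsFactors = FALSE)
      flags <- c(if (trunc) "truncated_upstream",
                 if (hasIntron[g]) "joined_over_intron",
                 if (nonAug[g]) "non_aug_start")
      excluded <- trunc || nonAug[g]
      truth[[gid]] <- data.frame(
        gene_id = gid, seq_id = sprintf("contig%02d", ci),
        strand = strandCh, start_codon_coord = coordA,
        context = if (excluded) NA_character_ else sevenmers[g],
        flags = paste(sort(flags %||% character(0)), collapse = ","),
        ok = !excluded, stringsAsFactors = FALSE)
      parts <- c(parts, spacer, block)
      pos <- s + B - 1L
    }
    parts <- c(parts, rnd(intergenicLength))  # trailing tail
    contigs[[sprintf("contig%02d", ci)]] <- paste(parts, collapse = "")
  }

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fastaFile <- file.path(dir, "toy_genome.fasta")
  gffFile <- file.path(dir, "toy_genome.gff3")
  writeXStringSet(DNAStringSet(unlist(contigs)), fastaFile)
  writeToyGff(do.call(rbind, c(feats, make.row.names = FALSE)), gffFile)
  truthTab <- do.call(rbind, c(truth, make.row.names = FALSE))
  list(fasta = fastaFile, gff = gffFile, truth = truthTab)
}

# minimal, valid GFF3 writer for the toy annotation
writeToyGff <- function(feats, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attr <- ifelse(is.na(feats$Parent),
                 paste0("ID=", feats$ID),
                 paste0("ID=", feats$ID, ";Parent=", feats$Parent))
  phase <- ifelse(feats$type == "CDS", "0", ".")
  writeLines(paste(feats$seqid, "bacscan", feats$type, feats$start,
                   feats$end, ".", feats$strand, phase, attr,
                   sep = "\t"), con)
  invisible(file)
}
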