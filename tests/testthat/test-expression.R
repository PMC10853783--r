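toyRecords <- function() {
  data.frame(context_id = rep(1:2, each = 2),
             species = "rabbit",
             plate_id = rep(c("p1", "p2"), times = 2),
             replicate = rep(1:2, times = 2),
             fluc_raw = c(100, 100, 50, 200))
}
toyControls <- function() {
  data.frame(plate_id = rep(c("p1", "p2"), each = 2),
             rluc_raw = c(40, 60, 200, 200))
}

test_that("firefly readings are standardised to the plate control mean", {
  out <- normalizePlates(toyRecords(), toyControls())
  # p1 control mean 50, p2 control mean 200 — plates scale independently
  expect_equal(out$normalized, c(2.0, 0.5, 1.0, 1.0))
  expect_equal(out$fluc_raw, toyRecords()$fluc_raw)  # raw untouched
  z <- toyRecords(); z$fluc_raw[1] <- 0
  expect_equal(normalizePlates(z, toyControls())$normalized[1], 0)
})

test_that("normalisation fails loudly on bad controls", {
  rec <- toyRecords()
  expect_error(normalizePlates(rec, data.frame(plate_id = "p1",
                                               rluc_raw = 50)),
               "p2")
  badCtl <- data.frame(plate_id = c("p1", "p2"), rluc_raw = c(50, -1))
  expect_error(normalizePlates(rec, badCtl), "not positive")
})

test_that("normalisation is invariant to a common plate rescaling", {
  rec <- toyRecords(); ctl <- toyControls()
  base <- normalizePlates(rec, ctl)$normalized
  rec2 <- rec; ctl2 <- ctl
  sel <- rec2$plate_id == "p1"
  rec2$fluc_raw[sel] <- rec2$fluc_raw[sel] * 7.3
  ctl2$rluc_raw[ctl2$plate_id == "p1"] <-
    ctl2$rluc_raw[ctl2$plate_id == "p1"] * 7.3
  expect_equal(normalizePlates(rec2, ctl2)$normalized, base)
})

test_that("context summaries are replicate means", {
  rec <- data.frame(context_id = rep(1:4, each = 3), species = "wheat",
                    plate_id = "p1", replicate = rep(1:3, 4),
                    fluc_raw = c(1, 2, 3, 4, 4, 4, 0, 1, 2, 10, 20, 30))
  ctl <- data.frame(plate_id = "p1", rluc_raw = 1)
  s <- summarizeContexts(normalizePlates(rec, ctl))
  expect_equal(s$mean_normalized, c(2, 4, 1, 20))
  expect_equal(s$n, rep(3L, 4))
  expect_error(summarizeContexts(rec), "not normalised")
  expect_warning(summarizeContexts(normalizePlates(rec, ctl),
                                   contexts = c(1, 99)), "99")
})

test_that("percentile splits are deterministic partitions", {
  s <- data.frame(context_id = 1:10, species = "rabbit", n = 3,
                  mean_normalized = c(5, 9, 1, 7, 3, 10, 2, 8, 4, 6))
  sp <- rankAndSplit(s, 0.2)
  expect_equal(sp$k, 2L)
  expect_setequal(sp$selected, c(6, 2))
  expect_setequal(c(sp$selected, sp$background), s$context_id)
  # bottom side selects the lowest activities
  expect_setequal(rankAndSplit(s, 0.2, "bottom")$selected, c(3, 7))
  # half-up k on a 115-context panel
  s115 <- data.frame(context_id = 1:115, species = "rabbit", n = 3,
                     mean_normalized = seq_len(115))
  expect_equal(rankAndSplit(s115, 0.2)$k, 23L)
  # ties at the cut break by ascending context id
  tie <- data.frame(context_id = c(4, 2, 9), species = "x", n = 1,
                    mean_normalized = c(5, 5, 1))
  expect_equal(rankAndSplit(tie, 0.4)$selected, 2)
  expect_error(rankAndSplit(s, 1.2), "between 0 and 1")
  expect_error(rankAndSplit(s, 0), "between 0 and 1")
})

test_that("top set equals the k largest under a brute-force sort", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    s <- data.frame(context_id = seq_len(n), species = "x", n = 1,
                    mean_normalized = runif(n))
    k <- floor(0.2 * n + 0.5)
    if (k < 1) next
    want <- s$context_id[order(-s$mean_normalized)][seq_len(k)]
    expect_setequal(rankAndSplit(s, 0.2)$selected, want)
  }
})

test_that("top/bottom ratio matches forced arithmetic", {
  eq <- data.frame(context_id = 1:10, species = "x", n = 1,
                   mean_normalized = rep(4, 10))
  expect_equal(topBottomRatio(eq), 1.0)
  s <- data.frame(context_id = 1:10, species = "x", n = 1,
                  mean_normalized = 1:10)
  expect_equal(topBottomRatio(s, 0.2), 9.5 / 1.5)
  z <- s; z$mean_normalized[1] <- 0; z$mean_normalized[2] <- 0
  expect_error(topBottomRatio(z, 0.2), "zero")
})

test_that("rank-sum test matches the enumeration oracle", {
  rs <- rankSumTest(1:3, 4:6)
  expect_equal(rs$u, 0)
  expect_equal(rs$p, 0.1)
  set.seed(7)
  for (i in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    v <- sample(seq_len(50), na + nb)   # tie-free
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    expect_equal(rankSumTest(a, b)$p, exactRankSumP(a, b),
                 tolerance = 1e-12)
  }
  expect_error(rankSumTest(numeric(0), 1:3), "nonempty")
})

test_that("rank-sum statistic is symmetric and tie-safe", {
  set.seed(11)
  for (i in 1:10) {
    a <- runif(5); b <- runif(7)
    f <- rankSumTest(a, b); r <- rankSumTest(b, a)
    expect_equal(r$u, length(a) * length(b) - f$u)
    expect_equal(r$p, f$p)
  }
  expect_equal(rankSumTest(c(1, 2), c(1, 2))$p, 1.0)
})

test_that("exact and approximate p agree for small tie-free samples", {
  set.seed(3)
  for (i in 1:40) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    v <- sample(seq_len(100), na + nb)
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    pEx <- exactRankSumP(a, b)
    pAp <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(pEx - pAp), 0.05)
  }
})

test_that("motif fold change splits matching against remaining contexts", {
  tab1 <- loadTable1()
  s <- data.frame(context_id = tab1$id[tab1$tested], species = "rabbit",
                  n = 3, mean_normalized = 27.39)
  hit <- matchesPattern("YCMAUGY", tab1$sevenmer[tab1$tested])
  s$mean_normalized[hit] <- 1
  gc <- motifFoldChange(s, "YCMAUGY")
  expect_equal(foldChange(gc), 27.39)
  expect_equal(gc@nA, sum(hit))
  expect_lt(pValue(gc), 1e-6)
  # reciprocal fold changes: swap which group is "matching"
  gcBacs <- motifFoldChange(s, exactSet = bacsSequences())
  notBacs <- setdiff(tab1$sevenmer[tab1$tested], bacsSequences())
  gcInv <- motifFoldChange(s, exactSet = notBacs)
  expect_equal(foldChange(gcInv), 1 / foldChange(gcBacs))
  # degenerate splits are rejected
  expect_error(motifFoldChange(s, "NNNAUGN"), "all")
  expect_error(motifFoldChange(s, exactSet = "AAAAAAA"), "no")
})

test_that("identical groups give unit fold change and p = 1", {
  tab1 <- loadTable1()
  s <- data.frame(context_id = tab1$id[tab1$tested], species = "y",
                  n = 3, mean_normalized = 5)
  gc <- motifFoldChange(s, "YCMAUGY")
  expect_equal(foldChange(gc), 1.0)
  expect_equal(pValue(gc), 1.0)
})
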