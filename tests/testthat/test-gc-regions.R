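test_that("gc windows handle uniform, partial-bin and N cases", {
  g1 <- genomeRecord("gc1", strrep("GGCC", 100))
  prof <- gcWindows(g1, binSize = 100L)
  expect_true(all(prof$bins$gc == 1))
  expect_equal(prof$genome_mean, 1)
  g0 <- genomeRecord("gc0", strrep("ATAT", 100))
  expect_true(all(gcWindows(g0, binSize = 100L)$bins$gc == 0))
  # trailing partial bin carries its own weight
  g <- genomeRecord("mix", paste0(strrep("G", 250), strrep("A", 100)))
  prof <- gcWindows(g, binSize = 250L)
  expect_equal(prof$bins$gc, c(1, 0))
  expect_equal(prof$genome_mean, 250 / 350)
  # N bases excluded from numerator and denominator
  gn <- genomeRecord("withN", paste0("GGNN", strrep("AT", 4)))
  expect_equal(gcWindows(gn, binSize = 12L)$genome_mean, 2 / 10)
  expect_error(gcWindows(genomeRecord("alln", strrep("N", 100))),
               "all N")
  expect_error(gcWindows(g1, binSize = 5L), ">= 10")
})

test_that("whole-genome bin agrees with single-pass GC", {
  set.seed(11)
  g <- genomeRecord("r", randomSeqChar(4217, 0.59))
  prof <- gcWindows(g, binSize = 10000L)
  expect_equal(nrow(prof$bins), 1L)
  expect_equal(prof$bins$gc[1], prof$genome_mean)
  g2 <- genPhageGenome(prophageTemplate(
    length = 42000L, gcByRegion = c(early = 0.59, middle = 0.59,
                                    late = 0.59)), seed = 12)
  expect_lt(abs(gcWindows(g2)$genome_mean - 0.59), 0.01)
})

test_that("region GC covers unions, complements and degenerate layouts", {
  seq <- paste0(strrep("G", 100), strrep("A", 100), strrep("G", 50),
                strrep("A", 50))
  g <- genomeRecord("reg", seq)
  model <- list(early = IRanges::IRanges(c(1L, 201L), c(100L, 250L)))
  gc <- regionGC(g, model)
  # early union: 100 G + 50 G = 150 GC over 150 bases
  expect_equal(gc[["early"]], 1)
  expect_equal(gc[["rest"]], 0)
  # early covering everything leaves no rest
  whole <- list(early = IRanges::IRanges(1L, 300L))
  gcw <- regionGC(g, whole)
  expect_equal(gcw[["early"]],
               gcWindows(genomeRecord("t", substr(seq, 1, 300)),
                         binSize = 300L)$genome_mean)
  expect_true(is.na(gcw[["rest"]]))
  expect_error(regionGC(g, list(early = IRanges::IRanges(1L, 5000L))),
               "outside")
})

test_that("paired early-vs-rest test matches the closed-form paired t", {
  set.seed(31)
  panel <- lapply(1:3, function(i) {
    g <- genPhageGenome(prophageTemplate(length = 30000L), id =
                          paste0("g", i))
    g
  })
  res <- compareEarlyVsRest(panel)
  d <- res$perGenome$rest - res$perGenome$early
  tHand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, tHand, tolerance = 1e-9)
  expect_equal(res$df, length(d) - 1L)
  pHand <- 2 * pt(-abs(tHand), length(d) - 1L)
  expect_equal(res$p, pHand, tolerance = 1e-9)
  # invariant to panel order
  res2 <- compareEarlyVsRest(rev(panel))
  expect_equal(res2$t, res$t, tolerance = 1e-12)
})

test_that("identical early and rest GC gives t = 0, p = 1", {
  g <- genomeRecord("flat", strrep("GCAT", 2500),
                    features = featureRanges("flat", 1L, 5000L, "region",
                                             "early"))
  panel <- replicate(10, g, simplify = FALSE)
  res <- compareEarlyVsRest(panel)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 9L)
})

test_that("genomes without early regions are excluded with a warning", {
  g1 <- genPhageGenome(prophageTemplate(length = 30000L), seed = 41)
  noEarly <- genomeRecord("bare", strrep("ACGT", 1000))
  expect_warning(
    expect_error(compareEarlyVsRest(list(g1, noEarly)), "fewer than 2"),
    "excluded")
})
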