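test_that("generated phage genomes honor length, GC structure and screening", {
  ph <- genPhageGenome(seed = 7)
  expect_gte(length(ph), 42000L)
  expect_lte(length(ph), 45000L)
  gc <- regionGC(ph)
  expect_lt(abs(gc[["early"]] - 0.543), 0.01)
  expect_lt(abs(gc[["rest"]] - 0.599), 0.011)
  # att motif screened out on both strands
  expect_equal(nrow(findMotif(ph, maxMismatch = 1L)), 0L)
  # determinism
  ph2 <- genPhageGenome(seed = 7)
  expect_identical(as.character(genomeSeq(ph)), as.character(genomeSeq(ph2)))
})

test_that("uniform GC template gives uniform genomes; bad bounds rejected", {
  tm <- prophageTemplate(length = 20000L,
                         gcByRegion = c(early = 0.5, middle = 0.5,
                                        late = 0.5))
  g <- genPhageGenome(tm, seed = 1)
  expect_lt(abs(gcWindows(g)$genome_mean - 0.5), 0.01)
  expect_error(
    prophageTemplate(length = 1000L,
                     regionBounds = list(early = c(1, 200),
                                         middle = c(100, 600),
                                         late = c(601, 1000))),
    "partition")
})

test_that("implantation creates a direct repeat inside the tRNA locus", {
  host <- simHostGenome(length = 30000L, seed = 21)
  ph <- genPhageGenome(prophageTemplate(length = 42000L), seed = 22)
  expect_equal(nrow(findMotif(host, maxMismatch = 0L)), 1L)
  lys <- implantProphage(host, ph)
  expect_equal(length(lys), length(host) + length(ph) + 12L)
  expect_equal(nrow(findMotif(lys, maxMismatch = 0L)), 2L)
  # interrupted tRNA is relabelled
  f <- genomeFeatures(lys)
  expect_true(any(S4Vectors::mcols(f)$label == "tRNA-Leu:interrupted"))
  # non-tRNA site warns but proceeds
  naked <- genomeRecord("naked", paste0(
    strrep("AC", 500), "CAGATTTAGGTT", strrep("GT", 500)))
  expect_warning(implantProphage(naked, genomeRecord("p", "ACGTACGTACGT")),
                 "tRNA")
  # absent motif is a precondition error
  expect_error(implantProphage(genomeRecord("x", strrep("ACGT", 100)), ph),
               "exactly once")
})

test_that("att copies can be degenerated with bounded mismatches", {
  host <- simHostGenome(length = 30000L, seed = 31)
  ph <- genPhageGenome(prophageTemplate(length = 42000L), seed = 32)
  lys <- implantProphage(host, ph, attMismatches = 1L, seed = 33)
  expect_equal(nrow(findMotif(lys, maxMismatch = 0L)), 0L)
  hits <- findMotif(lys, maxMismatch = 1L)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$mismatches == 1L))
})

test_that("point mutation hits the requested rate and is seeded", {
  g <- genomeRecord("g", randomSeqChar(20000, 0.5))
  m <- mutateGenome(g, 0.05, seed = 4)
  diff <- sum(strsplit(as.character(genomeSeq(g)), "")[[1]] !=
              strsplit(as.character(genomeSeq(m)), "")[[1]])
  expect_gt(diff / 20000, 0.04)
  expect_lt(diff / 20000, 0.06)
  m2 <- mutateGenome(g, 0.05, seed = 4)
  expect_identical(as.character(genomeSeq(m)), as.character(genomeSeq(m2)))
})
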