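test_that("findMotif equals the naive double-strand scan", {
  motif <- "CAGATTTAGGTT"
  set.seed(101)
  for (i in 1:50) {
    s <- randomSeqChar(20000, 0.5)
    # plant an exact hit, a 1-mismatch hit, and a reverse-strand hit
    substr(s, 2000, 2011) <- motif
    near <- motif; substr(near, 5, 5) <- "C"
    substr(s, 9000, 9011) <- near
    substr(s, 15000, 15011) <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    g <- genomeRecord(paste0("g", i), s)
    for (mm in 0:2) {
      got <- findMotif(g, motif, maxMismatch = mm)
      want <- naiveMotifScan(s, motif, mm)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("motif scan validates its arguments", {
  g <- genomeRecord("g", strrep("ACGT", 100))
  expect_error(findMotif(g, "CAGNTTTAGGTT"), "\\{A,C,G,T\\}")
  expect_error(findMotif(g, "ACGT"), "at least 8")
  expect_error(findMotif(g, "CAGATTTAGGTT", maxMismatch = 3L), "<= 2")
})

test_that("prophage calls respect the size window and round-trip exactly", {
  host <- simHostGenome(length = 40000L, seed = 51)
  ph <- genPhageGenome(prophageTemplate(length = 43000L), seed = 52)
  lys <- implantProphage(host, ph)
  calls <- callProphages(lys, sizeWindow = c(30000, 60000))
  expect_length(calls, 1L)
  call <- calls[[1]]
  expect_equal(call@length, 43012L)
  interior <- as.character(Biostrings::subseq(
    call@excisedSeq, 13L, length(call@excisedSeq) - 12L))
  expect_identical(interior, as.character(genomeSeq(ph)))
  expect_error(validObject(call), NA)
  # two hits only 5 kb apart yield no call
  s <- randomSeqChar(20000, 0.5)
  m <- "CAGATTTAGGTT"
  substr(s, 1000, 1011) <- m
  substr(s, 6000, 6011) <- m
  expect_length(callProphages(genomeRecord("near", s),
                              sizeWindow = c(30000, 60000)), 0L)
})

test_that("two implanted prophages give two calls at the right coordinates", {
  set.seed(61)
  s <- randomSeqChar(120000, 0.6)
  s <- ProphageKit:::screenMotif(s, "CAGATTTAGGTT", 0.6, maxMismatch = 1L)
  m <- "CAGATTTAGGTT"
  pA <- randomSeqChar(32000, 0.55)
  pB <- randomSeqChar(35000, 0.55)
  # insert [m pA m] at 10000 and [m pB m] far downstream
  s2 <- paste0(substr(s, 1, 9999), m, pA, m,
               substr(s, 10000, 59999), m, pB, m,
               substr(s, 60000, nchar(s)))
  calls <- callProphages(genomeRecord("dual", s2),
                         sizeWindow = c(30000, 40000))
  expect_length(calls, 2L)
  starts <- sort(vapply(calls, function(x) IRanges::start(x@attL),
                        integer(1)))
  expect_equal(starts, c(10000L, 10000L + 12L + 32000L + 12L + 50000L))
  lens <- sort(vapply(calls, function(x) x@length, integer(1)))
  expect_equal(lens, c(32012L, 35012L))
})

test_that("attB sites are located and annotated by tRNA context", {
  host <- simHostGenome(length = 30000L, seed = 71)
  ph <- genPhageGenome(prophageTemplate(length = 42000L), seed = 72)
  ab <- findAttB(host)
  expect_equal(nrow(ab), 1L)
  expect_true(ab$within_tRNA)
  expect_equal(ab$tRNA_label, "tRNA-Leu")
  lys <- implantProphage(host, ph)
  ab2 <- findAttB(lys)
  expect_equal(nrow(ab2), 2L)
  expect_false(any(ab2$within_tRNA))
  empty <- genomeRecord("none", strrep("ACGT", 1000))
  expect_equal(nrow(findAttB(empty)), 0L)
})

test_that("circular normalization recovers rotation and strand", {
  ref <- genomeRecord("ref", randomSeqChar(5000, 0.5))
  rot <- rotateSeq(genomeSeq(ref), 1000)
  res <- rotateToReference(rot, ref)
  expect_identical(res$seq, as.character(genomeSeq(ref)))
  expect_equal(res$offset, 4000L)  # left-rotation restoring the origin
  expect_equal(res$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rot)))
  res2 <- rotateToReference(rc, ref)
  expect_identical(res2$seq, as.character(genomeSeq(ref)))
  expect_equal(res2$strand, "-")
  expect_error(rotateToReference(randomSeqChar(3000, 0.5), ref),
               "unrelated")
})

test_that("normalization of a mutated copy matches the brute-force offset", {
  set.seed(81)
  refSeq <- randomSeqChar(3000, 0.5)
  ref <- genomeRecord("ref", refSeq)
  trueRot <- 700L
  mut <- mutateGenome(genomeRecord("m", rotateSeq(refSeq, trueRot)),
                      0.05, seed = 82)
  res <- rotateToReference(genomeSeq(mut), ref, k = 12L, stride = 25L)
  # brute force: identity over all left-rotations of the candidate
  cand <- as.character(genomeSeq(mut))
  refCh <- strsplit(refSeq, "")[[1]]
  ident <- vapply(0:(nchar(cand) - 1L), function(r)
    sum(strsplit(rotateSeq(cand, r), "")[[1]] == refCh), numeric(1))
  expect_equal(res$offset, which.max(ident) - 1L)
  expect_identical(res$seq, rotateSeq(cand, which.max(ident) - 1L))
})
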