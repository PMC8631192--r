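# one direction of the intergenomic similarity: fragment `a`, seed each
# fragment into `b`, extend by alignment in a windowed band
similarityOneWay <- function(aseq, bseq, fragmentLen, k, seedStride, band) {
  aChar <- as.character(aseq)
  bDna <- Biostrings::DNAString(as.character(bseq))
  lenA <- nchar(aChar)
  lenB <- length(bDna)
  starts <- seq.int(1L, lenA, by = fragmentLen)
  idSum <- 0
  colSum <- 0
  alignedBases <- 0
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (s in starts) {
    e <- min(s + fragmentLen - 1L, lenA)
    fl <- e - s + 1L
    if (fl < k) next
    frag <- substr(aChar, s, e)
    diag <- seedDiagonal(frag, bDna, k, seedStride)
    strand <- "+"
    if (is.na(diag)) {
      frag2 <- revComp(frag)
      diag <- seedDiagonal(frag2, bDna, k, seedStride)
      if (!is.na(diag)) { frag <- frag2; strand <- "-" }
    }
    if (is.na(diag)) next
    ws <- max(1L, diag - band)
    we <- min(lenB, diag + fl - 1L + band)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(frag),
      Biostrings::subseq(bDna, ws, we),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 1)
    idSum <- idSum + Biostrings::nmatch(aln)
    colSum <- colSum + Biostrings::nchar(aln)
    alignedBases <- alignedBases + fl
  }
  if (colSum == 0) return(c(identity = 0, alignedFraction = 0))
  c(identity = idSum / colSum, alignedFraction = alignedBases / lenA)
}

# modal seed diagonal (start of the fragment's alignment in b); NA unless
# at least two seeds agree (one when the fragment is too short to carry
# two seeds), which suppresses chance k-mer hits between unrelated genomes
seedDiagonal <- function(frag, bDna, k, seedStride) {
  offs <- seq.int(1L, nchar(frag) - k + 1L, by = seedStride)
  votes <- integer(0)
  for (o in offs) {
    seed <- substr(frag, o, o + k - 1L)
    pos <- Biostrings::start(Biostrings::matchPattern(seed, bDna))
    if (length(pos)) votes <- c(votes, pos - o + 1L)
  }
  if (!length(votes)) return(NA_integer_)
  tb <- table(votes)
  minVotes <- min(2L, length(offs))
  if (max(tb) < minVotes) return(NA_integer_)
  as.integer(names(tb)[which.max(tb)])
}

#' Intergenomic similarity between two genomes (VIRIDIC-style)
#'
#' Cuts each genome into non-overlapping fragments, places each fragment on
#' the partner by exact k-mer seeding (both strands) and extends with a
#' unit-cost-gap alignment inside a fixed band around the seed diagonal.
#' Directional similarity is (summed identities / summed aligned columns)
#' scaled by the aligned fraction of the query; the reported similarity
#' averages both directions and is expressed in percent. This is a
#' self-contained VIRIDIC-style measure, not bit-identical to VIRIDIC
#' (which delegates to BLASTN).
#'
#' @param a,b [GenomeRecord-class] objects, each at least `fragmentLen` bp.
#' @param fragmentLen fragment size in bp.
#' @param k seed k-mer length.
#' @param seedStride spacing of seeds along each fragment.
#' @param band alignment band half-width around the seed diagonal.
#' @return named numeric: `similarity` (percent) and `alignedFraction`.
#' @export
pairSimilarity <- function(a, b, fragmentLen = 1000L, k = 11L,
                           seedStride = 100L, band = 32L) {
  stopIfNot(length(a) >= fragmentLen && length(b) >= fragmentLen,
            "both genomes must be at least fragmentLen bp")
  ab <- similarityOneWay(genomeSeq(a), genomeSeq(b), fragmentLen, k,
                         seedStride, band)
  ba <- similarityOneWay(genomeSeq(b), genomeSeq(a), fragmentLen, k,
                         seedStride, band)
  sim <- mean(c(ab[["identity"]] * ab[["alignedFraction"]],
                ba[["identity"]] * ba[["alignedFraction"]])) * 100
  c(similarity = sim,
    alignedFraction = mean(c(ab[["alignedFraction"]],
                             ba[["alignedFraction"]])))
}

#' All-pairs similarity matrix for a genome panel
#'
#' @param genomes list of [GenomeRecord-class] with unique ids (>= 2).
#' @param ... passed to [pairSimilarity()].
#' @return a `SimilarityMatrix` list: `ids`, `similarity` (symmetric percent
#'   matrix, diagonal 100), `alignedFraction` matrix.
#' @export
similarityMatrix <- function(genomes, ...) {
  stopIfNot(length(genomes) >= 2L, "need at least 2 genomes")
  ids <- vapply(genomes, genomeId, character(1))
  stopIfNot(!anyDuplicated(ids), "duplicate genome ids: %s",
            paste(ids[duplicated(ids)], collapse = ", "))
  n <- length(genomes)
  sim <- matrix(100, n, n, dimnames = list(ids, ids))
  af <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ps <- pairSimilarity(genomes[[i]], genomes[[j]], ...)
      sim[i, j] <- sim[j, i] <- ps[["similarity"]]
      af[i, j] <- af[j, i] <- ps[["alignedFraction"]]
    }
  }
  structure(list(ids = ids, similarity = sim, alignedFraction = af),
            class = "SimilarityMatrix")
}

#' Threshold clustering of a similarity matrix
#'
#' Single-linkage connected components of the graph whose edges join
#' genome pairs with similarity at or above the threshold -- the operation
#' behind genus-level (similarity > 70) and species-level (similarity < 97)
#' demarcation of phage panels.
#'
#' @param mat a `SimilarityMatrix` from [similarityMatrix()], or a plain
#'   symmetric percent matrix.
#' @param threshold percent threshold in (0, 100).
#' @return named integer vector of cluster memberships (1-based, numbered
#'   by first appearance).
#' @export
clusterAt <- function(mat, threshold) {
  stopIfNot(threshold > 0 && threshold < 100,
            "threshold must lie in (0, 100)")
  m <- if (inherits(mat, "SimilarityMatrix")) mat$similarity else mat
  d <- stats::as.dist(100 - m)
  hc <- stats::hclust(d, method = "single")
  cl <- stats::cutree(hc, h = 100 - threshold)
  # renumber by first appearance for determinism
  stats::setNames(as.integer(factor(cl, levels = unique(cl))),
                  rownames(m))
}
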