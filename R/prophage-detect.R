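# shared motif scan: all starts (forward coordinates) on both strands where
# the motif matches within maxMismatch substitutions
motifHitStarts <- function(seq, motif, maxMismatch = 0L) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  scan1 <- function(pat, strand) {
    v <- Biostrings::matchPattern(pat, seq, max.mismatch = maxMismatch,
                                  with.indels = FALSE)
    st <- Biostrings::start(v)
    if (!length(st))
      return(data.frame(start = integer(), strand = character(),
                        mismatches = integer()))
    mm <- Biostrings::neditStartingAt(pat, seq, starting.at = st)
    data.frame(start = st, strand = strand, mismatches = as.integer(mm))
  }
  fw <- scan1(Biostrings::DNAString(motif), "+")
  rc <- scan1(Biostrings::reverseComplement(Biostrings::DNAString(motif)), "-")
  out <- rbind(fw, rc)
  out <- out[out$start >= 1L & out$start + nchar(motif) - 1L <= length(seq), ,
             drop = FALSE]
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a genome for an attachment-site motif
#'
#' Reports every position, on both strands, where the motif matches within
#' `maxMismatch` substitutions (Hamming distance; no indels). Coordinates
#' are starts on the forward strand; reverse-strand hits are reported at
#' their forward-strand footprint.
#'
#' @param genome a [GenomeRecord-class].
#' @param motif motif string over A/C/G/T, length >= 8.
#' @param maxMismatch maximum substitutions per hit (0--2).
#' @return data.frame with columns `genome_id`, `start`, `strand`,
#'   `mismatches`, sorted by start.
#' @export
findMotif <- function(genome, motif = "CAGATTTAGGTT", maxMismatch = 1L) {
  stopIfNot(!grepl("[^ACGT]", motif), "motif must be over {A,C,G,T}")
  stopIfNot(nchar(motif) >= 8L, "motif must be at least 8 bp")
  stopIfNot(maxMismatch <= 2L, "maxMismatch must be <= 2")
  hits <- motifHitStarts(genomeSeq(genome), motif, maxMismatch)
  data.frame(genome_id = rep(genomeId(genome), nrow(hits)), hits,
             row.names = NULL)
}

#' Call prophages from paired att direct repeats
#'
#' Every pair of same-strand motif hits whose spacing (attR start minus
#' attL start, i.e. the inferred circular-phage length) falls inside
#' `sizeWindow` becomes a candidate call. Nested and overlapping candidates
#' are resolved by keeping the shortest call per attL and then greedily
#' discarding calls that overlap an accepted one (scanning left to right).
#' Opposite-strand (inverted repeat) pairings inside the window are not
#' called but raised as a warning, since att sites of an integrated phage
#' are direct repeats.
#'
#' @param genome a [GenomeRecord-class].
#' @param motif att motif.
#' @param sizeWindow numeric `c(min_bp, max_bp)` window on the inferred
#'   phage length; the default (30, 60 kb) brackets the 42--45 kb family.
#' @param maxMismatch per-copy mismatch tolerance.
#' @return list of [ProphageCall-class] objects (possibly empty).
#' @export
callProphages <- function(genome, motif = "CAGATTTAGGTT",
                          sizeWindow = c(30000, 60000), maxMismatch = 1L) {
  stopIfNot(sizeWindow[1] < sizeWindow[2],
            "sizeWindow must satisfy min < max")
  hits <- findMotif(genome, motif, maxMismatch)
  m <- nchar(motif)
  seqc <- genomeSeq(genome)
  cands <- list()
  invWarn <- 0L
  if (nrow(hits) >= 2L) {
    for (i in seq_len(nrow(hits) - 1L)) {
      for (j in seq.int(i + 1L, nrow(hits))) {
        sep <- hits$start[j] - hits$start[i]
        if (sep < sizeWindow[1]) next
        if (sep > sizeWindow[2]) break
        if (hits$strand[i] != hits$strand[j]) {
          invWarn <- invWarn + 1L
          next
        }
        cands[[length(cands) + 1L]] <- list(i = i, j = j, len = sep)
      }
    }
  }
  if (invWarn > 0L)
    warning(sprintf(
      "%d inverted-repeat pairing(s) within the size window were ignored",
      invWarn))
  if (!length(cands)) return(list())
  # shortest call per attL
  byL <- split(cands, vapply(cands, function(x) x$i, integer(1)))
  best <- lapply(byL, function(g) g[[which.min(vapply(g, function(x) x$len,
                                                      numeric(1)))]])
  best <- best[order(vapply(best, function(x) hits$start[x$i], numeric(1)))]
  accepted <- list()
  occupied <- IRanges::IRanges()
  for (cand in best) {
    s <- hits$start[cand$i]
    e <- hits$start[cand$j] + m - 1L
    rg <- IRanges::IRanges(s, e)
    if (length(occupied) &&
        sum(IRanges::countOverlaps(rg, occupied)) > 0L) next
    occupied <- c(occupied, rg)
    accepted[[length(accepted) + 1L]] <- new(
      "ProphageCall",
      genomeId = genomeId(genome),
      attL = IRanges::IRanges(s, s + m - 1L),
      attR = IRanges::IRanges(hits$start[cand$j], e),
      prophageRange = rg,
      excisedSeq = Biostrings::DNAString(as.character(
        Biostrings::subseq(seqc, s, e))),
      length = as.integer(cand$len),
      mismatches = as.integer(hits$mismatches[cand$i] +
                              hits$mismatches[cand$j]))
  }
  accepted
}

#' Locate candidate attB sites in a (phage-free) genome
#'
#' Annotates every motif hit with whether it falls inside an intact tRNA
#' feature (interrupted tRNAs -- label ending `":interrupted"` -- do not
#' count, mirroring integration disrupting the chromosomal copy).
#'
#' @param genome a [GenomeRecord-class].
#' @param motif att motif.
#' @param trnaFeatures optional `GRanges` of tRNA loci; defaults to the
#'   genome's own `type == "tRNA"` features.
#' @param maxMismatch mismatch tolerance for the scan.
#' @return data.frame with columns `genome_id`, `position`, `strand`,
#'   `within_tRNA`, `tRNA_label`, sorted by position.
#' @export
findAttB <- function(genome, motif = "CAGATTTAGGTT", trnaFeatures = NULL,
                     maxMismatch = 1L) {
  hits <- findMotif(genome, motif, maxMismatch)
  if (is.null(trnaFeatures)) {
    f <- genomeFeatures(genome)
    trnaFeatures <- f[S4Vectors::mcols(f)$type == "tRNA"]
  }
  intact <- trnaFeatures[!grepl(":interrupted$",
                                S4Vectors::mcols(trnaFeatures)$label)]
  m <- nchar(motif)
  within <- logical(nrow(hits))
  lab <- rep(NA_character_, nrow(hits))
  if (nrow(hits) && length(intact)) {
    hitR <- IRanges::IRanges(hits$start, hits$start + m - 1L)
    ov <- IRanges::findOverlaps(hitR, IRanges::ranges(intact),
                                type = "within")
    within[S4Vectors::queryHits(ov)] <- TRUE
    lab[S4Vectors::queryHits(ov)] <-
      S4Vectors::mcols(intact)$label[S4Vectors::subjectHits(ov)]
  }
  data.frame(genome_id = rep(genomeId(genome), nrow(hits)),
             position = hits$start, strand = hits$strand,
             within_tRNA = within, tRNA_label = lab, row.names = NULL)
}

#' Left-rotate a circular sequence
#'
#' @param x character or `DNAString`.
#' @param r rotation in bp; position `r + 1` becomes position 1.
#' @return character sequence.
#' @export
rotateSeq <- function(x, r) {
  x <- as.character(x)
  n <- nchar(x)
  r <- ((r %% n) + n) %% n
  if (r == 0) return(x)
  paste0(substr(x, r + 1L, n), substr(x, 1L, r))
}

#' Normalize a circular sequence to a reference origin and strand
#'
#' Treats `x` as circular and finds the rotation (and strand) that best
#' agrees with the reference, by voting over exact shared k-mer seeds: each
#' seed drawn from the reference is located in the doubled candidate and
#' votes for the implied rotation offset. The winning strand/offset is
#' applied; if forward and reverse complement tie, forward wins.
#'
#' @param x candidate circular sequence (character, `DNAString` or
#'   [GenomeRecord-class]).
#' @param reference reference circular genome (same types accepted).
#' @param k seed length.
#' @param stride spacing between sampled reference seeds.
#' @return list with `seq` (normalized character sequence), `offset` (the
#'   detected left-rotation of the input relative to the reference) and
#'   `strand` (`"+"` or `"-"`).
#' @export
rotateToReference <- function(x, reference, k = 15L, stride = 50L) {
  xs <- if (is(x, "GenomeRecord")) as.character(genomeSeq(x)) else
    as.character(x)
  rs <- if (is(reference, "GenomeRecord")) as.character(genomeSeq(reference))
    else as.character(reference)
  stopIfNot(nchar(xs) > 0 && nchar(rs) > 0, "sequences must be non-empty")
  stopIfNot(nchar(xs) >= k && nchar(rs) >= k, "sequences shorter than k")
  n <- nchar(xs)
  starts <- seq.int(1L, nchar(rs) - k + 1L, by = stride)
  voteFor <- function(cand) {
    doubled <- Biostrings::DNAString(paste0(cand, substr(cand, 1L, k - 1L)))
    votes <- integer(0)
    for (s in starts) {
      seed <- substr(rs, s, s + k - 1L)
      pos <- Biostrings::start(
        Biostrings::matchPattern(seed, doubled))
      pos <- pos[pos <= n]
      if (length(pos))
        votes <- c(votes, (pos - s) %% n)
    }
    votes
  }
  vf <- voteFor(xs)
  xr <- revComp(xs)
  vr <- voteFor(xr)
  bestOf <- function(v) {
    if (!length(v)) return(c(NA_integer_, 0L))
    tb <- table(v)
    off <- as.integer(names(tb)[which.max(tb)])
    c(off, max(tb))
  }
  bf <- bestOf(vf)
  br <- bestOf(vr)
  if (bf[2] == 0L && br[2] == 0L)
    stop("no shared k-mers with the reference: unrelated sequence",
         call. = FALSE)
  if (bf[2] >= br[2]) {
    list(seq = rotateSeq(xs, bf[1]), offset = bf[1], strand = "+")
  } else {
    list(seq = rotateSeq(xr, br[1]), offset = br[1], strand = "-")
  }
}
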