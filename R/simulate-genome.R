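#' Template for a synthetic temperate-phage genome
#'
#' Describes the genome the generator emulates: total length (drawn
#' uniformly from 42--45 kb when not fixed, the size range of the phage
#' family being modelled), a 12-bp attachment-site motif, a partition of the
#' genome into early/middle/late transcription-class regions, and a target
#' GC fraction per region. Defaults put the hypervariable, horizontally
#' acquired early region at GC 0.543 and the remainder at 0.599.
#'
#' @param length total genome length in bp, or `NULL` to draw from
#'   `lengthRange` at generation time.
#' @param lengthRange 2-vector of bp bounds for the draw.
#' @param attMotif attachment-site motif (>= 8 bp, A/C/G/T only).
#' @param regionBounds named list `early`, `middle`, `late` of `c(start,
#'   end)` 1-based closed intervals partitioning `[1, length]`, or `NULL`
#'   for the default layout (early = first 5 kb, middle = to half-length,
#'   late = remainder).
#' @param gcByRegion named numeric GC fractions, in (0, 1).
#' @return a `ProphageTemplate` list.
#' @export
prophageTemplate <- function(length = NULL,
                             lengthRange = c(42000L, 45000L),
                             attMotif = "CAGATTTAGGTT",
                             regionBounds = NULL,
                             gcByRegion = c(early = 0.543, middle = 0.599,
                                            late = 0.599)) {
  stopIfNot(nchar(attMotif) >= 8L, "attMotif must be at least 8 bp")
  stopIfNot(!grepl("[^ACGT]", attMotif), "attMotif must be over {A,C,G,T}")
  stopIfNot(all(gcByRegion > 0 & gcByRegion < 1),
            "gcByRegion fractions must lie in (0, 1)")
  stopIfNot(all(c("early", "middle", "late") %in% names(gcByRegion)),
            "gcByRegion must name early, middle and late")
  if (!is.null(regionBounds)) {
    stopIfNot(is.null(length) == FALSE,
              "regionBounds require a fixed genome length")
    b <- regionBounds[c("early", "middle", "late")]
    flat <- sort(unlist(lapply(b, function(x) seq.int(x[1], x[2]))))
    if (!identical(flat, seq_len(length)))
      stop("regionBounds must partition [1, length]", call. = FALSE)
  }
  structure(list(length = length, lengthRange = as.integer(lengthRange),
                 attMotif = attMotif, regionBounds = regionBounds,
                 gcByRegion = gcByRegion),
            class = "ProphageTemplate")
}

defaultRegionBounds <- function(len) {
  early_end <- min(5000L, len %/% 3L)
  mid_end <- len %/% 2L
  list(early = c(1L, early_end),
       middle = c(early_end + 1L, mid_end),
       late = c(mid_end + 1L, len))
}

# Resample any window matching `motif` on either strand within
# `maxMismatch`, so the att site stays unique at the detector's tolerance.
screenMotif <- function(seq, motif, gc, maxMismatch = 1L, maxIter = 50L) {
  m <- nchar(motif)
  for (i in seq_len(maxIter)) {
    hits <- motifHitStarts(seq, motif, maxMismatch)
    if (nrow(hits) == 0L) return(seq)
    for (s in hits$start) {
      substr(seq, s, s + m - 1L) <- randomDNA(m, gc)
    }
  }
  stop("could not screen att motif out of the simulated sequence",
       call. = FALSE)
}

#' Generate a synthetic phage genome with region-structured GC
#'
#' Draws an iid nucleotide sequence with a distinct target GC fraction per
#' early/middle/late region, resampling each region until its realized GC
#' is within `gcTol` of target, and screening out any occurrence of the att
#' motif (either strand, up to 1 mismatch) so that attachment sites occur
#' only where [implantProphage()] puts them. The returned record carries
#' `region` features labelled early/middle/late and a decoy internal
#' tRNA-Leu feature (temperate phages of this family carry their own
#' motif-free tRNA-Leu copy).
#'
#' @param template a [prophageTemplate()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param id genome id.
#' @param gcTol per-region GC tolerance (default 0.01).
#' @return a circular [GenomeRecord-class] with region features.
#' @export
genPhageGenome <- function(template = prophageTemplate(), seed = NULL,
                           id = "synthetic_phage", gcTol = 0.01) {
  stopifnot(inherits(template, "ProphageTemplate"))
  withSeed(seed, {
    len <- template$length
    if (is.null(len))
      len <- sample(seq.int(template$lengthRange[1], template$lengthRange[2]),
                    1L)
    bounds <- template$regionBounds
    if (is.null(bounds)) bounds <- defaultRegionBounds(len)
    parts <- character(3)
    names(parts) <- c("early", "middle", "late")
    for (rg in names(parts)) {
      b <- bounds[[rg]]
      n <- b[2] - b[1] + 1L
      gc <- template$gcByRegion[[rg]]
      repeat {
        s <- randomDNA(n, gc)
        obs <- gcFractionChar(s)
        if (abs(obs - gc) <= gcTol) break
      }
      parts[rg] <- s
    }
    seq <- paste(parts, collapse = "")
    # screening perturbs GC negligibly (expected hits << 1 per genome)
    seq <- screenMotif(seq, template$attMotif,
                       gc = template$gcByRegion[["middle"]])
    feats <- featureRanges(
      id,
      start = c(vapply(bounds, `[`, integer(1), 1L), bounds$middle[1] + 100L),
      end = c(vapply(bounds, `[`, integer(1), 2L), bounds$middle[1] + 184L),
      type = c(rep("region", 3), "tRNA"),
      label = c("early", "middle", "late", "tRNA-Leu"))
    genomeRecord(id, seq, circular = TRUE, features = feats)
  })
}

# GC fraction of a character sequence, N excluded from both counts
gcFractionChar <- function(s) {
  af <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
  acgt <- sum(af[c("A", "C", "G", "T")])
  if (acgt == 0L) return(NA_real_)
  sum(af[c("G", "C")]) / acgt
}

#' Generate a synthetic phage-free host genome
#'
#' An iid background sequence (default GC 0.60, Rhizobium-like) screened
#' free of att-motif near-matches (either strand, up to `screenMismatch`
#' mismatches), with a single tRNA-Leu locus carrying one exact copy of the
#' att motif -- the attB integration site. The 100 kb default is a
#' deliberately desk-scale stand-in for a bacterial chromosome; detection
#' operates per base, so scan behaviour is unchanged.
#'
#' @param id genome id.
#' @param length host length in bp.
#' @param gc background GC fraction.
#' @param attMotif the att 12-mer.
#' @param trnaStart start of the 85-bp tRNA-Leu feature (default: centred).
#' @param screenMismatch screening tolerance for spurious near-matches.
#' @param seed integer seed or `NULL`.
#' @return a linear [GenomeRecord-class] with `tRNA` and `att` features.
#' @export
simHostGenome <- function(id = "synthetic_host", length = 100000L,
                          gc = 0.60, attMotif = "CAGATTTAGGTT",
                          trnaStart = NULL, screenMismatch = 2L,
                          seed = NULL) {
  withSeed(seed, {
    m <- nchar(attMotif)
    seq <- randomDNA(length, gc)
    seq <- screenMotif(seq, attMotif, gc, maxMismatch = screenMismatch)
    if (is.null(trnaStart)) trnaStart <- as.integer(length %/% 2L)
    trnaEnd <- trnaStart + 84L
    stopIfNot(trnaStart >= 1L && trnaEnd <= length,
              "tRNA locus falls outside the genome")
    attStart <- trnaStart + 30L
    substr(seq, attStart, attStart + m - 1L) <- attMotif
    feats <- featureRanges(
      id,
      start = c(trnaStart, attStart),
      end = c(trnaEnd, attStart + m - 1L),
      type = c("tRNA", "att"),
      label = c("tRNA-Leu", "attB"))
    genomeRecord(id, seq, circular = FALSE, features = feats)
  })
}

mutateCopy <- function(motif, nMismatch) {
  if (nMismatch <= 0L) return(motif)
  pos <- sample(nchar(motif), nMismatch)
  for (p in pos) {
    cur <- substr(motif, p, p)
    substr(motif, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  motif
}

#' Integrate a phage genome into a host at its attB site
#'
#' Site-specific integration: the phage sequence plus a second copy of the
#' att motif is inserted immediately after the host's attB copy, leaving the
#' prophage flanked by the motif as a direct repeat (attL/attR). The host
#' grows by `length(phage) + nchar(attMotif)` bp. The interrupted tRNA
#' feature is relabelled, downstream features are shifted, and attL/attR
#' plus a `prophage` feature are recorded. Optionally each att copy is
#' degenerated by `attMismatches` random substitutions to emulate imperfect
#' repeats.
#'
#' @param host a [GenomeRecord-class] containing `attMotif` exactly once.
#' @param phage a [GenomeRecord-class]; its sequence is the circular phage
#'   genome minus the att copy.
#' @param attMotif the att motif; must match the host's attB.
#' @param site optional attB start; defaults to the unique motif occurrence.
#' @param attMismatches substitutions applied independently to each att copy
#'   (0--2).
#' @param seed integer seed or `NULL` (only used when `attMismatches > 0`).
#' @return the lysogenized [GenomeRecord-class].
#' @export
implantProphage <- function(host, phage, attMotif = "CAGATTTAGGTT",
                            site = NULL, attMismatches = 0L, seed = NULL) {
  m <- nchar(attMotif)
  hseq <- as.character(genomeSeq(host))
  occ <- Biostrings::start(Biostrings::matchPattern(attMotif, genomeSeq(host)))
  if (is.null(site)) {
    stopIfNot(length(occ) == 1L,
              "host must contain the att motif exactly once (found %d)",
              length(occ))
    site <- occ[1]
  } else {
    stopIfNot(site %in% occ, "no att motif at the requested site")
  }
  feats <- genomeFeatures(host)
  inTRNA <- FALSE
  if (length(feats)) {
    tr <- feats[S4Vectors::mcols(feats)$type == "tRNA"]
    inTRNA <- any(GenomicRanges::start(tr) <= site &
                  GenomicRanges::end(tr) >= site + m - 1L)
  }
  if (!inTRNA)
    warning("att site is not inside a tRNA feature; implanting anyway")
  withSeed(seed, {
    attL <- mutateCopy(attMotif, attMismatches)
    attR <- mutateCopy(attMotif, attMismatches)
    pseq <- as.character(genomeSeq(phage))
    ins <- nchar(pseq) + m
    newseq <- paste0(substr(hseq, 1L, site - 1L), attL, pseq, attR,
                     substr(hseq, site + m, nchar(hseq)))
    id <- genomeId(host)
    newfeats <- feats
    if (length(newfeats)) {
      after <- GenomicRanges::start(newfeats) > site + m - 1L
      newfeats[after] <- GenomicRanges::shift(newfeats[after], ins)
      trna <- S4Vectors::mcols(newfeats)$type == "tRNA" &
        GenomicRanges::start(newfeats) <= site &
        GenomicRanges::end(newfeats) >= site
      S4Vectors::mcols(newfeats)$label[trna] <-
        paste0(S4Vectors::mcols(newfeats)$label[trna], ":interrupted")
      newfeats <- newfeats[S4Vectors::mcols(newfeats)$label != "attB"]
    }
    extra <- featureRanges(
      id,
      start = c(site, site + m + nchar(pseq), site),
      end = c(site + m - 1L, site + 2L * m + nchar(pseq) - 1L,
              site + 2L * m + nchar(pseq) - 1L),
      type = c("att", "att", "prophage"),
      label = c("attL", "attR", genomeId(phage)))
    genomeRecord(id, newseq, circular = isCircular(host),
                 features = c(newfeats, extra))
  })
}

#' Point-mutate a genome
#'
#' Substitutes each base independently with probability `rate` (to a
#' uniformly chosen different base), emulating simple sequence divergence;
#' used to build panels of known relatedness for similarity calibration.
#'
#' @param genome a [GenomeRecord-class].
#' @param rate per-base substitution probability.
#' @param seed integer seed or `NULL`.
#' @param id id for the mutant (default: input id + ".mut").
#' @return a mutated [GenomeRecord-class] (features dropped).
#' @export
mutateGenome <- function(genome, rate, seed = NULL, id = NULL) {
  stopIfNot(rate >= 0 && rate <= 1, "rate must lie in [0, 1]")
  if (is.null(id)) id <- paste0(genomeId(genome), ".mut")
  withSeed(seed, {
    ch <- strsplit(as.character(genomeSeq(genome)), "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate & ch != "N")
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    genomeRecord(id, paste(ch, collapse = ""),
                 circular = isCircular(genome))
  })
}
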