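# tiny builders shared across test files

tp <- function(hostNwk, phageNwk, map) {
  treePair(ape::read.tree(text = hostNwk), ape::read.tree(text = phageNwk),
           map)
}

congruentPair <- function(n) {
  labs <- paste0("H", seq_len(n))
  plabs <- paste0("P", seq_len(n))
  nest <- function(labs) {
    if (length(labs) == 1L) return(labs)
    paste0("(", labs[1], ",", nest(labs[-1]), ")")
  }
  tp(paste0(nest(labs), ";"), paste0(nest(plabs), ";"),
     stats::setNames(labs, plabs))
}

# naive double-strand Hamming scan, the oracle for findMotif
naiveMotifScan <- function(seqChar, motif, maxMismatch) {
  scanOne <- function(pat, strand) {
    ch <- strsplit(seqChar, "", fixed = TRUE)[[1]]
    pt <- strsplit(pat, "", fixed = TRUE)[[1]]
    n <- length(ch); m <- length(pt)
    if (n < m) return(data.frame(start = integer(), strand = character(),
                                 mismatches = integer()))
    starts <- seq_len(n - m + 1L)
    mm <- integer(length(starts))
    for (j in seq_len(m))
      mm <- mm + (ch[starts + j - 1L] != pt[j])
    keep <- mm <= maxMismatch
    data.frame(start = starts[keep], strand = strand,
               mismatches = mm[keep])
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  out <- rbind(scanOne(motif, "+"), scanOne(rc, "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

randomSeqChar <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
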