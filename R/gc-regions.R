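# cumulative GC / ACGT counts for O(1) interval queries
gcCumulants <- function(seq) {
  ch <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
  isGC <- ch == "G" | ch == "C"
  isN <- ch == "N"
  list(gc = cumsum(isGC), acgt = cumsum(!isN))
}

intervalGC <- function(cum, start, end) {
  gc <- sum(cum$gc[end]) - sum(ifelse(start > 1L, cum$gc[start - 1L], 0))
  acgt <- sum(cum$acgt[end]) - sum(ifelse(start > 1L, cum$acgt[start - 1L], 0))
  if (acgt == 0) return(NA_real_)
  gc / acgt
}

#' GC content in fixed-width windows
#'
#' Bins the genome into consecutive `binSize`-bp windows (the trailing
#' partial bin is kept, weighted by its own length) and reports the GC
#' fraction per bin. `N` bases are excluded from both numerator and
#' denominator; a bin of all `N` gets `NA`. The genome mean is the
#' length-weighted mean over informative bases, identical to a single-pass
#' whole-genome GC.
#'
#' @param genome a [GenomeRecord-class].
#' @param binSize window width in bp (>= 10); default 250.
#' @return a `GCProfile` list: `genome_id`, `bin_size`, `bins` (data.frame
#'   `start`, `end`, `gc`), `genome_mean`.
#' @export
gcWindows <- function(genome, binSize = 250L) {
  stopIfNot(binSize >= 10L, "binSize must be >= 10")
  len <- length(genome)
  cum <- gcCumulants(genomeSeq(genome))
  if (cum$acgt[len] == 0L)
    stop(sprintf("genome '%s' is all N: GC undefined", genomeId(genome)),
         call. = FALSE)
  starts <- seq.int(1L, len, by = binSize)
  ends <- pmin(starts + binSize - 1L, len)
  gc <- vapply(seq_along(starts), function(i)
    intervalGC(cum, starts[i], ends[i]), numeric(1))
  structure(list(
    genome_id = genomeId(genome),
    bin_size = as.integer(binSize),
    bins = data.frame(start = starts, end = ends, gc = gc),
    genome_mean = cum$gc[len] / cum$acgt[len]),
    class = "GCProfile")
}

# normalize a region model to a named list of IRanges
asRegionModel <- function(genome, model = NULL) {
  if (is.null(model)) {
    f <- genomeFeatures(genome)
    model <- f[S4Vectors::mcols(f)$type == "region"]
  }
  if (is(model, "GRanges")) {
    labs <- S4Vectors::mcols(model)$label
    model <- split(IRanges::ranges(model), labs)
  }
  stopIfNot(length(model) > 0L, "genome '%s' has no region model",
            genomeId(genome))
  bad <- setdiff(names(model), c("early", "middle", "late"))
  stopIfNot(length(bad) == 0L, "unknown region label(s): %s",
            paste(bad, collapse = ", "))
  model
}

#' Per-region GC means
#'
#' GC fraction over the (possibly disjoint) intervals of each labelled
#' region, plus `rest`: the complement of the early region. Regions come
#' from the genome's own `type == "region"` features or an explicit model.
#'
#' @param genome a [GenomeRecord-class].
#' @param model optional region model: a `GRanges` with `label` mcol in
#'   `early`/`middle`/`late`, or a named list of `IRanges`.
#' @return named numeric of GC fractions (labels present, plus `rest`);
#'   empty labels are dropped with a warning, and `rest` is `NA` when the
#'   early region covers the whole genome.
#' @export
regionGC <- function(genome, model = NULL) {
  model <- asRegionModel(genome, model)
  len <- length(genome)
  cum <- gcCumulants(genomeSeq(genome))
  out <- numeric(0)
  for (lab in names(model)) {
    r <- IRanges::reduce(model[[lab]])
    stopIfNot(all(IRanges::start(r) >= 1L) && all(IRanges::end(r) <= len),
              "region '%s' falls outside genome '%s'", lab, genomeId(genome))
    if (length(r) == 0L) {
      warning(sprintf("region '%s' is empty and was omitted", lab))
      next
    }
    out[lab] <- intervalGC(cum, IRanges::start(r), IRanges::end(r))
  }
  if ("early" %in% names(out)) {
    comp <- IRanges::setdiff(IRanges::IRanges(1L, len),
                             IRanges::reduce(model[["early"]]))
    out["rest"] <- if (length(comp) == 0L) NA_real_ else
      intervalGC(cum, IRanges::start(comp), IRanges::end(comp))
  }
  out
}

#' Paired early-vs-rest GC comparison across a phage panel
#'
#' For each genome, computes the GC fraction of its early region and of the
#' rest of the genome (complement of early), then runs a paired two-sided
#' t-test on the per-genome (early, rest) pairs -- the design implied by a
#' t statistic on n - 1 degrees of freedom over an n-genome panel. Genomes
#' lacking an early region are excluded with a warning.
#'
#' @param panel list of [GenomeRecord-class] objects (region features
#'   embedded) or of `list(genome =, model =)` pairs.
#' @return list: `t`, `df`, `p`, `perGenome` (data.frame `genome_id`,
#'   `early`, `rest`), `groupMean` and `groupSd` (named, early/rest).
#' @export
compareEarlyVsRest <- function(panel) {
  stopIfNot(length(panel) >= 2L, "panel must contain at least 2 genomes")
  rows <- list()
  for (item in panel) {
    if (is(item, "GenomeRecord")) {
      genome <- item; model <- NULL
    } else {
      genome <- item$genome; model <- item$model
    }
    g <- tryCatch(regionGC(genome, model), error = function(e) NULL)
    if (is.null(g) || !("early" %in% names(g)) || is.na(g[["rest"]])) {
      warning(sprintf("genome '%s' lacks a usable early region; excluded",
                      genomeId(genome)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genomeId(genome), early = g[["early"]], rest = g[["rest"]])
  }
  stopIfNot(length(rows) >= 2L,
            "fewer than 2 genomes with early regions remain")
  per <- do.call(rbind, rows)
  # test on rest - early so GC depletion of the early region gives t > 0
  d <- per$rest - per$early
  n <- nrow(per)
  if (stats::sd(d) == 0) {
    tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    pval <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(per$rest, per$early, paired = TRUE)
    tval <- unname(tt$statistic)
    pval <- tt$p.value
  }
  list(t = tval,
       df = n - 1L,
       p = pval,
       perGenome = per,
       groupMean = c(early = mean(per$early), rest = mean(per$rest)),
       groupSd = c(early = stats::sd(per$early), rest = stats::sd(per$rest)))
}
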