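#' Construct a GenomeRecord
#'
#' @param id genome identifier.
#' @param seq a `DNAString`, or a character string coerced to one (uppercased
#'   first).
#' @param circular is the replicon circular?
#' @param features optional `GRanges` with mcols `type` and `label`; an
#'   empty feature set is used when missing.
#' @return a [GenomeRecord-class].
#' @examples
#' gr <- genomeRecord("toy", "ACGTACGT")
#' genomeId(gr)
#' @export
genomeRecord <- function(id, seq, circular = FALSE, features = NULL) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  if (is.null(features)) {
    features <- GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(),
      type = character(), label = character())
  }
  new("GenomeRecord", id = as.character(id), seq = seq,
      circular = isTRUE(circular), features = features)
}

#' Construct a TreePair
#'
#' @param hostTree,phageTree rooted binary `phylo` trees.
#' @param tipMap named character vector mapping every phage tip label to a
#'   host tip label.
#' @return a [TreePair-class].
#' @export
treePair <- function(hostTree, phageTree, tipMap) {
  new("TreePair", hostTree = hostTree, phageTree = phageTree,
      tipMap = tipMap)
}

#' Build a feature GRanges for a genome
#'
#' Convenience wrapper used by the simulators and GFF reader: one range per
#' feature with `type` (e.g. `"tRNA"`, `"region"`, `"att"`) and `label`
#' metadata columns.
#'
#' @param genomeId sequence name for the ranges.
#' @param start,end 1-based closed coordinates.
#' @param type,label character vectors recycled to the number of ranges.
#' @param strand strand characters, default `"+"`.
#' @return a `GRanges`.
#' @export
featureRanges <- function(genomeId, start, end, type, label, strand = "+") {
  n <- length(start)
  GenomicRanges::GRanges(
    seqnames = rep(genomeId, n),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = rep(strand, length.out = n),
    type = rep(type, length.out = n),
    label = rep(label, length.out = n))
}

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)
#' @rdname accessors
#' @export
setMethod("isCircular", "GenomeRecord", function(x) x@circular)
#' @rdname accessors
#' @export
setMethod("genomeFeatures", "GenomeRecord", function(x) x@features)
setMethod("length", "GenomeRecord", function(x) length(x@seq))

#' @rdname accessors
#' @export
setMethod("hostTree", "TreePair", function(x) x@hostTree)
#' @rdname accessors
#' @export
setMethod("phageTree", "TreePair", function(x) x@phageTree)
#' @rdname accessors
#' @export
setMethod("tipMap", "TreePair", function(x) x@tipMap)

#' @rdname accessors
#' @export
setMethod("eventCounts", "Reconciliation", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("totalCost", "Reconciliation", function(x) x@totalCost)
#' @rdname accessors
#' @export
setMethod("nodeMap", "Reconciliation", function(x) x@nodeMap)
#' @rdname accessors
#' @export
setMethod("eventTable", "Reconciliation", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("mprCount", "MPRSet", function(x) x@count)
#' @rdname accessors
#' @export
setMethod("mprSample", "MPRSet", function(x) x@sample)

#' @rdname accessors
#' @export
setMethod("scenarioPair", "CophylogenyScenario", function(x) x@pair)
#' @rdname accessors
#' @export
setMethod("trueEvents", "CophylogenyScenario", function(x) x@trueEvents)

#' @rdname accessors
#' @export
setMethod("latentPeriod", "GrowthFit", function(x) x@latentMin)
#' @rdname accessors
#' @export
setMethod("burstSize", "GrowthFit", function(x) x@burstSize)

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s': %d bp, %s, %d feature(s)\n",
              object@id, length(object@seq),
              if (object@circular) "circular" else "linear",
              length(object@features)))
})

setMethod("show", "TreePair", function(object) {
  cat(sprintf("TreePair: host %d tips, phage %d tips, %d tip association(s)\n",
              ape::Ntip(object@hostTree), ape::Ntip(object@phageTree),
              length(object@tipMap)))
})

setMethod("show", "ProphageCall", function(object) {
  cat(sprintf(
    "ProphageCall on '%s': attL [%d,%d], attR [%d,%d], phage length %d bp (%d att mismatch(es))\n",
    object@genomeId,
    IRanges::start(object@attL), IRanges::end(object@attL),
    IRanges::start(object@attR), IRanges::end(object@attR),
    object@length, object@mismatches))
})

setMethod("show", "Reconciliation", function(object) {
  cnt <- object@counts
  cat(sprintf(
    "Reconciliation: cost %g (%d cospeciation, %d duplication, %d transfer, %d loss)\n",
    object@totalCost, cnt[["cospeciation"]], cnt[["duplication"]],
    cnt[["transfer"]], cnt[["loss"]]))
})

setMethod("show", "MPRSet", function(object) {
  cat(sprintf("MPRSet: %g MPR(s) at cost %g; %d enumerated",
              object@count, object@minCost, length(object@sample)))
  if (length(object@clusters))
    cat(sprintf("; %d cluster(s)", length(unique(object@clusters))))
  cat("\n")
})

setMethod("show", "CophylogenyScenario", function(object) {
  te <- object@trueEvents
  cat(sprintf(
    "CophylogenyScenario: host %d tips, phage %d tips | true events: %d cosp, %d dup, %d transfer, %d loss\n",
    ape::Ntip(object@pair@hostTree), ape::Ntip(object@pair@phageTree),
    te[["cospeciation"]], te[["duplication"]], te[["transfer"]], te[["loss"]]))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit '%s' rep %s: latent %s min, burst %.1f\n",
              object@phageId, object@replicate,
              if (is.na(object@latentMin)) "NA" else
                sprintf("%.1f", object@latentMin),
              object@burstSize))
})
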