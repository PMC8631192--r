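#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

setOldClass("phylo")

#' GenomeRecord: a named nucleotide sequence with optional features
#'
#' Container for one genome (bacterial host, phage or prophage): a DNA
#' sequence over the alphabet A, C, G, T, N, a circular/linear flag and a
#' set of feature annotations (tRNA loci, transcription-class regions,
#' attachment sites) held as a [GenomicRanges::GRanges] with metadata
#' columns `type` and `label`. All coordinates are 1-based and closed, the
#' IRanges/GFF convention.
#'
#' @slot id single character identifier.
#' @slot seq a [Biostrings::DNAString].
#' @slot circular logical flag; `TRUE` for circular replicons (e.g. a phage
#'   sequenced in its circular form).
#' @slot features a `GRanges` on this genome with mcols `type` and `label`.
#'
#' @seealso [genomeRecord()] for the user-facing constructor,
#'   [readGenomeFasta()] to build records from FASTA files.
#' @export
setClass("GenomeRecord",
  representation(
    id = "character",
    seq = "DNAString",
    circular = "logical",
    features = "GRanges"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) == 0L)
    msg <- c(msg, sprintf("record '%s' has an empty sequence", object@id))
  af <- Biostrings::alphabetFrequency(object@seq)
  bad <- sum(af) - sum(af[c("A", "C", "G", "T", "N")])
  if (bad > 0L)
    msg <- c(msg, sprintf(
      "record '%s' contains %d characters outside {A,C,G,T,N}", object@id, bad))
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(object@features)) {
    st <- GenomicRanges::start(object@features)
    en <- GenomicRanges::end(object@features)
    if (any(st < 1L) || any(en > length(object@seq)) || any(st > en))
      msg <- c(msg, sprintf(
        "features of '%s' fall outside [1, %d]", object@id, length(object@seq)))
    mc <- names(S4Vectors::mcols(object@features))
    if (!all(c("type", "label") %in% mc))
      msg <- c(msg, "features need metadata columns 'type' and 'label'")
  }
  if (length(msg)) msg else TRUE
})

#' TreePair: rooted host and phage trees linked by a tip association
#'
#' Holds a rooted binary host tree, a rooted binary phage tree and a total
#' map from phage tips to host tips (each prophage to its lysogen strain).
#' Host tips may be unmapped: phage-free strains carry no symbiont.
#'
#' @slot hostTree,phageTree rooted binary `phylo` objects (ape).
#' @slot tipMap named character vector; names are phage tip labels, values
#'   host tip labels.
#'
#' @seealso [treePair()], [readTreePair()], [dtlMinCost()].
#' @export
setClass("TreePair",
  representation(
    hostTree = "phylo",
    phageTree = "phylo",
    tipMap = "character"
  )
)

setValidity("TreePair", function(object) {
  msg <- character()
  for (nm in c("hostTree", "phageTree")) {
    tr <- slot(object, nm)
    if (!ape::is.rooted(tr)) msg <- c(msg, sprintf("%s is not rooted", nm))
    if (ape::Ntip(tr) >= 2L && !ape::is.binary(tr))
      msg <- c(msg, sprintf("%s is not binary (polytomy present)", nm))
  }
  ph <- object@phageTree$tip.label
  ho <- object@hostTree$tip.label
  if (is.null(names(object@tipMap)) ||
      !setequal(names(object@tipMap), ph) ||
      length(object@tipMap) != length(ph))
    msg <- c(msg, "tipMap must name every phage tip exactly once")
  if (!all(object@tipMap %in% ho))
    msg <- c(msg, "tipMap targets must be host tip labels")
  if (length(msg)) msg else TRUE
})

#' ProphageCall: one detected prophage
#'
#' The attL/attR coordinates, the spanned prophage interval, the excised
#' sequence and the inferred circular-phage length for one prophage detected
#' from a pair of direct-repeat attachment-site motifs. The prophage
#' interval runs from the start of attL to the end of attR; `length` counts
#' the interior plus a single motif copy, i.e. the length of the circular
#' phage genome that integrated.
#'
#' @slot genomeId host genome id.
#' @slot attL,attR [IRanges::IRanges] of the two motif copies.
#' @slot prophageRange `IRanges` spanning attL start to attR end.
#' @slot excisedSeq `DNAString` of the spanned interval.
#' @slot length inferred circular phage length (interior + one att copy).
#' @slot mismatches total att mismatches across the two copies.
#' @export
setClass("ProphageCall",
  representation(
    genomeId = "character",
    attL = "IRanges",
    attR = "IRanges",
    prophageRange = "IRanges",
    excisedSeq = "DNAString",
    length = "integer",
    mismatches = "integer"
  )
)

setValidity("ProphageCall", function(object) {
  msg <- character()
  if (IRanges::end(object@attL) >= IRanges::start(object@attR))
    msg <- c(msg, "attL must precede attR")
  expect_len <- IRanges::start(object@attR) - IRanges::end(object@attL) - 1L +
    IRanges::width(object@attL)
  if (object@length != expect_len)
    msg <- c(msg, "length must equal interior plus one att copy")
  if (length(object@excisedSeq) != IRanges::width(object@prophageRange))
    msg <- c(msg, "excisedSeq must match the prophage interval width")
  if (length(msg)) msg else TRUE
})

#' Reconciliation: an event-annotated mapping of a phage tree onto a host tree
#'
#' A certificate for one duplication-transfer-loss maximum-parsimony
#' reconciliation: every phage node is mapped to a host node, every internal
#' phage node is labelled with its event (cospeciation, duplication or
#' transfer), loss passages along host edges are listed, and the per-event
#' counts and total cost are recorded. Certificates can be re-evaluated
#' bottom-up with [validateReconciliation()].
#'
#' @slot nodeMap integer vector over phage nodes (ape numbering) giving the
#'   host node each maps to.
#' @slot events data.frame with columns `phageNode`, `event`
#'   (`cospeciation`/`duplication`/`transfer`/`loss`), `hostNode`.
#' @slot counts named numeric: cospeciation, duplication, transfer, loss.
#' @slot totalCost numeric.
#' @slot costs the [dtlCosts()] vector the certificate was scored under.
#' @export
setClass("Reconciliation",
  representation(
    nodeMap = "integer",
    events = "data.frame",
    counts = "numeric",
    totalCost = "numeric",
    costs = "numeric"
  )
)

setValidity("Reconciliation", function(object) {
  msg <- character()
  need <- c("cospeciation", "duplication", "transfer", "loss")
  if (!all(need %in% names(object@counts)))
    msg <- c(msg, "counts must name cospeciation, duplication, transfer, loss")
  if (!all(need %in% names(object@costs)))
    msg <- c(msg, "costs must name cospeciation, duplication, transfer, loss")
  if (all(need %in% names(object@counts)) && all(need %in% names(object@costs))) {
    implied <- sum(object@counts[need] * object@costs[need])
    if (abs(implied - object@totalCost) > 1e-9)
      msg <- c(msg, "totalCost must equal sum(counts * costs)")
  }
  if (length(msg)) msg else TRUE
})

#' MPRSet: the minimum-cost reconciliations of a tree pair
#'
#' The number of distinct maximum-parsimony reconciliations (MPRs), an
#' enumerated sample of certificates (possibly capped), and, after
#' [clusterMPRs()], a partition of the sample with one representative
#' (medoid) per cluster.
#'
#' @slot count exact number of distinct MPRs (numeric to allow large counts).
#' @slot sample list of [Reconciliation-class] certificates.
#' @slot clusters integer cluster id per sample member (0-length until
#'   clustered).
#' @slot representatives indices into `sample` of the cluster medoids.
#' @slot minCost the shared total cost.
#' @export
setClass("MPRSet",
  representation(
    count = "numeric",
    sample = "list",
    clusters = "integer",
    representatives = "integer",
    minCost = "numeric"
  )
)

setValidity("MPRSet", function(object) {
  msg <- character()
  if (object@count < length(object@sample))
    msg <- c(msg, "count cannot be smaller than the enumerated sample")
  costs <- vapply(object@sample, function(r) r@totalCost, numeric(1))
  if (length(costs) && any(abs(costs - object@minCost) > 1e-9))
    msg <- c(msg, "every sampled certificate must attain the minimum cost")
  if (length(msg)) msg else TRUE
})

#' CophylogenyScenario: a simulated host/phage tree pair with ground truth
#'
#' Output of [simCophylogeny()]: the simulated [TreePair-class] plus the true
#' event history (cospeciation, duplication, transfer, loss counts and the
#' ordered event log), used as ground truth in recovery experiments.
#'
#' @slot pair a [TreePair-class].
#' @slot trueEvents named numeric counts (cospeciation, duplication,
#'   transfer, loss).
#' @slot eventLog data.frame with columns `event` and `hostEdge` in the
#'   order the events occurred.
#' @export
setClass("CophylogenyScenario",
  representation(
    pair = "TreePair",
    trueEvents = "numeric",
    eventLog = "data.frame"
  )
)

setValidity("CophylogenyScenario", function(object) {
  msg <- character()
  need <- c("cospeciation", "duplication", "transfer", "loss")
  if (!all(need %in% names(object@trueEvents)))
    msg <- c(msg, "trueEvents must name all four event types")
  tally <- table(factor(object@eventLog$event, levels = need))
  if (!all(object@trueEvents[need] == as.numeric(tally)))
    msg <- c(msg, "trueEvents must equal the event-log tallies")
  if (length(msg)) msg else TRUE
})

#' GrowthFit: latent period and burst size from a one-step growth curve
#'
#' @slot phageId,replicate identifiers for the fitted series.
#' @slot latentMin estimated latent period in minutes (`NA` when no lysis
#'   rise was detected).
#' @slot burstSize final plateau / baseline plateau, in PFU per infected
#'   cell.
#' @slot diagnostics list with `baseline`, `plateau`, `rss`, `riseDetected`.
#' @export
setClass("GrowthFit",
  representation(
    phageId = "character",
    replicate = "character",
    latentMin = "numeric",
    burstSize = "numeric",
    diagnostics = "list"
  )
)
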