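#' Parameters for the cophylogeny simulator
#'
#' Per-lineage, per-host-edge probabilities of the optional events. At most
#' one optional event is drawn per lineage per edge traversal, so the
#' probabilities must sum to at most 1.
#'
#' @param nHostTips number of host tips (>= 2).
#' @param transferRate,duplicationRate,lossRate per-lineage probabilities
#'   in `[0, 1]`.
#' @param seed integer seed carried with the parameters, or `NULL`.
#' @return a `CophyloSimParams` list.
#' @export
cophyloSimParams <- function(nHostTips = 8L, transferRate = 0.15,
                             duplicationRate = 0, lossRate = 0,
                             seed = NULL) {
  stopIfNot(nHostTips >= 2L, "nHostTips must be >= 2")
  pr <- c(transferRate, duplicationRate, lossRate)
  stopIfNot(all(pr >= 0 & pr <= 1), "rates must lie in [0, 1]")
  stopIfNot(sum(pr) <= 1, "event probabilities must sum to at most 1")
  structure(list(nHostTips = as.integer(nHostTips),
                 transferRate = transferRate,
                 duplicationRate = duplicationRate,
                 lossRate = lossRate, seed = seed),
            class = "CophyloSimParams")
}

#' Simulate a host/phage cophylogeny scenario with known event history
#'
#' The host tree is drawn from a pure-birth process. A single phage lineage
#' then evolves down the host tree: it cospeciates at every host split it
#' reaches, and on each host edge it may (with the configured
#' probabilities) be lost, duplicate, or transfer -- the transferred copy
#' reattaching to a host edge alive at the (uniform) event time, chosen
#' uniformly among edges other than the donor's. The surviving lineages
#' become phage tips mapped to their host tips; lineages whose descendants
#' all die are pruned from the returned phage tree, but every event is kept
#' in the true history.
#'
#' @param params a [cophyloSimParams()].
#' @return a [CophylogenyScenario-class]; errors with a suggestion to lower
#'   the loss rate if no phage lineage survives.
#' @export
simCophylogeny <- function(params = cophyloSimParams()) {
  stopifnot(inherits(params, "CophyloSimParams"))
  withSeed(params$seed, {
    host <- ape::rphylo(params$nHostTips, birth = 1, death = 0)
    host$tip.label <- paste0("H", seq_len(params$nHostTips))
    info <- treeInfo(host)
    tAt <- ape::node.depth.edgelength(host)
    env <- new.env()
    env$tipN <- 0L
    env$events <- list()
    env$map <- character(0)
    logEvent <- function(event, hostEdge) {
      env$events[[length(env$events) + 1L]] <-
        data.frame(event = event, hostEdge = hostEdge)
    }
    pick1 <- function(x) x[sample.int(length(x), 1L)]
    joinPair <- function(a, b) {
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      paste0("(", a, ",", b, ")")
    }
    arrive <- function(v) {
      if (v <= info$n) {
        env$tipN <- env$tipN + 1L
        lab <- paste0("P", env$tipN)
        env$map[lab] <- host$tip.label[v]
        return(lab)
      }
      logEvent("cospeciation", v)
      ch <- info$children[[v]]
      joinPair(descend(ch[1]), descend(ch[2]))
    }
    descend <- function(v, tEnter = tAt[info$parent[v]]) {
      u <- stats::runif(1)
      pl <- params$lossRate
      pd <- params$duplicationRate
      pt <- params$transferRate
      if (u < pl) {
        logEvent("loss", v)
        return(NULL)
      }
      if (u < pl + pd) {
        logEvent("duplication", v)
        return(joinPair(arrive(v), arrive(v)))
      }
      if (u < pl + pd + pt) {
        tEv <- stats::runif(1, tEnter, tAt[v])
        alive <- which(vapply(seq_len(info$N), function(w) {
          w != info$root && w != v &&
            tAt[info$parent[w]] < tEv && tEv <= tAt[w]
        }, logical(1)))
        if (length(alive)) {
          recip <- pick1(alive)
          logEvent("transfer", recip)
          return(joinPair(arrive(v), descend(recip, tEv)))
        }
      }
      arrive(v)
    }
    nwk <- arrive(info$root)
    if (is.null(nwk))
      stop("all phage lineages were lost; lower the loss rate",
           call. = FALSE)
    phage <- ape::read.tree(text = paste0(
      if (env$tipN == 1L) paste0("(", nwk, ")") else nwk, ";"))
    log <- do.call(rbind, env$events)
    counts <- vapply(c("cospeciation", "duplication", "transfer", "loss"),
                     function(e) sum(log$event == e), numeric(1))
    pair <- treePair(host, phage, env$map)
    new("CophylogenyScenario", pair = pair, trueEvents = counts,
        eventLog = log)
  })
}

#' Cost of a scenario's true event history
#'
#' Prices the simulator's logged events under a cost vector; by the
#' parsimony bound this is always at least [dtlMinCost()] of the scenario's
#' tree pair.
#'
#' @param scenario a [CophylogenyScenario-class].
#' @param costs a [dtlCosts()] vector.
#' @return numeric cost.
#' @export
trueHistoryCost <- function(scenario, costs = dtlCosts()) {
  te <- trueEvents(scenario)
  sum(te[names(costs)] * costs)
}
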