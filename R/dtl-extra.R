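# event-set signature of a certificate, used for MPR distances
eventSetKey <- function(rec) {
  ev <- rec@events
  sort(paste(ev$phageNode, ev$event, ev$hostNode, sep = "|"))
}

#' Cluster enumerated MPRs and pick representatives
#'
#' Pairwise distance between two reconciliations is the size of the
#' symmetric difference of their event sets (an event being a (phage node,
#' event type, host node) triple, losses included). The sample is
#' partitioned by k-medoids (PAM, deterministic) and each cluster is
#' represented by its medoid.
#'
#' @param mprs an [MPRSet-class] from [enumerateMPRs()].
#' @param k number of clusters; must not exceed the number of distinct
#'   certificates in the sample.
#' @return the [MPRSet-class] with `clusters` and `representatives` filled.
#' @export
clusterMPRs <- function(mprs, k) {
  n <- length(mprs@sample)
  stopIfNot(k >= 1L && k <= n,
            "k = %d exceeds the sample size (%d) or is below 1", k, n)
  keys <- lapply(mprs@sample, eventSetKey)
  nDistinct <- length(unique(vapply(keys, paste, character(1),
                                    collapse = ";")))
  stopIfNot(k <= nDistinct,
            "k = %d exceeds the %d distinct certificate(s)", k, nDistinct)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      D[i, j] <- D[j, i] <-
        length(setdiff(keys[[i]], keys[[j]])) +
        length(setdiff(keys[[j]], keys[[i]]))
    }
  }
  if (k == n) {
    cl <- seq_len(n)
    med <- seq_len(n)
  } else if (k == 1L) {
    cl <- rep(1L, n)
    med <- which.min(rowSums(D))
  } else {
    fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
    cl <- as.integer(fit$clustering)
    med <- as.integer(fit$id.med)
  }
  mprs@clusters <- cl
  mprs@representatives <- med
  mprs
}

#' Map reconciliation outcomes over a (transfer, loss) cost grid
#'
#' Re-runs the reconciliation at every grid point of transfer and loss
#' costs (cospeciation and duplication fixed), recording the minimum cost
#' and the set of optimal event-count signatures (one
#' cospeciation/duplication/transfer/loss tuple per enumerated MPR, capped).
#' Adjacent grid cells sharing the same signature set are merged into
#' numbered regions, exposing where in cost space the predicted outcome
#' changes.
#'
#' @param pair a [TreePair-class].
#' @param transferRange,lossRange numeric vectors of grid values (>= 2
#'   points each).
#' @param cospeciation,duplication the fixed costs.
#' @param cap enumeration cap per cell.
#' @return data.frame with one row per cell: `transfer`, `loss`,
#'   `minCost`, `signatures` (semicolon-joined `co,dup,tr,lo` tuples),
#'   `region`.
#' @export
costSpace <- function(pair, transferRange, lossRange, cospeciation = 0,
                      duplication = 2, cap = 200L) {
  stopIfNot(length(transferRange) >= 2L && length(lossRange) >= 2L,
            "cost ranges need at least 2 grid points each")
  grid <- expand.grid(transfer = transferRange, loss = lossRange,
                      KEEP.OUT.ATTRS = FALSE)
  sigs <- character(nrow(grid))
  minCost <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    costs <- dtlCosts(cospeciation, duplication, grid$transfer[i],
                      grid$loss[i])
    mprs <- enumerateMPRs(pair, costs, cap = cap)
    minCost[i] <- mprs@minCost
    cnts <- vapply(mprs@sample, function(r)
      paste(r@counts[c("cospeciation", "duplication", "transfer", "loss")],
            collapse = ","), character(1))
    sigs[i] <- paste(sort(unique(cnts)), collapse = ";")
  }
  # merge grid-adjacent cells with identical signature sets
  nT <- length(transferRange); nL <- length(lossRange)
  idx <- function(it, il) (il - 1L) * nT + it
  region <- rep(NA_integer_, nrow(grid))
  nxt <- 0L
  for (start in seq_len(nrow(grid))) {
    if (!is.na(region[start])) next
    nxt <- nxt + 1L
    queue <- start
    region[start] <- nxt
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      it <- (cell - 1L) %% nT + 1L
      il <- (cell - 1L) %/% nT + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        jt <- it + d[1]; jl <- il + d[2]
        if (jt < 1L || jt > nT || jl < 1L || jl > nL) next
        j <- idx(jt, jl)
        if (is.na(region[j]) && sigs[j] == sigs[cell]) {
          region[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  data.frame(transfer = grid$transfer, loss = grid$loss, minCost = minCost,
             signatures = sigs, region = region,
             stringsAsFactors = FALSE)
}

#' Permutation test of host-phage codivergence
#'
#' Compares the observed minimum reconciliation cost with a null built by
#' uniformly permuting the tip association (which host tip each phage tip
#' attaches to). The p-value is `(1 + #{null <= observed}) / (nPerm + 1)`:
#' small when the observed association is cheaper to reconcile than random
#' attachments, i.e. when the trees are more congruent than chance.
#' An alternative null that redraws random binary phage topologies on the
#' same tips is available via `null = "topology"`.
#'
#' @param pair a [TreePair-class].
#' @param costs a [dtlCosts()] vector.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed or `NULL`.
#' @param null `"tipmap"` (default) or `"topology"`.
#' @return list: `observed`, `null` (numeric vector of null costs), `p`.
#' @export
permutationTest <- function(pair, costs = dtlCosts(), nPerm = 999L,
                            seed = NULL, null = c("tipmap", "topology")) {
  null <- match.arg(null)
  stopIfNot(nPerm >= 99L, "nPerm must be >= 99")
  stopIfNot(length(pair@tipMap) >= 2L, "need at least 2 mappable tips")
  obs <- dtlMinCost(pair, costs)$minCost
  withSeed(seed, {
    nullCosts <- vapply(seq_len(nPerm), function(i) {
      if (null == "tipmap") {
        tm <- pair@tipMap
        tm[] <- tm[sample(length(tm))]
        p2 <- treePair(pair@hostTree, pair@phageTree, tm)
      } else {
        pt <- ape::rtree(ape::Ntip(pair@phageTree), rooted = TRUE)
        pt$tip.label <- sample(pair@phageTree$tip.label)
        p2 <- treePair(pair@hostTree, pt, pair@tipMap)
      }
      dtlMinCost(p2, costs)$minCost
    }, numeric(1))
    list(observed = obs, null = nullCosts,
         p = (1 + sum(nullCosts <= obs)) / (nPerm + 1))
  })
}
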