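# Brute-force DTL oracle, independent of the package's dynamic program.
# Enumerates every assignment of internal phage nodes to host nodes; given
# a full node mapping the candidate events at each internal phage node are
# determined geometrically and their loss passages counted directly.

oracleTreeTables <- function(tree) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  kids <- lapply(seq_len(N), function(v) tree$edge[tree$edge[, 1] == v, 2])
  desc <- matrix(FALSE, N, N)
  dist <- matrix(NA_real_, N, N)
  fill <- function(v) {
    desc[v, v] <<- TRUE
    dist[v, v] <<- 0
    for (ch in kids[[v]]) {
      fill(ch)
      w <- which(desc[ch, ])
      desc[v, w] <<- TRUE
      dist[v, w] <<- dist[ch, w] + 1
    }
  }
  fill(n + 1L)
  list(n = n, N = N, kids = kids, desc = desc, dist = dist,
       incomp = !(desc | t(desc)))
}

# per-node candidate events for mapping (h; children at m1, m2):
# returns numeric vector of candidate costs (possibly empty)
oracleNodeOptions <- function(H, h, m1, m2, costs) {
  opts <- numeric(0)
  hk <- H$kids[[h]]
  if (length(hk) == 2L) {
    if (H$desc[hk[1], m1] && H$desc[hk[2], m2])
      opts <- c(opts, costs[["cospeciation"]] +
                  costs[["loss"]] * (H$dist[hk[1], m1] + H$dist[hk[2], m2]))
    if (H$desc[hk[2], m1] && H$desc[hk[1], m2])
      opts <- c(opts, costs[["cospeciation"]] +
                  costs[["loss"]] * (H$dist[hk[2], m1] + H$dist[hk[1], m2]))
  }
  if (H$desc[h, m1] && H$desc[h, m2])
    opts <- c(opts, costs[["duplication"]] +
                costs[["loss"]] * (H$dist[h, m1] + H$dist[h, m2]))
  if (H$desc[h, m1] && H$incomp[h, m2])
    opts <- c(opts, costs[["transfer"]] + costs[["loss"]] * H$dist[h, m1])
  if (H$desc[h, m2] && H$incomp[h, m1])
    opts <- c(opts, costs[["transfer"]] + costs[["loss"]] * H$dist[h, m2])
  opts
}

oracleDTL <- function(pair, costs) {
  host <- hostTree(pair)
  phage <- phageTree(pair)
  H <- oracleTreeTables(host)
  P <- oracleTreeTables(phage)
  tmap <- tipMap(pair)
  leafTo <- vapply(phage$tip.label, function(lb)
    match(tmap[[lb]], host$tip.label), integer(1))
  internals <- which(lengths(P$kids) == 2L)
  if (!length(internals)) {
    return(list(minCost = 0, count = 1))
  }
  nInt <- length(internals)
  bestCost <- Inf
  bestCount <- 0
  assign <- rep(1L, nInt)
  repeat {
    m <- rep(NA_integer_, P$N)
    m[seq_len(P$n)] <- leafTo
    m[internals] <- assign
    tot <- 0
    cnt <- 1
    ok <- TRUE
    for (idx in seq_len(nInt)) {
      p <- internals[idx]
      ck <- P$kids[[p]]
      opts <- oracleNodeOptions(H, m[p], m[ck[1]], m[ck[2]], costs)
      if (!length(opts)) { ok <- FALSE; break }
      lo <- min(opts)
      tot <- tot + lo
      cnt <- cnt * sum(opts <= lo + 1e-9)
      if (tot > bestCost + 1e-9) { ok <- FALSE; break }
    }
    if (ok) {
      if (tot < bestCost - 1e-9) {
        bestCost <- tot
        bestCount <- cnt
      } else if (tot <= bestCost + 1e-9) {
        bestCount <- bestCount + cnt
      }
    }
    # next assignment in mixed-radix order
    i <- 1L
    while (i <= nInt) {
      assign[i] <- assign[i] + 1L
      if (assign[i] <= H$N) break
      assign[i] <- 1L
      i <- i + 1L
    }
    if (i > nInt) break
  }
  list(minCost = bestCost, count = bestCount)
}

# all rooted binary tree shapes on n tips as newick strings with the given
# tip labels assigned left to right
treeShapes <- function(n, labels) {
  shapes <- function(k) {
    if (k == 1L) return(list(1L))
    out <- list()
    for (l in seq_len(k %/% 2)) {
      for (a in shapes(l)) for (b in shapes(k - l)) {
        out[[length(out) + 1L]] <- list(a, b)
      }
    }
    out
  }
  toNwk <- function(s, env) {
    if (is.integer(s)) {
      env$i <- env$i + 1L
      return(labels[env$i])
    }
    paste0("(", toNwk(s[[1]], env), ",", toNwk(s[[2]], env), ")")
  }
  lapply(shapes(n), function(s) {
    env <- new.env(); env$i <- 0L
    paste0(toNwk(s, env), ";")
  })
}
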