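#' Event costs for DTL reconciliation
#'
#' @param cospeciation,duplication,transfer,loss non-negative event costs.
#'   Defaults are the weighting used throughout: cospeciation free,
#'   transfer 1, duplication 2, loss 1 (loss 2 is the alternative setting).
#' @return named numeric cost vector.
#' @export
dtlCosts <- function(cospeciation = 0, duplication = 2, transfer = 1,
                     loss = 1) {
  out <- c(cospeciation = cospeciation, duplication = duplication,
           transfer = transfer, loss = loss)
  stopIfNot(all(out >= 0), "event costs must be non-negative")
  out
}

# static topology tables for one rooted binary tree (ape numbering:
# tips 1..n, internals n+1..; root = n+1)
treeInfo <- function(tree) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  children <- vector("list", N)
  parent <- rep(NA_integer_, N)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    children[[a]] <- c(children[[a]], b)
    parent[b] <- a
  }
  root <- if (n == 1L) N else n + 1L
  # postorder: children before parents
  post <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(v, post)
    stack <- c(stack, children[[v]])
  }
  desc <- matrix(FALSE, N, N)     # desc[a, b]: b inside subtree of a
  distDown <- matrix(NA_real_, N, N)  # edges from a down to b
  for (v in post) {
    desc[v, v] <- TRUE
    distDown[v, v] <- 0
    for (ch in children[[v]]) {
      inCh <- which(desc[ch, ])
      desc[v, inCh] <- TRUE
      distDown[v, inCh] <- distDown[ch, inCh] + 1
    }
  }
  incomp <- !(desc | t(desc))
  list(tree = tree, n = n, N = N, root = root, children = children,
       parent = parent, post = post, desc = desc, distDown = distDown,
       incomp = incomp)
}

# assemble DP inputs shared by all reconciliation operations
dtlSetup <- function(pair, costs) {
  stopifnot(is(pair, "TreePair"))
  validObject(pair)
  H <- treeInfo(pair@hostTree)
  P <- treeInfo(pair@phageTree)
  hostIdx <- stats::setNames(seq_len(H$n), pair@hostTree$tip.label)
  leafMap <- rep(NA_integer_, P$N)
  for (tipLab in pair@phageTree$tip.label) {
    tgt <- pair@tipMap[[tipLab]]
    stopIfNot(!is.null(tgt) && !is.na(tgt), "phage tip '%s' is unmapped",
              tipLab)
    leafMap[match(tipLab, pair@phageTree$tip.label)] <- hostIdx[[tgt]]
  }
  list(H = H, P = P, leafMap = leafMap, costs = costs)
}

EPS <- 1e-9

# The undated DTL dynamic program. For each phage node p and host node h:
#   C[p,h]  cheapest reconciliation of p's subtree with p mapped exactly at h
#   IN[p,h] cheapest with p mapped at h or anywhere below, charging one loss
#           per host edge passed
#   OUT[p,h] cheapest with p mapped at any host node incomparable to h
# N* are the matching solution counts.
dtlTables <- function(setup) {
  H <- setup$H; P <- setup$P; costs <- setup$costs
  co <- costs[["cospeciation"]]; du <- costs[["duplication"]]
  tr <- costs[["transfer"]]; lo <- costs[["loss"]]
  C <- matrix(Inf, P$N, H$N); NC <- matrix(0, P$N, H$N)
  IN <- matrix(Inf, P$N, H$N); NIN <- matrix(0, P$N, H$N)
  OUT <- matrix(Inf, P$N, H$N); NOUT <- matrix(0, P$N, H$N)
  for (p in P$post) {
    kids <- P$children[[p]]
    if (!length(kids)) {
      h0 <- setup$leafMap[p]
      C[p, h0] <- 0; NC[p, h0] <- 1
    } else if (length(kids) == 1L) {
      # a single-tip phage tree carries a degenerate root: pass through
      C[p, ] <- C[kids, ]; NC[p, ] <- NC[kids, ]
    } else {
      p1 <- kids[1]; p2 <- kids[2]
      for (h in seq_len(H$N)) {
        hk <- H$children[[h]]
        opts <- numeric(0); cnts <- numeric(0)
        if (length(hk) == 2L) {
          hL <- hk[1]; hR <- hk[2]
          opts <- c(opts, co + IN[p1, hL] + IN[p2, hR],
                          co + IN[p1, hR] + IN[p2, hL])
          cnts <- c(cnts, NIN[p1, hL] * NIN[p2, hR],
                          NIN[p1, hR] * NIN[p2, hL])
        }
        opts <- c(opts, du + IN[p1, h] + IN[p2, h])
        cnts <- c(cnts, NIN[p1, h] * NIN[p2, h])
        opts <- c(opts, tr + IN[p1, h] + OUT[p2, h],
                        tr + IN[p2, h] + OUT[p1, h])
        cnts <- c(cnts, NIN[p1, h] * NOUT[p2, h],
                        NIN[p2, h] * NOUT[p1, h])
        best <- min(opts)
        C[p, h] <- best
        if (is.finite(best))
          NC[p, h] <- sum(cnts[opts <= best + EPS])
      }
    }
    # IN: allow descent through host edges at `lo` per edge
    for (h in H$post) {
      opts <- C[p, h]; cnts <- NC[p, h]
      for (hc in H$children[[h]]) {
        opts <- c(opts, lo + IN[p, hc])
        cnts <- c(cnts, NIN[p, hc])
      }
      best <- min(opts)
      IN[p, h] <- best
      if (is.finite(best)) NIN[p, h] <- sum(cnts[opts <= best + EPS])
    }
    # OUT: cheapest placement at an incomparable host node
    for (h in seq_len(H$N)) {
      inc <- which(H$incomp[h, ])
      if (!length(inc)) next
      best <- min(C[p, inc])
      OUT[p, h] <- best
      if (is.finite(best))
        NOUT[p, h] <- sum(NC[p, inc][C[p, inc] <= best + EPS])
    }
  }
  list(C = C, NC = NC, IN = IN, NIN = NIN, OUT = OUT, NOUT = NOUT)
}

#' Minimum DTL reconciliation cost
#'
#' Dynamic program over (phage node, host node) pairs for the undated
#' duplication-transfer-loss maximum-parsimony model: internal phage nodes
#' resolve as cospeciation (children split into the two host child
#' subtrees), duplication (both children stay within the host subtree) or
#' transfer (one child stays, the other lands on a host node incomparable
#' to the donor -- neither ancestor nor descendant; no timing constraint),
#' with one loss charged per host edge a lineage passes. The minimum over
#' host placements of the phage root is returned.
#'
#' @param pair a [TreePair-class] (both trees binary, tip map total).
#' @param costs a [dtlCosts()] vector.
#' @return list: `minCost`, `tables` (the DP matrices), `setup` (internal
#'   topology tables, reused by the other reconciliation operations).
#' @export
dtlMinCost <- function(pair, costs = dtlCosts()) {
  setup <- dtlSetup(pair, costs)
  tab <- dtlTables(setup)
  rootRow <- tab$C[setup$P$root, ]
  list(minCost = min(rootRow), tables = tab, setup = setup)
}

#' Count maximum-parsimony reconciliations
#'
#' Number of distinct minimum-cost event certificates, computed inside the
#' DP by summing counts over cost-tied choices and multiplying counts over
#' independent subproblems.
#'
#' @inheritParams dtlMinCost
#' @return numeric count (exact).
#' @export
countMPRs <- function(pair, costs = dtlCosts()) {
  fit <- dtlMinCost(pair, costs)
  rootRow <- fit$tables$C[fit$setup$P$root, ]
  best <- min(rootRow)
  sum(fit$tables$NC[fit$setup$P$root, ][rootRow <= best + EPS])
}

# --- certificate enumeration by DP backtracking ------------------------

# a partial certificate: list(map = named int vector phage->host,
# events = data.frame(phageNode, event, hostNode))
emptyCert <- function() list(
  map = integer(0),
  events = data.frame(phageNode = integer(), event = character(),
                      hostNode = integer()))

mergeCerts <- function(a, b) list(
  map = c(a$map, b$map),
  events = rbind(a$events, b$events))

addEvent <- function(cert, p, event, h) {
  cert$events <- rbind(cert$events, data.frame(
    phageNode = p, event = event, hostNode = h))
  cert
}

# Each enum* function returns at most `limit` certificates, in a fixed
# deterministic order (cospeciation, duplication, transfer; host nodes in
# child order for losses; incomparable hosts in index order for transfers).
enumC <- function(p, h, tab, setup, limit) {
  if (limit <= 0L) return(list())
  P <- setup$P; H <- setup$H; costs <- setup$costs
  kids <- P$children[[p]]
  if (!length(kids)) {
    cert <- emptyCert()
    cert$map <- stats::setNames(h, p)
    return(list(cert))
  }
  if (length(kids) == 1L) {
    out <- enumC(kids, h, tab, setup, limit)
    return(lapply(out, function(cert) {
      cert$map <- c(cert$map, stats::setNames(h, p))
      cert
    }))
  }
  p1 <- kids[1]; p2 <- kids[2]
  target <- tab$C[p, h]
  out <- list()
  cross <- function(lhs, rhsFun, event) {
    for (a in lhs) {
      if (length(out) >= limit) break
      for (b in rhsFun(limit - length(out))) {
        cert <- addEvent(mergeCerts(a, b), p, event, h)
        cert$map <- c(cert$map, stats::setNames(h, p))
        out[[length(out) + 1L]] <<- cert
        if (length(out) >= limit) break
      }
    }
  }
  hk <- H$children[[h]]
  if (length(hk) == 2L) {
    hL <- hk[1]; hR <- hk[2]
    if (costs[["cospeciation"]] + tab$IN[p1, hL] + tab$IN[p2, hR] <=
        target + EPS)
      cross(enumIN(p1, hL, tab, setup, limit - length(out)),
            function(l) enumIN(p2, hR, tab, setup, l), "cospeciation")
    if (costs[["cospeciation"]] + tab$IN[p1, hR] + tab$IN[p2, hL] <=
        target + EPS)
      cross(enumIN(p1, hR, tab, setup, limit - length(out)),
            function(l) enumIN(p2, hL, tab, setup, l), "cospeciation")
  }
  if (costs[["duplication"]] + tab$IN[p1, h] + tab$IN[p2, h] <= target + EPS)
    cross(enumIN(p1, h, tab, setup, limit - length(out)),
          function(l) enumIN(p2, h, tab, setup, l), "duplication")
  if (costs[["transfer"]] + tab$IN[p1, h] + tab$OUT[p2, h] <= target + EPS)
    cross(enumIN(p1, h, tab, setup, limit - length(out)),
          function(l) enumOUT(p2, h, tab, setup, l), "transfer")
  if (costs[["transfer"]] + tab$IN[p2, h] + tab$OUT[p1, h] <= target + EPS)
    cross(enumIN(p2, h, tab, setup, limit - length(out)),
          function(l) enumOUT(p1, h, tab, setup, l), "transfer")
  out
}

enumIN <- function(p, h, tab, setup, limit) {
  if (limit <= 0L) return(list())
  target <- tab$IN[p, h]
  out <- list()
  if (tab$C[p, h] <= target + EPS)
    out <- enumC(p, h, tab, setup, limit)
  for (hc in setup$H$children[[h]]) {
    if (length(out) >= limit) break
    if (setup$costs[["loss"]] + tab$IN[p, hc] <= target + EPS) {
      sub <- enumIN(p, hc, tab, setup, limit - length(out))
      out <- c(out, lapply(sub, addEvent, p = p, event = "loss", h = hc))
    }
  }
  out
}

enumOUT <- function(p, h, tab, setup, limit) {
  if (limit <= 0L) return(list())
  target <- tab$OUT[p, h]
  out <- list()
  for (hp in which(setup$H$incomp[h, ])) {
    if (length(out) >= limit) break
    if (tab$C[p, hp] <= target + EPS)
      out <- c(out, enumC(p, hp, tab, setup, limit - length(out)))
  }
  out
}

certToReconciliation <- function(cert, setup, minCost) {
  costs <- setup$costs
  ev <- cert$events
  counts <- c(
    cospeciation = sum(ev$event == "cospeciation"),
    duplication = sum(ev$event == "duplication"),
    transfer = sum(ev$event == "transfer"),
    loss = sum(ev$event == "loss"))
  nm <- rep(NA_integer_, setup$P$N)
  nm[as.integer(names(cert$map))] <- as.integer(cert$map)
  new("Reconciliation", nodeMap = nm, events = ev, counts = counts,
      totalCost = sum(counts * costs[names(counts)]), costs = costs)
}

#' Enumerate maximum-parsimony reconciliations
#'
#' Backtracks the counting DP, yielding distinct certificates in a
#' deterministic order (cospeciation before duplication before transfer;
#' host nodes in a fixed tree order) until `cap` certificates have been
#' produced. The exact MPR count is reported alongside even when the
#' sample is truncated.
#'
#' @inheritParams dtlMinCost
#' @param cap maximum number of certificates to materialize (>= 1).
#' @return an [MPRSet-class].
#' @export
enumerateMPRs <- function(pair, costs = dtlCosts(), cap = 100L) {
  stopIfNot(cap >= 1L, "cap must be >= 1")
  fit <- dtlMinCost(pair, costs)
  tab <- fit$tables; setup <- fit$setup
  rootRow <- tab$C[setup$P$root, ]
  best <- min(rootRow)
  total <- sum(tab$NC[setup$P$root, ][rootRow <= best + EPS])
  certs <- list()
  for (h in seq_len(setup$H$N)) {
    if (length(certs) >= cap) break
    if (rootRow[h] <= best + EPS)
      certs <- c(certs, enumC(setup$P$root, h, tab, setup,
                              cap - length(certs)))
  }
  sample <- lapply(certs, certToReconciliation, setup = setup,
                   minCost = best)
  for (r in sample)
    stopIfNot(abs(r@totalCost - best) < 1e-6,
              "internal error: enumerated certificate off the minimum cost")
  new("MPRSet", count = total, sample = sample, clusters = integer(0),
      representatives = integer(0), minCost = best)
}

#' Re-check a reconciliation certificate bottom-up
#'
#' Independently verifies that a certificate is consistent: leaf mappings
#' agree with the tip map; each internal phage node's event is geometrically
#' valid for the host placements of the node and its children; the loss
#' rows equal the host-edge passages those placements imply; and the total
#' cost equals the event counts priced at the certificate's costs.
#'
#' @param pair the [TreePair-class] the certificate reconciles.
#' @param rec a [Reconciliation-class].
#' @return `TRUE`, invisibly; otherwise an error describing the violation.
#' @export
validateReconciliation <- function(pair, rec) {
  setup <- dtlSetup(pair, rec@costs)
  H <- setup$H; P <- setup$P
  nm <- rec@nodeMap
  for (tip in seq_len(P$n))
    stopIfNot(nm[tip] == setup$leafMap[tip],
              "leaf mapping disagrees with the tip map at phage tip %d", tip)
  ev <- rec@events
  lossTally <- 0L
  for (p in P$post) {
    kids <- P$children[[p]]
    if (length(kids) != 2L) next
    h <- nm[p]; m1 <- nm[kids[1]]; m2 <- nm[kids[2]]
    type <- ev$event[ev$phageNode == p & ev$event != "loss"]
    stopIfNot(length(type) == 1L,
              "phage node %d needs exactly one non-loss event", p)
    hk <- H$children[[h]]
    passages <- switch(type,
      cospeciation = {
        stopIfNot(length(hk) == 2L, "cospeciation at a host tip (node %d)", p)
        ok1 <- H$desc[hk[1], m1] && H$desc[hk[2], m2]
        ok2 <- H$desc[hk[2], m1] && H$desc[hk[1], m2]
        stopIfNot(ok1 || ok2, "invalid cospeciation geometry at node %d", p)
        if (ok1) H$distDown[hk[1], m1] + H$distDown[hk[2], m2]
        else H$distDown[hk[2], m1] + H$distDown[hk[1], m2]
      },
      duplication = {
        stopIfNot(H$desc[h, m1] && H$desc[h, m2],
                  "invalid duplication geometry at node %d", p)
        H$distDown[h, m1] + H$distDown[h, m2]
      },
      transfer = {
        ok1 <- H$desc[h, m1] && H$incomp[h, m2]
        ok2 <- H$desc[h, m2] && H$incomp[h, m1]
        stopIfNot(ok1 || ok2, "invalid transfer geometry at node %d", p)
        if (ok1) H$distDown[h, m1] else H$distDown[h, m2]
      },
      stop(sprintf("unknown event '%s'", type)))
    lossTally <- lossTally + passages
  }
  stopIfNot(lossTally == sum(ev$event == "loss"),
            "loss rows (%d) do not match implied host-edge passages (%d)",
            sum(ev$event == "loss"), lossTally)
  counts <- rec@counts
  implied <- sum(counts * rec@costs[names(counts)])
  stopIfNot(abs(implied - rec@totalCost) < 1e-9,
            "stated total cost disagrees with counts and costs")
  invisible(TRUE)
}
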