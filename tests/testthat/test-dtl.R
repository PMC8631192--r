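test_that("congruent trees reconcile at zero cost with a single MPR", {
  for (n in c(3, 4, 6)) {
    pair <- congruentPair(n)
    expect_equal(dtlMinCost(pair)$minCost, 0)
    expect_equal(countMPRs(pair), 1)
    m <- enumerateMPRs(pair)
    expect_length(m@sample, 1L)
    rec <- m@sample[[1]]
    expect_equal(unname(eventCounts(rec)), c(n - 1, 0, 0, 0))
    expect_true(validateReconciliation(pair, rec))
  }
})

test_that("single-tip trees reconcile trivially", {
  pair <- tp("(H1);", "(P1);", c(P1 = "H1"))
  expect_equal(dtlMinCost(pair)$minCost, 0)
  expect_equal(countMPRs(pair), 1)
})

test_that("the DP agrees with the exhaustive oracle on a discordant case", {
  pair <- tp("((A,B),C);", "((a,c),b);",
             c(a = "A", c = "C", b = "B"))
  for (costs in list(dtlCosts(), dtlCosts(loss = 2),
                     dtlCosts(0.5, 1.5, 1.2, 0.8))) {
    want <- oracleDTL(pair, costs)
    expect_equal(dtlMinCost(pair, costs)$minCost, want$minCost)
    expect_equal(countMPRs(pair, costs), want$count)
  }
})

test_that("enumeration is exhaustive, valid and deterministic", {
  pair <- tp("((A,B),(C,D));", "((a,c),(b,d));",
             c(a = "A", b = "B", c = "C", d = "D"))
  costs <- dtlCosts()
  cnt <- countMPRs(pair, costs)
  m <- enumerateMPRs(pair, costs, cap = 1000L)
  expect_equal(length(m@sample), cnt)
  expect_equal(m@count, cnt)
  keys <- vapply(m@sample, function(r)
    paste(ProphageKit:::eventSetKey(r), collapse = ";"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (r in m@sample) {
    expect_equal(totalCost(r), m@minCost)
    expect_true(validateReconciliation(pair, r))
  }
  m2 <- enumerateMPRs(pair, costs, cap = 1000L)
  expect_identical(vapply(m2@sample, function(r)
    paste(ProphageKit:::eventSetKey(r), collapse = ";"), character(1)),
    keys)
  # capped enumeration truncates the sample but not the count
  m3 <- enumerateMPRs(pair, costs, cap = 2L)
  expect_length(m3@sample, min(2L, cnt))
  expect_equal(m3@count, cnt)
})

test_that("tied transfer targets multiply the MPR count", {
  # phage tip d attaches far from its siblings: several equally cheap
  # transfer placements must be counted and enumerated consistently
  pair <- tp("(((A,B),C),(D,E));", "(((a,b),d),(c,e));",
             c(a = "A", b = "B", c = "C", d = "D", e = "E"))
  costs <- dtlCosts()
  want <- oracleDTL(pair, costs)
  expect_equal(dtlMinCost(pair, costs)$minCost, want$minCost)
  expect_equal(countMPRs(pair, costs), want$count)
  expect_gt(want$count, 1)
  m <- enumerateMPRs(pair, costs, cap = 10000L)
  expect_equal(length(m@sample), want$count)
})

test_that("invalid inputs are rejected", {
  pair <- congruentPair(3)
  expect_error(dtlCosts(loss = -1), "non-negative")
  poly <- ape::read.tree(text = "(P1,P2,P3);")
  expect_error(treePair(hostTree(pair), poly,
                        tipMap(pair)), "rooted|binary")
  poly4 <- ape::read.tree(text = "((P1,P2,P3),P4);")
  expect_error(treePair(ape::read.tree(text = "((H1,H2),(H3,H4));"), poly4,
                        stats::setNames(paste0("H", 1:4), paste0("P", 1:4))),
               "binary")
  tm <- tipMap(pair)
  tm["P2"] <- NA
  expect_error(treePair(hostTree(pair), phageTree(pair), tm),
               "host tip labels")
})

test_that("DP and oracle agree across random tree pairs", {
  set.seed(42)
  for (rep in 1:10) {
    nh <- sample(3:5, 1)
    np <- sample(3:5, 1)
    host <- ape::rtree(nh, tip.label = paste0("H", 1:nh))
    phage <- ape::rtree(np, tip.label = paste0("P", 1:np))
    tm <- stats::setNames(paste0("H", sample(nh, np, replace = TRUE)),
                          paste0("P", 1:np))
    pair <- treePair(host, phage, tm)
    for (costs in list(dtlCosts(), dtlCosts(loss = 2))) {
      want <- oracleDTL(pair, costs)
      expect_equal(dtlMinCost(pair, costs)$minCost, want$minCost)
      expect_equal(countMPRs(pair, costs), want$count)
    }
  }
})
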