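test_that("MPR clustering separates constructed certificate groups", {
  # a discordant pair with several MPRs differing in transfer placement
  pair <- tp("(((A,B),C),(D,E));", "(((a,b),d),(c,e));",
             c(a = "A", b = "B", c = "C", d = "D", e = "E"))
  m <- enumerateMPRs(pair, dtlCosts(), cap = 500L)
  k <- 2L
  cl <- clusterMPRs(m, k)
  expect_length(cl@clusters, length(m@sample))
  expect_equal(sort(unique(cl@clusters)), 1:2)
  expect_length(cl@representatives, 2L)
  # medoids carry their own cluster label
  expect_equal(cl@clusters[cl@representatives], 1:2)
})

test_that("identical certificates cannot be split", {
  pair <- congruentPair(4)
  m <- enumerateMPRs(pair)
  cl <- clusterMPRs(m, 1L)
  expect_equal(unique(cl@clusters), 1L)
  expect_error(clusterMPRs(m, 2L), "exceeds")
})

test_that("medoids minimize within-cluster distance sums (brute force)", {
  pair <- tp("(((A,B),C),(D,E));", "(((a,b),d),(c,e));",
             c(a = "A", b = "B", c = "C", d = "D", e = "E"))
  m <- enumerateMPRs(pair, dtlCosts(), cap = 8L)
  n <- length(m@sample)
  keys <- lapply(m@sample, ProphageKit:::eventSetKey)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- length(setdiff(keys[[i]], keys[[j]])) +
      length(setdiff(keys[[j]], keys[[i]]))
  cl <- clusterMPRs(m, 1L)
  expect_equal(sum(D[cl@representatives[1], ]), min(rowSums(D)))
})

test_that("cost space is a single cospeciation region for congruent trees", {
  pair <- congruentPair(5)
  cs <- costSpace(pair, transferRange = c(0.5, 1, 2),
                  lossRange = c(0.5, 1, 2))
  expect_equal(unique(cs$region), 1L)
  expect_true(all(cs$signatures == "4,0,0,0"))
  expect_true(all(cs$minCost == 0))
})

test_that("optimal cost is monotone in each cost parameter", {
  sc <- simCophylogeny(cophyloSimParams(6, 0.2, 0.05, 0.1, seed = 77))
  pair <- scenarioPair(sc)
  tr <- c(0.5, 1, 1.5, 2)
  lr <- c(0.5, 1, 1.5, 2)
  cs <- costSpace(pair, tr, lr, cap = 50L)
  for (l in lr) {
    mc <- cs$minCost[cs$loss == l][order(cs$transfer[cs$loss == l])]
    expect_true(all(diff(mc) >= -1e-9))
  }
  for (t in tr) {
    mc <- cs$minCost[cs$transfer == t][order(cs$loss[cs$transfer == t])]
    expect_true(all(diff(mc) >= -1e-9))
  }
})

test_that("loss weighting can flip the optimal event signature", {
  # b sits with C: either one transfer, or duplication plus losses;
  # the balance shifts between loss = 1 and loss = 2
  pair <- tp("((A,B),C);", "((a,c),b);", c(a = "A", c = "C", b = "B"))
  cs <- costSpace(pair, transferRange = c(1, 3), lossRange = c(0.25, 2),
                  cap = 100L)
  sigs <- unique(cs$signatures)
  expect_gt(length(sigs), 1L)
})

test_that("permutation p-values are reproducible, bounded and sensitive", {
  pair <- congruentPair(8)
  pt1 <- permutationTest(pair, nPerm = 199, seed = 5)
  pt2 <- permutationTest(pair, nPerm = 199, seed = 5)
  expect_identical(pt1$p, pt2$p)
  expect_gt(pt1$p, 0)
  expect_lte(pt1$p, 1)
  expect_equal(pt1$observed, 0)
  # congruence is rare under permuted associations
  expect_lte(pt1$p, 0.05)
  expect_error(permutationTest(pair, nPerm = 10), ">= 99")
  # topology null runs and is seeded
  pt3 <- permutationTest(pair, nPerm = 99, seed = 6, null = "topology")
  expect_gt(pt3$p, 0)
})

test_that("a randomly attached panel shows no codivergence signal", {
  set.seed(8)
  host <- ape::rtree(8, tip.label = paste0("H", 1:8))
  phage <- ape::rtree(8, tip.label = paste0("P", 1:8))
  tm <- stats::setNames(paste0("H", sample(8)), paste0("P", 1:8))
  pair <- treePair(host, phage, tm)
  pt <- permutationTest(pair, nPerm = 199, seed = 9)
  expect_gt(pt$p, 0.05)
})
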