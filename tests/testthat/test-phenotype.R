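mkAssay <- function(plusVals, minusVals, times = c(0, 20, 40)) {
  assayTable(data.frame(
    series_id = rep(c("p", "c"), each = length(times)),
    phage_id = rep(c("phi", "none"), each = length(times)),
    host_id = "h", replicate = "r1",
    time = rep(times, 2), value = c(plusVals, minusVals),
    treatment = rep(c("phage+", "phage-"), each = length(times))))
}

test_that("RBG reproduces its defining arithmetic and identities", {
  # delta+ = 0.2, delta- = 0.5 -> 0.6
  at <- mkAssay(c(0.1, 0.2, 0.3), c(0.1, 0.3, 0.6))
  expect_equal(computeRBG(at, tx = 40)$rbg, 0.6)
  # phage+ identical to control -> 0
  at0 <- mkAssay(c(0.1, 0.3, 0.6), c(0.1, 0.3, 0.6))
  expect_equal(computeRBG(at0, tx = 40)$rbg, 0)
  # flat phage+ -> 1
  at1 <- mkAssay(c(0.2, 0.2, 0.2), c(0.1, 0.3, 0.6))
  expect_equal(computeRBG(at1, tx = 40)$rbg, 1)
})

test_that("RBG is invariant to blank subtraction and OD rescaling", {
  base <- mkAssay(c(0.10, 0.15, 0.30), c(0.10, 0.30, 0.60))
  r0 <- computeRBG(base, tx = 40)$rbg
  shifted <- base; shifted$value <- shifted$value + 0.37
  expect_equal(computeRBG(shifted, tx = 40)$rbg, r0, tolerance = 1e-12)
  scaled <- base; scaled$value <- scaled$value * 3.1
  expect_equal(computeRBG(scaled, tx = 40)$rbg, r0, tolerance = 1e-12)
})

test_that("non-growing controls are flagged rather than divided by", {
  at <- mkAssay(c(0.1, 0.2, 0.3), c(0.6, 0.3, 0.1))
  res <- computeRBG(at, tx = 40)
  expect_true(is.na(res$rbg))
  expect_equal(res$flag, "control_nonpositive")
})

test_that("host-range grading follows the spot-assay rules", {
  expect_equal(as.character(gradeHostRange("turbid", FALSE, FALSE,
                                           FALSE)$grade), "weak")
  expect_equal(as.character(gradeHostRange("clear", TRUE, FALSE,
                                           FALSE)$grade), "strong")
  expect_equal(as.character(gradeHostRange("clear", TRUE, TRUE,
                                           TRUE)$grade), "lysogenization")
  expect_equal(as.character(gradeHostRange("none", FALSE, FALSE,
                                           FALSE)$grade), "none")
  # regrowth without a PCR verdict stays strong, flagged
  res <- gradeHostRange("clear", TRUE, TRUE, NA)
  expect_equal(as.character(res$grade), "strong")
  expect_equal(res$flag, "lysogeny_untested")
  expect_error(gradeHostRange("hazy", FALSE, FALSE, FALSE), "day1Clearing")
})

test_that("one-step fits recover the generator's parameters", {
  clean <- simOneStep(latentMin = 50, burst = 255, noiseSd = 0)
  fit <- fitOneStep(clean)
  expect_equal(fit@burstSize, 255, tolerance = 1e-9)
  expect_lt(abs(fit@latentMin - 50), 30)
  # flat series: burst near 1, latent undefined
  flat <- simOneStep(latentMin = 50, burst = 1, noiseSd = 0)
  ffit <- fitOneStep(flat)
  expect_true(is.na(ffit@latentMin))
  expect_equal(ffit@burstSize, 1, tolerance = 1e-6)
  expect_false(ffit@diagnostics$riseDetected)
  # noisy recovery at slow-phage parameter values
  lat <- vapply(1:4, function(i)
    latentPeriod(fitOneStep(simOneStep(latentMin = 90, burst = 60,
                                       noiseSd = 0.05, seed = i))),
    numeric(1))
  expect_lt(abs(mean(lat) - 90), 5)
  expect_error(fitOneStep(simOneStep()[1:4, ]), "at least 6")
})

test_that("parameter recovery holds across the latent/burst grid", {
  set.seed(7)
  cases <- expand.grid(L = seq(30, 120, by = 10), B = c(10, 60, 150, 300))
  res <- t(mapply(function(L, B) {
    s <- simOneStep(latentMin = L, burst = B, noiseSd = 0.05)
    f <- fitOneStep(s)
    c(latErr = f@latentMin - L, relBurst = f@burstSize / B - 1)
  }, cases$L, cases$B))
  expect_lte(median(abs(res[, "latErr"])), 15)
  expect_lte(median(abs(res[, "relBurst"])), 0.10)
})

test_that("two-way ANOVA matches the closed-form decomposition", {
  # balanced 2x2 with 2 reps, hand-computable
  y <- c(10, 12, 20, 22, 30, 28, 44, 46)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(rep(c("b1", "b2"), each = 2), 2)
  res <- anovaWithContrasts(y, A, B)
  gm <- mean(y)
  ssA <- 4 * sum((tapply(y, A, mean) - gm)^2)
  ssB <- 4 * sum((tapply(y, B, mean) - gm)^2)
  cellMeans <- tapply(y, list(A, B), mean)
  ssAB <- 2 * sum((cellMeans - outer(tapply(y, A, mean),
                                     tapply(y, B, mean), "+") + gm)^2)
  ssE <- sum((y - cellMeans[cbind(A, B)])^2)
  expect_equal(res$anova$F[1], (ssA / 1) / (ssE / 4), tolerance = 1e-9)
  expect_equal(res$anova$F[2], (ssB / 1) / (ssE / 4), tolerance = 1e-9)
  expect_equal(res$anova$F[3], (ssAB / 1) / (ssE / 4), tolerance = 1e-9)
  # contrast t from pooled error
  tHand <- (mean(y[A == "a1"]) - mean(y[A == "a2"])) /
    sqrt((ssE / 4) * (1 / 4 + 1 / 4))
  expect_equal(res$contrasts$t[1], tHand, tolerance = 1e-9)
})

test_that("the 3x2x3 virulence design yields the expected df structure", {
  set.seed(8)
  phage <- rep(c("phiA", "phiB", "phiC"), each = 6)
  host <- rep(rep(c("hostA", "hostB"), each = 3), 3)
  y <- rnorm(18)
  res <- anovaWithContrasts(y, phage, host)
  expect_equal(res$anova$df[res$anova$term == "factorA"], 2L)
  expect_equal(res$residDf, 12L)
  expect_equal(nrow(res$contrasts), 3L)
  # saturated zero-variance design reports F = 0, p = 1
  resFlat <- anovaWithContrasts(rep(1, 18), phage, host)
  expect_true(all(resFlat$anova$F == 0))
  expect_true(all(resFlat$anova$p == 1))
  expect_true(all(resFlat$contrasts$p == 1))
  # empty cells are named
  expect_error(anovaWithContrasts(y[-(1:3)], phage[-(1:3)], host[-(1:3)]),
               "no observations")
})
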