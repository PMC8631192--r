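#' Reduction in bacterial growth (RBG)
#'
#' Virulence of a phage on a host over a window `[t0, tx]`:
#' `1 - (OD+(tx) - OD+(t0)) / (OD-(tx) - OD-(t0))`, the OD gain of the
#' infected culture relative to its paired uninfected control. 0 means the
#' phage did not slow growth, 1 means the infected culture did not grow at
#' all. Each phage+ series is paired with the phage- control sharing its
#' host and replicate; readings are taken at the recorded time nearest to
#' `t0`/`tx` within half a sampling interval.
#'
#' @param assay an `AssayTable` of OD series ([assayTable()]).
#' @param tx window end in minutes (e.g. 600 for the early lysis read-out,
#'   2400 for the overall impact).
#' @param t0 window start in minutes; default the first reading of each
#'   series.
#' @return data.frame: `phage_id`, `host_id`, `replicate`, `t0`, `tx`,
#'   `rbg`, `flag` (`"ok"` or `"control_nonpositive"`, where `rbg` is `NA`
#'   because the control gained no OD).
#' @export
computeRBG <- function(assay, tx, t0 = NULL) {
  df <- assay[if (is.null(assay$measure)) rep(TRUE, nrow(assay)) else
    assay$measure == "OD", , drop = FALSE]
  plus <- df[df$treatment == "phage+", , drop = FALSE]
  res <- list()
  for (sid in unique(plus$series_id)) {
    sp <- plus[plus$series_id == sid, , drop = FALSE]
    ctrl <- df[df$treatment == "phage-" &
               df$host_id == sp$host_id[1] &
               df$replicate == sp$replicate[1], , drop = FALSE]
    stopIfNot(nrow(ctrl) > 0, "no phage- control for series '%s'", sid)
    step <- stats::median(diff(sort(unique(sp$time))))
    readAt <- function(series, t) {
      i <- which.min(abs(series$time - t))
      stopIfNot(abs(series$time[i] - t) <= step / 2 + 1e-9,
                "no reading within half a step of t = %g in '%s'",
                t, series$series_id[1])
      series$value[i]
    }
    tt0 <- if (is.null(t0)) min(sp$time) else t0
    dPlus <- readAt(sp, tx) - readAt(sp, tt0)
    dMinus <- readAt(ctrl, tx) - readAt(ctrl, tt0)
    if (dMinus <= 0) {
      rbg <- NA_real_; flag <- "control_nonpositive"
    } else {
      rbg <- 1 - dPlus / dMinus; flag <- "ok"
    }
    res[[length(res) + 1L]] <- data.frame(
      phage_id = sp$phage_id[1], host_id = sp$host_id[1],
      replicate = sp$replicate[1], t0 = tt0, tx = tx, rbg = rbg,
      flag = flag)
  }
  do.call(rbind, res)
}

#' Grade spot-assay host range
#'
#' Deterministic grading from four observations per phage x host spot:
#' no clearing is `none`; turbid clearing at high titre after day 1 is
#' `weak`; a clear zone plus individual plaques at dilution is `strong`;
#' a strong infection whose spot regrows and whose colonies are
#' PCR-positive for the phage is `lysogenization`. Regrowth without a PCR
#' result stays `strong` with a `lysogeny_untested` flag; clear zones
#' without plaques are graded `weak` (no productive infection shown).
#'
#' @param day1Clearing `"none"`, `"turbid"` or `"clear"` (vectorized).
#' @param plaquesAtDilution logical: individual plaques at lower titre?
#' @param regrowthInSpot logical: regrowth inside the high-titre spot over
#'   the following days?
#' @param lysogenPcrPositive logical or `NA` (untested).
#' @return data.frame with `grade` (factor: none, weak, strong,
#'   lysogenization) and `flag`.
#' @export
gradeHostRange <- function(day1Clearing, plaquesAtDilution,
                           regrowthInSpot, lysogenPcrPositive) {
  stopIfNot(all(day1Clearing %in% c("none", "turbid", "clear")),
            "day1Clearing must be none, turbid or clear")
  n <- length(day1Clearing)
  grade <- character(n)
  flag <- rep("", n)
  for (i in seq_len(n)) {
    g <- if (day1Clearing[i] == "none") "none"
      else if (day1Clearing[i] == "turbid") "weak"
      else if (isTRUE(plaquesAtDilution[i])) "strong"
      else "weak"
    if (g == "strong" && isTRUE(regrowthInSpot[i])) {
      if (is.na(lysogenPcrPositive[i])) {
        flag[i] <- "lysogeny_untested"
      } else if (isTRUE(lysogenPcrPositive[i])) {
        g <- "lysogenization"
      }
    }
    grade[i] <- g
  }
  data.frame(grade = factor(grade, levels = c("none", "weak", "strong",
                                              "lysogenization")),
             flag = flag)
}

#' Estimate latent period and burst size from a one-step growth curve
#'
#' Plateau/tangent estimator on log10(PFU): the lysis rise is located at
#' the steepest segment of the log-titre curve; the baseline plateau is the
#' mean of pre-rise points and the final plateau the mean of post-rise
#' points (points within 2% / beyond 95% of the log-range); burst size is
#' `10^(plateau - baseline)`; the latent period is where the tangent at the
#' steepest segment intersects the baseline. When the titre never at least
#' doubles, no lysis is declared: burst is still reported and the latent
#' period is `NA`.
#'
#' @param series an `AssayTable` (or data.frame with `time`, `value`)
#'   holding one PFU series with at least 6 time points.
#' @param i0 infected centres; defaults to the fitted baseline.
#' @return a [GrowthFit-class].
#' @export
fitOneStep <- function(series, i0 = NULL) {
  stopIfNot(nrow(series) >= 6L, "need at least 6 time points")
  t <- series$time
  y <- log10(pmax(series$value, .Machine$double.xmin))
  n <- length(t)
  slopes <- diff(y) / diff(t)
  i <- which.max(slopes)
  b0 <- stats::median(y[1:3])
  p0 <- stats::median(y[(n - 2):n])
  rng <- p0 - b0
  preIdx <- which(t <= t[i] & y <= b0 + 0.02 * max(rng, 0))
  if (!length(preIdx)) preIdx <- 1L
  postIdx <- which(t >= t[i + 1] & y >= b0 + 0.95 * max(rng, 0))
  if (!length(postIdx)) postIdx <- which.max(y)
  baseline <- if (is.null(i0)) mean(y[preIdx]) else log10(i0)
  plateau <- mean(y[postIdx])
  burst <- 10^(plateau - baseline)
  riseDetected <- is.finite(burst) && burst >= 2
  if (riseDetected) {
    tMid <- (t[i] + t[i + 1]) / 2
    yMid <- (y[i] + y[i + 1]) / 2
    latent <- tMid - (yMid - baseline) / slopes[i]
    latent <- min(max(latent, min(t)), max(t))
  } else {
    latent <- NA_real_
  }
  fitted <- ifelse(t <= if (is.na(latent)) Inf else latent, baseline,
                   pmin(baseline + (t - ifelse(is.na(latent), 0, latent)) *
                          slopes[i], plateau))
  new("GrowthFit",
      phageId = as.character(series$phage_id[1] %||% "unknown"),
      replicate = as.character(series$replicate[1] %||% "r1"),
      latentMin = latent,
      burstSize = burst,
      diagnostics = list(baseline = 10^baseline, plateau = 10^plateau,
                         rss = sum((y - fitted)^2),
                         riseDetected = riseDetected))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixed-effects ANOVA with pairwise contrasts
#'
#' Sequential (type-I) sums of squares in the order A, B, A:B via
#' `stats::lm`/`stats::anova`, then pairwise contrasts between the levels
#' of factor A on the pooled residual error: `t = (m_i - m_j) /
#' sqrt(MSE (1/n_i + 1/n_j))` with residual degrees of freedom, two-sided
#' p. Contrast p-values are unadjusted by default; `adjust = "tukey"`
#' applies the Tukey studentized-range correction.
#'
#' @param values numeric response.
#' @param factorA primary factor (>= 2 levels).
#' @param factorB optional second factor; when present the model includes
#'   the interaction.
#' @param adjust `"none"` (default) or `"tukey"`.
#' @return list: `anova` (data.frame `term`, `df`, `F`, `p`), `contrasts`
#'   (data.frame `pair`, `estimate`, `t`, `p`), `residDf`, `mse`.
#' @export
anovaWithContrasts <- function(values, factorA, factorB = NULL,
                               adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  A <- factor(factorA)
  stopIfNot(nlevels(A) >= 2L, "factorA needs at least 2 levels")
  if (!is.null(factorB)) {
    B <- factor(factorB)
    cells <- table(A, B)
    if (any(cells == 0)) {
      bad <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("design cell (%s, %s) has no observations",
                   levels(A)[bad[1]], levels(B)[bad[2]]), call. = FALSE)
    }
    fit <- stats::lm(values ~ A * B)
  } else {
    cells <- table(A)
    if (any(cells == 0))
      stop(sprintf("factor level '%s' has no observations",
                   names(cells)[cells == 0][1]), call. = FALSE)
    fit <- stats::lm(values ~ A)
  }
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  terms <- rownames(an)
  keep <- terms != "Residuals"
  residDf <- an["Residuals", "Df"]
  mse <- an["Residuals", "Mean Sq"]
  Fv <- an[keep, "F value"]
  ss <- an[keep, "Sum Sq"]
  pv <- an[keep, "Pr(>F)"]
  # a saturated zero-variance response: report F = 0, p = 1, not 0/0
  degenerate <- mse < 1e-12 & ss < 1e-12
  Fv[degenerate] <- 0
  pv[degenerate] <- 1
  tidyTerm <- function(x) vapply(x, function(tm) switch(
    tm, A = "factorA", B = "factorB", `A:B` = "factorA:factorB", tm),
    character(1), USE.NAMES = FALSE)
  anovaTab <- data.frame(term = tidyTerm(terms[keep]), df = an[keep, "Df"],
                         F = Fv, p = pv, row.names = NULL)
  lev <- levels(A)
  means <- tapply(values, A, mean)
  ns <- tapply(values, A, length)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  ctr <- do.call(rbind, lapply(pairs, function(pr) {
    est <- means[[pr[1]]] - means[[pr[2]]]
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tval <- if (se == 0) { if (est == 0) 0 else Inf * sign(est) } else
      est / se
    p <- if (se == 0) { if (est == 0) 1 else 0 } else if (adjust == "tukey")
      stats::ptukey(sqrt(2) * abs(tval), nlevels(A), residDf,
                    lower.tail = FALSE)
    else 2 * stats::pt(-abs(tval), residDf)
    data.frame(pair = paste(pr[1], pr[2], sep = " - "), estimate = est,
               t = tval, p = p)
  }))
  list(anova = anovaTab, contrasts = ctr, residDf = residDf, mse = mse)
}
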