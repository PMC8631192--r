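#' Kinetic parameters for the infection OD simulator
#'
#' Parameters of the three-compartment model behind [simInfectionOD()]:
#' susceptible bacteria S, lysogens L (immune, inheriting the host growth
#' rate) and free phage P, with
#' \deqn{dS/dt = r S (1 - (S+L)/K) - a S P}
#' \deqn{dL/dt = r L (1 - (S+L)/K) + q a S P}
#' \deqn{dP/dt = \beta (1-q) a S P - a S P - \delta P}
#' Bacteria are measured in OD600 units and phage in OD-equivalent
#' infection units, so the adsorption term `a S P` removes susceptible OD
#' directly. The published cultures come with no kinetic constants; the
#' defaults are order-of-magnitude choices producing the characteristic
#' lysis-then-recovery trajectory of a temperate infection and are meant
#' to be overridden freely.
#'
#' @param r host growth rate (1/h).
#' @param K carrying capacity (OD600).
#' @param adsorption adsorption/killing rate a (1/(OD h)).
#' @param burst effective burst yield beta (OD-equivalents of phage per
#'   lysed OD-equivalent of bacteria).
#' @param latent latent period in minutes (kept for reporting; the ODE is
#'   unstructured in age of infection).
#' @param lysogenyProb probability q that an infection lysogenizes
#'   (0 disables lysogeny).
#' @param decay free-phage decay rate delta (1/h).
#' @return an `InfectionParams` list.
#' @export
infectionParams <- function(r = 0.25, K = 1.0, adsorption = 10,
                            burst = 3, latent = 50, lysogenyProb = 0.01,
                            decay = 0.1) {
  vals <- c(r = r, K = K, adsorption = adsorption, burst = burst,
            latent = latent, decay = decay)
  stopIfNot(all(vals >= 0), "all rates must be >= 0")
  stopIfNot(lysogenyProb >= 0 && lysogenyProb <= 1,
            "lysogenyProb must lie in [0, 1]")
  structure(list(r = r, K = K, adsorption = adsorption, burst = burst,
                 latent = latent, lysogenyProb = lysogenyProb,
                 decay = decay),
            class = "InfectionParams")
}

infectionODE <- function(t, y, p) {
  S <- y[1]; L <- y[2]; P <- y[3]
  tot <- S + L
  inf <- p$adsorption * S * P
  dS <- p$r * S * (1 - tot / p$K) - inf
  dL <- p$r * L * (1 - tot / p$K) + p$lysogenyProb * inf
  dP <- p$burst * (1 - p$lysogenyProb) * inf - inf - p$decay * P
  list(c(dS, dL, dP))
}

#' Simulate paired phage+/phage- OD600 growth series
#'
#' Integrates the three-compartment infection model (fixed-step RK4) on the
#' plate-reader sampling grid and emits a long-format assay table with one
#' `phage+` and one paired `phage-` control series per replicate.
#' Observed OD is S + L under multiplicative lognormal noise. With
#' `lysogenyProb > 0` the phage+ culture collapses and then recovers as
#' lysogens take over; with `lysogenyProb = 0` it collapses without
#' recovery; the control follows logistic growth throughout.
#'
#' @param params an [infectionParams()].
#' @param horizonH assay duration in hours (40 h or more is needed for the
#'   late virulence read-out; default 72 h).
#' @param stepMin sampling interval in minutes (default 20, the
#'   plate-reader cadence emulated).
#' @param nRep replicates per treatment.
#' @param s0 starting susceptible OD.
#' @param moi phage:bacteria ratio setting the phage inoculum.
#' @param noiseSd lognormal noise sd (on log scale).
#' @param seed integer seed or `NULL`.
#' @param phageId,hostId labels for the output table.
#' @return an `AssayTable` (see [assayTable()]) with `measure = "OD"`.
#' @export
simInfectionOD <- function(params = infectionParams(), horizonH = 72,
                           stepMin = 20, nRep = 3, s0 = 0.05, moi = 0.1,
                           noiseSd = 0.02, seed = NULL,
                           phageId = "phageA", hostId = "hostA") {
  stopIfNot(stepMin > 0, "stepMin must be > 0")
  stopIfNot(horizonH > 0, "horizonH must be > 0")
  if (horizonH < 40)
    warning("horizons below 40 h cannot support the 40 h virulence read-out")
  timesMin <- seq(0, horizonH * 60, by = stepMin)
  timesH <- timesMin / 60
  runODE <- function(p0) {
    out <- deSolve::ode(y = c(S = s0, L = 0, P = p0), times = timesH,
                        func = infectionODE, parms = params,
                        method = "rk4")
    pmax(out[, "S"] + out[, "L"], 0)
  }
  odPlus <- runODE(s0 * moi)
  odMinus <- runODE(0)
  withSeed(seed, {
    rows <- list()
    for (rep in seq_len(nRep)) {
      noisy <- function(x) x * exp(stats::rnorm(length(x), 0, noiseSd))
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sprintf("%s_%s_r%d_plus", phageId, hostId, rep),
        phage_id = phageId, host_id = hostId,
        replicate = sprintf("r%d", rep), time = timesMin,
        value = noisy(odPlus), treatment = "phage+", measure = "OD")
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sprintf("none_%s_r%d_minus", hostId, rep),
        phage_id = "none", host_id = hostId,
        replicate = sprintf("r%d", rep), time = timesMin,
        value = noisy(odMinus), treatment = "phage-", measure = "OD")
    }
    assayTable(do.call(rbind, rows))
  })
}

#' Simulate a one-step growth curve (PFU over time)
#'
#' Expected free-phage titre is flat at `i0` infected centres until the
#' latent period ends, rises along a logistic wave in log space over
#' `riseMin` minutes (rescaled to hit both plateaus exactly), and plateaus
#' at `i0 * burst`. Observations get multiplicative lognormal noise.
#'
#' @param latentMin latent period L in minutes; must be below `horizonMin`.
#' @param burst burst size B (PFU per infected cell, >= 1).
#' @param i0 infected centres (PFU/ml at time zero, > 0).
#' @param stepMin sampling interval (default 30 min).
#' @param horizonMin assay duration (default 480 min, i.e. 8 h).
#' @param riseMin duration of the lysis wave.
#' @param noiseSd lognormal noise sd (log scale); 0 for noise-free curves.
#' @param seed integer seed or `NULL`.
#' @param phageId,hostId,replicate labels for the output table.
#' @return an `AssayTable` with `measure = "PFU"`.
#' @export
simOneStep <- function(latentMin = 50, burst = 255, i0 = 1e4,
                       stepMin = 30, horizonMin = 480, riseMin = 30,
                       noiseSd = 0, seed = NULL, phageId = "phageA",
                       hostId = "hostA", replicate = "r1") {
  stopIfNot(i0 > 0, "i0 must be > 0")
  stopIfNot(burst >= 1, "burst must be >= 1")
  stopIfNot(latentMin < horizonMin, "latentMin must be below horizonMin")
  stopIfNot(stepMin > 0, "stepMin must be > 0")
  times <- seq(0, horizonMin, by = stepMin)
  u <- pmin(pmax((times - latentMin) / riseMin, 0), 1)
  k <- 10
  f <- stats::plogis(k * (u - 0.5))
  s <- (f - stats::plogis(-k / 2)) / (stats::plogis(k / 2) -
                                      stats::plogis(-k / 2))
  pfu <- i0 * burst^s
  withSeed(seed, {
    if (noiseSd > 0)
      pfu <- pfu * exp(stats::rnorm(length(pfu), 0, noiseSd))
    assayTable(data.frame(
      series_id = sprintf("%s_%s_%s_onestep", phageId, hostId, replicate),
      phage_id = phageId, host_id = hostId, replicate = replicate,
      time = times, value = pfu, treatment = "phage+", measure = "PFU"))
  })
}
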