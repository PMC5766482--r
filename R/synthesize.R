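## Vectorized WLC fractional extension, using interpolation when the
## force vector is dense (ramps) and exact inversion otherwise.
.wlcZVec <- function(F, params) {
  uF <- unique(F)
  if (length(uF) <= 64) {
    z <- wlcFractionalExtension(uF, params)
    return(z[match(F, uF)])
  }
  rng <- range(F)
  knots <- seq(rng[1], rng[2], length.out = 512)
  zk <- wlcFractionalExtension(knots, params)
  stats::approx(knots, zk, xout = F)$y
}

## Ideal (noise-free) extension signal from an event log: WLC extension of
## the currently released contour minus the folded-length correction for
## each currently unfolded domain. This is the same arithmetic as
## predictStepSize, so in the noiseless limit every synthetic step equals
## its EventRecord size.
.idealExtension <- function(t, F, events, params, geometry, topology) {
  n <- length(t)
  rel <- numeric(n)                       # released residues at each sample
  unf <- numeric(n)                       # currently unfolded domains
  if (nrow(events)) {
    ev <- events[order(events$time), , drop = FALSE]
    dRel <- vapply(seq_len(nrow(ev)), function(i) {
      lab <- ev$transition[i]
      after <- c(ev$fold_after[i], ev$redox_after[i])
      before <- .beforeState(lab, after)
      releasedResidues(before, after, topology, geometry)
    }, 0)
    dUnf <- ifelse(startsWith(ev$transition, "unfold_"), 1,
                   ifelse(startsWith(ev$transition, "refold_"), -1, 0))
    idx <- findInterval(t, ev$time)       # events at time <= t
    rel <- c(0, cumsum(dRel))[idx + 1]
    unf <- c(0, cumsum(dUnf))[idx + 1]
  }
  z <- .wlcZVec(F, params)
  rel * params@lAA * z - unf * geometry@dFolded
}

## Reconstruct the pre-transition state from an event label and the state
## after the event.
.beforeState <- function(label, after) {
  if (startsWith(label, "unfold_")) return(c("FOLDED", after[2]))
  if (startsWith(label, "refold_")) return(c("UNFOLDED", after[2]))
  if (label == "iso_BG_BF" || label == "iso_BG_FG")
    return(c("UNFOLDED", "SS_BG"))
  if (label == "iso_BF_BG") return(c("UNFOLDED", "SS_BF"))
  if (label == "iso_FG_BG") return(c("UNFOLDED", "SS_FG"))
  if (startsWith(label, "red_")) return(c("UNFOLDED", sub("^red_", "",
                                                          label)))
  stop("unknown event label: ", label)
}

#' Synthesize a noisy AFM trace with ground truth
#'
#' Runs the stochastic domain engine for a polyprotein tether under the
#' given protocol, renders the resulting staircase as a sampled extension
#' signal (WLC elasticity of the currently released contour, minus the
#' folded-length correction per unfolded domain), applies the instrument
#' model (exponential step response, linear drift, Gaussian baseline
#' noise) and returns the trace together with its ground-truth event log.
#'
#' @param tether a \linkS4class{TetherSpec}.
#' @param rates a \linkS4class{RateSet}.
#' @param protocol a \linkS4class{ForceProtocol}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer RNG seed (required; covers both kinetics and noise).
#' @param params a \linkS4class{PolymerParams}.
#' @param pickup optional probability that each domain is actually under
#'   load (tether pickup variability); NULL (default) loads all domains.
#' @return A list with \code{trace} (a \linkS4class{Trace}) and
#'   \code{events} (the ground-truth event log).
#' @examples
#' out <- synthesizeTrace(tetherSpec(8, "RED"), defaultRates(),
#'                        constantForce(170, 6), noiseModel(), seed = 2)
#' out$trace
#' @export
synthesizeTrace <- function(tether, rates, protocol, noise = noiseModel(),
                            seed, params = polymerParams(),
                            pickup = NULL) {
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(seed)
  nd <- tether@nDomains
  keep <- rep(TRUE, nd)
  if (!is.null(pickup)) keep <- stats::runif(nd) < pickup
  states <- lapply(which(keep), function(d)
    c(tether@fold[d], tether@redox[d]))
  # missing redox rates for a state present on the tether
  for (s in states) {
    if (!s[2] %in% names(rates@k0Unfold) ||
        !s[2] %in% names(rates@kFold))
      stop("rates are incompatible with tether state ", s[2],
           ": no rate entry for that redox state")
  }
  sim <- if (length(states))
    simulateEnsemble(length(states), states, rates, protocol,
                     seed = sample.int(.Machine$integer.max, 1),
                     params = params, geometry = tether@geometry,
                     topology = tether@topology)
  else list(events = data.frame(time = numeric(0),
                                transition = character(0)))
  dur <- protocolDuration(protocol)
  nSamp <- floor(dur * noise@sampling)
  t <- (seq_len(nSamp) - 1) / noise@sampling
  F <- forceAt(protocol, t)
  ext <- .idealExtension(t, F, sim$events, params, tether@geometry,
                         tether@topology)
  if (noise@responseTau > 0) {            # single-pole low-pass
    a <- exp(-1 / (noise@sampling * noise@responseTau))
    ext <- as.numeric(stats::filter((1 - a) * ext, a, method = "recursive",
                                    init = ext[1]))
  }
  ext <- ext + noise@drift * t +
    stats::rnorm(nSamp, 0, noise@sigma)
  trace <- newTrace(t, ext, F,
                    metadata = list(seed = seed, protocol = protocol,
                                    tether = tether))
  list(trace = trace, events = sim$events)
}

#' Synthesize a three-pulse refolding experiment
#'
#' Convenience wrapper around \code{\link{synthesizeTrace}} for the
#' unfold/quench/probe protocol: domains unfold in the first pulse,
#' refold stochastically at their redox-specific zero-force rates during
#' the quench, and refolded domains unfold again in the probe pulse with
#' redox-correct step sizes. Also tallies per-pulse unfolding counts.
#'
#' @inheritParams synthesizeTrace
#' @param protocol a three-pulse \linkS4class{ForceProtocol} from
#'   \code{\link{threePulse}} (quench force must not exceed
#'   \code{rates@refoldForceMax}).
#' @return A list with \code{trace}, \code{events} and \code{counts}
#'   (named vector: \code{unfoldPulse}, \code{probePulse},
#'   \code{refolds}).
#' @export
synthesizeThreePulse <- function(tether, rates, protocol,
                                 noise = noiseModel(), seed,
                                 params = polymerParams()) {
  if (protocol@variant != "three_pulse")
    stop("protocol must come from threePulse()")
  qF <- protocol@segments$F0[2]
  if (qF > rates@refoldForceMax)
    stop("quench force exceeds refoldForceMax; no refolding is possible")
  out <- synthesizeTrace(tether, rates, protocol, noise, seed, params)
  ev <- out$events
  w <- protocol@pulses
  inWin <- function(tt, win) tt >= win[1] & tt < win[2]
  isUnfold <- startsWith(ev$transition, "unfold_")
  out$counts <- c(
    unfoldPulse = sum(isUnfold & inWin(ev$time, w$unfold)),
    probePulse = sum(isUnfold & inWin(ev$time, w$probe)),
    refolds = sum(startsWith(ev$transition, "refold_") &
                    inWin(ev$time, w$quench)))
  out
}

#' Batch-synthesize force-clamp traces
#'
#' Generates \code{n} independent traces (seeded reproducibly from
#' \code{seed}) and optionally writes trace/truth CSV pairs.
#'
#' @inheritParams synthesizeTrace
#' @param n number of traces.
#' @param dir optional output directory for \code{trace_###.csv} /
#'   \code{truth_###.csv} pairs.
#' @return Invisibly, a list of \code{synthesizeTrace} results.
#' @export
synthesizeBatch <- function(n, tether, rates, protocol,
                            noise = noiseModel(), seed,
                            params = polymerParams(), dir = NULL) {
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- synthesizeTrace(tether, rates, protocol, noise,
                                seed = seeds[i], params = params)
    if (!is.null(dir)) {
      writeTraceCsv(out[[i]]$trace,
                    file.path(dir, sprintf("trace_%03d.csv", i)))
      writeEventCsv(out[[i]]$events,
                    file.path(dir, sprintf("truth_%03d.csv", i)))
    }
  }
  invisible(out)
}
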