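#' Bell force-dependent rate
#'
#' \deqn{k(F) = k_0 \exp(F \Delta x / kT)}
#'
#' @param k0 zero-force rate, 1/s (>= 0).
#' @param dx distance to the transition state, nm (>= 0).
#' @param F force, pN (vectorized).
#' @param kT thermal energy, pN nm.
#' @return Rate(s) in 1/s.
#' @examples
#' bellRate(7.2e-4, 0.3, 100)  # ~1.07 1/s
#' @export
bellRate <- function(k0, dx, F, kT = 4.11) {
  if (any(c(k0, dx) < 0) || any(F < 0) || kT <= 0)
    stop("k0, dx and F must be non-negative and kT positive")
  k0 * exp(F * dx / kT)
}

## Transition table for a given state under a RateSet.
## Columns: label, kind, toFold, toRedox, k0, dx, gated (refold-only flag).
.activeTransitions <- function(fold, redox, rates) {
  rows <- list()
  if (fold == "FOLDED") {
    rows[[1]] <- list(label = paste0("unfold_", redox), toFold = "UNFOLDED",
                      toRedox = redox, k0 = rates@k0Unfold[[redox]],
                      dx = rates@dxUnfold[[redox]], gated = FALSE)
  } else {
    rows[[length(rows) + 1]] <-
      list(label = paste0("refold_", redox), toFold = "FOLDED",
           toRedox = redox, k0 = rates@kFold[[redox]], dx = 0, gated = TRUE)
    if (redox == "SS_BG") {
      rows[[length(rows) + 1]] <-
        list(label = "iso_BG_BF", toFold = "UNFOLDED", toRedox = "SS_BF",
             k0 = rates@kIso1, dx = rates@dxIso, gated = FALSE)
      rows[[length(rows) + 1]] <-
        list(label = "iso_BG_FG", toFold = "UNFOLDED", toRedox = "SS_FG",
             k0 = rates@kIso2, dx = rates@dxIso, gated = FALSE)
    }
    if (redox != "RED" && rates@kRed2 * rates@tcepMM > 0) {
      rows[[length(rows) + 1]] <-
        list(label = paste0("red_", redox), toFold = "UNFOLDED",
             toRedox = "RED", k0 = rates@kRed2 * rates@tcepMM, dx = 0,
             gated = FALSE)
    }
  }
  rows <- Filter(function(r) r$k0 > 0, rows)
  rows
}

## Integrated hazard of one Bell transition over [0, tau] of a segment with
## F(s) = F0 + slope * s. Closed form for linear ramps:
##   int k0 exp((F0 + r s) dx / kT) ds
##     = k0 * kT/(r dx) * (exp((F0 + r tau) dx/kT) - exp(F0 dx/kT))
.hazardIntegral <- function(k0, dx, F0, slope, tau, kT) {
  if (k0 == 0 || tau <= 0) return(0)
  if (dx == 0 || slope == 0) return(k0 * exp(F0 * dx / kT) * tau)
  c0 <- dx / kT
  (k0 / (slope * c0)) * (exp((F0 + slope * tau) * c0) - exp(F0 * c0))
}

## Simulate one domain through (pre-split) protocol segments.
## Exact sampling: within each piecewise-linear segment the cumulative
## hazard has a closed form, so event times are drawn by inverting
## Lambda(s) = E with E ~ Exp(1) (uniroot on a monotone function).
.simulateDomain <- function(fold, redox, rates, seg, params, geometry,
                            topology) {
  events <- list()
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t0[i]; segDur <- seg$duration[i]
    F0 <- seg$F0[i]; slope <- seg$slope[i]
    segFmax <- max(F0, F0 + slope * segDur)
    offset <- 0                           # elapsed time within the segment
    repeat {
      tau <- segDur - offset
      if (tau <= 1e-12) break
      trans <- .activeTransitions(fold, redox, rates)
      # refolding hazard active only where F <= refoldForceMax; segments
      # are pre-split so the gate is constant within a segment
      Fhere <- F0 + slope * offset
      Fgate <- max(Fhere, F0 + slope * segDur)  # max force over remainder
      trans <- Filter(function(r) {
        !r$gated || (Fgate <= rates@refoldForceMax + 1e-9)
      }, trans)
      if (!length(trans)) break
      Ltot <- sum(vapply(trans, function(r)
        .hazardIntegral(r$k0, r$dx, Fhere, slope, tau, params@kT), 0))
      E <- stats::rexp(1)
      if (Ltot < E) break                 # survives the segment remainder
      if (slope == 0) {
        s <- E / (Ltot / tau)             # constant hazard: exact inverse
      } else {
        cum <- function(s) sum(vapply(trans, function(r)
          .hazardIntegral(r$k0, r$dx, Fhere, slope, s, params@kT), 0)) - E
        s <- stats::uniroot(cum, c(0, tau), tol = 1e-12)$root
      }
      Fev <- Fhere + slope * s
      ki <- vapply(trans, function(r)
        bellRate(r$k0, r$dx, Fev, params@kT), 0)
      pick <- trans[[sample.int(length(trans), 1, prob = ki)]]
      before <- c(fold, redox)
      after <- c(pick$toFold, pick$toRedox)
      step <- if (Fev > 0)
        predictStepSize(before, after, Fev, params, geometry, topology)
      else 0                              # collapse at zero force
      events[[length(events) + 1]] <- data.frame(
        time = t0 + offset + s, transition = pick$label, step_nm = step,
        force_pN = Fev, fold_after = pick$toFold,
        redox_after = pick$toRedox, stringsAsFactors = FALSE)
      fold <- pick$toFold; redox <- pick$toRedox
      offset <- offset + s
    }
  }
  list(events = if (length(events)) do.call(rbind, events) else NULL,
       fold = fold, redox = redox)
}

#' Simulate an ensemble of independent Ig domains under a force protocol
#'
#' Exact stochastic simulation of the domain state machine: within every
#' piecewise-linear force segment, waiting times are drawn by inverting
#' the closed-form cumulative hazard of the Bell rates (the continuous-time
#' generalization of the Gillespie algorithm), so no time discretization
#' error is incurred. Isomerization and Tcep reduction are only available
#' from the unfolded state; refolding only while the force does not exceed
#' \code{refoldForceMax}.
#'
#' @param nDomains number of independent domains (>= 1).
#' @param initialStates character vector of initial redox states (recycled),
#'   or a list of \linkS4class{DomainState} objects of length
#'   \code{nDomains}.
#' @param rates a \linkS4class{RateSet}.
#' @param protocol a \linkS4class{ForceProtocol}.
#' @param seed integer RNG seed (required for reproducibility).
#' @param params a \linkS4class{PolymerParams}.
#' @param geometry a \linkS4class{DomainGeometry}.
#' @param topology a \linkS4class{DisulfideTopology}.
#' @return A list with \code{events}, a data.frame with columns
#'   \code{time}, \code{domain}, \code{transition}, \code{step_nm},
#'   \code{force_pN}, \code{fold_after}, \code{redox_after} (time-ordered
#'   within each domain), and \code{finalStates}, a data.frame with one
#'   row per domain.
#' @examples
#' sim <- simulateEnsemble(10, "SS_BG", defaultRates(),
#'                         constantForce(100, 20), seed = 1)
#' head(sim$events)
#' @export
simulateEnsemble <- function(nDomains, initialStates = "SS_BG",
                             rates = defaultRates(),
                             protocol = constantForce(100, 20),
                             seed,
                             params = polymerParams(),
                             geometry = domainGeometry(),
                             topology = disulfideTopology()) {
  if (nDomains < 1) stop("nDomains must be >= 1")
  if (missing(seed)) stop("an explicit integer seed is required")
  if (any(protocol@segments$F0 < 0))
    stop("protocol forces must be non-negative")
  set.seed(seed)
  if (is.list(initialStates)) {
    st <- lapply(initialStates, .asState)
    if (length(st) != nDomains)
      stop("initialStates list must have one entry per domain")
    fold0 <- vapply(st, `[`, "", 1L)
    redox0 <- vapply(st, `[`, "", 2L)
  } else {
    redox0 <- rep_len(initialStates, nDomains)
    fold0 <- rep_len("FOLDED", nDomains)
    if (!all(redox0 %in% .REDOX_LEVELS)) stop("invalid redox state")
  }
  seg <- .splitSegmentsAt(protocol@segments, rates@refoldForceMax)
  evs <- vector("list", nDomains)
  finFold <- character(nDomains); finRedox <- character(nDomains)
  for (d in seq_len(nDomains)) {
    res <- .simulateDomain(fold0[d], redox0[d], rates, seg, params,
                           geometry, topology)
    if (!is.null(res$events)) {
      res$events$domain <- d
      evs[[d]] <- res$events
    }
    finFold[d] <- res$fold; finRedox[d] <- res$redox
  }
  evs <- Filter(Negate(is.null), evs)
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(time = numeric(0), transition = character(0),
               step_nm = numeric(0), force_pN = numeric(0),
               fold_after = character(0), redox_after = character(0),
               domain = integer(0))
  events <- events[c("time", "domain", "transition", "step_nm", "force_pN",
                     "fold_after", "redox_after")]
  rownames(events) <- NULL
  list(events = events,
       finalStates = data.frame(domain = seq_len(nDomains), fold = finFold,
                                redox = finRedox))
}

#' Mean unfolding force under a linear force ramp (closed form)
#'
#' For Bell kinetics \eqn{k(F) = k_0 e^{F \Delta x / kT}} under a constant
#' loading rate r, the mean unfolding force is
#' \deqn{E[F] = (kT/\Delta x)\, e^{a} E_1(a), \quad a = k_0 kT/(r \Delta x)}
#' with \eqn{E_1} the exponential integral. Serves as the analytic oracle
#' for ramp simulations; the most probable force is
#' \eqn{(kT/\Delta x)\ln(r \Delta x/(k_0 kT))}.
#'
#' @param k0 zero-force unfolding rate, 1/s (> 0).
#' @param dx transition-state distance, nm (> 0).
#' @param rate loading rate, pN/s (> 0).
#' @param kT thermal energy, pN nm.
#' @return Mean unfolding force, pN.
#' @examples
#' meanRampUnfoldingForce(5e-6, 0.3, 40)  # ~174 pN (reduced I69)
#' @export
meanRampUnfoldingForce <- function(k0, dx, rate, kT = 4.11) {
  if (any(c(k0, dx, rate, kT) <= 0))
    stop("k0, dx, rate and kT must all be strictly positive")
  a <- k0 * kT / (rate * dx)
  (kT / dx) * exp(a) * pracma::expint_E1(a)
}

#' Event CSV round trip
#'
#' Write or read a simulation event log in the five-column exchange format
#' (time, domain, transition, step_nm, force_pN).
#'
#' @param events event data.frame as returned by
#'   \code{\link{simulateEnsemble}}.
#' @param path file path.
#' @return \code{readEventCsv} returns the event data.frame.
#' @export
writeEventCsv <- function(events, path) {
  utils::write.csv(events[c("time", "domain", "transition", "step_nm",
                            "force_pN")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventCsv
#' @export
readEventCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
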