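#' @import methods
NULL

## Fold / redox state vocabulary used throughout the package.
.FOLD_LEVELS  <- c("FOLDED", "UNFOLDED")
.REDOX_LEVELS <- c("RED", "SS_BG", "SS_BF", "SS_FG")

#' Polymer elasticity parameters
#'
#' Container for the constants that map force to fractional extension and
#' residue counts to contour length. \code{kT} is the thermal energy in
#' pN nm (4.11 pN nm at about 298 K), \code{lAA} the contour length gained
#' per released residue in nm, \code{p} the worm-like-chain persistence
#' length in nm, and \code{b} the freely-jointed-chain Kuhn length in nm.
#'
#' @slot kT numeric(1), thermal energy, pN nm.
#' @slot lAA numeric(1), contour length per residue, nm.
#' @slot p numeric(1), WLC persistence length, nm.
#' @slot b numeric(1), FJC Kuhn length, nm.
#' @export
setClass("PolymerParams",
  representation(kT = "numeric", lAA = "numeric", p = "numeric",
                 b = "numeric"),
  prototype(kT = 4.11, lAA = 0.4, p = 0.4, b = 1.1),
  validity = function(object) {
    v <- c(kT = object@kT, lAA = object@lAA, p = object@p, b = object@b)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all polymer parameters must be finite and strictly positive")
    TRUE
  })

#' Construct polymer parameters
#'
#' @param kT thermal energy, pN nm.
#' @param lAA contour length per residue, nm.
#' @param p WLC persistence length, nm.
#' @param b FJC Kuhn length, nm.
#' @return A \linkS4class{PolymerParams} object.
#' @examples
#' polymerParams()
#' @export
polymerParams <- function(kT = 4.11, lAA = 0.4, p = 0.4, b = 1.1)
  new("PolymerParams", kT = kT, lAA = lAA, p = p, b = b)

#' Ig-domain unfolding geometry
#'
#' \code{nExt} is the number of residues that become force-bearing when a
#' fully reduced domain unfolds; \code{dFolded} is the folded-state
#' end-to-end distance (nm) that is lost from the measured step when a
#' domain leaves the folded state. The defaults reproduce the 26.4 nm
#' unfolding step of reduced domains at 170 pN.
#'
#' @slot nExt integer-like numeric(1), extensible residues on unfolding.
#' @slot dFolded numeric(1), folded end-to-end distance, nm.
#' @export
setClass("DomainGeometry",
  representation(nExt = "numeric", dFolded = "numeric"),
  prototype(nExt = 88, dFolded = 4.4),
  validity = function(object) {
    if (object@nExt <= 0) return("nExt must be > 0")
    if (object@dFolded < 0) return("dFolded must be >= 0")
    TRUE
  })

#' @rdname DomainGeometry-class
#' @param nExt extensible residues on full unfolding of a reduced domain.
#' @param dFolded folded end-to-end distance subtracted on unfolding, nm.
#' @return A \linkS4class{DomainGeometry} object.
#' @export
domainGeometry <- function(nExt = 88, dFolded = 4.4)
  new("DomainGeometry", nExt = nExt, dFolded = dFolded)

#' Residue counts sequestered by the CysB/CysF/CysG disulfides
#'
#' Number of residues trapped behind each disulfide of the triad:
#' \code{loopBF} between CysB and CysF (released when the CysF-CysG bond
#' forms by isomerization), \code{loopFG} between CysF and CysG (released
#' when CysB-CysF forms), and \code{loopBG} behind the native CysB-CysG
#' bond. The I69 defaults (51, 11, 57) reproduce the printed 17 nm, 4 nm
#' and 19 nm step sizes; note that \code{loopBG < loopBF + loopFG}, so the
#' default triad is deliberately not additive (see the package vignette).
#'
#' @slot loopBF numeric(1), residues between CysB and CysF.
#' @slot loopFG numeric(1), residues between CysF and CysG.
#' @slot loopBG numeric(1), residues behind CysB-CysG.
#' @export
setClass("DisulfideTopology",
  representation(loopBF = "numeric", loopFG = "numeric", loopBG = "numeric"),
  prototype(loopBF = 51, loopFG = 11, loopBG = 57),
  validity = function(object) {
    if (any(c(object@loopBF, object@loopFG, object@loopBG) < 0))
      return("loop residue counts must be non-negative")
    if (object@loopBG < max(object@loopBF, object@loopFG))
      return("loopBG must be >= max(loopBF, loopFG)")
    TRUE
  })

#' @rdname DisulfideTopology-class
#' @param loopBF,loopFG,loopBG residue counts, see slot descriptions.
#' @return A \linkS4class{DisulfideTopology} object.
#' @export
disulfideTopology <- function(loopBF = 51, loopFG = 11, loopBG = 57)
  new("DisulfideTopology", loopBF = loopBF, loopFG = loopFG, loopBG = loopBG)

#' Single Ig-domain state
#'
#' A domain is described by its fold status (\code{"FOLDED"} or
#' \code{"UNFOLDED"}) and its redox status: \code{"RED"} (free thiols),
#' \code{"SS_BG"}, \code{"SS_BF"} or \code{"SS_FG"} for the three possible
#' triad disulfides. Isomerization and reduction are only possible in the
#' unfolded state because the native CysB-CysG bond is buried in the
#' folded core.
#'
#' @slot fold character(1), \code{"FOLDED"} or \code{"UNFOLDED"}.
#' @slot redox character(1), one of \code{"RED"}, \code{"SS_BG"},
#'   \code{"SS_BF"}, \code{"SS_FG"}.
#' @export
setClass("DomainState",
  representation(fold = "character", redox = "character"),
  prototype(fold = "FOLDED", redox = "SS_BG"),
  validity = function(object) {
    if (!object@fold %in% .FOLD_LEVELS)
      return(sprintf("fold must be one of %s",
                     paste(.FOLD_LEVELS, collapse = ", ")))
    if (!object@redox %in% .REDOX_LEVELS)
      return(sprintf("redox must be one of %s",
                     paste(.REDOX_LEVELS, collapse = ", ")))
    TRUE
  })

#' @rdname DomainState-class
#' @param fold,redox state labels, see slot descriptions.
#' @return A \linkS4class{DomainState} object.
#' @examples
#' domainState("UNFOLDED", "SS_BG")
#' @export
domainState <- function(fold = "FOLDED", redox = "SS_BG")
  new("DomainState", fold = fold, redox = redox)

## Accept either a DomainState or a character(2) c(fold, redox).
.asState <- function(x) {
  if (is(x, "DomainState")) return(c(x@fold, x@redox))
  if (is.character(x) && length(x) == 2L) {
    s <- new("DomainState", fold = x[[1L]], redox = x[[2L]])
    return(c(s@fold, s@redox))
  }
  stop("a domain state must be a DomainState or character(2) c(fold, redox)")
}

#' First-order rate constants of the domain state machine
#'
#' Bell pairs (zero-force rate \code{k0Unfold} in 1/s and transition-state
#' distance \code{dxUnfold} in nm, one per redox state) govern mechanical
#' unfolding; \code{kIso1}/\code{kIso2} are the isomerization branch rates
#' SS_BG to SS_BF and SS_BG to SS_FG at the reference force (force
#' independent unless \code{dxIso > 0}); \code{kFold} are zero-force
#' refolding rates per redox state, applied only when the instantaneous
#' force does not exceed \code{refoldForceMax}; \code{kRed2} is the
#' second-order Tcep reduction rate (1/s/mM) scaled by \code{tcepMM}.
#'
#' @slot k0Unfold named numeric(4), zero-force unfolding rates, 1/s.
#' @slot dxUnfold named numeric(4), unfolding transition-state distances, nm.
#' @slot kIso1 numeric(1), SS_BG -> SS_BF rate, 1/s.
#' @slot kIso2 numeric(1), SS_BG -> SS_FG rate, 1/s.
#' @slot dxIso numeric(1), optional isomerization distance, nm (default 0).
#' @slot kFold named numeric(4), refolding rates, 1/s.
#' @slot kRed2 numeric(1), Tcep reduction rate, 1/s/mM.
#' @slot tcepMM numeric(1), Tcep concentration, mM.
#' @slot refoldForceMax numeric(1), maximum force permitting refolding, pN.
#' @export
setClass("RateSet",
  representation(k0Unfold = "numeric", dxUnfold = "numeric",
                 kIso1 = "numeric", kIso2 = "numeric", dxIso = "numeric",
                 kFold = "numeric", kRed2 = "numeric", tcepMM = "numeric",
                 refoldForceMax = "numeric"),
  validity = function(object) {
    for (nm in c("k0Unfold", "dxUnfold", "kFold")) {
      v <- slot(object, nm)
      if (!all(.REDOX_LEVELS %in% names(v)))
        return(sprintf("%s must be named with all of %s", nm,
                       paste(.REDOX_LEVELS, collapse = ", ")))
      if (any(v < 0)) return(sprintf("%s must be non-negative", nm))
    }
    if (any(c(object@kIso1, object@kIso2, object@dxIso, object@kRed2,
              object@tcepMM, object@refoldForceMax) < 0))
      return("rates, distances and concentrations must be non-negative")
    TRUE
  })

#' Default rate constants for I69-like triad domains
#'
#' The oxidized unfolding pair is calibrated so that the unfolding rate at
#' 100 pN is exactly 1.06 1/s with dx = 0.3 nm; the reduced pair (5e-6 1/s,
#' 0.3 nm) places the most probable unfolding force in a 40 pN/s ramp near
#' 182 pN. Isomerization branch rates default to their measured 100 pN
#' values (0.021 and 0.027 1/s) with no force dependence. Refolding rates
#' derive from measured 10 s refolding fractions via k = -log(1 - f)/dt:
#' 0.058 1/s (SS_BG), 0.054 1/s (SS_BF), 0 (SS_FG) and 0.01 1/s (RED).
#'
#' @param k0UnfoldOx zero-force unfolding rate of disulfide-bonded domains,
#'   1/s. Default solves k(100 pN) = 1.06 1/s at dx = 0.3 nm.
#' @param k0UnfoldRed zero-force unfolding rate of reduced domains, 1/s.
#' @param dxUnfold transition-state distance shared by all redox states, nm.
#' @param kIso1,kIso2 isomerization branch rates, 1/s.
#' @param dxIso isomerization transition-state distance, nm.
#' @param kFoldRed,kFoldBG,kFoldBF,kFoldFG refolding rates, 1/s.
#' @param kRed2 second-order Tcep reduction rate, 1/s/mM.
#' @param tcepMM Tcep concentration, mM (0 switches reduction off).
#' @param refoldForceMax maximum force permitting refolding, pN.
#' @param kT thermal energy used in the 100 pN calibration, pN nm.
#' @return A \linkS4class{RateSet} object.
#' @examples
#' rs <- defaultRates()
#' bellRate(rs@k0Unfold[["SS_BG"]], rs@dxUnfold[["SS_BG"]], 100) # 1.06
#' @export
defaultRates <- function(k0UnfoldOx = 1.06 * exp(-100 * 0.3 / kT),
                         k0UnfoldRed = 5e-6,
                         dxUnfold = 0.3,
                         kIso1 = 0.021, kIso2 = 0.027, dxIso = 0,
                         kFoldRed = 0.01, kFoldBG = 0.058,
                         kFoldBF = 0.054, kFoldFG = 0,
                         kRed2 = 0.0025, tcepMM = 0,
                         refoldForceMax = 1, kT = 4.11) {
  k0 <- c(RED = k0UnfoldRed, SS_BG = k0UnfoldOx, SS_BF = k0UnfoldOx,
          SS_FG = k0UnfoldOx)
  dx <- c(RED = dxUnfold, SS_BG = dxUnfold, SS_BF = dxUnfold,
          SS_FG = dxUnfold)
  kf <- c(RED = kFoldRed, SS_BG = kFoldBG, SS_BF = kFoldBF, SS_FG = kFoldFG)
  new("RateSet", k0Unfold = k0, dxUnfold = dx, kIso1 = kIso1, kIso2 = kIso2,
      dxIso = dxIso, kFold = kf, kRed2 = kRed2, tcepMM = tcepMM,
      refoldForceMax = refoldForceMax)
}

#' Force protocol
#'
#' A pulling protocol is a sequence of piecewise-linear force segments.
#' Each row of \code{segments} holds the segment start time \code{t0} (s),
#' its \code{duration} (s), the force at its start \code{F0} (pN) and the
#' loading rate \code{slope} (pN/s). Use the constructors
#' \code{\link{constantForce}}, \code{\link{forceRamp}},
#' \code{\link{triangleWave}} and \code{\link{threePulse}}.
#'
#' @slot variant character(1), protocol family label.
#' @slot segments data.frame with columns t0, duration, F0, slope.
#' @slot pulses list of named pulse windows (three-pulse protocols only).
#' @export
setClass("ForceProtocol",
  representation(variant = "character", segments = "data.frame",
                 pulses = "list"),
  prototype(variant = "constant",
            segments = data.frame(t0 = 0, duration = 1, F0 = 0, slope = 0),
            pulses = list()),
  validity = function(object) {
    s <- object@segments
    need <- c("t0", "duration", "F0", "slope")
    if (!all(need %in% names(s)))
      return("segments must have columns t0, duration, F0, slope")
    if (any(s$duration <= 0)) return("segment durations must be > 0")
    Fend <- s$F0 + s$slope * s$duration
    if (any(s$F0 < 0) || any(Fend < -1e-9))
      return("forces must be non-negative throughout the protocol")
    TRUE
  })

#' Instrument noise model for synthetic AFM traces
#'
#' @slot sigma numeric(1), Gaussian baseline noise per sample, nm.
#' @slot drift numeric(1), linear drift, nm/s.
#' @slot sampling numeric(1), sampling rate, Hz.
#' @slot responseTau numeric(1), exponential step-response time constant, s.
#' @export
setClass("NoiseModel",
  representation(sigma = "numeric", drift = "numeric", sampling = "numeric",
                 responseTau = "numeric"),
  prototype(sigma = 1, drift = 0, sampling = 1000, responseTau = 0.001),
  validity = function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@sampling <= 0) return("sampling must be > 0")
    if (object@responseTau < 0) return("responseTau must be >= 0")
    TRUE
  })

#' @rdname NoiseModel-class
#' @param sigma Gaussian baseline noise per sample, nm.
#' @param drift linear drift, nm/s.
#' @param sampling sampling rate, Hz.
#' @param stepResponseMs exponential smoothing time constant applied to
#'   instantaneous extension steps, ms.
#' @return A \linkS4class{NoiseModel} object.
#' @export
noiseModel <- function(sigma = 1, drift = 0, sampling = 1000,
                       stepResponseMs = 1)
  new("NoiseModel", sigma = sigma, drift = drift, sampling = sampling,
      responseTau = stepResponseMs / 1000)

#' Polyprotein tether specification
#'
#' Describes the molecule held between tip and surface: the number of Ig
#' domains, their initial states and the shared geometry/topology. Use
#' e.g. 8 domains in state SS_BG for an oxidized I69 octamer, or 8 RED
#' domains for the reduced construct.
#'
#' @slot nDomains integer(1), number of domains.
#' @slot fold character, initial fold state per domain (recycled).
#' @slot redox character, initial redox state per domain (recycled).
#' @slot geometry a \linkS4class{DomainGeometry}.
#' @slot topology a \linkS4class{DisulfideTopology}.
#' @export
setClass("TetherSpec",
  representation(nDomains = "integer", fold = "character",
                 redox = "character", geometry = "DomainGeometry",
                 topology = "DisulfideTopology"),
  validity = function(object) {
    if (object@nDomains < 1L) return("nDomains must be >= 1")
    if (length(object@fold) != object@nDomains ||
        length(object@redox) != object@nDomains)
      return("fold and redox must have one entry per domain")
    if (!all(object@fold %in% .FOLD_LEVELS)) return("invalid fold state")
    if (!all(object@redox %in% .REDOX_LEVELS)) return("invalid redox state")
    TRUE
  })

#' @rdname TetherSpec-class
#' @param nDomains number of domains in the polyprotein.
#' @param redox initial redox state(s), recycled across domains.
#' @param fold initial fold state(s), recycled across domains.
#' @param geometry a \linkS4class{DomainGeometry}.
#' @param topology a \linkS4class{DisulfideTopology}.
#' @return A \linkS4class{TetherSpec} object.
#' @examples
#' tetherSpec(8, redox = "SS_BG")  # oxidized (I69)8
#' @export
tetherSpec <- function(nDomains, redox = "SS_BG", fold = "FOLDED",
                       geometry = domainGeometry(),
                       topology = disulfideTopology())
  new("TetherSpec", nDomains = as.integer(nDomains),
      fold = rep_len(fold, nDomains), redox = rep_len(redox, nDomains),
      geometry = geometry, topology = topology)

#' AFM trace container
#'
#' A uniformly sampled recording of time (s), extension (nm) and force
#' (pN), plus free-form metadata (seed, protocol, ground-truth link).
#'
#' @slot time numeric, sample times, s (uniform grid).
#' @slot extension numeric, tether extension, nm.
#' @slot force numeric, applied force, pN.
#' @slot metadata list.
#' @export
setClass("Trace",
  representation(time = "numeric", extension = "numeric", force = "numeric",
                 metadata = "list"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@extension) != n || length(object@force) != n)
      return("time, extension and force must have equal length")
    if (n >= 3) {
      dt <- diff(object@time)
      if (any(!is.finite(dt)) ||
          (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
        return("time must be a uniform grid with no missing values")
    }
    if (anyNA(object@extension) || anyNA(object@force))
      return("extension and force must not contain missing values")
    TRUE
  })

#' @rdname Trace-class
#' @param time,extension,force numeric vectors of equal length.
#' @param metadata list of free-form metadata.
#' @return A \linkS4class{Trace} object.
#' @export
newTrace <- function(time, extension, force, metadata = list())
  new("Trace", time = as.numeric(time), extension = as.numeric(extension),
      force = as.numeric(force), metadata = metadata)

.IG_CLASSES <- c("TRIAD", "PAIR_BF", "PAIR_FG", "PAIR_BG", "SINGLE", "NONE")

#' Titin isoform I-band inventory
#'
#' Describes the extensible I-band of a titin isoform for filament-scale
#' Monte Carlo: the residue ranges of the two entropic springs (N2B unique
#' sequence and PEVK, 1-based inclusive in canonical titin numbering), the
#' cysteine class of every I-band Ig domain, and the length contributed by
#' a folded Ig along the filament axis.
#'
#' @slot name character(1).
#' @slot n2bRange numeric(2), N2B spring residue range.
#' @slot pevkRange numeric(2), PEVK spring residue range.
#' @slot igClasses character, one of TRIAD, PAIR_BF, PAIR_FG, PAIR_BG,
#'   SINGLE, NONE per Ig domain.
#' @slot foldedNm numeric(1), folded Ig contribution, nm.
#' @export
setClass("IsoformSpec",
  representation(name = "character", n2bRange = "numeric",
                 pevkRange = "numeric", igClasses = "character",
                 foldedNm = "numeric"),
  validity = function(object) {
    if (length(object@n2bRange) != 2L || length(object@pevkRange) != 2L)
      return("n2bRange and pevkRange must have length 2")
    if (diff(object@n2bRange) < 0 || diff(object@pevkRange) < 0)
      return("residue ranges must be increasing")
    if (!all(object@igClasses %in% .IG_CLASSES))
      return(sprintf("igClasses must be in %s",
                     paste(.IG_CLASSES, collapse = ", ")))
    if (object@foldedNm < 0) return("foldedNm must be >= 0")
    TRUE
  })

#' Filament Monte Carlo configuration
#'
#' @slot dt numeric(1), Monte Carlo step, s (must be <= 0.010 so that
#'   results are step-size stable).
#' @slot duration numeric(1), simulated time, s.
#' @slot fMin,fMax numeric(1), force cycle bounds, pN.
#' @slot frequency numeric(1), force cycle frequency, Hz.
#' @slot scenario character(1), \code{"oxidized"} or \code{"reduced"}.
#' @slot reisomerize logical(1), allow isomerized triads to return to
#'   SS_BG while unfolded.
#' @export
setClass("SimulationConfig",
  representation(dt = "numeric", duration = "numeric", fMin = "numeric",
                 fMax = "numeric", frequency = "numeric",
                 scenario = "character", reisomerize = "logical"),
  prototype(dt = 0.010, duration = 1200, fMin = 0, fMax = 30,
            frequency = 1, scenario = "oxidized", reisomerize = FALSE),
  validity = function(object) {
    if (object@dt <= 0 || object@dt > 0.010 + 1e-12)
      return("dt must be in (0, 0.010] s")
    if (object@duration <= 0) return("duration must be > 0")
    if (object@fMin < 0 || object@fMax <= object@fMin)
      return("need 0 <= fMin < fMax")
    if (object@frequency <= 0) return("frequency must be > 0")
    if (!object@scenario %in% c("oxidized", "reduced"))
      return("scenario must be 'oxidized' or 'reduced'")
    TRUE
  })

#' @rdname SimulationConfig-class
#' @param dt Monte Carlo step, s.
#' @param duration simulated time, s.
#' @param fMin,fMax force cycle bounds, pN.
#' @param frequency force cycle frequency, Hz.
#' @param scenario \code{"oxidized"} or \code{"reduced"}.
#' @param reisomerize allow unfolded SS_BF/SS_FG triads to revert to SS_BG.
#' @return A \linkS4class{SimulationConfig} object.
#' @export
simulationConfig <- function(dt = 0.010, duration = 1200, fMin = 0,
                             fMax = 30, frequency = 1,
                             scenario = c("oxidized", "reduced"),
                             reisomerize = FALSE)
  new("SimulationConfig", dt = dt, duration = duration, fMin = fMin,
      fMax = fMax, frequency = frequency,
      scenario = match.arg(scenario), reisomerize = reisomerize)

#' Rate constants for filament-scale Monte Carlo
#'
#' In the 0-30 pN cyclic-force regime of the I-band the redox contrast is
#' carried by residue sequestration and by the refolding rates; a single
#' generic unfolding Bell pair is shared by all Ig domains (see the
#' package vignette for the rationale and calibration).
#'
#' @slot k0Unfold numeric(1), shared zero-force unfolding rate, 1/s.
#' @slot dxUnfold numeric(1), shared unfolding distance, nm.
#' @slot kIso1,kIso2 numeric(1), isomerization branch rates, 1/s.
#' @slot kFold named numeric(4), refolding rates per redox state of
#'   cysteine-triad/pair domains, 1/s.
#' @slot kFoldPlain numeric(1), refolding rate of SINGLE/NONE domains, 1/s.
#' @slot refoldForceMax numeric(1), maximum force permitting refolding, pN.
#' @export
setClass("FilamentRates",
  representation(k0Unfold = "numeric", dxUnfold = "numeric",
                 kIso1 = "numeric", kIso2 = "numeric", kFold = "numeric",
                 kFoldPlain = "numeric", refoldForceMax = "numeric"),
  validity = function(object) {
    if (!all(.REDOX_LEVELS %in% names(object@kFold)))
      return("kFold must be named with all redox states")
    if (any(c(object@k0Unfold, object@dxUnfold, object@kIso1, object@kIso2,
              object@kFold, object@kFoldPlain, object@refoldForceMax) < 0))
      return("all rates and distances must be non-negative")
    TRUE
  })

#' @rdname FilamentRates-class
#' @param k0Unfold shared zero-force unfolding rate, 1/s.
#' @param dxUnfold shared unfolding transition-state distance, nm.
#' @param kIso1,kIso2 isomerization branch rates, 1/s.
#' @param kFoldRed,kFoldBG,kFoldBF,kFoldFG refolding rates of
#'   cysteine-containing domains per redox state, 1/s.
#' @param kFoldPlain refolding rate of domains without triad cysteines, 1/s.
#' @param refoldForceMax maximum force permitting refolding, pN.
#' @return A \linkS4class{FilamentRates} object.
#' @export
filamentRates <- function(k0Unfold = 1e-4, dxUnfold = 0.9,
                          kIso1 = 0.021, kIso2 = 0.027,
                          kFoldRed = 0.01, kFoldBG = 0.058,
                          kFoldBF = 0.054, kFoldFG = 0,
                          kFoldPlain = 0.3, refoldForceMax = 1)
  new("FilamentRates", k0Unfold = k0Unfold, dxUnfold = dxUnfold,
      kIso1 = kIso1, kIso2 = kIso2,
      kFold = c(RED = kFoldRed, SS_BG = kFoldBG, SS_BF = kFoldBF,
                SS_FG = kFoldFG),
      kFoldPlain = kFoldPlain, refoldForceMax = refoldForceMax)
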