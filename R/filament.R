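#' Default I-band inventory of the canonical N2BA titin isoform
#'
#' 101 I-band Ig domains with cysteine-class counts TRIAD 21, PAIR_BF 24,
#' PAIR_FG 17, PAIR_BG 6, SINGLE 24, NONE 9; entropic springs N2B
#' (residues 3712-4289) and PEVK (10216-12022) in canonical numbering.
#'
#' @param foldedNm folded Ig contribution along the filament axis, nm.
#' @return An \linkS4class{IsoformSpec}.
#' @export
n2baIsoform <- function(foldedNm = 4.4) {
  classes <- rep(c("TRIAD", "PAIR_BF", "PAIR_FG", "PAIR_BG", "SINGLE",
                   "NONE"), c(21, 24, 17, 6, 24, 9))
  new("IsoformSpec", name = "N2BA", n2bRange = c(3712, 4289),
      pevkRange = c(10216, 12022), igClasses = classes,
      foldedNm = foldedNm)
}

#' Default I-band inventory of the short cardiac N2B isoform
#'
#' The N2B isoform lacks the differentially spliced middle I-band, which
#' removes most triad-containing domains and most of the PEVK spring
#' (residues 11851-12022 remain). The exact per-domain list is not fixed
#' by the canonical annotation, so the default inventory is built to match
#' the observed triad fraction of about 9 percent of I-band Igs: 44
#' domains with classes TRIAD 4, PAIR_BF 6, PAIR_FG 5, PAIR_BG 2,
#' SINGLE 12, NONE 15.
#'
#' @inheritParams n2baIsoform
#' @return An \linkS4class{IsoformSpec}.
#' @export
n2bIsoform <- function(foldedNm = 4.4) {
  classes <- rep(c("TRIAD", "PAIR_BF", "PAIR_FG", "PAIR_BG", "SINGLE",
                   "NONE"), c(4, 6, 5, 2, 12, 15))
  new("IsoformSpec", name = "N2B", n2bRange = c(3712, 4289),
      pevkRange = c(11851, 12022), igClasses = classes,
      foldedNm = foldedNm)
}

.springResidues <- function(isoform)
  (diff(isoform@n2bRange) + 1) + (diff(isoform@pevkRange) + 1)

## Residues sequestered behind the current disulfide, per redox state.
.seqResLookup <- function(topology)
  c(RED = 0, SS_BG = topology@loopBG, SS_BF = topology@loopBF,
    SS_FG = topology@loopFG)

## Initial redox state per Ig class under a redox scenario.
.initialRedox <- function(classes, scenario) {
  if (scenario == "reduced") return(rep("RED", length(classes)))
  unname(c(TRIAD = "SS_BG", PAIR_BF = "SS_BF", PAIR_FG = "SS_FG",
           PAIR_BG = "SS_BG", SINGLE = "RED", NONE = "RED")[classes])
}

#' End-to-end length of the titin I-band at a given force
#'
#' Freely-jointed-chain extension of all unstructured contour (the N2B and
#' PEVK springs plus the non-sequestered residues of unfolded Ig domains)
#' plus the folded contribution of every folded Ig:
#' \deqn{L(F) = N_{unstructured}\, l_{aa}\, z_{FJC}(F) +
#'       N_{folded}\, d_{Ig}}
#'
#' @param isoform an \linkS4class{IsoformSpec}.
#' @param fold logical vector, TRUE for folded, one per Ig.
#' @param redox character vector of redox states, one per Ig.
#' @param F force, pN (vectorized).
#' @param params a \linkS4class{PolymerParams}.
#' @param geometry a \linkS4class{DomainGeometry}.
#' @param topology a \linkS4class{DisulfideTopology}.
#' @return Length in nm.
#' @examples
#' iso <- n2baIsoform()
#' filamentLength(iso, rep(TRUE, 101), rep("RED", 101), F = 30)
#' @export
filamentLength <- function(isoform, fold, redox, F,
                           params = polymerParams(),
                           geometry = domainGeometry(),
                           topology = disulfideTopology()) {
  if (any(F < 0)) stop("force must be non-negative")
  nIg <- length(isoform@igClasses)
  stopifnot(length(fold) == nIg, length(redox) == nIg)
  seqRes <- .seqResLookup(topology)
  rel <- sum((geometry@nExt - seqRes[redox])[!fold])
  nUnstruct <- .springResidues(isoform) + rel
  z <- fjcFractionalExtension(F, params)
  nUnstruct * params@lAA * z + sum(fold) * isoform@foldedNm
}

#' Kinetic Monte Carlo of the titin I-band under cyclic force
#'
#' Fixed-step Monte Carlo (default 10 ms) of all I-band Ig domains under a
#' triangular force cycle. Each step, every domain attempts at most one
#' transition with probability \code{1 - exp(-k(F) dt)}: folded domains
#' may unfold (shared Bell pair), unfolded domains may refold while the
#' instantaneous force is below \code{refoldForceMax}, and unfolded
#' triad-class domains in state SS_BG may isomerize to SS_BF or SS_FG
#' (optionally back, if \code{reisomerize}). Pair-class domains carry
#' their disulfide but cannot isomerize; SINGLE/NONE domains are always
#' reduced-like. Filament length follows \code{\link{filamentLength}};
#' residue bookkeeping is conservative (unstructured + sequestered +
#' folded residue totals are invariant).
#'
#' @param isoform an \linkS4class{IsoformSpec}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param rates a \linkS4class{FilamentRates}.
#' @param seed integer RNG seed.
#' @param params a \linkS4class{PolymerParams}.
#' @param geometry a \linkS4class{DomainGeometry}.
#' @param topology a \linkS4class{DisulfideTopology}.
#' @return A list of class \code{"filamentRun"}: \code{time}, \code{force},
#'   \code{length} (per step, nm), \code{peaks} (data.frame per force
#'   cycle: cycle, time, length at peak force, unfolded domain count),
#'   \code{states} (final fold/redox per domain), \code{config},
#'   \code{isoform}.
#' @examples
#' run <- runFilamentMC(n2baIsoform(),
#'                      simulationConfig(duration = 30), seed = 1)
#' utils::head(run$peaks)
#' @export
runFilamentMC <- function(isoform, config = simulationConfig(),
                          rates = filamentRates(), seed,
                          params = polymerParams(),
                          geometry = domainGeometry(),
                          topology = disulfideTopology()) {
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(seed)
  dt <- config@dt
  nSteps <- ceiling(config@duration / dt)
  t <- seq_len(nSteps) * dt
  # triangular force cycle
  phase <- (t * config@frequency) %% 1
  Fv <- config@fMin + (config@fMax - config@fMin) *
    (1 - abs(2 * phase - 1))
  zv <- fjcFractionalExtension(Fv, params)
  cls <- isoform@igClasses
  nIg <- length(cls)
  plain <- cls %in% c("SINGLE", "NONE")
  triad <- cls == "TRIAD"
  redox <- .initialRedox(cls, config@scenario)
  fold <- rep(TRUE, nIg)                  # all folded initially
  seqRes <- .seqResLookup(topology)
  kFoldVec <- ifelse(plain, rates@kFoldPlain, rates@kFold[redox])
  springRes <- .springResidues(isoform)
  relTot <- 0                             # released residues (unfolded Ig)
  lenOut <- numeric(nSteps)
  kIsoTot <- rates@kIso1 + rates@kIso2
  pIso <- -expm1(-kIsoTot * dt)
  pBranchFG <- if (kIsoTot > 0) rates@kIso2 / kIsoTot else 0
  c0 <- rates@dxUnfold / params@kT
  maxRateDt <- bellRate(rates@k0Unfold, rates@dxUnfold, config@fMax,
                        params@kT) * dt
  if (max(maxRateDt, kIsoTot * dt, rates@kFold * dt,
          rates@kFoldPlain * dt) > 0.25)
    warning("rate * dt exceeds 0.25 at peak force; decrease dt")
  for (i in seq_len(nSteps)) {
    F <- Fv[i]
    # unfolding (shared Bell pair, scalar rate)
    iF <- which(fold)
    if (length(iF)) {
      pU <- -expm1(-rates@k0Unfold * exp(F * c0) * dt)
      fire <- iF[stats::runif(length(iF)) < pU]
      if (length(fire)) {
        fold[fire] <- FALSE
        relTot <- relTot + sum(geometry@nExt - seqRes[redox[fire]])
      }
    }
    iU <- which(!fold)
    if (length(iU)) {
      # competing refold / isomerization, at most one event per domain
      canFold <- F <= rates@refoldForceMax
      kf <- if (canFold) kFoldVec[iU] else numeric(length(iU))
      isBG <- triad[iU] & redox[iU] == "SS_BG"
      isIsoRev <- config@reisomerize & triad[iU] & redox[iU] != "SS_BG" &
        redox[iU] != "RED"
      ki <- ifelse(isBG, kIsoTot, ifelse(isIsoRev, kIsoTot, 0))
      kTot <- kf + ki
      act <- which(kTot > 0)
      if (length(act)) {
        u <- stats::runif(length(act))
        fire <- u < -expm1(-kTot[act] * dt)
        for (j in act[fire]) {
          d <- iU[j]
          # choose refold vs isomerization in proportion to rates
          kfj <- if (canFold) kFoldVec[d] else 0
          kij <- if (triad[d] && (redox[d] == "SS_BG" ||
                                  (config@reisomerize &&
                                   redox[d] %in% c("SS_BF", "SS_FG"))))
            kIsoTot else 0
          if (stats::runif(1) < kfj / (kfj + kij)) {
            fold[d] <- TRUE
            relTot <- relTot - (geometry@nExt - seqRes[redox[d]])
          } else if (redox[d] == "SS_BG") {
            newRedox <- if (stats::runif(1) < pBranchFG) "SS_FG" else
              "SS_BF"
            relTot <- relTot + (seqRes["SS_BG"] - seqRes[newRedox])
            redox[d] <- newRedox
            kFoldVec[d] <- rates@kFold[newRedox]
          } else {                        # reisomerization back to SS_BG
            relTot <- relTot + (seqRes[redox[d]] - seqRes["SS_BG"])
            redox[d] <- "SS_BG"
            kFoldVec[d] <- rates@kFold["SS_BG"]
          }
        }
      }
    }
    lenOut[i] <- (springRes + relTot) * params@lAA * zv[i] +
      sum(fold) * isoform@foldedNm
  }
  # per-cycle peak-force samples (peak at the half-cycle point)
  ncyc <- floor(config@duration * config@frequency)
  peakT <- (seq_len(ncyc) - 0.5) / config@frequency
  peakI <- pmin(pmax(round(peakT / dt), 1L), nSteps)
  peaks <- data.frame(cycle = seq_len(ncyc), time = t[peakI],
                      length = lenOut[peakI])
  structure(list(time = t, force = Fv, length = lenOut, peaks = peaks,
                 states = data.frame(class = cls, fold = fold,
                                     redox = redox),
                 releasedResidues = unname(relTot),
                 config = config, isoform = isoform),
            class = "filamentRun")
}

#' @export
print.filamentRun <- function(x, ...) {
  cat("filamentRun <", x$isoform@name, "/", x$config@scenario, ">: ",
      length(x$time), " steps of ", x$config@dt * 1000, " ms, ",
      nrow(x$peaks), " force cycles\n", sep = "")
  invisible(x)
}

#' Steady-state summary of peak-force filament lengths
#'
#' Summarizes the per-cycle lengths at peak force after discarding a
#' burn-in, and tests for a residual trend (slope of a linear fit of peak
#' length on time).
#'
#' @param run a \code{filamentRun} from \code{\link{runFilamentMC}}.
#' @param burnIn burn-in discarded before summarizing, s (default 600).
#' @param window optional length of the summary window, s (default: all
#'   cycles after burn-in).
#' @return A list with \code{mean}, \code{sd}, \code{nCycles},
#'   \code{slope} (nm/s) and \code{slopeP} (p-value of the trend test).
#' @export
steadyStateSummary <- function(run, burnIn = 600, window = NULL) {
  dur <- run$config@duration
  if (burnIn >= dur) stop("burnIn must be smaller than the run duration")
  pk <- run$peaks
  hi <- if (is.null(window)) dur else burnIn + window
  pk <- pk[pk$time > burnIn & pk$time <= hi, , drop = FALSE]
  if (nrow(pk) == 0) stop("summary window contains no cycles")
  if (nrow(pk) >= 10 && stats::sd(pk$length) > 0) {
    # consecutive cycle peaks carry minute-scale kinetic memory, so the
    # trend test runs on peaks averaged within ~150 s blocks, which are
    # close to independent
    win <- diff(range(pk$time))
    nb <- max(4, min(8, floor(win / 150)))
    blk <- cut(pk$time, breaks = nb)
    bt <- tapply(pk$time, blk, mean)
    bl <- tapply(pk$length, blk, mean)
    fitAll <- stats::lm(length ~ time, data = pk)
    slope <- stats::coef(fitAll)[[2]]
    if (length(bt) >= 4 && stats::sd(bl) > 0) {
      fitB <- stats::lm(bl ~ bt)
      slopeP <- summary(fitB)$coefficients[2, 4]
    } else slopeP <- 1
  } else {
    slope <- 0; slopeP <- 1
  }
  list(mean = mean(pk$length), sd = stats::sd(pk$length),
       nCycles = nrow(pk), slope = slope, slopeP = slopeP)
}

#' Time-step stability check for the filament Monte Carlo
#'
#' Runs the same scenario at \code{dt} and \code{dt/10} and compares the
#' steady-state mean peak-force lengths; results should agree within 1
#' percent for a converged step size.
#'
#' @inheritParams runFilamentMC
#' @param burnIn burn-in passed to \code{\link{steadyStateSummary}}, s.
#' @return A list with the two means, their relative difference
#'   \code{relDiff} and logical \code{stable} (relDiff < 0.01).
#' @export
checkDtStability <- function(isoform, config = simulationConfig(),
                             rates = filamentRates(), seed,
                             burnIn = min(600, config@duration / 2),
                             params = polymerParams(),
                             geometry = domainGeometry(),
                             topology = disulfideTopology()) {
  r1 <- runFilamentMC(isoform, config, rates, seed, params, geometry,
                      topology)
  cfg2 <- config; cfg2@dt <- config@dt / 10
  r2 <- runFilamentMC(isoform, cfg2, rates, seed + 1, params, geometry,
                      topology)
  m1 <- steadyStateSummary(r1, burnIn)$mean
  m2 <- steadyStateSummary(r2, burnIn)$mean
  rel <- abs(m1 - m2) / ((m1 + m2) / 2)
  list(meanDt = m1, meanDt10 = m2, relDiff = rel, stable = rel < 0.01)
}

#' Write a filament trajectory as CSV plus a JSON summary
#'
#' @param run a \code{filamentRun}.
#' @param csvPath path for the (t, force, length) trajectory CSV.
#' @param jsonPath optional path for the steady-state summary JSON.
#' @param burnIn burn-in for the summary, s.
#' @return \code{csvPath}, invisibly.
#' @export
writeFilamentRun <- function(run, csvPath, jsonPath = NULL,
                             burnIn = min(600, run$config@duration / 2)) {
  utils::write.csv(data.frame(time_s = run$time, force_pN = run$force,
                              length_nm = run$length),
                   csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    s <- steadyStateSummary(run, burnIn)
    jsonlite::write_json(s, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}
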