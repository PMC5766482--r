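#' @describeIn ForceProtocol-class constant-force (force-clamp) protocol.
#' @param F clamp force, pN.
#' @param duration clamp duration, s.
#' @return A \linkS4class{ForceProtocol}.
#' @export
constantForce <- function(F, duration) {
  new("ForceProtocol", variant = "constant",
      segments = data.frame(t0 = 0, duration = duration, F0 = F, slope = 0))
}

#' @describeIn ForceProtocol-class linear force ramp at a fixed loading
#'   rate, from \code{F0} up to \code{Fmax}.
#' @param rate loading rate, pN/s.
#' @param Fmax final force, pN.
#' @param F0 starting force, pN.
#' @export
forceRamp <- function(rate, Fmax, F0 = 0) {
  if (rate <= 0 || Fmax <= F0) stop("need rate > 0 and Fmax > F0")
  new("ForceProtocol", variant = "ramp",
      segments = data.frame(t0 = 0, duration = (Fmax - F0) / rate,
                            F0 = F0, slope = rate))
}

#' @describeIn ForceProtocol-class symmetric triangular force cycling
#'   between \code{Fmin} and \code{Fmax}.
#' @param Fmin,Fmax cycle bounds, pN.
#' @param frequency cycle frequency, Hz.
#' @export
triangleWave <- function(Fmin = 0, Fmax = 30, frequency = 1, duration) {
  if (Fmax <= Fmin) stop("need Fmax > Fmin")
  half <- 1 / (2 * frequency)
  ncyc <- ceiling(duration * frequency)
  t0 <- rep(seq_len(ncyc) - 1, each = 2) / frequency +
    rep(c(0, half), ncyc)
  seg <- data.frame(t0 = t0, duration = half,
                    F0 = rep(c(Fmin, Fmax), ncyc),
                    slope = rep(c(1, -1) * (Fmax - Fmin) / half, ncyc))
  seg <- seg[seg$t0 < duration, , drop = FALSE]
  last <- nrow(seg)
  seg$duration[last] <- min(seg$duration[last], duration - seg$t0[last])
  new("ForceProtocol", variant = "triangle", segments = seg)
}

#' @describeIn ForceProtocol-class three-pulse refolding protocol:
#'   unfolding pulse, zero-force quench, probe pulse.
#' @param FUnfold,tUnfold unfolding-pulse force (pN) and duration (s).
#' @param tQuench quench duration, s.
#' @param FProbe,tProbe probe-pulse force (pN) and duration (s).
#' @param FQuench quench force, pN (default 0).
#' @export
threePulse <- function(FUnfold, tUnfold, tQuench, FProbe, tProbe,
                       FQuench = 0) {
  seg <- data.frame(
    t0 = c(0, tUnfold, tUnfold + tQuench),
    duration = c(tUnfold, tQuench, tProbe),
    F0 = c(FUnfold, FQuench, FProbe),
    slope = 0)
  new("ForceProtocol", variant = "three_pulse", segments = seg,
      pulses = list(unfold = c(0, tUnfold),
                    quench = c(tUnfold, tUnfold + tQuench),
                    probe = c(tUnfold + tQuench, tUnfold + tQuench + tProbe)))
}

#' Total duration of a force protocol
#' @param protocol a \linkS4class{ForceProtocol}.
#' @return Duration in seconds.
#' @export
protocolDuration <- function(protocol) {
  s <- protocol@segments
  max(s$t0 + s$duration)
}

#' Force applied by a protocol at given times
#'
#' @param protocol a \linkS4class{ForceProtocol}.
#' @param t times, s (vectorized; clamped to the protocol span).
#' @return Forces in pN.
#' @export
forceAt <- function(protocol, t) {
  s <- protocol@segments
  tc <- pmin(pmax(t, 0), protocolDuration(protocol) - 1e-12)
  i <- findInterval(tc, s$t0, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  pmax(s$F0[i] + s$slope[i] * (tc - s$t0[i]), 0)
}

## Split ramp segments of a protocol at the force threshold `thr`, so that
## within every resulting segment the predicate F <= thr has a constant
## truth value (needed to gate refolding hazards exactly).
.splitSegmentsAt <- function(seg, thr) {
  out <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$slope == 0) { out[[i]] <- s; next }
    tc <- (thr - s$F0) / s$slope          # crossing time within segment
    if (is.finite(tc) && tc > 1e-12 && tc < s$duration - 1e-12) {
      a <- s; a$duration <- tc
      b <- s; b$t0 <- s$t0 + tc; b$F0 <- thr; b$duration <- s$duration - tc
      out[[i]] <- rbind(a, b)
    } else out[[i]] <- s
  }
  do.call(rbind, out)
}
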