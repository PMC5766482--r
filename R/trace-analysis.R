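## Sum of squared errors of x[lo..hi] around its mean, from cumulants.
.sseFromCums <- function(cs, cs2, lo, hi) {
  n <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  s2 - s * s / n
}

## Binary segmentation for mean shifts. Returns sorted breakpoints
## (last index of each left plateau).
.binSeg <- function(x, penalty, minPlateau) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x * x))
  bps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1]; hi <- seg[2]
    if (hi - lo + 1 < 2 * minPlateau) next
    ks <- (lo + minPlateau - 1):(hi - minPlateau)
    nl <- ks - lo + 1
    sl <- cs[ks + 1] - cs[lo]; sl2 <- cs2[ks + 1] - cs2[lo]
    nr <- hi - ks
    sr <- cs[hi + 1] - cs[ks + 1]; sr2 <- cs2[hi + 1] - cs2[ks + 1]
    tot <- (sl2 - sl^2 / nl) + (sr2 - sr^2 / nr)
    best <- which.min(tot)
    gain <- .sseFromCums(cs, cs2, lo, hi) - tot[best]
    if (gain > penalty) {
      k <- ks[best]
      bps <- c(bps, k)
      stack[[length(stack) + 1]] <- c(lo, k)
      stack[[length(stack) + 1]] <- c(k + 1L, hi)
    }
  }
  sort(bps)
}

#' Detect extension steps in a staircase trace
#'
#' Change-point segmentation of the extension signal into plateaus
#' (binary segmentation minimizing within-plateau squared error, with a
#' per-breakpoint penalty), followed by merging of neighboring plateaus
#' whose level difference falls below \code{minStep}. Plateau levels are
#' medians; a step is the difference between consecutive plateau levels.
#'
#' @param trace a \linkS4class{Trace} (uniform time grid, >= 100 samples).
#' @param minStep minimum reported step size, nm (default 2).
#' @param penalty per-breakpoint penalty on the squared-error reduction;
#'   default \code{4 * sigma^2 * log(n)} with the noise scale estimated
#'   from the median absolute first difference (a BIC-style choice).
#' @param minPlateau minimum plateau length in samples (default 20).
#' @param detrend remove a linear drift estimated on the first plateau
#'   before detection (default FALSE).
#' @return A data.frame of step calls with columns \code{time} (s),
#'   \code{size} (nm), \code{pre}, \code{post} (plateau levels, nm) and
#'   \code{force_pN}; zero rows if no step exceeds \code{minStep}.
#' @export
detectSteps <- function(trace, minStep = 2, penalty = NULL,
                        minPlateau = 20, detrend = FALSE) {
  stopifnot(is(trace, "Trace"))
  x <- trace@extension
  n <- length(x)
  if (n < 100) stop("trace must have at least 100 samples")
  dt <- diff(trace@time)
  if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("trace time grid is not uniform")
  if (detrend) {
    tt <- trace@time
    fit <- stats::lm(x ~ tt)
    x <- x - stats::coef(fit)[[2]] * tt
  }
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (is.null(penalty)) penalty <- 4 * max(sigma, 1e-6)^2 * log(n)
  bps <- .binSeg(x, penalty, minPlateau)
  bounds <- c(0L, bps, n)
  med <- vapply(seq_len(length(bounds) - 1), function(i)
    stats::median(x[(bounds[i] + 1):bounds[i + 1]]), 0)
  # merge neighboring plateaus closer than minStep
  while (length(med) > 1 && any(abs(diff(med)) < minStep)) {
    i <- which.min(abs(diff(med)))        # merge most similar pair
    bounds <- bounds[-(i + 1)]
    med <- vapply(seq_len(length(bounds) - 1), function(j)
      stats::median(x[(bounds[j] + 1):bounds[j + 1]]), 0)
  }
  if (length(med) < 2)
    return(data.frame(time = numeric(0), size = numeric(0),
                      pre = numeric(0), post = numeric(0),
                      force_pN = numeric(0)))
  k <- bounds[2:(length(bounds) - 1)]
  data.frame(time = trace@time[k], size = diff(med),
             pre = med[-length(med)], post = med[-1],
             force_pN = trace@force[k])
}

#' Fit a sum of Gaussians to a step-size histogram
#'
#' Bins the sizes at \code{binWidth} and fits
#' \eqn{\sum_j A_j \exp(-(x-\mu_j)^2 / 2\sigma_j^2)} to the counts by
#' Levenberg-Marquardt nonlinear least squares. Initial means are the
#' highest local maxima of the (lightly smoothed) histogram.
#'
#' @param sizes numeric vector of step sizes, nm (>= 20 values).
#' @param nComponents number of Gaussian components.
#' @param binWidth histogram bin width, nm (default 1).
#' @return A data.frame with one row per component (\code{mean}, \code{sd},
#'   \code{amplitude}), ordered by mean, with attribute
#'   \code{"binWidth"}.
#' @examples
#' set.seed(1)
#' fitGaussianMixtureHist(rnorm(300, 26.4, 0.7), 1)
#' @export
fitGaussianMixtureHist <- function(sizes, nComponents = 1, binWidth = 1) {
  sizes <- sizes[is.finite(sizes)]
  if (length(sizes) < max(20, 10 * nComponents))
    stop("need at least ", max(20, 10 * nComponents), " sizes to fit ",
         nComponents, " component(s)")
  breaks <- seq(floor(min(sizes) / binWidth) * binWidth - binWidth,
                ceiling(max(sizes) / binWidth) * binWidth + binWidth,
                by = binWidth)
  h <- graphics::hist(sizes, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  # greedy peak picking with a 3-bin exclusion zone so multi-component
  # starts never collapse onto one cluster
  cand <- order(y, decreasing = TRUE)
  picked <- integer(0)
  for (i in cand) {
    if (y[i] == 0) break
    if (!length(picked) || all(abs(i - picked) > 3))
      picked <- c(picked, i)
    if (length(picked) == nComponents) break
  }
  if (length(picked) < nComponents)
    picked <- utils::head(unique(c(picked, cand)), nComponents)
  mu0 <- x[picked]
  start <- list()
  for (j in seq_len(nComponents)) {
    start[[paste0("A", j)]] <- max(y[which.min(abs(x - mu0[j]))], 1)
    start[[paste0("m", j)]] <- mu0[j]
    start[[paste0("s", j)]] <- binWidth
  }
  terms <- paste(sprintf("A%d * exp(-(x - m%d)^2 / (2 * s%d^2))",
                         seq_len(nComponents), seq_len(nComponents),
                         seq_len(nComponents)), collapse = " + ")
  form <- stats::as.formula(paste("y ~", terms))
  lower <- unlist(lapply(seq_len(nComponents), function(j)
    c(0, min(x), binWidth / 10)))
  fit <- minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                           start = start, lower = lower,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  cf <- stats::coef(fit)
  out <- data.frame(
    mean = cf[paste0("m", seq_len(nComponents))],
    sd = abs(cf[paste0("s", seq_len(nComponents))]),
    amplitude = cf[paste0("A", seq_len(nComponents))])
  out <- out[order(out$mean), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "binWidth") <- binWidth
  out
}

#' Refolding fraction with bootstrap SEM
#'
#' The refolding fraction is the total number of unfolding events in the
#' probe pulses divided by the total in the unfolding pulses. The SEM is
#' the standard deviation of the fraction over nonparametric bootstrap
#' resamples of whole traces.
#'
#' @param nUnfoldFirst integer vector, unfolding-pulse event count per
#'   trace.
#' @param nUnfoldProbe integer vector, probe-pulse event count per trace.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed integer RNG seed.
#' @return A list with \code{fraction}, \code{sem}, \code{nTraces},
#'   \code{nFirst}, \code{nProbe}.
#' @examples
#' refoldingFraction(rep(1, 50), rbinom(50, 1, 0.44), seed = 1)
#' @export
refoldingFraction <- function(nUnfoldFirst, nUnfoldProbe, nBoot = 1000,
                              seed = 1) {
  if (length(nUnfoldFirst) != length(nUnfoldProbe))
    stop("per-trace count vectors must have equal length")
  if (sum(nUnfoldFirst) <= 0) stop("no unfolding-pulse events")
  frac <- sum(nUnfoldProbe) / sum(nUnfoldFirst)
  set.seed(seed)
  n <- length(nUnfoldFirst)
  bs <- vapply(seq_len(nBoot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    den <- sum(nUnfoldFirst[i])
    if (den > 0) sum(nUnfoldProbe[i]) / den else NA_real_
  }, 0)
  list(fraction = frac, sem = stats::sd(bs, na.rm = TRUE),
       nTraces = n, nFirst = sum(nUnfoldFirst), nProbe = sum(nUnfoldProbe))
}

#' Single-molecule fingerprint filters
#'
#' Emulates the trace-selection criteria of constant-force AFM work:
#' \code{"repeat-step"} keeps traces showing at least two steps of the
#' same size (within \code{sizeTol} nm), the signature of a single tether
#' carrying repeated domains; \code{"match-extension"} keeps three-pulse
#' traces whose extensions at the end of the unfolding and probe pulses
#' agree within \code{extTol} nm.
#'
#' @param x for \code{"repeat-step"}: a list of step-call data.frames from
#'   \code{\link{detectSteps}}; for \code{"match-extension"}: a list of
#'   \linkS4class{Trace} objects whose metadata contain the three-pulse
#'   \code{protocol}.
#' @param mode \code{"repeat-step"} or \code{"match-extension"}.
#' @param sizeTol step-size matching tolerance, nm (default 1).
#' @param extTol extension matching tolerance, nm (default 3).
#' @return Logical vector marking the selected traces.
#' @export
fingerprintFilter <- function(x, mode = c("repeat-step", "match-extension"),
                              sizeTol = 1, extTol = 3) {
  mode <- match.arg(mode)
  if (mode == "repeat-step") {
    vapply(x, function(calls) {
      s <- calls$size
      if (length(s) < 2) return(FALSE)
      d <- abs(outer(s, s, "-"))
      any(d[upper.tri(d)] <= sizeTol)
    }, NA)
  } else {
    vapply(x, function(tr) {
      stopifnot(is(tr, "Trace"))
      prot <- tr@metadata$protocol
      if (is.null(prot) || !is(prot, "ForceProtocol") ||
          prot@variant != "three_pulse")
        stop("match-extension requires traces with a three-pulse protocol ",
             "in their metadata")
      tailOf <- function(win) {
        i <- which(tr@time >= win[1] & tr@time < win[2])
        i <- utils::tail(i, max(10, round(length(i) * 0.05)))
        stats::median(tr@extension[i])
      }
      abs(tailOf(prot@pulses$unfold) - tailOf(prot@pulses$probe)) <= extTol
    }, NA)
  }
}

#' Trace CSV round trip
#'
#' Traces are exchanged as delimited text with columns \code{time_s},
#' \code{extension_nm}, \code{force_pN}.
#'
#' @param trace a \linkS4class{Trace}.
#' @param path file path (.csv or .tsv).
#' @param sep field separator; inferred from the file extension when NULL.
#' @return \code{readTraceCsv} returns a \linkS4class{Trace}.
#' @export
writeTraceCsv <- function(trace, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(
    data.frame(time_s = trace@time, extension_nm = trace@extension,
               force_pN = trace@force),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE)
  need <- c("time_s", "extension_nm", "force_pN")
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  newTrace(df$time_s, df$extension_nm, df$force_pN,
           metadata = list(source = path))
}
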