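#' Worm-like-chain force at a given fractional extension
#'
#' Standard WLC interpolation formula
#' \deqn{F(z) = (kT/p)\,[1/(4(1-z)^2) - 1/4 + z]}
#' with \code{z} the end-to-end distance over contour length.
#'
#' @param z fractional extension in [0, 1).
#' @param params a \linkS4class{PolymerParams}.
#' @return Force in pN (vectorized over \code{z}).
#' @seealso \code{\link{wlcFractionalExtension}} for the numerical inverse.
#' @export
wlcForce <- function(z, params = polymerParams()) {
  if (any(z < 0 | z >= 1)) stop("z must lie in [0, 1)")
  (params@kT / params@p) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

## Vectorized WLC inversion by bracketed bisection on z in [0, 1 - 1e-12].
## Bisection is preferred over uniroot here because the bracket is fixed
## and 60 halvings already exceed the 1e-9 relative tolerance.
.wlcInvert <- function(F, kT, p) {
  f <- F * p / kT                         # dimensionless force
  lo <- rep(0, length(f))
  hi <- rep(1 - 1e-12, length(f))
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    below <- (1 / (4 * (1 - mid)^2) - 0.25 + mid) < f
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Fractional extension of a worm-like chain
#'
#' Numerically inverts the WLC interpolation formula (bracketed bisection,
#' relative tolerance better than 1e-9). Used for the high-force step-size
#' theory of single Ig domains.
#'
#' @param F force, pN (vectorized, must be >= 0).
#' @param params a \linkS4class{PolymerParams}.
#' @return Fractional extension z in [0, 1); z = 0 at F = 0, strictly
#'   increasing in F.
#' @examples
#' wlcFractionalExtension(100)  # ~0.835 with default p = 0.4 nm
#' @export
wlcFractionalExtension <- function(F, params = polymerParams()) {
  if (any(!is.finite(F)) || any(F < 0))
    stop("force must be finite and non-negative")
  z <- numeric(length(F))
  pos <- F > 0
  if (any(pos)) z[pos] <- .wlcInvert(F[pos], params@kT, params@p)
  z
}

#' Fractional extension of a freely jointed chain
#'
#' Langevin function \eqn{z(u) = \coth(u) - 1/u} with \eqn{u = F b / kT},
#' extended continuously by z(0) = 0. Used for the entropic springs of the
#' titin I-band.
#'
#' @param F force, pN (vectorized, must be >= 0).
#' @param params a \linkS4class{PolymerParams}.
#' @return Fractional extension in [0, 1).
#' @examples
#' fjcFractionalExtension(30)  # ~0.875 with default b = 1.1 nm
#' @export
fjcFractionalExtension <- function(F, params = polymerParams()) {
  if (any(!is.finite(F)) || any(F < 0))
    stop("force must be finite and non-negative")
  u <- F * params@b / params@kT
  z <- numeric(length(u))
  small <- u < 1e-4                       # series: u/3 - u^3/45
  z[small] <- u[small] / 3 - u[small]^3 / 45
  z[!small] <- 1 / tanh(u[!small]) - 1 / u[!small]
  z
}

## Identify an allowed transition between two states.
## Returns list(kind, label) or stops with an informative error.
.transitionInfo <- function(before, after) {
  b <- .asState(before); a <- .asState(after)
  pair <- sprintf("(%s,%s) -> (%s,%s)", b[1], b[2], a[1], a[2])
  if (b[1] == "FOLDED" && a[1] == "UNFOLDED" && b[2] == a[2])
    return(list(kind = "unfold", label = paste0("unfold_", b[2])))
  if (b[1] == "UNFOLDED" && a[1] == "FOLDED" && b[2] == a[2])
    return(list(kind = "refold", label = paste0("refold_", b[2])))
  if (b[1] == "UNFOLDED" && a[1] == "UNFOLDED") {
    key <- paste(b[2], a[2], sep = ">")
    lab <- switch(key,
      "SS_BG>SS_BF" = list(kind = "iso",     label = "iso_BG_BF"),
      "SS_BG>SS_FG" = list(kind = "iso",     label = "iso_BG_FG"),
      "SS_BF>SS_BG" = list(kind = "iso_rev", label = "iso_BF_BG"),
      "SS_FG>SS_BG" = list(kind = "iso_rev", label = "iso_FG_BG"),
      "SS_BG>RED"   = list(kind = "reduce",  label = "red_SS_BG"),
      "SS_BF>RED"   = list(kind = "reduce",  label = "red_SS_BF"),
      "SS_FG>RED"   = list(kind = "reduce",  label = "red_SS_FG"),
      NULL)
    if (!is.null(lab)) return(lab)
  }
  stop("disallowed domain transition: ", pair)
}

.loopOf <- function(redox, topo) {
  switch(redox, RED = 0, SS_BG = topo@loopBG, SS_BF = topo@loopBF,
         SS_FG = topo@loopFG)
}

#' Residues released by a domain transition
#'
#' Converts the chemistry of a transition into the number of residues that
#' newly become force-bearing: unfolding releases \code{nExt} minus the
#' residues still sequestered behind the current disulfide; isomerization
#' SS_BG to SS_BF releases \code{loopFG} residues (the printed 11-residue /
#' 4 nm step) and SS_BG to SS_FG releases \code{loopBF} (51 residues /
#' 17 nm); reduction releases the loop of the cleaved disulfide. Refolding
#' and reverse isomerization return negative counts (residues
#' re-sequestered).
#'
#' @param before,after \linkS4class{DomainState} objects (or character(2)
#'   vectors \code{c(fold, redox)}).
#' @param topology a \linkS4class{DisulfideTopology}.
#' @param geometry a \linkS4class{DomainGeometry}.
#' @return Signed residue count.
#' @examples
#' releasedResidues(domainState("FOLDED", "SS_BG"),
#'                  domainState("UNFOLDED", "SS_BG"))  # 88 - 57 = 31
#' @export
releasedResidues <- function(before, after,
                             topology = disulfideTopology(),
                             geometry = domainGeometry()) {
  info <- .transitionInfo(before, after)
  b <- .asState(before); a <- .asState(after)
  switch(info$kind,
    unfold  = geometry@nExt - .loopOf(b[2], topology),
    refold  = -(geometry@nExt - .loopOf(b[2], topology)),
    iso     = if (a[2] == "SS_BF") topology@loopFG else topology@loopBF,
    iso_rev = if (b[2] == "SS_BF") -topology@loopFG else -topology@loopBF,
    reduce  = .loopOf(b[2], topology))
}

#' Predicted extension step of a domain transition
#'
#' The extension gained at force \code{F} when a transition releases
#' \code{n} residues is \code{n * lAA * z_wlc(F)}; transitions that leave
#' (enter) the folded state additionally subtract (restore) the folded
#' end-to-end distance \code{dFolded}. With the defaults this yields the
#' 17.0 nm (51 residues) and 3.7 nm (11 residues) isomerization steps at
#' 100 pN and the 26.4 nm reduced unfolding step at 170 pN.
#'
#' @inheritParams releasedResidues
#' @param F force at the event, pN (> 0).
#' @param params a \linkS4class{PolymerParams}.
#' @return Step size in nm (negative for refolding).
#' @examples
#' predictStepSize(domainState("UNFOLDED", "SS_BG"),
#'                 domainState("UNFOLDED", "SS_FG"), F = 100)  # ~17 nm
#' @export
predictStepSize <- function(before, after, F,
                            params = polymerParams(),
                            geometry = domainGeometry(),
                            topology = disulfideTopology()) {
  if (length(F) != 1L || !is.finite(F) || F <= 0)
    stop("F must be a single positive force in pN")
  info <- .transitionInfo(before, after)
  n <- releasedResidues(before, after, topology, geometry)
  if (n == 0)
    stop("transition releases zero residues; no step is defined")
  z <- wlcFractionalExtension(F, params)
  base <- n * params@lAA * z
  switch(info$kind,
    unfold = base - geometry@dFolded,
    refold = base + geometry@dFolded,
    base)
}
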