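---
title: "Modelling disulfide isomerization mechanics in titin Ig domains"
author: "titinIso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disulfide isomerization mechanics in titin Ig domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titinIso)
```

## The system

Titin spans half a sarcomere and sets the passive stiffness of striated
muscle. Its extensible I-band combines two unstructured entropic springs
(the N2B unique sequence and the PEVK segment) with a tandem array of
immunoglobulin (Ig) domains that unfold and refold under load. Many
I-band Ig domains carry a conserved cysteine triad on beta-strands B, F
and G (CysB, CysF, CysG; reference columns 23, 73 and 80 in I91
numbering). Under oxidizing conditions the preferred disulfide forms
between CysB and CysG. That bond is buried in the folded core, so thiol
chemistry only becomes possible after mechanical unfolding, when the
free CysF can attack either sulfur of the CysB-CysG bond and relocate
the crosslink (disulfide isomerization), releasing the residues trapped
behind it. This package models that mechanochemistry at three scales:
single domains (step-size theory and stochastic kinetics), single
molecules (synthetic AFM traces and their analysis), and the whole
I-band (kinetic Monte Carlo), plus a sequence scanner that maps the
triad across the titin Ig inventory.

## Step-size theory

A transition that makes $n$ residues force-bearing at force $F$ produces
an extension step

$$\Delta L(F) = n\, l_{aa}\, z_{\mathrm{WLC}}(F) \; [-\; d_{\mathrm{folded}}],$$

where $z_{\mathrm{WLC}}$ is the fractional extension of a worm-like
chain obtained by numerically inverting the interpolation formula
$F = (kT/p)\,[1/(4(1-z)^2) - 1/4 + z]$ (bracketed bisection on
$z \in [0, 1-10^{-12}]$, relative tolerance better than $10^{-9}$), and
the folded end-to-end distance $d_{\mathrm{folded}}$ is subtracted only
by transitions that leave the folded state. Defaults: $kT = 4.11$ pN nm
(25 C), $l_{aa} = 0.4$ nm/residue, $p = 0.4$ nm — conventional
single-molecule values.

Residue counts come from the disulfide topology of I69: 51 residues
between CysB and CysF, 11 between CysF and CysG, and 57 sequestered
behind the native CysB-CysG bond, with $n_{ext} = 88$ residues released
by unfolding of a reduced domain and $d_{\mathrm{folded}} = 4.4$ nm.
With these defaults the model reproduces the observed step populations:
26.4 nm (reduced unfolding at 170 pN), ~6 nm (oxidized unfolding at
100 pN), 17.0 and 3.7 nm (the two isomerization branches) and ~19 nm
(Tcep reduction of CysB-CysG).

Two numerical caveats are deliberate. First, the loop counts are
reverse-engineered from the printed step sizes because the exact residue
bookkeeping of the folded-length correction is not published; they are
all configurable through `disulfideTopology()`. Second, the default
CysB-CysG loop (57) is smaller than the sum of the two sub-loops
(51 + 11 = 62): choosing 57 lets the ~6 nm oxidized unfolding step and
the 19 nm reduction step coexist, at the cost of exact additivity of
step sizes along multi-reaction paths (the defaults over-count a
complete oxidized-to-reduced path by 5 residues, about 1.7 nm at
100 pN). The path-conservation identities therefore hold exactly for
*additive* topologies (loopBG = loopBF + loopFG), which is what the
invariant tests use; with the I69 defaults the discrepancy is the
documented price of matching all printed populations simultaneously.

## Domain kinetics

All force-dependent rates follow Bell's model,
$k(F) = k_0 e^{F \Delta x / kT}$. Defaults:

* oxidized unfolding: $\Delta x = 0.3$ nm with $k_0$ solving
  $k(100\,\mathrm{pN}) = 1.06\,\mathrm{s}^{-1}$ ($k_0 = 7.2 \times
  10^{-4}\,\mathrm{s}^{-1}$);
* reduced unfolding: $\Delta x = 0.3$ nm (the measured transition-state
  distance is similar for both redox states) and $k_0 = 5 \times
  10^{-6}\,\mathrm{s}^{-1}$, which places the most probable unfolding
  force in a 40 pN/s ramp at ~182 pN. The printed mean of 114 pN for
  oxidized domains and the 1.06 s$^{-1}$ clamp rate are not exactly
  co-satisfiable by one Bell pair; the defaults prioritize the clamp
  rate, and the resulting ramp means (~106 vs ~174 pN) preserve the
  observed ordering and gap;
* isomerization: $k_{iso1} = 0.021$ (to CysB-CysF) and $k_{iso2} =
  0.027\,\mathrm{s}^{-1}$ (to CysF-CysG), force-independent by default
  ($\Delta x_{iso} = 0$) because they were measured at a single force; a
  Bell option exists;
* refolding, from measured 10 s refolding fractions via
  $k = -\ln(1-f)/\Delta t$: 0.058 (CysB-CysG), 0.054 (CysB-CysF), 0
  (CysF-CysG) and 0.01 s$^{-1}$ (reduced), gated to forces at or below
  `refoldForceMax` (1 pN);
* Tcep reduction: second order, $k_{red} \cdot [\mathrm{Tcep}] =
  0.025\,\mathrm{s}^{-1}$ at 10 mM, off by default.

The buried-disulfide rule is structural: isomerization and reduction
are only offered from the unfolded state.

`simulateEnsemble()` samples trajectories exactly. Within every
piecewise-linear force segment the cumulative hazard of a Bell
transition has a closed form, so waiting times are drawn by inverting
$\Lambda(t) = E$ with $E \sim \mathrm{Exp}(1)$ — the continuous-time
generalization of the Gillespie algorithm with no discretization error.
Segments are pre-split at the refolding force gate so every hazard is
either fully on or fully off within a segment. This choice was made
over thinning or fixed-stepping because ramps to high force make
bounded-rate approaches either slow or inexact.

## Dwell-time fitting

The sequential scheme folded $\to$ unfolded(BG) $\to$ {BF, FG} is fitted
by censored-exponential maximum likelihood: $\hat k = N_{events} /
\sum \mathrm{exposure}$, where censored observations contribute their
observation window. The total isomerization rate is split into branch
rates by the observed branch counts. Confidence intervals come from a
nonparametric bootstrap (default 1000 resamples) over whole traces, not
events, to respect within-trace correlation. Mirroring the experimental
practice of keeping only recordings long enough for isomerization to
complete, traces shorter than 20 s are excluded from the isomerization
fit (`minTraceLength`). When no isomerization is observed the branch
rates are reported as 0 with a rule-of-three upper bound
($3/\mathrm{exposure}$).

## Synthetic AFM traces

`synthesizeTrace()` renders an event trajectory as a sampled recording:
the WLC extension of the currently released contour at the protocol
force, minus $d_{\mathrm{folded}}$ per currently unfolded domain, passed
through a single-pole low-pass filter (step response 1 ms), plus linear
drift and i.i.d. Gaussian baseline noise (default $\sigma = 1$ nm at
1 kHz — a conventional AFM figure, since the instrument noise of the
original recordings is not published). Because the baseline uses the
same contour arithmetic as the step-size theory, every noiseless step
equals its ground-truth event size to numerical precision, which is
what makes the generator usable as an oracle for the detector.

What the generator does *not* emulate: cantilever dynamics and thermal
spectra, surface adhesion artifacts, nonlinear drift, force-feedback
overshoot, and multiple tethers. Passing the round-trip tests therefore
shows that the analysis recovers what this instrument model produces,
not that it is robust to every artifact of real recordings. Tether
pickup variability (a random subset of domains under load) is available
via the `pickup` argument but off by default.

The three-pulse wrapper (`synthesizeThreePulse()`) chains an unfolding
pulse, a zero-force quench (where refolding competes at the
redox-specific rates) and a probe pulse, and tallies per-pulse
unfolding counts. One modelling point deserves emphasis: the published
refolding fractions are *conditional on disulfide identity* — a
fraction of 0.44 for domains that kept CysB-CysG, measured on traces
selected by their step signatures. In an unconditional simulation,
isomerization (which never reverses and whose FG product cannot refold)
competes with refolding and drags the raw fraction well below 0.44. The
refolding assay in the acceptance tests therefore fixes the disulfide
identity (isomerization rates zeroed) when reproducing the conditional
0.44, which is the generative equivalent of the experimental trace
selection.

## Step detection and histogram fitting

The detector is binary segmentation for mean shifts: recursively split
the extension signal where the within-plateau squared error drops the
most, accept a split when the drop exceeds a BIC-style penalty (default
$4\hat\sigma^2 \log n$, with $\hat\sigma$ from the median absolute
first difference), respect a minimum plateau length, then merge
neighboring plateaus closer than `minStep` (2 nm). Plateau levels are
medians, so single-sample excursions do not bias step sizes. The
default minimum plateau (20 samples) is conservative; dense staircases
(eight domains unfolding at ~1 s$^{-1}$ each) benefit from
`minPlateau = 8`, which the round-trip tests use — near-coincident
events closer than the minimum plateau are irreducibly merged into one
call, which is the main detection failure mode at these event rates.

Histogram populations are quantified by least-squares fits of Gaussian
sums to the binned step sizes (1 nm bins by default, matching the
published histograms), with initial means from well-separated histogram
peaks and Levenberg-Marquardt refinement.

## Whole-I-band Monte Carlo

`runFilamentMC()` advances all I-band Ig domains in fixed steps
(default 10 ms, checked stable against 1 ms) under a triangular 0-30 pN,
1 Hz force cycle for 20 simulated minutes. Filament length is the
freely-jointed-chain extension (Kuhn length 1.1 nm for all unstructured
polypeptide — the per-segment values used in the original simulations
are not published, so one conventional value is used and is
configurable) of the two springs plus all non-sequestered residues of
unfolded domains, plus 4.4 nm per folded domain. The N2BA inventory is
101 I-band Igs with cysteine classes TRIAD 21, PAIR_BF 24, PAIR_FG 17,
PAIR_BG 6, SINGLE 24, NONE 9, with springs at residues 3712-4289 (N2B)
and 10216-12022 (PEVK). The N2B isoform keeps the short PEVK
(11851-12022); its per-domain inventory is not fixed by the canonical
annotation, so the default (44 Igs, 4 triads) is constructed to match
the reported ~9 percent triad fraction.

Rate choices at this scale differ deliberately from the single-domain
module. The 0-30 pN cycling regime is far below the forces where the
oxidized/reduced stability difference was measured, and the comparison
between redox scenarios is meant to isolate what oxidation does through
residue sequestration, faster refolding and isomerization. All domains
therefore share one generic unfolding Bell pair ($k_0 = 10^{-4}$
s$^{-1}$, $\Delta x = 0.9$ nm, giving ~0.07 s$^{-1}$ at 30 pN, in the
range used by prior cyclic-force titin simulations), while redox enters
through the sequestered residue counts and the refolding rates
(disulfide-specific values above; 0.3 s$^{-1}$ for domains without
triad cysteines, the lower of the published I4/I91 rates). Refolding is
only attempted below 1 pN, i.e. at the cycle troughs. With per-redox
unfolding pairs taken from the high-force measurements instead, the
143-fold faster unfolding of oxidized domains overwhelms sequestration
and refolding and reverses the redox ordering — a regime the published
whole-filament result excludes; the shared-pair default is the
package's resolution of that underdetermined trade-off, and every rate
is exposed through `filamentRates()`.

Residue bookkeeping in the filament is strictly conservative:
isomerization releases the *difference* of sequestered counts (57 - 11
= 46 residues for BG to FG), so unstructured + sequestered + folded
residues are invariant along any trajectory, whereas the single-domain
step-size theory uses the printed per-reaction loop counts (51
residues / 17 nm for the same reaction). The two conventions coincide
for additive topologies; with the I69 defaults they differ by the same
5 residues discussed above.

Steady state is assessed on per-cycle peak-force lengths after a
burn-in (default 600 s). Successive cycle peaks carry minute-scale
kinetic memory, so the trend test regresses peaks averaged in ~150 s
blocks, which are close to independent; naive per-cycle regression
would reject stationarity spuriously. The triad's SS_BG pool empties
irreversibly unless `reisomerize = TRUE` re-opens the return path
(off by default, matching the main published simulations).

Test problem sizes: the redox/isoform ordering tests run 1200 s with a
600 s burn-in; the step-size stability check runs 600 s at 10 vs 1 ms.
These horizons hold the orderings with wide margins (the N2BA
oxidized-reduced gap is several hundred nm against cycle-to-cycle
fluctuations of tens of nm).

## Triad scanning

Domains are cut from a parent sequence by 1-based inclusive
annotations, aligned globally to the packaged I91 reference (PDB 1TIT,
89 residues) with BLOSUM62 scoring and affine gaps (open 11, extend 1 —
surfaced in the interface because the original alignment parameters are
unstated), and classified by which of the reference columns 23/73/80
their cysteines occupy within a +/-2 column tolerance. Alignments
scoring below a floor are flagged UNALIGNED rather than forced into a
class. Classification is deterministic and invariant to terminal flanks
of up to 5 residues. Band regions default to conventional titin
boundaries and are editable; the 12 manually curated Ig domains absent
from the automatic annotation ship as a packaged table. Published
tallies of pair-containing I-band domains differ between two summaries
(43 in one, 24+17+6 = 47 in the other); the scanner reports raw counts
and leaves the discrepancy to the user rather than reconciling it. The
canonical-titin reproduction (163 Igs, 101 I-band, 21 triads) needs the
UniProt Q8WZ42-1 sequence and its Ig feature table supplied as
`inst/extdata/Q8WZ42-1.fasta` and `Q8WZ42-1_domains.tsv`; they are not
redistributed with the package.

## Known limitations

* Loop residue counts and the folded-length correction are calibrated
  to printed step sizes, not taken from structure.
* Isomerization force dependence is unconstrained by data away from
  100 pN; the default assumes none.
* The filament model has no domain-domain coupling, no sarcomere
  mechanics, and its absolute lengths depend on unpublished
  contour/Kuhn parameters — only orderings and differences are
  meaningful.
* The instrument model omits cantilever dynamics; detector performance
  on real recordings will be worse than on synthetic traces near the
  published noise figure.
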