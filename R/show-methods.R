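setMethod("show", "PolymerParams", function(object) {
  cat("PolymerParams: kT =", object@kT, "pN nm | lAA =", object@lAA,
      "nm | p =", object@p, "nm | b =", object@b, "nm\n")
})

setMethod("show", "DomainState", function(object) {
  cat("DomainState:", object@fold, "/", object@redox, "\n")
})

setMethod("show", "DisulfideTopology", function(object) {
  cat("DisulfideTopology: loopBF =", object@loopBF, "| loopFG =",
      object@loopFG, "| loopBG =", object@loopBG, "residues\n")
})

setMethod("show", "DomainGeometry", function(object) {
  cat("DomainGeometry: nExt =", object@nExt, "residues | dFolded =",
      object@dFolded, "nm\n")
})

setMethod("show", "RateSet", function(object) {
  cat("RateSet\n  unfolding k0 (1/s):",
      paste(sprintf("%s=%.3g", names(object@k0Unfold), object@k0Unfold),
            collapse = " "),
      "\n  unfolding dx (nm): ",
      paste(sprintf("%s=%.3g", names(object@dxUnfold), object@dxUnfold),
            collapse = " "),
      "\n  kIso1 =", object@kIso1, "1/s, kIso2 =", object@kIso2,
      "1/s, dxIso =", object@dxIso, "nm\n  refolding (1/s):",
      paste(sprintf("%s=%.3g", names(object@kFold), object@kFold),
            collapse = " "),
      "\n  Tcep:", object@tcepMM, "mM x", object@kRed2,
      "1/s/mM | refold allowed below", object@refoldForceMax, "pN\n")
})

setMethod("show", "ForceProtocol", function(object) {
  cat("ForceProtocol <", object@variant, "> ",
      nrow(object@segments), " segment(s), total ",
      protocolDuration(object), " s\n", sep = "")
})

setMethod("show", "Trace", function(object) {
  n <- length(object@time)
  cat("Trace:", n, "samples over",
      if (n) round(object@time[n] - object@time[1], 4) else 0, "s\n")
  if (n) cat("  force range:", round(min(object@force), 2), "-",
             round(max(object@force), 2), "pN\n")
})

setMethod("show", "TetherSpec", function(object) {
  cat("TetherSpec:", object@nDomains, "domains [",
      paste(object@redox, collapse = " "), "]\n")
})

setMethod("show", "IsoformSpec", function(object) {
  tab <- table(factor(object@igClasses, levels = .IG_CLASSES))
  cat("IsoformSpec <", object@name, ">: ", length(object@igClasses),
      " I-band Ig domains\n  ", sep = "")
  cat(paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n  N2B spring ", object@n2bRange[1], "-", object@n2bRange[2],
      " | PEVK ", object@pevkRange[1], "-", object@pevkRange[2], "\n",
      sep = "")
})

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel: sigma =", object@sigma, "nm |", object@sampling,
      "Hz | drift =", object@drift, "nm/s | response =",
      object@responseTau * 1000, "ms\n")
})
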