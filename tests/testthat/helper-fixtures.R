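# Shared fixtures built in code.

# A disulfide topology in which the native CysB-CysG loop equals the sum of
# the two sub-loops, so that released-residue counts are additive along
# every unfolding/isomerization/reduction path.
additiveTopology <- function(loopBF = 51, loopFG = 11)
  disulfideTopology(loopBF = loopBF, loopFG = loopFG,
                    loopBG = loopBF + loopFG)

# Synthetic polyprotein parent sequence assembled from I91-derived domains
# with cysteines substituted at chosen reference columns. Returns the
# AAStringSet of extracted domains (with annotation attribute).
syntheticTriadConstruct <- function() {
  ref <- as.character(i91Reference())
  mut <- function(s, pos) { substring(s, pos, pos) <- "C"; s }
  doms <- c(
    TRIAD   = mut(mut(mut(ref, 23), 73), 80),
    PAIR_BF = mut(mut(ref, 23), 73),
    PAIR_FG = mut(mut(ref, 73), 80),
    PAIR_BG = mut(mut(ref, 23), 80),
    SINGLE_G = mut(ref, 80),
    NONE    = ref)
  linker <- "GGSGGSGGSG"
  parent <- linker
  starts <- integer(length(doms))
  for (i in seq_along(doms)) {
    starts[i] <- nchar(parent) + 1L
    parent <- paste0(parent, doms[[i]], linker)
  }
  ann <- data.frame(id = names(doms), start = starts,
                    end = starts + nchar(doms) - 1L,
                    region = c(rep("I-band", 5), "A-band"),
                    stringsAsFactors = FALSE)
  loadDomains(Biostrings::AAStringSet(parent), ann)
}

# Match detected steps to ground-truth events one-to-one
# (time within 50 ms, size within 1.5 nm). "spurious" counts calls with
# no truth event anywhere near in time (genuine false positives, as
# opposed to near-coincident events merged into one call).
matchEvents <- function(calls, events, timeTol = 0.05, sizeTol = 1.5) {
  used <- rep(FALSE, nrow(calls))
  hits <- 0L
  for (i in seq_len(nrow(events))) {
    j <- which(!used & abs(calls$time - events$time[i]) < timeTol &
                 abs(calls$size - events$step_nm[i]) < sizeTol)
    if (length(j)) { hits <- hits + 1L; used[j[1]] <- TRUE }
  }
  spur <- sum(vapply(which(!used), function(j)
    all(abs(events$time - calls$time[j]) > timeTol), NA))
  list(matched = hits, truth = nrow(events), extra = sum(!used),
       spurious = spur)
}
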