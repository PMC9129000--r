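# Shared synthetic worlds, built once per test session and cached.
# Heavy objects (aligned libraries) live here so several test files can
# reuse them without re-running the aligner.

.fx <- new.env(parent = emptyenv())

fxCache <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# 20-kb mitochondrial-like toy circle with two planted direct repeats
# (intermediate-size, one inside and one outside the soft-clip detection
# envelope) placed well away from bin boundaries.
fxMtGenome <- function() fxCache("mt", {
  g <- randomGenome(20000, name = "mt", repeats = data.frame(
    start1 = c(3001, 14201), start2 = c(9001, 17201),
    len = c(127, 60), orientation = c("direct", "direct")), seed = 101)
  list(genome = g, repeats = findExactRepeats(g, minLen = 50))
})

# master-only, error-free library on the mt toy, aligned
fxMtMasterAligned <- function() fxCache("mtMaster", {
  w <- fxMtGenome()
  mix <- buildMixture(w$genome, list(), w$repeats)
  sim <- simulateReads(mix, libraryParams(depth = 40, errorRate = 0,
                                          seed = 7))
  recs <- withSeed(17, pairMates(w$genome, sim$reads))
  list(sim = sim, records = recs)
})
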