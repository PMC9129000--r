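# Synthetic paired-end library generator and its ground truth.

test_that("an empty spec list gives a master-only mixture with flat truth", {
  w <- fxMtGenome()
  mix <- buildMixture(w$genome, list(), w$repeats)
  expect_length(mix$molecules, 1L)
  expect_equal(perBinCopyNumber(mix$truth), rep(1, 20))
  expect_equal(nrow(plantedJunctions(mix$truth)), 0L)
})

test_that("a weight-7 loop-out raises interior bins to copy number 8", {
  w <- fxMtGenome()
  pair <- w$repeats[1, ]                       # ~127 bp at 3001 / 9001
  mix <- buildMixture(w$genome, list(
    subgenomeSpec("loopout_circle", weight = 7, repeatId = pair$id)),
    w$repeats)
  cn <- perBinCopyNumber(mix$truth)
  # bins wholly inside the loop-out segment (between the copies)
  inside <- (positionToBin(pair$copy1_end) + 1):(positionToBin(pair$copy2_start) - 1)
  outside <- setdiff(seq_along(cn), positionToBin(pair$copy1_start):positionToBin(pair$copy2_end))
  expect_equal(cn[inside], rep(8, length(inside)))
  expect_equal(cn[outside], rep(1, length(outside)))
  # the carried crossover junction is recorded
  pj <- plantedJunctions(mix$truth)
  expect_equal(nrow(pj), 1L)
  expect_identical(pj$kind, "crossover_2/1")
})

test_that("a chimera plants exactly its breakpoint pair and spans its bins", {
  w <- fxMtGenome()
  mix <- buildMixture(w$genome, list(
    subgenomeSpec("chimera", weight = 2, breakpoints = c(12500, 18500))),
    w$repeats)
  pj <- plantedJunctions(mix$truth)
  expect_equal(nrow(pj), 1L)
  expect_equal(pj$position_a, 12500)
  expect_equal(pj$position_b, 18500)
  expect_identical(pj$expected_support_class, "detectable")
  # chimeric circle runs 18500 -> 12500 (wrapping): those bins gain weight 2
  cn <- perBinCopyNumber(mix$truth)
  expect_equal(cn[positionToBin(19500)], 3)
  expect_equal(cn[positionToBin(1500)], 3)
  expect_equal(cn[positionToBin(15000)], 1)
  # enumerate the chimeric molecule: its length matches the spanned arc
  chim <- mix$molecules[[2]]$genome
  expect_equal(genomeLength(chim), (12500 - 18500) %% 20000 + 1)
})

test_that("unknown repeat ids and out-of-range breakpoints are rejected", {
  w <- fxMtGenome()
  expect_error(buildMixture(w$genome, list(
    subgenomeSpec("loopout_circle", 1, repeatId = "nope")), w$repeats),
    "unknown repeatId")
  expect_error(buildMixture(w$genome, list(
    subgenomeSpec("chimera", 1, breakpoints = c(5, 99999))), w$repeats),
    "breakpoints outside")
  expect_error(subgenomeSpec("loopout_circle", -1, repeatId = "R01"),
    "weight")
  expect_error(subgenomeSpec("chimera", 1), "breakpoints")
})

test_that("the same seed reproduces byte-identical FASTQ files", {
  w <- fxMtGenome()
  mix <- buildMixture(w$genome, list(), w$repeats)
  p <- libraryParams(depth = 5, seed = 77)
  d <- withr::local_tempdir()
  f1 <- writeFastqPair(simulateReads(mix, p), file.path(d, "a"))
  f2 <- writeFastqPair(simulateReads(mix, p), file.path(d, "b"))
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  # and a different seed does not
  f3 <- writeFastqPair(simulateReads(mix, libraryParams(depth = 5, seed = 78)),
                       file.path(d, "c"))
  expect_false(identical(readLines(f1[1]), readLines(f3[1])))
})

test_that("fragment count follows the coverage identity", {
  w <- fxMtGenome()
  pair <- w$repeats[1, ]
  mix <- buildMixture(w$genome, list(
    subgenomeSpec("loopout_circle", weight = 3, repeatId = pair$id)),
    w$repeats)
  p <- libraryParams(depth = 10, seed = 3)
  sim <- simulateReads(mix, p)
  twl <- sum(vapply(mix$molecules,
                    function(m) m$weight * genomeLength(m$genome), 0))
  # documented rule: fragments (read pairs) = round(depth * TWL / (2 * RL)),
  # which makes expected master fold coverage equal `depth`
  expect_equal(nrow(sim$reads), round(10 * twl / (2 * 150)))
})

test_that("error-free master-only depth is Poisson-consistent in every bin", {
  w <- fxMtGenome()
  sim <- fxMtMasterAligned()$sim
  r <- sim$reads
  # per-bin count of read-start events (2 per fragment), against Poisson
  starts1 <- r$frag_start
  starts2 <- circPos(r$frag_start + r$frag_len - 150, genomeLength(w$genome))
  bins <- positionToBin(c(starts1, starts2))
  counts <- tabulate(bins, nbins = 20)
  lambda <- length(bins) / 20
  expect_true(all(abs(counts - lambda) < 4 * sqrt(lambda)))
})

test_that("reads carry truth headers and FASTQ round-trips through the reader", {
  w <- fxMtGenome()
  mix <- buildMixture(w$genome, list(), w$repeats)
  sim <- simulateReads(mix, libraryParams(depth = 2, seed = 9))
  d <- withr::local_tempdir()
  paths <- writeFastqPair(sim, file.path(d, "lib"))
  r1 <- readFastq(paths[1])
  expect_equal(nrow(r1), nrow(sim$reads))
  expect_identical(r1$seq, sim$reads$seq1)
  expect_identical(r1$mate, rep(1L, nrow(r1)))
  expect_match(r1$comment[1], "^mol:master start:[0-9]+ len:[0-9]+$")
  r2 <- readFastq(paths[2])
  expect_identical(r2$seq, sim$reads$seq2)
  expect_identical(r1$id, r2$id)
})

test_that("substitution errors appear at roughly the requested rate", {
  w <- fxMtGenome()
  mix <- buildMixture(w$genome, list(), w$repeats)
  clean <- simulateReads(mix, libraryParams(depth = 10, errorRate = 0,
                                            seed = 21))
  noisy <- simulateReads(mix, libraryParams(depth = 10, errorRate = 0.01,
                                            seed = 21))
  # same seed: identical fragments, so differences are exactly the errors
  expect_identical(clean$reads$frag_start, noisy$reads$frag_start)
  nd <- sum(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                   clean$reads$seq1, noisy$reads$seq1))
  tot <- sum(nchar(clean$reads$seq1))
  expect_gt(nd / tot, 0.005)
  expect_lt(nd / tot, 0.02)
})

test_that("raising a subgenome weight raises depth only in its unique bins", {
  w <- fxMtGenome()
  pair <- w$repeats[1, ]
  depthIn <- function(wt) {
    specs <- if (wt == 0) list() else list(
      subgenomeSpec("loopout_circle", weight = wt, repeatId = pair$id))
    mix <- buildMixture(w$genome, specs, w$repeats)
    sim <- simulateReads(mix, libraryParams(depth = 8, seed = 31))
    recs <- withSeed(41, pairMates(w$genome, sim$reads))
    prof <- binCoverage(recs, w$genome, 1e6)
    bins <- profileBins(prof)$mean_depth
    inside <- (positionToBin(pair$copy1_end) + 1):(positionToBin(pair$copy2_start) - 1)
    c(inside = mean(bins[inside]), outside = mean(bins[-(1:10)]))
  }
  d0 <- depthIn(0); d1 <- depthIn(1); d7 <- depthIn(7)
  expect_lt(d0[["inside"]], d1[["inside"]])
  expect_lt(d1[["inside"]], d7[["inside"]])
  # bins unique to the master stay at the master's coverage
  expect_lt(abs(d7[["outside"]] - d0[["outside"]]), 3)
})
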