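# Soft-clip junction detection: CIGAR filter, clip remapping, event
# calling, isomerization filtering and per-copy abundance.

mkRec <- function(cigar, seq = strrep("A", cigarQueryLength(cigar)),
                  pos = 101L, mapped = TRUE, unique = TRUE) {
  list(read_id = "r", mate = 1L, ref_name = "mt", pos = pos,
       strand = "+", mapq = if (unique) 60L else 0L, cigar = cigar,
       seq = seq, mapped = mapped, is_unique = unique)
}

test_that("the clip filter applies the 20-nt threshold and the indel veto", {
  res <- passesClipFilter(mkRec("100M50S"))
  expect_true(res$accept)
  expect_identical(res$clips$side, "right")
  expect_equal(res$clips$clip_len, 50L)
  expect_false(passesClipFilter(mkRec("140M10S"))$accept)
  expect_false(passesClipFilter(mkRec("60M5I60M25S"))$accept)
  expect_false(passesClipFilter(mkRec("60M5D60M25S"))$accept)
  expect_false(passesClipFilter(mkRec("5H120M25S"))$accept)
  expect_false(passesClipFilter(mkRec("150M"))$accept)
  expect_false(passesClipFilter(mkRec("*", seq = "ACGT",
                                      mapped = FALSE))$accept)
})

test_that("clip descriptors carry side, sequence and anchor breakpoint", {
  seq <- paste0(strrep("C", 30), strrep("G", 100), strrep("T", 25))
  res <- passesClipFilter(mkRec("30S100M25S", seq = seq, pos = 501L))
  expect_true(res$accept)
  expect_equal(nrow(res$clips), 2L)
  left <- res$clips[res$clips$side == "left", ]
  right <- res$clips[res$clips$side == "right", ]
  expect_identical(left$clip_seq, strrep("C", 30))
  expect_equal(left$anchor_breakpoint, 501L)
  expect_identical(right$clip_seq, strrep("T", 25))
  expect_equal(right$anchor_breakpoint, 600L)   # 501 + 100 - 1
})

test_that("clip remapping is strict: end-to-end, unique, or dropped with counts", {
  w <- fxMtGenome()
  pair <- w$repeats[1, ]
  set.seed(12)
  clips <- data.frame(
    side = "right",
    clip_len = 40L,
    clip_seq = c(subseqCircular(w$genome, 12001, 40),
                 paste(sample(c("A", "C"), 40, TRUE), collapse = ""),
                 subseqCircular(w$genome, pair$copy1_start, 40)),
    anchor_breakpoint = c(500L, 600L, 700L),
    read_id = c("ok", "junk", "rep"), mate = 1L,
    anchor_strand = "+", stringsAsFactors = FALSE)
  mp <- mapClips(clips, w$genome)
  expect_equal(unname(mp$stats["placed"]), 1L)
  expect_equal(unname(mp$stats["unmapped"]), 1L)
  expect_equal(unname(mp$stats["non_unique"]), 1L)
  expect_identical(mp$placed$read_id, "ok")
  expect_equal(mp$placed$clip_pos, 12001L)
  expect_identical(mp$placed$orientation, "same_strand")
})

test_that("junction events group reciprocal read orientations into one call", {
  w <- fxMtGenome()
  reps <- w$repeats
  mix <- buildMixture(w$genome, list(
    subgenomeSpec("chimera", weight = 1, breakpoints = c(10500, 16500))),
    reps)
  sim <- simulateReads(mix, libraryParams(depth = 40, errorRate = 0,
                                          seed = 13))
  recs <- withSeed(14, pairMates(w$genome, sim$reads))
  jn <- withSeed(15, detectJunctions(recs, w$genome))
  ev <- jn$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$anchor_bin, 11L)
  expect_equal(ev$clip_bin, 17L)
  expect_identical(ev$orientation, "same_strand")
  # support counts every distinct junction-spanning read once
  expect_gte(ev$support, 5L)
  expect_false(ev$is_isomerization)
})

test_that("a master-only error-free library yields zero junction events", {
  w <- fxMtGenome()
  fx <- fxMtMasterAligned()
  jn <- withSeed(16, detectJunctions(fx$records, w$genome))
  expect_equal(nrow(jn$events), 0L)
})

test_that("crossover junctions are detectable iff the repeat fits the read envelope", {
  # envelope: repeat length <= read 150 - minAnchor 30 - minClip 20 = 100
  w <- fxMtGenome()
  reps <- w$repeats           # repeat 1 ~127 bp (outside), repeat 2 = 60 bp
  short <- reps[reps$length < 100, ][1, ]
  long <- reps[reps$length > 100, ][1, ]
  mix <- buildMixture(w$genome, list(
    subgenomeSpec("loopout_circle", weight = 2, repeatId = short$id),
    subgenomeSpec("loopout_circle", weight = 2, repeatId = long$id)),
    reps)
  pj <- plantedJunctions(mix$truth)
  expect_setequal(pj$expected_support_class,
                  c("detectable", "undetectable_repeat_too_long"))
  sim <- simulateReads(mix, libraryParams(depth = 50, errorRate = 0,
                                          seed = 17))
  recs <- withSeed(18, pairMates(w$genome, sim$reads))
  ev <- withSeed(19, detectJunctions(recs, w$genome))$events
  nearBin <- function(bins, pos) any(abs(bins - positionToBin(pos)) <= 1)
  shortJ <- pj[pj$molecule == paste0("mt_", short$id, "_loopout"), ]
  longJ <- pj[pj$molecule == paste0("mt_", long$id, "_loopout"), ]
  hits <- function(j) any(vapply(seq_len(nrow(ev)), function(i)
    nearBin(c(ev$anchor_bin[i], ev$clip_bin[i]), j$position_a) &&
    nearBin(c(ev$anchor_bin[i], ev$clip_bin[i]), j$position_b), TRUE))
  expect_true(hits(shortJ))
  expect_false(hits(longJ))
})

test_that("isomerization flagging matches corresponding IR boundaries only", {
  L <- 30000
  reps <- rbind(
    repeatPair("IRL", 6001, 16001, 700, "inverted", L),
    repeatPair("SM", 2001, 25001, 80, "direct", L))
  ev <- data.frame(
    anchor_bin = c(positionToBin(6700), positionToBin(6001),
                   positionToBin(6700), positionToBin(3000),
                   positionToBin(6700)),
    clip_bin = c(positionToBin(16001), positionToBin(16700),
                 positionToBin(16001), positionToBin(9000),
                 positionToBin(25000)),
    orientation = c("opposite_strand", "opposite_strand", "same_strand",
                    "opposite_strand", "opposite_strand"),
    support = 5L, is_isomerization = FALSE, stringsAsFactors = FALSE)
  out <- filterIsomerization(ev, reps)
  expect_identical(out$is_isomerization, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # empty repeat list (mtDNA mode): vacuous filter
  out2 <- filterIsomerization(ev, NULL)
  expect_false(any(out2$is_isomerization))
  # only large inverted pairs are considered
  out3 <- filterIsomerization(ev, reps[reps$id == "SM", ])
  expect_false(any(out3$is_isomerization))
})

test_that("events per genome copy is support over mean depth", {
  g <- randomGenome(5000, seed = 20)
  recs <- data.frame(read_id = sprintf("r%d", 1:400), mate = 1L,
                     ref_name = "toy",
                     pos = rep(seq(1, 4851, by = 50), length.out = 400),
                     strand = "+", mapq = 60L, cigar = "125M",
                     seq = strrep("A", 125), mapped = TRUE,
                     is_unique = TRUE, stringsAsFactors = FALSE)
  prof <- binCoverage(recs, g, 1e6)
  ev <- data.frame(anchor_bin = 1L, clip_bin = 3L,
                   orientation = "same_strand", support = 5L,
                   is_isomerization = FALSE)
  expect_equal(eventsPerGenomeCopy(ev, prof),
               5 / meanGenomeDepth(prof))
  expect_equal(eventsPerGenomeCopy(ev[0, ], prof), 0)
  ev2 <- rbind(ev, data.frame(anchor_bin = 2L, clip_bin = 4L,
                              orientation = "opposite_strand",
                              support = 7L, is_isomerization = TRUE))
  expect_equal(eventsPerGenomeCopy(ev2, prof), 5 / meanGenomeDepth(prof))
  empty <- binCoverage(recs[0, ], g, 10)
  expect_error(eventsPerGenomeCopy(ev, empty), "zero mean depth")
})

test_that("the junction rate grows with the weight of a planted chimera", {
  w <- fxMtGenome()
  rate <- function(wt) {
    # short (6 kb) chimeric circle so the molecule's own contribution to
    # mean depth does not swamp the junction-support signal
    mix <- buildMixture(w$genome, list(
      subgenomeSpec("chimera", weight = wt, breakpoints = c(16500, 10500))),
      w$repeats)
    sim <- simulateReads(mix, libraryParams(depth = 60, errorRate = 0,
                                            seed = 22))
    recs <- withSeed(23, pairMates(w$genome, sim$reads))
    jn <- withSeed(24, detectJunctions(recs, w$genome))
    eventsPerGenomeCopy(jn$events,
                        binCoverage(recs, w$genome, 1e6))
  }
  r <- c(rate(0.1), rate(0.5), rate(1))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})
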