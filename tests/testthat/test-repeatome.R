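# Repeat discovery and recombination-product prediction on circular genomes.

test_that("a planted direct duplication is found and matches the brute-force scan", {
  g <- randomGenome(10000, repeats = data.frame(
    start1 = 2001, start2 = 6001, len = 127, orientation = "direct"),
    seed = 42)
  found <- findExactRepeats(g, minLen = 50)
  expect_identical(canonRepeats(found), oracleRepeats(g, 50))
  expect_equal(nrow(found), 1L)
  expect_identical(found$orientation, "direct")
  # chance flank matches may extend the planted 127 bp by a few bases;
  # the maximal repeat must contain the planted interval
  expect_lte(found$copy1_start, 2001L)
  expect_gte(found$copy1_end, 2001L + 127L - 1L)
  expect_gte(found$length, 127L)
  expect_identical(found$size_class, "intermediate")
})

test_that("a repeat-free random genome yields no repeat, agreeing with the oracle", {
  g <- randomGenome(5000, seed = 43)
  found <- findExactRepeats(g, minLen = 50)
  expect_equal(nrow(found), 0L)
  expect_equal(nrow(oracleRepeats(g, 50)), 0L)
})

test_that("a planted inverted repeat is found and matches the oracle", {
  g <- randomGenome(10000, repeats = data.frame(
    start1 = 1001, start2 = 7001, len = 200, orientation = "inverted"),
    seed = 44)
  found <- findExactRepeats(g, minLen = 50)
  expect_identical(canonRepeats(found), oracleRepeats(g, 50))
  expect_true(any(found$orientation == "inverted" & found$length >= 200))
})

test_that("repeats spanning the circular origin are found once with modular coordinates", {
  g <- randomGenome(6000, repeats = data.frame(
    start1 = 5950, start2 = 3000, len = 120, orientation = "direct"),
    seed = 45)
  found <- findExactRepeats(g, minLen = 50)
  expect_identical(canonRepeats(found), oracleRepeats(g, 50))
  expect_equal(nrow(found), 1L)
  # copy2 wraps: end coordinate re-enters the circle
  expect_lt(found$copy2_end, found$copy2_start)
})

test_that("guard rails: tiny minLen and degenerate genomes error", {
  g <- randomGenome(1000, seed = 1)
  expect_error(findExactRepeats(g, minLen = 10), "microhomology")
  expect_error(circularGenome("x", ""), "non-empty")
})

test_that("finder agrees exactly with the rotation oracle on random planted worlds", {
  set.seed(2024)
  for (i in 1:12) {
    L <- sample(800:3000, 1)
    nrep <- sample(0:3, 1)
    reps <- NULL
    if (nrep > 0) {
      len <- sample(50:220, nrep, replace = TRUE)
      reps <- data.frame(start1 = sample(L, nrep), start2 = sample(L, nrep),
                         len = len,
                         orientation = sample(c("direct", "inverted"),
                                              nrep, replace = TRUE))
      # keep planted copies disjoint so the planted world is well-defined
      ok <- TRUE
      for (a in seq_len(nrep)) for (b in seq_len(nrep)) {
        if (a == b) next
        for (pa in c(reps$start1[a], reps$start2[a]))
          for (pb in c(reps$start1[b], reps$start2[b]))
            if (min((pa - pb) %% L, (pb - pa) %% L) < 250) ok <- FALSE
      }
      if (min((reps$start1 - reps$start2) %% L,
              (reps$start2 - reps$start1) %% L) < 250) ok <- FALSE
      if (!ok) reps <- NULL
    }
    g <- randomGenome(L, repeats = reps, seed = 5000 + i)
    expect_identical(canonRepeats(findExactRepeats(g, 50)),
                     oracleRepeats(g, 50),
                     info = paste("world", i, "L", L))
  }
})

test_that("loop-out product circles partition the parent genome", {
  g <- randomGenome(10000, seed = 50)
  # exact toy coordinates: copies at 1001..1100 and 5001..5100
  gs <- strsplit(as.character(genomeSeq(g)), "")[[1]]
  gs[5001:5100] <- gs[1001:1100]
  g <- circularGenome("toy", paste(gs, collapse = ""))
  pair <- repeatPair("P", 1001, 5001, 100, "direct", 10000)
  pred <- predictProducts(g, pair)
  expect_equal(genomeLength(pred$loopout), 4000L)
  expect_equal(genomeLength(pred$remainder), 6000L)
  expect_equal(genomeLength(pred$loopout) + genomeLength(pred$remainder),
               10000L)
  expect_identical(unname(pred$carried_junction["loopout"]), "2/1")
  expect_identical(unname(pred$carried_junction["remainder"]), "1/2")
  # each product contains exactly one copy of the repeat sequence
  rep <- subseqCircular(g, 1001, 100)
  countHits <- function(circle) {
    # doubled string, counting only matches starting in the first copy
    s <- paste0(as.character(genomeSeq(circle)),
                as.character(genomeSeq(circle)))
    starts <- gregexpr(rep, s, fixed = TRUE)[[1]]
    sum(starts >= 1 & starts <= genomeLength(circle))
  }
  expect_equal(countHits(pred$loopout), 1L)
  expect_equal(countHits(pred$remainder), 1L)
})

test_that("crossover junction sequences equal direct slicing of the parent", {
  g <- randomGenome(10000, seed = 51)
  gs <- strsplit(as.character(genomeSeq(g)), "")[[1]]
  gs[5001:5100] <- gs[1001:1100]
  g <- circularGenome("toy", paste(gs, collapse = ""))
  pair <- repeatPair("P", 1001, 5001, 100, "direct", 10000)
  js <- junctionSequence(g, pair, "1/2", flank = 200)
  expected <- paste0(subseqCircular(g, 801, 200),     # copy1 upstream
                     subseqCircular(g, 1001, 100),    # repeat
                     subseqCircular(g, 5101, 200))    # copy2 downstream
  expect_identical(js$junction_sequence, expected)
  expect_identical(js$product_role, "crossover")
  expect_identical(junctionSequence(g, pair, "1/1", 200)$product_role,
                   "parental")
  # the 1/2 product appears verbatim in the remainder circle
  pred <- predictProducts(g, pair)
  doubled <- paste0(as.character(genomeSeq(pred$remainder)),
                    as.character(genomeSeq(pred$remainder)))
  expect_true(grepl(js$junction_sequence, doubled, fixed = TRUE))
})

test_that("adjacent (tandem) copies loop out a circle of exactly the repeat length", {
  g <- randomGenome(8000, seed = 52)
  gs <- strsplit(as.character(genomeSeq(g)), "")[[1]]
  gs[2101:2200] <- gs[2001:2100]
  g <- circularGenome("toy", paste(gs, collapse = ""))
  pair <- repeatPair("T", 2001, 2101, 100, "direct", 8000)
  pred <- predictProducts(g, pair)
  expect_equal(genomeLength(pred$loopout), 100L)
  expect_equal(genomeLength(pred$remainder), 7900L)
})

test_that("predictProducts and invertSegment reject the wrong orientation", {
  g <- randomGenome(5000, seed = 53)
  dpair <- repeatPair("D", 1001, 3001, 100, "direct", 5000)
  ipair <- repeatPair("I", 1001, 3001, 100, "inverted", 5000)
  expect_error(predictProducts(g, ipair), "invertSegment")
  expect_error(invertSegment(g, dpair), "predictProducts")
})

test_that("invertSegment is a length-preserving involution that keeps the pair inverted", {
  g <- randomGenome(10000, repeats = data.frame(
    start1 = 2001, start2 = 7001, len = 150, orientation = "inverted"),
    seed = 54)
  pair <- findExactRepeats(g, 50)
  pair <- pair[pair$orientation == "inverted", ][1, ]
  iso <- invertSegment(g, pair)
  expect_equal(genomeLength(iso), genomeLength(g))
  expect_false(identical(as.character(genomeSeq(iso)),
                         as.character(genomeSeq(g))))
  # the isomer still carries the inverted pair at the same coordinates
  isoReps <- findExactRepeats(iso, 50)
  expect_true(any(isoReps$orientation == "inverted" &
                  isoReps$copy1_start == pair$copy1_start))
  back <- invertSegment(iso, pair)
  expect_identical(as.character(genomeSeq(back)),
                   as.character(genomeSeq(g)))
})

test_that("a zero-length intervening segment makes invertSegment the identity", {
  g <- randomGenome(4000, seed = 55)
  gs <- strsplit(as.character(genomeSeq(g)), "")[[1]]
  gs[1101:1200] <- rev(chartr("ACGT", "TGCA", gs[1001:1100]))
  g <- circularGenome("toy", paste(gs, collapse = ""))
  pair <- repeatPair("I0", 1001, 1101, 100, "inverted", 4000)
  expect_identical(as.character(genomeSeq(invertSegment(g, pair))),
                   as.character(genomeSeq(g)))
})

test_that("repeat tables round-trip through TSV", {
  g <- randomGenome(10000, repeats = data.frame(
    start1 = 2001, start2 = 6001, len = 127, orientation = "direct"),
    seed = 42)
  tab <- findExactRepeats(g, 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRepeatTable(tab, path)
  expect_identical(readRepeatTable(path), tab)
})
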