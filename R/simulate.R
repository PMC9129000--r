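## Synthetic read-library generator.
##
## Emulates a paired-end Illumina library (2 x 150 bp by default) drawn from
## a mixture of the master circular genome plus recombination-derived
## molecules at specified relative copy numbers: loop-out subgenomic circles
## and their remainder circles (direct repeats), inverted-segment isomers
## (inverted repeats), and arbitrary chimeric fusions. Every library comes
## with a TruthSet: the expected per-kb copy number and the catalogue of
## planted junctions.

#' Describe one subgenomic molecule of a mixture
#'
#' @param kind one of "loopout_circle", "remainder_circle", "inversion"
#'   (repeat-mediated kinds, requiring `repeatId`) or "chimera" (requiring
#'   `breakpoints`).
#' @param weight non-negative relative copy number per master-genome copy.
#' @param repeatId label of the mediating repeat pair (matched against the
#'   `id` column of the repeat table passed to [buildMixture()]).
#' @param breakpoints for a chimera, integer vector `c(a, b)`: the chimeric
#'   circle runs forward from position `b` around to position `a`, creating
#'   the novel adjacency a -> b.
#' @return a `SubgenomeSpec` list.
#' @export
subgenomeSpec <- function(kind = c("loopout_circle", "remainder_circle",
                                   "inversion", "chimera"),
                          weight, repeatId = NULL, breakpoints = NULL) {
  kind <- match.arg(kind)
  if (weight < 0) stop("weight must be >= 0")
  if (kind == "chimera") {
    if (is.null(breakpoints) || length(breakpoints) != 2L)
      stop("chimera requires two breakpoints")
  } else if (is.null(repeatId)) {
    stop("repeat-mediated kind '", kind, "' requires a repeatId")
  }
  structure(list(kind = kind, weight = weight, repeatId = repeatId,
                 breakpoints = as.integer(breakpoints)),
            class = "SubgenomeSpec")
}

#' Library simulation parameters
#'
#' Defaults emulate a MiSeq 2 x 150 bp paired-end run with a conventional
#' short-insert library and a low substitution error rate.
#'
#' @param readLength read length in bp (>= 50).
#' @param fragmentMean,fragmentSd fragment (insert) length distribution;
#'   lengths are drawn normal and redrawn until they fall in
#'   `[readLength, 3 * fragmentMean]`.
#' @param depth expected fold coverage of the master genome.
#' @param errorRate per-base substitution probability, in `[0, 0.05)`.
#' @param seed integer RNG seed; a fixed seed gives byte-identical FASTQ.
#' @return a `LibraryParams` list.
#' @export
libraryParams <- function(readLength = 150L, fragmentMean = 400L,
                          fragmentSd = 50L, depth = 30, errorRate = 0.002,
                          seed = 1L) {
  stopifnot(readLength >= 50L, fragmentMean >= readLength,
            errorRate >= 0, errorRate < 0.05)
  list(readLength = as.integer(readLength),
       fragmentMean = as.integer(fragmentMean),
       fragmentSd = as.numeric(fragmentSd),
       depth = depth, errorRate = errorRate, seed = as.integer(seed))
}

## intervals (start, len, share) of master coordinates covered by a molecule
.specMolecule <- function(genome, spec, repeats) {
  L <- genomeLength(genome)
  if (spec$kind == "chimera") {
    bp <- circPos(spec$breakpoints, L)
    a <- bp[1]; b <- bp[2]
    len <- (a - b) %% L + 1L
    mol <- circularGenome(paste0(genomeName(genome), "_chimera_",
                                 a, "_", b),
                          subseqCircular(genome, b, len))
    return(list(molecule = mol,
                intervals = data.frame(start = b, len = len,
                                       weight_share = 1),
                junctions = data.frame(position_a = a, position_b = b,
                                       kind = "chimera",
                                       orientation = "same_strand",
                                       stringsAsFactors = FALSE)))
  }
  row <- repeats[repeats$id == spec$repeatId, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown repeatId '", spec$repeatId, "'")
  p <- as.list(row[1L, ])
  if (spec$kind == "inversion") {
    if (!identical(p$orientation, "inverted"))
      stop("inversion requires an inverted repeat pair")
    mol <- invertSegment(genome, row)
    junc <- data.frame(
      position_a = c(p$copy1_end, p$copy1_start),
      position_b = c(p$copy2_start, p$copy2_end),
      kind = "isomerization", orientation = "opposite_strand",
      stringsAsFactors = FALSE)
    return(list(molecule = mol,
                intervals = data.frame(start = 1L, len = L,
                                       weight_share = 1),
                junctions = junc))
  }
  if (!identical(p$orientation, "direct"))
    stop(spec$kind, " requires a direct repeat pair")
  pred <- predictProducts(genome, row)
  which <- if (spec$kind == "loopout_circle") "loopout" else "remainder"
  ints <- pred$master_intervals
  ints <- ints[ints$circle == which & ints$len > 0, c("start", "len",
                                                      "weight_share")]
  jun <- if (which == "loopout") {
    ## 2/1 junction: end of c flank joined through the repeat to start of b
    data.frame(position_a = circPos(p$copy2_start - 1L, L),
               position_b = circPos(p$copy1_end + 1L, L),
               kind = "crossover_2/1", orientation = "same_strand",
               stringsAsFactors = FALSE)
  } else {
    data.frame(position_a = circPos(p$copy1_start - 1L, L),
               position_b = circPos(p$copy2_end + 1L, L),
               kind = "crossover_1/2", orientation = "same_strand",
               stringsAsFactors = FALSE)
  }
  list(molecule = pred[[which]], intervals = ints, junctions = jun)
}

## expected copy number per 1-kb bin from weighted master intervals
.truthBins <- function(L, intervals, weights) {
  nb <- ceiling(L / 1000)
  cn <- rep(1, nb)
  if (length(weights)) {
    perbase <- rep(0, L)
    for (i in seq_along(weights)) {
      ints <- intervals[[i]]
      for (j in seq_len(nrow(ints))) {
        if (ints$len[j] < 1) next
        idx <- circPos(seq(ints$start[j], length.out = ints$len[j]), L)
        perbase[idx] <- perbase[idx] + weights[i] * ints$weight_share[j]
      }
    }
    bin <- positionToBin(seq_len(L))
    cn <- cn + as.numeric(tapply(perbase, bin, mean))
  }
  cn
}

#' Materialize a genome mixture with ground truth
#'
#' Builds the weighted set of molecules defined by a master genome and a
#' list of subgenome specifications, together with a [TruthSet-class]:
#' expected relative copy number per 1-kb master bin (the master contributes
#' 1.0 everywhere; each subgenome adds its weight over the master intervals
#' it covers, with repeat copies of a loop-out product split half/half
#' between the two master copies, mirroring ambiguous read placement) and
#' the list of planted junctions.
#'
#' @param genome master [CircularGenome-class].
#' @param specs list of [subgenomeSpec()] objects (may be empty).
#' @param repeats repeat table ([findExactRepeats()] format) resolving any
#'   `repeatId` referenced by the specs.
#' @param readLength read length used to classify junction detectability:
#'   a crossover across a repeat of length r is detectable by soft-clip
#'   analysis only when a single read can span the repeat plus a minimum
#'   anchor and a minimum clip (r <= readLength - 30 - 20).
#' @param label sample label stored in the TruthSet.
#' @return list with `molecules` (list of `list(genome, weight, label)`;
#'   first element is the master at weight 1) and `truth`
#'   ([TruthSet-class]).
#' @export
buildMixture <- function(genome, specs = list(), repeats = NULL,
                         readLength = 150L, label = "sample") {
  stopifnot(is(genome, "CircularGenome"))
  L <- genomeLength(genome)
  molecules <- list(list(genome = genome, weight = 1, label = "master"))
  intervals <- list()
  weights <- numeric()
  junctions <- list()
  for (spec in specs) {
    if (!inherits(spec, "SubgenomeSpec")) stop("specs must be subgenomeSpec()")
    if (spec$kind == "chimera" &&
        any(spec$breakpoints < 1L | spec$breakpoints > L))
      stop("chimera breakpoints outside genome")
    sm <- .specMolecule(genome, spec, repeats)
    molecules[[length(molecules) + 1L]] <-
      list(genome = sm$molecule, weight = spec$weight,
           label = genomeName(sm$molecule))
    intervals[[length(intervals) + 1L]] <- sm$intervals
    weights <- c(weights, spec$weight)
    jn <- sm$junctions
    jn$molecule <- genomeName(sm$molecule)
    envelope <- readLength - 30L - 20L
    jn$expected_support_class <- if (spec$weight == 0) "absent" else
      switch(spec$kind,
        chimera = "detectable",
        inversion = "undetectable_isomer_seamless",
        if (repeats$length[repeats$id == spec$repeatId] <= envelope)
          "detectable" else "undetectable_repeat_too_long")
    junctions[[length(junctions) + 1L]] <- jn
  }
  pj <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame(position_a = integer(), position_b = integer(),
               kind = character(), orientation = character(),
               molecule = character(), expected_support_class = character(),
               stringsAsFactors = FALSE)
  truth <- new("TruthSet", sampleLabel = label,
               perBinCopyNumber = .truthBins(L, intervals, weights),
               plantedJunctions = pj)
  list(molecules = molecules, truth = truth)
}

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet '", object@sampleLabel, "': ",
      length(object@perBinCopyNumber), " bins, ",
      nrow(object@plantedJunctions), " planted junction(s)\n", sep = "")
})

#' @rdname truthAccessors
#' @export
setGeneric("perBinCopyNumber", function(x) standardGeneric("perBinCopyNumber"))

#' TruthSet accessors
#'
#' @param x a [TruthSet-class].
#' @name truthAccessors
#' @export
setGeneric("plantedJunctions", function(x) standardGeneric("plantedJunctions"))

#' @rdname truthAccessors
setMethod("perBinCopyNumber", "TruthSet", function(x) x@perBinCopyNumber)

#' @rdname truthAccessors
setMethod("plantedJunctions", "TruthSet", function(x) x@plantedJunctions)

#' Simulate a paired-end read library from a genome mixture
#'
#' Draws fragments from the mixture with probability proportional to
#' weight x molecule length; fragment starts are uniform on each circle and
#' fragment lengths normal(fragmentMean, fragmentSd), redrawn until inside
#' `[readLength, 3 * fragmentMean]`. Each fragment yields a forward read
#' from its 5' end and a reverse-complemented read from its 3' end, with
#' per-base substitution errors at `errorRate`. The number of fragments is
#' `round(depth * total_weighted_length / (2 * readLength))`, which makes
#' the expected fold coverage of the master genome equal `depth`. A fixed
#' seed gives byte-identical output.
#'
#' Read names are `frag%07d` with a truth comment
#' `mol:<label> start:<pos> len:<fragment length>` carried in the FASTQ
#' header after the first space.
#'
#' @param mixture result of [buildMixture()] (or a bare list of
#'   `list(genome, weight, label)` molecules).
#' @param params [libraryParams()].
#' @return list with `reads` (data.frame: id, seq1, seq2, mol, frag_start,
#'   frag_len), `truth` (the mixture's [TruthSet-class], if present) and
#'   `params`.
#' @export
simulateReads <- function(mixture, params = libraryParams()) {
  molecules <- if (!is.null(mixture$molecules)) mixture$molecules else mixture
  truth <- mixture$truth
  w <- vapply(molecules, function(m) m$weight, 0)
  len <- vapply(molecules, function(m) genomeLength(m$genome), 0L)
  wl <- w * len
  if (sum(wl) <= 0) stop("mixture has zero total weight")
  if (params$depth <= 0) stop("depth must be > 0")
  nfrag <- round(params$depth * sum(wl) / (2 * params$readLength))
  if (nfrag < 1) stop("parameters give zero fragments")

  withSeed(params$seed, {
    molIdx <- sample.int(length(molecules), nfrag, replace = TRUE,
                         prob = wl / sum(wl))
    molIdx <- sort(molIdx)                     # deterministic grouping
    starts <- integer(nfrag)
    for (i in unique(molIdx)) {
      sel <- molIdx == i
      starts[sel] <- sample.int(len[i], sum(sel), replace = TRUE)
    }
    flen <- integer(nfrag)
    todo <- rep(TRUE, nfrag)
    while (any(todo)) {
      draw <- round(stats::rnorm(sum(todo), params$fragmentMean,
                                 params$fragmentSd))
      ok <- draw >= params$readLength & draw <= 3 * params$fragmentMean
      flen[which(todo)[ok]] <- as.integer(draw[ok])
      todo[which(todo)[ok]] <- FALSE
    }
    rl <- params$readLength
    seq1 <- character(nfrag); seq2 <- character(nfrag)
    for (i in unique(molIdx)) {
      ## vectorized extraction: tile the circle so any fragment (possibly
      ## wrapping several times around a small subgenomic circle) is a plain
      ## substring; mate 2 comes from the precomputed reverse complement
      sel <- which(molIdx == i)
      Li <- len[i]
      reps <- ceiling((max(flen[sel]) + Li) / Li)
      tiled <- strrep(as.character(genomeSeq(molecules[[i]]$genome)), reps)
      rctiled <- revComp(tiled)
      nL <- Li * reps
      s <- starts[sel]
      e <- s + flen[sel] - 1L
      seq1[sel] <- substring(tiled, s, s + rl - 1L)
      seq2[sel] <- substring(rctiled, nL - e + 1L, nL - e + rl)
    }
    if (params$errorRate > 0) {
      seq1 <- .addSubstitutions(seq1, params$errorRate)
      seq2 <- .addSubstitutions(seq2, params$errorRate)
    }
    reads <- data.frame(
      id = sprintf("frag%07d", seq_len(nfrag)),
      seq1 = seq1, seq2 = seq2,
      mol = vapply(molecules[molIdx], function(m) m$label, ""),
      frag_start = starts, frag_len = flen,
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, params = params)
  })
}

.addSubstitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(seqs)
  nmut <- stats::rbinom(length(seqs), n, rate)
  for (i in which(nmut > 0)) {
    pos <- sample.int(n[i], nmut[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write a simulated library as paired FASTQ files
#'
#' Standard 4-line records; mate names carry `/1` and `/2` suffixes and the
#' truth comment after a space. Qualities are constant 'I' (Q40): the
#' pipeline never consumes base qualities.
#'
#' @param sim result of [simulateReads()].
#' @param prefix output path prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written.
#' @return character vector of the two paths, invisibly.
#' @export
writeFastqPair <- function(sim, prefix) {
  r <- sim$reads
  comment <- sprintf("mol:%s start:%d len:%d", r$mol, r$frag_start,
                     r$frag_len)
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    seqs <- if (m == 1) r$seq1 else r$seq2
    rec <- paste0("@", r$id, "/", m, " ", comment, "\n", seqs, "\n+\n",
                  strrep("I", nchar(seqs)))
    writeLines(rec, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ file
#'
#' Minimal 4-line-record reader. Read names are the header token before the
#' first space, with a trailing `/1` or `/2` stripped into the `mate`
#' column; the remainder of the header is kept as `comment`.
#'
#' @param path FASTQ file.
#' @return data.frame: id, mate (0 when unsuffixed), seq, comment.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(id = character(), mate = integer(),
                      seq = character(), comment = character(),
                      stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ record count not a multiple of 4 in ", path)
  heads <- sub("^@", "", lines[seq(1, length(lines), by = 4L)])
  seqs <- lines[seq(2, length(lines), by = 4L)]
  name <- sub("\\s.*$", "", heads)
  comment <- ifelse(grepl("\\s", heads), sub("^\\S+\\s+", "", heads), "")
  mate <- ifelse(grepl("/[12]$", name),
                 as.integer(sub("^.*/", "", name)), 0L)
  data.frame(id = sub("/[12]$", "", name), mate = mate, seq = seqs,
             comment = comment, stringsAsFactors = FALSE)
}

#' Serialize a TruthSet to JSON
#'
#' @param truth a [TruthSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthSet <- function(truth, path) {
  jsonlite::write_json(
    list(sample_label = truth@sampleLabel,
         per_bin_copy_number = truth@perBinCopyNumber,
         planted_junctions = truth@plantedJunctions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
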