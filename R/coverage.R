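## Per-kilobase coverage stoichiometry scanning.
##
## Depth is accumulated from the reference-consuming CIGAR operations of
## mapped reads into fixed 1-kb bins, normalized to a library of 1,000,000
## reads, and two libraries are compared bin-by-bin on a log2 scale.
## Regions of changed stoichiometry whose boundaries fall near the copies
## of a repeat pair are the signature of a recombination-derived subgenome
## replicating at altered copy number.

.BIN_SIZE <- 1000L

#' Map a genome position to its 1-kb bin
#'
#' Bin b spans positions (b-1)*1000 + 1 .. b*1000, i.e. each position is
#' labeled by the kilobase boundary above it.
#'
#' @param pos 1-based position(s).
#' @return integer bin indices.
#' @examples
#' positionToBin(c(1, 1000, 1001))  # 1 1 2
#' @export
positionToBin <- function(pos) {
  if (any(pos < 1)) stop("positions must be >= 1")
  as.integer(ceiling(pos / .BIN_SIZE))
}

## reference intervals covered by each mapped record, split at the origin
.alignedRanges <- function(records, L) {
  recs <- records[records$mapped, , drop = FALSE]
  if (!nrow(recs)) return(IRanges::IRanges())
  starts <- integer(0); ends <- integer(0)
  reflen <- vapply(recs$cigar, cigarRefLength, 0L, USE.NAMES = FALSE)
  s <- recs$pos
  e <- s + reflen - 1L
  wraps <- e > L
  if (any(!wraps)) {
    starts <- c(starts, s[!wraps]); ends <- c(ends, e[!wraps])
  }
  if (any(wraps)) {
    starts <- c(starts, s[wraps], rep(1L, sum(wraps)))
    ends <- c(ends, rep(L, sum(wraps)), e[wraps] - L)
  }
  IRanges::IRanges(start = starts, end = ends)
}

#' Bin read coverage of a circular genome
#'
#' Accumulates per-base depth over the reference-consuming CIGAR operations
#' (M, D, N, =, X) of all mapped records into 1-kb bins ([positionToBin()]),
#' wrapping alignments that cross the origin. `normalized_depth` is
#' `mean_depth * 1e6 / totalReads`: depth per million library reads.
#'
#' @param records alignment record data.frame.
#' @param genome the [CircularGenome-class] aligned against.
#' @param totalReads library read count used for normalization, mapped plus
#'   unmapped (pass the mapped-only count for mapped-normalized profiles);
#'   defaults to `nrow(records)`.
#' @return a [CoverageProfile-class].
#' @export
binCoverage <- function(records, genome, totalReads = nrow(records)) {
  if (is.null(totalReads) || totalReads == 0)
    stop("totalReads must be a positive library size")
  L <- genomeLength(genome)
  nb <- ceiling(L / .BIN_SIZE)
  binStart <- (seq_len(nb) - 1L) * .BIN_SIZE + 1L
  binEnd <- pmin(seq_len(nb) * .BIN_SIZE, L)
  ir <- .alignedRanges(records, L)
  if (length(ir)) {
    cov <- IRanges::coverage(ir, width = L)
    baseCount <- IRanges::viewSums(IRanges::Views(cov, start = binStart,
                                                  end = binEnd))
  } else baseCount <- rep(0, nb)
  meanDepth <- baseCount / (binEnd - binStart + 1)
  new("CoverageProfile",
      genomeName = genomeName(genome), genomeLength = L,
      binSize = .BIN_SIZE,
      bins = data.frame(bin_index = seq_len(nb), bin_start = binStart,
                        bin_end = binEnd, base_count = as.numeric(baseCount),
                        mean_depth = meanDepth,
                        normalized_depth = meanDepth * 1e6 / totalReads),
      totalReads = as.numeric(totalReads))
}

#' @rdname profileAccessors
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' CoverageProfile accessors
#'
#' `profileBins()` returns the per-bin table, `totalReads()` the library
#' size used for normalization and `meanGenomeDepth()` the mean of the
#' per-bin mean depths (the "fold coverage of the genome").
#'
#' @param x a [CoverageProfile-class].
#' @name profileAccessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname profileAccessors
#' @export
setGeneric("meanGenomeDepth", function(x) standardGeneric("meanGenomeDepth"))

#' @rdname profileAccessors
setMethod("profileBins", "CoverageProfile", function(x) x@bins)

#' @rdname profileAccessors
setMethod("totalReads", "CoverageProfile", function(x) x@totalReads)

#' @rdname profileAccessors
setMethod("meanGenomeDepth", "CoverageProfile",
          function(x) mean(x@bins$mean_depth))

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile of '", object@genomeName, "' (",
      object@genomeLength, " bp): ", nrow(object@bins), " bins of ",
      object@binSize, " bp\n  mean depth ",
      signif(mean(object@bins$mean_depth), 4), "x, ",
      format(object@totalReads, big.mark = ","), " library reads\n",
      sep = "")
})

#' Compare two coverage profiles and flag stoichiometry changes
#'
#' Computes the per-bin log2 ratio of normalized depth, sample over
#' control, with a pseudocount equal to the normalized depth contributed by
#' a single read to one bin (readLength / binSize * 1e6 / totalReads of
#' each library), so empty bins give finite ratios. Maximal runs of bins
#' with |log2 ratio| >= `flagThreshold` become flagged regions; each region
#' is annotated with the repeat pairs that have a copy boundary within one
#' bin of a region boundary — the candidate substrates of the loop-out
#' recombination that changed the region's copy number.
#'
#' @param sample,control [CoverageProfile-class] objects on the same genome
#'   and binning.
#' @param flagThreshold |log2| flag threshold (default 1: two-fold change).
#' @param repeats optional repeat table used for the boundary annotation.
#' @param readLength read length used for the pseudocount (bp).
#' @return a [StoichiometryReport-class].
#' @export
compareProfiles <- function(sample, control, flagThreshold = 1,
                            repeats = NULL, readLength = 150L) {
  stopifnot(is(sample, "CoverageProfile"), is(control, "CoverageProfile"))
  if (sample@genomeLength != control@genomeLength ||
      sample@binSize != control@binSize ||
      nrow(sample@bins) != nrow(control@bins))
    stop("profiles use different genomes or binnings")
  epsS <- readLength / sample@binSize * 1e6 / sample@totalReads
  epsC <- readLength / control@binSize * 1e6 / control@totalReads
  lr <- log2((sample@bins$normalized_depth + epsS) /
             (control@bins$normalized_depth + epsC))
  flagged <- abs(lr) >= flagThreshold
  ratios <- data.frame(bin_index = sample@bins$bin_index,
                       bin_start = sample@bins$bin_start,
                       bin_end = sample@bins$bin_end,
                       sample_norm = sample@bins$normalized_depth,
                       control_norm = control@bins$normalized_depth,
                       log2_ratio = lr, flagged = flagged)
  regions <- .flaggedRegions(lr, flagged, repeats)
  new("StoichiometryReport", ratios = ratios, regions = regions,
      threshold = flagThreshold, epsilon = c(sample = epsS, control = epsC))
}

.flaggedRegions <- function(lr, flagged, repeats) {
  out <- data.frame(start_bin = integer(), end_bin = integer(),
                    n_bins = integer(), mean_log2 = numeric(),
                    direction = character(), repeat_ids = character(),
                    stringsAsFactors = FALSE)
  if (!any(flagged)) return(out)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  for (i in seq_along(starts)) {
    bins <- starts[i]:ends[i]
    ids <- ""
    if (!is.null(repeats) && nrow(repeats)) {
      hit <- vapply(seq_len(nrow(repeats)), function(j) {
        bb <- positionToBin(unlist(repeats[j, c("copy1_start", "copy1_end",
                                                "copy2_start", "copy2_end")]))
        any(abs(outer(bb, c(starts[i], ends[i]), "-")) <= 1L)
      }, TRUE)
      ids <- paste(repeats$id[hit], collapse = ",")
    }
    out <- rbind(out, data.frame(
      start_bin = starts[i], end_bin = ends[i], n_bins = length(bins),
      mean_log2 = mean(lr[bins]),
      direction = if (mean(lr[bins]) > 0) "amplified" else "depleted",
      repeat_ids = ids, stringsAsFactors = FALSE))
  }
  out
}

#' @rdname reportAccessors
#' @export
setGeneric("flaggedRegions", function(x) standardGeneric("flaggedRegions"))

#' StoichiometryReport accessors
#'
#' `flaggedRegions()` returns the flagged-region table, `binRatios()` the
#' per-bin log2 ratio table.
#'
#' @param x a [StoichiometryReport-class].
#' @name reportAccessors
#' @export
setGeneric("binRatios", function(x) standardGeneric("binRatios"))

#' @rdname reportAccessors
setMethod("flaggedRegions", "StoichiometryReport", function(x) x@regions)

#' @rdname reportAccessors
setMethod("binRatios", "StoichiometryReport", function(x) x@ratios)

setMethod("show", "StoichiometryReport", function(object) {
  cat("StoichiometryReport: ", nrow(object@ratios), " bins, |log2| >= ",
      object@threshold, " flags ", nrow(object@regions), " region(s)\n",
      sep = "")
  if (nrow(object@regions)) print(object@regions)
})

#' Write a coverage profile or comparison as TSV
#'
#' @param x a [CoverageProfile-class] or [StoichiometryReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(x, path) {
  tab <- if (is(x, "CoverageProfile")) profileBins(x) else binRatios(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
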