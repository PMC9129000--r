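#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement
#' @importFrom IRanges IRanges coverage Views viewSums
NULL

#' CircularGenome: a circular nucleotide sequence
#'
#' Container for a circular organellar genome (mitochondrial or plastid).
#' All coordinates used by the package are 1-based inclusive and are
#' interpreted modulo the genome length, so intervals may wrap across the
#' sequence origin.
#'
#' @slot name single character identifier (used as the SAM reference name).
#' @slot sequence a [Biostrings::DNAString] over the alphabet A, C, G, T, N.
#'
#' @seealso [circularGenome()], [genomeLength()], [subseqCircular()]
#' @export
setClass("CircularGenome",
  representation(name = "character", sequence = "DNAString")
)

setValidity("CircularGenome", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "genome sequence must be non-empty")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains letters outside {A,C,G,T,N}: ",
                         paste(bad, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' CoverageProfile: per-kilobase read depth of a genome
#'
#' Read depth of a circular genome accumulated into fixed 1-kb bins.
#' Position p belongs to bin ceiling(p / 1000), i.e. bin b spans positions
#' (b-1)*1000 + 1 .. b*1000; the final bin may be shorter than 1 kb.
#' `normalized_depth` rescales mean depth to a library of 1,000,000 reads.
#'
#' @slot genomeName reference name the alignments were binned against.
#' @slot genomeLength genome length in bp.
#' @slot binSize bin width in bp (fixed at 1000).
#' @slot bins data.frame with columns bin_index, bin_start, bin_end,
#'   base_count, mean_depth, normalized_depth.
#' @slot totalReads library read count used for normalization.
#'
#' @seealso [binCoverage()], [compareProfiles()]
#' @export
setClass("CoverageProfile",
  representation(genomeName = "character", genomeLength = "integer",
                 binSize = "integer", bins = "data.frame",
                 totalReads = "numeric")
)

setValidity("CoverageProfile", function(object) {
  msg <- character()
  need <- c("bin_index", "bin_start", "bin_end", "base_count",
            "mean_depth", "normalized_depth")
  if (!all(need %in% names(object@bins)))
    msg <- c(msg, "bins must have columns bin_index, bin_start, bin_end, base_count, mean_depth, normalized_depth")
  else {
    nb <- ceiling(object@genomeLength / object@binSize)
    if (nrow(object@bins) != nb ||
        !identical(object@bins$bin_index, seq_len(nb)))
      msg <- c(msg, "bin_index must cover 1..ceiling(genomeLength/binSize)")
  }
  if (object@totalReads <= 0)
    msg <- c(msg, "totalReads must be positive")
  if (length(msg)) msg else TRUE
})

#' StoichiometryReport: per-bin copy-number comparison of two libraries
#'
#' Per-bin log2 ratio of normalized depth (sample over control) together with
#' flagged regions: maximal runs of bins whose |log2 ratio| reaches the flag
#' threshold, annotated with the repeat pairs whose copies lie within one bin
#' of a region boundary (candidate recombination substrates for the
#' stoichiometry change).
#'
#' @slot ratios data.frame: bin_index, bin_start, bin_end, sample_norm,
#'   control_norm, log2_ratio, flagged.
#' @slot regions data.frame: start_bin, end_bin, n_bins, mean_log2,
#'   direction, repeat_ids (comma-separated labels, "" if none).
#' @slot threshold absolute log2 ratio at or above which a bin is flagged.
#' @slot epsilon pseudocounts (sample, control) added to normalized depths.
#'
#' @seealso [compareProfiles()]
#' @export
setClass("StoichiometryReport",
  representation(ratios = "data.frame", regions = "data.frame",
                 threshold = "numeric", epsilon = "numeric")
)

#' TruthSet: simulator ground truth
#'
#' Expected per-bin relative copy number and the catalogue of planted
#' junctions for a simulated library. The master genome contributes 1.0 to
#' every bin; each subgenome adds its weight over the master-genome bins it
#' covers.
#'
#' @slot sampleLabel text label for the simulated sample.
#' @slot perBinCopyNumber numeric vector, one entry per 1-kb bin of the
#'   master genome.
#' @slot plantedJunctions data.frame: position_a, position_b, kind,
#'   orientation, expected_support_class, molecule.
#'
#' @seealso [buildMixture()], [simulateReads()]
#' @export
setClass("TruthSet",
  representation(sampleLabel = "character", perBinCopyNumber = "numeric",
                 plantedJunctions = "data.frame")
)

#' ConfigCounts: read-pair counts of parental and crossover configurations
#'
#' Counts of informative read pairs supporting each flank configuration
#' around a direct repeat pair: parental arrangements 1/1 and 2/2 versus the
#' crossover arrangements 1/2 and 2/1 produced by recombination between the
#' two copies.
#'
#' @slot repeatId repeat pair label.
#' @slot counts named integer vector with elements "1/1", "2/2", "1/2", "2/1".
#' @slot informativePairs total fragments with both mates uniquely anchored
#'   in the flanking unique sequence of either copy.
#' @slot flank flank width (bp) used on each side of the repeat copies.
#'
#' @seealso [classifySpanningPairs()], [relativeAccumulation()]
#' @export
setClass("ConfigCounts",
  representation(repeatId = "character", counts = "integer",
                 informativePairs = "integer", flank = "integer")
)

setValidity("ConfigCounts", function(object) {
  if (!identical(names(object@counts), c("1/1", "2/2", "1/2", "2/1")))
    return("counts must be named '1/1','2/2','1/2','2/1'")
  if (any(object@counts < 0) || any(object@counts > object@informativePairs))
    return("each count must lie in [0, informativePairs]")
  TRUE
})
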