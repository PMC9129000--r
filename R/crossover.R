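## Quantification of parental vs crossover configurations across a direct
## repeat pair — the sequencing analog of qPCR with primers in the unique
## flanks. A fragment whose two mates anchor uniquely in an upstream flank
## (a, upstream of copy1; c, upstream of copy2) and a downstream flank
## (b, downstream of copy1; d, downstream of copy2) reports the
## configuration it spans: a-b = 1/1 and c-d = 2/2 (parental),
## a-d = 1/2 and c-b = 2/1 (crossover products of recombination between
## the copies).

## is position p inside the circular interval starting at s of length len?
.inCirc <- function(p, s, len, L) ((p - s) %% L) < len

## is the read interval [p, p+w-1] (circular) wholly inside the interval?
.withinCirc <- function(p, w, s, len, L) {
  off <- (p - s) %% L
  off + w <= len
}

#' Count read pairs spanning each configuration of a direct repeat pair
#'
#' Defines four flanks of width `flank` around the repeat copies and
#' classifies every fragment with both mates mapped, unique, and wholly
#' contained in one upstream and one downstream flank. The repeat pair must
#' be direct and the flanks must not overlap the other repeat copy
#' (an error suggests a smaller flank). Mates lying in more than one flank
#' (possible when the segment between the copies is shorter than two
#' flanks) are ambiguous and skipped.
#'
#' @param records alignment record data.frame with mate columns
#'   ([pairMates()] / [alignPairs()]).
#' @param pair one repeat-table row, orientation "direct".
#' @param genome the [CircularGenome-class].
#' @param flank flank width in bp; the default of two read lengths (300)
#'   leaves a read-length's worth of valid placements inside each flank.
#' @return a [ConfigCounts-class].
#' @export
classifySpanningPairs <- function(records, pair, genome, flank = 300L) {
  p <- .pairRow(pair)
  if (!identical(p$orientation, "direct"))
    stop("classifySpanningPairs() requires a direct repeat pair")
  L <- genomeLength(genome)
  flank <- as.integer(flank)
  flanks <- list(
    a = c(s = circPos(p$copy1_start - flank, L), len = flank),
    b = c(s = circPos(p$copy1_end + 1L, L), len = flank),
    c = c(s = circPos(p$copy2_start - flank, L), len = flank),
    d = c(s = circPos(p$copy2_end + 1L, L), len = flank))
  copies <- list(c(s = p$copy1_start, len = p$length),
                 c(s = p$copy2_start, len = p$length))
  for (f in names(flanks)) for (cp in copies) {
    if (.circOverlap(flanks[[f]]["s"], flanks[[f]]["len"],
                     cp["s"], cp["len"], L))
      stop("flank '", f, "' (width ", flank, ") overlaps a repeat copy; ",
           "use a smaller flank")
  }
  recs <- records[records$mapped & records$is_unique &
                  records$mate %in% c(1L, 2L), , drop = FALSE]
  if (!nrow(recs)) {
    counts <- stats::setNames(integer(4), c("1/1", "2/2", "1/2", "2/1"))
    warning("no usable read pairs; repeat may exceed the fragment span")
    return(new("ConfigCounts", repeatId = as.character(p$id),
               counts = counts, informativePairs = 0L, flank = flank))
  }
  w <- vapply(recs$cigar, cigarRefLength, 0L, USE.NAMES = FALSE)
  memberOf <- function(pos, width) {
    hits <- vapply(flanks, function(f)
      .withinCirc(pos, width, f["s"], f["len"], L), TRUE)
    if (sum(hits) == 1L) names(flanks)[hits] else NA_character_
  }
  fl <- vapply(seq_len(nrow(recs)),
               function(i) memberOf(recs$pos[i], w[i]), "")
  byRead <- split(fl, recs$read_id)
  counts <- stats::setNames(integer(4), c("1/1", "2/2", "1/2", "2/1"))
  informative <- 0L
  for (m in byRead) {
    if (length(m) != 2L || any(is.na(m))) next
    up <- intersect(m, c("a", "c"))
    down <- intersect(m, c("b", "d"))
    if (length(up) != 1L || length(down) != 1L) next
    informative <- informative + 1L
    config <- paste0(if (up == "a") "1" else "2", "/",
                     if (down == "b") "1" else "2")
    counts[config] <- counts[config] + 1L
  }
  if (informative == 0L)
    warning("no informative pairs for repeat '", p$id,
            "'; repeat may exceed the fragment span")
  new("ConfigCounts", repeatId = as.character(p$id), counts = counts,
      informativePairs = informative, flank = flank)
}

#' @rdname configAccessors
#' @export
setGeneric("configCounts", function(x) standardGeneric("configCounts"))

#' ConfigCounts accessors
#'
#' @param x a [ConfigCounts-class].
#' @name configAccessors
#' @export
setGeneric("informativePairs", function(x) standardGeneric("informativePairs"))

#' @rdname configAccessors
setMethod("configCounts", "ConfigCounts", function(x) x@counts)

#' @rdname configAccessors
setMethod("informativePairs", "ConfigCounts", function(x) x@informativePairs)

setMethod("show", "ConfigCounts", function(object) {
  cat("ConfigCounts for repeat '", object@repeatId, "' (flank ",
      object@flank, " bp): ", object@informativePairs,
      " informative pairs\n", sep = "")
  print(object@counts)
})

#' Relative accumulation of each configuration, sample vs control
#'
#' For each configuration x with count `x_s` among `N_s` informative sample
#' fragments and `x_c` among `N_c` control fragments, reports
#' `log2(((x_s + 1/2) / N_s) / ((x_c + 1/2) / N_c))` — a Haldane-corrected
#' log2 fold change of the configuration's frequency, finite even for
#' products entirely absent from one sample (recombination products are
#' often undetectable in wild type). Antisymmetric under swapping sample
#' and control.
#'
#' @param sample,control [ConfigCounts-class] objects for the same repeat
#'   pair and flank definition.
#' @return data.frame: repeat_id, config, x_sample, n_sample, x_control,
#'   n_control, log2_ratio.
#' @export
relativeAccumulation <- function(sample, control) {
  stopifnot(is(sample, "ConfigCounts"), is(control, "ConfigCounts"))
  if (sample@repeatId != control@repeatId ||
      sample@flank != control@flank)
    stop("sample and control quantify different repeats or flanks")
  ns <- sample@informativePairs
  nc <- control@informativePairs
  if (ns == 0L || nc == 0L)
    stop("informative pair count is zero in ",
         if (ns == 0L) "sample" else "control")
  cfg <- names(sample@counts)
  lr <- log2(((sample@counts + 0.5) / ns) / ((control@counts + 0.5) / nc))
  data.frame(repeat_id = sample@repeatId, config = cfg,
             x_sample = unname(sample@counts), n_sample = ns,
             x_control = unname(control@counts), n_control = nc,
             log2_ratio = unname(lr), stringsAsFactors = FALSE)
}

#' Write a crossover quantification table as TSV
#'
#' @param quant [relativeAccumulation()] table (or several rbind-ed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQuantTable <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
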