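## Predicted recombination products of a repeat pair.
##
## Crossover between the two copies of a DIRECT repeat on a circle excises a
## subgenomic circle ("loop-out"): each product circle keeps exactly one full
## repeat copy, and the two circle lengths sum to the parent length.
## Recombination between INVERTED copies flips the intervening segment
## (isomerization) and conserves length.
##
## Flank nomenclature around a pair (the field's qPCR convention):
##   a = upstream of copy1, b = downstream of copy1,
##   c = upstream of copy2, d = downstream of copy2.
## Parental configurations are a-(repeat)-b = 1/1 and c-(repeat)-d = 2/2;
## crossover configurations are a-(repeat)-d = 1/2 and c-(repeat)-b = 2/1.

.pairRow <- function(pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L)
    as.list(pair[1L, ])
  } else as.list(pair)
}

#' Predict the loop-out products of a direct repeat pair
#'
#' Returns the two circular molecules produced by a crossover between the
#' copies of a direct repeat: the loop-out circle spanning from copy1 through
#' the segment between the copies (carrying the 2/1 crossover junction) and
#' the remainder circle spanning from copy2 through the complementary
#' segment (carrying the 1/2 junction). Each product retains one full repeat
#' copy and the two lengths sum to the parent genome length.
#'
#' @param genome parent [CircularGenome-class].
#' @param pair one row of a repeat table ([findExactRepeats()] /
#'   [repeatPair()]); orientation must be "direct".
#' @return list with elements `repeat_id`, `loopout` and `remainder`
#'   ([CircularGenome-class] circles), `carried_junction` (named character:
#'   which crossover configuration each circle carries) and
#'   `master_intervals` (data.frame of master-genome intervals each circle
#'   covers, used by the simulator's ground truth).
#' @export
predictProducts <- function(genome, pair) {
  p <- .pairRow(pair)
  if (!identical(p$orientation, "direct"))
    stop("predictProducts() handles direct repeats only; ",
         "use invertSegment() for inverted pairs")
  L <- genomeLength(genome)
  rlen <- as.integer(p$length)
  s1 <- p$copy1_start; e1 <- p$copy1_end
  s2 <- p$copy2_start; e2 <- p$copy2_end
  gap12 <- (s2 - e1 - 1L) %% L     # between copy1 end and copy2 start
  gap21 <- (s1 - e2 - 1L) %% L     # between copy2 end and copy1 start
  loop <- circularGenome(paste0(genomeName(genome), "_", p$id, "_loopout"),
                         subseqCircular(genome, s1, rlen + gap12))
  rem <- circularGenome(paste0(genomeName(genome), "_", p$id, "_remainder"),
                        subseqCircular(genome, s2, rlen + gap21))
  list(
    repeat_id = p$id,
    loopout = loop,
    remainder = rem,
    carried_junction = c(loopout = "2/1", remainder = "1/2"),
    master_intervals = data.frame(
      circle = c("loopout", "loopout", "loopout",
                 "remainder", "remainder", "remainder"),
      start = c(circPos(e1 + 1L, L), s1, s2,
                circPos(e2 + 1L, L), s1, s2),
      len = c(gap12, rlen, rlen, gap21, rlen, rlen),
      weight_share = c(1, 0.5, 0.5, 1, 0.5, 0.5),
      stringsAsFactors = FALSE
    )
  )
}

#' Junction sequence of a parental or crossover configuration
#'
#' Builds the nucleotide sequence of one configuration across a direct
#' repeat pair: an upstream flank, one full repeat copy, and a downstream
#' flank. Parental configurations (1/1, 2/2) reproduce the parent genome;
#' crossover configurations (1/2, 2/1) are the sequences created by
#' recombination between the copies.
#'
#' @param genome parent [CircularGenome-class].
#' @param pair one repeat-table row, orientation "direct".
#' @param config one of "1/1", "2/2", "1/2", "2/1".
#' @param flank flank width in bp on each side.
#' @return list with `config`, `product_role` ("parental" or "crossover")
#'   and `junction_sequence` (character, length `2 * flank + repeat length`).
#' @export
junctionSequence <- function(genome, pair, config = c("1/1", "2/2", "1/2", "2/1"),
                             flank = 200L) {
  config <- match.arg(config)
  p <- .pairRow(pair)
  if (!identical(p$orientation, "direct"))
    stop("junctionSequence() is defined for direct repeat pairs")
  L <- genomeLength(genome)
  flank <- as.integer(flank)
  rlen <- as.integer(p$length)
  up <- function(s) subseqCircular(genome, s - flank, flank)       # upstream
  down <- function(e) subseqCircular(genome, e + 1L, flank)        # downstream
  rep1 <- subseqCircular(genome, p$copy1_start, rlen)
  seqs <- switch(config,
    "1/1" = paste0(up(p$copy1_start), rep1, down(p$copy1_end)),
    "2/2" = paste0(up(p$copy2_start), rep1, down(p$copy2_end)),
    "1/2" = paste0(up(p$copy1_start), rep1, down(p$copy2_end)),
    "2/1" = paste0(up(p$copy2_start), rep1, down(p$copy1_end)))
  list(config = config,
       product_role = if (config %in% c("1/1", "2/2")) "parental" else "crossover",
       junction_sequence = seqs)
}

#' Flip the segment between the copies of an inverted repeat pair
#'
#' Models isomerization: recombination between the two copies of an inverted
#' repeat reverse-complements the segment lying between them (from the end
#' of copy1 to the start of copy2, walking forward on the circle). Genome
#' length is conserved and the operation is an involution.
#'
#' @param genome a [CircularGenome-class].
#' @param pair one repeat-table row; orientation must be "inverted".
#' @return a new [CircularGenome-class] of identical length.
#' @export
invertSegment <- function(genome, pair) {
  p <- .pairRow(pair)
  if (!identical(p$orientation, "inverted"))
    stop("invertSegment() handles inverted repeats only; ",
         "use predictProducts() for direct pairs")
  L <- genomeLength(genome)
  gap <- (p$copy2_start - p$copy1_end - 1L) %% L
  if (gap == 0L) return(circularGenome(paste0(genomeName(genome), "_isomer"),
                                       as.character(genomeSeq(genome))))
  chars <- strsplit(as.character(genomeSeq(genome)), "")[[1]]
  idx <- circPos(seq(p$copy1_end + 1L, length.out = gap), L)
  chars[idx] <- rev(chartr("ACGTN", "TGCAN", chars[idx]))
  circularGenome(paste0(genomeName(genome), "_isomer"),
                 paste(chars, collapse = ""))
}
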