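## Repeat-pair discovery on circular genomes.
##
## A repeat pair is two non-overlapping intervals carrying identical sequence
## (direct) or reverse-complementary sequence (inverted). Detection is exact
## and maximal: a reported pair can be extended in neither direction.
## Circularity is handled by seeding on the doubled sequence and reducing all
## coordinates modulo the genome length.

.SIZE_BREAKS <- c(micro_max = 49L, intermediate_max = 500L)

#' Classify a repeat length
#'
#' Organellar repeat biology distinguishes large repeats (> 500 bp, frequent
#' reciprocal recombination), intermediate-size repeats (50-500 bp, rare
#' ectopic recombination) and microhomologies (< 50 bp).
#'
#' @param len repeat length(s) in bp.
#' @return character vector: "large", "intermediate" or "micro".
#' @export
repeatSizeClass <- function(len) {
  ifelse(len > .SIZE_BREAKS["intermediate_max"], "large",
         ifelse(len >= 50L, "intermediate", "micro"))
}

#' Build a repeat-pair record by hand
#'
#' Convenience constructor for a repeat-pair table row with the same columns
#' as [findExactRepeats()] output, given the two copy start positions and the
#' repeat length. Used to describe planted repeats whose coordinates are
#' known.
#'
#' @param id text label (e.g. "A", "EE", "LR1").
#' @param start1,start2 1-based start positions of the two copies.
#' @param len repeat length in bp.
#' @param orientation "direct" or "inverted".
#' @param genomeLength circle length, for modular end coordinates.
#' @return one-row data.frame.
#' @export
repeatPair <- function(id, start1, start2, len, orientation, genomeLength) {
  stopifnot(orientation %in% c("direct", "inverted"), len >= 1)
  s <- sort(circPos(c(start1, start2), genomeLength))
  data.frame(
    id = as.character(id),
    copy1_start = s[1], copy1_end = circPos(s[1] + len - 1L, genomeLength),
    copy2_start = s[2], copy2_end = circPos(s[2] + len - 1L, genomeLength),
    orientation = orientation, length = as.integer(len),
    size_class = unname(repeatSizeClass(len)),
    stringsAsFactors = FALSE
  )
}

## circular interval overlap: intervals given as (start, len) on a circle
.circOverlap <- function(s1, len1, s2, len2, L) {
  d12 <- (s2 - s1) %% L
  d21 <- (s1 - s2) %% L
  d12 < len1 || d21 < len2
}

## integer encoding with N mapped to a code that never matches anything
.encodeDNA <- function(chars) {
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- -seq_len(sum(is.na(code)))  # each N unique
  code
}

.complementCode <- function(code) ifelse(code > 0L, 5L - code, code)

## circular runs of TRUE in logical vector m; returns data.frame(start, len)
.circularRuns <- function(m) {
  L <- length(m)
  if (all(m)) return(data.frame(start = 1L, len = L))
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], len = r$lengths[r$values])
  if (nrow(runs) >= 2L && m[1L] && m[L]) {
    ## merge the wrap-around run
    first <- which(runs$start == 1L)
    last <- which(runs$start + runs$len - 1L == L)
    runs$start[last] <- runs$start[last]
    runs$len[last] <- runs$len[last] + runs$len[first]
    runs <- runs[-first, , drop = FALSE]
  }
  runs
}

#' Find all maximal exact repeat pairs on a circular genome
#'
#' Scans a circular genome for pairs of non-overlapping intervals of length
#' at least `minLen` carrying identical sequence (direct orientation) or
#' reverse-complementary sequence (inverted orientation). Pairs are maximal:
#' extendable in neither direction along the circle. Pairs spanning the
#' sequence origin are found; each pair is reported once, with `copy1` the
#' copy with the smaller start position. Detection seeds on shared
#' `minLen`-mers, then extends matches along the (anti-)diagonal and takes
#' maximal runs, deduplicating coordinates modulo the genome length.
#'
#' Positions containing N never match. Palindromic or otherwise overlapping
#' copies are not reported (copies of a pair must be disjoint).
#'
#' @param genome a [CircularGenome-class].
#' @param minLen minimum repeat length in bp; must be >= 20 (shorter
#'   thresholds explode into microhomology noise).
#' @param orientations subset of `c("direct", "inverted")`.
#' @return data.frame with columns id, copy1_start, copy1_end, copy2_start,
#'   copy2_end, orientation, length, size_class, ordered by copy1_start,
#'   copy2_start, orientation. Zero rows when no repeat exists.
#' @examples
#' g <- randomGenome(2000, repeats = data.frame(
#'   start1 = 101, start2 = 1101, len = 127, orientation = "direct"),
#'   seed = 7)
#' findExactRepeats(g, minLen = 50)
#' @export
findExactRepeats <- function(genome, minLen = 50L,
                             orientations = c("direct", "inverted")) {
  stopifnot(is(genome, "CircularGenome"))
  if (genomeLength(genome) < 1L) stop("empty genome")
  minLen <- as.integer(minLen)
  if (minLen < 20L)
    stop("minLen must be >= 20 (guards against microhomology explosion)")
  orientations <- match.arg(orientations, c("direct", "inverted"),
                            several.ok = TRUE)
  L <- genomeLength(genome)
  s <- as.character(genomeSeq(genome))
  chars <- strsplit(s, "")[[1]]
  code <- .encodeDNA(chars)
  if (L < 2L * minLen) {
    return(.emptyRepeatTable())
  }

  ## k-mers over every circular start position (k = minLen)
  doubled <- paste0(s, s)
  k <- minLen
  kmers <- substring(doubled, 1:L, 1:L + k - 1L)

  found <- list()

  if ("direct" %in% orientations) {
    dup <- kmers %in% kmers[duplicated(kmers)]
    groups <- split(which(dup), kmers[dup])
    diags <- unique(unlist(lapply(groups, function(g) {
      if (length(g) < 2L) return(integer())
      p <- utils::combn(g, 2L)
      (p[2L, ] - p[1L, ]) %% L
    })))
    diags <- setdiff(diags, 0L)
    for (d in diags) {
      shifted <- code[circPos(seq_len(L) + d, L)]
      m <- code == shifted & code > 0L
      runs <- .circularRuns(m)
      runs <- runs[runs$len >= minLen & runs$len < L, , drop = FALSE]
      for (i in seq_len(nrow(runs))) {
        a <- runs$start[i]; len <- runs$len[i]
        b <- circPos(a + d, L)
        if (.circOverlap(a, len, b, len, L)) next
        key <- paste("D", min(a, b), max(a, b), len)
        found[[key]] <- c(start1 = min(a, b), start2 = max(a, b),
                          len = len, dir = 1L)
      }
    }
  }

  if ("inverted" %in% orientations) {
    rck <- revComp(kmers)
    hit <- match(rck, kmers)                    # one representative suffices
    present <- rck %in% kmers
    antis <- integer()
    if (any(present)) {
      i <- which(present)
      j <- hit[present]
      antis <- unique((i + (j + k - 1L)) %% L)  # p + q constant on the circle
    }
    ccode <- .complementCode(code)
    for (cc in antis) {
      partner <- circPos(cc - seq_len(L), L)
      m <- code == ccode[partner] & code > 0L
      runs <- .circularRuns(m)
      runs <- runs[runs$len >= minLen & runs$len < L, , drop = FALSE]
      for (i in seq_len(nrow(runs))) {
        a <- runs$start[i]; len <- runs$len[i]
        b <- circPos(cc - (a + len - 1L), L)    # start of the mirrored copy
        if (a == b) next                        # palindrome: same interval
        if (.circOverlap(a, len, b, len, L)) next
        key <- paste("I", min(a, b), max(a, b), len)
        found[[key]] <- c(start1 = min(a, b), start2 = max(a, b),
                          len = len, dir = 0L)
      }
    }
  }

  if (!length(found)) return(.emptyRepeatTable())
  tab <- as.data.frame(do.call(rbind, found))
  tab <- tab[order(tab$start1, tab$start2, -tab$dir), , drop = FALSE]
  out <- data.frame(
    id = sprintf("R%02d", seq_len(nrow(tab))),
    copy1_start = as.integer(tab$start1),
    copy1_end = circPos(tab$start1 + tab$len - 1L, L),
    copy2_start = as.integer(tab$start2),
    copy2_end = circPos(tab$start2 + tab$len - 1L, L),
    orientation = ifelse(tab$dir == 1L, "direct", "inverted"),
    length = as.integer(tab$len),
    size_class = unname(repeatSizeClass(tab$len)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.emptyRepeatTable <- function() {
  data.frame(id = character(), copy1_start = integer(),
             copy1_end = integer(), copy2_start = integer(),
             copy2_end = integer(), orientation = character(),
             length = integer(), size_class = character(),
             stringsAsFactors = FALSE)
}

#' Write / read a repeat-pair table as TSV
#'
#' @param repeats data.frame as returned by [findExactRepeats()].
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
writeRepeatTable <- function(repeats, path) {
  utils::write.table(repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRepeatTable
#' @export
readRepeatTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
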