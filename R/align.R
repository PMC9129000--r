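## Deterministic seed-and-extend micro-aligner for small circular genomes.
##
## Exact seeding on fixed-length k-mers, then ungapped extension in both
## directions while the running mismatch rate stays within bounds.
## Unextendable read ends become soft clips (CIGAR S); there is no gapped
## alignment, so reads requiring indels end up soft-clipped or unmapped —
## which matches the downstream junction filter's discard of indel records.
## Circularity: the genome sequence is doubled for seeding and extension and
## positions are reported modulo the genome length.

#' Alignment parameters
#'
#' @param seedLength exact-match seed length in bp (>= 15).
#' @param maxMismatchRate maximum running mismatch rate tolerated during
#'   extension, in `[0, 0.2)`.
#' @param minAnchor minimum aligned block length; shorter placements are
#'   reported unmapped.
#' @return an `AlignParams` list.
#' @export
alignParams <- function(seedLength = 31L, maxMismatchRate = 0.04,
                        minAnchor = 30L) {
  stopifnot(seedLength >= 15L, maxMismatchRate >= 0, maxMismatchRate < 0.2)
  list(seedLength = as.integer(seedLength),
       maxMismatchRate = maxMismatchRate,
       minAnchor = as.integer(minAnchor))
}

#' Build a seed index for a circular genome
#'
#' Hashes every k-mer start position of the circle (computed on the doubled
#' sequence) into an environment for O(1) seed lookup. Build once, reuse for
#' many reads.
#'
#' @param genome a [CircularGenome-class].
#' @param params [alignParams()].
#' @return an opaque index list consumed by [alignRead()].
#' @export
buildGenomeIndex <- function(genome, params = alignParams()) {
  L <- genomeLength(genome)
  s <- as.character(genomeSeq(genome))
  doubled <- paste0(s, s)
  k <- params$seedLength
  if (L < k) stop("genome shorter than seed length")
  kmers <- substring(doubled, 1:L, 1:L + k - 1L)
  env <- list2env(split(1:L, kmers), hash = TRUE)
  list(name = genomeName(genome), L = L,
       int = utf8ToInt(doubled), env = env, k = k,
       nCode = utf8ToInt("N"), params = params)
}

## fast single-string reverse complement (hot path; avoids Biostrings
## object construction per read)
.rc <- function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))

.unmappedRecord <- function(id, mate, seq) {
  list(read_id = id, mate = mate, ref_name = "*", pos = 0L,
       strand = "+", mapq = 0L, cigar = "*", seq = seq,
       mapped = FALSE, is_unique = FALSE)
}

## assemble a list of .alignOne() results into an AlignmentRecord data.frame
.recordsFrame <- function(lst) {
  data.frame(
    read_id = vapply(lst, `[[`, "", "read_id"),
    mate = vapply(lst, `[[`, 0L, "mate"),
    ref_name = vapply(lst, `[[`, "", "ref_name"),
    pos = vapply(lst, `[[`, 0L, "pos"),
    strand = vapply(lst, `[[`, "", "strand"),
    mapq = vapply(lst, `[[`, 0L, "mapq"),
    cigar = vapply(lst, `[[`, "", "cigar"),
    seq = vapply(lst, `[[`, "", "seq"),
    mapped = vapply(lst, `[[`, TRUE, "mapped"),
    is_unique = vapply(lst, `[[`, TRUE, "is_unique"),
    stringsAsFactors = FALSE)
}

## core: align one read sequence against an index; returns a one-row
## data.frame (AlignmentRecord fields). Ties on score are broken uniformly
## at random using the caller's RNG stream (and reported is_unique = FALSE).
.alignOne <- function(index, id, mate, read) {
  p <- index$params
  n <- nchar(read)
  L <- index$L
  k <- index$k
  if (n < p$minAnchor || n < k || n > L)
    return(.unmappedRecord(id, mate, read))
  rate <- p$maxMismatchRate
  cands <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") read else .rc(read)
    rsInt <- utf8ToInt(rs)
    offsets <- unique(c(seq(1L, n - k + 1L, by = k), n - k + 1L))
    seen <- integer()
    for (o in offsets) {
      hits <- index$env[[substr(rs, o, o + k - 1L)]]
      if (is.null(hits)) next
      for (h in hits) {
        d <- circPos(h - o + 1L, L)
        if (d %in% seen) next
        seen <- c(seen, d)
        gInt <- index$int[d:(d + n - 1L)]
        mism <- rsInt != gInt | gInt == index$nCode | rsInt == index$nCode
        ## right extension from the exact seed [o, o+k-1]
        qe <- o + k - 1L
        mm <- 0L
        if (qe < n) {
          cm <- cumsum(mism[(qe + 1L):n])
          lim <- rate * (k + seq_along(cm))
          v <- which(cm > lim)
          ext <- if (length(v)) v[1L] - 1L else length(cm)
          qe <- qe + ext
          mm <- if (ext > 0L) cm[ext] else 0L
        }
        ## left extension, counting mismatches already accepted
        qs <- o
        if (qs > 1L) {
          cm <- cumsum(mism[(qs - 1L):1L]) + mm
          lim <- rate * ((qe - qs + 1L) + seq_along(cm))
          v <- which(cm > lim)
          ext <- if (length(v)) v[1L] - 1L else length(cm)
          qs <- qs - ext
          mm <- if (ext > 0L) cm[ext] else mm
        }
        ## blocks never end on a mismatch
        while (qe > qs && mism[qe]) { qe <- qe - 1L; mm <- mm - 1L }
        while (qs < qe && mism[qs]) { qs <- qs + 1L; mm <- mm - 1L }
        blen <- qe - qs + 1L
        if (blen < p$minAnchor) next
        cands[[length(cands) + 1L]] <-
          list(strand = strand, d = d, qs = qs, qe = qe,
               score = blen - 2L * mm, blen = blen)
      }
    }
  }
  if (!length(cands)) return(.unmappedRecord(id, mate, read))
  score <- vapply(cands, `[[`, 0, "score")
  blen <- vapply(cands, `[[`, 0, "blen")
  top <- which(score == max(score))
  if (length(top) > 1L) {
    ## deterministic rule first: longer block wins, then leftmost, + strand
    top <- top[order(-blen[top],
                     vapply(cands[top], `[[`, 0, "d"),
                     vapply(cands[top], `[[`, "", "strand"))]
    best_blen <- blen[top[1L]]
    tied <- top[blen[top] == best_blen]
    unique_hit <- FALSE
    pick <- if (length(tied) > 1L) tied[sample.int(length(tied), 1L)]
            else top[1L]
  } else {
    unique_hit <- TRUE
    pick <- top
  }
  b <- cands[[pick]]
  cigar <- paste0(if (b$qs > 1L) paste0(b$qs - 1L, "S"),
                  b$blen, "M",
                  if (b$qe < n) paste0(n - b$qe, "S"))
  list(read_id = id, mate = mate, ref_name = index$name,
       pos = circPos(b$d + b$qs - 1L, L), strand = b$strand,
       mapq = if (unique_hit) 60L else 0L, cigar = cigar,
       seq = if (b$strand == "+") read else .rc(read),
       mapped = TRUE, is_unique = unique_hit)
}

#' Align a single read to a circular genome
#'
#' Exact-seed, ungapped-extension placement. The best-scoring placement
#' (aligned block length minus twice the mismatches) wins; among equal
#' scores the longer block wins, then the leftmost position, then the
#' + strand; exact ties are resolved uniformly at random from the session
#' RNG and reported with `is_unique = FALSE` and MAPQ 0. Reads with no
#' placement of at least `minAnchor` aligned bases are returned unmapped
#' (not an error).
#'
#' @param genome a [CircularGenome-class] or a prebuilt
#'   [buildGenomeIndex()] index.
#' @param read read sequence (character).
#' @param params [alignParams()]; ignored when `genome` is an index.
#' @param id,mate read name and mate number stored in the record.
#' @return one-row data.frame: read_id, mate, ref_name, pos, strand, mapq,
#'   cigar, seq (aligned orientation, as in SAM), mapped, is_unique.
#' @export
alignRead <- function(genome, read, params = alignParams(), id = "read",
                      mate = 0L) {
  index <- if (is(genome, "CircularGenome"))
    buildGenomeIndex(genome, params) else genome
  .recordsFrame(list(.alignOne(index, id, mate, toupper(read))))
}

#' Align a table of reads
#'
#' @param genome a [CircularGenome-class] or index.
#' @param reads data.frame with columns id, mate, seq (e.g. [readFastq()]).
#' @param params [alignParams()].
#' @return data.frame of alignment records, input order preserved.
#' @export
alignReads <- function(genome, reads, params = alignParams()) {
  index <- if (is(genome, "CircularGenome"))
    buildGenomeIndex(genome, params) else genome
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads)))
    out[[i]] <- .alignOne(index, reads$id[i], reads$mate[i],
                          reads$seq[i])
  .recordsFrame(out)
}

#' Align paired FASTQ files and fill mate fields
#'
#' Aligns both mates of each pair independently, then records each mate's
#' placement in the partner's `mate_ref` / `mate_pos` / `mate_strand` /
#' `mate_mapped` columns. Output order is input order (mate 1 then mate 2
#' per fragment).
#'
#' @param genome a [CircularGenome-class].
#' @param fastq1,fastq2 paths of the paired FASTQ files; read names must
#'   match pairwise.
#' @param params [alignParams()].
#' @param samPath optional path; when given, the records are also written
#'   as SAM via [writeSam()].
#' @return data.frame of alignment records for both mates.
#' @export
alignPairs <- function(genome, fastq1, fastq2, params = alignParams(),
                       samPath = NULL) {
  r1 <- readFastq(fastq1)
  r2 <- readFastq(fastq2)
  if (nrow(r1) != nrow(r2))
    stop("paired FASTQ files differ in record count")
  bad <- which(r1$id != r2$id)
  if (length(bad))
    stop("read name mismatch at record ", bad[1L], ": '", r1$id[bad[1L]],
         "' vs '", r2$id[bad[1L]], "'")
  recs <- pairMates(genome, data.frame(id = r1$id, seq1 = r1$seq,
                                       seq2 = r2$seq,
                                       stringsAsFactors = FALSE), params)
  if (!is.null(samPath)) writeSam(recs, genome, samPath)
  recs
}

#' @rdname alignPairs
#' @param pairs data.frame with columns id, seq1, seq2 (e.g.
#'   `simulateReads()$reads`), aligned without touching the filesystem.
#' @export
pairMates <- function(genome, pairs, params = alignParams()) {
  index <- if (is(genome, "CircularGenome"))
    buildGenomeIndex(genome, params) else genome
  n <- nrow(pairs)
  if (n == 0L) {
    recs <- .recordsFrame(list())[0, , drop = FALSE]
    recs$mate_ref <- character(); recs$mate_pos <- integer()
    recs$mate_strand <- character(); recs$mate_mapped <- logical()
    return(recs)
  }
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    out[[2L * i - 1L]] <- .alignOne(index, pairs$id[i], 1L, pairs$seq1[i])
    out[[2L * i]] <- .alignOne(index, pairs$id[i], 2L, pairs$seq2[i])
  }
  recs <- .recordsFrame(out)
  i1 <- seq(1L, 2L * n, by = 2L)
  i2 <- i1 + 1L
  recs$mate_ref <- recs$ref_name[c(rbind(i2, i1))]
  recs$mate_pos <- recs$pos[c(rbind(i2, i1))]
  recs$mate_strand <- recs$strand[c(rbind(i2, i1))]
  recs$mate_mapped <- recs$mapped[c(rbind(i2, i1))]
  recs
}
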