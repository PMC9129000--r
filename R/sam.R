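## SAM text import/export.
##
## The micro-aligner emits only M and S CIGAR operations, but the reader
## accepts the full SAM operation alphabet so that alignments produced by
## external short-read aligners can be ingested in place of the built-in
## one. Text SAM only (no BAM): convert externally with samtools if needed.

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

#' Parse a CIGAR string
#'
#' @param cigar single CIGAR string (e.g. "100M50S").
#' @param context optional text prepended to the error message (such as a
#'   line number) when the string is malformed.
#' @return data.frame with columns `op` and `len`; zero rows for "*".
#' @export
parseCigar <- function(cigar, context = NULL) {
  if (identical(cigar, "*"))
    return(data.frame(op = character(), len = integer(),
                      stringsAsFactors = FALSE))
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (m[1] == -1L || paste(toks, collapse = "") != cigar)
    stop(if (!is.null(context)) paste0(context, ": "),
         "malformed CIGAR string '", cigar, "'")
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
             stringsAsFactors = FALSE)
}

#' Query and reference lengths implied by a CIGAR
#'
#' `cigarQueryLength()` sums the query-consuming operations (M, I, S, =, X);
#' `cigarRefLength()` the reference-consuming ones (M, D, N, =, X).
#'
#' @param cigar CIGAR string.
#' @return integer length.
#' @export
cigarQueryLength <- function(cigar) {
  ops <- parseCigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

#' @rdname cigarQueryLength
#' @export
cigarRefLength <- function(cigar) {
  ops <- parseCigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

.samFlag <- function(rec) {
  paired <- rec$mate %in% c(1L, 2L)
  flag <- ifelse(paired, 1L, 0L)
  flag <- flag + ifelse(!rec$mapped, 4L, 0L)
  if ("mate_mapped" %in% names(rec))
    flag <- flag + ifelse(paired & !rec$mate_mapped, 8L, 0L)
  flag <- flag + ifelse(rec$mapped & rec$strand == "-", 16L, 0L)
  if ("mate_strand" %in% names(rec))
    flag <- flag + ifelse(paired & rec$mate_mapped & rec$mate_strand == "-",
                          32L, 0L)
  flag <- flag + ifelse(rec$mate == 1L, 64L, 0L) +
    ifelse(rec$mate == 2L, 128L, 0L)
  flag
}

#' Write alignment records as SAM
#'
#' Emits a minimal valid SAM 1.6 file: `@HD`/`@SQ` header for the genome,
#' then the standard 11 mandatory columns. MAPQ is 60 for unique placements
#' and 0 for ties, mirroring common aligner practice.
#'
#' @param records alignment record data.frame ([alignReads()] /
#'   [pairMates()]).
#' @param genome the [CircularGenome-class] the records refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", genomeName(genome), "\tLN:",
                  genomeLength(genome)))
  if (nrow(records) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  r <- records
  if (!"mate_ref" %in% names(r)) {
    r$mate_ref <- "*"; r$mate_pos <- 0L
  }
  rnext <- ifelse(r$mate_ref == "*", "*",
                  ifelse(r$mate_ref == r$ref_name, "=", r$mate_ref))
  body <- paste(r$read_id, .samFlag(r),
                ifelse(r$mapped, r$ref_name, "*"),
                ifelse(r$mapped, r$pos, 0L),
                r$mapq, r$cigar, rnext, r$mate_pos, 0L, r$seq, "*",
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Parses the 11 mandatory columns. Records with the unmapped FLAG bit
#' (0x4) get `mapped = FALSE`; strand comes from bit 0x10 and mate number
#' from bits 0x40/0x80. `is_unique` is derived as MAPQ > 0 (the convention
#' used when the aligner's own tie information is absent). CIGAR strings
#' are validated; a malformed CIGAR raises an error naming the line.
#'
#' @param path SAM file.
#' @param refName optional reference name; when given, mapped records on
#'   other references are dropped (their mates' fields are kept as read).
#' @return alignment record data.frame (read_id, mate, ref_name, pos,
#'   strand, mapq, cigar, seq, mapped, is_unique, mate_ref, mate_pos).
#' @export
readSam <- function(path, refName = NULL) {
  lines <- readLines(path)
  isHdr <- startsWith(lines, "@")
  body <- lines[!isHdr]
  lineNo <- which(!isHdr)
  if (!length(body)) {
    return(data.frame(read_id = character(), mate = integer(),
                      ref_name = character(), pos = integer(),
                      strand = character(), mapq = integer(),
                      cigar = character(), seq = character(),
                      mapped = logical(), is_unique = logical(),
                      mate_ref = character(), mate_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t")
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("SAM line ", lineNo[which(nf < 11L)[1]],
         ": fewer than 11 mandatory columns")
  col <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(col(2))
  cigar <- col(6)
  for (i in seq_along(cigar))
    if (cigar[i] != "*") parseCigar(cigar[i],
                                    paste0("SAM line ", lineNo[i]))
  mapq <- as.integer(col(5))
  rec <- data.frame(
    read_id = col(1),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                  ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)),
    ref_name = col(3),
    pos = as.integer(col(4)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = mapq,
    cigar = cigar,
    seq = col(10),
    mapped = bitwAnd(flag, 4L) == 0L,
    is_unique = bitwAnd(flag, 4L) == 0L & mapq > 0L,
    mate_ref = col(7),
    mate_pos = as.integer(col(8)),
    stringsAsFactors = FALSE)
  rec$mate_ref[rec$mate_ref == "="] <- rec$ref_name[rec$mate_ref == "="]
  if (!is.null(refName))
    rec <- rec[!rec$mapped | rec$ref_name == refName, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
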