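#' Construct a circular genome
#'
#' @param name single character identifier.
#' @param sequence character string or [Biostrings::DNAString] over
#'   A, C, G, T, N.
#' @return a [CircularGenome-class] object.
#' @examples
#' g <- circularGenome("toy", "ACGTACGTAC")
#' genomeLength(g)
#' @export
circularGenome <- function(name, sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("CircularGenome", name = as.character(name), sequence = sequence)
}

#' @rdname genomeLength
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))

#' Genome accessors
#'
#' `genomeName()` returns the identifier, `genomeLength()` the length in bp
#' and `genomeSeq()` the sequence as a [Biostrings::DNAString].
#'
#' @param x a [CircularGenome-class].
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname genomeLength
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname genomeLength
setMethod("genomeName", "CircularGenome", function(x) x@name)

#' @rdname genomeLength
setMethod("genomeLength", "CircularGenome", function(x) length(x@sequence))

#' @rdname genomeLength
setMethod("genomeSeq", "CircularGenome", function(x) x@sequence)

setMethod("show", "CircularGenome", function(object) {
  L <- length(object@sequence)
  head <- as.character(Biostrings::subseq(object@sequence, 1,
                                          min(30L, L)))
  cat("CircularGenome '", object@name, "': ", L, " bp (circular)\n",
      "  5'-", head, if (L > 30) "..." else "", "\n", sep = "")
})

## -- circular coordinate helpers ------------------------------------------

#' Map a position onto the circle
#'
#' Reduces any integer position to its 1-based equivalent on a circle of
#' length `L`.
#'
#' @param pos integer vector of positions (may be < 1 or > L).
#' @param L genome length.
#' @return positions in `[1, L]`.
#' @export
circPos <- function(pos, L) ((as.integer(pos) - 1L) %% as.integer(L)) + 1L

#' Extract a circular subsequence
#'
#' Returns `len` bases starting at `start` (1-based), wrapping across the
#' origin when needed.
#'
#' @param genome a [CircularGenome-class].
#' @param start 1-based start position (interpreted modulo genome length).
#' @param len number of bases to extract; must be between 1 and the genome
#'   length.
#' @return character string of length `len`.
#' @export
subseqCircular <- function(genome, start, len) {
  L <- genomeLength(genome)
  stopifnot(len >= 1, len <= L)
  s <- circPos(start, L)
  e <- s + len - 1L
  if (e <= L) {
    as.character(Biostrings::subseq(genome@sequence, s, e))
  } else {
    paste0(as.character(Biostrings::subseq(genome@sequence, s, L)),
           as.character(Biostrings::subseq(genome@sequence, 1L, e - L)))
  }
}

#' Reverse complement of a character sequence
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## -- FASTA I/O -------------------------------------------------------------

#' Read circular genomes from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return a list of [CircularGenome-class] objects, named by record id
#'   (first whitespace-delimited token of the header).
#' @export
readGenomeFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out <- lapply(seq_along(ss), function(i)
    circularGenome(ids[i], ss[[i]]))
  names(out) <- ids
  out
}

#' Write circular genomes to a FASTA file
#'
#' Records are wrapped at 60 characters per line.
#'
#' @param genomes a [CircularGenome-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path) {
  if (is(genomes, "CircularGenome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(lapply(genomes, genomeSeq))
  names(ss) <- vapply(genomes, genomeName, "")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Generate a random genome, optionally with planted repeats
#'
#' Draws an i.i.d. uniform A/C/G/T sequence and optionally plants exact
#' repeat pairs by copying (or reverse-complementing) a source segment to a
#' second location. Used to build test worlds with known repeat content.
#'
#' @param length genome length in bp.
#' @param name genome name.
#' @param repeats optional data.frame with columns `start1`, `start2`, `len`,
#'   `orientation` ("direct" or "inverted"): the segment at `start1` of
#'   length `len` is copied (reverse-complemented when inverted) over
#'   position `start2`.
#' @param seed optional integer seed (uses and restores the session RNG).
#' @return a [CircularGenome-class].
#' @export
randomGenome <- function(length, name = "toy", repeats = NULL, seed = NULL) {
  run <- function() {
    s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    if (!is.null(repeats)) {
      for (i in seq_len(nrow(repeats))) {
        r <- repeats[i, ]
        src <- s[circPos(seq(r$start1, length.out = r$len), length)]
        if (identical(r$orientation, "inverted"))
          src <- rev(chartr("ACGT", "TGCA", src))
        s[circPos(seq(r$start2, length.out = r$len), length)] <- src
      }
    }
    circularGenome(name, paste(s, collapse = ""))
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, then restores the previous RNG
#' state, so seeded helpers do not perturb the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
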