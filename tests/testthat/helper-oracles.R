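# Independent oracles used to validate the package's own algorithms.
# These deliberately use different algorithmic routes from the implementation:
# the repeat oracle scans every rotation of the genome (O(L^2)), and the
# CIGAR oracle works by regular expressions on the raw string.

# Brute-force maximal exact repeat scan on a circular genome.
# For every shift d, positions matching their d-rotation are computed as a
# logical vector; maximal circular runs of TRUE of length >= minLen are
# repeats at distance d. Inverted repeats use anti-diagonals against the
# complement. Returns a canonical table (start1 < start2) comparable with
# findExactRepeats() output.
oracleRepeats <- function(genome, minLen,
                          orientations = c("direct", "inverted")) {
  s <- strsplit(as.character(genomeSeq(genome)), "")[[1]]
  L <- length(s)
  enc <- match(s, c("A", "C", "G", "T"))        # N -> NA, never matches
  cenc <- 5L - enc
  circ <- function(p) ((p - 1L) %% L) + 1L
  runsTRUE <- function(m) {
    if (all(m)) return(data.frame(start = 1L, len = L))
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    df <- data.frame(start = starts[r$values], len = r$lengths[r$values])
    if (nrow(df) >= 2L && m[1L] && m[L]) {
      first <- which(df$start == 1L)
      last <- which(df$start + df$len - 1L == L)
      df$len[last] <- df$len[last] + df$len[first]
      df <- df[-first, , drop = FALSE]
    }
    df
  }
  seen <- new.env()
  out <- list()
  keep <- function(a, b, len, ori) {
    lo <- min(a, b); hi <- max(a, b)
    key <- paste(ori, lo, hi, len)
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <<- data.frame(
      start1 = lo, start2 = hi, len = len, orientation = ori,
      stringsAsFactors = FALSE)
  }
  if ("direct" %in% orientations) {
    for (d in seq_len(L - 1L)) {
      sh <- enc[circ(seq_len(L) + d)]
      m <- !is.na(enc) & !is.na(sh) & enc == sh
      if (sum(m) < minLen) next
      runs <- runsTRUE(m)
      runs <- runs[runs$len >= minLen & runs$len < L, , drop = FALSE]
      for (i in seq_len(nrow(runs))) {
        a <- runs$start[i]; len <- runs$len[i]; b <- circ(a + d)
        if ((b - a) %% L < len || (a - b) %% L < len) next  # overlap
        keep(a, b, len, "direct")
      }
    }
  }
  if ("inverted" %in% orientations) {
    for (cc in seq_len(L)) {
      q <- circ(cc - seq_len(L))
      pm <- cenc[q]
      m <- !is.na(enc) & !is.na(pm) & enc == pm
      if (sum(m) < minLen) next
      runs <- runsTRUE(m)
      runs <- runs[runs$len >= minLen & runs$len < L, , drop = FALSE]
      for (i in seq_len(nrow(runs))) {
        a <- runs$start[i]; len <- runs$len[i]
        b <- circ(cc - (a + len - 1L))
        if (a == b) next
        if ((b - a) %% L < len || (a - b) %% L < len) next
        keep(a, b, len, "inverted")
      }
    }
  }
  if (!length(out))
    return(data.frame(start1 = integer(), start2 = integer(),
                      len = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$start1, tab$start2, tab$orientation), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# canonical form of a findExactRepeats() table for oracle comparison
canonRepeats <- function(tab) {
  if (!nrow(tab))
    return(data.frame(start1 = integer(), start2 = integer(),
                      len = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(start1 = tab$copy1_start, start2 = tab$copy2_start,
                    len = tab$length, orientation = tab$orientation,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start1, out$start2, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Regex oracle for the soft-clip filter: accept iff the CIGAR contains a
# soft clip of at least minClip nucleotides and no I, D or H operation.
oracleClipFilter <- function(cigar, minClip = 20L) {
  if (grepl("[IDH]", cigar)) return(FALSE)
  s <- regmatches(cigar, gregexpr("[0-9]+(?=S)", cigar, perl = TRUE))[[1]]
  length(s) > 0 && any(as.integer(s) >= minClip)
}

# Random mapped-read CIGAR following the SAM grammar (clips only terminal,
# hard clips outermost), covering all op types the reader accepts.
randomCigar <- function() {
  lens <- function(n) sample(1:80, n, replace = TRUE)
  mid <- character()
  nblock <- sample(1:4, 1)
  core <- sample(c("M", "=", "X"), nblock, replace = TRUE)
  if (nblock > 1) {
    gaps <- sample(c("I", "D", "N"), nblock - 1, replace = TRUE)
    mid <- c(rbind(core[-nblock], gaps), core[nblock])
  } else mid <- core
  ops <- mid
  if (stats::runif(1) < 0.5) ops <- c("S", ops)
  if (stats::runif(1) < 0.5) ops <- c(ops, "S")
  if (stats::runif(1) < 0.15) ops <- c("H", ops)
  if (stats::runif(1) < 0.15) ops <- c(ops, "H")
  paste0(lens(length(ops)), ops, collapse = "")
}
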