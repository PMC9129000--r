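## Rearrangement junction detection from soft-clipped reads.
##
## A read spanning the junction of a rearranged molecule aligns partially
## (the anchor) with the remainder soft-clipped; remapping the clip locates
## the junction partner. The workflow: (1) keep mapped reads whose CIGAR
## has a soft clip of at least 20 nt and no I/D/H operation; (2) extract
## the clipped sequence(s); (3) remap each clip end-to-end, dropping
## unplaceable or non-unique clips; (4) bin anchor breakpoint and clip
## position to 1 kb and count supporting reads per (anchor bin, clip bin,
## orientation); (5) in chloroplast mode, discard events explained by
## flip-flop isomerization across the large inverted repeat.

#' Soft-clip filter parameters
#'
#' @param minClip minimum soft-clip length in nt retained for junction
#'   analysis (>= 1; default 20).
#' @return a `ClipFilterParams` list. The forbidden operations (I, D, H)
#'   and the required operation (S) are fixed by the filter's definition.
#' @export
clipFilterParams <- function(minClip = 20L) {
  stopifnot(minClip >= 1L)
  list(minClip = as.integer(minClip),
       forbiddenOps = c("I", "D", "H"), requiredOp = "S")
}

#' Test a record against the soft-clip filter
#'
#' Accepts a mapped record iff its CIGAR contains at least one soft clip
#' (S) of length >= `minClip` and no insertion, deletion or hard clip
#' (I, D, H). Pure predicate plus clip descriptors; never errors.
#'
#' @param record one-row alignment record data.frame (or a list with
#'   `cigar`, `seq`, `pos` fields).
#' @param params [clipFilterParams()].
#' @return list: `accept` (logical) and `clips`, a data.frame with one row
#'   per qualifying clip: side ("left"/"right"), clip_len, clip_seq and
#'   anchor_breakpoint (genome position where the aligned block ends on the
#'   clipped side).
#' @export
passesClipFilter <- function(record, params = clipFilterParams()) {
  rec <- if (is.data.frame(record)) as.list(record[1L, ]) else record
  empty <- data.frame(side = character(), clip_len = integer(),
                      clip_seq = character(),
                      anchor_breakpoint = integer(),
                      stringsAsFactors = FALSE)
  if (identical(rec$cigar, "*") || isFALSE(rec$mapped))
    return(list(accept = FALSE, clips = empty))
  ops <- parseCigar(rec$cigar)
  if (any(ops$op %in% params$forbiddenOps))
    return(list(accept = FALSE, clips = empty))
  nop <- nrow(ops)
  sIdx <- which(ops$op == "S" & ops$len >= params$minClip)
  sIdx <- sIdx[sIdx %in% c(1L, nop)]         # terminal clips only
  if (!length(sIdx)) return(list(accept = FALSE, clips = empty))
  refLen <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  n <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  clips <- lapply(sIdx, function(i) {
    if (i == 1L) {
      data.frame(side = "left", clip_len = ops$len[i],
                 clip_seq = substr(rec$seq, 1L, ops$len[i]),
                 anchor_breakpoint = rec$pos, stringsAsFactors = FALSE)
    } else {
      data.frame(side = "right", clip_len = ops$len[i],
                 clip_seq = substr(rec$seq, n - ops$len[i] + 1L, n),
                 anchor_breakpoint = rec$pos + refLen - 1L,
                 stringsAsFactors = FALSE)
    }
  })
  list(accept = TRUE, clips = do.call(rbind, clips))
}

#' Extract qualifying clips from a set of alignment records
#'
#' Applies [passesClipFilter()] to every mapped record and collects the
#' clip descriptors. Records whose anchor placement is not unique are
#' dropped (multi-mapped anchors cannot locate a junction) and counted.
#'
#' @param records alignment record data.frame.
#' @param genome the [CircularGenome-class] (for modular breakpoints).
#' @param params [clipFilterParams()].
#' @return list: `clips` data.frame (read_id, mate, side, clip_len,
#'   clip_seq, anchor_breakpoint, anchor_strand) and `stats` (named counts:
#'   records_in, non_unique_anchor, accepted_reads, clips_extracted).
#' @export
extractClips <- function(records, genome, params = clipFilterParams()) {
  L <- genomeLength(genome)
  mapped <- records[records$mapped, , drop = FALSE]
  ## cheap prefilter: only records whose CIGAR mentions S can pass
  mapped <- mapped[grepl("S", mapped$cigar, fixed = TRUE), , drop = FALSE]
  nonUnique <- 0L
  out <- list()
  for (i in seq_len(nrow(mapped))) {
    res <- passesClipFilter(as.list(mapped[i, ]), params)
    if (!res$accept) next
    if (!mapped$is_unique[i]) { nonUnique <- nonUnique + 1L; next }
    cl <- res$clips
    cl$read_id <- mapped$read_id[i]
    cl$mate <- mapped$mate[i]
    cl$anchor_strand <- mapped$strand[i]
    cl$anchor_breakpoint <- circPos(cl$anchor_breakpoint, L)
    out[[length(out) + 1L]] <- cl
  }
  clips <- if (length(out)) do.call(rbind, out) else
    data.frame(side = character(), clip_len = integer(),
               clip_seq = character(), anchor_breakpoint = integer(),
               read_id = character(), mate = integer(),
               anchor_strand = character(), stringsAsFactors = FALSE)
  list(clips = clips,
       stats = c(records_in = nrow(records),
                 non_unique_anchor = nonUnique,
                 accepted_reads = length(out),
                 clips_extracted = nrow(clips)))
}

#' Remap clipped sequences onto the genome
#'
#' Each clip is aligned as an independent segment and kept only when the
#' ENTIRE clip aligns (no further clipping) within the mismatch-rate bound
#' and at a unique position — the strict equivalent of remapping clips with
#' an end-to-end aligner and discarding partial or ambiguous placements.
#' Dropped clips are counted, not errors.
#'
#' @param clips `extractClips()$clips` data.frame.
#' @param genome [CircularGenome-class] or [buildGenomeIndex()] index.
#' @param params [alignParams()]; the seed length is capped at the shortest
#'   clip so short clips remain seedable.
#' @return list: `placed` (clips with clip_pos, clip_end, clip_strand,
#'   junction_pos — the mapped position of the clip base adjacent to the
#'   junction — and orientation relative to the anchor) and `stats` (drop
#'   counts: unmapped, partial, non_unique).
#' @export
mapClips <- function(clips, genome, params = alignParams()) {
  stats <- c(clips_in = nrow(clips), unmapped = 0L, partial = 0L,
             non_unique = 0L, placed = 0L)
  placedRows <- list()
  if (nrow(clips)) {
    params <- alignParams(
      seedLength = max(15L, min(params$seedLength, min(clips$clip_len))),
      maxMismatchRate = params$maxMismatchRate,
      minAnchor = max(15L, min(params$minAnchor, min(clips$clip_len))))
    index <- if (is(genome, "CircularGenome"))
      buildGenomeIndex(genome, params) else genome
    L <- index$L
    for (i in seq_len(nrow(clips))) {
      a <- .alignOne(index, clips$read_id[i], 0L, clips$clip_seq[i])
      if (!a$mapped) { stats["unmapped"] <- stats["unmapped"] + 1L; next }
      if (a$cigar != paste0(clips$clip_len[i], "M")) {
        stats["partial"] <- stats["partial"] + 1L; next
      }
      if (!a$is_unique) {
        stats["non_unique"] <- stats["non_unique"] + 1L; next
      }
      row <- clips[i, , drop = FALSE]
      row$clip_pos <- a$pos
      row$clip_end <- circPos(a$pos + clips$clip_len[i] - 1L, L)
      row$clip_strand <- a$strand
      ## the clip base that abuts the junction: for a right clip its first
      ## base (read order), for a left clip its last base
      row$junction_pos <- if (row$side == "right") {
        if (a$strand == "+") row$clip_pos else row$clip_end
      } else {
        if (a$strand == "+") row$clip_end else row$clip_pos
      }
      ## clip_seq was taken from the SAM-oriented (reference-forward) read,
      ## so the junction joins reference-forward sequence to the clip:
      ## a "+" clip placement means a same-strand fusion irrespective of
      ## which strand the anchor read came from
      row$orientation <- if (row$clip_strand == "+")
        "same_strand" else "opposite_strand"
      placedRows[[length(placedRows) + 1L]] <- row
    }
  }
  placed <- if (length(placedRows)) do.call(rbind, placedRows) else
    cbind(clips[0, , drop = FALSE],
          data.frame(clip_pos = integer(), clip_end = integer(),
                     clip_strand = character(), junction_pos = integer(),
                     orientation = character(), stringsAsFactors = FALSE))
  stats["placed"] <- nrow(placed)
  rownames(placed) <- NULL
  list(placed = placed, stats = stats)
}

#' Call junction events from placed clips
#'
#' Bins the anchor breakpoint and the clip's junction-side position to
#' 1 kb and groups by (anchor bin, clip bin, orientation); support is the
#' number of distinct reads. The bin pair is canonicalised with
#' anchor_bin <= clip_bin so the two read orientations across one junction
#' merge into a single event. Events are ordered by decreasing support,
#' then coordinates.
#'
#' @param placed `mapClips()$placed` data.frame.
#' @return data.frame: anchor_bin, clip_bin, orientation, support,
#'   is_isomerization (initialised FALSE).
#' @export
callJunctions <- function(placed) {
  empty <- data.frame(anchor_bin = integer(), clip_bin = integer(),
                      orientation = character(), support = integer(),
                      is_isomerization = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(placed)) return(empty)
  a <- positionToBin(placed$anchor_breakpoint)
  b <- positionToBin(placed$junction_pos)
  key <- data.frame(anchor_bin = pmin(a, b), clip_bin = pmax(a, b),
                    orientation = placed$orientation,
                    read_id = placed$read_id, stringsAsFactors = FALSE)
  agg <- stats::aggregate(read_id ~ anchor_bin + clip_bin + orientation,
                          key, function(x) length(unique(x)))
  names(agg)[4] <- "support"
  agg$is_isomerization <- FALSE
  agg <- agg[order(-agg$support, agg$anchor_bin, agg$clip_bin,
                   agg$orientation), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Flag junction events explained by inverted-repeat isomerization
#'
#' Chloroplast genomes interconvert between two isomers by recombination
#' across the large inverted repeat; the resulting junctions are a normal
#' feature, not rearrangements of interest. An event is flagged when its
#' bin pair lies within one bin of the corresponding boundaries of a large
#' (> 500 bp) inverted repeat pair — inner boundary of one copy with inner
#' boundary of the other, or outer with outer — with opposite-strand
#' orientation. With an empty repeat list (mitochondrial mode) no event is
#' flagged.
#'
#' @param events [callJunctions()] table.
#' @param repeats repeat table; only rows with orientation "inverted" and
#'   size_class "large" are considered.
#' @return the events table with `is_isomerization` set.
#' @export
filterIsomerization <- function(events, repeats = NULL) {
  if (!nrow(events)) return(events)
  events$is_isomerization <- FALSE
  if (is.null(repeats) || !nrow(repeats)) return(events)
  irs <- repeats[repeats$orientation == "inverted" &
                 repeats$size_class == "large", , drop = FALSE]
  for (j in seq_len(nrow(irs))) {
    p <- as.list(irs[j, ])
    pairsOf <- list(inner = c(positionToBin(p$copy1_end),
                              positionToBin(p$copy2_start)),
                    outer = c(positionToBin(p$copy1_start),
                              positionToBin(p$copy2_end)))
    for (bp in pairsOf) {
      lo <- min(bp); hi <- max(bp)
      hit <- events$orientation == "opposite_strand" &
        abs(events$anchor_bin - lo) <= 1L & abs(events$clip_bin - hi) <= 1L
      events$is_isomerization <- events$is_isomerization | hit
    }
  }
  events
}

#' Junction events per genome copy
#'
#' Total read support of retained (non-isomerization) events divided by the
#' genome's mean per-base depth — "how many rearranged molecules exist per
#' copy of the genome". Values well below 1 indicate rearrangements too
#' rare to matter phenotypically.
#'
#' @param events events table with `is_isomerization` set.
#' @param profile [CoverageProfile-class] of the same library.
#' @return a single number.
#' @export
eventsPerGenomeCopy <- function(events, profile) {
  depth <- meanGenomeDepth(profile)
  if (depth == 0) stop("zero mean depth: profile has no aligned bases")
  if (!nrow(events)) return(0)
  sum(events$support[!events$is_isomerization]) / depth
}

#' Run the full soft-clip junction workflow on aligned records
#'
#' Convenience wrapper: [extractClips()] -> [mapClips()] ->
#' [callJunctions()] -> [filterIsomerization()].
#'
#' @param records alignment record data.frame.
#' @param genome [CircularGenome-class].
#' @param repeats repeat table for the isomerization filter (NULL for
#'   mitochondrial mode).
#' @param clipParams [clipFilterParams()].
#' @param alnParams [alignParams()] used for clip remapping.
#' @return list: `events`, `stats` (concatenated drop statistics),
#'   `placed` clips.
#' @export
detectJunctions <- function(records, genome, repeats = NULL,
                            clipParams = clipFilterParams(),
                            alnParams = alignParams()) {
  ex <- extractClips(records, genome, clipParams)
  mp <- mapClips(ex$clips, genome, alnParams)
  ev <- filterIsomerization(callJunctions(mp$placed), repeats)
  list(events = ev, stats = c(ex$stats, mp$stats), placed = mp$placed)
}

#' Write junction events as TSV
#'
#' @param events events table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJunctionTable <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
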