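## End-to-end orchestration: simulate (or ingest) -> align -> coverage ->
## junctions -> crossovers, with every intermediate written to disk and a
## manifest recording parameters, seed and file checksums. Identical config
## and seed give byte-identical outputs.

#' Build a pipeline run configuration
#'
#' A run analyses one `sample` library, optionally against a `control`
#' library, on one circular genome. Each library block must name exactly
#' one input source: `simulate` (a list of [subgenomeSpec()]), `fastq`
#' (character vector of the two mate files) or `sam` (one path).
#'
#' @param genome a [CircularGenome-class] or FASTA path (first record).
#' @param sample,control library blocks, e.g.
#'   `list(simulate = list(subgenomeSpec(...)))`,
#'   `list(fastq = c("r1.fq", "r2.fq"))` or `list(sam = "aln.sam")`;
#'   `control` may be NULL (coverage comparison and crossover fold changes
#'   are then skipped).
#' @param mode "mtDNA-like" (no isomerization filter) or "cpDNA-like"
#'   (junction events across detected large inverted repeats are filtered).
#' @param outDir output directory (created if missing).
#' @param seed integer seed driving simulation and alignment tie-breaks.
#' @param library,align,clip parameter blocks ([libraryParams()],
#'   [alignParams()], [clipFilterParams()]).
#' @param minRepeatLen minimum repeat length for [findExactRepeats()].
#' @param flagThreshold |log2| threshold for [compareProfiles()].
#' @param flank flank width for [classifySpanningPairs()].
#' @param nominalLibrarySize library size used to normalize coverage of
#'   both libraries. Real organellar libraries are a small slice of a
#'   whole-plant run, so "per million total reads" leaves unchanged regions
#'   comparable across samples; a purely organellar simulated library must
#'   emulate that with a fixed nominal size (default 1e6). Set NULL to
#'   normalize by each library's own read count (external whole-library
#'   data).
#' @return validated `RunConfig` list.
#' @export
runConfig <- function(genome, sample, control = NULL,
                      mode = c("mtDNA-like", "cpDNA-like"),
                      outDir = "orgrecomb_run", seed = 1L,
                      library = libraryParams(), align = alignParams(),
                      clip = clipFilterParams(), minRepeatLen = 50L,
                      flagThreshold = 1, flank = 300L,
                      nominalLibrarySize = 1e6) {
  mode <- match.arg(mode)
  checkLib <- function(block, what) {
    src <- intersect(names(block), c("simulate", "fastq", "sam"))
    if (length(src) != 1L)
      stop("config error: '", what, "' must have exactly one input ",
           "source among simulate/fastq/sam (found ",
           if (length(src)) paste(src, collapse = "+") else "none", ")")
    src
  }
  checkLib(sample, "sample")
  if (!is.null(control)) checkLib(control, "control")
  structure(list(genome = genome, sample = sample, control = control,
                 mode = mode, outDir = outDir, seed = as.integer(seed),
                 library = library, align = align, clip = clip,
                 minRepeatLen = as.integer(minRepeatLen),
                 flagThreshold = flagThreshold, flank = as.integer(flank),
                 nominalLibrarySize = nominalLibrarySize),
            class = "RunConfig")
}

#' Read a pipeline configuration from JSON
#'
#' Same fields as [runConfig()]; `simulate` blocks are lists of
#' `{kind, weight, repeatId | breakpoints}` objects and the genome is a
#' FASTA path.
#'
#' @param path JSON file.
#' @return validated `RunConfig`.
#' @export
readRunConfig <- function(path) {
  cf <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  lib <- function(block) {
    if (is.null(block)) return(NULL)
    if (!is.null(block$simulate))
      block$simulate <- lapply(block$simulate, function(s)
        subgenomeSpec(kind = s$kind, weight = s$weight,
                      repeatId = s$repeatId,
                      breakpoints = unlist(s$breakpoints)))
    block
  }
  args <- list(genome = cf$genome, sample = lib(cf$sample),
               control = lib(cf$control))
  for (f in c("mode", "outDir", "seed", "minRepeatLen", "flagThreshold",
              "flank", "nominalLibrarySize"))
    if (!is.null(cf[[f]])) args[[f]] <- cf[[f]]
  if (!is.null(cf$library)) args$library <- do.call(libraryParams, cf$library)
  if (!is.null(cf$align)) args$align <- do.call(alignParams, cf$align)
  if (!is.null(cf$clip)) args$clip <- do.call(clipFilterParams, cf$clip)
  do.call(runConfig, args)
}

## run one library block through simulate/ingest + align; returns records,
## totalReads, truth (or NULL), and the files it wrote
.runLibrary <- function(label, block, genome, repeats, config, dir) {
  files <- character()
  truth <- NULL
  if (!is.null(block$simulate)) {
    mix <- buildMixture(genome, block$simulate, repeats,
                        readLength = config$library$readLength,
                        label = label)
    params <- config$library
    params$seed <- config$seed + match(label, c("sample", "control"))
    sim <- simulateReads(mix, params)
    truth <- sim$truth
    fq <- writeFastqPair(sim, file.path(dir, label))
    truthPath <- file.path(dir, paste0(label, "_truth.json"))
    writeTruthSet(truth, truthPath)
    files <- c(files, fq, truthPath)
    recs <- withSeed(config$seed + 100L,
                     pairMates(genome, sim$reads, config$align))
  } else if (!is.null(block$fastq)) {
    recs <- withSeed(config$seed + 100L,
                     alignPairs(genome, block$fastq[1], block$fastq[2],
                                config$align))
  } else {
    recs <- readSam(block$sam, refName = genomeName(genome))
  }
  samPath <- file.path(dir, paste0(label, ".sam"))
  writeSam(recs, genome, samPath)
  files <- c(files, samPath)
  list(records = recs, totalReads = nrow(recs), truth = truth,
       files = files)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: repeat discovery on the genome; per-library input
#' (simulation, FASTQ alignment or SAM ingestion); per-kb coverage
#' profiling; sample/control stoichiometry comparison; soft-clip junction
#' detection (with isomerization filtering in cpDNA-like mode); and
#' parental/crossover quantification over every direct intermediate-size or
#' large repeat pair. All intermediates are written under `config$outDir`
#' and a `manifest.json` records the parameters, seed and an md5 checksum
#' of every output, so a run is reproducible and auditable. A failing stage
#' aborts with the stage name; outputs of completed stages are preserved.
#'
#' @param config a `RunConfig` ([runConfig()] / [readRunConfig()]).
#' @return (invisibly) list with `repeats`, `profiles`, `comparison`,
#'   `junctions`, `eventsPerCopy`, `quant`, `manifest`.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) stop("config must be a RunConfig")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load-genome"
  result <- tryCatch({
    genome <- if (is(config$genome, "CircularGenome")) config$genome
              else readGenomeFasta(config$genome)[[1]]
    files <- character()

    stage <- "repeats"
    repeats <- findExactRepeats(genome, minLen = config$minRepeatLen)
    f <- file.path(config$outDir, "repeats.tsv")
    writeRepeatTable(repeats, f); files <- c(files, f)

    stage <- "sample-library"
    smp <- .runLibrary("sample", config$sample, genome, repeats, config,
                       config$outDir)
    files <- c(files, smp$files)
    ctl <- NULL
    if (!is.null(config$control)) {
      stage <- "control-library"
      ctl <- .runLibrary("control", config$control, genome, repeats,
                         config, config$outDir)
      files <- c(files, ctl$files)
    }

    stage <- "coverage"
    nls <- config$nominalLibrarySize
    profS <- binCoverage(smp$records, genome,
                         if (is.null(nls)) smp$totalReads else nls)
    f <- file.path(config$outDir, "sample_coverage.tsv")
    writeProfileTable(profS, f); files <- c(files, f)
    comparison <- NULL
    if (!is.null(ctl)) {
      profC <- binCoverage(ctl$records, genome,
                           if (is.null(nls)) ctl$totalReads else nls)
      f <- file.path(config$outDir, "control_coverage.tsv")
      writeProfileTable(profC, f); files <- c(files, f)
      comparison <- compareProfiles(profS, profC,
                                    flagThreshold = config$flagThreshold,
                                    repeats = repeats,
                                    readLength = config$library$readLength)
      f <- file.path(config$outDir, "stoichiometry.tsv")
      writeProfileTable(comparison, f); files <- c(files, f)
      f <- file.path(config$outDir, "flagged_regions.tsv")
      utils::write.table(flaggedRegions(comparison), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }

    stage <- "junctions"
    irFilter <- if (config$mode == "cpDNA-like") repeats else NULL
    jn <- withSeed(config$seed + 200L,
                   detectJunctions(smp$records, genome, irFilter,
                                   clipParams = config$clip,
                                   alnParams = config$align))
    f <- file.path(config$outDir, "junctions.tsv")
    writeJunctionTable(jn$events, f); files <- c(files, f)
    epc <- eventsPerGenomeCopy(jn$events, profS)

    stage <- "crossovers"
    quant <- NULL
    direct <- repeats[repeats$orientation == "direct" &
                      repeats$size_class != "micro", , drop = FALSE]
    quantRows <- list()
    for (i in seq_len(nrow(direct))) {
      cs <- tryCatch(classifySpanningPairs(smp$records, direct[i, ],
                                           genome, config$flank),
                     error = function(e) NULL)
      if (is.null(cs)) next
      if (!is.null(ctl)) {
        cc <- tryCatch(classifySpanningPairs(ctl$records, direct[i, ],
                                             genome, config$flank),
                       error = function(e) NULL)
        if (!is.null(cc) && informativePairs(cs) > 0L &&
            informativePairs(cc) > 0L)
          quantRows[[length(quantRows) + 1L]] <- relativeAccumulation(cs, cc)
      } else {
        quantRows[[length(quantRows) + 1L]] <- data.frame(
          repeat_id = direct$id[i], config = names(configCounts(cs)),
          x_sample = unname(configCounts(cs)),
          n_sample = informativePairs(cs), stringsAsFactors = FALSE)
      }
    }
    if (length(quantRows)) {
      quant <- do.call(rbind, quantRows)
      f <- file.path(config$outDir, "crossovers.tsv")
      writeQuantTable(quant, f); files <- c(files, f)
    }

    stage <- "manifest"
    manifest <- list(
      package = "orgRecomb",
      version = as.character(utils::packageVersion("orgRecomb")),
      seed = config$seed, mode = config$mode,
      genome = list(name = genomeName(genome),
                    length = genomeLength(genome)),
      parameters = list(library = config$library, align = config$align,
                        clip = config$clip,
                        minRepeatLen = config$minRepeatLen,
                        flagThreshold = config$flagThreshold,
                        flank = config$flank),
      events_per_genome_copy = epc,
      outputs = as.list(tools::md5sum(sort(files))))
    mf <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    list(repeats = repeats, profiles = list(sample = profS,
         control = if (!is.null(ctl)) profC),
         comparison = comparison, junctions = jn, eventsPerCopy = epc,
         quant = quant, manifest = manifest,
         truth = list(sample = smp$truth,
                      control = if (!is.null(ctl)) ctl$truth))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
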