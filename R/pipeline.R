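# End-to-end orchestration: simulate -> classify -> detect -> report, both
# in memory and over files.

#' Run classification and detection on an in-memory simulation
#'
#' Convenience wrapper chaining [classifyAssembly()] and [detectHgt()] on an
#' [HgtSimulation-class] object.
#'
#' @param sim an [HgtSimulation-class].
#' @param params see [hgtParams()].
#' @return an [HgtCallSet-class].
#' @export
#' @examples
#' sim <- simulateHgtExperiment(simulationConfig(seed = 7, hostLength = 2e5,
#'     hostScaffolds = 2, symbiontLength = 1e5, symbiontScaffolds = 1,
#'     nInsertions = 1, insertionMax = 5000, chimeraCount = 1,
#'     chimeraFragment = 10000))
#' analyzeSimulation(sim)
analyzeSimulation <- function(sim, params = hgtParams()) {
    classif <- classifyAssembly(sim@assembly, sim@hits, sim@depth, params)
    detectHgt(sim@assembly, classif, sim@depth, sim@hostRef,
              sim@symbiontRef, features = sim@features, fpkm = sim@fpkm,
              altAssemblies = sim@altAssemblies, params = params)
}

#' Write a simulated experiment bundle to disk
#'
#' Materialises every pipeline input of an [HgtSimulation-class] in the
#' standard formats (FASTA assembly and references, depth TSV, BLAST-tabular
#' hits with a taxon map, GFF3 features, FPKM TSV, alternative-assembly
#' FASTAs, truth BED/TSV, optionally FASTQ reads), plus a manifest with md5
#' checksums. Deterministic for a fixed configuration seed.
#'
#' @param config a [SimulationConfig-class] (seed mandatory), or an already
#'   generated [HgtSimulation-class].
#' @param outDir output directory (created if needed).
#' @param fastq also write simulated reads as FASTQ (large; the depth tracks,
#'   not the reads, carry the detection evidence).
#' @return invisibly, the [HgtSimulation-class] with the file manifest in
#'   `metadata`-style attribute `files`.
#' @export
runSimulate <- function(config, outDir, fastq = FALSE) {
    sim <- if (methods::is(config, "HgtSimulation")) config
           else simulateHgtExperiment(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(outDir, x)

    writeFastaScaffolds(sim@assembly, fp("assembly.fasta"))
    writeFastaScaffolds(sim@hostRef, fp("host_ref.fasta"))
    writeFastaScaffolds(sim@symbiontRef, fp("symbiont_ref.fasta"))
    for (i in seq_along(sim@altAssemblies))
        writeFastaScaffolds(sim@altAssemblies[[i]],
                            fp(sprintf("alt_assembly_%d.fasta", i)))
    writeDepthTsv(sim@depth, fp("depth.tsv"))
    writeTabularHits(sim@hits, fp("hits.tsv"))
    tm <- c(stats::setNames(rep("host", length(sim@hostRef)),
                            names(sim@hostRef)),
            stats::setNames(rep("symbiont", length(sim@symbiontRef)),
                            names(sim@symbiontRef)))
    data.table::fwrite(data.table::data.table(subject = names(tm),
                                              taxon = unname(tm)),
                       fp("taxon_map.tsv"), sep = "\t", col.names = FALSE)
    if (length(sim@features))
        writeGffFeatures(sim@features, fp("features.gff3"))
    writeFpkmTsv(sim@fpkm, fp("fpkm.tsv"))
    truthIns <- sim@truth$insertions
    if (length(truthIns)) truthIns$name <- paste0("insertion",
                                                  seq_along(truthIns))
    writeBedCalls(truthIns, fp("truth_insertions.bed"))
    data.table::fwrite(sim@truth$chimeras, fp("truth_chimeras.tsv"),
                       sep = "\t")
    if (fastq) {
        cfg <- sim@config
        reads <- simulateReads(sim@assembly,
            ifelse(grepl("^wsc", names(sim@assembly)),
                   cfg@symbiontDepth, cfg@hostDepth),
            readLength = cfg@readLength, emitReads = TRUE,
            errorRate = cfg@errorRate)$reads
        writeSimulatedFastq(reads, fp("reads.fastq"))
    }
    files <- list.files(outDir, full.names = TRUE)
    files <- files[basename(files) != "manifest.tsv"]
    manifest <- data.table::data.table(file = basename(files),
                                       md5 = unname(tools::md5sum(files)))
    data.table::fwrite(manifest, fp("manifest.tsv"), sep = "\t")
    attr(sim, "files") <- c(files, fp("manifest.tsv"))
    invisible(sim)
}

#' Run the detection pipeline over files
#'
#' File-based front end: reads an assembly, hit table with taxon map, depth
#' tracks, features, expression table and alternative assemblies; runs TAGC
#' classification, HGT detection and assembly statistics; writes a
#' classification TSV, a calls BED, a tabular call report, a statistics
#' report, optionally a strain-evidence report, and a structured log of
#' every parameter value used. Exits cleanly (no error) when no calls are
#' made; raises an error on malformed inputs or on a scaffold id mismatch
#' between the depth file and the assembly.
#'
#' @param assemblyFasta,hostRefFasta,symbiontRefFasta FASTA paths.
#' @param hitsTsv BLAST-tabular hit table path.
#' @param taxonMapTsv two-column TSV `subject <TAB> taxon`.
#' @param depthTsv per-base depth TSV path.
#' @param outDir output directory.
#' @param featuresGff3 optional GFF3 path.
#' @param fpkmTsv optional FPKM TSV path.
#' @param altFastas character vector of alternative-assembly FASTA paths.
#' @param singleCopyPlacements,variantsTsv,markerPlacementsTsv optional
#'   strain-evidence inputs (TSVs with the column layouts of
#'   [duplicatedSingleCopy()], [polymorphicSingleCopy()] and
#'   [markerDuplication()]; variant columns: scaffold, position, refBase,
#'   altBase, refCount, altCount).
#' @param params see [hgtParams()].
#' @return invisibly, a list with `classification`, `calls`
#'   ([HgtCallSet-class]), `stats` ([AssemblyStats-class]) and `strain`
#'   (a [StrainEvidenceReport-class] or NULL).
#' @export
runPipeline <- function(assemblyFasta, hitsTsv, taxonMapTsv, depthTsv,
                        outDir, hostRefFasta = NULL, symbiontRefFasta = NULL,
                        featuresGff3 = NULL, fpkmTsv = NULL,
                        altFastas = character(),
                        singleCopyPlacements = NULL, variantsTsv = NULL,
                        markerPlacementsTsv = NULL,
                        params = hgtParams()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    assembly <- readFastaScaffolds(assemblyFasta)
    tmTab <- data.table::fread(taxonMapTsv, header = FALSE, sep = "\t",
                               col.names = c("subject", "taxon"))
    taxonMap <- stats::setNames(tmTab$taxon, tmTab$subject)
    hits <- readTabularHits(hitsTsv, taxonMap)
    depth <- readDepthTsv(depthTsv,
        stats::setNames(Biostrings::width(assembly), names(assembly)))
    features <- if (!is.null(featuresGff3)) readGffFeatures(featuresGff3)
                else GenomicRanges::GRanges()
    fpkm <- if (!is.null(fpkmTsv)) readFpkmTsv(fpkmTsv)
            else stats::setNames(numeric(), character())
    alts <- lapply(altFastas, readFastaScaffolds)
    hostRef <- if (!is.null(hostRefFasta)) readFastaScaffolds(hostRefFasta)
               else NULL
    symRef <- if (!is.null(symbiontRefFasta))
                  readFastaScaffolds(symbiontRefFasta) else NULL

    classif <- classifyAssembly(assembly, hits, depth, params)
    calls <- if (!is.null(hostRef) && !is.null(symRef))
        detectHgt(assembly, classif, depth, hostRef, symRef,
                  features = features, fpkm = fpkm, altAssemblies = alts,
                  params = params)
    else
        methods::new("HgtCallSet", calls = callHgt(.emptyEvidence(), params),
                     classification = classif, params = params)
    stats <- assemblyStats(assembly)

    strain <- NULL
    if (!is.null(singleCopyPlacements)) {
        pl <- data.table::fread(singleCopyPlacements, data.table = FALSE)
        vr <- if (!is.null(variantsTsv))
            data.table::fread(variantsTsv, data.table = FALSE)
        else data.frame(scaffold = character(), position = integer(),
                        refCount = integer(), altCount = integer())
        mp <- if (!is.null(markerPlacementsTsv))
            data.table::fread(markerPlacementsTsv, data.table = FALSE)
        else data.frame(markerId = character(), scaffold = character())
        genes <- features[features$featureType %in% c("gene", "marker")]
        strain <- strainReport(pl, vr, genes, mp)
    }

    fp <- function(x) file.path(outDir, x)
    utils::write.table(classif, fp("classifications.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gr <- hgtCalls(calls)
    bed <- gr[gr$verdict == "hgt"]
    if (length(bed)) bed$name <- paste0("hgt", seq_along(bed))
    writeBedCalls(bed, fp("hgt_calls.bed"))
    utils::write.table(callReport(calls), fp("hgt_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    statsDf <- data.frame(
        metric = c("total_length", "n_contigs", "n50", "n75", "l50", "l75",
                   "gc_percent"),
        value = c(stats@totalLength, stats@nContigs, stats@n50, stats@n75,
                  stats@l50, stats@l75, round(stats@gcPercent, 2)))
    utils::write.table(statsDf, fp("assembly_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(strain)) {
        con <- file(fp("strain_report.txt"), "w")
        sink(con); show(strain); sink(); close(con)
    }
    log <- c(sprintf("hgtscan run %s", format(Sys.time(), "%Y-%m-%dT%H:%M")),
             sprintf("input assembly: %s (%d scaffolds)", assemblyFasta,
                     length(assembly)),
             "parameters:",
             sprintf("  %s = %s", names(params),
                     vapply(params, format, character(1))))
    writeLines(log, fp("run_log.txt"))
    invisible(list(classification = classif, calls = calls, stats = stats,
                   strain = strain))
}

#' Compare calls against a simulation truth table
#'
#' Scores an [HgtCallSet-class] against the truth of the
#' [HgtSimulation-class] it was computed from: per planted insertion, whether
#' a call with verdict `hgt` recovers it and the worst junction boundary
#' error; false `hgt` calls (calls not matching any planted insertion);
#' and per constructed chimera, whether its scaffold received a
#' `chimera_suspect` verdict.
#'
#' @param calls an [HgtCallSet-class].
#' @param sim the [HgtSimulation-class] scored against.
#' @param tolerance maximum boundary error (bp) for an insertion to count as
#'   recovered.
#' @return list with `sensitivity`, `maxBoundaryError`, `falseHgtCalls`,
#'   `chimeraRecall`, and the per-insertion table `detail`.
#' @export
scoreAgainstTruth <- function(calls, sim, tolerance = 50) {
    truth <- sim@truth$insertions
    gr <- hgtCalls(calls)
    hgt <- gr[gr$verdict == "hgt"]
    detail <- data.frame(scaffold = character(), start = integer(),
                         end = integer(), recovered = logical(),
                         boundaryError = integer(), stringsAsFactors = FALSE)
    matched <- rep(FALSE, length(hgt))
    for (i in seq_along(truth)) {
        t <- truth[i]
        cand <- which(as.character(GenomicRanges::seqnames(hgt)) ==
                          as.character(GenomicRanges::seqnames(t)) &
                      abs(GenomicRanges::start(hgt) -
                          GenomicRanges::start(t)) <= tolerance &
                      abs(GenomicRanges::end(hgt) -
                          GenomicRanges::end(t)) <= tolerance)
        err <- if (length(cand)) min(pmax(
            abs(GenomicRanges::start(hgt)[cand] - GenomicRanges::start(t)),
            abs(GenomicRanges::end(hgt)[cand] - GenomicRanges::end(t))))
        else NA_integer_
        if (length(cand)) matched[cand[1]] <- TRUE
        detail <- rbind(detail, data.frame(
            scaffold = as.character(GenomicRanges::seqnames(t)),
            start = GenomicRanges::start(t), end = GenomicRanges::end(t),
            recovered = length(cand) > 0,
            boundaryError = err, stringsAsFactors = FALSE))
    }
    chim <- sim@truth$chimeras
    chimRecall <- if (nrow(chim) == 0) NA_real_ else {
        sus <- unique(as.character(GenomicRanges::seqnames(
            gr[gr$verdict == "chimera_suspect"])))
        mean(chim$scaffold %in% sus)
    }
    list(sensitivity = if (length(truth)) mean(detail$recovered) else NA,
         maxBoundaryError = if (any(detail$recovered))
             max(detail$boundaryError, na.rm = TRUE) else NA,
         falseHgtCalls = sum(!matched),
         chimeraRecall = chimRecall,
         detail = detail)
}
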