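# Accessors and show methods.

#' @describeIn HgtSimulation the assembly scaffolds under scrutiny.
#' @param x,object an object.
#' @param ... unused.
#' @export
setMethod("scaffolds", "HgtSimulation", function(x, ...) x@assembly)

#' @describeIn HgtSimulation per-base depth tracks (RleList).
#' @export
setMethod("depthTracks", "HgtSimulation", function(x, ...) x@depth)

#' @describeIn HgtSimulation taxon-annotated similarity hit table.
#' @export
setMethod("taxonHits", "HgtSimulation", function(x, ...) x@hits)

#' @describeIn HgtSimulation truth tables (planted insertions, chimera
#'   junctions, strain variant sites).
#' @export
setMethod("truthTable", "HgtSimulation", function(x, ...) x@truth)

#' @describeIn HgtSimulation the configuration used.
#' @export
setMethod("simConfig", "HgtSimulation", function(x, ...) x@config)

#' @describeIn HgtSimulation list of alternative assemblies.
#' @export
setMethod("altAssemblies", "HgtSimulation", function(x, ...) x@altAssemblies)

#' @export
setMethod("show", "HgtSimulation", function(object) {
    cfg <- object@config
    cat("HgtSimulation with", length(object@assembly), "assembly scaffolds\n")
    cat("  host:", cfg@hostScaffolds, "scaffolds,",
        format(cfg@hostLength, big.mark = ","), "bp, GC",
        cfg@hostGc, ", depth", cfg@hostDepth, "x\n")
    cat("  symbiont:", cfg@symbiontScaffolds, "scaffolds,",
        format(cfg@symbiontLength, big.mark = ","), "bp, GC",
        cfg@symbiontGc, ", depth", cfg@symbiontDepth, "x\n")
    cat("  planted insertions:", length(object@truth$insertions),
        "; chimeras:", nrow(object@truth$chimeras),
        "; alt assemblies:", length(object@altAssemblies), "\n")
    cat("  seed:", cfg@seed, "\n")
})

#' @describeIn HgtCallSet the calls as a GRanges with evidence columns.
#' @param x,object an object.
#' @param ... unused.
#' @export
setMethod("hgtCalls", "HgtCallSet", function(x, ...) x@calls)

#' @describeIn HgtCallSet the per-scaffold classification table.
#' @export
setMethod("classification", "HgtCallSet", function(x, ...) x@classification)

#' @describeIn HgtCallSet a flat data.frame report, one row per call:
#'   scaffold, interval, length, verdict, junction log2 depth ratios,
#'   corroborations, transposase distance, overlapping and transcribed genes.
#' @export
setMethod("callReport", "HgtCallSet", function(x, ...) {
    gr <- x@calls
    if (length(gr) == 0) {
        return(data.frame(scaffold = character(), start = integer(),
                          end = integer(), length = integer(),
                          verdict = character(), junctions = character(),
                          corroborations = integer(),
                          transposaseDistance = integer(),
                          nGenes = integer(), nTranscribed = integer(),
                          notes = character(), stringsAsFactors = FALSE))
    }
    data.frame(
        scaffold = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        length = GenomicRanges::width(gr),
        verdict = gr$verdict,
        junctions = vapply(gr$junctions, function(j) {
            if (nrow(j) == 0) return("none")
            paste(sprintf("%d:%s(%.2f)", j$position, j$verdict, j$log2Ratio),
                  collapse = ";")
        }, character(1)),
        corroborations = gr$corroborations,
        transposaseDistance = gr$transposaseDistance,
        nGenes = lengths(gr$genes),
        nTranscribed = lengths(gr$transcribed),
        notes = gr$notes,
        stringsAsFactors = FALSE)
})

#' @export
setMethod("show", "HgtCallSet", function(object) {
    v <- if (length(object@calls)) object@calls$verdict else character()
    cat("HgtCallSet with", length(object@calls), "calls on",
        sum(object@classification$label == "hgt_candidate"),
        "candidate scaffolds\n")
    if (length(v)) {
        tab <- table(v)
        cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
    }
    cat("  scaffolds classified:",
        paste(names(table(object@classification$label)),
              table(object@classification$label),
              sep = "=", collapse = ", "), "\n")
})

#' @describeIn StrainEvidenceReport TRUE if the assembly shows multi-strain
#'   evidence.
#' @param x,object an object.
#' @param ... unused.
#' @export
setMethod("multiStrain", "StrainEvidenceReport", function(x, ...)
    x@multiStrain)

#' @export
setMethod("show", "StrainEvidenceReport", function(object) {
    cat("StrainEvidenceReport (", object@nSingleCopyTotal,
        "single-copy genes examined )\n")
    cat("  duplicated single-copy genes: ", object@nDuplicated, "\n")
    cat("  polymorphic single-copy genes:", object@nPolymorphic, "\n")
    cat("  duplicated markers:          ",
        if (length(object@duplicatedMarkers))
            paste(object@duplicatedMarkers, collapse = ", ") else "none",
        "\n")
    cat("  multi-strain flag:           ", object@multiStrain, "\n")
})

#' @export
setMethod("show", "AssemblyStats", function(object) {
    cat("AssemblyStats\n")
    cat("  Total length:", format(object@totalLength, big.mark = ","),
        "bp in", object@nContigs, "contigs\n")
    cat("  N50:", format(object@n50, big.mark = ","),
        "bp  L50:", object@l50, "\n")
    cat("  N75:", format(object@n75, big.mark = ","),
        "bp  L75:", object@l75, "\n")
    cat("  GC (%):", sprintf("%.2f", object@gcPercent), "\n")
    for (i in seq_len(nrow(object@countsGe)))
        cat(sprintf("  Contigs (>= %d bp): %d (%.2f%% genome)\n",
                    object@countsGe$threshold[i], object@countsGe$count[i],
                    100 * object@countsGe$fraction[i]))
})
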