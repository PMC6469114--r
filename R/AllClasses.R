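# S4 class definitions.

#' Simulation configuration
#'
#' Parameters of the synthetic host/endosymbiont sequencing experiment that
#' the detection pipeline is validated against. The defaults emulate a wood-ant
#' host sequenced to moderate depth carrying a high-copy intracellular
#' *Wolbachia*-like endosymbiont: host GC 36%, symbiont GC 35.13%, host depth
#' 47.37x, symbiont depth 120x, insertions of 0.5--20 kb planted into the host
#' scaffolds, plus one chimeric scaffold whose read depth steps at the joint.
#'
#' @slot hostLength total host genome length (bp), split into `hostScaffolds`
#'   equally sized scaffolds.
#' @slot hostGc host GC fraction in (0, 1).
#' @slot hostScaffolds number of host scaffolds.
#' @slot symbiontLength total symbiont genome length (bp).
#' @slot symbiontGc symbiont GC fraction in (0, 1).
#' @slot symbiontScaffolds number of symbiont scaffolds.
#' @slot hostDepth mean fold-coverage of the host.
#' @slot symbiontDepth mean fold-coverage of the symbiont.
#' @slot nInsertions number of symbiont-derived insertions planted in the host.
#' @slot insertionMin,insertionMax insertion length range (bp); minimum 100.
#' @slot strainDivergence per-base substitution probability between
#'   co-infecting symbiont strains, in \[0, 0.2).
#' @slot nStrains number of co-infecting symbiont strains.
#' @slot chimeraCount number of artificial chimeric scaffolds.
#' @slot chimeraFragment length (bp) of each fragment of a chimeric scaffold.
#' @slot readLength simulated read length (bp).
#' @slot meanFragment mean contig length (bp) of the shredded alternative
#'   assembly.
#' @slot nAltAssemblies number of independently shredded alternative
#'   assemblies.
#' @slot transposaseFlank whether a transposase feature accompanies each
#'   planted insertion.
#' @slot errorRate per-base substitution error rate of simulated reads.
#' @slot seed integer seed; every simulation is deterministic given the seed.
#'
#' @seealso [simulationConfig()], [simulateHgtExperiment()]
#' @export
setClass("SimulationConfig",
    representation(
        hostLength = "numeric", hostGc = "numeric", hostScaffolds = "numeric",
        symbiontLength = "numeric", symbiontGc = "numeric",
        symbiontScaffolds = "numeric",
        hostDepth = "numeric", symbiontDepth = "numeric",
        nInsertions = "numeric", insertionMin = "numeric",
        insertionMax = "numeric",
        strainDivergence = "numeric", nStrains = "numeric",
        chimeraCount = "numeric", chimeraFragment = "numeric",
        readLength = "numeric", meanFragment = "numeric",
        nAltAssemblies = "numeric",
        transposaseFlank = "logical", errorRate = "numeric",
        seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pos <- c(hostLength = object@hostLength,
             symbiontLength = object@symbiontLength,
             hostScaffolds = object@hostScaffolds,
             symbiontScaffolds = object@symbiontScaffolds,
             hostDepth = object@hostDepth,
             symbiontDepth = object@symbiontDepth,
             readLength = object@readLength,
             meanFragment = object@meanFragment)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
        msg <- c(msg, paste0("slots must be > 0: ",
                             paste(bad, collapse = ", ")))
    for (gc in c(object@hostGc, object@symbiontGc))
        if (!is.finite(gc) || gc <= 0 || gc >= 1)
            msg <- c(msg, "GC fractions must lie strictly inside (0, 1)")
    if (object@nInsertions < 0)
        msg <- c(msg, "nInsertions must be >= 0")
    if (object@insertionMin < 100)
        msg <- c(msg, "insertionMin must be >= 100 bp")
    if (object@insertionMax < object@insertionMin)
        msg <- c(msg, "insertionMax must be >= insertionMin")
    if (object@strainDivergence < 0 || object@strainDivergence >= 0.2)
        msg <- c(msg, "strainDivergence must lie in [0, 0.2)")
    if (object@nStrains < 1)
        msg <- c(msg, "nStrains must be >= 1")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must lie in [0, 1)")
    if (!is.finite(object@seed))
        msg <- c(msg, "a finite integer seed is required")
    if (length(msg)) msg else TRUE
})

#' A synthetic HGT sequencing experiment with known truth
#'
#' Container for one simulated dataset: the assembly under scrutiny (host
#' scaffolds carrying planted symbiont insertions, pure symbiont scaffolds,
#' and chimeric artifact scaffolds), the clean host and symbiont reference
#' genomes, exact per-base depth tracks derived from the recorded read
#' placements, a taxon-annotated similarity hit table, gene/transposase
#' features, an expression table, shredded alternative assemblies, and the
#' truth tables the pipeline is scored against.
#'
#' @slot assembly [Biostrings::DNAStringSet] of assembly scaffolds.
#' @slot hostRef,symbiontRef reference genomes ([Biostrings::DNAStringSet]).
#' @slot depth an [IRanges::RleList] of per-base depth, one track per scaffold.
#' @slot hits data.frame of taxon-annotated similarity hits (BLAST-tabular
#'   content, internal 1-based closed coordinates).
#' @slot features [GenomicRanges::GRanges] with `featureType` (gene /
#'   transposase / marker) and `featureId` metadata columns.
#' @slot fpkm named numeric vector of gene expression values.
#' @slot altAssemblies list of [Biostrings::DNAStringSet], the alternative
#'   assemblies.
#' @slot truth list with elements `insertions` (GRanges on assembly
#'   coordinates with source coordinates in metadata), `chimeras`
#'   (data.frame scaffold/junction) and `variantSites`.
#' @slot config the [SimulationConfig-class] used.
#'
#' @seealso [simulateHgtExperiment()]
#' @export
setClass("HgtSimulation",
    representation(
        assembly = "DNAStringSet",
        hostRef = "DNAStringSet",
        symbiontRef = "DNAStringSet",
        depth = "RleList",
        hits = "data.frame",
        features = "GRanges",
        fpkm = "numeric",
        altAssemblies = "list",
        truth = "list",
        config = "SimulationConfig"))

setValidity("HgtSimulation", function(object) {
    msg <- character()
    if (!all(names(object@depth) %in% names(object@assembly)))
        msg <- c(msg, "depth track names must match assembly scaffolds")
    dl <- S4Vectors::elementNROWS(object@depth)
    sl <- Biostrings::width(object@assembly)[
        match(names(object@depth), names(object@assembly))]
    if (any(dl != sl))
        msg <- c(msg, "each depth track must have one value per base")
    if (length(msg)) msg else TRUE
})

#' A set of HGT calls with their supporting evidence
#'
#' Result container of [detectHgt()]: one range per candidate insertion,
#' carrying junction depth-continuity verdicts, cross-assembly corroboration
#' counts, transposase proximity, overlapping genes and the final verdict
#' (`hgt`, `chimera_suspect` or `unresolved`), together with the scaffold
#' classification table and the parameter set used.
#'
#' @slot calls [GenomicRanges::GRanges] of candidate intervals with evidence
#'   metadata columns.
#' @slot classification data.frame produced by [classifyAssembly()].
#' @slot params list of detection parameters (see [hgtParams()]).
#' @export
setClass("HgtCallSet",
    representation(calls = "GRanges",
                   classification = "data.frame",
                   params = "list"))

#' Multi-strain evidence report for an endosymbiont assembly
#'
#' Summarises the three lines of evidence that an endosymbiont assembly
#' contains more than one co-infecting strain: reference single-copy genes
#' present at two or more loci, single-copy genes harbouring within-sample
#' polymorphism, and marker genes (e.g. MLST or *cif*) duplicated across
#' scaffolds.
#'
#' @slot nDuplicated count of duplicated single-copy genes.
#' @slot nPolymorphic count of polymorphic single-copy genes.
#' @slot duplicatedMarkers ids of markers found on >= 2 scaffolds.
#' @slot nSingleCopyTotal size of the single-copy reference set examined.
#' @slot multiStrain TRUE if any evidence line exceeds its threshold.
#' @slot details list of the underlying gene-id sets and thresholds.
#' @seealso [strainReport()]
#' @export
setClass("StrainEvidenceReport",
    representation(nDuplicated = "integer",
                   nPolymorphic = "integer",
                   duplicatedMarkers = "character",
                   nSingleCopyTotal = "integer",
                   multiStrain = "logical",
                   details = "list"))

setValidity("StrainEvidenceReport", function(object) {
    msg <- character()
    if (object@nDuplicated > object@nSingleCopyTotal ||
        object@nPolymorphic > object@nSingleCopyTotal)
        msg <- c(msg, "evidence counts cannot exceed nSingleCopyTotal")
    if (length(msg)) msg else TRUE
})

#' Assembly contiguity and composition statistics
#'
#' N50/N75 and L50/L75 contiguity metrics, GC percentage and contig counts
#' above length thresholds, as reported for draft genome assemblies.
#'
#' @slot totalLength summed contig length (bp).
#' @slot nContigs number of contigs.
#' @slot n50,n75 Nxx lengths (bp).
#' @slot l50,l75 Lxx counts.
#' @slot gcPercent assembly GC content in percent.
#' @slot countsGe data.frame with one row per length threshold: count of
#'   contigs at or above it and the genome fraction they contain.
#' @seealso [assemblyStats()], [nxx()]
#' @export
setClass("AssemblyStats",
    representation(totalLength = "numeric", nContigs = "integer",
                   n50 = "numeric", n75 = "numeric",
                   l50 = "integer", l75 = "integer",
                   gcPercent = "numeric", countsGe = "data.frame"))

setValidity("AssemblyStats", function(object) {
    msg <- character()
    if (object@n50 < object@n75) msg <- c(msg, "N50 must be >= N75")
    if (object@l50 > object@l75) msg <- c(msg, "L50 must be <= L75")
    if (length(msg)) msg else TRUE
})
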