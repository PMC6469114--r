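# End-to-end synthetic experiments: the full HGT bundle (assembly, depth,
# hits, features, expression, alternative assemblies, truth) and the
# strain-evidence bundle (single-copy gene placements, variant sites, marker
# placements from a one- or two-strain symbiont).

.splitGenome <- function(totalLength, n, gc, prefix) {
    w <- rep(floor(totalLength / n), n)
    w[n] <- totalLength - sum(w[-n])
    seqs <- Biostrings::DNAStringSet(vapply(w, function(len)
        as.character(generateGenome(len, gc)), character(1)))
    names(seqs) <- paste0(prefix, seq_len(n))
    seqs
}

# shift post-insertion coordinates back to the reference coordinate system
.refCoord <- function(pos, insStarts, insWidths) {
    pos - sum(insWidths[insStarts <= pos])
}

#' Simulate a complete HGT sequencing experiment
#'
#' Generates, deterministically in `config@seed`, every input the detection
#' pipeline consumes plus the truth it is scored against: a host genome and a
#' symbiont genome at their configured GC and depths, symbiont fragments
#' planted into host scaffolds (with transposase and gene annotations and a
#' sparse low-FPKM expression table), chimeric artifact scaffolds whose depth
#' steps at the joint, exact per-base depth tracks from placed reads, a
#' taxon-annotated hit table (the BLAST-screening stand-in, emitted from
#' truth), and shredded alternative assemblies.
#'
#' @param config a [SimulationConfig-class], see [simulationConfig()].
#' @return an [HgtSimulation-class] object.
#' @export
#' @examples
#' sim <- simulateHgtExperiment(simulationConfig(seed = 1, hostLength = 2e5,
#'     hostScaffolds = 2, symbiontLength = 1e5, symbiontScaffolds = 1,
#'     nInsertions = 1, insertionMax = 5000))
#' sim
simulateHgtExperiment <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)

    hostRef <- .splitGenome(config@hostLength, config@hostScaffolds,
                            config@hostGc, "ant_ref")
    symRef <- .splitGenome(config@symbiontLength, config@symbiontScaffolds,
                           config@symbiontGc, "wolb_ref")

    host <- hostRef
    names(host) <- paste0("scaffold", seq_along(host))
    symbiont <- symRef
    names(symbiont) <- paste0("wsc", seq_along(symbiont))

    planted <- plantInsertions(host, symbiont,
        nInsertions = config@nInsertions,
        lengthRange = c(config@insertionMin, config@insertionMax),
        transposaseFlank = config@transposaseFlank)
    host <- planted$host
    ins <- planted$insertions
    features <- planted$transposases

    # gene features inside large inserts; a sparse low-FPKM expression table
    fpkm <- stats::setNames(numeric(), character())
    geneGr <- list()
    for (i in seq_along(ins)) {
        w <- GenomicRanges::width(ins)[i]
        if (w < 2000) next
        gs <- seq(GenomicRanges::start(ins)[i] + 200,
                  GenomicRanges::end(ins)[i] - 900, by = 1200)
        if (!length(gs)) next
        g <- GenomicRanges::GRanges(
            as.character(GenomicRanges::seqnames(ins))[i],
            IRanges::IRanges(gs, width = 700))
        g$featureType <- "gene"
        g$featureId <- paste0("hgtg_", i, "_", seq_along(g))
        geneGr[[length(geneGr) + 1L]] <- g
        expressed <- stats::runif(length(g)) < 0.1
        if (any(expressed))
            fpkm <- c(fpkm, stats::setNames(
                round(stats::runif(sum(expressed), 0.04, 1.6), 2),
                g$featureId[expressed]))
    }
    if (length(geneGr))
        features <- suppressWarnings(c(features, do.call(c, geneGr)))

    # chimeric artifact scaffolds: clean host fragment + symbiont fragment
    chim <- data.frame(scaffold = character(), junction = integer(),
                       hostSrc = character(), symSrc = character(),
                       stringsAsFactors = FALSE)
    chimSeqs <- list()
    chimTracks <- list()
    chimHits <- list()
    for (ci in seq_len(config@chimeraCount)) {
        frag <- config@chimeraFragment
        hsc <- sample(names(hostRef), 1)
        hw <- Biostrings::width(hostRef)[names(hostRef) == hsc]
        hs <- sample.int(hw - frag, 1)
        ssc <- sample(names(symRef), 1)
        sw <- Biostrings::width(symRef)[names(symRef) == ssc]
        ss <- sample.int(sw - frag, 1)
        mk <- makeChimera(
            Biostrings::subseq(hostRef[[hsc]], hs, hs + frag - 1),
            Biostrings::subseq(symRef[[ssc]], ss, ss + frag - 1),
            config@hostDepth, config@symbiontDepth,
            readLength = config@readLength)
        nm <- paste0("chimera", ci)
        chimSeqs[[nm]] <- as.character(mk$sequence)
        chimTracks[[nm]] <- mk$depth
        chim <- rbind(chim, data.frame(
            scaffold = nm, junction = mk$junction,
            hostSrc = hsc, symSrc = ssc, stringsAsFactors = FALSE))
        chimHits[[nm]] <- data.frame(
            queryId = nm, subjectId = c(hsc, ssc),
            taxonBin = c("host", "symbiont"),
            percentIdentity = c(100, 99),
            qStart = c(1L, frag + 1L), qEnd = c(frag, 2L * frag),
            sStart = c(hs, ss), sEnd = c(hs + frag - 1L, ss + frag - 1L),
            strand = "+", bitscore = 2 * frag, stringsAsFactors = FALSE)
    }

    assembly <- c(host, symbiont,
                  if (length(chimSeqs))
                      Biostrings::DNAStringSet(unlist(chimSeqs))
                  else Biostrings::DNAStringSet())

    # reads and exact depth tracks (chimera tracks were built above)
    hostSim <- simulateReads(host, config@hostDepth,
                             readLength = config@readLength)
    symSim <- simulateReads(symbiont, config@symbiontDepth,
                            readLength = config@readLength)
    depth <- methods::as(c(as.list(hostSim$depth), as.list(symSim$depth),
                           chimTracks), "RleList")

    # taxon-annotated hit table, emitted from truth
    hits <- list()
    for (sc in names(host)) {
        w <- Biostrings::width(host)[names(host) == sc]
        insHere <- ins[as.character(GenomicRanges::seqnames(ins)) == sc]
        insHere <- GenomicRanges::sort(insHere)
        refSc <- sub("^scaffold", "ant_ref", sc)
        hostSeg <- IRanges::gaps(IRanges::ranges(insHere), start = 1,
                                 end = w)
        is0 <- GenomicRanges::start(insHere)
        iw0 <- GenomicRanges::width(insHere)
        if (length(hostSeg)) {
            qs <- IRanges::start(hostSeg)
            qe <- IRanges::end(hostSeg)
            hits[[length(hits) + 1L]] <- data.frame(
                queryId = sc, subjectId = refSc, taxonBin = "host",
                percentIdentity = 100,
                qStart = qs, qEnd = qe,
                sStart = vapply(qs, .refCoord, numeric(1), is0, iw0),
                sEnd = vapply(qe, .refCoord, numeric(1), is0, iw0),
                strand = "+", bitscore = 2 * (qe - qs + 1),
                stringsAsFactors = FALSE)
        }
        if (length(insHere)) {
            hits[[length(hits) + 1L]] <- data.frame(
                queryId = sc,
                subjectId = sub("^wsc", "wolb_ref", insHere$srcScaffold),
                taxonBin = "symbiont", percentIdentity = 99,
                qStart = GenomicRanges::start(insHere),
                qEnd = GenomicRanges::end(insHere),
                sStart = insHere$srcStart, sEnd = insHere$srcEnd,
                strand = "+", bitscore = 2 * GenomicRanges::width(insHere),
                stringsAsFactors = FALSE)
        }
    }
    for (sc in names(symbiont)) {
        w <- Biostrings::width(symbiont)[names(symbiont) == sc]
        hits[[length(hits) + 1L]] <- data.frame(
            queryId = sc, subjectId = sub("^wsc", "wolb_ref", sc),
            taxonBin = "symbiont", percentIdentity = 99,
            qStart = 1L, qEnd = w, sStart = 1L, sEnd = w,
            strand = "+", bitscore = 2 * w, stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, c(hits, unname(chimHits)))

    alts <- lapply(seq_len(config@nAltAssemblies), function(a)
        shredAssembly(c(host, symbiont), config@meanFragment,
                      prefix = paste0("alt", a)))

    methods::new("HgtSimulation",
        assembly = assembly, hostRef = hostRef, symbiontRef = symRef,
        depth = depth, hits = hits, features = features, fpkm = fpkm,
        altAssemblies = alts,
        truth = list(insertions = ins,
                     chimeras = chim[, c("scaffold", "junction")],
                     variantSites = data.frame()),
        config = config)
}

#' Simulate strain-evidence inputs for a one- or multi-strain symbiont
#'
#' Emulates the assembly of a symbiont sequenced from `nStrains` co-infecting
#' strains at pairwise divergence `divergence`: single-copy genes are tiled
#' on a main contig; for a fraction of genes (and for all marker genes) the
#' diverged strain copy is "resolved" by the assembler into a separate
#' contig, producing duplicated loci, while the remaining loci are collapsed,
#' so pooled reads from the strains pile up as intra-sample polymorphism at
#' the strain-variant sites. Read support at each variant site is computed
#' from placed reads of each strain (depth split equally among strains).
#'
#' With `nStrains = 1` the output carries no duplicated loci and no variant
#' sites: the single-strain negative control.
#'
#' @param nStrains number of strains (1 or 2 supported).
#' @param divergence per-base substitution probability between strains.
#' @param genomeLength symbiont genome length (bp).
#' @param nGenes number of single-copy genes tiled on the genome.
#' @param geneLength gene length (bp).
#' @param dupFraction fraction of genes whose second-strain copy is resolved
#'   as a separate locus.
#' @param markers marker gene ids (MLST / CI panel).
#' @param depth total pooled fold-coverage.
#' @param readLength read length (bp).
#' @param seed integer seed.
#' @return list with `placements` (single-copy gene placements: `geneId`,
#'   `scaffold`, `identity`, `coverage`, `sStart`, `sEnd`), `variants`
#'   (site table: `scaffold`, `position`, `refBase`, `altBase`, `refCount`,
#'   `altCount`), `genes` ([GenomicRanges::GRanges] of single-copy gene
#'   intervals on the main contig), `markerPlacements` (`markerId`,
#'   `scaffold`), `nSingleCopyTotal`, and `truth` (duplicated gene ids and
#'   planted variant positions).
#' @export
simulateStrainEvidence <- function(nStrains = 2, divergence = 0.03,
                                   genomeLength = 1.2e5, nGenes = 80,
                                   geneLength = 900, dupFraction = 0.15,
                                   markers = c("ftsZ", "hcpA", "gatB",
                                               "cifA", "cifB"),
                                   depth = 120, readLength = 100,
                                   seed) {
    if (missing(seed)) stop("a seed is required")
    if (!nStrains %in% c(1, 2))
        stop("nStrains must be 1 or 2")
    set.seed(seed)
    spacing <- geneLength + 300
    need <- (nGenes + length(markers)) * spacing + 400
    if (genomeLength < need)
        stop("genomeLength too small for ", nGenes, " genes + markers (need ",
             need, " bp)")
    main <- "wsc_main"
    genomeA <- generateGenome(genomeLength, 0.3513)

    ids <- c(paste0("scg", seq_len(nGenes)), markers)
    starts <- 200 + (seq_along(ids) - 1L) * spacing
    genes <- GenomicRanges::GRanges(main,
        IRanges::IRanges(starts, width = geneLength), featureId = ids)

    placements <- data.frame(
        geneId = ids, scaffold = main, identity = 1, coverage = 1,
        sStart = starts, sEnd = starts + geneLength - 1L,
        stringsAsFactors = FALSE)
    markerPlacements <- data.frame(markerId = markers, scaffold = main,
                                   stringsAsFactors = FALSE)
    variants <- data.frame(scaffold = character(), position = integer(),
                           refBase = character(), altBase = character(),
                           refCount = integer(), altCount = integer(),
                           stringsAsFactors = FALSE)
    dupGenes <- character()
    variantPositions <- integer()

    if (nStrains == 2) {
        strB <- deriveStrain(genomeA, divergence)
        dupGenes <- sample(paste0("scg", seq_len(nGenes)),
                           round(dupFraction * nGenes))
        dupLoci <- c(dupGenes, markers)
        chA <- strsplit(as.character(genomeA), "")[[1]]
        chB <- strsplit(as.character(strB$sequence), "")[[1]]
        for (g in dupLoci) {
            i <- match(g, ids)
            lo <- max(1L, starts[i] - 100L)
            hi <- min(genomeLength, starts[i] + geneLength - 1L + 100L)
            gi <- starts[i]:(starts[i] + geneLength - 1L)
            mism <- sum(chA[gi] != chB[gi])
            placements <- rbind(placements, data.frame(
                geneId = g, scaffold = paste0("dup_", g),
                identity = 1 - mism / geneLength, coverage = 1,
                sStart = starts[i] - lo + 1L,
                sEnd = starts[i] - lo + geneLength,
                stringsAsFactors = FALSE))
            if (g %in% markers)
                markerPlacements <- rbind(markerPlacements, data.frame(
                    markerId = g, scaffold = paste0("dup_", g),
                    stringsAsFactors = FALSE))
        }
        # pooled reads: half the depth from each strain; collapsed loci show
        # the strain variants as polymorphic sites with read support
        reps <- Biostrings::DNAStringSet(
            stats::setNames(as.character(genomeA), main))
        covA <- simulateReads(reps, depth / 2, readLength)$depth[[main]]
        covB <- simulateReads(reps, depth / 2, readLength)$depth[[main]]
        dupRegions <- IRanges::IRanges(
            starts[match(dupLoci, ids)],
            width = geneLength)
        keep <- strB$positions[!IRanges::overlapsAny(
            IRanges::IRanges(strB$positions, width = 1), dupRegions)]
        if (length(keep)) {
            variants <- data.frame(
                scaffold = main, position = keep,
                refBase = chA[keep], altBase = chB[keep],
                refCount = as.integer(as.numeric(covA[keep])),
                altCount = as.integer(as.numeric(covB[keep])),
                stringsAsFactors = FALSE)
        }
        variantPositions <- keep
    }
    list(placements = placements, variants = variants, genes = genes,
         markerPlacements = markerPlacements,
         nSingleCopyTotal = length(ids),
         truth = list(duplicatedGenes = sort(dupGenes),
                      variantPositions = variantPositions))
}
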