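# Locating symbiont-derived blocks on candidate scaffolds, testing junction
# depth continuity against the chimera hypothesis, corroborating junctions
# across independent assemblies, and emitting final calls.

#' Detection parameter set
#'
#' Every tunable of the detection pipeline with its default. Units are bp
#' unless stated.
#'
#' @param k anchor word size of the aligner.
#' @param mRep maximum reference multiplicity of a usable k-mer.
#' @param maxGap maximum within-chain gap, and the block-merge distance when
#'   segmenting candidates.
#' @param minBlock minimum similarity-block span; below the smallest genuine
#'   insert worth calling, with margin for alignment fraying.
#' @param window junction depth window width.
#' @param guard gap left between the junction and each depth window, so that
#'   boundary-overlapping reads do not blur the step.
#' @param tauJunction depth-ratio threshold: a junction is continuous iff
#'   |log2(left/right)| <= log2(tauJunction).
#' @param flank sequence flank taken around a junction for corroboration.
#' @param flankCovered bases that one alternative-assembly block must cover
#'   on each side of the junction to corroborate it.
#' @param cMin minimum corroborating assemblies for an `hgt` verdict.
#' @param maxDist maximum transposase distance reported.
#' @param minFpkm FPKM at or above which a gene counts as transcribed.
#' @param fPure symbiont-covered fraction for a pure-symbiont label.
#' @param tauDepth depth-ratio band of the TAGC `intermediate` cluster.
#' @param edgeTol distance from a scaffold end within which a symbiont run
#'   is treated as reaching the edge (only one testable junction).
#' @return named list of parameters.
#' @export
hgtParams <- function(k = 21, mRep = 10, maxGap = 500, minBlock = 300,
                      window = 500, guard = 50, tauJunction = 1.5,
                      flank = 500, flankCovered = 200, cMin = 1,
                      maxDist = 2000, minFpkm = 0.01, fPure = 0.90,
                      tauDepth = 1.5, edgeTol = 100) {
    as.list(environment())
}

#' Segment a candidate scaffold into host/symbiont alternation
#'
#' Builds candidate insertion intervals from the similarity blocks of a
#' candidate scaffold: overlaps between host and symbiont blocks are resolved
#' in favour of the higher identity (ties are marked ambiguous and excluded
#' from junctions), symbiont blocks separated by at most `maxGap` are merged
#' into runs, and each run flanked by a host block on at least one side
#' becomes a candidate. Junction positions sit at the midpoint of the
#' inter-block gap (anchors fray at edit-dense boundaries; the midpoint
#' minimises the worst-case boundary error). A side at which the run reaches
#' the scaffold edge (within `edgeTol`) carries no testable junction.
#'
#' @param blocksHost,blocksSymbiont [GenomicRanges::GRanges] from
#'   [anchorChainAlign()] against the host and symbiont references, on one
#'   scaffold.
#' @param scaffoldLength scaffold length (bp).
#' @param maxGap merge distance (bp).
#' @param edgeTol scaffold-edge tolerance (bp).
#' @param overlapTol host/symbiont block overlaps up to this width (bp) are
#'   treated as boundary sharing (junction-adjacent bases matching both
#'   references) and split at the overlap midpoint; larger overlaps are
#'   resolved by identity, with ties marked ambiguous.
#' @return a [GenomicRanges::GRanges] of candidate insertion intervals with
#'   metadata columns `leftJunction` / `rightJunction` (position of the first
#'   inserted base / first base after the insert; NA at a scaffold edge or at
#'   an ambiguous boundary) and `ambiguous`.
#' @export
segmentCandidate <- function(blocksHost, blocksSymbiont, scaffoldLength,
                             maxGap = 500, edgeTol = 100, overlapTol = 50) {
    sn <- unique(c(as.character(GenomicRanges::seqnames(blocksHost)),
                   as.character(GenomicRanges::seqnames(blocksSymbiont))))
    if (length(sn) > 1)
        stop("blocks must lie on a single scaffold")
    if (length(blocksSymbiont) == 0)
        return(GenomicRanges::GRanges())

    hb <- IRanges::IRanges(GenomicRanges::start(blocksHost),
                           GenomicRanges::end(blocksHost))
    sb <- IRanges::IRanges(GenomicRanges::start(blocksSymbiont),
                           GenomicRanges::end(blocksSymbiont))
    hid <- blocksHost$identity
    sid <- blocksSymbiont$identity
    ambiguous <- IRanges::IRanges()

    ov <- IRanges::findOverlaps(hb, sb)
    if (length(ov)) {
        for (p in seq_along(ov)) {
            i <- S4Vectors::queryHits(ov)[p]
            j <- S4Vectors::subjectHits(ov)[p]
            inter <- IRanges::pintersect(hb[i], sb[j])
            if (IRanges::width(inter) <= overlapTol) {
                # boundary sharing: the junction-adjacent bases genuinely
                # match both references; split at the overlap midpoint
                mid <- (IRanges::start(inter) + IRanges::end(inter)) %/% 2L
                if (IRanges::start(hb[i]) < IRanges::start(sb[j])) {
                    hb[i] <- IRanges::IRanges(IRanges::start(hb[i]),
                        width = max(0L, mid - IRanges::start(hb[i]) + 1L))
                    sb[j] <- IRanges::IRanges(mid + 1L,
                        width = max(0L, IRanges::end(sb[j]) - mid))
                } else {
                    sb[j] <- IRanges::IRanges(IRanges::start(sb[j]),
                        width = max(0L, mid - IRanges::start(sb[j]) + 1L))
                    hb[i] <- IRanges::IRanges(mid + 1L,
                        width = max(0L, IRanges::end(hb[i]) - mid))
                }
            } else if (hid[i] > sid[j]) {
                sb[j] <- .trimRange(sb[j], inter)
            } else if (hid[i] < sid[j]) {
                hb[i] <- .trimRange(hb[i], inter)
            } else {
                ambiguous <- c(ambiguous, inter)
                sb[j] <- .trimRange(sb[j], inter)
                hb[i] <- .trimRange(hb[i], inter)
            }
        }
        hb <- hb[IRanges::width(hb) > 0]
        sb <- sb[IRanges::width(sb) > 0]
    }
    if (length(sb) == 0) return(GenomicRanges::GRanges())

    hr <- IRanges::reduce(hb, min.gapwidth = maxGap + 1)
    sr <- IRanges::reduce(sb, min.gapwidth = maxGap + 1)

    out <- list()
    for (i in seq_along(sr)) {
        rs <- IRanges::start(sr)[i]
        re <- IRanges::end(sr)[i]
        lefts <- hr[IRanges::end(hr) < rs]
        rights <- hr[IRanges::start(hr) > re]
        hasLeft <- length(lefts) > 0
        hasRight <- length(rights) > 0
        atLeftEdge <- rs <= edgeTol
        atRightEdge <- re >= scaffoldLength - edgeTol + 1
        if (!hasLeft && !hasRight) next  # no host flank: not a candidate
        if (hasLeft) {
            le <- max(IRanges::end(lefts))
            gapL <- rs - le - 1L
            bStart <- le + 1L + floor(gapL / 2)
            junL <- bStart
        } else {
            bStart <- 1L
            junL <- NA_integer_
        }
        if (hasRight) {
            rstart <- min(IRanges::start(rights))
            gapR <- rstart - re - 1L
            bEnd <- re + floor(gapR / 2)
            junR <- bEnd + 1L
        } else {
            bEnd <- scaffoldLength
            junR <- NA_integer_
        }
        # a junction falling inside an ambiguous (tied-identity) region is
        # excluded from testing
        if (!is.na(junL) && length(ambiguous) &&
            any(IRanges::overlapsAny(IRanges::IRanges(junL, junL),
                                     ambiguous)))
            junL <- NA_integer_
        if (!is.na(junR) && length(ambiguous) &&
            any(IRanges::overlapsAny(IRanges::IRanges(junR, junR),
                                     ambiguous)))
            junR <- NA_integer_
        g <- GenomicRanges::GRanges(sn, IRanges::IRanges(bStart, bEnd))
        g$leftJunction <- as.integer(junL)
        g$rightJunction <- as.integer(junR)
        g$atEdge <- (!hasLeft && atLeftEdge) || (!hasRight && atRightEdge)
        g$ambiguous <- length(ambiguous) > 0
        out[[length(out) + 1L]] <- g
    }
    if (!length(out)) return(GenomicRanges::GRanges())
    suppressWarnings(do.call(c, out))
}

.trimRange <- function(r, inter) {
    # remove `inter` from range `r`, keeping the larger remaining piece
    leftW <- IRanges::start(inter) - IRanges::start(r)
    rightW <- IRanges::end(r) - IRanges::end(inter)
    if (leftW >= rightW)
        IRanges::IRanges(IRanges::start(r),
                         width = max(0L, leftW))
    else
        IRanges::IRanges(IRanges::end(inter) + 1L,
                         width = max(0L, rightW))
}

#' Depth-continuity test at a junction
#'
#' Compares mean read depth in a window on each side of a junction, leaving a
#' guard gap around the junction itself. The junction is `continuous` iff
#' |log2 ratio| <= log2(tauJunction) (a pseudo-depth of 0.5 guards the ratio
#' against dropout windows), `step_change` otherwise, and `indeterminate`
#' when either window extends beyond the scaffold. A depth step at the joint
#' of two similarity blocks is the signature of an erroneous chimeric
#' assembly; a genuine insertion shows no change in depth across the
#' junction.
#'
#' @param track an [S4Vectors::Rle] per-base depth track.
#' @param position junction coordinate: the first base of the right-hand
#'   side.
#' @param window window width (bp), >= 100.
#' @param guard guard gap (bp) between the junction and each window.
#' @param tauJunction depth-ratio threshold.
#' @return data.frame row: `position`, `leftMean`, `rightMean`, `log2Ratio`,
#'   `verdict`.
#' @export
junctionDepthTest <- function(track, position, window = 500, guard = 50,
                              tauJunction = 1.5) {
    if (window < 100) stop("window must be >= 100")
    if (guard < 0) stop("guard must be >= 0")
    ls <- position - guard - window
    le <- position - guard - 1
    rs <- position + guard
    re <- position + guard + window - 1
    if (ls < 1 || re > length(track)) {
        return(data.frame(position = position, leftMean = NA_real_,
                          rightMean = NA_real_, log2Ratio = NA_real_,
                          verdict = "indeterminate",
                          stringsAsFactors = FALSE))
    }
    eps <- 0.5
    lm <- mean(as.numeric(S4Vectors::window(track, ls, le)))
    rm <- mean(as.numeric(S4Vectors::window(track, rs, re)))
    lr <- log2((lm + eps) / (rm + eps))
    data.frame(position = position, leftMean = lm, rightMean = rm,
               log2Ratio = lr,
               verdict = if (abs(lr) <= log2(tauJunction)) "continuous"
                         else "step_change",
               stringsAsFactors = FALSE)
}

#' Corroborate a junction across alternative assemblies
#'
#' A junction is corroborated by an alternative assembly when a single contig
#' of that assembly aligns contiguously across it: one similarity block
#' (via [anchorChainAlign()]) covering at least `flankCovered` bases on each
#' side of the junction within the `flank`-sized window extracted around it.
#' Returns the number of corroborating assemblies.
#'
#' @param scaffoldSeq the candidate scaffold sequence
#'   ([Biostrings::DNAString] or character).
#' @param position junction coordinate (first base of the right-hand side).
#' @param altAssemblies list of [Biostrings::DNAStringSet] or prebuilt
#'   [kmerIndex()] objects, one per assembly.
#' @param flank window half-width (bp), >= 200; the junction must sit at
#'   least `flank` bases from either scaffold end.
#' @param flankCovered bases required on each side within one block.
#' @param k,maxGap,mRep aligner parameters.
#' @return integer count of corroborating assemblies.
#' @export
corroborateJunction <- function(scaffoldSeq, position, altAssemblies,
                                flank = 500, flankCovered = 200, k = 21,
                                maxGap = 500, mRep = 10) {
    if (flank < 200) stop("flank must be >= 200")
    if (!length(altAssemblies)) return(0L)
    seqc <- as.character(scaffoldSeq)
    if (position - flank < 1 || position + flank - 1 > nchar(seqc))
        return(0L)  # junction too close to the scaffold end to window
    win <- substr(seqc, position - flank, position + flank - 1)
    center <- flank + 1L  # junction coordinate inside the window
    count <- 0L
    for (alt in altAssemblies) {
        idx <- if (inherits(alt, "kmerIndex")) alt
               else kmerIndex(alt, k = k, mRep = mRep)
        blocks <- anchorChainAlign(win, idx, k = k, maxGap = maxGap,
                                   minBlock = min(2L * flankCovered,
                                                  2L * flank))
        spans <- GenomicRanges::start(blocks) <= center - flankCovered &
                 GenomicRanges::end(blocks) >= center + flankCovered - 1L
        if (any(spans)) count <- count + 1L
    }
    count
}

#' Distance from a candidate interval to the nearest transposase
#'
#' Minimum gap (bp) between the candidate interval and any transposase
#' feature on the same scaffold; 0 when overlapping; `NA` when none lies
#' within `maxDist`.
#'
#' @param candidate a [GenomicRanges::GRanges] of length 1.
#' @param features feature [GenomicRanges::GRanges] with `featureType`.
#' @param maxDist maximum distance reported (bp).
#' @return integer distance or `NA`.
#' @export
transposaseProximity <- function(candidate, features, maxDist = 2000) {
    tp <- features[features$featureType == "transposase" &
                   as.character(GenomicRanges::seqnames(features)) ==
                       as.character(GenomicRanges::seqnames(candidate))]
    if (length(tp) == 0) return(NA_integer_)
    d <- min(IRanges::distance(IRanges::ranges(candidate),
                               IRanges::ranges(tp)), na.rm = TRUE)
    if (d > maxDist) NA_integer_ else as.integer(d)
}

#' Genes overlapping a candidate interval
#'
#' Gene features intersecting the candidate by at least one base. A gene
#' merely abutting the interval (shared boundary, zero overlap) is excluded.
#'
#' @param candidate a [GenomicRanges::GRanges] of length 1.
#' @param features feature [GenomicRanges::GRanges] with `featureType` and
#'   `featureId`.
#' @return character vector of gene ids.
#' @export
overlapGenes <- function(candidate, features) {
    g <- features[features$featureType == "gene"]
    if (length(g) == 0) return(character())
    hit <- suppressWarnings(
        IRanges::overlapsAny(g, candidate, minoverlap = 1L))
    g$featureId[hit]
}

#' Transcribed subset of a gene set
#'
#' Genes whose FPKM is at least `minFpkm`; genes absent from the table count
#' as FPKM 0.
#'
#' @param geneIds character vector of gene ids.
#' @param fpkm named numeric FPKM vector.
#' @param minFpkm threshold, >= 0.
#' @return character vector of transcribed gene ids.
#' @export
transcribedSubset <- function(geneIds, fpkm, minFpkm = 0.01) {
    if (minFpkm < 0) stop("minFpkm must be >= 0")
    v <- fpkm[geneIds]
    v[is.na(v)] <- 0
    geneIds[v >= minFpkm]
}

#' Assign final verdicts to candidate calls
#'
#' Applies the verdict rule to a set of candidates with computed evidence:
#' `chimera_suspect` iff any junction shows a depth step; `hgt` iff every
#' testable junction is continuous (junctions missing at a scaffold edge do
#' not block the verdict) and at least `cMin` alternative assemblies
#' corroborate the call; `unresolved` otherwise. When the host and symbiont
#' reference depths are within `tauJunction` of each other the depth test
#' cannot separate a chimera from an insertion, and the call is annotated
#' accordingly rather than silently passed.
#'
#' @param candidates a [GenomicRanges::GRanges] with metadata columns
#'   `junctions` (list of [junctionDepthTest()] rows), `corroborations`,
#'   `transposaseDistance`, `genes`, `transcribed` (list columns), `notes`.
#' @param params see [hgtParams()].
#' @param depthRefs optional named vector of cohort depths used only for the
#'   depth-confound annotation.
#' @return the candidates with a `verdict` metadata column, sorted.
#' @export
callHgt <- function(candidates, params = hgtParams(), depthRefs = NULL) {
    if (length(candidates) == 0) {
        candidates$verdict <- character()
        return(candidates)
    }
    verdict <- vapply(seq_along(candidates), function(i) {
        v <- candidates$junctions[[i]]$verdict
        if (any(v == "step_change")) return("chimera_suspect")
        # indeterminate junctions arise only at scaffold edges (insufficient
        # window) and do not block an hgt verdict
        ok <- length(v) > 0 && all(v %in% c("continuous", "indeterminate"))
        if (ok && candidates$corroborations[i] >= params$cMin) "hgt"
        else "unresolved"
    }, character(1))
    candidates$verdict <- verdict
    if (!is.null(depthRefs) &&
        abs(log2(depthRefs[["host"]] / depthRefs[["symbiont"]])) <=
            log2(params$tauJunction)) {
        candidates$notes <- paste0(candidates$notes,
            "; host and symbiont depths are indistinguishable: ",
            "chimeras cannot be excluded by depth")
    }
    GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(candidates),
                        ignore.strand = TRUE)
}

#' Detect HGT insertions on the candidate scaffolds of an assembly
#'
#' Full detection pass: candidate scaffolds (from [classifyAssembly()]) are
#' aligned against the host and symbiont references with
#' [anchorChainAlign()], segmented into host/symbiont alternation
#' ([segmentCandidate()]), junctions are depth-tested
#' ([junctionDepthTest()]) and corroborated across alternative assemblies
#' ([corroborateJunction()]), candidates are annotated with transposase
#' proximity, overlapping genes and transcription, and final verdicts are
#' assigned ([callHgt()]).
#'
#' @param scaffolds assembly [Biostrings::DNAStringSet].
#' @param classif classification data.frame from [classifyAssembly()].
#' @param depth [IRanges::RleList] of per-base depth tracks.
#' @param hostRef,symbiontRef reference [Biostrings::DNAStringSet]s.
#' @param features feature [GenomicRanges::GRanges] (may be empty).
#' @param fpkm named numeric FPKM vector (may be empty).
#' @param altAssemblies list of [Biostrings::DNAStringSet].
#' @param params see [hgtParams()].
#' @return an [HgtCallSet-class].
#' @export
detectHgt <- function(scaffolds, classif, depth, hostRef, symbiontRef,
                      features = GenomicRanges::GRanges(),
                      fpkm = stats::setNames(numeric(), character()),
                      altAssemblies = list(), params = hgtParams()) {
    cands <- classif$scaffold[classif$label == "hgt_candidate"]
    depthRefs <- attr(classif, "depthRefs")
    empty <- GenomicRanges::GRanges()
    empty$leftJunction <- integer()
    empty$rightJunction <- integer()
    empty$atEdge <- logical()
    empty$ambiguous <- logical()
    if (length(cands) == 0)
        return(methods::new("HgtCallSet",
            calls = callHgt(.emptyEvidence(), params),
            classification = classif, params = params))

    hostIdx <- kmerIndex(hostRef, k = params$k, mRep = params$mRep)
    symIdx <- kmerIndex(symbiontRef, k = params$k, mRep = params$mRep)
    altIdx <- lapply(altAssemblies, kmerIndex, k = params$k,
                     mRep = params$mRep)

    calls <- list()
    for (sc in cands) {
        qry <- stats::setNames(as.character(scaffolds[[sc]]), sc)
        bh <- anchorChainAlign(qry, hostIdx, k = params$k,
                               maxGap = params$maxGap,
                               minBlock = params$minBlock)
        bs <- anchorChainAlign(qry, symIdx, k = params$k,
                               maxGap = params$maxGap,
                               minBlock = params$minBlock)
        cnds <- segmentCandidate(bh, bs, nchar(qry),
                                 maxGap = params$maxGap,
                                 edgeTol = params$edgeTol)
        if (length(cnds) == 0) next
        track <- depth[[sc]]
        for (i in seq_along(cnds)) {
            cand <- cnds[i]
            juncPos <- c(cand$leftJunction, cand$rightJunction)
            juncPos <- juncPos[!is.na(juncPos)]
            jt <- if (length(juncPos))
                do.call(rbind, lapply(juncPos, function(p)
                    junctionDepthTest(track, p, window = params$window,
                                      guard = params$guard,
                                      tauJunction = params$tauJunction)))
            else
                data.frame(position = integer(), leftMean = numeric(),
                           rightMean = numeric(), log2Ratio = numeric(),
                           verdict = character(), stringsAsFactors = FALSE)
            # an assembly corroborates the call when it spans at least one
            # of its junctions contiguously; a junction missed because a
            # contig happens to end elsewhere is uninformative, not
            # contradictory
            corr <- if (length(juncPos)) sum(vapply(altIdx, function(a)
                any(vapply(juncPos, function(p)
                    corroborateJunction(qry, p, list(a),
                                        flank = params$flank,
                                        flankCovered = params$flankCovered,
                                        k = params$k,
                                        maxGap = params$maxGap) > 0,
                    logical(1))), logical(1))) else 0L
            genes <- overlapGenes(cand, features)
            ev <- cand
            ev$junctions <- list(jt)
            ev$corroborations <- corr
            ev$transposaseDistance <- transposaseProximity(
                cand, features, maxDist = params$maxDist)
            ev$genes <- list(genes)
            ev$transcribed <- list(transcribedSubset(genes, fpkm,
                                                     params$minFpkm))
            ev$notes <- if (cand$atEdge)
                "reaches scaffold edge; one junction untestable" else ""
            calls[[length(calls) + 1L]] <- ev
        }
    }
    allCalls <- if (length(calls)) suppressWarnings(do.call(c, calls))
                else .emptyEvidence()
    methods::new("HgtCallSet",
        calls = callHgt(allCalls, params, depthRefs = depthRefs),
        classification = classif, params = params)
}

.emptyEvidence <- function() {
    g <- GenomicRanges::GRanges()
    g$leftJunction <- integer()
    g$rightJunction <- integer()
    g$atEdge <- logical()
    g$ambiguous <- logical()
    g$junctions <- list()
    g$corroborations <- integer()
    g$transposaseDistance <- integer()
    g$genes <- list()
    g$transcribed <- list()
    g$notes <- character()
    g
}
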