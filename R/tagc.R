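# Taxon-annotated GC-coverage (TAGC) scaffold screening.
#
# Scaffolds are partitioned by the taxon composition of their similarity
# hits: fully symbiont-covered scaffolds are the symbiont genome, scaffolds
# carrying both symbiont and host blocks are HGT candidates, and read depth
# relative to the host and symbiont cohorts is recorded as supporting
# evidence (the candidate signature is symbiont similarity at host-like
# coverage). GC is computed for the blob plot but is deliberately not a
# classification criterion: a host at 36% GC and a symbiont at 35% GC are
# inseparable on that axis.

#' GC fraction of a sequence
#'
#' (G + C) / (A + C + G + T); IUPAC ambiguity codes are excluded from both
#' numerator and denominator. Returns 0 when no unambiguous base is present.
#'
#' @param sequence a [Biostrings::DNAString], length-1 `DNAStringSet`, or
#'   character scalar; must be non-empty.
#' @return GC fraction in \[0, 1\].
#' @export
#' @examples
#' computeGc("ATGC")  # 0.5
#' computeGc("AANN")  # 0 over denominator 2
computeGc <- function(sequence) {
    if (methods::is(sequence, "DNAStringSet")) {
        if (length(sequence) != 1) stop("one sequence at a time")
        sequence <- sequence[[1]]
    }
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(sequence)
    if (length(sequence) == 0)
        stop("empty sequence")
    f <- Biostrings::alphabetFrequency(sequence)
    denom <- sum(f[c("A", "C", "G", "T")])
    if (denom == 0) return(0)
    unname(sum(f[c("G", "C")]) / denom)
}

#' Mean read depth over an interval
#'
#' Arithmetic mean of the per-base depth values over an interval (or the
#' whole track).
#'
#' @param track an [S4Vectors::Rle] depth track (one value per base).
#' @param interval optional [IRanges::IRanges] of length 1 (1-based closed);
#'   default: the whole track.
#' @return mean fold-coverage.
#' @export
meanDepth <- function(track, interval = NULL) {
    if (is.null(interval))
        return(mean(as.numeric(track)))
    if (length(interval) != 1 || IRanges::width(interval) < 1)
        stop("interval must be a single non-empty range")
    if (IRanges::start(interval) < 1 ||
        IRanges::end(interval) > length(track))
        stop("interval outside the depth track")
    mean(as.numeric(S4Vectors::window(track, IRanges::start(interval),
                                      IRanges::end(interval))))
}

#' Per-taxon covered length on a scaffold
#'
#' For each taxon bin, the total length of the union of query intervals of
#' that bin's hits, counting only merged runs of at least `minBlock` bases.
#'
#' @param hits data.frame of hits on one scaffold (columns `taxonBin`,
#'   `qStart`, `qEnd`; see [readTabularHits()]).
#' @param scaffoldLength scaffold length (bp).
#' @param minBlock minimum merged-run length (bp) that counts.
#' @return named numeric vector `c(symbiont = , host = )` of covered bp.
#' @export
assignTaxonCoverage <- function(hits, scaffoldLength, minBlock = 300) {
    if (minBlock <= 0) stop("minBlock must be > 0")
    if (nrow(hits) && any(hits$qEnd > scaffoldLength | hits$qStart < 1))
        stop("hit interval exceeds scaffold bounds")
    covered <- function(bin) {
        h <- hits[hits$taxonBin == bin, , drop = FALSE]
        if (nrow(h) == 0) return(0)
        runs <- IRanges::reduce(IRanges::IRanges(h$qStart, h$qEnd))
        as.numeric(sum(IRanges::width(runs)[
            IRanges::width(runs) >= minBlock]))
    }
    c(symbiont = covered("symbiont"), host = covered("host"))
}

#' Classify one scaffold from taxon coverage and depth
#'
#' Label rules (`len` = scaffold length):
#' * `symbiont` -- symbiont-covered >= `fPure * len` and host-covered
#'   < `minBlock` ("matched completely" to the symbiont);
#' * `hgt_candidate` -- both symbiont- and host-covered >= `minBlock`
#'   (interleaved similarity, the candidate signature);
#' * `host` -- host-covered >= `minBlock` and symbiont-covered < `minBlock`;
#' * `unassigned` otherwise.
#'
#' The depth cluster is the cohort (host-like / symbiont-like) whose
#' reference depth is nearest in log2, or `intermediate` when the scaffold
#' depth is within `log2(tauDepth)` of both references.
#'
#' @param scaffoldLength scaffold length (bp).
#' @param coverage named vector from [assignTaxonCoverage()].
#' @param scaffoldDepth mean depth of the scaffold.
#' @param depthRefs named vector `c(host = , symbiont = )` of cohort
#'   reference (median) depths, both > 0.
#' @param fPure fraction of the scaffold that must be symbiont-covered to
#'   count as "matched completely".
#' @param minBlock minimum covered run (bp).
#' @param tauDepth depth-ratio band for the `intermediate` cluster.
#' @return list with `label`, `depthCluster` and `notes`.
#' @export
classifyScaffold <- function(scaffoldLength, coverage, scaffoldDepth,
                             depthRefs, fPure = 0.90, minBlock = 300,
                             tauDepth = 1.5) {
    if (any(depthRefs <= 0)) stop("depthRefs must be > 0")
    sym <- coverage[["symbiont"]]
    hos <- coverage[["host"]]
    label <- if (sym >= minBlock && hos >= minBlock) "hgt_candidate"
        else if (sym >= fPure * scaffoldLength && hos < minBlock) "symbiont"
        else if (hos >= minBlock && sym < minBlock) "host"
        else "unassigned"
    eps <- 0.5
    dH <- abs(log2((scaffoldDepth + eps) / (depthRefs[["host"]] + eps)))
    dS <- abs(log2((scaffoldDepth + eps) / (depthRefs[["symbiont"]] + eps)))
    band <- log2(tauDepth)
    cluster <- if (dH <= band && dS <= band) "intermediate"
        else if (dH <= dS) "host-like" else "symbiont-like"
    notes <- character()
    if (label == "hgt_candidate" && cluster == "host-like")
        notes <- "interleaved similarity at host-like coverage"
    list(label = label, depthCluster = cluster,
         notes = paste(notes, collapse = "; "))
}

#' Classify every scaffold of an assembly (TAGC screening)
#'
#' Two-pass scheme: labels are assigned from taxon hit coverage alone, then
#' cohort reference depths are taken as the medians over the confidently
#' labelled host and symbiont scaffolds and used to attach a depth cluster to
#' every scaffold (refined once, so candidate scaffolds never contaminate the
#' cohort medians). When a cohort is empty its reference depth falls back to
#' the overall median.
#'
#' @param scaffolds a named [Biostrings::DNAStringSet].
#' @param hits hit table (see [readTabularHits()]) with `queryId` matching
#'   scaffold names.
#' @param depth an [IRanges::RleList] of per-base depth tracks.
#' @param params parameter list, see [hgtParams()].
#' @return data.frame with one row per scaffold: `scaffold`, `length`,
#'   `gcFraction`, `meanDepth`, `symbiontCovered`, `hostCovered`, `label`,
#'   `depthCluster`, `notes`; reference depths in
#'   `attr(, "depthRefs")`.
#' @export
classifyAssembly <- function(scaffolds, hits, depth, params = hgtParams()) {
    ids <- names(scaffolds)
    if (!all(ids %in% names(depth)))
        stop("missing depth track for scaffold '",
             setdiff(ids, names(depth))[1], "'")
    lens <- stats::setNames(Biostrings::width(scaffolds), ids)
    gc <- vapply(ids, function(sc) computeGc(scaffolds[[sc]]), numeric(1))
    md <- vapply(ids, function(sc) meanDepth(depth[[sc]]), numeric(1))
    cov <- t(vapply(ids, function(sc)
        assignTaxonCoverage(hits[hits$queryId == sc, , drop = FALSE],
                            lens[[sc]], params$minBlock),
        numeric(2)))

    # pass 1: labels from hits alone
    lab1 <- vapply(ids, function(sc) {
        classifyScaffold(lens[[sc]], cov[sc, ], md[[sc]],
                         c(host = 1, symbiont = 1),
                         fPure = params$fPure, minBlock = params$minBlock,
                         tauDepth = params$tauDepth)$label
    }, character(1))
    refOf <- function(which) {
        v <- md[lab1 == which]
        if (length(v)) stats::median(v) else stats::median(md)
    }
    refs <- c(host = refOf("host"), symbiont = refOf("symbiont"))

    # pass 2: attach depth clusters against the cohort medians
    out <- do.call(rbind, lapply(ids, function(sc) {
        cl <- classifyScaffold(lens[[sc]], cov[sc, ], md[[sc]], refs,
                               fPure = params$fPure,
                               minBlock = params$minBlock,
                               tauDepth = params$tauDepth)
        data.frame(scaffold = sc, length = unname(lens[[sc]]),
                   gcFraction = unname(gc[[sc]]),
                   meanDepth = unname(md[[sc]]),
                   symbiontCovered = unname(cov[sc, "symbiont"]),
                   hostCovered = unname(cov[sc, "host"]),
                   label = cl$label, depthCluster = cl$depthCluster,
                   notes = cl$notes, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "depthRefs") <- refs
    out
}

#' TAGC blob plot
#'
#' Scatter of scaffolds by GC fraction and log-scaled mean depth, coloured by
#' classification label -- the visual used to separate host, symbiont and
#' candidate bins.
#'
#' @param classification data.frame from [classifyAssembly()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the classification.
#' @export
plotTagc <- function(classification, ...) {
    labs <- c(host = "#1b9e77", symbiont = "#d95f02",
              hgt_candidate = "#7570b3", unassigned = "grey60")
    col <- labs[classification$label]
    graphics::plot(classification$gcFraction,
                   pmax(classification$meanDepth, 0.1),
                   log = "y", col = col, pch = 19,
                   cex = 0.5 + 1.5 * sqrt(classification$length /
                                          max(classification$length)),
                   xlab = "GC fraction", ylab = "mean depth (log scale)",
                   main = "Taxon-annotated GC-coverage plot", ...)
    graphics::legend("topleft", legend = names(labs), col = labs, pch = 19,
                     bty = "n")
    invisible(classification)
}
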