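# Multi-strain evidence for an endosymbiont assembly: three independent
# lines -- reference single-copy genes present at two or more loci,
# single-copy genes with within-sample polymorphism, and marker genes
# duplicated across scaffolds -- plus reference gene-set recovery.

#' Duplicated single-copy genes
#'
#' A gene counts as duplicated when it has at least two placements at
#' identity >= `idMin`, each covering >= `covMin` of the gene length, at loci
#' that do not overlap on the assembly (overlapping placements are split
#' hits of one locus and are merged).
#'
#' @param placements data.frame with columns `geneId`, `scaffold`,
#'   `identity` (fraction), `coverage` (fraction of gene length), `sStart`,
#'   `sEnd`.
#' @param idMin minimum placement identity.
#' @param covMin minimum per-locus coverage of the gene length.
#' @return character vector of duplicated gene ids, sorted.
#' @export
duplicatedSingleCopy <- function(placements, idMin = 0.90, covMin = 0.80) {
    p <- placements[placements$identity >= idMin &
                    placements$coverage >= covMin, , drop = FALSE]
    if (nrow(p) == 0) return(character())
    nLoci <- vapply(split(p, p$geneId), function(d) {
        gr <- GenomicRanges::GRanges(d$scaffold,
                                     IRanges::IRanges(d$sStart, d$sEnd))
        length(GenomicRanges::reduce(gr))
    }, integer(1))
    sort(names(nLoci)[nLoci >= 2])
}

#' Polymorphic single-copy genes
#'
#' A gene is flagged when at least `vMin` variant sites inside it have total
#' read depth >= `dMin` and minor-allele fraction >= `mafMin` -- the
#' within-sample genetic variation expected when reads from several strains
#' collapse onto one assembled locus.
#'
#' @param variants data.frame with columns `scaffold`, `position`,
#'   `refCount`, `altCount`.
#' @param genes a [GenomicRanges::GRanges] of single-copy gene intervals
#'   with a `featureId` metadata column.
#' @param vMin minimum qualifying sites per gene.
#' @param mafMin minimum minor-allele fraction.
#' @param dMin minimum total depth at a site.
#' @return character vector of flagged gene ids, sorted.
#' @export
polymorphicSingleCopy <- function(variants, genes, vMin = 2, mafMin = 0.10,
                                  dMin = 10) {
    if (vMin <= 0 || mafMin <= 0 || dMin <= 0)
        stop("thresholds must be positive")
    if (nrow(variants) == 0 || length(genes) == 0) return(character())
    tot <- variants$refCount + variants$altCount
    maf <- pmin(variants$refCount, variants$altCount) / pmax(tot, 1)
    v <- variants[tot >= dMin & maf >= mafMin, , drop = FALSE]
    if (nrow(v) == 0) return(character())
    sites <- GenomicRanges::GRanges(v$scaffold,
                                    IRanges::IRanges(v$position, width = 1))
    n <- GenomicRanges::countOverlaps(genes, sites)
    sort(genes$featureId[n >= vMin])
}

#' Markers duplicated across scaffolds
#'
#' Marker genes (e.g. the MLST panel or the *cifA*/*cifB* pair) whose
#' placements span at least two distinct scaffolds.
#'
#' @param markerPlacements data.frame with columns `markerId`, `scaffold`.
#' @return character vector of duplicated marker ids, sorted.
#' @export
markerDuplication <- function(markerPlacements) {
    if (nrow(markerPlacements) == 0) return(character())
    n <- vapply(split(markerPlacements$scaffold,
                      markerPlacements$markerId),
                function(s) length(unique(s)), integer(1))
    sort(names(n)[n >= 2])
}

#' Recovery of a reference gene set
#'
#' Count and percentage of a reference gene set found in an assembly. The
#' percentage is truncated (not rounded) to two decimals, matching the
#' convention under which 80 of 84 genes is printed as 95.23\% and 212 of
#' 1796 as 11.80\%.
#'
#' @param reference character vector of reference gene ids (non-empty).
#' @param found character vector of gene ids found.
#' @return list with `nFound` and `percentage`.
#' @export
#' @examples
#' geneSetRecovery(paste0("g", 1:84), paste0("g", 1:80))  # 80, 95.23
geneSetRecovery <- function(reference, found) {
    if (length(reference) == 0)
        stop("reference gene set must be non-empty")
    nFound <- length(intersect(found, reference))
    pct <- floor(1e4 * nFound / length(reference) + 1e-9) / 100
    list(nFound = nFound, percentage = pct)
}

#' Multi-strain evidence report
#'
#' Combines the three evidence lines into a [StrainEvidenceReport-class];
#' the multi-strain flag is raised when the number of duplicated single-copy
#' genes reaches `tDup`, OR the number of polymorphic single-copy genes
#' reaches `tPoly`, OR any marker is duplicated across scaffolds.
#'
#' @param placements see [duplicatedSingleCopy()].
#' @param variants,genes see [polymorphicSingleCopy()].
#' @param markerPlacements see [markerDuplication()].
#' @param nSingleCopyTotal size of the single-copy reference set.
#' @param idMin,covMin,vMin,mafMin,dMin evidence-line thresholds.
#' @param tDup,tPoly flag thresholds on the evidence counts.
#' @return a [StrainEvidenceReport-class].
#' @export
strainReport <- function(placements, variants, genes, markerPlacements,
                         nSingleCopyTotal = length(genes),
                         idMin = 0.90, covMin = 0.80, vMin = 2,
                         mafMin = 0.10, dMin = 10, tDup = 5, tPoly = 5) {
    dup <- duplicatedSingleCopy(placements, idMin = idMin, covMin = covMin)
    poly <- polymorphicSingleCopy(variants, genes, vMin = vMin,
                                  mafMin = mafMin, dMin = dMin)
    mk <- markerDuplication(markerPlacements)
    methods::new("StrainEvidenceReport",
        nDuplicated = length(dup),
        nPolymorphic = length(poly),
        duplicatedMarkers = mk,
        nSingleCopyTotal = as.integer(nSingleCopyTotal),
        multiStrain = length(dup) >= tDup || length(poly) >= tPoly ||
                      length(mk) > 0,
        details = list(duplicatedGenes = dup, polymorphicGenes = poly,
                       thresholds = list(idMin = idMin, covMin = covMin,
                                         vMin = vMin, mafMin = mafMin,
                                         dMin = dMin, tDup = tDup,
                                         tPoly = tPoly)))
}
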