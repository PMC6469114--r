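# Multi-strain evidence lines and gene-set recovery.

test_that("duplication needs two high-identity non-overlapping loci", {
    pl <- function(gene, sc, s, e, id = 0.99, cov = 1)
        data.frame(geneId = gene, scaffold = sc, identity = id,
                   coverage = cov, sStart = s, sEnd = e)
    # loci on two scaffolds at 99% identity: duplicated
    expect_identical(duplicatedSingleCopy(rbind(pl("g1", "s1", 1, 900),
                                                pl("g1", "s9", 50, 950))),
                     "g1")
    # two overlapping placements are a split hit of one locus
    expect_identical(duplicatedSingleCopy(rbind(pl("g2", "s1", 1, 500),
                                                pl("g2", "s1", 400, 900))),
                     character())
    # identity or coverage below threshold does not count
    expect_identical(duplicatedSingleCopy(rbind(pl("g3", "s1", 1, 900),
                                                pl("g3", "s2", 1, 900,
                                                   id = 0.80))),
                     character())
    expect_identical(duplicatedSingleCopy(rbind(pl("g4", "s1", 1, 900),
                                                pl("g4", "s2", 1, 900,
                                                   cov = 0.5))),
                     character())
})

test_that("polymorphism needs enough qualifying sites inside the gene", {
    genes <- GenomicRanges::GRanges("s1", IRanges::IRanges(100, 1000),
                                    featureId = "g1")
    site <- function(pos, refC, altC)
        data.frame(scaffold = "s1", position = pos, refBase = "A",
                   altBase = "G", refCount = refC, altCount = altC)
    # three 50/50 sites with vMin = 2: flagged
    v3 <- rbind(site(200, 30, 30), site(300, 25, 35), site(400, 30, 28))
    expect_identical(polymorphicSingleCopy(v3, genes), "g1")
    # minor-allele fraction below threshold everywhere: not flagged
    low <- rbind(site(200, 60, 2), site(300, 60, 3))
    expect_identical(polymorphicSingleCopy(low, genes), character())
    # depth below dMin: not flagged
    shallow <- rbind(site(200, 3, 3), site(300, 4, 3))
    expect_identical(polymorphicSingleCopy(shallow, genes), character())
    # sites outside the gene do not count
    outside <- rbind(site(2000, 30, 30), site(3000, 30, 30))
    expect_identical(polymorphicSingleCopy(outside, genes), character())
})

test_that("marker duplication means two distinct scaffolds", {
    mp <- data.frame(markerId = c("ftsZ", "ftsZ", "gatB"),
                     scaffold = c("s1", "s9", "s1"))
    expect_identical(markerDuplication(mp), "ftsZ")
    expect_identical(markerDuplication(mp[3, ]), character())
    expect_identical(markerDuplication(mp[0, ]), character())
})

test_that("gene-set recovery truncates its percentage to two decimals", {
    expect_identical(geneSetRecovery(paste0("g", 1:84), paste0("g", 1:80)),
                     list(nFound = 80L, percentage = 95.23))
    expect_identical(geneSetRecovery(paste0("g", 1:1796),
                                     paste0("g", 1:212)),
                     list(nFound = 212L, percentage = 11.80))
    full <- geneSetRecovery(paste0("g", 1:7), paste0("g", 1:7))
    expect_identical(full$percentage, 100)
    expect_error(geneSetRecovery(character(), "g1"), "non-empty")
})

test_that("the multi-strain flag is an OR over the three evidence lines", {
    genes <- GenomicRanges::GRanges("s1", IRanges::IRanges(100, 1000),
                                    featureId = "g1")
    noPl <- data.frame(geneId = character(), scaffold = character(),
                       identity = numeric(), coverage = numeric(),
                       sStart = integer(), sEnd = integer())
    noVar <- data.frame(scaffold = character(), position = integer(),
                        refCount = integer(), altCount = integer())
    onlyMarker <- data.frame(markerId = c("cifA", "cifA"),
                             scaffold = c("s1", "s2"))
    r <- strainReport(noPl, noVar, genes, onlyMarker, nSingleCopyTotal = 1)
    expect_true(multiStrain(r))
    expect_identical(r@duplicatedMarkers, "cifA")
    none <- strainReport(noPl, noVar, genes, onlyMarker[0, ],
                         nSingleCopyTotal = 1)
    expect_false(multiStrain(none))
})

test_that("two-strain simulations raise the flag and the polymorphic set
          matches the planted variant truth", {
    se <- simulateStrainEvidence(nStrains = 2, divergence = 0.03, seed = 31)
    r <- strainReport(se$placements, se$variants, se$genes,
                      se$markerPlacements,
                      nSingleCopyTotal = se$nSingleCopyTotal)
    expect_true(multiStrain(r))
    # duplicated loci recovered exactly (markers duplicate by construction)
    expect_identical(setdiff(r@details$duplicatedGenes,
                             se$markerPlacements$markerId),
                     se$truth$duplicatedGenes)
    expect_setequal(r@duplicatedMarkers,
                    c("ftsZ", "hcpA", "gatB", "cifA", "cifB"))
    # flagged genes are exactly those holding >= 2 planted variant sites at
    # qualifying depth
    sites <- GenomicRanges::GRanges("wsc_main",
        IRanges::IRanges(se$truth$variantPositions, width = 1))
    expected <- sort(se$genes$featureId[
        GenomicRanges::countOverlaps(se$genes, sites) >= 2])
    expect_identical(r@details$polymorphicGenes, expected)
})

test_that("single-strain controls never raise the flag", {
    for (seed in 32:35) {
        se <- simulateStrainEvidence(nStrains = 1, seed = seed)
        r <- strainReport(se$placements, se$variants, se$genes,
                          se$markerPlacements,
                          nSingleCopyTotal = se$nSingleCopyTotal)
        expect_false(multiStrain(r))
        expect_identical(r@nDuplicated, 0L)
        expect_identical(r@nPolymorphic, 0L)
    }
})
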