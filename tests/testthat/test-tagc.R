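# TAGC screening: GC, depth, taxon coverage, and the scaffold partition.

test_that("GC computation handles ambiguity codes and hits simulated
          targets", {
    expect_identical(computeGc("ATGC"), 0.5)
    expect_identical(computeGc("AANN"), 0)   # denominator 2, no G/C
    expect_error(computeGc(""), "empty")
    g <- generateGenome(1e5, 0.3513, seed = 12)
    expect_equal(computeGc(g), 0.3513, tolerance = 0.005 / 0.3513)
})

test_that("mean depth is the arithmetic mean over the interval", {
    expect_identical(meanDepth(S4Vectors::Rle(47, 1000)), 47)
    expect_identical(meanDepth(S4Vectors::Rle(c(0, 0, 10, 10))), 5)
    expect_identical(meanDepth(S4Vectors::Rle(c(0, 0, 10, 10)),
                               IRanges::IRanges(3, 4)), 10)
    expect_error(meanDepth(S4Vectors::Rle(1, 10), IRanges::IRanges(5, 20)),
                 "outside")
})

test_that("taxon coverage is a union, not a sum, and respects minBlock", {
    hit <- function(bin, s, e)
        data.frame(taxonBin = bin, qStart = s, qEnd = e)
    one <- assignTaxonCoverage(hit("symbiont", 1, 1000), 2000)
    expect_identical(one[["symbiont"]], 1000)
    expect_identical(one[["host"]], 0)

    two <- assignTaxonCoverage(rbind(hit("symbiont", 1, 600),
                                     hit("symbiont", 401, 1000)), 2000)
    expect_identical(two[["symbiont"]], 1000)  # union of overlapping hits

    short <- assignTaxonCoverage(hit("symbiont", 1, 200), 2000,
                                 minBlock = 300)
    expect_identical(short[["symbiont"]], 0)

    expect_error(assignTaxonCoverage(hit("host", 1, 3000), 2000), "exceeds")

    # brute-force per-base union oracle on random hit sets
    set.seed(14)
    for (rep in 1:20) {
        n <- sample(1:15, 1)
        s <- sample(1:4500, n, replace = TRUE)
        e <- pmin(5000, s + sample(50:800, n, replace = TRUE))
        got <- assignTaxonCoverage(hit("symbiont", s, e), 5000,
                                   minBlock = 300)
        expect_identical(got[["symbiont"]],
                         bruteCoveredBp(s, e, 5000, 300))
    }
})

test_that("scaffold labels follow the coverage rules and depth clusters
          follow the log2 bands", {
    refs <- c(host = 47, symbiont = 120)
    pure <- classifyScaffold(10000, c(symbiont = 9800, host = 0), 118, refs)
    expect_identical(pure$label, "symbiont")
    expect_identical(pure$depthCluster, "symbiont-like")

    cand <- classifyScaffold(10000, c(symbiont = 4000, host = 5900), 46,
                             refs)
    expect_identical(cand$label, "hgt_candidate")
    expect_identical(cand$depthCluster, "host-like")

    none <- classifyScaffold(10000, c(symbiont = 0, host = 0), 47, refs)
    expect_identical(none$label, "unassigned")

    host <- classifyScaffold(10000, c(symbiont = 0, host = 9000), 47, refs)
    expect_identical(host$label, "host")

    mid <- classifyScaffold(10000, c(symbiont = 0, host = 9000), 80,
                            c(host = 70, symbiont = 100))
    expect_identical(mid$depthCluster, "intermediate")
    expect_error(classifyScaffold(10, c(symbiont = 0, host = 0), 1,
                                  c(host = 0, symbiont = 1)), "depthRefs")
})

test_that("the assembly partition labels every scaffold exactly once and
          recovers the simulated structure", {
    sim <- simulateHgtExperiment(smallConfig(17))
    cl <- classifyAssembly(scaffolds(sim), taxonHits(sim), depthTracks(sim))
    expect_identical(nrow(cl), length(scaffolds(sim)))
    expect_true(all(cl$label %in% c("host", "symbiont", "hgt_candidate",
                                    "unassigned")))
    # pure symbiont scaffolds labelled symbiont at symbiont-like depth
    expect_identical(cl$label[cl$scaffold == "wsc1"], "symbiont")
    expect_identical(cl$depthCluster[cl$scaffold == "wsc1"],
                     "symbiont-like")
    # insertion-bearing host scaffolds are candidates at host-like depth
    insSc <- unique(as.character(GenomicRanges::seqnames(
        truthTable(sim)$insertions)))
    expect_true(all(cl$label[cl$scaffold %in% insSc] == "hgt_candidate"))
    expect_true(all(cl$depthCluster[cl$scaffold %in% insSc] == "host-like"))
    # insertion-free host scaffolds stay host
    freeSc <- setdiff(paste0("scaffold", 1:2), insSc)
    expect_true(all(cl$label[cl$scaffold %in% freeSc] == "host"))
    # chimeras carry both taxa
    expect_identical(cl$label[cl$scaffold == "chimera1"], "hgt_candidate")
})

test_that("classification is invariant to hit order and to splitting a hit
          into abutting pieces", {
    sim <- simulateHgtExperiment(smallConfig(18))
    hits <- taxonHits(sim)
    cl <- classifyAssembly(scaffolds(sim), hits, depthTracks(sim))

    shuffled <- hits[sample(nrow(hits)), ]
    cl2 <- classifyAssembly(scaffolds(sim), shuffled, depthTracks(sim))
    expect_identical(cl$label, cl2$label)

    # split the widest hit into two abutting hits
    i <- which.max(hits$qEnd - hits$qStart)
    mid <- floor((hits$qStart[i] + hits$qEnd[i]) / 2)
    a <- hits[i, ]; b <- hits[i, ]
    a$qEnd <- mid; b$qStart <- mid + 1
    split <- rbind(hits[-i, ], a, b)
    cl3 <- classifyAssembly(scaffolds(sim), split, depthTracks(sim))
    expect_identical(cl$label, cl3$label)
})
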