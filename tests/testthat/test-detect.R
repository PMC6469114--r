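# Candidate segmentation, junction depth testing, corroboration, annotation
# and the verdict rule.

.block <- function(sc, s, e, id = 1) {
    g <- GenomicRanges::GRanges(sc, IRanges::IRanges(s, e))
    g$identity <- id
    g
}

test_that("alternating host/symbiont blocks segment into candidates with
          midpoint junctions", {
    host <- suppressWarnings(c(.block("s", 1, 10000),
                               .block("s", 24191, 30000)))
    sym <- .block("s", 10001, 24190)
    cand <- segmentCandidate(host, sym, 30000)
    expect_length(cand, 1)
    expect_identical(GenomicRanges::width(cand), 14190L)
    expect_identical(cand$leftJunction, 10001L)
    expect_identical(cand$rightJunction, 24191L)

    # symbiont run at the scaffold start with host after: one junction
    edge <- segmentCandidate(.block("s", 30001, 40000),
                             .block("s", 1, 29900), 40000)
    expect_length(edge, 1)
    expect_identical(GenomicRanges::start(edge), 1L)
    expect_true(is.na(edge$leftJunction))
    expect_false(is.na(edge$rightJunction))
    expect_true(edge$atEdge)

    # only host blocks: nothing to call
    expect_length(segmentCandidate(.block("s", 1, 9000),
                                   GenomicRanges::GRanges(), 9000), 0)

    # gap between blocks: junction at the midpoint of the gap
    gap <- segmentCandidate(.block("s", 1, 9900),
                            .block("s", 10101, 20000), 30000)
    expect_identical(gap$leftJunction, 10001L)
})

test_that("junction depth testing applies the closed-form log2 rule", {
    flat <- S4Vectors::Rle(47, 10000)
    jt <- junctionDepthTest(flat, 5000)
    expect_identical(jt$verdict, "continuous")
    expect_identical(jt$log2Ratio, 0)

    step <- c(S4Vectors::Rle(47, 5000), S4Vectors::Rle(120, 5000))
    jt2 <- junctionDepthTest(step, 5001)
    expect_identical(jt2$verdict, "step_change")
    expect_equal(abs(jt2$log2Ratio), log2(120.5 / 47.5), tolerance = 1e-12)
    expect_gt(abs(jt2$log2Ratio), log2(1.5))

    # 50 bp from the scaffold end: the window cannot fit
    expect_identical(junctionDepthTest(flat, 50)$verdict, "indeterminate")
    expect_identical(junctionDepthTest(flat, 9960)$verdict, "indeterminate")
    expect_error(junctionDepthTest(flat, 5000, window = 50), "window")
})

test_that("junction verdicts are symmetric under mirroring the track", {
    set.seed(19)
    for (rep in 1:10) {
        v <- sample(30:130, 2000, replace = TRUE)
        p <- sample(700:1300, 1)
        fwd <- junctionDepthTest(S4Vectors::Rle(v), p)
        rev <- junctionDepthTest(S4Vectors::Rle(rev(v)), length(v) - p + 2)
        expect_identical(fwd$verdict, rev$verdict)
        expect_equal(fwd$log2Ratio, -rev$log2Ratio, tolerance = 1e-9)
    }
})

test_that("corroboration requires one contig spanning the junction", {
    scaffold <- randomSeq(20000, 120)
    junction <- 10001L
    intact <- list(Biostrings::DNAStringSet(c(alt1 = scaffold)))
    expect_identical(corroborateJunction(scaffold, junction, intact), 1L)

    # a forced breakpoint exactly at the junction defeats corroboration
    broken <- list(Biostrings::DNAStringSet(c(
        altA = substr(scaffold, 1, 10000),
        altB = substr(scaffold, 10001, 20000))))
    expect_identical(corroborateJunction(scaffold, junction, broken), 0L)

    expect_identical(corroborateJunction(scaffold, junction, list()), 0L)
    # both assemblies counted independently
    expect_identical(
        corroborateJunction(scaffold, junction, c(intact, broken)), 1L)
})

test_that("transposase proximity is a gap distance with an absence cutoff", {
    cand <- GenomicRanges::GRanges("s", IRanges::IRanges(1000, 2000))
    tps <- function(s, e) {
        g <- GenomicRanges::GRanges("s", IRanges::IRanges(s, e))
        g$featureType <- "transposase"
        g$featureId <- "t"
        g
    }
    expect_identical(transposaseProximity(cand, tps(1000, 2000)), 0L)
    expect_identical(transposaseProximity(cand, tps(1200, 1300)), 0L)
    expect_identical(transposaseProximity(cand, tps(3201, 3400)), 1200L)
    expect_identical(transposaseProximity(cand, tps(9000, 9400)),
                     NA_integer_)
    expect_identical(transposaseProximity(cand, GenomicRanges::GRanges()),
                     NA_integer_)
})

test_that("gene overlap uses >= 1 shared base; abutment does not count", {
    cand <- GenomicRanges::GRanges("s", IRanges::IRanges(1000, 2000))
    gene <- function(id, s, e) {
        g <- GenomicRanges::GRanges("s", IRanges::IRanges(s, e))
        g$featureType <- "gene"
        g$featureId <- id
        g
    }
    feats <- suppressWarnings(c(gene("inside", 1200, 1800),
                                gene("abut", 2001, 2500),
                                gene("spans", 900, 1000)))
    expect_identical(overlapGenes(cand, feats), c("inside", "spans"))
    expect_identical(overlapGenes(cand, GenomicRanges::GRanges()),
                     character())
})

test_that("the transcribed subset thresholds FPKM with absent genes at 0", {
    fpkm <- c(a = 1.6, b = 0.04, c = 0)
    expect_identical(transcribedSubset(c("a", "b", "c"), fpkm, 0.01),
                     c("a", "b"))
    expect_identical(transcribedSubset(c("a", "b", "c"), fpkm, 1), "a")
    expect_identical(transcribedSubset(c("a", "d"), fpkm, 0.01), "a")
    expect_identical(transcribedSubset(character(), fpkm, 0.01),
                     character())
})

test_that("verdicts gate on junction continuity and corroboration", {
    sim <- simulateHgtExperiment(smallConfig(23))
    res <- analyzeSimulation(sim)
    rep <- callReport(res)
    ins <- truthTable(sim)$insertions
    # positive control: the planted insertion is called hgt
    expect_identical(
        rep$verdict[rep$scaffold == as.character(
            GenomicRanges::seqnames(ins))[1] ], "hgt")
    # the constructed chimera is a chimera suspect
    expect_identical(rep$verdict[rep$scaffold == "chimera1"],
                     "chimera_suspect")

    # without any alternative assembly and cMin = 1, evidence gating keeps
    # the same insertion unresolved
    simNoAlt <- sim
    simNoAlt@altAssemblies <- list()
    repNoAlt <- callReport(analyzeSimulation(simNoAlt))
    expect_identical(
        repNoAlt$verdict[repNoAlt$scaffold == as.character(
            GenomicRanges::seqnames(ins))[1] ], "unresolved")
})

test_that("call intervals satisfy length = end - start + 1 and match the
          planted lengths", {
    sim <- simulateHgtExperiment(smallConfig(29))
    rep <- callReport(analyzeSimulation(sim))
    expect_identical(rep$length, rep$end - rep$start + 1L)
    hgt <- rep[rep$verdict == "hgt", ]
    ins <- truthTable(sim)$insertions
    for (i in seq_len(nrow(hgt))) {
        truthW <- GenomicRanges::width(ins)[
            as.character(GenomicRanges::seqnames(ins)) == hgt$scaffold[i]]
        expect_lt(abs(hgt$length[i] - truthW), 2 * 50)
    }
})
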