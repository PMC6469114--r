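# The synthetic-data generator: distributional targets, determinism, and the
# exactness of the planted truth.

test_that("generated genomes hit the target GC and are seed-deterministic", {
    g <- generateGenome(1e5, 0.36, seed = 42)
    expect_equal(computeGc(g), 0.36, tolerance = 0.01 / 0.36)
    g2 <- generateGenome(1e5, 0.36, seed = 42)
    expect_identical(as.character(g), as.character(g2))
    expect_error(generateGenome(100, 1.0), "gc")
    expect_error(generateGenome(0, 0.5), "length")
})

test_that("derived strains substitute at the configured rate and report
          exactly the substituted sites", {
    g <- generateGenome(1e5, 0.35, seed = 7)
    same <- deriveStrain(g, 0)
    expect_identical(as.character(same$sequence), as.character(g))
    expect_length(same$positions, 0)

    d <- deriveStrain(g, 0.01, seed = 8)
    expect_gt(length(d$positions), 900)   # binomial: 1000 +/- 100
    expect_lt(length(d$positions), 1100)
    a <- strsplit(as.character(g), "")[[1]]
    b <- strsplit(as.character(d$sequence), "")[[1]]
    expect_identical(which(a != b), d$positions)
    expect_true(all(a[d$positions] != b[d$positions]))
})

test_that("planted insertions carry exact truth and never overlap", {
    host <- Biostrings::DNAStringSet(c(h1 = randomSeq(5e4, 1),
                                       h2 = randomSeq(5e4, 2)))
    sym <- Biostrings::DNAStringSet(c(w1 = randomSeq(3e4, 3)))
    none <- plantInsertions(host, sym, 0)
    expect_identical(as.character(none$host), as.character(host))
    expect_length(none$insertions, 0)

    p <- plantInsertions(host, sym, 3, lengthRange = c(475, 475), seed = 5)
    ins <- p$insertions
    expect_length(ins, 3)
    expect_true(all(GenomicRanges::width(ins) == 475))
    expect_true(GenomicRanges::isDisjoint(ins))
    # modified scaffold lengths grew by exactly the planted bases
    grown <- sum(Biostrings::width(p$host)) - sum(Biostrings::width(host))
    expect_identical(grown, 3L * 475L)
    # the planted subsequence equals its recorded symbiont source
    for (i in seq_along(ins)) {
        sc <- as.character(GenomicRanges::seqnames(ins))[i]
        planted <- as.character(Biostrings::subseq(
            p$host[[sc]], GenomicRanges::start(ins)[i],
            GenomicRanges::end(ins)[i]))
        source <- as.character(Biostrings::subseq(
            sym[[ins$srcScaffold[i]]], ins$srcStart[i], ins$srcEnd[i]))
        expect_identical(planted, source)
    }
    # a transposase feature accompanies each insertion within 2 kb
    expect_length(p$transposases, 3)
    expect_true(all(suppressWarnings(GenomicRanges::distance(
        p$transposases, ins[match(p$transposases$featureId,
                                  paste0("tps_", seq_along(ins)))])) == 0))
})

test_that("read simulation produces the exact read count and an exact
          depth track", {
    reps <- Biostrings::DNAStringSet(c(r1 = randomSeq(1e4, 11)))
    sim <- simulateReads(reps, 10, readLength = 100, seed = 1)
    expect_length(sim$placements, 1000)      # round(10 * 1e4 / 100)
    expect_equal(mean(as.numeric(sim$depth[["r1"]])), 10, tolerance = 0.05)
    # a depth track is the exact coverage of the placements
    cov <- IRanges::coverage(IRanges::ranges(sim$placements), width = 1e4)
    expect_identical(as.numeric(sim$depth[["r1"]]), as.numeric(cov))

    one <- simulateReads(Biostrings::DNAStringSet(c(x = strrep("A", 200))),
                         100 / 200, readLength = 100, seed = 3)
    expect_length(one$placements, 1)
    tr <- as.numeric(one$depth[["x"]])
    s <- GenomicRanges::start(one$placements)
    expect_identical(sum(tr == 1), 100L)
    expect_true(all(tr[s:(s + 99)] == 1))
    expect_warning(
        simulateReads(Biostrings::DNAStringSet(c(x = strrep("A", 200))),
                      0.01, readLength = 100), "zero reads")
})

test_that("simulated FASTQ is byte-identical for a fixed seed", {
    reps <- Biostrings::DNAStringSet(c(r1 = randomSeq(2000, 21)))
    f1 <- tempfile(fileext = ".fastq")
    f2 <- tempfile(fileext = ".fastq")
    writeSimulatedFastq(
        simulateReads(reps, 5, seed = 9, emitReads = TRUE)$reads, f1)
    writeSimulatedFastq(
        simulateReads(reps, 5, seed = 9, emitReads = TRUE)$reads, f2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    expect_identical(readLines(f1)[4], strrep("I", 100))
})

test_that("chimeras step in depth exactly at the recorded junction", {
    h <- randomSeq(5000, 31)
    s <- randomSeq(5000, 32)
    # exact Rle tracks: the step sits precisely at the junction
    mk <- makeChimera(h, s, S4Vectors::Rle(47, 5000), S4Vectors::Rle(120, 5000))
    expect_identical(mk$junction, 5000L)
    expect_identical(length(mk$depth), 10000L)
    expect_identical(as.numeric(mk$depth[5000]), 47)
    expect_identical(as.numeric(mk$depth[5001]), 120)

    # simulated tracks: the window-mean ratio across the junction matches
    # the configured 120/47 within sampling noise
    mk2 <- makeChimera(h, s, 47, 120, seed = 4)
    left <- mean(as.numeric(S4Vectors::window(mk2$depth, 4001, 4900)))
    right <- mean(as.numeric(S4Vectors::window(mk2$depth, 5101, 6000)))
    expect_equal(right / left, 120 / 47, tolerance = 0.15)

    # equal depths: the designed confound, continuous by depth alone
    mk3 <- makeChimera(h, s, S4Vectors::Rle(47, 5000), S4Vectors::Rle(47, 5000))
    jt <- junctionDepthTest(mk3$depth, mk3$junction + 1)
    expect_identical(jt$verdict, "continuous")
})

test_that("shredded assemblies tile the genome without gaps or overlaps", {
    genome <- Biostrings::DNAStringSet(c(g1 = randomSeq(1e5, 41)))
    alt <- shredAssembly(genome, 1e4, seed = 2)
    og <- S4Vectors::metadata(alt)$origin
    # roughly Poisson-many contigs at 100 kb / 10 kb
    expect_gt(length(alt), 3)
    expect_lt(length(alt), 25)
    og <- og[order(og$srcStart), ]
    expect_identical(og$srcStart, c(1L, og$srcEnd[-nrow(og)] + 1L))
    expect_identical(og$srcEnd[nrow(og)], 1e5L)
    rebuilt <- paste(vapply(og$contig, function(cn)
        as.character(alt[[cn]]), character(1)), collapse = "")
    expect_identical(rebuilt, as.character(genome[[1]]))
    expect_error(shredAssembly(genome, 500), ">= 1 kb")
})

test_that("a whole simulated bundle is deterministic in its seed", {
    s1 <- simulateHgtExperiment(smallConfig(99))
    s2 <- simulateHgtExperiment(smallConfig(99))
    expect_identical(as.character(scaffolds(s1)), as.character(scaffolds(s2)))
    expect_identical(truthTable(s1)$insertions, truthTable(s2)$insertions)
    expect_identical(taxonHits(s1), taxonHits(s2))
    expect_identical(as.list(depthTracks(s1)), as.list(depthTracks(s2)))
})
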