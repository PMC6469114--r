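# The k-mer anchor-chaining aligner, against planted truth and the
# brute-force maximal-exact-match oracle.

test_that("an exact planted copy is recovered as one near-complete block", {
    ref <- c(w1 = randomSeq(3e4, 101))
    copy <- substr(ref[[1]], 10001, 15000)
    qry <- paste0(randomSeq(4000, 102), copy, randomSeq(4000, 103))
    b <- anchorChainAlign(qry, ref, minBlock = 300)
    expect_gte(length(b), 1)
    main <- b[which.max(GenomicRanges::width(b))]
    expect_gte(GenomicRanges::width(main), 0.99 * 5000)
    expect_gte(main$identity, 0.9)
    expect_equal(GenomicRanges::start(main), 4001, tolerance = 25)
    expect_equal(main$refStart, 10001, tolerance = 25)
})

test_that("queries sharing no k-mers yield no blocks", {
    b <- anchorChainAlign(randomSeq(2000, 104), c(r = randomSeq(2000, 105)),
                          minBlock = 300)
    expect_length(b, 0)
})

test_that("a copy with 1% substitutions still chains into one block", {
    ref <- c(w1 = randomSeq(2e4, 106))
    copy <- substr(ref[[1]], 5001, 10000)
    mut <- deriveStrain(copy, 0.01, seed = 107)
    qry <- paste0(randomSeq(3000, 108), as.character(mut$sequence),
                  randomSeq(3000, 109))
    b <- anchorChainAlign(qry, ref, k = 21, maxGap = 500, minBlock = 300)
    main <- b[which.max(GenomicRanges::width(b))]
    expect_length(main, 1)
    expect_gte(GenomicRanges::width(main), 0.95 * 5000)
    # anchored fraction tracks the 21-mer survival probability 0.99^21
    expect_gt(main$identity, 0.5)
})

test_that("repetitive k-mers beyond mRep are skipped as anchors", {
    motif <- randomSeq(30, 110)
    ref <- c(r = paste(rep(motif, 40), collapse = ""))
    qry <- paste0(randomSeq(500, 111), motif, randomSeq(500, 112))
    # every motif k-mer occurs 40 times in the reference: all skipped
    b <- anchorChainAlign(qry, ref, mRep = 10, minBlock = 30)
    expect_length(b, 0)
})

test_that("chained blocks match the brute-force exact-match finder on
          random pairs with planted shared segments", {
    set.seed(113)
    for (rep in 1:30) {
        nq <- sample(500:2000, 1)
        nr <- sample(500:2000, 1)
        q <- randomSeq(nq)
        r <- randomSeq(nr)
        if (rep %% 2 == 0) {  # plant a shared segment in half the pairs
            w <- sample(300:450, 1)
            frag <- randomSeq(w)
            qp <- sample(nq - w, 1)
            rp <- sample(nr - w, 1)
            substr(q, qp, qp + w - 1) <- frag
            substr(r, rp, rp + w - 1) <- frag
        }
        oracle <- bruteForceBlocks(q, r, minBlock = 300)
        got <- anchorChainAlign(q, r, k = 21, maxGap = 50, minBlock = 300)
        expect_identical(length(got), nrow(oracle))
        if (nrow(oracle)) {
            expect_identical(GenomicRanges::start(got), oracle$qstart)
            expect_identical(GenomicRanges::end(got), oracle$qend)
            expect_identical(got$refStart, oracle$rstart)
            expect_identical(got$refEnd, oracle$rend)
            expect_true(all(got$identity == 1))
        }
    }
})

test_that("aligner preconditions are enforced", {
    expect_error(anchorChainAlign("ACGT", c(r = randomSeq(100, 114))),
                 "shorter than k")
    expect_error(kmerIndex(c(r = randomSeq(100, 115)), k = 5), "k must")
})
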