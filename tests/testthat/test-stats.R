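# Contiguity metrics and exact library accounting.

test_that("Nxx/Lxx follow the cumulative-length definition", {
    expect_identical(nxx(c(10, 4, 3, 2, 1), 50), c(nxx = 10, lxx = 1))
    # all contigs equal: Nxx is that length, Lxx = ceil(n * x / 100)
    expect_identical(nxx(rep(500, 7), 50), c(nxx = 500, lxx = 4))
    expect_identical(nxx(rep(500, 8), 50), c(nxx = 500, lxx = 4))
    # a single contig qualifies for any x
    expect_identical(nxx(1234, 75), c(nxx = 1234, lxx = 1))
    expect_error(nxx(numeric(), 50), "non-empty")
    expect_error(nxx(c(10, 0), 50), "> 0")
    expect_error(nxx(10, 100), "x must")
})

test_that("Nxx matches the brute-force oracle on random multisets", {
    set.seed(37)
    for (rep in 1:200) {
        lens <- sample(1:5000, sample(1:200, 1), replace = TRUE)
        x <- sample(c(25, 50, 75, 90), 1)
        expect_identical(nxx(lens, x), bruteNxx(lens, x))
    }
})

test_that("Nxx is monotone non-increasing and Lxx non-decreasing in x", {
    set.seed(38)
    for (rep in 1:20) {
        lens <- sample(1:5000, sample(2:100, 1), replace = TRUE)
        xs <- c(10, 25, 50, 75, 90)
        res <- vapply(xs, function(x) nxx(lens, x), numeric(2))
        expect_true(all(diff(res["nxx", ]) <= 0))
        expect_true(all(diff(res["lxx", ]) >= 0))
    }
})

test_that("threshold counts report contig count and genome fraction", {
    cg <- countsGe(c(500, 1500, 2000), 1000)
    expect_identical(cg$count, 2L)
    expect_identical(cg$fraction, 3500 / 4000)
    expect_identical(countsGe(c(500, 1500, 2000), 1)$count, 3L)
    expect_identical(countsGe(c(500, 1500, 2000), 1)$fraction, 1)
    high <- countsGe(c(500, 1500, 2000), 10000)
    expect_identical(high$count, 0L)
    expect_identical(high$fraction, 0)
})

test_that("library accounting reproduces printed totals exactly", {
    expect_identical(
        libraryAccounting(c(22.68, 8.54, 8.84, 13.23, 14.51, 11.77, 20.40)),
        99.97)
    expect_identical(libraryAccounting(numeric()), 0)
    expect_identical(libraryAccounting(1.00), 1.00)
    # the naive float sum drifts; the fixed-point sum does not
    many <- rep(0.01, 1000)
    expect_identical(libraryAccounting(many), 10)
    expect_error(libraryAccounting(c(1, -2)), ">= 0")
})

test_that("assembly GC equals the length-weighted mean of per-contig GC", {
    set.seed(39)
    asm <- Biostrings::DNAStringSet(c(a = randomSeq(3000), b = randomSeq(800),
                                      c = randomSeq(12000)))
    st <- assemblyStats(asm)
    perContig <- vapply(seq_along(asm), function(i) computeGc(asm[[i]]),
                        numeric(1))
    w <- Biostrings::width(asm)
    expect_equal(st@gcPercent, 100 * sum(perContig * w) / sum(w),
                 tolerance = 1e-12)
    expect_identical(st@totalLength, sum(w))
    expect_gte(st@n50, st@n75)
    expect_lte(st@l50, st@l75)
})
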