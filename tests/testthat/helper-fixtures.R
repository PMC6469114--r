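# Shared fixtures and independent oracles.

# small, fast simulation used by unit tests (the full-size study conditions
# live in the acceptance suite)
smallConfig <- function(seed, ...) {
    args <- list(seed = seed, hostLength = 2e5, hostScaffolds = 2,
                 symbiontLength = 6e4, symbiontScaffolds = 1,
                 nInsertions = 1, insertionMin = 500,
                 insertionMax = 5000, chimeraCount = 1,
                 chimeraFragment = 10000, meanFragment = 2e4)
    args[names(list(...))] <- list(...)
    do.call(simulationConfig, args)
}

randomSeq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force O(n*m) maximal exact-match block finder: scans every diagonal
# for runs of matching bases; reports runs >= minBlock as blocks
# (qstart, qend, rstart, rend). Independent of the k-mer/chaining path.
bruteForceBlocks <- function(query, reference, minBlock) {
    q <- strsplit(query, "")[[1]]
    r <- strsplit(reference, "")[[1]]
    nq <- length(q); nr <- length(r)
    out <- list()
    for (d in (-(nq - 1)):(nr - 1)) {
        qi <- max(1, 1 - d):min(nq, nr - d)
        if (length(qi) < minBlock) next
        m <- q[qi] == r[qi + d]
        rl <- rle(m)
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1
        for (j in which(rl$values & rl$lengths >= minBlock)) {
            qs <- qi[starts[j]]; qe <- qi[ends[j]]
            out[[length(out) + 1]] <- data.frame(
                qstart = qs, qend = qe, rstart = qs + d, rend = qe + d)
        }
    }
    if (!length(out))
        return(data.frame(qstart = integer(), qend = integer(),
                          rstart = integer(), rend = integer()))
    res <- do.call(rbind, out)
    res[order(res$qstart, res$rstart), , drop = FALSE]
}

# brute-force Nxx oracle: walk the descending lengths accumulating until the
# cumulative sum reaches x percent of the total
bruteNxx <- function(lengths, x) {
    s <- sort(lengths, decreasing = TRUE)
    target <- sum(s) * x / 100
    acc <- 0
    for (i in seq_along(s)) {
        acc <- acc + s[i]
        if (acc >= target - 1e-9) return(c(nxx = s[i], lxx = i))
    }
}

# brute-force per-base coverage union oracle for assignTaxonCoverage
bruteCoveredBp <- function(starts, ends, scaffoldLength, minBlock) {
    covered <- logical(scaffoldLength)
    for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
    rl <- rle(covered)
    as.numeric(sum(rl$lengths[rl$values & rl$lengths >= minBlock]))
}
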