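# Assembly contiguity and composition metrics, and library accounting.

#' Nxx / Lxx contiguity statistics
#'
#' Contig lengths are sorted in descending order; Nxx is the length of the
#' first contig at which the cumulative length reaches x% of the total, and
#' Lxx is the 1-based count of contigs up to and including it. Ties report
#' the qualifying contig's own length (the standard QUAST-style definition).
#'
#' @param lengths contig lengths (bp), non-empty, all > 0.
#' @param x percentage in (0, 100).
#' @return named numeric vector `c(nxx = , lxx = )`.
#' @export
#' @examples
#' nxx(c(10, 4, 3, 2, 1), 50)  # N50 = 10, L50 = 1
nxx <- function(lengths, x) {
    if (length(lengths) == 0) stop("lengths must be non-empty")
    if (any(lengths <= 0)) stop("lengths must be > 0")
    if (x <= 0 || x >= 100) stop("x must lie in (0, 100)")
    s <- sort(lengths, decreasing = TRUE)
    idx <- which(cumsum(s) >= sum(s) * x / 100 - 1e-9)[1]
    c(nxx = s[idx], lxx = idx)
}

#' Contig counts above length thresholds
#'
#' For each threshold, the number of contigs at least that long and the
#' fraction of the total assembly length they contain.
#'
#' @param lengths contig lengths (bp).
#' @param thresholds length thresholds (bp), > 0.
#' @return data.frame with columns `threshold`, `count`, `fraction`.
#' @export
countsGe <- function(lengths, thresholds) {
    if (any(thresholds <= 0)) stop("thresholds must be > 0")
    total <- sum(lengths)
    do.call(rbind, lapply(thresholds, function(t) {
        keep <- lengths >= t
        data.frame(threshold = t, count = sum(keep),
                   fraction = if (total > 0) sum(lengths[keep]) / total
                              else 0)
    }))
}

#' Sum per-library sequencing yields exactly
#'
#' Sums yields quoted in gigabases with two-decimal fixed-point arithmetic,
#' so that printed per-library yields reproduce their printed total without
#' binary floating-point drift.
#'
#' @param yields numeric vector of per-library yields (gigabases), >= 0.
#' @return the total, exact to two decimals.
#' @export
#' @examples
#' libraryAccounting(c(22.68, 8.54, 8.84, 13.23, 14.51, 11.77, 20.40))
libraryAccounting <- function(yields) {
    if (length(yields) == 0) return(0)
    if (any(yields < 0)) stop("yields must be >= 0")
    sum(round(yields * 100)) / 100
}

#' Assembly statistics
#'
#' Computes the contiguity and composition summary of an assembly: total
#' length, contig count, N50/N75, L50/L75, GC percentage (length-weighted
#' over contigs) and contig counts above length thresholds.
#'
#' @param assembly a [Biostrings::DNAStringSet] (or numeric contig lengths,
#'   in which case GC is reported as `NA`).
#' @param thresholds length thresholds (bp) for [countsGe()].
#' @return an [AssemblyStats-class].
#' @export
assemblyStats <- function(assembly, thresholds = c(1000, 50000)) {
    if (is.numeric(assembly)) {
        lens <- assembly
        gcp <- NA_real_
    } else {
        lens <- Biostrings::width(assembly)
        f <- Biostrings::alphabetFrequency(assembly)
        acgt <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
        gcp <- 100 * sum(f[, c("G", "C")]) / sum(acgt)
    }
    s50 <- nxx(lens, 50)
    s75 <- nxx(lens, 75)
    methods::new("AssemblyStats",
        totalLength = sum(lens), nContigs = length(lens),
        n50 = unname(s50["nxx"]), n75 = unname(s75["nxx"]),
        l50 = as.integer(s50["lxx"]), l75 = as.integer(s75["lxx"]),
        gcPercent = gcp, countsGe = countsGe(lens, thresholds))
}
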