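# Light k-mer anchor-chaining aligner.
#
# Exact k-mers shared between query and reference are used as anchors
# (k-mers occurring more than mRep times in the reference are skipped as
# repetitive), runs of consecutive anchors on one diagonal are collapsed into
# exact segments, and collinear segments separated by at most maxGap bases on
# both sequences are chained into similarity blocks. Block identity is the
# fraction of the block span covered by anchored bases. This stands in for a
# whole-genome aligner at the scale where both sequences fit comfortably in
# memory; it is forward-strand only (the detection evidence is
# strand-agnostic and simulated insertions are forward copies).

.BASE_CODE <- local({
    m <- rep(NA_real_, 256)
    m[utf8ToInt("A") + 1] <- 0
    m[utf8ToInt("C") + 1] <- 1
    m[utf8ToInt("G") + 1] <- 2
    m[utf8ToInt("T") + 1] <- 3
    m
})

.seqCodes <- function(seq) {
    # 0..3 per base, NA for ambiguity codes
    .BASE_CODE[as.integer(charToRaw(as.character(seq))) + 1]
}

.kmerKeys <- function(codes, k) {
    n <- length(codes)
    if (n < k) return(numeric(0))
    m <- n - k + 1
    key <- numeric(m)
    for (j in seq_len(k))               # 4^k < 2^53 for k <= 26: exact
        key <- key * 4 + codes[j:(m + j - 1)]
    key
}

#' Build a k-mer index of a reference
#'
#' Precomputes the k-mer position table of a reference sequence set so that
#' several queries can be aligned against it without re-hashing (used by the
#' pipeline, which aligns every candidate scaffold against the same
#' references). K-mers occurring more than `mRep` times in the whole
#' reference are dropped as repetitive.
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character vector).
#' @param k k-mer (anchor word) size; at least 11. With the double-precision
#'   packing used, k can be at most 26.
#' @param mRep maximum reference multiplicity of a usable k-mer.
#' @return an opaque index object for [anchorChainAlign()].
#' @export
kmerIndex <- function(reference, k = 21, mRep = 10) {
    if (k < 11 || k > 26)
        stop("k must lie in [11, 26]")
    if (is.character(reference))
        reference <- Biostrings::DNAStringSet(reference)
    if (is.null(names(reference)))
        names(reference) <- paste0("ref", seq_along(reference))
    tabs <- lapply(seq_along(reference), function(i) {
        keys <- .kmerKeys(.seqCodes(reference[[i]]), k)
        if (!length(keys)) return(NULL)
        data.table::data.table(code = keys, rid = i,
                               rpos = seq_along(keys))
    })
    dt <- data.table::rbindlist(tabs)
    if (nrow(dt)) {
        dt <- dt[!is.na(dt$code)]
        cnt <- NULL  # NSE guard
        dt[, cnt := .N, by = "code"]
        dt <- dt[dt$cnt <= mRep, c("code", "rid", "rpos"), with = FALSE]
        data.table::setkeyv(dt, "code")
    }
    structure(list(table = dt, k = k, mRep = mRep,
                   refNames = names(reference),
                   refWidths = Biostrings::width(reference)),
              class = "kmerIndex")
}

# Collapse anchors into exact diagonal segments, then chain collinear
# segments. Returns a data.table of blocks.
.chainAnchors <- function(anchors, k, maxGap, minBlock) {
    k <- as.integer(k)
    empty <- data.table::data.table(
        qstart = integer(), qend = integer(), rid = integer(),
        rstart = integer(), rend = integer(), identity = numeric(),
        anchors = integer())
    if (nrow(anchors) == 0) return(empty)
    diag <- anchors$rpos - anchors$qpos
    o <- order(anchors$rid, diag, anchors$qpos)
    rid <- anchors$rid[o]; dg <- diag[o]; qp <- anchors$qpos[o]
    newseg <- c(TRUE, rid[-1] != rid[-length(rid)] |
                      dg[-1] != dg[-length(dg)] |
                      qp[-1] != qp[-length(qp)] + 1L)
    segid <- cumsum(newseg)
    first <- which(newseg)
    last <- c(first[-1] - 1L, length(qp))
    seg <- data.table::data.table(
        qs = qp[first], qe = qp[last] + k - 1L,
        rs = qp[first] + dg[first], re = qp[last] + dg[last] + k - 1L,
        rid = rid[first])
    data.table::setorderv(seg, c("rid", "qs", "rs"))

    qs <- seg$qs; qe <- seg$qe; rs <- seg$rs; re <- seg$re; srid <- seg$rid
    blocks <- vector("list", length(qs))
    nb <- 0L
    cur <- NULL
    flush <- function(chain) {
        span <- chain$qend - chain$qstart + 1L
        if (span < minBlock) return(NULL)
        chain$identity <- min(1, chain$covered / span)
        chain$covered <- NULL
        chain
    }
    for (i in seq_along(qs)) {
        if (!is.null(cur) &&
            srid[i] == cur$rid &&
            (qs[i] - cur$qend - 1L) <= maxGap &&
            (qs[i] - cur$qend - 1L) >= -(k - 1L) &&
            (rs[i] - cur$rend - 1L) <= maxGap &&
            (rs[i] - cur$rend - 1L) >= -(k - 1L)) {
            add <- max(0L, qe[i] - max(qs[i], cur$qend + 1L) + 1L)
            cur$covered <- cur$covered + add
            cur$anchors <- cur$anchors + (qe[i] - qs[i] - k + 2L)
            cur$qend <- max(cur$qend, qe[i])
            cur$rend <- max(cur$rend, re[i])
        } else {
            if (!is.null(cur)) {
                b <- flush(cur)
                if (!is.null(b)) { nb <- nb + 1L; blocks[[nb]] <- b }
            }
            cur <- list(qstart = qs[i], qend = qe[i], rid = srid[i],
                        rstart = rs[i], rend = re[i],
                        covered = qe[i] - qs[i] + 1L,
                        anchors = qe[i] - qs[i] - k + 2L)
        }
    }
    if (!is.null(cur)) {
        b <- flush(cur)
        if (!is.null(b)) { nb <- nb + 1L; blocks[[nb]] <- b }
    }
    if (nb == 0L) return(empty)
    out <- data.table::rbindlist(blocks[seq_len(nb)])
    data.table::setcolorder(out, c("qstart", "qend", "rid", "rstart",
                                   "rend", "identity", "anchors"))
    data.table::setorderv(out, "qstart")
    out
}

#' Align a query against a reference by k-mer anchor chaining
#'
#' Finds similarity blocks between one query sequence and a reference
#' sequence set: exact shared k-mers are anchored, collapsed into exact
#' diagonal segments and chained when collinear with gaps of at most
#' `maxGap` bases on both sequences; chains shorter than `minBlock` on the
#' query are dropped. Each block lies within a single reference sequence.
#'
#' @param query a single sequence ([Biostrings::DNAString], length-1
#'   `DNAStringSet`, or character scalar). Its name (default `"query"`) is
#'   used as the seqname of the result.
#' @param reference a [Biostrings::DNAStringSet] / named character vector, or
#'   a prebuilt [kmerIndex()].
#' @param k anchor word size (>= 11).
#' @param maxGap maximum gap (bp) between chained anchors, on both sequences.
#' @param minBlock minimum block span (bp) on the query.
#' @param mRep maximum reference multiplicity of a usable k-mer.
#' @return a [GenomicRanges::GRanges] on the query, sorted by start, with
#'   metadata columns `refId`, `refStart`, `refEnd`, `identity` (anchored
#'   bases / block span) and `anchors` (number of anchoring k-mers).
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(w1 = paste(
#'     sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")))
#' qry <- as.character(Biostrings::subseq(ref[[1]], 501, 1500))
#' anchorChainAlign(qry, ref, minBlock = 300)
anchorChainAlign <- function(query, reference, k = 21, maxGap = 500,
                             minBlock = 300, mRep = 10) {
    if (inherits(reference, "kmerIndex")) {
        idx <- reference
        if (idx$k != k)
            stop("index was built with k = ", idx$k)
    } else {
        idx <- kmerIndex(reference, k = k, mRep = mRep)
    }
    qname <- "query"
    if (methods::is(query, "DNAStringSet")) {
        if (length(query) != 1)
            stop("query must be a single sequence")
        if (!is.null(names(query))) qname <- names(query)[1]
        query <- query[[1]]
    } else if (is.character(query)) {
        if (length(query) != 1)
            stop("query must be a single sequence")
        if (!is.null(names(query))) qname <- names(query)[1]
    }
    qseq <- as.character(query)
    if (nchar(qseq) < k)
        stop("query shorter than k")
    keys <- .kmerKeys(.seqCodes(qseq), k)
    dtq <- data.table::data.table(code = keys, qpos = seq_along(keys))
    dtq <- dtq[!is.na(dtq$code)]
    if (nrow(idx$table) == 0 || nrow(dtq) == 0) {
        anchors <- data.table::data.table(rid = integer(), rpos = integer(),
                                          qpos = integer())
    } else {
        anchors <- idx$table[dtq, on = "code", nomatch = NULL,
                             allow.cartesian = TRUE]
    }
    blocks <- .chainAnchors(anchors, k, maxGap, minBlock)
    gr <- GenomicRanges::GRanges(
        rep(qname, nrow(blocks)),
        IRanges::IRanges(start = blocks$qstart, end = blocks$qend))
    gr$refId <- idx$refNames[blocks$rid]
    gr$refStart <- blocks$rstart
    gr$refEnd <- blocks$rend
    gr$identity <- blocks$identity
    gr$anchors <- blocks$anchors
    gr
}
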