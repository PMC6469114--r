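# Readers and writers for the external formats the pipeline touches.
#
# Internal convention: 1-based, closed intervals (the native IRanges/GRanges
# convention). Every dialect conversion happens here, exactly once:
#   * BLAST tabular and GFF3 are natively 1-based inclusive (no shift);
#     reversed subject coordinates are normalised to forward with the strand
#     recorded.
#   * BED is 0-based half-open; rtracklayer performs the conversion on both
#     read and write.
#   * Printed intervals of the form "scaffold83: 2271642-2,272,117" follow the
#     convention that the printed length equals end - start; see
#     parsePrintedInterval().

#' Read assembly scaffolds from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces
#' non-empty headers and sequences, trims headers at the first whitespace and
#' upper-cases sequences (IUPAC ambiguity codes are preserved).
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] in file order.
#' @export
readFastaScaffolds <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0)
        stop("no FASTA records in ", path)
    if (any(!nzchar(names(x))))
        stop("FASTA record ", which(!nzchar(names(x)))[1], " in ", path,
             " has an empty header")
    if (any(Biostrings::width(x) == 0))
        stop("FASTA record '", names(x)[Biostrings::width(x) == 0][1],
             "' has an empty sequence")
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaScaffolds <- function(x, path) {
    if (!methods::is(x, "DNAStringSet"))
        x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a taxon-annotated similarity hit table (BLAST tabular dialect)
#'
#' Parses 12-column BLAST `outfmt 6` rows (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore; 1-based inclusive
#' coordinates). Reversed subject coordinates are normalised to forward
#' intervals with strand `-` recorded. Each subject is assigned a taxon bin
#' through `taxonMap`; subjects absent from the map are labelled `"other"`.
#'
#' @param path path to the tab-separated hit table.
#' @param taxonMap named character vector mapping subject id to taxon bin
#'   (typically `"host"` or `"symbiont"`).
#' @return data.frame with columns `queryId`, `subjectId`, `taxonBin`,
#'   `percentIdentity`, `qStart`, `qEnd`, `sStart`, `sEnd`, `strand`,
#'   `bitscore`.
#' @export
readTabularHits <- function(path, taxonMap = character()) {
    dt <- if (file.size(path) == 0) data.frame()
          else data.table::fread(path, header = FALSE, sep = "\t",
                                 colClasses = "character",
                                 data.table = FALSE)
    if (nrow(dt) == 0)
        return(data.frame(queryId = character(), subjectId = character(),
                          taxonBin = character(), percentIdentity = numeric(),
                          qStart = integer(), qEnd = integer(),
                          sStart = integer(), sEnd = integer(),
                          strand = character(), bitscore = numeric(),
                          stringsAsFactors = FALSE))
    if (ncol(dt) < 12)
        stop("hit table must have >= 12 tab-separated columns, got ",
             ncol(dt))
    num <- function(col, what) {
        v <- suppressWarnings(as.numeric(dt[[col]]))
        if (anyNA(v))
            stop("non-numeric ", what, " in hit table row ",
                 which(is.na(v))[1])
        v
    }
    qs <- num(7, "query start"); qe <- num(8, "query end")
    ss <- num(9, "subject start"); se <- num(10, "subject end")
    pid <- num(3, "percent identity")
    bits <- num(12, "bitscore")
    if (any(pid < 0 | pid > 100))
        stop("percent identity outside [0, 100] in hit table row ",
             which(pid < 0 | pid > 100)[1])
    if (any(bits < 0))
        stop("negative bitscore in hit table row ", which(bits < 0)[1])
    strand <- ifelse(ss > se | qs > qe, "-", "+")
    hits <- data.frame(
        queryId = dt[[1]], subjectId = dt[[2]],
        taxonBin = unname(ifelse(dt[[2]] %in% names(taxonMap),
                                 taxonMap[dt[[2]]], "other")),
        percentIdentity = pid,
        qStart = as.integer(pmin(qs, qe)), qEnd = as.integer(pmax(qs, qe)),
        sStart = as.integer(pmin(ss, se)), sEnd = as.integer(pmax(ss, se)),
        strand = strand, bitscore = bits, stringsAsFactors = FALSE)
    if (any(hits$qStart < 1 | hits$sStart < 1))
        stop("coordinates must be 1-based positive in hit table")
    hits
}

#' Write a hit table in BLAST tabular dialect
#'
#' Inverse of [readTabularHits()] (coordinates written 1-based inclusive;
#' reverse-strand subject intervals written with reversed coordinates).
#'
#' @param hits data.frame as returned by [readTabularHits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTabularHits <- function(hits, path) {
    rev <- hits$strand == "-"
    out <- data.frame(
        hits$queryId, hits$subjectId, hits$percentIdentity,
        hits$qEnd - hits$qStart + 1L, 0L, 0L,
        hits$qStart, hits$qEnd,
        ifelse(rev, hits$sEnd, hits$sStart),
        ifelse(rev, hits$sStart, hits$sEnd),
        0, hits$bitscore)
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Parse a printed genomic interval
#'
#' Parses intervals printed as `"<scaffold>: <start>-<end>"` (hyphen or
#' en-dash; optional thousands separators), e.g.
#' `"scaffold83: 2271642-2,272,117"`. In this printing convention the length
#' of the interval is `end - start` (all five published insert lengths are
#' consistent with that rule, e.g. 2272117 - 2271642 = 475 bp). Whether the
#' printed start is 0- or 1-based is not recoverable from the lengths alone;
#' the parser therefore fixes the length and maps the interval to the internal
#' 1-based closed convention as `[start + 1, end]`.
#'
#' @param text character vector of printed intervals.
#' @return a [GenomicRanges::GRanges] with one range per input; widths equal
#'   the printed lengths.
#' @export
#' @examples
#' parsePrintedInterval("scaffold83: 2271642-2,272,117")  # width 475
parsePrintedInterval <- function(text) {
    pat <- "^\\s*(\\S+):\\s*([0-9,]+)\\s*[-–—]\\s*([0-9,]+)\\s*$"
    ok <- grepl(pat, text)
    if (any(!ok))
        stop("cannot parse printed interval: '", text[!ok][1], "'")
    id <- sub(pat, "\\1", text)
    s <- as.numeric(gsub(",", "", sub(pat, "\\2", text)))
    e <- as.numeric(gsub(",", "", sub(pat, "\\3", text)))
    if (any(e <= s))
        stop("printed interval end must exceed start: '",
             text[e <= s][1], "'")
    GenomicRanges::GRanges(id, IRanges::IRanges(start = s + 1, end = e))
}

#' Write interval calls to BED
#'
#' Writes 0-based half-open BED (conversion handled by
#' [rtracklayer::export.bed()]), sorted by scaffold then start. An empty call
#' set produces a file holding a single comment line.
#'
#' @param calls a [GenomicRanges::GRanges]; a `name` metadata column is used
#'   as the BED name field when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedCalls <- function(calls, path) {
    if (length(calls) == 0) {
        writeLines("# no calls", path)
        return(invisible(path))
    }
    calls <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(calls))
    keep <- intersect("name", colnames(S4Vectors::mcols(calls)))
    S4Vectors::mcols(calls) <- S4Vectors::mcols(calls)[, keep, drop = FALSE]
    rtracklayer::export.bed(calls, path)
    invisible(path)
}

#' Read interval calls from BED
#'
#' @param path path to a BED file written by [writeBedCalls()].
#' @return a [GenomicRanges::GRanges] (empty if the file holds no intervals).
#' @export
readBedCalls <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0)
        return(GenomicRanges::GRanges())
    gr <- rtracklayer::import.bed(path)
    GenomicRanges::strand(gr) <- "*"
    gr
}

#' Read per-base depth tracks from TSV
#'
#' The dialect is `scaffold <TAB> pos <TAB> depth`, one row per base,
#' 1-based positions. Every scaffold must be covered contiguously from 1 to
#' its length; depths must be non-negative.
#'
#' @param path path to the depth TSV.
#' @param scaffoldLengths optional named vector of expected scaffold lengths;
#'   a track shorter than its scaffold raises an error naming the scaffold.
#' @return an [IRanges::RleList], one run-length encoded track per scaffold.
#' @export
readDepthTsv <- function(path, scaffoldLengths = NULL) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("scaffold", "pos", "depth"))
    if (any(dt$depth < 0))
        stop("negative depth at ", dt$scaffold[dt$depth < 0][1], ":",
             dt$pos[dt$depth < 0][1])
    tracks <- lapply(split(dt, by = "scaffold", sorted = FALSE,
                           keep.by = TRUE), function(d) {
        d <- d[order(d$pos), ]
        if (!identical(as.integer(d$pos), seq_len(nrow(d))))
            stop("depth track for scaffold '", d$scaffold[1],
                 "' is not contiguous from position 1")
        S4Vectors::Rle(d$depth)
    })
    out <- methods::as(tracks, "RleList")
    if (!is.null(scaffoldLengths)) {
        for (sc in names(scaffoldLengths)) {
            if (!sc %in% names(out))
                stop("no depth track for scaffold '", sc, "'")
            if (length(out[[sc]]) != scaffoldLengths[[sc]])
                stop("depth track for scaffold '", sc, "' has ",
                     length(out[[sc]]), " values but the scaffold is ",
                     scaffoldLengths[[sc]], " bp")
        }
    }
    out
}

#' Write per-base depth tracks to TSV
#'
#' Inverse of [readDepthTsv()].
#'
#' @param depth an [IRanges::RleList] (or list of [S4Vectors::Rle]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDepthTsv <- function(depth, path) {
    tabs <- lapply(names(depth), function(sc) {
        v <- as.numeric(depth[[sc]])
        data.table::data.table(scaffold = sc, pos = seq_along(v), depth = v)
    })
    data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t",
                       col.names = FALSE)
    invisible(path)
}

.FEATURE_TYPES <- c("gene", "transposase", "marker")

#' Read gene/transposase/marker features from GFF3
#'
#' Reads GFF3 (1-based inclusive; no conversion needed internally) through
#' [rtracklayer::import.gff3()] and keeps features of type `gene`,
#' `transposase` or `marker`; other types are dropped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return a [GenomicRanges::GRanges] with `featureType` and `featureId`
#'   metadata columns.
#' @export
readGffFeatures <- function(path) {
    gr <- rtracklayer::import.gff3(path)
    type <- as.character(gr$type)
    keep <- type %in% .FEATURE_TYPES
    if (any(!keep))
        warning(sum(!keep), " GFF features of unsupported type dropped")
    gr <- gr[keep]
    id <- gr$ID
    if (is.null(id))
        id <- paste0("feature", seq_along(gr))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    out$featureType <- as.character(gr$type)
    out$featureId <- as.character(id)
    out
}

#' Write features to GFF3
#'
#' Inverse of [readGffFeatures()].
#'
#' @param features a [GenomicRanges::GRanges] with `featureType` and
#'   `featureId` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGffFeatures <- function(features, path) {
    gr <- features
    gr$type <- gr$featureType
    gr$ID <- gr$featureId
    gr$featureType <- NULL
    gr$featureId <- NULL
    gr$source <- "hgtscan"
    rtracklayer::export.gff3(gr, path)
    invisible(path)
}

#' Read a gene expression table (gene id to FPKM)
#'
#' The dialect is `gene <TAB> fpkm`. Values must be non-negative.
#'
#' @param path path to the TSV.
#' @return named numeric vector of FPKM values.
#' @export
readFpkmTsv <- function(path) {
    if (file.size(path) == 0)
        return(stats::setNames(numeric(), character()))
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("gene", "fpkm"))
    if (nrow(dt) == 0) return(stats::setNames(numeric(), character()))
    if (any(!is.finite(dt$fpkm) | dt$fpkm < 0))
        stop("negative or non-numeric FPKM for gene '",
             dt$gene[!is.finite(dt$fpkm) | dt$fpkm < 0][1], "'")
    stats::setNames(dt$fpkm, dt$gene)
}

#' Write a gene expression table
#'
#' @param fpkm named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFpkmTsv <- function(fpkm, path) {
    data.table::fwrite(data.table::data.table(gene = names(fpkm),
                                              fpkm = unname(fpkm)),
                       path, sep = "\t", col.names = FALSE)
    invisible(path)
}
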