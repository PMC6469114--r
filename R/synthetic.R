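# Synthetic host/symbiont sequencing experiments with known truth.
#
# Reads are placed, never mapped: depth tracks are computed exactly from the
# recorded placements, because the detection evidence is depth, not
# per-read alignment. Read starts are uniform (no GC bias) and error-free by
# default; neither property enters any implemented statistic.

.DNA <- c("A", "C", "G", "T")

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of every parameter. The
#' defaults are the validation conditions used throughout the package: a 1 Mb
#' host genome at GC 0.36 sequenced to 47.37x in five scaffolds, a 300 kb
#' symbiont at GC 0.3513 sequenced to 120x in three scaffolds, three planted
#' insertions of 0.5--20 kb with transposase-annotated flanks, one chimeric
#' scaffold, 100 bp reads, and one alternative assembly shredded at a mean
#' contig length of 50 kb.
#'
#' @param seed integer seed (mandatory; all outputs are deterministic in it).
#' @param hostLength,hostGc,hostScaffolds host genome size (bp), GC fraction,
#'   scaffold count.
#' @param symbiontLength,symbiontGc,symbiontScaffolds symbiont genome size
#'   (bp), GC fraction, scaffold count.
#' @param hostDepth,symbiontDepth mean fold-coverages.
#' @param nInsertions,insertionMin,insertionMax planted insertion count and
#'   length range (bp).
#' @param strainDivergence,nStrains co-infecting strain structure.
#' @param chimeraCount,chimeraFragment chimeric-scaffold count and fragment
#'   length (bp).
#' @param readLength read length (bp).
#' @param meanFragment mean contig length (bp) of shredded alternative
#'   assemblies.
#' @param nAltAssemblies number of alternative assemblies.
#' @param transposaseFlank place a transposase feature with each insertion.
#' @param errorRate per-base read substitution error rate.
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(seed,
                             hostLength = 1e6, hostGc = 0.36,
                             hostScaffolds = 5,
                             symbiontLength = 3e5, symbiontGc = 0.3513,
                             symbiontScaffolds = 3,
                             hostDepth = 47.37, symbiontDepth = 120,
                             nInsertions = 3,
                             insertionMin = 500, insertionMax = 20000,
                             strainDivergence = 0.03, nStrains = 1,
                             chimeraCount = 1, chimeraFragment = 20000,
                             readLength = 100, meanFragment = 5e4,
                             nAltAssemblies = 1,
                             transposaseFlank = TRUE, errorRate = 0) {
    if (missing(seed))
        stop("a seed is required")
    methods::new("SimulationConfig",
        hostLength = hostLength, hostGc = hostGc,
        hostScaffolds = hostScaffolds,
        symbiontLength = symbiontLength, symbiontGc = symbiontGc,
        symbiontScaffolds = symbiontScaffolds,
        hostDepth = hostDepth, symbiontDepth = symbiontDepth,
        nInsertions = nInsertions, insertionMin = insertionMin,
        insertionMax = insertionMax,
        strainDivergence = strainDivergence, nStrains = nStrains,
        chimeraCount = chimeraCount, chimeraFragment = chimeraFragment,
        readLength = readLength, meanFragment = meanFragment,
        nAltAssemblies = nAltAssemblies,
        transposaseFlank = transposaseFlank, errorRate = errorRate,
        seed = seed)
}

#' Generate a random genome sequence at a target GC content
#'
#' Bases are i.i.d. with P(G) + P(C) = `gc`, split evenly within the
#' strong/weak pairs.
#'
#' @param length sequence length (bp), > 0.
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (callers that orchestrate several generators seed once).
#' @return a [Biostrings::DNAString].
#' @export
generateGenome <- function(length, gc, seed = NULL) {
    if (length <= 0)
        stop("length must be > 0")
    if (!is.finite(gc) || gc <= 0 || gc >= 1)
        stop("gc must lie strictly inside (0, 1)")
    if (!is.null(seed)) set.seed(seed)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    Biostrings::DNAString(paste(sample(.DNA, length, replace = TRUE,
                                       prob = p), collapse = ""))
}

#' Derive a diverged strain from a genome
#'
#' Substitutes each base independently with probability `divergence` to a
#' different base chosen uniformly.
#'
#' @param genome a [Biostrings::DNAString] (or character scalar).
#' @param divergence per-base substitution probability in \[0, 0.2).
#' @param seed optional integer seed.
#' @return list with `sequence` (the variant [Biostrings::DNAString]) and
#'   `positions` (1-based sites that were substituted).
#' @export
deriveStrain <- function(genome, divergence, seed = NULL) {
    if (divergence < 0 || divergence >= 0.2)
        stop("divergence must lie in [0, 0.2)")
    if (!is.null(seed)) set.seed(seed)
    chars <- strsplit(as.character(genome), "")[[1]]
    pos <- which(stats::runif(length(chars)) < divergence)
    if (length(pos)) {
        # replace by a uniform draw from the three other bases
        repl <- vapply(chars[pos], function(b)
            sample(setdiff(.DNA, b), 1), character(1), USE.NAMES = FALSE)
        chars[pos] <- repl
    }
    list(sequence = Biostrings::DNAString(paste(chars, collapse = "")),
         positions = pos)
}

#' Plant symbiont-derived insertions into host scaffolds
#'
#' Inserts `nInsertions` non-overlapping symbiont fragments (lengths uniform
#' in `lengthRange`) at uniform positions in the host scaffolds, keeping a
#' margin from scaffold ends and a minimum separation between insertions so
#' that every junction is testable. Optionally a transposase feature is
#' placed in or near each insertion: inserts shorter than 2 kb get a
#' transposase annotation spanning the whole insert (the degenerate-
#' transposase pattern of the smallest published inserts), longer ones an
#' internal transposase near one end.
#'
#' @param host a named [Biostrings::DNAStringSet] of host scaffolds.
#' @param symbiont a named [Biostrings::DNAStringSet] of symbiont scaffolds.
#' @param nInsertions number of insertions.
#' @param lengthRange numeric length-2 vector, insertion length range (bp).
#' @param seed optional integer seed.
#' @param margin minimum distance (bp) of an insertion point from a scaffold
#'   end.
#' @param minSeparation minimum distance (bp) between insertion points on one
#'   scaffold.
#' @param transposaseFlank place transposase features (see above).
#' @param maxRetries placement retries before failing.
#' @return list with `host` (modified DNAStringSet), `insertions` (a
#'   [GenomicRanges::GRanges] on the modified host with `srcScaffold`,
#'   `srcStart`, `srcEnd` metadata) and `transposases` (GRanges of
#'   transposase features, possibly empty).
#' @export
plantInsertions <- function(host, symbiont, nInsertions,
                            lengthRange = c(500, 20000), seed = NULL,
                            margin = 2000, minSeparation = 5000,
                            transposaseFlank = TRUE, maxRetries = 200) {
    if (!is.null(seed)) set.seed(seed)
    if (nInsertions == 0)
        return(list(host = host,
                    insertions = GenomicRanges::GRanges(),
                    transposases = GenomicRanges::GRanges()))
    lens <- as.integer(round(stats::runif(nInsertions, lengthRange[1],
                                          lengthRange[2])))
    if (sum(lens) + nInsertions * 100 > sum(Biostrings::width(symbiont)))
        stop("symbiont too short to supply the requested fragments")

    # non-overlapping source fragments on the symbiont
    srcUsed <- GenomicRanges::GRanges()
    src <- vector("list", nInsertions)
    for (i in seq_len(nInsertions)) {
        placed <- FALSE
        for (try in seq_len(maxRetries)) {
            sc <- sample(names(symbiont), 1,
                         prob = Biostrings::width(symbiont))
            w <- Biostrings::width(symbiont)[names(symbiont) == sc]
            if (w < lens[i] + 2) next
            s <- sample.int(w - lens[i], 1)
            cand <- GenomicRanges::GRanges(sc,
                IRanges::IRanges(s, width = lens[i]))
            if (length(srcUsed) == 0 ||
                !any(suppressWarnings(
                    IRanges::overlapsAny(cand, srcUsed)))) {
                srcUsed <- suppressWarnings(c(srcUsed, cand))
                src[[i]] <- cand
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("could not place source fragment ", i,
                 " without overlap after ", maxRetries, " retries")
    }

    # destination points on the host (original coordinates)
    destScaffold <- character(nInsertions)
    destPoint <- integer(nInsertions)
    for (i in seq_len(nInsertions)) {
        placed <- FALSE
        for (try in seq_len(maxRetries)) {
            sc <- sample(names(host), 1, prob = Biostrings::width(host))
            w <- Biostrings::width(host)[names(host) == sc]
            if (w < 2 * margin + minSeparation) next
            p <- sample(seq(margin, w - margin), 1)
            same <- destScaffold == sc & destPoint > 0
            if (!any(same) || all(abs(destPoint[same] - p) >= minSeparation)) {
                destScaffold[i] <- sc
                destPoint[i] <- p
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("could not place insertion ", i, " after ", maxRetries,
                 " retries")
    }

    # splice, scaffold by scaffold, adjusting coordinates for upstream inserts
    newHost <- as.list(as.character(host))
    insGr <- vector("list", nInsertions)
    tpsGr <- list()
    for (sc in unique(destScaffold)) {
        idx <- which(destScaffold == sc)
        idx <- idx[order(destPoint[idx])]
        seqc <- newHost[[sc]]
        shift <- 0L
        for (i in idx) {
            frag <- as.character(Biostrings::subseq(
                symbiont[[GenomicRanges::seqnames(src[[i]]) |>
                              as.character()]],
                GenomicRanges::start(src[[i]]), GenomicRanges::end(src[[i]])))
            at <- destPoint[i] + shift     # insert after this base
            seqc <- paste0(substr(seqc, 1, at), frag,
                           substr(seqc, at + 1, nchar(seqc)))
            istart <- at + 1L
            iend <- at + lens[i]
            insGr[[i]] <- GenomicRanges::GRanges(sc,
                IRanges::IRanges(istart, iend),
                srcScaffold = as.character(GenomicRanges::seqnames(src[[i]])),
                srcStart = GenomicRanges::start(src[[i]]),
                srcEnd = GenomicRanges::end(src[[i]]))
            if (transposaseFlank) {
                if (lens[i] < 2000) {
                    tw <- IRanges::IRanges(istart, iend)
                } else {
                    tw <- IRanges::IRanges(iend - 500L, iend - 200L)
                }
                g <- GenomicRanges::GRanges(sc, tw)
                g$featureType <- "transposase"
                g$featureId <- paste0("tps_", i)
                tpsGr[[length(tpsGr) + 1L]] <- g
            }
            shift <- shift + lens[i]
        }
        newHost[[sc]] <- seqc
    }
    ins <- suppressWarnings(do.call(c, insGr))
    # coordinates of earlier inserts are unaffected by later ones because we
    # spliced left to right; verify disjointness as an internal invariant
    stopifnot(GenomicRanges::isDisjoint(ins))
    list(host = Biostrings::DNAStringSet(unlist(newHost)),
         insertions = ins,
         transposases = if (length(tpsGr)) suppressWarnings(do.call(c, tpsGr))
                        else GenomicRanges::GRanges())
}

#' Simulate uniform shotgun reads and exact depth tracks
#'
#' For each replicon, `round(depth * length / readLength)` reads of fixed
#' length are placed with uniform start positions, and the per-base depth
#' track is computed exactly from the placements (no mapping step). Read
#' sequences (with optional substitution errors and a fixed quality symbol)
#' are materialised only when `emitReads = TRUE`.
#'
#' @param replicons a named [Biostrings::DNAStringSet].
#' @param depth mean fold-coverage, recycled along `replicons`.
#' @param readLength read length (bp); must be shorter than each replicon.
#' @param seed optional integer seed.
#' @param emitReads materialise read sequences.
#' @param errorRate per-base substitution error rate applied to emitted reads.
#' @return list with `placements` ([GenomicRanges::GRanges]), `depth`
#'   ([IRanges::RleList], one exact track per replicon) and `reads`
#'   (DNAStringSet or NULL).
#' @export
simulateReads <- function(replicons, depth, readLength = 100, seed = NULL,
                          emitReads = FALSE, errorRate = 0) {
    if (!is.null(seed)) set.seed(seed)
    depth <- rep_len(depth, length(replicons))
    if (any(readLength >= Biostrings::width(replicons)))
        stop("readLength must be shorter than every replicon")
    placements <- list()
    tracks <- list()
    for (i in seq_along(replicons)) {
        sc <- names(replicons)[i]
        w <- Biostrings::width(replicons)[i]
        n <- round(depth[i] * w / readLength)
        if (n == 0) {
            warning("depth ", depth[i], " yields zero reads for ", sc)
            tracks[[sc]] <- S4Vectors::Rle(0, w)
            next
        }
        starts <- sample.int(w - readLength + 1L, n, replace = TRUE)
        ir <- IRanges::IRanges(start = starts, width = readLength)
        tracks[[sc]] <- IRanges::coverage(ir, width = w)
        placements[[sc]] <- GenomicRanges::GRanges(sc, ir)
    }
    pl <- if (length(placements))
              suppressWarnings(do.call(c, unname(placements)))
          else GenomicRanges::GRanges()
    reads <- NULL
    if (emitReads && length(pl)) {
        seqs <- character(length(pl))
        off <- 0L
        for (sc in names(placements)) {
            p <- placements[[sc]]
            s <- as.character(replicons[[sc]])
            seqs[off + seq_along(p)] <- substring(
                s, GenomicRanges::start(p), GenomicRanges::end(p))
            off <- off + length(p)
        }
        if (errorRate > 0) {
            chars <- strsplit(seqs, "")
            chars <- lapply(chars, function(cc) {
                hit <- which(stats::runif(length(cc)) < errorRate)
                if (length(hit))
                    cc[hit] <- vapply(cc[hit], function(b)
                        sample(setdiff(.DNA, b), 1), character(1),
                        USE.NAMES = FALSE)
                cc
            })
            seqs <- vapply(chars, paste, character(1), collapse = "")
        }
        reads <- Biostrings::DNAStringSet(seqs)
        names(reads) <- paste0("read", seq_along(reads))
    }
    list(placements = pl,
         depth = methods::as(tracks, "RleList"),
         reads = reads)
}

#' Write simulated reads as FASTQ
#'
#' Writes reads with a constant quality symbol (`"I"`). Byte-identical for a
#' fixed simulation seed.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimulatedFastq <- function(reads, path) {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
    invisible(path)
}

#' Construct a chimeric scaffold with a depth step at the junction
#'
#' Concatenates a host-derived and a symbiont-derived fragment into one
#' artificial scaffold whose depth track steps from the host to the symbiont
#' coverage regime exactly at the junction -- the signature expected of an
#' erroneous chimeric assembly, and the designed confound for the junction
#' depth-continuity test (equal depths make a chimera indistinguishable from
#' a genuine insertion by depth alone).
#'
#' @param hostFragment,symbiontFragment sequences ([Biostrings::DNAString] or
#'   character).
#' @param hostDepth,symbiontDepth either mean fold-coverages (numeric
#'   scalars; exact tracks are then simulated with [simulateReads()]) or
#'   precomputed [S4Vectors::Rle] depth tracks of matching length.
#' @param readLength read length used when simulating tracks.
#' @param seed optional integer seed.
#' @return list with `sequence` (DNAString), `depth` (Rle over the chimera)
#'   and `junction` (the length of the host fragment: the last host-derived
#'   base).
#' @export
makeChimera <- function(hostFragment, symbiontFragment, hostDepth,
                        symbiontDepth, readLength = 100, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    hseq <- as.character(hostFragment)
    sseq <- as.character(symbiontFragment)
    trackOf <- function(seq, d, nm) {
        if (methods::is(d, "Rle")) {
            if (length(d) != nchar(seq))
                stop("depth track length does not match fragment")
            return(d)
        }
        sim <- simulateReads(Biostrings::DNAStringSet(
            stats::setNames(seq, nm)), d, readLength = readLength)
        sim$depth[[nm]]
    }
    ht <- trackOf(hseq, hostDepth, "h")
    st <- trackOf(sseq, symbiontDepth, "s")
    list(sequence = Biostrings::DNAString(paste0(hseq, sseq)),
         depth = c(ht, st),
         junction = nchar(hseq))
}

#' Shred a genome into an alternative assembly
#'
#' Cuts each scaffold at Poisson-process breakpoints (exponential fragment
#' spacing with the given mean) and shuffles the fragment order, emulating
#' the contig structure an independent assembler would produce from the same
#' molecule. Fragments tile the genome without gaps or overlaps; the origin
#' of each contig is recorded in `metadata(result)$origin`.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param meanFragment mean fragment length (bp), >= 1000.
#' @param seed optional integer seed.
#' @param prefix contig name prefix.
#' @return a [Biostrings::DNAStringSet] of contigs in shuffled order with an
#'   `origin` data.frame (contig, srcScaffold, srcStart, srcEnd) in its
#'   metadata.
#' @export
shredAssembly <- function(genome, meanFragment, seed = NULL,
                          prefix = "alt") {
    if (meanFragment < 1000)
        stop("meanFragment must be >= 1 kb")
    if (!is.null(seed)) set.seed(seed)
    frags <- list()
    origin <- list()
    for (sc in names(genome)) {
        w <- Biostrings::width(genome)[names(genome) == sc]
        cuts <- integer(0)
        pos <- 0
        repeat {
            pos <- pos + stats::rexp(1, rate = 1 / meanFragment)
            if (pos >= w - 1) break
            cuts <- c(cuts, floor(pos))
        }
        bounds <- unique(c(0L, as.integer(cuts), as.integer(w)))
        s <- bounds[-length(bounds)] + 1L
        e <- bounds[-1]
        seqc <- as.character(genome[[sc]])
        for (j in seq_along(s)) {
            frags[[length(frags) + 1L]] <- substr(seqc, s[j], e[j])
            origin[[length(origin) + 1L]] <-
                data.frame(srcScaffold = sc, srcStart = s[j], srcEnd = e[j],
                           stringsAsFactors = FALSE)
        }
    }
    ord <- sample(length(frags))
    out <- Biostrings::DNAStringSet(unlist(frags[ord]))
    names(out) <- paste0(prefix, "_contig", seq_along(out))
    og <- do.call(rbind, origin)[ord, , drop = FALSE]
    og <- cbind(contig = names(out), og)
    rownames(og) <- NULL
    S4Vectors::metadata(out)$origin <- og
    out
}
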