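## Shared fixtures and independent oracles for the test suite.

suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
    library(Biostrings)
})

## --- brute-force DBSCAN oracle -----------------------------------------
## Generic O(n^2) implementation straight from the algorithm definition:
## neighbourhood counts from a full distance matrix, cluster expansion by
## BFS over density-reachability from core points, border points attached
## to the nearest core (ties to the leftmost core). Independent of the
## sorted-sweep implementation in the package.
bruteDbscan <- function(positions, eps, minPts) {
    n <- length(positions)
    if (n == 0L) return(integer(0))
    d <- abs(outer(positions, positions, "-"))
    nbr <- d <= eps
    core <- rowSums(nbr) >= minPts
    labels <- integer(n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (!core[i] || labels[i] != 0L) next
        cl <- cl + 1L
        queue <- i
        labels[i] <- cl
        while (length(queue)) {
            q <- queue[1L]; queue <- queue[-1L]
            reach <- which(nbr[q, ] & core & labels == 0L)
            labels[reach] <- cl
            queue <- c(queue, reach)
        }
    }
    ## border points: nearest core within eps, ties to leftmost core
    for (i in which(!core)) {
        cand <- which(core & nbr[i, ])
        if (length(cand) == 0L) next
        best <- cand[order(d[i, cand], positions[cand], cand)][1L]
        labels[i] <- labels[best]
    }
    ## renumber by leftmost member
    used <- labels > 0L
    if (any(used)) {
        first <- tapply(seq_len(n)[used], labels[used], min)
        remap <- integer(max(labels))
        remap[as.integer(names(first))] <- rank(first,
                                                ties.method = "first")
        labels[used] <- remap[labels[used]]
    }
    labels
}

## --- brute-force CIGAR walk --------------------------------------------
## Enumerates insertion ops and soft clips of a single CIGAR by regex
## walking, independent of the vectorised extractor.
bruteCigarEvents <- function(cigar, pos1) {
    m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    r <- pos1 - 1L   # 0-based ref cursor
    q <- 0L          # query cursor
    out <- list()
    for (k in seq_along(op)) {
        if (op[k] == "I")
            out[[length(out) + 1L]] <- data.frame(
                kind = "insertion_op", position = r, qstart = q,
                len = len[k])
        if (op[k] == "S")
            out[[length(out) + 1L]] <- data.frame(
                kind = if (q == 0L) "left_clip" else "right_clip",
                position = NA_integer_, qstart = q, len = len[k])
        if (op[k] %in% c("M", "D", "N", "=", "X")) r <- r + len[k]
        if (op[k] %in% c("M", "I", "S", "=", "X")) q <- q + len[k]
    }
    df <- do.call(rbind, out)
    if (!is.null(df)) {
        ## clip positions: left = ref start, right = ref end
        df$position[df$kind == "left_clip"] <- pos1 - 1L
        df$position[df$kind == "right_clip"] <- r
    }
    df
}

## --- read / BAM fixtures -----------------------------------------------
cigarQueryLen <- function(cigar) {
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(len[op %in% c("M", "I", "S", "=", "X")])
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

## read list for the per-read API; seq autogenerated to match the CIGAR
makeRead <- function(cigar, pos = 1001L, qname = "r1", rname = "chr1",
                     mapq = 60L, seq = NULL, hp = NA, ps = NA) {
    if (is.null(seq)) seq <- randomSeq(cigarQueryLen(cigar))
    list(qname = qname, rname = rname, pos = pos, mapq = mapq,
         cigar = cigar, seq = seq, hp = hp, ps = ps)
}

## write reads to a sorted indexed BAM; reads is a list of makeRead() lists
writeFixtureBam <- function(reads, contigLen = 100000L, contig = "chr1",
                            path = tempfile(fileext = ".bam")) {
    lines <- vapply(reads, function(r) {
        tags <- character(0)
        if (!is.na(r$hp)) tags <- c(tags, paste0("HP:i:", r$hp))
        if (!is.na(r$ps)) tags <- c(tags, paste0("PS:i:", r$ps))
        paste(c(r$qname, "0", r$rname, r$pos, r$mapq, r$cigar, "*", "0",
                "0", r$seq, "*", tags), collapse = "\t")
    }, "")
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", contig, contigLen),
                 lines), sam)
    tmp <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
    Rsamtools::sortBam(tmp, sub("\\.bam$", "", path))
    Rsamtools::indexBam(path)
    unlink(c(sam, tmp))
    path
}

## evidence GRanges fixture for clustering / refinement tests
makeEvidence <- function(positions, contig = "chr1",
                         readIds = sprintf("r%d", seq_along(positions)),
                         kind = "insertion_op",
                         seqs = NULL, lens = NULL, hap = NA_integer_) {
    if (is.null(seqs)) seqs <- vapply(seq_along(positions),
                                      function(i) randomSeq(200L), "")
    if (is.null(lens)) lens <- nchar(seqs)
    gr <- GenomicRanges::GRanges(rep(contig, length(positions)),
                                 IRanges::IRanges(positions + 1L,
                                                  width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        readId = readIds, kind = rep_len(kind, length(positions)),
        sequence = seqs, len = as.integer(lens),
        haplotype = rep_len(as.integer(hap), length(positions)),
        phaseSet = rep_len(NA_integer_, length(positions)))
    gr
}

## small deterministic TE library for classification tests
testTELibrary <- function() syntheticTELibrary(seed = 42L)
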