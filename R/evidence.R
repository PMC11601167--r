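## Evidence extraction: CIGAR insertion operations and soft-clipped read ends
## from a coordinate-sorted BAM/CRAM. Coordinates are handled 0-based
## half-open internally; an evidence "position" is the 0-based insertion
## point on the reference (the coordinate of the first reference base to the
## right of the junction). GRanges anchors store position + 1.

#' @importFrom GenomicAlignments explodeCigarOps explodeCigarOpLengths
#'   cigarWidthAlongReferenceSpace
#' @importFrom Rsamtools ScanBamParam scanBamFlag scanBam scanBamHeader
#'   BamFile countBam
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

.EVIDENCE_KINDS <- c("insertion_op", "left_clip", "right_clip")

## cumulative sum of x restarting at each new value of grp (grp is
## run-length grouped, i.e. sorted); returns the sum *before* each element
.cumsumBefore <- function(x, grpLens) {
    cs <- cumsum(x)
    before <- cs - x
    if (length(grpLens) == 0L)
        return(before)
    starts <- cumsum(c(1L, grpLens[-length(grpLens)]))
    before - rep(before[starts], grpLens)
}

.emptyEvidence <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(readId = character(0), kind = character(0),
                           sequence = character(0), len = integer(0),
                           haplotype = integer(0), phaseSet = integer(0))
    gr
}

## Vectorised core shared by the per-read API and scanAlignments.
## rec: list of parallel vectors qname, rname, pos (1-based), cigar, seq
## (character), hp, ps. Returns GRanges + counter attributes.
.extractEvidence <- function(rec, params, doInsertions = TRUE,
                             doClips = TRUE) {
    n <- length(rec$cigar)
    counters <- c(nReads = n, nHardClipOps = 0L, nNoSequence = 0L)
    if (n == 0L) {
        out <- .emptyEvidence()
        attr(out, "counters") <- counters
        return(out)
    }

    noSeq <- is.na(rec$seq) | rec$seq == "" | rec$seq == "*"
    counters["nNoSequence"] <- sum(noSeq)
    keep <- which(!noSeq)

    ops  <- explodeCigarOps(rec$cigar[keep])
    lens <- explodeCigarOpLengths(rec$cigar[keep])
    nops <- lengths(ops)
    ridx <- rep(keep, nops)
    op   <- unlist(ops, use.names = FALSE)
    len  <- unlist(lens, use.names = FALSE)

    counters["nHardClipOps"] <- sum(op == "H")

    qw <- ifelse(op %in% c("M", "I", "S", "=", "X"), len, 0L)
    rw <- ifelse(op %in% c("M", "D", "N", "=", "X"), len, 0L)
    qBefore <- .cumsumBefore(qw, nops)
    rBefore <- .cumsumBefore(rw, nops)

    pos0 <- rec$pos - 1L  # 0-based reference start per read

    pick <- function(i, kind, position0) {
        if (length(i) == 0L)
            return(NULL)
        data.frame(
            readId    = rec$qname[ridx[i]],
            contig    = rec$rname[ridx[i]],
            position  = position0,
            kind      = kind,
            sequence  = substr(rec$seq[ridx[i]],
                               qBefore[i] + 1L, qBefore[i] + len[i]),
            len       = len[i],
            haplotype = rec$hp[ridx[i]],
            phaseSet  = rec$ps[ridx[i]],
            stringsAsFactors = FALSE)
    }

    pieces <- list()
    if (doInsertions) {
        i <- which(op == "I" & len >= params@minInsertionLen)
        pieces$ins <- pick(i, "insertion_op", pos0[ridx[i]] + rBefore[i])
    }
    if (doClips) {
        ## a soft clip is "leading" when no query base precedes it and
        ## "trailing" when none follows; hard clips carry no sequence
        qAfter <- rep(vapply(split(qw, rep.int(seq_along(nops), nops)),
                             sum, 0L), nops) - qBefore - qw
        iL <- which(op == "S" & qBefore == 0L & len >= params@minClipLen)
        iR <- which(op == "S" & qAfter == 0L & qBefore > 0L &
                    len >= params@minClipLen)
        refTot <- rep(vapply(split(rw, rep.int(seq_along(nops), nops)),
                             sum, 0L), nops)
        pieces$left  <- pick(iL, "left_clip", pos0[ridx[iL]])
        pieces$right <- pick(iR, "right_clip", pos0[ridx[iR]] + refTot[iR])
    }
    df <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
    if (is.null(df) || nrow(df) == 0L) {
        out <- .emptyEvidence()
        attr(out, "counters") <- counters
        return(out)
    }
    o <- order(df$contig, df$position, df$readId, df$kind)
    df <- df[o, , drop = FALSE]
    out <- GRanges(df$contig, IRanges(df$position + 1L, width = 1L))
    mcols(out) <- DataFrame(readId = df$readId, kind = df$kind,
                            sequence = df$sequence, len = df$len,
                            haplotype = df$haplotype,
                            phaseSet = df$phaseSet)
    attr(out, "counters") <- counters
    out
}

.asRecord <- function(read) {
    list(qname = as.character(read$qname),
         rname = as.character(read$rname),
         pos   = as.integer(read$pos),
         mapq  = as.integer(read$mapq),
         cigar = as.character(read$cigar),
         seq   = as.character(read$seq),
         hp    = as.integer(if (is.null(read$hp)) NA else read$hp),
         ps    = as.integer(if (is.null(read$ps)) NA else read$ps))
}

#' Evidence positions (0-based insertion points)
#'
#' @param evidence evidence GRanges as returned by the extractors.
#' @return integer vector of 0-based insertion-point coordinates.
#' @export
evidencePositions <- function(evidence) start(evidence) - 1L

#' Extract insertion-operation evidence from one aligned read
#'
#' Walks the CIGAR string of a single mapped, primary read and emits one
#' evidence item per insertion operation of length at least
#' \code{minInsertionLen}. The evidence position is the 0-based reference
#' insertion point (reference bases consumed before the operation, offset by
#' the read's start), and the evidence sequence is the inserted query bases.
#'
#' @param read a list with elements \code{qname}, \code{rname}, \code{pos}
#'   (1-based leftmost mapping position, SAM convention), \code{mapq},
#'   \code{cigar}, \code{seq}, and optionally \code{hp}/\code{ps} phasing
#'   tags.
#' @param params a \linkS4class{TEIParams}.
#' @return GRanges of evidence (possibly empty) with mcols \code{readId},
#'   \code{kind}, \code{sequence}, \code{len}, \code{haplotype},
#'   \code{phaseSet}.
#' @examples
#' rd <- list(qname = "r1", rname = "chr1", pos = 1001L, mapq = 60L,
#'            cigar = "100M300I100M",
#'            seq = paste(rep("A", 500), collapse = ""))
#' extractInsertionOps(rd, teiParameters(minInsertionLen = 50))
#' @export
extractInsertionOps <- function(read, params = teiParameters()) {
    rec <- .asRecord(read)
    if (is.na(rec$seq) || rec$seq == "" || rec$seq == "*") {
        warning("read '", rec$qname, "' has no query sequence; skipped")
        return(.emptyEvidence())
    }
    if (!is.na(rec$mapq) && rec$mapq < params@minMapq)
        return(.emptyEvidence())
    ev <- .extractEvidence(lapply(rec, identity), params, doClips = FALSE)
    attr(ev, "counters") <- NULL
    ev
}

#' Extract soft-clip (split-read) evidence from one aligned read
#'
#' Soft-clipped segments of length at least \code{minClipLen} become
#' evidence: a leading clip anchors at the read's reference start
#' (kind \code{left_clip}), a trailing clip at the read's reference end
#' (kind \code{right_clip}); the clipped bases are the candidate sequence.
#' Hard clips carry no sequence and yield nothing.
#'
#' @inheritParams extractInsertionOps
#' @return GRanges of evidence (possibly empty).
#' @export
extractClipEvents <- function(read, params = teiParameters()) {
    rec <- .asRecord(read)
    if (is.na(rec$seq) || rec$seq == "" || rec$seq == "*") {
        warning("read '", rec$qname, "' has no query sequence; skipped")
        return(.emptyEvidence())
    }
    if (!is.na(rec$mapq) && rec$mapq < params@minMapq)
        return(.emptyEvidence())
    ev <- .extractEvidence(lapply(rec, identity), params,
                           doInsertions = FALSE)
    attr(ev, "counters") <- NULL
    ev
}

.requireIndex <- function(file) {
    idx <- c(paste0(file, ".bai"), sub("\\.bam$", ".bai", file),
             paste0(file, ".csi"), paste0(file, ".crai"),
             sub("\\.cram$", ".crai", file))
    if (!any(file.exists(idx)))
        stop("alignment file '", file, "' has no index; create one with ",
             "'samtools index ", file, "' (the caller requires a ",
             "coordinate-sorted, indexed BAM/CRAM)")
    invisible(TRUE)
}

#' Scan an alignment file for TE insertion evidence
#'
#' Streams all primary, non-duplicate, non-supplementary reads passing the
#' mapping-quality threshold and returns the union of insertion-operation
#' and soft-clip evidence, sorted by contig and position. Phasing tags
#' (\code{HP}/\code{PS}) are carried along when present.
#'
#' @param file path to a coordinate-sorted, indexed BAM (or CRAM) file.
#' @param region optional GRanges of one interval, or a string
#'   \code{"contig"} or \code{"contig:start-end"} restricting the scan.
#' @param params a \linkS4class{TEIParams}.
#' @return GRanges of evidence with seqlengths from the file header and a
#'   \code{counters} attribute (reads seen, hard-clip ops, sequence-less
#'   reads skipped).
#' @export
scanAlignments <- function(file, region = NULL, params = teiParameters()) {
    .requireIndex(file)
    hdr <- scanBamHeader(file)[[1]]$targets
    which <- NULL
    if (!is.null(region)) {
        if (is.character(region)) {
            m <- regmatches(region,
                            regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
            ctg <- m[2]
            if (!ctg %in% names(hdr))
                stop("contig '", ctg, "' not present in '", file, "'")
            if (m[3] == "")
                region <- GRanges(ctg, IRanges(1L, hdr[[ctg]]))
            else
                region <- GRanges(ctg, IRanges(as.integer(m[4]),
                                               as.integer(m[5])))
        }
        if (!all(as.character(seqnames(region)) %in% names(hdr)))
            stop("region contig not present in '", file, "'")
        which <- region
    }
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isDuplicate = FALSE, isSupplementaryAlignment = FALSE)
    what <- c("qname", "rname", "pos", "mapq", "cigar", "seq")
    p <- if (is.null(which))
        ScanBamParam(flag = flag, mapqFilter = params@minMapq, what = what,
                     tag = c("HP", "PS"))
    else
        ScanBamParam(flag = flag, mapqFilter = params@minMapq, what = what,
                     tag = c("HP", "PS"), which = which)
    res <- scanBam(file, param = p)
    rec <- list(
        qname = unlist(lapply(res, `[[`, "qname"), use.names = FALSE),
        rname = as.character(unlist(lapply(res, `[[`, "rname"),
                                    use.names = FALSE)),
        pos   = unlist(lapply(res, `[[`, "pos"), use.names = FALSE),
        mapq  = unlist(lapply(res, `[[`, "mapq"), use.names = FALSE),
        cigar = unlist(lapply(res, `[[`, "cigar"), use.names = FALSE),
        seq   = unlist(lapply(res, function(x) as.character(x$seq)),
                       use.names = FALSE),
        hp    = unlist(lapply(res, function(x) {
                    v <- x$tag$HP
                    if (is.null(v)) rep(NA_integer_, length(x$qname)) else v
                }), use.names = FALSE),
        ps    = unlist(lapply(res, function(x) {
                    v <- x$tag$PS
                    if (is.null(v)) rep(NA_integer_, length(x$qname)) else v
                }), use.names = FALSE))
    ## region queries can return the same read once per overlapped range
    if (!is.null(which) && length(which) > 1L) {
        dup <- duplicated(paste(rec$qname, rec$pos, rec$cigar))
        rec <- lapply(rec, `[`, !dup)
    }
    ev <- .extractEvidence(rec, params)
    if (length(ev) > 0L)
        seqlengths(ev) <- hdr[seqlevels(ev)]
    ev
}

## local read depth at 0-based positions: primary, MAPQ-passing,
## non-duplicate reads overlapping each position
.localDepth <- function(file, contigs, positions0, params) {
    if (length(positions0) == 0L)
        return(integer(0))
    ## count reads overlapping either base flanking the insertion point
    gr <- GRanges(contigs, IRanges(pmax(positions0, 1L), positions0 + 1L))
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isDuplicate = FALSE, isSupplementaryAlignment = FALSE)
    p <- ScanBamParam(flag = flag, mapqFilter = params@minMapq, which = gr,
                      what = character(0))
    countBam(file, param = p)$records
}
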