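## Seeded synthetic benchmark: a random genome, planted TE insertions on a
## diploid pair of haplotypes with a recorded truth set, and noisy long
## reads at a target fold-coverage. "Direct-BAM" mode writes each read's
## generative alignment to the *un-inserted* reference with an exact CIGAR
## (planted insertions appear as I operations, reads ending inside an
## insertion as soft clips), so the caller can be exercised hermetically
## without an external aligner.

#' Simulation configuration
#'
#' @slot genomeLen integer(1) reference length in bp.
#' @slot nInsertions named integer vector: insertions to plant per TE
#'   family (names must exist in the TE library).
#' @slot coverage numeric(1) diploid fold-coverage of the simulated reads.
#' @slot errorRates named numeric(3): per-base \code{mismatch},
#'   \code{insertion} and \code{deletion} rates, each in [0, 0.2].
#' @slot readLen named numeric(2): \code{mean} and \code{sd} of read
#'   length; lengths are truncated below at 1 kb.
#' @slot hetFraction numeric(1) fraction of insertions planted
#'   heterozygous (on one haplotype only).
#' @slot minSpacing integer(1) minimum distance between planted insertions
#'   and to the contig ends.
#' @slot seed integer(1) RNG seed; every simulation stage derives from it.
#' @export
setClass("SimConfig", representation(
    genomeLen   = "integer",
    nInsertions = "integer",
    coverage    = "numeric",
    errorRates  = "numeric",
    readLen     = "numeric",
    hetFraction = "numeric",
    minSpacing  = "integer",
    seed        = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@genomeLen < 10000L)
        msg <- c(msg, "genomeLen must be >= 10000")
    if (object@coverage <= 0)
        msg <- c(msg, "coverage must be > 0")
    if (any(object@errorRates < 0) || any(object@errorRates > 0.2))
        msg <- c(msg, "error rates must each be in [0, 0.2]")
    if (!all(c("mismatch", "insertion", "deletion") %in%
             names(object@errorRates)))
        msg <- c(msg, "errorRates needs mismatch/insertion/deletion")
    if (object@hetFraction < 0 || object@hetFraction > 1)
        msg <- c(msg, "hetFraction must be in [0, 1]")
    if (is.null(names(object@nInsertions)) && length(object@nInsertions))
        msg <- c(msg, "nInsertions must be named by family")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the package's reference benchmark: a 5 Mb genome with
#' 60 Alu, 60 L1, 30 HERV and 30 SVA full-length homozygous insertions and
#' 20x long reads carrying PacBio-RS-II-like errors (6% mismatch, 3%
#' insertion, 3% deletion).
#'
#' @param genomeLen reference length (bp).
#' @param nInsertions named vector of per-family insertion counts.
#' @param coverage diploid fold-coverage.
#' @param errorRates named per-base error rates
#'   (mismatch/insertion/deletion).
#' @param readLen named mean/sd of read length (bp).
#' @param hetFraction fraction of insertions planted heterozygous.
#' @param minSpacing minimum spacing between insertions and from contig
#'   ends (bp).
#' @param seed RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' simConfig(genomeLen = 1e5, nInsertions = c(Alu = 2), coverage = 5)
#' @export
simConfig <- function(genomeLen = 5e6,
                      nInsertions = c(Alu = 60L, L1 = 60L, HERV = 30L,
                                      SVA = 30L),
                      coverage = 20,
                      errorRates = c(mismatch = 0.06, insertion = 0.03,
                                     deletion = 0.03),
                      readLen = c(mean = 8000, sd = 3000),
                      hetFraction = 0,
                      minSpacing = 1000L,
                      seed = 1L) {
    new("SimConfig",
        genomeLen = as.integer(genomeLen),
        nInsertions = stats::setNames(as.integer(nInsertions),
                                      names(nInsertions)),
        coverage = as.numeric(coverage),
        errorRates = errorRates[c("mismatch", "insertion", "deletion")],
        readLen = readLen[c("mean", "sd")],
        hetFraction = as.numeric(hetFraction),
        minSpacing = as.integer(minSpacing),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@genomeLen, "bp genome,",
        sum(object@nInsertions), "insertions (",
        paste(names(object@nInsertions), object@nInsertions, sep = "=",
              collapse = ", "), "),",
        object@coverage, "x coverage, seed", object@seed, "\n")
})

.randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random reference genome
#'
#' A single contig (\code{sim1}) of seeded uniform-random A/C/G/T with no
#' planted TE homology; byte-identical for identical seeds.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return \code{DNAStringSet} of one record.
#' @export
simulateGenome <- function(cfg) {
    set.seed(cfg@seed)
    g <- DNAStringSet(.randomDNA(cfg@genomeLen))
    names(g) <- "sim1"
    g
}

#' Synthetic TE consensus library
#'
#' Seeded random stand-ins for the canonical TE family consensus sequences
#' at their characteristic full lengths (Alu 300 bp, SVA 1.6 kb, L1 6 kb,
#' HERV 9.5 kb), each ending in a 20 bp poly-A tail. These are synthetic
#' sequences: mutually and genomically non-homologous, which is what the
#' caller's realignment step requires; they carry no real TE biology.
#'
#' @param seed RNG seed.
#' @return named \code{DNAStringSet} (Alu, L1, SVA, HERV).
#' @export
syntheticTELibrary <- function(seed = 42L) {
    set.seed(seed)
    lens <- c(Alu = 300L, L1 = 6000L, SVA = 1600L, HERV = 9500L)
    seqs <- vapply(lens, function(n)
        paste0(.randomDNA(n - 20L), strrep("A", 20L)), "")
    out <- DNAStringSet(seqs)
    names(out) <- names(lens)
    out
}

## spaced uniform positions: >= minSpacing apart and from both ends
.spacedPositions <- function(n, genomeLen, minSpacing) {
    pad <- max(minSpacing, 1000L)
    lo <- pad
    hi <- genomeLen - pad
    if (n * minSpacing * 2 > hi - lo)
        stop("requested insertion density infeasible: ", n,
             " insertions with ", minSpacing, " bp spacing in ",
             genomeLen, " bp")
    for (try in 1:100) {
        cand <- sort(sample(seq.int(lo, hi), min(n * 4L, hi - lo)))
        keep <- cand[c(TRUE, diff(cand) >= minSpacing)]
        while (any(diff(keep) < minSpacing))
            keep <- keep[c(TRUE, diff(keep) >= minSpacing)]
        if (length(keep) >= n)
            return(sort(sample(keep, n)))
    }
    stop("could not place ", n, " spaced insertions after 100 attempts")
}

#' Plant TE insertions into a diploid genome
#'
#' Draws uniform-random, mutually spaced insertion points, assigns each a
#' family (per the configured counts), a strand, and a zygosity
#' (heterozygous with probability \code{hetFraction}, placed on one random
#' haplotype; homozygous on both), and builds the two haplotype sequences.
#'
#' @param genome \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @param teLib TE library \code{DNAStringSet} (or FASTA path); planted
#'   sequences are full-length library entries.
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{haplotypes} (\code{DNAStringSet} hap1/hap2),
#'   \code{truth} (data.frame: contig, position = 0-based insertion point
#'   on the un-inserted reference, family, insertedLen, zygosity, strand,
#'   hap), \code{blocks} (per-haplotype coordinate maps used by the read
#'   simulator), \code{genome} and \code{config}.
#' @export
plantInsertions <- function(genome, teLib, cfg) {
    force(genome)  # evaluate promises before touching the RNG
    if (!is(teLib, "DNAStringSet"))
        teLib <- .loadTELibrary(teLib)
    fams <- names(cfg@nInsertions)
    miss <- setdiff(fams, names(teLib))
    if (length(miss))
        stop("families absent from TE library: ",
             paste(miss, collapse = ", "))
    set.seed(cfg@seed + 1L)
    n <- sum(cfg@nInsertions)
    gstr <- as.character(genome[[1]])
    contig <- names(genome)[1]

    truth <- data.frame(contig = character(0), position = integer(0),
                        family = character(0), insertedLen = integer(0),
                        zygosity = character(0), strand = character(0),
                        hap = integer(0), stringsAsFactors = FALSE)
    if (n > 0L) {
        pos <- .spacedPositions(n, cfg@genomeLen, cfg@minSpacing)
        fam <- sample(rep(fams, cfg@nInsertions))
        strand <- sample(c("+", "-"), n, replace = TRUE)
        het <- stats::runif(n) < cfg@hetFraction
        hap <- ifelse(het, sample(1:2, n, replace = TRUE), NA_integer_)
        truth <- data.frame(contig = contig, position = pos, family = fam,
                            insertedLen = width(teLib)[match(fam,
                                                             names(teLib))],
                            zygosity = ifelse(het, "het", "hom"),
                            strand = strand, hap = hap,
                            stringsAsFactors = FALSE)
    }

    buildHap <- function(h) {
        ev <- truth[truth$zygosity == "hom" |
                    (truth$zygosity == "het" & truth$hap == h), ,
                    drop = FALSE]
        ev <- ev[order(ev$position), , drop = FALSE]
        ## blocks: alternating reference segments and insertions, with the
        ## haplotype-coordinate start and (for ref blocks) reference start
        segStarts <- c(0L, ev$position)          # ref segment starts
        segEnds <- c(ev$position, cfg@genomeLen) # ref segment ends
        pieces <- character(2L * nrow(ev) + 1L)
        bl <- list()
        hapAt <- 0L
        for (k in seq_len(nrow(ev) + 1L)) {
            segLen <- segEnds[k] - segStarts[k]
            pieces[2L * k - 1L] <- substr(gstr, segStarts[k] + 1L,
                                          segEnds[k])
            bl[[length(bl) + 1L]] <- data.frame(
                hapStart = hapAt, len = segLen, type = "ref",
                refStart = segStarts[k], stringsAsFactors = FALSE)
            hapAt <- hapAt + segLen
            if (k <= nrow(ev)) {
                te <- teLib[[ev$family[k]]]
                if (ev$strand[k] == "-")
                    te <- reverseComplement(te)
                tes <- as.character(te)
                pieces[2L * k] <- tes
                bl[[length(bl) + 1L]] <- data.frame(
                    hapStart = hapAt, len = nchar(tes), type = "ins",
                    refStart = ev$position[k], stringsAsFactors = FALSE)
                hapAt <- hapAt + nchar(tes)
            }
        }
        blocks <- do.call(rbind, bl)
        blocks <- blocks[blocks$len > 0L, , drop = FALSE]
        list(seq = paste(pieces, collapse = ""), blocks = blocks)
    }
    h1 <- buildHap(1L)
    h2 <- buildHap(2L)
    haps <- DNAStringSet(c(h1$seq, h2$seq))
    names(haps) <- c("hap1", "hap2")
    list(haplotypes = haps, truth = truth,
         blocks = list(h1$blocks, h2$blocks), genome = genome,
         config = cfg)
}

## one simulated read: returns SAM fields or NULL when the read has no
## reference anchor (fully inside an insertion)
.simulateOneRead <- function(hapStr, blocks, s, e, rates, qname, hap) {
    L0 <- e - s
    hapPos <- s:(e - 1L)
    bi <- findInterval(hapPos, blocks$hapStart)
    isRef <- blocks$type[bi] == "ref"
    base <- strsplit(substr(hapStr, s + 1L, e), "", fixed = TRUE)[[1]]
    op <- ifelse(isRef, "M", "i")
    refPos <- blocks$refStart[bi] + (hapPos - blocks$hapStart[bi])
    refPos[!isRef] <- NA_integer_

    ## deletion errors: a deleted reference base becomes D, a deleted
    ## inserted base simply vanishes from the read
    if (rates[["deletion"]] > 0) {
        ndel <- stats::rbinom(1L, L0, rates[["deletion"]])
        if (ndel > 0L) {
            di <- sample.int(L0, ndel)
            op[di[isRef[di]]] <- "D"
            drop <- rep(FALSE, L0)
            drop[di[!isRef[di]]] <- TRUE
            keep <- !drop
            op <- op[keep]; base <- base[keep]; refPos <- refPos[keep]
        }
    }
    rc <- which(op != "D")
    if (rates[["mismatch"]] > 0 && length(rc) > 0L) {
        nmm <- stats::rbinom(1L, length(rc), rates[["mismatch"]])
        if (nmm > 0L) {
            mi <- rc[sample.int(length(rc), nmm)]
            alpha <- c("A", "C", "G", "T")
            shift <- sample.int(3L, nmm, replace = TRUE)
            cur <- match(base[mi], alpha)
            cur[is.na(cur)] <- 1L
            base[mi] <- alpha[((cur - 1L + shift) %% 4L) + 1L]
        }
    }
    key <- as.numeric(seq_along(op))
    if (rates[["insertion"]] > 0 && length(rc) > 0L) {
        nins <- stats::rbinom(1L, length(rc), rates[["insertion"]])
        nins <- min(nins, length(rc))
        if (nins > 0L) {
            at <- rc[sample.int(length(rc), nins)]
            op <- c(op, rep("e", nins))
            base <- c(base, sample(c("A", "C", "G", "T"), nins,
                                   replace = TRUE))
            refPos <- c(refPos, rep(NA_integer_, nins))
            key <- c(key, at + 0.5)
            o <- order(key)
            op <- op[o]; base <- base[o]; refPos <- refPos[o]
        }
    }

    cig <- ifelse(op == "M", "M", ifelse(op == "D", "D", "I"))
    readSeq <- paste(base[cig != "D"], collapse = "")
    anchors <- which(cig == "M")
    if (length(anchors) == 0L)
        return(list(sam = NULL, seq = readSeq))
    a <- anchors[1L]; b <- anchors[length(anchors)]
    ## outside the anchored span: I becomes a soft clip, D is dropped
    head <- cig[seq_len(a - 1L)]
    tail <- if (b < length(cig)) cig[(b + 1L):length(cig)] else character(0)
    keep <- c(seq_len(a - 1L)[head != "D"], a:b,
              ((b + 1L):length(cig))[tail != "D"])
    if (b >= length(cig))
        keep <- c(seq_len(a - 1L)[head != "D"], a:b)
    cig <- cig[keep]; base2 <- base[keep]
    cig[seq_along(cig) < which(keep == a) & cig == "I"] <- "S"
    cig[seq_along(cig) > which(keep == b) & cig == "I"] <- "S"
    readSeqAln <- paste(base2[cig != "D"], collapse = "")
    r <- rle(cig)
    cigar <- paste0(r$lengths, r$values, collapse = "")
    pos1 <- refPos[a] + 1L
    list(sam = c(qname = qname, pos = pos1, cigar = cigar,
                 seq = readSeqAln, hp = hap),
         seq = readSeq)
}

#' Simulate long reads from planted haplotypes
#'
#' Reads are drawn uniformly across both haplotypes to the target diploid
#' fold-coverage, with truncated-normal lengths (minimum 1 kb) and per-base
#' mismatch/insertion/deletion errors at the configured rates. With
#' \code{bamOut}, each anchored read's generative alignment to the
#' un-inserted reference is written directly as a coordinate-sorted,
#' indexed BAM with exact CIGARs and \code{HP}/\code{PS} haplotype tags;
#' reads lying entirely within a planted insertion have no reference anchor
#' and are left out of the BAM (they still appear in the FASTQ).
#'
#' @param planted result of \code{\link{plantInsertions}}.
#' @param cfg a \linkS4class{SimConfig} (usually \code{planted$config}).
#' @param bamOut optional path of the direct-alignment BAM to write
#'   (without the \code{.bam} suffix added by sorting; give the full
#'   desired path, e.g. \code{"sim.bam"}).
#' @param fastqOut optional FASTQ path.
#' @return list: \code{bam}, \code{fastq} (paths or NULL), \code{nReads},
#'   \code{nUnanchored}, \code{totalBases}.
#' @export
simulateReads <- function(planted, cfg = planted$config, bamOut = NULL,
                          fastqOut = NULL) {
    force(planted)  # evaluate promises before touching the RNG
    force(cfg)
    set.seed(cfg@seed + 2L)
    refLen <- cfg@genomeLen
    contig <- names(planted$genome)[1]
    rates <- cfg@errorRates
    samLines <- character(0)
    fqLines <- list()
    nReads <- 0L
    nUnanchored <- 0L
    totalBases <- 0
    for (h in 1:2) {
        hapStr <- as.character(planted$haplotypes[[h]])
        blocks <- planted$blocks[[h]]
        hapLen <- nchar(hapStr)
        nR <- ceiling((cfg@coverage / 2) * hapLen / cfg@readLen[["mean"]])
        lens <- pmax(1000, round(stats::rnorm(nR, cfg@readLen[["mean"]],
                                              cfg@readLen[["sd"]])))
        starts <- sample.int(hapLen, nR, replace = TRUE) - 1L
        ends <- pmin(starts + lens, hapLen)
        ok <- (ends - starts) >= 500
        starts <- starts[ok]; ends <- ends[ok]
        out <- vector("list", length(starts))
        fqh <- vector("list", length(starts))
        for (i in seq_along(starts)) {
            qname <- sprintf("hap%d_%06d", h, i)
            rd <- .simulateOneRead(hapStr, blocks, starts[i], ends[i],
                                   rates, qname, h)
            nReads <- nReads + 1L
            totalBases <- totalBases + nchar(rd$seq)
            if (!is.null(fastqOut))
                fqh[[i]] <- c(paste0("@", qname), rd$seq, "+",
                              strrep("I", nchar(rd$seq)))
            if (is.null(rd$sam)) {
                nUnanchored <- nUnanchored + 1L
                next
            }
            out[[i]] <- paste(rd$sam[["qname"]], "0", contig,
                              rd$sam[["pos"]], "60", rd$sam[["cigar"]],
                              "*", "0", "0", rd$sam[["seq"]], "*",
                              paste0("HP:i:", h), "PS:i:1", sep = "\t")
        }
        samLines <- c(samLines, unlist(out))
        fqLines[[h]] <- unlist(fqh)
    }

    bam <- NULL
    if (!is.null(bamOut)) {
        samFile <- tempfile(fileext = ".sam")
        writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                     sprintf("@SQ\tSN:%s\tLN:%d", contig, refLen),
                     samLines), samFile)
        tmpBam <- Rsamtools::asBam(samFile, tempfile(),
                                   indexDestination = FALSE)
        Rsamtools::sortBam(tmpBam, sub("\\.bam$", "", bamOut))
        Rsamtools::indexBam(bamOut)
        unlink(c(samFile, tmpBam))
        bam <- bamOut
    }
    fastq <- NULL
    if (!is.null(fastqOut)) {
        writeLines(unlist(fqLines), fastqOut)
        fastq <- fastqOut
    }
    list(bam = bam, fastq = fastq, nReads = nReads,
         nUnanchored = nUnanchored, totalBases = totalBases)
}

#' Write / read a truth table
#'
#' Tab-separated truth records (contig, 0-based position, family,
#' insertedLen, zygosity, strand, hap).
#'
#' @param truth truth data.frame from \code{\link{plantInsertions}}.
#' @param path TSV path.
#' @return \code{path} / the truth data.frame.
#' @export
writeTruth <- function(truth, path) {
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(hap = "integer"))
}
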