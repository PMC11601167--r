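## VCF 4.2 serialisation of TE insertion calls as symbolic <INS:ME:FAMILY>
## records. The schema (INFO SVTYPE/SVLEN/END/TEFAMILY/SUPPORT, FORMAT
## GT:DP:HS) is the package's output contract; files are round-trip tested
## against VariantAnnotation's reader.

#' Write TE insertion calls to a VCF file
#'
#' One record per call: POS is the 1-based consensus insertion point, REF
#' the reference base at POS (N when no reference FASTA is supplied), ALT
#' the symbolic allele \code{<INS:ME:FAMILY>} with the family upper-cased.
#' INFO carries SVTYPE=INS, END=POS, SVLEN (median insert length), TEFAMILY
#' and SUPPORT; the single sample column carries GT:DP:HS, with GT
#' \code{|}-phased only for haplotype-resolved calls and HS the hap1,hap2
#' supporting-read counts.
#'
#' @param x a \linkS4class{TECallSet}; calls must be sorted by contig and
#'   position (unsorted input is an error).
#' @param out output path.
#' @param refFasta optional reference FASTA (indexed or small enough to
#'   read) used for REF bases.
#' @return \code{out}, invisibly.
#' @export
writeTEVcf <- function(x, out, refFasta = NULL) {
    stopifnot(is(x, "TECallSet"))
    calls <- teCalls(x)
    ctg <- as.character(seqnames(calls))
    if (is.unsorted(order(ctg, start(calls))) ||
        any(order(ctg, start(calls)) != seq_along(calls)))
        stop("calls must be sorted by (contig, position)")
    lens <- contigLengths(x)
    if (length(calls) > 0L && !all(ctg %in% names(lens)))
        stop("call on contig absent from contigLengths: ",
             paste(setdiff(unique(ctg), names(lens)), collapse = ", "))

    ref <- rep("N", length(calls))
    if (!is.null(refFasta) && length(calls) > 0L) {
        genome <- readDNAStringSet(refFasta)
        names(genome) <- sub("\\s.*$", "", names(genome))
        ref <- vapply(seq_along(calls), function(i)
            as.character(subseq(genome[[ctg[i]]], start(calls)[i],
                                start(calls)[i])), "")
    }

    fam <- mcols(calls)$family
    hdr <- c(
        "##fileformat=VCFv4.2",
        paste0("##source=teilr-",
               as.character(utils::packageVersion("teilr"))),
        sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
        sprintf("##ALT=<ID=INS:ME:%s,Description=\"%s mobile element insertion\">",
                unique(toupper(fam)), unique(toupper(fam))),
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Median length of the inserted sequence\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
        "##INFO=<ID=TEFAMILY,Number=1,Type=String,Description=\"Transposable element family of the insertion\">",
        "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of reads supporting the insertion\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Local read depth at the insertion point\">",
        "##FORMAT=<ID=HS,Number=2,Type=Integer,Description=\"Supporting reads on haplotype 1,2\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", sampleName(x), sep = "\t"))
    recs <- character(0)
    if (length(calls) > 0L) {
        m <- mcols(calls)
        dp <- ifelse(is.na(m$depth), ".", as.character(m$depth))
        recs <- paste(
            ctg, start(calls), paste0("teilr_", seq_along(calls)), ref,
            sprintf("<INS:ME:%s>", toupper(fam)), ".", "PASS",
            sprintf("SVTYPE=INS;SVLEN=%d;END=%d;TEFAMILY=%s;SUPPORT=%d",
                    m$insertLen, start(calls), fam, m$support),
            "GT:DP:HS",
            sprintf("%s:%s:%d,%d", m$genotype, dp, m$hap1Support,
                    m$hap2Support),
            sep = "\t")
    }
    writeLines(c(hdr, recs), out)
    invisible(out)
}

#' Read a teilr VCF back into a call table
#'
#' Parses a VCF written by \code{\link{writeTEVcf}} (or any VCF with
#' \code{SVTYPE=INS} records and a TE family encoded in TEFAMILY or the
#' symbolic ALT) with the standard reader and returns one row per call.
#'
#' @param path VCF path.
#' @return data.frame with \code{contig}, \code{position} (0-based
#'   insertion point), \code{family}, \code{insertLen}, \code{support},
#'   \code{genotype}.
#' @export
readTEVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    n <- nrow(vcf)
    if (n == 0L)
        return(data.frame(contig = character(0), position = integer(0),
                          family = character(0), insertLen = integer(0),
                          support = integer(0), genotype = character(0)))
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    fam <- if ("TEFAMILY" %in% colnames(info)) {
        as.character(info$TEFAMILY)
    } else {
        alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
        sub("^<INS:ME:(.*)>$", "\\1", alt)
    }
    gt <- tryCatch(as.character(VariantAnnotation::geno(vcf)$GT[, 1L]),
                   error = function(e) rep(NA_character_, n))
    data.frame(
        contig = as.character(seqnames(rr)),
        position = start(rr) - 1L,
        family = fam,
        insertLen = if ("SVLEN" %in% colnames(info))
            as.integer(info$SVLEN) else NA_integer_,
        support = if ("SUPPORT" %in% colnames(info))
            as.integer(info$SUPPORT) else NA_integer_,
        genotype = gt,
        stringsAsFactors = FALSE)
}
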