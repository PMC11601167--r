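## Call refinement: collapse a passing cluster to a consensus breakpoint,
## estimate insert length, and genotype haplotype-aware from read phasing
## tags (HP/PS).

## lower median: deterministic for even counts
.lowerMedian <- function(x) {
    x <- sort(x)
    x[ceiling(length(x) / 2)]
}

#' Consensus breakpoint of a cluster
#'
#' The lower median of the supporting members' insertion-point positions;
#' for an even count the smaller of the two central values is taken, so the
#' result is always an observed position and deterministic.
#'
#' @param cluster member-evidence GRanges.
#' @param supporting character vector of supporting read ids.
#' @return integer 0-based insertion-point position.
#' @examples
#' gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1100, 1101, 1102),
#'                                                    width = 1))
#' S4Vectors::mcols(gr)$readId <- c("a", "b", "c")
#' consensusPosition(gr, c("a", "b", "c"))
#' @export
consensusPosition <- function(cluster, supporting) {
    stopifnot(length(supporting) > 0L)
    pos <- start(cluster)[mcols(cluster)$readId %in% supporting] - 1L
    stopifnot(length(pos) > 0L)
    .lowerMedian(pos)
}

#' Haplotype-aware genotype of a call
#'
#' Supporting reads carrying phasing tags vote by haplotype: when at least
#' \code{purity} of the tagged reads share one haplotype the call is a
#' phased heterozygote with the ALT allele on that haplotype; when both
#' haplotypes are supported the call is a homozygous variant. Without any
#' tags the call defaults to an unphased heterozygote, upgraded to
#' homozygous when the supporting fraction of the local depth reaches
#' \code{homFraction}. Zero local depth yields an unknown genotype
#' (\code{"./."}) but the call is retained.
#'
#' @param haplotypes integer vector of per-supporting-read haplotype tags
#'   (1, 2 or NA for untagged).
#' @param nSupporting number of distinct supporting reads.
#' @param localDepth MAPQ-passing primary read depth at the consensus
#'   position.
#' @param purity haplotype-purity threshold for a phased het (default 0.8).
#' @param homFraction allele-fraction threshold for the unphased
#'   homozygous upgrade (default 0.8).
#' @return list with \code{genotype} (GT string, \code{|}-phased only when
#'   haplotype-resolved) and \code{hapSupport} (integer reads on hap1,
#'   hap2; untagged reads are in neither).
#' @export
genotypeCall <- function(haplotypes, nSupporting, localDepth,
                         purity = 0.8, homFraction = 0.8) {
    h1 <- sum(haplotypes == 1L, na.rm = TRUE)
    h2 <- sum(haplotypes == 2L, na.rm = TRUE)
    hs <- c(h1, h2)
    if (localDepth == 0L)
        return(list(genotype = "./.", hapSupport = hs))
    tagged <- h1 + h2
    if (tagged > 0L) {
        if (h1 / tagged >= purity)
            return(list(genotype = "1|0", hapSupport = hs))
        if (h2 / tagged >= purity)
            return(list(genotype = "0|1", hapSupport = hs))
        return(list(genotype = "1/1", hapSupport = hs))
    }
    if (nSupporting / localDepth >= homFraction)
        return(list(genotype = "1/1", hapSupport = hs))
    list(genotype = "0/1", hapSupport = hs)
}

## assemble TECallSet rows from passing clusters; assignments is a list
## parallel to clusters with NULL or list(family, supporting)
.refineClusters <- function(clusters, assignments, alignmentFile, params,
                            sampleName, contigLens) {
    pass <- which(!vapply(assignments, is.null, TRUE))
    if (length(pass) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(family = character(0), support = integer(0),
                               insertLen = integer(0),
                               genotype = character(0),
                               hap1Support = integer(0),
                               hap2Support = integer(0), depth = integer(0),
                               clusterId = integer(0))
        return(TECallSet(gr, sampleName, contigLens, params))
    }
    rows <- lapply(pass, function(i) {
        cl <- clusters[[i]]
        a <- assignments[[i]]
        sup <- mcols(cl)$readId %in% a$supporting
        list(contig = as.character(seqnames(cl))[1],
             position = consensusPosition(cl, a$supporting),
             family = a$family,
             support = length(unique(mcols(cl)$readId[sup])),
             insertLen = .lowerMedian(mcols(cl)$len[sup]),
             haplotypes = mcols(cl)$haplotype[sup],
             clusterId = as.integer(names(clusters)[i]))
    })
    depth <- if (is.null(alignmentFile))
        rep(NA_integer_, length(rows))
    else
        .localDepth(alignmentFile,
                    vapply(rows, `[[`, "", "contig"),
                    vapply(rows, `[[`, 0L, "position"), params)
    gt <- lapply(seq_along(rows), function(k)
        genotypeCall(rows[[k]]$haplotypes, rows[[k]]$support,
                     if (is.na(depth[k])) rows[[k]]$support else depth[k]))
    gr <- GRanges(vapply(rows, `[[`, "", "contig"),
                  IRanges(vapply(rows, `[[`, 0L, "position") + 1L,
                          width = 1L))
    mcols(gr) <- DataFrame(
        family = vapply(rows, `[[`, "", "family"),
        support = vapply(rows, `[[`, 0L, "support"),
        insertLen = as.integer(vapply(rows, `[[`, 0L, "insertLen")),
        genotype = vapply(gt, `[[`, "", "genotype"),
        hap1Support = vapply(gt, function(g) g$hapSupport[1], 0L),
        hap2Support = vapply(gt, function(g) g$hapSupport[2], 0L),
        depth = as.integer(depth),
        clusterId = vapply(rows, `[[`, 0L, "clusterId"))
    o <- order(as.character(seqnames(gr)), start(gr))
    TECallSet(gr[o], sampleName, contigLens, params)
}
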