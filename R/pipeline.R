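## End-to-end caller: evidence -> clusters -> TE classification -> refined,
## genotyped calls. All clusters' candidates are batched into a single
## aligner invocation; results are split back per cluster, so output is
## invariant to batching.

#' Call TE insertions from a long-read alignment file
#'
#' Runs the full five-stage pipeline: (1) stream the sorted BAM/CRAM,
#' (2) extract insertion-operation and soft-clip evidence, (3) cluster
#' breakpoint positions per contig with 1-D DBSCAN, (4) realign candidate
#' sequences against the TE consensus library and keep clusters with
#' sufficient same-family read support and match length, (5) refine each
#' passing cluster to a consensus position with a haplotype-aware genotype.
#'
#' @param alignmentFile coordinate-sorted, indexed BAM/CRAM.
#' @param teFasta TE consensus library FASTA (or \code{DNAStringSet}).
#' @param params a \linkS4class{TEIParams}.
#' @param region optional region restriction (see
#'   \code{\link{scanAlignments}}).
#' @param sampleName sample id for the VCF column.
#' @param familyMap optional TE name to family map
#'   (\code{\link{readFamilyMap}}).
#' @param aligner,preset,minimap2 realignment backend, see
#'   \code{\link{alignToTELibrary}}.
#' @param verbose emit per-stage counts to stderr.
#' @return A \linkS4class{TECallSet}. Stage counts (evidence items,
#'   clusters, passing clusters, calls) are in
#'   \code{metadata(teCalls(x))$stageCounts}.
#' @examples
#' \dontrun{
#' calls <- callTEI("sample.bam", "te_consensus.fa")
#' writeTEVcf(calls, "sample.te.vcf")
#' }
#' @export
callTEI <- function(alignmentFile, teFasta, params = teiParameters(),
                    region = NULL, sampleName = "sample",
                    familyMap = NULL,
                    aligner = c("auto", "minimap2", "builtin"),
                    preset = "map-ont", minimap2 = "minimap2",
                    verbose = FALSE) {
    aligner <- match.arg(aligner)
    say <- function(...) if (verbose) message(...)

    ev <- scanAlignments(alignmentFile, region, params)
    say("evidence items: ", length(ev))
    clusters <- buildClusters(ev, params)
    say("candidate clusters: ", length(clusters))

    contigLens <- scanBamHeader(alignmentFile)[[1]]$targets
    storage.mode(contigLens) <- "integer"

    assignments <- rep(list(NULL), length(clusters))
    if (length(clusters) > 0L) {
        ## one aligner invocation for all clusters' candidates
        cand <- lapply(seq_along(clusters), function(i) {
            s <- collectCandidateSequences(clusters[[i]])
            names(s) <- paste0(i, "::", names(s))
            s
        })
        cand <- do.call(c, cand)
        matches <- alignToTELibrary(cand, teFasta, aligner = aligner,
                                    preset = preset, minimap2 = minimap2)
        cidx <- as.integer(sub("::.*$", "", matches$readId))
        matches$readId <- sub("^[0-9]+::", "", matches$readId)
        byCluster <- split(matches, factor(cidx,
                                           levels = seq_along(clusters)))
        assignments <- lapply(seq_along(clusters), function(i)
            filterAndAssign(clusters[[i]], byCluster[[i]], params,
                            familyMap))
    }
    say("passing clusters: ",
        sum(!vapply(assignments, is.null, TRUE)))

    res <- .refineClusters(clusters, assignments, alignmentFile, params,
                           sampleName, contigLens)
    say("calls: ", length(res))
    gr <- res@calls
    metadata(gr)$stageCounts <- c(
        evidence = length(ev),
        clusters = length(clusters),
        passing = sum(!vapply(assignments, is.null, TRUE)),
        calls = length(gr))
    res@calls <- gr
    res
}
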