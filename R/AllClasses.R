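#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
NULL

#' Caller parameters
#'
#' Container for the tunable thresholds of the TEI caller. All stages of the
#' pipeline read their thresholds from one \code{TEIParams} object so that a
#' run is fully described by it.
#'
#' @slot minSupportingReads integer(1). Minimum number of reads whose
#'   candidate sequence must match the same TE family for a cluster to be
#'   reported (default 3).
#' @slot clusterEps integer(1). DBSCAN neighbourhood radius in bp: maximum
#'   distance between neighbouring breakpoint positions (default 100).
#' @slot clusterMinPoints integer(1). DBSCAN minimum neighbourhood size
#'   (core-point threshold); defaults to \code{minSupportingReads}.
#' @slot minInsertionLen integer(1). Minimum CIGAR insertion-operation length
#'   (bp) retained as evidence (default 100).
#' @slot minClipLen integer(1). Minimum soft-clip length (bp) retained as
#'   evidence (default 150).
#' @slot minMapq integer(1). Minimum mapping quality of reads considered
#'   (default 10).
#' @slot matchFraction numeric(1). A TE-library match is valid when its
#'   aligned length covers at least this fraction of the candidate sequence
#'   (default 0.10).
#' @slot matchWindowBp integer(1). Breakpoint window (bp) used only by the
#'   evaluator when matching calls to truth records (default 50).
#' @export
setClass("TEIParams", representation(
    minSupportingReads = "integer",
    clusterEps         = "integer",
    clusterMinPoints   = "integer",
    minInsertionLen    = "integer",
    minClipLen         = "integer",
    minMapq            = "integer",
    matchFraction      = "numeric",
    matchWindowBp      = "integer"
))

setValidity("TEIParams", function(object) {
    msg <- character()
    if (object@minSupportingReads < 1L)
        msg <- c(msg, "minSupportingReads must be >= 1")
    if (object@clusterEps <= 0L)
        msg <- c(msg, "clusterEps must be > 0")
    if (object@clusterMinPoints < 1L)
        msg <- c(msg, "clusterMinPoints must be >= 1")
    if (object@matchFraction <= 0 || object@matchFraction > 1)
        msg <- c(msg, "matchFraction must be in (0, 1]")
    if (object@minInsertionLen < 1L || object@minClipLen < 1L)
        msg <- c(msg, "minimum event lengths must be >= 1")
    if (object@minMapq < 0L)
        msg <- c(msg, "minMapq must be >= 0")
    if (object@matchWindowBp <= 0L)
        msg <- c(msg, "matchWindowBp must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct caller parameters
#'
#' @param minSupportingReads Minimum same-family supporting reads per call.
#' @param clusterEps DBSCAN neighbourhood radius in bp.
#' @param clusterMinPoints DBSCAN core-point threshold; defaults to
#'   \code{minSupportingReads} so one knob moves both, mirroring the usual
#'   sensitivity control of TEI callers.
#' @param minInsertionLen Minimum insertion-operation length (bp).
#' @param minClipLen Minimum soft-clip length (bp).
#' @param minMapq Minimum mapping quality.
#' @param matchFraction Minimum aligned fraction of a candidate sequence for
#'   a TE match to count.
#' @param matchWindowBp Evaluation breakpoint window (bp).
#' @return A \linkS4class{TEIParams} object.
#' @examples
#' teiParameters(minSupportingReads = 5)
#' @export
teiParameters <- function(minSupportingReads = 3L,
                          clusterEps = 100L,
                          clusterMinPoints = minSupportingReads,
                          minInsertionLen = 100L,
                          minClipLen = 150L,
                          minMapq = 10L,
                          matchFraction = 0.10,
                          matchWindowBp = 50L) {
    new("TEIParams",
        minSupportingReads = as.integer(minSupportingReads),
        clusterEps         = as.integer(clusterEps),
        clusterMinPoints   = as.integer(clusterMinPoints),
        minInsertionLen    = as.integer(minInsertionLen),
        minClipLen         = as.integer(minClipLen),
        minMapq            = as.integer(minMapq),
        matchFraction      = as.numeric(matchFraction),
        matchWindowBp      = as.integer(matchWindowBp))
}

setMethod("show", "TEIParams", function(object) {
    cat("TEIParams\n")
    cat("  minSupportingReads:", object@minSupportingReads, "\n")
    cat("  clusterEps:        ", object@clusterEps, "bp\n")
    cat("  clusterMinPoints:  ", object@clusterMinPoints, "\n")
    cat("  minInsertionLen:   ", object@minInsertionLen, "bp\n")
    cat("  minClipLen:        ", object@minClipLen, "bp\n")
    cat("  minMapq:           ", object@minMapq, "\n")
    cat("  matchFraction:     ", object@matchFraction, "\n")
    cat("  matchWindowBp:     ", object@matchWindowBp, "bp\n")
})

#' Set of refined TE insertion calls
#'
#' Final product of the caller: one range per insertion call, 1-based
#' anchored at the consensus insertion point, with per-call metadata columns
#' \code{family}, \code{support}, \code{insertLen}, \code{genotype},
#' \code{hap1Support}, \code{hap2Support}, \code{depth} and
#' \code{clusterId}.
#'
#' @slot calls GRanges of calls (width-1 anchors at the insertion point).
#' @slot sampleName character(1) sample identifier used in the VCF.
#' @slot contigLengths named integer vector of contig lengths (VCF header).
#' @slot parameters the \linkS4class{TEIParams} the calls were made with.
#' @export
setClass("TECallSet", representation(
    calls         = "GRanges",
    sampleName    = "character",
    contigLengths = "integer",
    parameters    = "TEIParams"
))

setValidity("TECallSet", function(object) {
    msg <- character()
    need <- c("family", "support", "insertLen", "genotype",
              "hap1Support", "hap2Support", "depth", "clusterId")
    miss <- setdiff(need, colnames(mcols(object@calls)))
    if (length(miss))
        msg <- c(msg, paste("calls lack mcols:", paste(miss, collapse = ", ")))
    if (length(object@sampleName) != 1L)
        msg <- c(msg, "sampleName must be a single string")
    if (is.null(names(object@contigLengths)) &&
        length(object@contigLengths) > 0L)
        msg <- c(msg, "contigLengths must be named")
    if (length(msg)) msg else TRUE
})

#' @describeIn TECallSet constructor.
#' @param calls GRanges of calls.
#' @param sampleName sample identifier.
#' @param contigLengths named integer vector of contig lengths.
#' @param parameters a \linkS4class{TEIParams}.
#' @export
TECallSet <- function(calls, sampleName = "sample",
                      contigLengths = integer(0),
                      parameters = teiParameters()) {
    new("TECallSet", calls = calls, sampleName = sampleName,
        contigLengths = contigLengths, parameters = parameters)
}

#' @export
setGeneric("teCalls", function(x) standardGeneric("teCalls"))

#' Extract the calls GRanges from a TECallSet
#' @param x A \linkS4class{TECallSet}.
#' @return GRanges of calls.
#' @export
setMethod("teCalls", "TECallSet", function(x) x@calls)

#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @describeIn TECallSet sample identifier accessor.
#' @export
setMethod("sampleName", "TECallSet", function(x) x@sampleName)

#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @describeIn TECallSet contig-length accessor.
#' @export
setMethod("contigLengths", "TECallSet", function(x) x@contigLengths)

#' @export
setGeneric("callerParams", function(x) standardGeneric("callerParams"))

#' @describeIn TECallSet caller-parameter accessor.
#' @export
setMethod("callerParams", "TECallSet", function(x) x@parameters)

setMethod("show", "TECallSet", function(object) {
    n <- length(object@calls)
    cat("TECallSet with", n, "call(s) for sample", object@sampleName, "\n")
    if (n > 0L) {
        fam <- table(mcols(object@calls)$family)
        cat("  families:",
            paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
    }
})

setMethod("length", "TECallSet", function(x) length(x@calls))
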