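## Benchmark scoring: per-family sensitivity and precision of a call set
## against a simulated truth set, under a breakpoint window and greedy
## one-to-one distance matching.

.asCallTable <- function(calls) {
    if (is.character(calls))
        return(readTEVcf(calls))
    if (is(calls, "TECallSet"))
        calls <- teCalls(calls)
    if (is(calls, "GRanges"))
        return(data.frame(contig = as.character(seqnames(calls)),
                          position = start(calls) - 1L,
                          family = mcols(calls)$family,
                          stringsAsFactors = FALSE))
    stopifnot(all(c("contig", "position", "family") %in% colnames(calls)))
    calls
}

#' Score calls against a truth set
#'
#' A call is a true positive when a truth record of the same family (case
#' insensitive) lies within \code{window} bp on the same contig; matching
#' is one-to-one and greedy by increasing distance, so a second call on an
#' already-matched truth record counts as a false positive. Sensitivity is
#' TP / truth count and precision TP / (TP + FP); a family with no truth
#' records reports precision only, and an absent quantity is NA.
#'
#' @param calls a \linkS4class{TECallSet}, a GRanges with a \code{family}
#'   mcol, a data.frame (contig/position/family), or a VCF path.
#' @param truth truth data.frame from \code{\link{plantInsertions}} (or a
#'   TSV path from \code{\link{writeTruth}}).
#' @param window breakpoint window in bp (default 50).
#' @return data.frame with one row per family: \code{family} (upper case),
#'   \code{nTruth}, \code{tp}, \code{fn}, \code{fp}, \code{sensitivity},
#'   \code{precision}.
#' @export
evaluateCalls <- function(calls, truth, window = 50L) {
    stopifnot(window > 0)
    calls <- .asCallTable(calls)
    if (is.character(truth))
        truth <- readTruth(truth)
    callFam <- toupper(calls$family)
    truthFam <- toupper(truth$family)
    fams <- sort(unique(c(callFam, truthFam)))
    rows <- lapply(fams, function(f) {
        tc <- truth[truthFam == f, , drop = FALSE]
        cc <- calls[callFam == f, , drop = FALSE]
        tp <- 0L
        if (nrow(tc) > 0L && nrow(cc) > 0L) {
            ## all candidate pairs within the window, nearest first
            pairs <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
                j <- which(tc$contig == cc$contig[i] &
                           abs(tc$position - cc$position[i]) <= window)
                if (length(j) == 0L)
                    return(NULL)
                data.frame(ci = i, ti = j,
                           d = abs(tc$position[j] - cc$position[i]))
            }))
            if (!is.null(pairs) && nrow(pairs) > 0L) {
                pairs <- pairs[order(pairs$d, pairs$ci, pairs$ti), ,
                               drop = FALSE]
                usedC <- rep(FALSE, nrow(cc))
                usedT <- rep(FALSE, nrow(tc))
                for (k in seq_len(nrow(pairs))) {
                    ci <- pairs$ci[k]; ti <- pairs$ti[k]
                    if (!usedC[ci] && !usedT[ti]) {
                        usedC[ci] <- TRUE
                        usedT[ti] <- TRUE
                        tp <- tp + 1L
                    }
                }
            }
        }
        fp <- nrow(cc) - tp
        fn <- nrow(tc) - tp
        data.frame(family = f, nTruth = nrow(tc), tp = tp, fn = fn,
                   fp = fp,
                   sensitivity = if (nrow(tc) > 0L) tp / nrow(tc) else
                       NA_real_,
                   precision = if (nrow(cc) > 0L) tp / (tp + fp) else
                       NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
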