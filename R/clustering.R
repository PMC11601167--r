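## 1-D DBSCAN over breakpoint positions. The generic algorithm specialises
## cleanly on the line: neighbourhood counts come from two binary searches
## over the sorted positions, core points chain into clusters when
## consecutive cores are within eps, and border points attach to the nearest
## core (ties to the leftmost). Labels are equivalent to generic DBSCAN with
## Euclidean distance; cluster numbering is by leftmost member, noise is 0.

#' One-dimensional DBSCAN
#'
#' Density-based clustering of integer positions on a line. A position is a
#' core point when at least \code{minPts} positions (itself included) lie
#' within \code{eps} of it; clusters are maximal chains of density-connected
#' core points plus their border points; everything else is noise.
#'
#' @param positions integer vector, sorted ascending (duplicates allowed).
#' @param eps neighbourhood radius (bp), > 0.
#' @param minPts minimum neighbourhood size for a core point, >= 1.
#' @return integer vector of cluster labels parallel to \code{positions}:
#'   0 marks noise, clusters are numbered 1, 2, ... by their leftmost
#'   member. Border points within \code{eps} of cores from two clusters are
#'   assigned to the nearest core (ties to the leftmost core).
#' @examples
#' dbscan1d(c(100L, 105L, 110L, 5000L), eps = 50, minPts = 3)
#' @export
dbscan1d <- function(positions, eps, minPts) {
    stopifnot(eps > 0, minPts >= 1)
    n <- length(positions)
    if (n == 0L)
        return(integer(0))
    if (is.unsorted(positions))
        stop("positions must be sorted ascending")
    p <- as.numeric(positions)

    ## neighbourhood size |{j : |p_j - p_i| <= eps}| via binary search
    hi <- findInterval(p + eps, p)
    lo <- findInterval(p - eps, p, left.open = TRUE) + 1L
    core <- (hi - lo + 1L) >= minPts

    labels <- integer(n)
    ci <- which(core)
    if (length(ci) == 0L)
        return(labels)

    ## consecutive core points within eps are density-connected
    newClust <- c(TRUE, diff(p[ci]) > eps)
    coreLab <- cumsum(newClust)
    labels[ci] <- coreLab

    ## border points: non-core within eps of some core -> nearest core,
    ## ties broken towards the smaller position
    bi <- which(!core)
    if (length(bi) > 0L) {
        ## nearest core at-or-left / strictly-right of each border point
        leftIdx <- findInterval(p[bi], p[ci])            # 0 if none
        rightIdx <- leftIdx + 1L
        hasLeft <- leftIdx >= 1L
        hasRight <- rightIdx <= length(ci)
        dLeft <- dRight <- rep(Inf, length(bi))
        dLeft[hasLeft] <- p[bi][hasLeft] - p[ci][leftIdx[hasLeft]]
        dRight[hasRight] <- p[ci][rightIdx[hasRight]] - p[bi][hasRight]
        leftIdx[!hasLeft] <- 1L    # placeholder; masked by Inf distance
        rightIdx[!hasRight] <- 1L
        useLeft <- dLeft <= dRight        # tie -> leftmost core
        d <- ifelse(useLeft, dLeft, dRight)
        lab <- ifelse(useLeft, coreLab[leftIdx], coreLab[rightIdx])
        ok <- d <= eps
        labels[bi[ok]] <- lab[ok]
    }

    ## renumber clusters by leftmost member
    used <- labels > 0L
    if (any(used)) {
        first <- tapply(seq_len(n)[used], labels[used], min)
        remap <- integer(max(labels))
        remap[as.integer(names(first))] <- rank(first, ties.method = "first")
        labels[used] <- remap[labels[used]]
    }
    labels
}

#' Cluster insertion evidence into candidate loci
#'
#' Runs 1-D DBSCAN per contig over the evidence positions (insertion
#' operations and soft clips jointly) with \code{clusterEps} and
#' \code{clusterMinPoints} from \code{params}. Noise evidence is discarded.
#'
#' @param evidence evidence GRanges from \code{\link{scanAlignments}}.
#' @param params a \linkS4class{TEIParams}.
#' @return A \code{GRangesList}, one element per candidate cluster holding
#'   its member evidence, ordered by (contig, leftmost position) and named
#'   by cluster id; \code{mcols()} of the list carries \code{contig},
#'   \code{posMin}, \code{posMax} (0-based insertion points) and \code{n}.
#' @export
buildClusters <- function(evidence, params = teiParameters()) {
    empty <- GRangesList()
    if (length(evidence) == 0L) {
        mcols(empty) <- DataFrame(contig = character(0),
                                  posMin = integer(0), posMax = integer(0),
                                  n = integer(0))
        return(empty)
    }
    ctg <- as.character(seqnames(evidence))
    o <- order(ctg, start(evidence))
    evidence <- evidence[o]
    ctg <- ctg[o]
    members <- list()
    for (cg in unique(ctg)) {
        idx <- which(ctg == cg)
        lab <- dbscan1d(start(evidence)[idx], params@clusterEps,
                        params@clusterMinPoints)
        for (k in seq_len(max(c(lab, 0L))))
            members[[length(members) + 1L]] <- evidence[idx[lab == k]]
    }
    if (length(members) == 0L) {
        mcols(empty) <- DataFrame(contig = character(0),
                                  posMin = integer(0), posMax = integer(0),
                                  n = integer(0))
        return(empty)
    }
    info <- data.frame(
        contig = vapply(members, function(m)
            as.character(seqnames(m))[1], ""),
        posMin = vapply(members, function(m) min(start(m)) - 1L, 0L),
        posMax = vapply(members, function(m) max(start(m)) - 1L, 0L),
        n = vapply(members, length, 0L))
    o <- order(info$contig, info$posMin)
    members <- members[o]
    info <- info[o, , drop = FALSE]
    out <- GRangesList(members)
    names(out) <- as.character(seq_along(members))
    mcols(out) <- DataFrame(contig = info$contig, posMin = info$posMin,
                            posMax = info$posMax, n = info$n)
    out
}
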