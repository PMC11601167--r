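## TE-library realignment and cluster filtering. Candidate sequences
## (inserted or clipped bases) are aligned against the TE consensus FASTA;
## a cluster is reported when enough reads carry a valid match to the same
## family. minimap2 is the default aligner when available; a built-in
## local (Smith-Waterman) aligner backs the same contract so the package
## works hermetically without external binaries.

#' Collect candidate sequences from a cluster
#'
#' One entry per cluster member, sequence kept verbatim. When the same read
#' contributes several evidence items to one cluster the ids are
#' disambiguated with a \code{#k} suffix (k = 2, 3, ...).
#'
#' @param cluster member-evidence GRanges (one element of
#'   \code{\link{buildClusters}} output).
#' @return named \code{DNAStringSet}, ordered by read id.
#' @export
collectCandidateSequences <- function(cluster) {
    stopifnot(length(cluster) > 0L)
    ids <- mcols(cluster)$readId
    o <- order(ids, start(cluster), mcols(cluster)$kind)
    ids <- ids[o]
    seqs <- mcols(cluster)$sequence[o]
    k <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[k > 1L] <- paste0(ids[k > 1L], "#", k[k > 1L])
    out <- DNAStringSet(seqs)
    names(out) <- ids
    out
}

.loadTELibrary <- function(teFasta) {
    if (is(teFasta, "DNAStringSet")) {
        lib <- teFasta
    } else {
        if (!file.exists(teFasta))
            stop("TE FASTA '", teFasta, "' not found")
        lib <- tryCatch(readDNAStringSet(teFasta),
                        error = function(e) stop("TE FASTA '", teFasta,
                                                 "' unreadable: ",
                                                 conditionMessage(e)))
    }
    if (length(lib) == 0L)
        stop("TE library is empty")
    ## first whitespace-delimited token of the FASTA header
    names(lib) <- sub("\\s.*$", "", names(lib))
    lib
}

.minimap2Available <- function(minimap2 = "minimap2") {
    nzchar(Sys.which(minimap2))
}

.alignMinimap2 <- function(candidates, lib, preset, minimap2) {
    tmpq <- tempfile(fileext = ".fa")
    tmpt <- tempfile(fileext = ".fa")
    on.exit(unlink(c(tmpq, tmpt)), add = TRUE)
    ## candidate names may contain characters minimap2 would split on;
    ## align under positional aliases and map back
    alias <- paste0("q", seq_along(candidates))
    aliased <- candidates
    names(aliased) <- alias
    writeXStringSet(aliased, tmpq)
    writeXStringSet(lib, tmpt)
    out <- tempfile(fileext = ".paf")
    errFile <- tempfile(fileext = ".log")
    on.exit(unlink(c(out, errFile)), add = TRUE)
    status <- system2(minimap2,
                      c("-c", "--secondary=no", "-x", preset, tmpt, tmpq),
                      stdout = out, stderr = errFile)
    if (status != 0L)
        stop("minimap2 failed (exit ", status, "): ",
             paste(readLines(errFile, warn = FALSE), collapse = "\n"))
    lines <- readLines(out)
    if (length(lines) == 0L)
        return(NULL)
    f <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(
        readId     = names(candidates)[match(vapply(f, `[`, "", 1L), alias)],
        queryLen   = as.integer(vapply(f, `[`, "", 2L)),
        alignedLen = as.integer(vapply(f, `[`, "", 4L)) -
                     as.integer(vapply(f, `[`, "", 3L)),
        strand     = vapply(f, `[`, "", 5L),
        teName     = vapply(f, `[`, "", 6L),
        score      = as.integer(vapply(f, `[`, "", 10L)),  # matching bases
        stringsAsFactors = FALSE)
}

.alignBuiltin <- function(candidates, lib, minScore) {
    submat <- nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                           baseOnly = FALSE, type = "DNA")
    rows <- list()
    for (j in seq_along(lib)) {
        for (strand in c("+", "-")) {
            subj <- if (strand == "+") lib[[j]] else
                reverseComplement(lib[[j]])
            pa <- pairwiseAlignment(candidates, subj, type = "local",
                                    substitutionMatrix = submat,
                                    gapOpening = 4, gapExtension = 2)
            pr <- pattern(pa)
            rows[[length(rows) + 1L]] <- data.frame(
                readId     = names(candidates),
                queryLen   = width(candidates),
                alignedLen = end(pr) - start(pr) + 1L,
                strand     = strand,
                teName     = names(lib)[j],
                score      = Biostrings::score(pa),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out[out$score >= minScore, , drop = FALSE]
}

#' Align candidate sequences to a TE consensus library
#'
#' Each candidate is locally aligned against every library entry; the best
#' hit per candidate (highest score, ties broken by longer query-aligned
#' length, then lexicographic target name) is reported. Candidates with no
#' hit yield no row. Uses minimap2 (preset for noisy long reads) when
#' available, otherwise a built-in Smith-Waterman aligner (match 2,
#' mismatch -4, gap open 4, gap extend 2, reported above \code{minScore}).
#'
#' @param candidates named \code{DNAStringSet} (or named character vector)
#'   of candidate insertion/clip sequences.
#' @param teFasta path to the TE consensus FASTA, or a \code{DNAStringSet}.
#' @param aligner \code{"auto"} (minimap2 when on PATH), \code{"minimap2"},
#'   or \code{"builtin"}.
#' @param preset minimap2 preset (default \code{"map-ont"}, whose chaining is the more sensitive choice for short, error-rich candidate segments).
#' @param minScore minimum local-alignment score for the built-in aligner
#'   to report a hit.
#' @param minimap2 name/path of the minimap2 executable.
#' @return data.frame with one row per matched candidate: \code{readId},
#'   \code{teName}, \code{alignedLen} (query bases covered by the
#'   alignment), \code{strand}, \code{queryLen}, \code{score}.
#' @export
alignToTELibrary <- function(candidates, teFasta,
                             aligner = c("auto", "minimap2", "builtin"),
                             preset = "map-ont", minScore = 40,
                             minimap2 = "minimap2") {
    aligner <- match.arg(aligner)
    if (is.character(candidates))
        candidates <- DNAStringSet(candidates)
    if (is.null(names(candidates)))
        stop("candidates must be named")
    lib <- .loadTELibrary(teFasta)
    if (length(candidates) == 0L)
        return(data.frame(readId = character(0), teName = character(0),
                          alignedLen = integer(0), strand = character(0),
                          queryLen = integer(0), score = numeric(0)))
    if (aligner == "auto")
        aligner <- if (.minimap2Available(minimap2)) "minimap2" else
            "builtin"
    hits <- if (aligner == "minimap2")
        .alignMinimap2(candidates, lib, preset, minimap2)
    else
        .alignBuiltin(candidates, lib, minScore)
    if (is.null(hits) || nrow(hits) == 0L)
        return(data.frame(readId = character(0), teName = character(0),
                          alignedLen = integer(0), strand = character(0),
                          queryLen = integer(0), score = numeric(0)))
    o <- order(hits$readId, -hits$score, -hits$alignedLen, hits$teName)
    hits <- hits[o, , drop = FALSE]
    hits <- hits[!duplicated(hits$readId), , drop = FALSE]
    rownames(hits) <- NULL
    hits[, c("readId", "teName", "alignedLen", "strand", "queryLen",
             "score")]
}

#' Read an optional TE name-to-family map
#'
#' Two-column whitespace/tab-separated file: TE name (FASTA header token),
#' family label. Lets e.g. many Alu subfamily consensus entries vote as one
#' family.
#'
#' @param path TSV path.
#' @return named character vector (name -> family).
#' @export
readFamilyMap <- function(path) {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("name", "family"))
    stats::setNames(df$family, df$name)
}

#' Filter a cluster on read support and match length
#'
#' A TE match is valid when its aligned length is at least
#' \code{matchFraction} of the candidate sequence length. The cluster
#' passes when at least \code{minSupportingReads} distinct reads hold valid
#' matches to the same family; the winning family is the one supported by
#' most reads (ties: larger cumulative aligned length, then lexicographic
#' name).
#'
#' @param cluster member-evidence GRanges.
#' @param matches data.frame from \code{\link{alignToTELibrary}} for this
#'   cluster's candidates.
#' @param params a \linkS4class{TEIParams}.
#' @param familyMap optional named character vector mapping TE names to
#'   family labels (see \code{\link{readFamilyMap}}); default identity.
#' @return \code{NULL} when the cluster fails, else
#'   \code{list(family =, supporting =)} with the sorted unique supporting
#'   read ids.
#' @export
filterAndAssign <- function(cluster, matches, params = teiParameters(),
                            familyMap = NULL) {
    if (is.null(matches) || nrow(matches) == 0L)
        return(NULL)
    valid <- matches$alignedLen >= params@matchFraction * matches$queryLen
    m <- matches[valid, , drop = FALSE]
    if (nrow(m) == 0L)
        return(NULL)
    fam <- m$teName
    if (!is.null(familyMap)) {
        hit <- fam %in% names(familyMap)
        fam[hit] <- unname(familyMap[fam[hit]])
    }
    readOrig <- sub("#[0-9]+$", "", m$readId)
    support <- tapply(readOrig, fam, function(x) length(unique(x)))
    cumLen <- tapply(m$alignedLen, fam, sum)
    fams <- names(support)
    o <- order(-as.integer(support), -as.numeric(cumLen[fams]), fams)
    best <- fams[o[1L]]
    if (support[[best]] < params@minSupportingReads)
        return(NULL)
    list(family = best,
         supporting = sort(unique(readOrig[fam == best])))
}
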