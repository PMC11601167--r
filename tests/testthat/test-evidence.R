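test_that("CIGAR insertion operations become evidence at the insertion point", {
    p <- teiParameters(minInsertionLen = 50)
    rd <- makeRead("100M300I100M", pos = 1001L)  # 0-based ref start 1000
    ev <- extractInsertionOps(rd, p)
    expect_equal(length(ev), 1L)
    expect_equal(evidencePositions(ev), 1100L)
    expect_equal(mcols(ev)$kind, "insertion_op")
    expect_equal(mcols(ev)$len, 300L)
    expect_equal(mcols(ev)$sequence, substr(rd$seq, 101L, 400L))

    expect_equal(length(extractInsertionOps(makeRead("200M"), p)), 0L)
})

test_that("insertion ops below the length threshold are dropped", {
    p <- teiParameters(minInsertionLen = 25)
    rd <- makeRead("50M30I50M20I50M", pos = 1L)  # 0-based start 0
    ev <- extractInsertionOps(rd, p)
    expect_equal(length(ev), 1L)
    expect_equal(mcols(ev)$len, 30L)
    expect_equal(evidencePositions(ev), 50L)
})

test_that("soft clips anchor at the read's reference start or end", {
    p <- teiParameters(minClipLen = 150)
    rd <- makeRead("400S1000M", pos = 5001L)  # 0-based ref start 5000
    ev <- extractClipEvents(rd, p)
    expect_equal(length(ev), 1L)
    expect_equal(mcols(ev)$kind, "left_clip")
    expect_equal(evidencePositions(ev), 5000L)
    expect_equal(mcols(ev)$len, 400L)
    expect_equal(mcols(ev)$sequence, substr(rd$seq, 1L, 400L))

    rdR <- makeRead("1000M200S", pos = 5001L)
    evR <- extractClipEvents(rdR, p)
    expect_equal(mcols(evR)$kind, "right_clip")
    expect_equal(evidencePositions(evR), 6000L)

    expect_equal(length(extractClipEvents(makeRead("1000M20S"), p)), 0L)
    expect_equal(length(extractClipEvents(makeRead("300H1000M"), p)), 0L)
})

test_that("sequence-less reads are skipped with a warning, not an error", {
    rd <- makeRead("100M300I100M")
    rd$seq <- "*"
    expect_warning(ev <- extractInsertionOps(rd, teiParameters()),
                   "no query sequence")
    expect_equal(length(ev), 0L)
})

test_that("scanAlignments unions extractors over a sorted fixture", {
    p <- teiParameters()
    empty <- writeFixtureBam(list())
    expect_equal(length(scanAlignments(empty, params = p)), 0L)

    ## five reads with a 300 bp insertion op at the same 0-based locus 2000
    reads <- lapply(1:5, function(i)
        makeRead("1000M300I1000M", pos = 1001L,
                 qname = paste0("r", i)))
    bam <- writeFixtureBam(reads)
    ev <- scanAlignments(bam, params = p)
    expect_equal(length(ev), 5L)
    expect_true(all(evidencePositions(ev) == 2000L))

    ## one insertion op plus one qualifying left clip, sorted by position
    reads2 <- list(makeRead("500M300I500M", pos = 3001L, qname = "a"),
                   makeRead("400S800M", pos = 9001L, qname = "b"))
    bam2 <- writeFixtureBam(reads2)
    ev2 <- scanAlignments(bam2, params = p)
    expect_equal(length(ev2), 2L)
    expect_equal(evidencePositions(ev2), c(3500L, 9000L))
    expect_equal(mcols(ev2)$kind, c("insertion_op", "left_clip"))

    ## hard-clip counter
    bam3 <- writeFixtureBam(list(makeRead("300H800M", pos = 101L)))
    ev3 <- scanAlignments(bam3, params = p)
    expect_equal(length(ev3), 0L)
    expect_equal(unname(attr(ev3, "counters")["nHardClipOps"]), 1L)
})

test_that("evidence is invariant to read order and MAPQ/region filters hold", {
    p <- teiParameters()
    reads <- list(makeRead("500M300I500M", pos = 3001L, qname = "a"),
                  makeRead("400S800M", pos = 9001L, qname = "b"),
                  makeRead("200M400I200M", pos = 7001L, qname = "c",
                           mapq = 5L))
    evFwd <- scanAlignments(writeFixtureBam(reads), params = p)
    evRev <- scanAlignments(writeFixtureBam(rev(reads)), params = p)
    expect_equal(as.data.frame(evFwd), as.data.frame(evRev))
    ## the MAPQ-5 read is filtered under minMapq 10
    expect_false("c" %in% mcols(evFwd)$readId)

    expect_error(scanAlignments(writeFixtureBam(reads), region = "nope",
                                params = p), "not present")
    expect_error(scanAlignments(tempfile(fileext = ".bam"), params = p),
                 "no index|not found|does not exist")
})

test_that("permissive thresholds recover exactly the brute-force CIGAR walk", {
    p0 <- teiParameters(minMapq = 0, minInsertionLen = 1, minClipLen = 1)
    set.seed(11)
    cigars <- c("10S50M5I40M", "60M3I10M8S", "5M1I5M1I5M", "20S30M20S",
                "100M", "7M2D6M9I3M")
    reads <- lapply(seq_along(cigars), function(i)
        makeRead(cigars[i], pos = 1000L * i + 1L,
                 qname = paste0("q", i)))
    bam <- writeFixtureBam(reads)
    ev <- scanAlignments(bam, params = p0)

    expected <- do.call(rbind, lapply(reads, function(r) {
        df <- bruteCigarEvents(r$cigar, r$pos)
        if (is.null(df)) return(NULL)
        df$readId <- r$qname
        df$sequence <- substring(r$seq, df$qstart + 1L, df$qstart + df$len)
        df
    }))
    expected <- expected[order(expected$position, expected$readId,
                               expected$kind), ]
    expect_equal(length(ev), nrow(expected))
    expect_equal(evidencePositions(ev), expected$position)
    expect_equal(mcols(ev)$kind, expected$kind)
    expect_equal(mcols(ev)$sequence, expected$sequence)
    ## every emitted sequence is a substring of its source read
    qseq <- setNames(vapply(reads, `[[`, "", "seq"),
                     vapply(reads, `[[`, "", "qname"))
    expect_true(all(mapply(grepl, mcols(ev)$sequence,
                           qseq[mcols(ev)$readId], fixed = TRUE)))
})

test_that("phasing tags are carried onto evidence", {
    reads <- list(makeRead("500M300I500M", pos = 1001L, qname = "a",
                           hp = 2L, ps = 7L))
    ev <- scanAlignments(writeFixtureBam(reads), params = teiParameters())
    expect_equal(mcols(ev)$haplotype, 2L)
    expect_equal(mcols(ev)$phaseSet, 7L)
})
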