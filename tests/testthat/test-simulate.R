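lib <- testTELibrary()

test_that("genome simulation is seed-deterministic with balanced GC", {
    cfg <- simConfig(genomeLen = 1e5, nInsertions = c(Alu = 0L), seed = 3)
    g1 <- simulateGenome(cfg)
    g2 <- simulateGenome(cfg)
    expect_identical(as.character(g1), as.character(g2))
    expect_equal(width(g1), 1e5)
    gc <- Biostrings::letterFrequency(g1, "GC", as.prob = TRUE)[1]
    expect_lt(abs(gc - 0.5), 0.02)
})

test_that("planting conserves sequence length and records every event", {
    cfg <- simConfig(genomeLen = 2e5,
                     nInsertions = c(Alu = 6L, SVA = 2L), seed = 21)
    g <- simulateGenome(cfg)
    pl <- plantInsertions(g, lib, cfg)
    expect_equal(nrow(pl$truth), 8L)
    expect_equal(sum(pl$truth$family == "Alu"), 6L)
    added <- sum(pl$truth$insertedLen)
    expect_equal(width(pl$haplotypes)[1], 2e5 + added)  # hom: both copies
    expect_equal(width(pl$haplotypes)[2], 2e5 + added)
    expect_true(all(diff(sort(pl$truth$position)) >= 1000L))
    expect_true(all(pl$truth$position >= 1000L &
                    pl$truth$position <= 2e5 - 1000L))

    ## zero insertions leave the genome untouched
    cfg0 <- simConfig(genomeLen = 5e4, nInsertions = c(Alu = 0L), seed = 4)
    pl0 <- plantInsertions(simulateGenome(cfg0), lib, cfg0)
    expect_equal(nrow(pl0$truth), 0L)
    expect_identical(as.character(pl0$haplotypes[[1]]),
                     as.character(pl0$genome[[1]]))
})

test_that("infeasible insertion density is fatal", {
    cfg <- simConfig(genomeLen = 5e4, nInsertions = c(Alu = 100L),
                     seed = 5)
    expect_error(plantInsertions(simulateGenome(cfg), lib, cfg),
                 "infeasible")
})

test_that("error-free direct-BAM reads carry exact insertion CIGARs at truth loci", {
    cfg <- simConfig(genomeLen = 2e5, nInsertions = c(Alu = 2L, SVA = 1L),
                     coverage = 10,
                     errorRates = c(mismatch = 0, insertion = 0,
                                    deletion = 0), seed = 8)
    pl <- plantInsertions(simulateGenome(cfg), lib, cfg)
    bam <- tempfile(fileext = ".bam")
    simulateReads(pl, cfg, bamOut = bam)
    ev <- scanAlignments(bam, params = teiParameters())
    ins <- ev[mcols(ev)$kind == "insertion_op"]
    expect_gt(length(ins), 0L)
    ## every insertion op sits exactly at a truth position with the exact
    ## planted length
    hit <- match(evidencePositions(ins), pl$truth$position)
    expect_false(any(is.na(hit)))
    expect_equal(mcols(ins)$len, pl$truth$insertedLen[hit])
    ## clips anchor at truth positions too
    clips <- ev[mcols(ev)$kind != "insertion_op"]
    expect_true(all(evidencePositions(clips) %in% pl$truth$position))
})

test_that("read simulation hits the target coverage and is byte-deterministic", {
    cfg <- simConfig(genomeLen = 1e6, nInsertions = c(Alu = 2L),
                     coverage = 4,
                     errorRates = c(mismatch = 0.02, insertion = 0.01,
                                    deletion = 0.01), seed = 17)
    pl <- plantInsertions(simulateGenome(cfg), lib, cfg)
    fq1 <- tempfile(fileext = ".fastq")
    r1 <- simulateReads(pl, cfg, fastqOut = fq1)
    expect_lt(abs(r1$totalBases - cfg@coverage * cfg@genomeLen) /
              (cfg@coverage * cfg@genomeLen), 0.05)
    fq2 <- tempfile(fileext = ".fastq")
    simulateReads(pl, cfg, fastqOut = fq2)
    expect_identical(readLines(fq1), readLines(fq2))
})

test_that("evaluateCalls implements windowed one-to-one greedy matching", {
    truth <- data.frame(contig = "c", position = c(1000L, 9000L),
                        family = c("Alu", "L1"), insertedLen = 300L,
                        zygosity = "hom", strand = "+", hap = NA_integer_)
    ## calls identical to truth
    calls <- data.frame(contig = "c", position = c(1000L, 9000L),
                        family = c("Alu", "L1"))
    m <- evaluateCalls(calls, truth, window = 50L)
    expect_equal(m$sensitivity, c(1, 1))
    expect_equal(m$precision, c(1, 1))

    ## empty calls: sensitivity 0, precision undefined
    m0 <- evaluateCalls(calls[0, ], truth, window = 50L)
    expect_equal(m0$sensitivity, c(0, 0))
    expect_true(all(is.na(m0$precision)))

    ## one truth, two calls in the window: one TP one FP
    m1 <- evaluateCalls(
        data.frame(contig = "c", position = c(990L, 1010L),
                   family = "Alu"),
        truth[1, ], window = 50L)
    expect_equal(m1$tp, 1L)
    expect_equal(m1$fp, 1L)
    expect_equal(m1$precision, 0.5)

    ## family mismatch within the window is not a TP
    m2 <- evaluateCalls(
        data.frame(contig = "c", position = 1000L, family = "L1"),
        truth[1, ], window = 50L)
    expect_equal(m2[m2$family == "ALU", "tp"], 0L)

    ## outside the window is not a TP
    m3 <- evaluateCalls(
        data.frame(contig = "c", position = 1051L, family = "Alu"),
        truth[1, ], window = 50L)
    expect_equal(m3$tp, 0L)
})

test_that("evaluation is symmetric under permutation of calls and truth", {
    set.seed(55)
    truth <- data.frame(contig = "c",
                        position = sort(sample.int(1e5, 20L)) ,
                        family = sample(c("Alu", "L1"), 20L,
                                        replace = TRUE),
                        insertedLen = 300L, zygosity = "hom",
                        strand = "+", hap = NA_integer_)
    calls <- data.frame(contig = "c",
                        position = truth$position +
                            sample(-30:30, 20L, replace = TRUE),
                        family = truth$family)
    ref <- evaluateCalls(calls, truth)
    p1 <- evaluateCalls(calls[sample(20L), ], truth[sample(20L), ])
    expect_equal(ref, p1)
})

test_that("truth tables round-trip through TSV", {
    cfg <- simConfig(genomeLen = 1e5, nInsertions = c(Alu = 3L), seed = 2)
    pl <- plantInsertions(simulateGenome(cfg), lib, cfg)
    path <- tempfile(fileext = ".tsv")
    writeTruth(pl$truth, path)
    expect_equal(readTruth(path), pl$truth)
})
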