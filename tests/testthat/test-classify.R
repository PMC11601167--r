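lib <- testTELibrary()

test_that("candidate sequences are collected verbatim, ordered by read id", {
    ev <- makeEvidence(c(100L, 100L, 101L), readIds = c("b", "a", "c"))
    cand <- collectCandidateSequences(ev)
    expect_equal(length(cand), 3L)
    expect_equal(names(cand), c("a", "b", "c"))
    expect_equal(as.character(cand[["b"]]),
                 mcols(ev)$sequence[mcols(ev)$readId == "b"])
})

test_that("duplicate read ids in one cluster are suffix-disambiguated", {
    ev <- makeEvidence(c(100L, 102L, 101L), readIds = c("a", "a", "b"))
    cand <- collectCandidateSequences(ev)
    expect_equal(names(cand), c("a", "a#2", "b"))
})

test_that("built-in aligner finds exact and reverse-complement library copies", {
    cand <- DNAStringSet(c(fwd = as.character(lib[["Alu"]]),
                           rev = as.character(reverseComplement(
                               lib[["Alu"]]))))
    m <- alignToTELibrary(cand, lib, aligner = "builtin")
    expect_equal(nrow(m), 2L)
    m <- m[order(m$readId), ]
    expect_equal(m$teName, c("Alu", "Alu"))
    expect_equal(m$strand, c("+", "-"))
    expect_gte(min(m$alignedLen), 295L)
})

test_that("random sequence finds no TE match", {
    set.seed(202)
    cand <- DNAStringSet(c(junk = randomSeq(300L)))
    m <- alignToTELibrary(cand, lib, aligner = "builtin")
    expect_equal(nrow(m), 0L)
})

test_that("minimap2 and the built-in aligner agree on clean copies", {
    skip_if(!nzchar(Sys.which("minimap2")), "minimap2 not on PATH")
    cand <- DNAStringSet(c(x = as.character(lib[["L1"]]),
                           y = as.character(reverseComplement(
                               lib[["SVA"]]))))
    mm <- alignToTELibrary(cand, lib, aligner = "minimap2")
    bi <- alignToTELibrary(cand, lib, aligner = "builtin")
    mm <- mm[order(mm$readId), ]; bi <- bi[order(bi$readId), ]
    expect_equal(mm$teName, bi$teName)
    expect_equal(mm$strand, bi$strand)
})

test_that("empty or missing TE library is fatal", {
    expect_error(alignToTELibrary(DNAStringSet(c(a = "ACGT")),
                                  DNAStringSet()), "empty")
    expect_error(alignToTELibrary(DNAStringSet(c(a = "ACGT")),
                                  tempfile(fileext = ".fa")), "not found")
})

mkMatches <- function(readId, teName, alignedLen, queryLen) {
    data.frame(readId = readId, teName = teName,
               alignedLen = as.integer(alignedLen),
               strand = "+", queryLen = as.integer(queryLen),
               score = as.numeric(alignedLen), stringsAsFactors = FALSE)
}

test_that("support and match-length filters follow the default semantics", {
    p <- teiParameters()  # minSupportingReads 3, matchFraction 0.10
    cl <- makeEvidence(rep(100L, 4L), readIds = paste0("r", 1:4))

    ## four valid Alu matches pass with support 4
    m <- mkMatches(paste0("r", 1:4), "Alu", 200, 300)
    res <- filterAndAssign(cl, m, p)
    expect_equal(res$family, "Alu")
    expect_equal(res$supporting, paste0("r", 1:4))

    ## a 25/300 match fails the 10% rule (25 < 30)
    m2 <- mkMatches(paste0("r", 1:4), "Alu", c(200, 200, 25, 25), 300)
    res2 <- filterAndAssign(cl, m2, p)
    expect_null(res2)

    ## exactly at the boundary (30/300) the match is valid
    m3 <- mkMatches(paste0("r", 1:3), "Alu", 30, 300)
    expect_equal(filterAndAssign(cl[1:3], m3, p)$family, "Alu")

    ## 2 Alu + 2 L1: no family reaches 3
    m4 <- mkMatches(paste0("r", 1:4), c("Alu", "Alu", "L1", "L1"),
                    200, 300)
    expect_null(filterAndAssign(cl, m4, p))
})

test_that("family vote uses the name-to-family map", {
    p <- teiParameters()
    cl <- makeEvidence(rep(100L, 3L), readIds = paste0("r", 1:3))
    m <- mkMatches(paste0("r", 1:3), c("AluYa5", "AluYb8", "AluY"),
                   200, 300)
    expect_null(filterAndAssign(cl, m, p))  # three singleton families
    fmap <- c(AluYa5 = "Alu", AluYb8 = "Alu", AluY = "Alu")
    expect_equal(filterAndAssign(cl, m, p, familyMap = fmap)$family, "Alu")
})

test_that("filtering is monotone and order-invariant", {
    set.seed(77)
    cl <- makeEvidence(rep(500L, 8L), readIds = paste0("r", 1:8))
    m <- mkMatches(paste0("r", 1:8),
                   sample(c("Alu", "L1"), 8L, replace = TRUE),
                   sample(20:300, 8L), 300)
    pass <- function(sr, mf) !is.null(filterAndAssign(
        cl, m, teiParameters(minSupportingReads = sr, matchFraction = mf)))
    for (sr in 1:5)
        expect_gte(pass(sr, 0.1), pass(sr + 1L, 0.1))
    for (mf in c(0.05, 0.2, 0.5))
        expect_gte(pass(1L, mf), pass(1L, min(mf * 2, 1)))
    ## limit behaviour: any aligned candidate passes at the loosest setting
    expect_true(pass(1L, 1e-9))
    ## order invariance
    res1 <- filterAndAssign(cl, m, teiParameters())
    res2 <- filterAndAssign(cl, m[sample(nrow(m)), ], teiParameters())
    expect_equal(res1, res2)
})

test_that("classification is invariant to batching across clusters", {
    set.seed(300)
    candA <- DNAStringSet(c(a1 = as.character(subseq(lib[["Alu"]], 1, 250)),
                            a2 = as.character(lib[["Alu"]])))
    candB <- DNAStringSet(c(b1 = as.character(subseq(lib[["L1"]], 100,
                                                     2000))))
    sep <- rbind(alignToTELibrary(candA, lib, aligner = "builtin"),
                 alignToTELibrary(candB, lib, aligner = "builtin"))
    joint <- alignToTELibrary(c(candA, candB), lib, aligner = "builtin")
    o1 <- sep[order(sep$readId), ]; rownames(o1) <- NULL
    o2 <- joint[order(joint$readId), ]; rownames(o2) <- NULL
    expect_equal(o1, o2)
})
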