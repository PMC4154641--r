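test_that("annotations are read from GFF3 and GTF equivalently", {
    gff <- writeToyGFF3(tempfile(fileext = ".gff3"))
    gtf <- writeToyGTF(tempfile(fileext = ".gtf"))
    a <- readAnnotations(gff)
    b <- readAnnotations(gtf)
    expect_equal(length(a), 3L)
    expect_equal(names(a), c("gA", "gB", "gC"))
    expect_equal(names(b), names(a))
    expect_equal(GenomicRanges::start(b), GenomicRanges::start(a))
    expect_equal(GenomicRanges::end(b), GenomicRanges::end(a))
    expect_equal(as.character(GenomicRanges::strand(b)),
                 as.character(GenomicRanges::strand(a)))
    ## TSS: start on "+", end on "-"
    expect_equal(tssOf(a), c(1999, 2400, 20000))
    ## malformed coordinates are rejected
    bad <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\ttoy\tgene\t500\t100\t.\t+\t.\tID=bad"), bad)
    expect_error(readAnnotations(bad), "malformed")
    ## duplicate ids are rejected
    dup <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\ttoy\tgene\t100\t200\t.\t+\t.\tID=g1",
                 "chr1\ttoy\tgene\t500\t800\t.\t+\t.\tID=g1"), dup)
    expect_error(readAnnotations(dup), "duplicate")
})

test_that("orientation classification follows the strand pattern", {
    g <- function(s, e, st) GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, e), strand = st)
    expect_equal(classifyOrientation(g(1, 100, "-"), g(300, 400, "+")),
                 "divergent")
    expect_equal(classifyOrientation(g(1, 100, "+"), g(300, 400, "-")),
                 "convergent")
    expect_equal(classifyOrientation(g(1, 100, "+"), g(300, 400, "+")),
                 "tandem")
    expect_equal(classifyOrientation(g(1, 100, "-"), g(300, 400, "-")),
                 "tandem")
    expect_error(classifyOrientation(g(1, 350, "+"), g(300, 400, "+")),
                 "overlap")
    expect_error(classifyOrientation(g(300, 400, "+"), g(1, 100, "+")),
                 "left")
})

test_that("pair separations use gap or TSS distance as requested", {
    ## adjacent units: no intervening base
    a <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 1000),
                                strand = "+")
    b0 <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 2000),
                                 strand = "+")
    expect_equal(pairSeparation(a, b0), 0)
    ## the worked gap example: units [1,1000] and [1401,2400]
    b <- GenomicRanges::GRanges("c", IRanges::IRanges(1401, 2400),
                                strand = "+")
    expect_equal(pairSeparation(a, b), 400)
    ## divergent pair with both TSSs at the inner edges: TSS distance
    ## equals the gap plus one edge step under inclusive coordinates
    ad <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 1000),
                                 strand = "-")
    expect_equal(pairSeparation(ad, b, mode = "tss"), 401)
    expect_equal(pairSeparation(ad, b, mode = "gap"), 400)
})

test_that("isolated-pair selection applies both criteria strictly", {
    mk <- function(starts, ends, strands, ids) {
        gr <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(starts, ends),
                                     strand = strands)
        names(gr) <- ids
        gr
    }
    ## two divergent genes 400 bp apart, nearest other gene 10 kb away
    g1 <- mk(c(1000, 3400, 15000), c(1999, 4399, 15999),
             c("-", "+", "+"), c("a", "b", "far"))
    p1 <- selectIsolatedPairs(g1)
    expect_equal(nrow(p1), 1L)
    expect_equal(p1$geneA, "a"); expect_equal(p1$geneB, "b")
    expect_equal(p1$orientation, "divergent")
    expect_equal(p1$separation, 1400)
    ## the same pair with a third gene ~2 kb from one TSS is excluded
    g2 <- mk(c(1000, 3400, 5500), c(1999, 4399, 6499),
             c("-", "+", "+"), c("a", "b", "near"))
    expect_equal(nrow(selectIsolatedPairs(g2)), 0L)
    ## a perturber exactly at the isolation radius still excludes
    ## ("more than" is strict); one base farther admits the pair
    tssB <- 3400
    gEdge <- mk(c(1000, 3400, tssB + 3001), c(1999, 4399, tssB + 4000),
                c("-", "+", "+"), c("a", "b", "edge"))
    expect_equal(nrow(selectIsolatedPairs(gEdge)), 0L)
    gEdge2 <- mk(c(1000, 3400, tssB + 3002),
                 c(1999, 4399, tssB + 4001),
                 c("-", "+", "+"), c("a", "b", "edge"))
    expect_equal(nrow(selectIsolatedPairs(gEdge2)), 1L)
    ## genes farther than the inclusion radius are not paired
    gFar <- mk(c(1000, 8000), c(1999, 8999), c("-", "+"), c("a", "b"))
    expect_equal(nrow(selectIsolatedPairs(gFar)), 0L)
    ## overlapping genes are dropped from pairing but still perturb
    gOv <- mk(c(1000, 3400, 3600), c(1999, 4399, 4599),
              c("-", "+", "-"), c("a", "b", "nested"))
    expect_message(pOv <- selectIsolatedPairs(gOv), "overlapping")
    expect_equal(nrow(pOv), 0L)
    expect_equal(attr(pOv, "droppedOverlapping"), 2L)
})

test_that("planted synthetic genomes are recovered exactly", {
    spec <- syntheticGenomeSpec(nPairs = c(20L, 15L, 15L),
                                nSpoiled = c(8L, 6L, 6L),
                                nBackground = 7L, seed = 3L)
    g <- makeGenome(spec)
    expect_equal(nrow(g$truth), 50L)
    expect_equal(sum(g$truth$expectIsolated), 30L)
    pairs <- suppressMessages(selectIsolatedPairs(g$genes))
    key <- function(df) paste(df$geneA, df$geneB)
    truthAcc <- g$truth[g$truth$expectIsolated, ]
    expect_setequal(key(pairs), key(truthAcc))
    m <- merge(pairs, g$truth, by = c("geneA", "geneB"))
    expect_equal(m$orientation.x, m$orientation.y)
    expect_equal(m$separation.x, m$separation.y)
})

test_that("correlation criterion requires co-expression and r", {
    set.seed(5)
    nE <- 24
    mkExpr <- function(...) {
        rows <- list(...)
        m <- do.call(rbind, rows)
        rownames(m) <- paste0("g", seq_len(nrow(m)))
        m
    }
    base <- c(rep(0, 14), rlnorm(10, 2, 1))
    ## identical nonzero profiles in 10 of 24 experiments: correlated
    expect_true(torsionCouple:::.pairCorrelated(base, 2 * base, 6, 0.5))
    ## joint expression below the threshold fails
    sparse <- c(rep(0, 20), rlnorm(4, 2, 1))
    expect_false(torsionCouple:::.pairCorrelated(sparse, 2 * sparse,
                                                 6, 0.5))
    ## anti- or un-correlated profiles fail despite co-expression
    x <- rlnorm(nE, 2, 1)
    expect_false(torsionCouple:::.pairCorrelated(x, max(x) + 1 - x,
                                                 6, 0.5))
    ## zero-variance profiles can never be correlated
    expect_false(torsionCouple:::.pairCorrelated(rep(1, nE), rep(1, nE),
                                                 6, 0.5))
})

test_that("binned statistics satisfy the count-mean identity", {
    spec <- syntheticGenomeSpec(nPairs = c(12L, 10L, 6L), seed = 21L)
    g <- makeGenome(spec)
    em <- makeExpression(g$genes, g$truth,
                         syntheticExpressionSpec(seed = 22L))
    pairs <- suppressMessages(selectIsolatedPairs(g$genes))
    st <- binnedStatistics(pairs, em$expr, window = 200)
    both <- st[st$member == "both", ]
    expect_gt(nrow(both), 0)
    ## total = 2 x count x mean, exactly
    expect_equal(both$totalExpression,
                 2 * both$nPairs * both$meanExpression)
    ## member rows only for tandem, with total = count x mean
    expect_setequal(unique(st$member[st$orientation == "tandem"]),
                    c("both", "upstream", "downstream"))
    mem <- st[st$member %in% c("upstream", "downstream"), ]
    expect_equal(mem$totalExpression, mem$nPairs * mem$meanExpression)
    ## pair counts decompose by window within each orientation
    for (or in unique(pairs$orientation))
        expect_equal(sum(both$nPairs[both$orientation == or]),
                     sum(pairs$orientation == or))
    ## an all-zero matrix yields zero expressed fraction and no
    ## correlated pairs
    zero <- em$expr * 0
    stz <- binnedStatistics(pairs, zero, window = 200)
    expect_true(all(stz$expressedFraction == 0))
    expect_true(all(stz$nCorrelated == 0))
    ## missing genes are reported and dropped
    expect_warning(
        pairCorrelation(pairs, em$expr[-1, , drop = FALSE]),
        "absent")
})

test_that("planted correlated pairs concentrate below 1 kb", {
    spec <- syntheticGenomeSpec(nPairs = c(25L, 15L, 8L), seed = 31L)
    g <- makeGenome(spec)
    em <- makeExpression(g$genes, g$truth, syntheticExpressionSpec(
        correlatedFraction = 0.5, correlatedMaxSeparation = 1000,
        seed = 32L))
    pairs <- suppressMessages(selectIsolatedPairs(g$genes))
    pc <- pairCorrelation(pairs, em$expr)
    m <- merge(pc, em$truth, by = c("geneA", "geneB"))
    ## all planted pairs are flagged, nothing else is
    expect_true(all(m$correlated.x[m$correlated.y]))
    expect_false(any(m$correlated.x[!m$correlated.y]))
    ## the flagged pairs sit below 1 kb by construction
    expect_true(all(pc$separation[pc$correlated] < 1000))
})

test_that("orientation ranking is stable under threshold changes", {
    ## correlated pairs are planted only below 1 kb, and only divergent
    ## pairs are placed that close: the divergent class must stay on
    ## top for every threshold combination
    spec <- syntheticGenomeSpec(nPairs = c(25L, 18L, 10L),
                                separationRange = list(
                                    divergent = c(100, 900),
                                    tandem = c(1200, 1900),
                                    convergent = c(1100, 2900)),
                                seed = 41L)
    g <- makeGenome(spec)
    em <- makeExpression(g$genes, g$truth, syntheticExpressionSpec(
        correlatedFraction = 0.6, correlationStrength = 0.7,
        seed = 42L))
    pairs <- suppressMessages(selectIsolatedPairs(g$genes))
    nAccepted <- integer(0)
    for (minCo in c(5, 6, 7)) for (rThr in c(0.4, 0.5, 0.6)) {
        pc <- pairCorrelation(pairs, em$expr, minCo, rThr)
        frac <- tapply(pc$correlated, pc$orientation, mean)
        nAccepted <- c(nAccepted, sum(pc$correlated))
        ## absolute numbers move with the thresholds, but divergent
        ## pairs remain the most-correlated class throughout
        expect_true(frac[["divergent"]] >= frac[["tandem"]])
        expect_true(frac[["divergent"]] >= frac[["convergent"]])
    }
    ## the thresholds do change the absolute accepted counts
    expect_gt(length(unique(nAccepted)), 1L)
})

test_that("the isolation filter removes more convergent pairs", {
    cand <- c(divergent = 0, convergent = 0, tandem = 0)
    kept <- cand
    for (s in 1:100) {
        g <- makeRandomGenome(120, 1.2e6, 1000, seed = s)
        pAll <- suppressMessages(
            selectIsolatedPairs(g, inclusionRadius = 5000,
                                isolationRadius = 0))
        pIso <- suppressMessages(selectIsolatedPairs(g))
        for (or in names(cand)) {
            cand[or] <- cand[or] + sum(pAll$orientation == or)
            kept[or] <- kept[or] + sum(pIso$orientation == or)
        }
    }
    rate <- kept / cand
    ## convergent pairs (outward-facing promoters) survive the filter
    ## least often
    expect_lt(rate[["convergent"]], rate[["divergent"]])
    expect_lt(rate[["convergent"]], rate[["tandem"]])
})

test_that("identical inputs give byte-identical scan outputs", {
    spec <- syntheticGenomeSpec(nPairs = c(8L, 6L, 4L), seed = 51L)
    g1 <- makeGenome(spec); g2 <- makeGenome(spec)
    expect_identical(g1, g2)
    f1 <- tempfile(); f2 <- tempfile()
    writeGenomeGFF3(g1$genes, f1); writeGenomeGFF3(g2$genes, f2)
    expect_identical(readLines(f1), readLines(f2))
    p1 <- suppressMessages(selectIsolatedPairs(g1$genes))
    p2 <- suppressMessages(selectIsolatedPairs(g2$genes))
    expect_identical(p1, p2)
})
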