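test_that("pair geometries are laid out as specified", {
    ## divergent: promoters face each other across the gap
    sysd <- buildPair("divergent", d = 500)
    ud <- sysd@units
    expect_equal(as.character(GenomicRanges::strand(ud)), c("-", "+"))
    expect_equal(abs(diff(tssOf(ud))), 500)
    expect_equal(GenomicRanges::start(ud)[2] - GenomicRanges::end(ud)[1],
                 500)
    ## convergent at d = l1 + l2 + 500: 3' ends separated by a short gap
    ## (d - l1 - l2 + 1 intervening bases under inclusive coordinates)
    sysc <- buildPair("convergent", d = 2500)
    uc <- sysc@units
    expect_equal(as.character(GenomicRanges::strand(uc)), c("+", "-"))
    expect_equal(abs(diff(tssOf(uc))), 2500)
    expect_equal(GenomicRanges::distance(uc[1], uc[2],
                                         ignore.strand = TRUE), 501L)
    ## tandem: downstream TSS lies past the upstream 3' end
    syst <- buildPair("tandem", d = 1500)
    ut <- syst@units
    expect_equal(as.character(GenomicRanges::strand(ut)), c("+", "+"))
    expect_equal(tssOf(ut)[2] - GenomicRanges::end(ut)[1] - 1, 500)
    ## overlapping geometries are rejected
    expect_error(buildPair("convergent", d = 1500), "overlap")
    expect_error(buildPair("tandem", d = 800), "overlap")
    ## gap mode places the stated number of bases between the units
    sysg <- buildPair("divergent", d = 300, distanceMode = "gap")
    expect_equal(GenomicRanges::distance(sysg@units[1], sysg@units[2],
                                         ignore.strand = TRUE), 300L)
})

test_that("decoupled and symmetric systems solve trivially", {
    ## no torsional output: fold-changes 1 in a single iteration
    sys0 <- buildPair("divergent", 500,
                      torsion = torsionParameters(alpha = 0))
    res0 <- solveCoupling(sys0)
    expect_equal(unname(foldChanges(res0)), c(1, 1))
    expect_equal(res0@iterations, 1L)
    expect_true(converged(res0))
    ## identical genes in symmetric orientations: exactly equal outputs
    for (or in c("divergent", "convergent")) {
        d <- if (or == "convergent") 2600 else 700
        res <- solveCoupling(buildPair(
            or, d, torsion = torsionParameters(sigma0 = -0.05)))
        expect_true(converged(res))
        expect_identical(rates(res)[[1]], rates(res)[[2]])
        expect_identical(promoterSigma(res)[[1]],
                         promoterSigma(res)[[2]])
    }
})

test_that("solver fixed points match the brute-force oracle", {
    set.seed(7)
    for (rep in 1:20) {
        sys <- randomPairSystem()
        res <- solveCoupling(sys)
        expect_true(converged(res))
        roots <- oraclePairRoots(sys)
        expect_gt(length(roots), 0)
        expect_lt(min(abs(rates(res)[1] - roots)), 1e-5)
        ## the residual of the fixed-point equation itself vanishes
        G <- torsionCouple:::.couplingMatrix(sys)
        s0 <- sys@torsion@sigma0
        k <- unname(rates(res))
        kmap <- c(transcriptionRate(s0 + G[1, 2] * k[2],
                                    sys@promoters[[1]]),
                  transcriptionRate(s0 + G[2, 1] * k[1],
                                    sys@promoters[[2]]))
        expect_equal(k, kmap, tolerance = 1e-6)
    }
})

test_that("one-way influence curves have the expected structure", {
    tp <- torsionParameters()
    u <- transcriptionUnits("g", 10001, 11000, "+", rate = 1)
    pm <- promoterModel()
    up <- seq(6001, 9800, by = 200)     # upstream of the TSS
    down <- seq(11201, 15001, by = 200) # downstream of the 3' end
    icUp <- influenceCurve(u, pm, up, 0, tp)
    icDown <- influenceCurve(u, pm, down, 0, tp)
    ## negative lobe upstream activates, positive lobe downstream
    ## represses (monotone opening model)
    expect_true(all(icUp$foldChange >= 1))
    expect_true(all(icDown$foldChange <= 1))
    ## influence fades far beyond the decay length
    far <- influenceCurve(u, pm, 11000 + 1 + 15 * tp@b, 0, tp)
    expect_equal(far$foldChange, 1, tolerance = 1e-6)
    ## |log fold-change| decays monotonically with distance
    expect_true(all(diff(abs(log(icDown$foldChange))) < 0))
    expect_true(all(diff(abs(log(rev(icUp$foldChange)))) < 0))
    ## composition consistency with the field and fold-change operations
    expect_equal(icDown$foldChange,
                 foldChange(fieldAt(u, down, tp), 0, pm))
    ## positions inside the unit are refused
    expect_error(influenceCurve(u, pm, 10500, 0, tp), "inside")
})

test_that("residual coupling at 3 kb drops to exp(-3) of the amplitude", {
    tp <- torsionParameters(b = 1000)
    u <- transcriptionUnits("g", 1, 1000, "+", rate = 1)
    expect_equal(abs(perturbationAt(u, 1000 + 1 + 3000, tp)),
                 0.03 * exp(-3))
    expect_lt(abs(perturbationAt(u, 1000 + 1 + 3000, tp)), 0.0015)
})

test_that("a two-gene chain through the N-gene solver equals the pair", {
    tor <- torsionParameters(sigma0 = -0.04)
    sysPair <- buildPair("divergent", 800, torsion = tor)
    ## same geometry assembled by hand as a generic gene system
    sysN <- new("GeneSystem", units = sysPair@units,
                promoters = sysPair@promoters, torsion = tor)
    resPair <- solveCoupling(sysPair)
    resN <- solveCoupling(sysN)
    expect_identical(rates(resPair), rates(resN))
    ## swapping gene labels permutes the outputs exactly
    sysSwap <- new("GeneSystem", units = rev(sysPair@units),
                   promoters = sysPair@promoters[2:1], torsion = tor)
    resSwap <- solveCoupling(sysSwap)
    expect_equal(unname(rates(resSwap)), unname(rates(resPair))[2:1])
})

test_that("phase diagrams reproduce the orientation-dependent structure", {
    s0G <- c(-0.08, -0.06, -0.03, 0)
    dDiv <- c(300, 900, 1800, 3500)
    pdDiv <- phaseDiagram("divergent", dDiv, s0G)
    expect_true(all(pdDiv$converged))
    ## divergent pairs mutually activate; the effect decays with
    ## distance and is essentially gone beyond ~3 kb
    expect_true(all(pdDiv$foldChange >= 1 - 1e-9))
    ## non-increasing in distance up to the solver's relative tolerance
    ## (rows saturated at the opening plateau are flat to ~1e-8)
    for (r in seq_along(s0G)) {
        fc <- pdDiv$foldChange[r, ]
        expect_true(all(diff(fc) <= 1e-6 * fc[-length(fc)]))
    }
    expect_lt(max(pdDiv$foldChange[, 4]), 1.25)
    ## convergent pairs mutually repress, most strongly at
    ## prokaryote-like basal levels
    pdConv <- phaseDiagram("convergent", c(2300, 2900, 4000), s0G)
    expect_true(all(pdConv$foldChange <= 1 + 1e-9))
    expect_lt(pdConv$foldChange[2, 1], pdConv$foldChange[4, 1])
    ## tandem: upstream gene gains, downstream gene loses
    pdTan <- phaseDiagram("tandem", c(1300, 1900, 2600),
                          c(-0.05, -0.04, -0.03))
    expect_true(all(pdTan$foldChangeUpstream >= 1 - 1e-9))
    expect_true(all(pdTan$foldChangeDownstream <= 1 + 1e-9))
    ## the sweep matches per-cell solves exactly
    sys <- buildPair("divergent", dDiv[2],
                     torsion = torsionParameters(sigma0 = s0G[2]))
    expect_equal(pdDiv$foldChange[2, 2],
                 unname(foldChanges(solveCoupling(sys))[1]))
    expect_error(phaseDiagram("divergent", numeric(0), s0G), "empty")
})
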