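## Independent oracles and small fixture builders shared across tests.

## Exhaustive single-run SIDD oracle: explicit per-state loops, per-base
## pairing sums, and numeric minimization of the torsional energy over
## the open-region twist (optimize), independent of the vectorized
## analytic engine.
oracleSiddDG <- function(seqchar, site, sigma, p) {
    chars <- strsplit(seqchar, "")[[1]]
    L <- length(chars)
    N <- if (is.na(p@domainSize)) L else p@domainSize
    RT <- 1.987204e-3 * p@temperature
    K <- p@Kcoef * RT / N
    stateE <- function(s, n) {
        if (n == 0) return(0.5 * K * (sigma * N / p@h)^2)
        pe <- 0
        for (i in s:(s + n - 1))
            pe <- pe + if (chars[i] %in% c("A", "T")) p@eAT else p@eGC
        A <- sigma * N / p@h + n / p@h
        et <- optimize(function(tau)
            0.5 * p@Copen * n * tau^2 +
                0.5 * K * (A - n * tau / (2 * pi))^2,
            interval = c(-20, 20), tol = 1e-14)$objective
        p@aNuc + pe + et
    }
    Es <- c(); covers <- c()
    for (n in 0:min(p@maxBubble, L)) {
        for (s in if (n == 0) 0 else 1:(L - n + 1)) {
            Es <- c(Es, stateE(s, n))
            covers <- c(covers,
                        n > 0 && s <= site[1] && s + n - 1 >= site[2])
        }
    }
    w <- exp(-(Es - min(Es)) / RT)
    popen <- sum(w[covers]) / sum(w)
    -RT * log(popen / (1 - popen))
}

## Brute-force fixed-point oracle for a two-gene system: dense scan of
## the composed map g(k1) = F1(F2(k1)) - k1 followed by hand-rolled
## bisection, entirely independent of the damped-iteration solver.
oraclePairRoots <- function(sys, nScan = 400) {
    G <- torsionCouple:::.couplingMatrix(sys)
    proms <- sys@promoters
    s0 <- sys@torsion@sigma0
    F1 <- function(k2) transcriptionRate(s0 + G[1, 2] * k2, proms[[1]])
    F2 <- function(k1) transcriptionRate(s0 + G[2, 1] * k1, proms[[2]])
    g <- function(k1) F1(F2(k1)) - k1
    kup <- 1.05 * max(vapply(proms, function(p) p@kmax, numeric(1)))
    kg <- seq(1e-9, kup, length.out = nScan)
    gv <- vapply(kg, g, numeric(1))
    roots <- c()
    for (i in which(gv[-1] * gv[-nScan] <= 0)) {
        lo <- kg[i]; hi <- kg[i + 1]
        for (it in 1:80) {
            mid <- (lo + hi) / 2
            if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
        }
        roots <- c(roots, (lo + hi) / 2)
    }
    roots
}

## Random pair configuration in the weak-coupling (contractive) regime.
randomPairSystem <- function() {
    or <- sample(c("divergent", "convergent", "tandem"), 1)
    d <- switch(or,
                divergent = sample(300:3000, 1),
                convergent = sample(2100:4000, 1),
                tandem = sample(1100:3500, 1))
    pm <- promoterModel(
        sigmoidOpening(sigmaC = runif(1, -0.06, -0.03),
                       w = runif(1, 0.01, 0.03),
                       m = runif(1, 2, 6), v = 0,
                       q = runif(1, 0.5, 3)),
        Te = runif(1, 400, 700))
    tor <- torsionParameters(sigma0 = runif(1, -0.07, 0), alpha = 1e-5)
    buildPair(or, d, promoter = pm, torsion = tor)
}

## Three-gene toy GFF3 (one divergent pair + one distant gene).
writeToyGFF3 <- function(path) {
    writeLines(c(
        "##gff-version 3",
        "chr1\ttoy\tgene\t1000\t1999\t.\t-\t.\tID=gA",
        "chr1\ttoy\tgene\t2400\t3399\t.\t+\t.\tID=gB",
        "chr1\ttoy\tgene\t20000\t20999\t.\t+\t.\tID=gC"),
        path)
    path
}

writeToyGTF <- function(path) {
    writeLines(c(
        paste0("chr1\ttoy\tgene\t1000\t1999\t.\t-\t.\t",
               "gene_id \"gA\"; gene_name \"gA\";"),
        paste0("chr1\ttoy\tgene\t2400\t3399\t.\t+\t.\t",
               "gene_id \"gB\"; gene_name \"gB\";"),
        paste0("chr1\ttoy\tgene\t20000\t20999\t.\t+\t.\t",
               "gene_id \"gC\"; gene_name \"gC\";")),
        path)
    path
}

randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
}
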