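## Synthetic fixtures: annotated toy genomes with planted pair structure,
## expression matrices with model-driven coupling signal, and promoter
## sequences for the melting calculator.  All generators are pure
## functions of (spec, seed).

.SPOILER_DISTANCE <- 2000   # bp from the targeted TSS to the spoiler
.INTER_CASSETTE <- 7000     # minimal spacing between planted cassettes

#' Generate a synthetic annotated genome with planted pairs
#'
#' Plants neighbour-gene pairs of known orientation and separation along a
#' single chromosome, spaced widely enough that every unspoiled pair is
#' torsionally isolated by construction. Spoiled pairs carry a cluster of
#' three perturber genes whose nearest edge sits 2 kb from the pair's
#' left promoter, violating the isolation criterion; the cluster genes
#' themselves can never form isolated pairs (they spoil each other).
#' Background genes are likewise laid out in tight clusters of three (plus
#' widely spaced singles for any remainder) so that they add annotation
#' density without creating unplanned isolated pairs.
#'
#' @param spec a \linkS4class{SyntheticGenomeSpec}
#' @return a list with \code{genes} (named GRanges) and \code{truth}
#'   (data.frame: pairId, geneA, geneB, orientation, separation, spoiled,
#'   expectIsolated)
#' @examples
#' g <- makeGenome(syntheticGenomeSpec(nPairs = c(5, 3, 2), seed = 11))
#' g$truth
#' @export
makeGenome <- function(spec) {
    stopifnot(is(spec, "SyntheticGenomeSpec"))
    validObject(spec)
    l <- spec@geneLength
    if (sum(spec@nSpoiled) > 0L && l >= 2000)
        .stopf("spoiler placement requires geneLength < 2000")

    .withSeed(spec@seed, {
        plan <- do.call(rbind, lapply(names(spec@nPairs), function(or) {
            n <- spec@nPairs[[or]]
            if (n == 0L) return(NULL)
            rng <- spec@separationRange[[or]]
            data.frame(orientation = or,
                       gap = round(runif(n, rng[1], rng[2])),
                       spoiled = seq_len(n) <= spec@nSpoiled[[or]],
                       stringsAsFactors = FALSE)
        }))
        if (!is.null(plan) && nrow(plan) > 1L)
            plan <- plan[sample.int(nrow(plan)), , drop = FALSE]

        ids <- character(); starts <- integer(); ends <- integer()
        strands <- character()
        truth <- list()
        cursor <- 10000
        addGene <- function(id, s, e, st) {
            ids <<- c(ids, id); starts <<- c(starts, as.integer(s))
            ends <<- c(ends, as.integer(e)); strands <<- c(strands, st)
        }
        for (k in seq_len(NROW(plan))) {
            or <- plan$orientation[k]; g <- plan$gap[k]
            pid <- sprintf("pair%03d", k)
            aStart <- cursor
            if (plan$spoiled[k]) {
                ## spoiler cluster ends .SPOILER_DISTANCE+1 bases left of
                ## the pair's left TSS (= aStart for "+" left genes,
                ## aStart + l - 1 for divergent "-" left genes)
                tssA <- if (or == "divergent") cursor + l - 1 else cursor
                spEnd <- tssA - .SPOILER_DISTANCE - 1
                for (m in 3:1) {
                    e <- spEnd - (3 - m) * 600
                    addGene(sprintf("%s_sp%d", pid, m), e - 499, e,
                            sample(c("+", "-"), 1))
                }
            }
            st <- switch(or, divergent = c("-", "+"),
                         convergent = c("+", "-"), tandem = c("+", "+"))
            aEnd <- aStart + l - 1
            bStart <- aEnd + g + 1; bEnd <- bStart + l - 1
            addGene(paste0(pid, "_A"), aStart, aEnd, st[1])
            addGene(paste0(pid, "_B"), bStart, bEnd, st[2])
            truth[[k]] <- data.frame(
                pairId = pid, geneA = paste0(pid, "_A"),
                geneB = paste0(pid, "_B"), orientation = or,
                separation = g, spoiled = plan$spoiled[k],
                expectIsolated = !plan$spoiled[k],
                stringsAsFactors = FALSE)
            cursor <- bEnd + .INTER_CASSETTE +
                round(runif(1, 0, 2000)) +
                if (plan$spoiled[k]) 0 else 0
        }
        ## background genes: clusters of three (never isolated pairs),
        ## singles (never close to anything) for the remainder
        nb <- spec@nBackground
        bi <- 0L
        while (nb >= 3L) {
            for (m in 1:3) {
                bi <- bi + 1L
                addGene(sprintf("bg%03d", bi), cursor, cursor + 799,
                        sample(c("+", "-"), 1))
                cursor <- cursor + 800 + 200
            }
            cursor <- cursor + .INTER_CASSETTE
            nb <- nb - 3L
        }
        while (nb > 0L) {
            bi <- bi + 1L
            addGene(sprintf("bg%03d", bi), cursor, cursor + 799,
                    sample(c("+", "-"), 1))
            cursor <- cursor + 800 + .INTER_CASSETTE
            nb <- nb - 1L
        }
        chromLength <- if (is.na(spec@chromLength)) cursor + 10000
                       else spec@chromLength
        if (length(ends) && max(ends) > chromLength)
            .stopf("infeasible packing: content extends to %d bp but chromLength is %g",
                   max(ends), chromLength)
        genes <- GenomicRanges::GRanges(
            "chrS", IRanges::IRanges(starts, ends), strand = strands,
            seqlengths = c(chrS = chromLength))
        names(genes) <- ids
        truth <- if (length(truth)) do.call(rbind, truth)
                 else data.frame(pairId = character(),
                                 geneA = character(),
                                 geneB = character(),
                                 orientation = character(),
                                 separation = numeric(),
                                 spoiled = logical(),
                                 expectIsolated = logical())
        list(genes = genes, truth = truth)
    })
}

#' Generate a uniformly random gene annotation
#'
#' Genes of fixed length dropped uniformly (without overlap rejection
#' beyond resampling) on one chromosome with random strands; used to study
#' the selection behaviour of the isolation filter on unstructured
#' genomes.
#'
#' @param nGenes number of genes
#' @param chromLength chromosome length (bp)
#' @param geneLength gene length (bp)
#' @param seed RNG seed
#' @return a named GRanges
#' @export
makeRandomGenome <- function(nGenes, chromLength = 2e6,
                             geneLength = 1000, seed = 1L) {
    .withSeed(seed, {
        starts <- sort(round(runif(nGenes, 1,
                                   chromLength - geneLength)))
        GenomicRanges::GRanges(
            "chrR",
            IRanges::IRanges(starts, starts + geneLength - 1),
            strand = sample(c("+", "-"), nGenes, replace = TRUE),
            seqlengths = c(chrR = chromLength)) -> gr
        names(gr) <- sprintf("rg%04d", seq_len(nGenes))
        gr
    })
}

#' Generate a synthetic expression matrix with model-driven coupling
#'
#' Per experiment, each gene draws a log-normal basal level (gene baseline
#' plus experiment noise) and suffers Bernoulli dropout. Member genes of
#' accepted (isolated) planted pairs are then multiplied by the
#' fold-changes of the self-consistent coupling model for their
#' orientation and separation, raised to \code{couplingAmplitude}.
#' A designated fraction of accepted pairs below
#' \code{correlatedMaxSeparation} additionally shares a per-experiment
#' latent factor (and a common dropout mask); at correlation strength 1
#' the two profiles are exactly proportional.
#'
#' @param genes named GRanges from \code{\link{makeGenome}}
#' @param truth truth table from \code{\link{makeGenome}}
#' @param espec a \linkS4class{SyntheticExpressionSpec}
#' @param promoter a \linkS4class{PromoterModel} for the coupling model
#' @param torsion a \linkS4class{TorsionParameters} for the coupling model
#' @return a list with \code{expr} (genes x experiments matrix) and
#'   \code{truth} (the truth table with a \code{correlated} column added)
#' @export
makeExpression <- function(genes, truth,
                           espec = syntheticExpressionSpec(),
                           promoter = promoterModel(),
                           torsion = torsionParameters()) {
    stopifnot(is(espec, "SyntheticExpressionSpec"))
    validObject(espec)
    nE <- espec@nExperiments
    nG <- length(genes)
    .withSeed(espec@seed, {
        mu <- rnorm(nG, espec@meanlog, espec@sdlog)
        eps <- matrix(rnorm(nG * nE, 0, espec@sdlog / 2), nG, nE)
        keep <- matrix(rbinom(nG * nE, 1, 1 - espec@dropout), nG, nE)
        logv <- mu + eps
        rownames(logv) <- rownames(keep) <- names(genes)

        ## designated correlated pairs share a latent factor and mask
        truth$correlated <- FALSE
        eligible <- which(truth$expectIsolated &
                          truth$separation < espec@correlatedMaxSeparation)
        nCor <- round(espec@correlatedFraction * length(eligible))
        chosen <- if (nCor > 0)
            sample(eligible, nCor) else integer(0)
        truth$correlated[chosen] <- TRUE
        s <- espec@correlationStrength
        for (k in chosen) {
            z <- rnorm(nE, 0, espec@sdlog)
            mask <- rbinom(nE, 1, 1 - espec@dropout)
            for (gene in c(truth$geneA[k], truth$geneB[k])) {
                logv[gene, ] <- mu[match(gene, names(genes))] +
                    s * z + sqrt(1 - s^2) * eps[match(gene, names(genes)), ]
                keep[gene, ] <- mask
            }
        }
        expr <- exp(logv) * keep

        ## apply the torsional coupling of accepted pairs
        amp <- espec@couplingAmplitude
        if (amp != 0) {
            for (k in which(truth$expectIsolated)) {
                sys <- buildPair(truth$orientation[k],
                                 d = truth$separation[k],
                                 promoter = promoter, torsion = torsion,
                                 distanceMode = "gap")
                fc <- foldChanges(solveCoupling(sys))
                expr[truth$geneA[k], ] <- expr[truth$geneA[k], ] *
                    fc[1]^amp
                expr[truth$geneB[k], ] <- expr[truth$geneB[k], ] *
                    fc[2]^amp
            }
        }
        colnames(expr) <- sprintf("exp%02d", seq_len(nE))
        list(expr = expr, truth = truth)
    })
}

#' Generate random promoter-like sequences with an AT-rich core
#'
#' Uniform-background sequences (A/T fraction 0.5) carrying a central
#' window of the stated A/T composition, emulating the thermodynamically
#' unstable cores of natural promoters.
#'
#' @param n number of sequences
#' @param length sequence length (>= 60 bp)
#' @param atFraction A+T fraction of the core window
#' @param seed RNG seed
#' @param coreLength core window length (default length/5, at least 20)
#' @return a \link[Biostrings]{DNAStringSet}; the core window (1-based,
#'   inclusive) is attached as attribute \code{"core"}
#' @examples
#' makePromoters(2, 100, atFraction = 1, seed = 3)
#' @export
makePromoters <- function(n, length, atFraction, seed = 1L,
                          coreLength = max(20, round(length / 5))) {
    if (length < 60) .stopf("promoter length must be >= 60 bp")
    if (coreLength > length) .stopf("core longer than sequence")
    coreStart <- floor((length - coreLength) / 2) + 1L
    core <- c(coreStart, coreStart + coreLength - 1L)
    pBack <- c(A = 0.25, T = 0.25, G = 0.25, C = 0.25)
    pCore <- c(A = atFraction / 2, T = atFraction / 2,
               G = (1 - atFraction) / 2, C = (1 - atFraction) / 2)
    .withSeed(seed, {
        seqs <- vapply(seq_len(n), function(i) {
            chars <- sample(names(pBack), length, replace = TRUE,
                            prob = pBack)
            chars[core[1]:core[2]] <- sample(names(pCore), coreLength,
                                             replace = TRUE, prob = pCore)
            paste(chars, collapse = "")
        }, character(1))
        out <- Biostrings::DNAStringSet(seqs)
        names(out) <- sprintf("promoter%02d", seq_len(n))
        attr(out, "core") <- core
        out
    })
}

#' Write a gene annotation as GFF3
#'
#' @param genes named GRanges
#' @param path output file
#' @return invisibly, the path
#' @export
writeGenomeGFF3 <- function(genes, path) {
    out <- genes
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        type = rep("gene", length(out)), ID = names(out))
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Write an expression matrix as TSV
#'
#' First column \code{gene_id}, one column per experiment; the format read
#' back by \code{\link{readExpression}}.
#'
#' @param expr genes x experiments matrix with rownames
#' @param path output file
#' @return invisibly, the path
#' @export
writeExpression <- function(expr, path) {
    df <- data.frame(gene_id = rownames(expr), expr,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
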