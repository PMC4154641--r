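## Self-consistent coupling of genes through the torsion field.
##
## Each gene's promoter feels the basal superhelical density plus the
## perturbations generated by the *other* transcribed units (a gene's own
## torsional lobes do not act back on its own promoter).  Because the
## perturbation amplitude is proportional to the partner's current rate,
## the coupled rates are the fixed point of
##   k_i = k_max,i exp(-dG_init(sigma_0 + sum_{j != i} G_ij k_j) / kB Te)
## solved by damped synchronous iteration starting from the rates in the
## absence of local supercoiling.

.ORIENTATIONS <- c("divergent", "convergent", "tandem")

#' Build a two-gene system with a given orientation and promoter distance
#'
#' Places two transcription units on a linear axis. With
#' \code{distanceMode = "tss"} (default) \code{d} is the TSS-to-TSS
#' distance; with \code{"gap"} it is the intergenic gap (bases strictly
#' between the units). Orientations: divergent (transcribing apart,
#' promoters facing each other), convergent (transcribing toward each
#' other), tandem (same strand, gene A upstream).
#'
#' By default each promoter's \code{kmax} is rescaled so that its basal
#' rate at \eqn{\sigma_0} equals \code{basalRate}; with the default
#' torsion parameters a 1-kb gene at unit basal rate then radiates an edge
#' amplitude \eqn{\sigma_a = 0.03}.
#'
#' @param orientation "divergent", "convergent" or "tandem"
#' @param d promoter distance in bp (TSS-to-TSS, or gap with
#'   \code{distanceMode = "gap"}); for convergent TSS-to-TSS geometry
#'   \code{d} must be at least the summed gene lengths
#' @param lengths numeric length-2, gene lengths in bp
#' @param promoter a single \linkS4class{PromoterModel} used for both
#'   genes, or a list of two
#' @param torsion a \linkS4class{TorsionParameters}
#' @param basalRate basal rate each gene is normalized to at
#'   \eqn{\sigma_0}; set to \code{NA} to keep \code{kmax} as given
#' @param distanceMode "tss" or "gap"
#' @param origin left coordinate of gene A
#' @return a \linkS4class{GeneSystem}
#' @examples
#' sys <- buildPair("divergent", d = 500)
#' solveCoupling(sys)
#' @export
buildPair <- function(orientation = .ORIENTATIONS, d,
                      lengths = c(1000, 1000),
                      promoter = promoterModel(),
                      torsion = torsionParameters(),
                      basalRate = 1,
                      distanceMode = c("tss", "gap"),
                      origin = 10000) {
    orientation <- match.arg(orientation)
    distanceMode <- match.arg(distanceMode)
    stopifnot(length(lengths) == 2L, all(lengths >= 1))
    l1 <- round(lengths[1]); l2 <- round(lengths[2])
    d <- round(d)
    promoters <- if (is.list(promoter)) promoter
                 else list(promoter, promoter)
    stopifnot(length(promoters) == 2L)

    aStart <- origin; aEnd <- origin + l1 - 1
    if (orientation == "divergent") {
        strands <- c("-", "+")
        bStart <- if (distanceMode == "tss") aEnd + d else aEnd + d + 1
    } else if (orientation == "convergent") {
        strands <- c("+", "-")
        bStart <- if (distanceMode == "tss") aStart + d - l2 + 1
                  else aEnd + d + 1
    } else {
        strands <- c("+", "+")
        bStart <- if (distanceMode == "tss") aStart + d else aEnd + d + 1
    }
    bEnd <- bStart + l2 - 1
    if (bStart <= aEnd)
        .stopf("genes overlap for %s geometry with d = %d (%s mode)",
               orientation, d, distanceMode)

    units <- transcriptionUnits(
        id = c("geneA", "geneB"),
        start = c(aStart, bStart), end = c(aEnd, bEnd),
        strand = strands, rate = c(0, 0))
    ## normalize kmax so the basal rate at sigma0 is basalRate
    if (!is.na(basalRate)) {
        promoters <- lapply(promoters, function(p) {
            k0 <- transcriptionRate(torsion@sigma0, p)
            p@kmax <- p@kmax * basalRate / k0
            p
        })
    }
    units$rate <- vapply(promoters, function(p)
        transcriptionRate(torsion@sigma0, p), numeric(1))
    new("GeneSystem", units = units, promoters = promoters,
        torsion = torsion)
}

## Plain-numeric rate evaluator for one promoter, with all slots (and any
## profile interpolant) extracted once: the solver's inner loop then runs
## without S4 dispatch.  The arithmetic is identical to
## transcriptionRate(), including the exponent cap.
.rateClosure <- function(p) {
    kBTe <- .RGAS * p@Te
    kmax <- p@kmax
    dGb <- p@dGbind
    op <- p@opening
    if (is(op, "SigmoidOpening")) {
        q <- op@q; v <- op@v; m <- op@m; sc <- op@sigmaC; w <- op@w
        function(sigma) {
            e <- -(q + v * sigma + m * plogis((sigma - sc) / w) + dGb) /
                kBTe
            kmax * exp(pmin(pmax(e, -.EXP_CAP), .EXP_CAP))
        }
    } else {
        ok <- !op@capped
        f <- stats::approxfun(op@sigma[ok], op@dGopen[ok], rule = 2)
        function(sigma) {
            e <- -(f(sigma) + dGb) / kBTe
            kmax * exp(pmin(pmax(e, -.EXP_CAP), .EXP_CAP))
        }
    }
}

## Damped synchronous fixed-point iteration on plain numerics; shared by
## solveCoupling() and the phaseDiagram() sweep.
.iterateFixedPoint <- function(G, sigma0, rateFun, opts) {
    n <- length(rateFun)
    k0 <- vapply(seq_len(n), function(i) rateFun[[i]](sigma0),
                 numeric(1))
    k <- k0
    iter <- 0L
    conv <- FALSE
    repeat {
        iter <- iter + 1L
        sigma <- sigma0 + as.numeric(G %*% k)
        knew <- vapply(seq_len(n), function(i) rateFun[[i]](sigma[i]),
                       numeric(1))
        kupd <- (1 - opts@damping) * k + opts@damping * knew
        resid <- max(abs(kupd - k) / pmax(abs(k), 1e-300))
        k <- kupd
        if (resid < opts@relTol * opts@damping) { conv <- TRUE; break }
        if (iter >= opts@maxIter) break
    }
    list(k = k, k0 = k0, sigma = sigma0 + as.numeric(G %*% k),
         iterations = iter, converged = conv)
}

## Signed geometric coupling matrix: G[i, j] is the superhelical
## perturbation at gene i's TSS per unit rate of gene j (0 on the
## diagonal and across chromosomes).
.couplingMatrix <- function(system) {
    units <- system@units
    n <- length(units)
    tss <- tssOf(units)
    chr <- as.character(GenomeInfoDb::seqnames(units))
    G <- matrix(0, n, n)
    unit1 <- units
    unit1$rate <- rep(1, n)
    for (j in seq_len(n)) {
        for (i in seq_len(n)) {
            if (i == j || chr[i] != chr[j]) next
            G[i, j] <- perturbationAt(unit1[j], tss[i], system@torsion)
        }
    }
    G
}

#' Solve the self-consistent coupling of a gene system
#'
#' Damped synchronous fixed-point iteration of the coupled rates, starting
#' from the rates in the absence of local (transcription-generated)
#' supercoiling. The perturbation amplitudes are recomputed from the
#' current rates at every step. With symmetric geometries and identical
#' genes the iteration preserves the symmetry, so the symmetric fixed
#' point is selected deterministically.
#'
#' @param system a \linkS4class{GeneSystem} (any number of genes)
#' @param opts a \linkS4class{SolverOptions}
#' @return a \linkS4class{CouplingResult}; if \code{maxIter} is reached
#'   the result is returned with \code{converged = FALSE}
#' @export
solveCoupling <- function(system, opts = solverOptions()) {
    stopifnot(is(system, "GeneSystem"), is(opts, "SolverOptions"))
    validObject(system)
    n <- length(system@units)
    sigma0 <- system@torsion@sigma0
    rateFun <- lapply(system@promoters, .rateClosure)
    G <- .couplingMatrix(system)
    fp <- .iterateFixedPoint(G, sigma0, rateFun, opts)
    ids <- names(system@units)
    if (is.null(ids)) ids <- paste0("gene", seq_len(n))
    new("CouplingResult",
        rates = setNames(fp$k, ids),
        basalRates = setNames(fp$k0, ids),
        foldChanges = setNames(fp$k / fp$k0, ids),
        promoterSigma = setNames(fp$sigma, ids),
        iterations = fp$iterations, converged = fp$converged)
}

#' One-way influence of a transcribed gene on a nearby promoter
#'
#' Fold-change of a passive promoter placed at each position, given the
#' torsion field of a single active gene transcribing at its stated rate
#' (no feedback). Positions must lie outside the active unit.
#'
#' @param activeUnit single-element GRanges with a \code{rate} column
#' @param promoter a \linkS4class{PromoterModel} for the passive promoter
#' @param positions numeric vector of promoter positions
#' @param sigma0 basal superhelical density
#' @param torsion a \linkS4class{TorsionParameters}; its \code{sigma0}
#'   slot is ignored in favour of the \code{sigma0} argument
#' @return data.frame with columns position, sigma and foldChange
#' @examples
#' u <- transcriptionUnits("g", 5001, 6000, "+", rate = 1)
#' influenceCurve(u, promoterModel(), c(3001, 4001, 7000), 0,
#'                torsionParameters())
#' @export
influenceCurve <- function(activeUnit, promoter, positions, sigma0,
                           torsion = torsionParameters()) {
    stopifnot(length(activeUnit) == 1L)
    inside <- positions >= GenomicRanges::start(activeUnit) &
        positions <= GenomicRanges::end(activeUnit)
    if (any(inside))
        .stopf("%d position(s) fall inside the active unit", sum(inside))
    dsig <- perturbationAt(activeUnit, positions, torsion)
    sigma <- sigma0 + dsig
    data.frame(position = positions, sigma = sigma,
               foldChange = foldChange(sigma, sigma0, promoter))
}

#' Orientation x distance x basal-density fold-change diagram
#'
#' Solves the coupled pair on a grid of promoter distances and basal
#' superhelical densities. For the symmetric divergent and convergent
#' geometries only gene A is reported; for tandem pairs both the upstream
#' (gene A) and downstream (gene B) fold-changes are returned.
#'
#' @param orientation "divergent", "convergent" or "tandem"
#' @param dGrid numeric vector of promoter distances (bp)
#' @param sigma0Grid numeric vector of basal superhelical densities
#' @param lengths gene lengths (bp)
#' @param promoter a \linkS4class{PromoterModel}
#' @param torsion a \linkS4class{TorsionParameters} providing \code{b} and
#'   \code{alpha} (the \code{sigma0} slot is swept)
#' @param opts a \linkS4class{SolverOptions}
#' @param distanceMode "tss" or "gap" (see \code{\link{buildPair}})
#' @return a list with elements \code{orientation}, \code{d},
#'   \code{sigma0}, \code{converged} (matrix, rows = sigma0, cols = d)
#'   and either \code{foldChange} (matrix) or, for tandem,
#'   \code{foldChangeUpstream} / \code{foldChangeDownstream}
#' @examples
#' pd <- phaseDiagram("divergent", dGrid = c(200, 1000, 3000),
#'                    sigma0Grid = c(-0.06, 0))
#' pd$foldChange
#' @export
phaseDiagram <- function(orientation = .ORIENTATIONS, dGrid, sigma0Grid,
                         lengths = c(1000, 1000),
                         promoter = promoterModel(),
                         torsion = torsionParameters(),
                         opts = solverOptions(),
                         distanceMode = c("tss", "gap")) {
    orientation <- match.arg(orientation)
    distanceMode <- match.arg(distanceMode)
    if (length(dGrid) == 0L || length(sigma0Grid) == 0L)
        .stopf("empty distance or sigma0 grid")
    nr <- length(sigma0Grid); nc <- length(dGrid)
    fcA <- matrix(NA_real_, nr, nc,
                  dimnames = list(sigma0Grid, dGrid))
    fcB <- fcA
    cv <- matrix(NA, nr, nc, dimnames = dimnames(fcA))
    ## geometry (and hence the coupling matrix) does not depend on
    ## sigma0, so each distance column is built once and the sigma0 sweep
    ## runs on the numeric core with the basal-rate normalization
    ## applied as a multiplicative rescaling
    for (cc in seq_len(nc)) {
        sys <- buildPair(orientation, dGrid[cc], lengths, promoter,
                         torsionParameters(0, torsion@b, torsion@alpha),
                         basalRate = NA, distanceMode = distanceMode)
        G <- .couplingMatrix(sys)
        base <- lapply(sys@promoters, .rateClosure)
        for (r in seq_len(nr)) {
            s0 <- sigma0Grid[r]
            rateFun <- lapply(base, function(f) {
                scale <- 1 / f(s0)   # basal rate 1 at sigma0
                function(sigma) scale * f(sigma)
            })
            fp <- .iterateFixedPoint(G, s0, rateFun, opts)
            fcA[r, cc] <- fp$k[1] / fp$k0[1]
            fcB[r, cc] <- fp$k[2] / fp$k0[2]
            cv[r, cc] <- fp$converged
        }
    }
    out <- list(orientation = orientation, d = dGrid,
                sigma0 = sigma0Grid, converged = cv)
    if (orientation == "tandem") {
        out$foldChangeUpstream <- fcA
        out$foldChangeDownstream <- fcB
    } else {
        out$foldChange <- fcA
    }
    out
}

#' Write a phase diagram as TSV matrices
#'
#' One TSV per fold-change matrix (rows = sigma0, columns = distance).
#'
#' @param diagram result of \code{\link{phaseDiagram}}
#' @param dir output directory (created if needed)
#' @param prefix filename prefix
#' @return invisibly, the written paths
#' @export
writePhaseDiagram <- function(diagram, dir, prefix = "diagram") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mats <- diagram[grep("^foldChange", names(diagram))]
    paths <- character(0)
    for (nm in names(mats)) {
        path <- file.path(dir, sprintf("%s_%s_%s.tsv", prefix,
                                       diagram$orientation, nm))
        df <- data.frame(sigma0 = diagram$sigma0, mats[[nm]],
                         check.names = FALSE)
        colnames(df) <- c("sigma0", diagram$d)
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        paths <- c(paths, path)
    }
    invisible(paths)
}
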