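#' @import methods
#' @importFrom stats coef lm median nls optimize plogis rbinom rexp rnorm
#'   runif sd setNames cor complete.cases
#' @importFrom utils write.table read.table packageVersion
NULL

## ---------------------------------------------------------------------------
## Torsion field
## ---------------------------------------------------------------------------

#' Parameters of the transcription-generated torsion field
#'
#' Holds the basal superhelical density \eqn{\sigma_0}, the decay length
#' \eqn{b} of the torsional perturbation (set by topoisomerase efficiency
#' \eqn{1/b}), and the amplitude coefficient \eqn{\alpha} relating the
#' perturbation amplitude to the product of expression rate and transcript
#' length, \eqn{\sigma_a = \alpha k l}.
#'
#' @slot sigma0 basal superhelical density (dimensionless; around -0.06 for
#'   bacteria, near 0 for eukaryotic free DNA)
#' @slot b decay length of the perturbation in bp (> 0)
#' @slot alpha amplitude per (rate unit x bp) (>= 0)
#' @export
setClass("TorsionParameters",
    slots = c(sigma0 = "numeric", b = "numeric", alpha = "numeric"))

setValidity("TorsionParameters", function(object) {
    msg <- character()
    for (s in c("sigma0", "b", "alpha")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (length(msg) == 0L) {
        if (object@b <= 0) msg <- c(msg, "'b' must be > 0")
        if (object@alpha < 0) msg <- c(msg, "'alpha' must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct torsion-field parameters
#'
#' Defaults correspond to the standard model conditions: a propagation
#' distance of 1000 bp, \eqn{\alpha = 3\times 10^{-5}} per (rate x bp) so
#' that a 1-kb gene at unit rate produces an amplitude
#' \eqn{\sigma_a = 0.03}, and a relaxed basal level \eqn{\sigma_0 = 0}.
#'
#' @param sigma0 basal superhelical density
#' @param b decay length (bp)
#' @param alpha amplitude coefficient per (rate x bp)
#' @return a \linkS4class{TorsionParameters} object
#' @examples
#' torsionParameters(sigma0 = -0.06)
#' @export
torsionParameters <- function(sigma0 = 0, b = 1000, alpha = 3e-5) {
    new("TorsionParameters", sigma0 = as.numeric(sigma0), b = as.numeric(b),
        alpha = as.numeric(alpha))
}

setMethod("show", "TorsionParameters", function(object) {
    cat("TorsionParameters: sigma0 =", object@sigma0,
        ", b =", object@b, "bp, alpha =", object@alpha, "\n")
})

## ---------------------------------------------------------------------------
## Opening energy
## ---------------------------------------------------------------------------

#' Energetic and elastic parameters of the duplex-destabilization model
#'
#' Parameters of the single-bubble stress-induced duplex destabilization
#' (SIDD) calculation: nucleation cost of a denatured run, per-base pairing
#' energies, torsional stiffness of the open region, quadratic coefficient
#' of the residual superhelicity, helical repeat, and temperature.
#'
#' @slot aNuc nucleation free energy per denatured run (kcal/mol)
#' @slot eAT pairing free energy per open A:T base pair (kcal/mol)
#' @slot eGC pairing free energy per open G:C base pair (kcal/mol)
#' @slot Copen torsional stiffness of the open region (kcal/mol/rad^2/bp)
#' @slot Kcoef dimensionless coefficient of the quadratic residual-linking
#'   energy; the quadratic stiffness used is \eqn{K = Kcoef \cdot RT / N}
#'   (kcal/mol per turn^2) for a domain of N bp
#' @slot h helical repeat (bp/turn)
#' @slot temperature absolute temperature (K)
#' @slot maxBubble maximal length of the denatured run (bp)
#' @slot domainSize size N (bp) of the superhelical domain carrying the
#'   linking difference \eqn{\alpha_{Lk} = \sigma N / h}; \code{NA}
#'   (default) uses the analysed sequence length. Setting it explicitly
#'   makes the opening energy of a site insensitive to how much flanking
#'   sequence is included in the calculation.
#' @slot dgCap cap applied to the opening free energy when the opening
#'   probability underflows (kcal/mol)
#' @export
setClass("SIDDParameters",
    slots = c(aNuc = "numeric", eAT = "numeric", eGC = "numeric",
              Copen = "numeric", Kcoef = "numeric", h = "numeric",
              temperature = "numeric", maxBubble = "integer",
              domainSize = "numeric", dgCap = "numeric"))

setValidity("SIDDParameters", function(object) {
    msg <- character()
    num <- c("aNuc", "eAT", "eGC", "Copen", "Kcoef", "h", "temperature", "dgCap")
    if (!(length(object@domainSize) == 1L &&
          (is.na(object@domainSize) ||
           (is.finite(object@domainSize) && object@domainSize >= 1))))
        msg <- c(msg, "'domainSize' must be NA or a single number >= 1")
    for (s in num) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (length(msg) == 0L) {
        if (object@h <= 0) msg <- c(msg, "'h' must be > 0")
        if (object@temperature <= 0)
            msg <- c(msg, "'temperature' must be > 0")
        if (object@Copen <= 0) msg <- c(msg, "'Copen' must be > 0")
        if (object@maxBubble < 1L) msg <- c(msg, "'maxBubble' must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct SIDD model parameters
#'
#' Defaults are declared, overridable desk-scale values at 37 C:
#' nucleation 10.8 kcal/mol, A:T and G:C pairing energies 0.26 and
#' 1.30 kcal/mol/bp, open-region torsional stiffness 2.5 kcal/mol/rad^2/bp,
#' helical repeat 10.4 bp/turn, and residual-superhelicity stiffness
#' \eqn{K = 2200\,RT/N}.
#'
#' @param aNuc,eAT,eGC,Copen,Kcoef,h,temperature,maxBubble,domainSize,dgCap see
#'   \linkS4class{SIDDParameters}
#' @return a \linkS4class{SIDDParameters} object
#' @examples
#' siddParameters(maxBubble = 60)
#' @export
siddParameters <- function(aNuc = 10.8, eAT = 0.26, eGC = 1.30, Copen = 2.5,
                           Kcoef = 2200, h = 10.4, temperature = 310.15,
                           maxBubble = 100L, domainSize = NA_real_,
                           dgCap = 50) {
    new("SIDDParameters", aNuc = as.numeric(aNuc), eAT = as.numeric(eAT),
        eGC = as.numeric(eGC), Copen = as.numeric(Copen), Kcoef = as.numeric(Kcoef),
        h = as.numeric(h), temperature = as.numeric(temperature),
        maxBubble = as.integer(maxBubble),
        domainSize = as.numeric(domainSize), dgCap = as.numeric(dgCap))
}

#' Supercoiling-dependent melting profile of an initiation site
#'
#' Result of a SIDD calculation over a grid of superhelical densities: the
#' probability that the designated initiation window is fully denatured and
#' the corresponding opening free energy
#' \eqn{\Delta G_{open}(\sigma) = -RT \log[p/(1-p)]}.
#'
#' @slot sigma superhelical density grid
#' @slot dGopen opening free energy at each grid point (kcal/mol)
#' @slot pOpen opening probability of the site at each grid point
#' @slot capped logical; TRUE where \code{pOpen} underflowed and
#'   \code{dGopen} was capped
#' @slot site integer start/end (1-based, inclusive) of the initiation
#'   window within the analysed sequence
#' @export
setClass("MeltingProfile",
    slots = c(sigma = "numeric", dGopen = "numeric", pOpen = "numeric",
              capped = "logical", site = "integer"))

setValidity("MeltingProfile", function(object) {
    n <- length(object@sigma)
    if (length(object@dGopen) != n || length(object@pOpen) != n ||
        length(object@capped) != n)
        return("sigma, dGopen, pOpen and capped must have equal length")
    if (any(object@pOpen < -1e-12 | object@pOpen > 1 + 1e-12))
        return("pOpen must lie in [0, 1]")
    TRUE
})

setMethod("show", "MeltingProfile", function(object) {
    cat("MeltingProfile over", length(object@sigma),
        "superhelical densities in [",
        min(object@sigma), ",", max(object@sigma), "]\n")
    cat("  site:", object@site[1], "-", object@site[2],
        "; dGopen range:", round(min(object@dGopen), 3), "-",
        round(max(object@dGopen), 3), "kcal/mol",
        if (any(object@capped)) sprintf("(%d capped)", sum(object@capped))
        else "", "\n")
})

#' @describeIn MeltingProfile-class coerce to a data.frame with columns
#'   sigma, dGopen, pOpen, capped
#' @param x a MeltingProfile
#' @param ... ignored
#' @export
#' @method as.data.frame MeltingProfile
as.data.frame.MeltingProfile <- function(x, ...) {
    data.frame(sigma = x@sigma, dGopen = x@dGopen, pOpen = x@pOpen,
               capped = x@capped)
}

setMethod("as.data.frame", "MeltingProfile", as.data.frame.MeltingProfile)

#' Sigmoidal parameterization of the opening free energy
#'
#' Monotone sigmoid used by the coupling simulations in place of the full
#' melting calculation:
#' \deqn{\Delta G_{open}(\sigma) = q + v\sigma + m\,\Lambda((\sigma-\sigma_c)/w)}
#' with \eqn{\Lambda} the standard logistic. \eqn{\sigma_c} is the
#' sequence-dependent destabilization threshold and \eqn{w} the width of the
#' transition; \eqn{m}, \eqn{v} and \eqn{q} are adjustable.
#'
#' @slot sigmaC transition threshold
#' @slot w transition width (> 0)
#' @slot m amplitude of the transition (kcal/mol)
#' @slot v linear slope (kcal/mol per unit sigma)
#' @slot q offset (kcal/mol)
#' @export
setClass("SigmoidOpening",
    slots = c(sigmaC = "numeric", w = "numeric", m = "numeric",
              v = "numeric", q = "numeric"))

setValidity("SigmoidOpening", function(object) {
    for (s in c("sigmaC", "w", "m", "v", "q")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            return(sprintf("'%s' must be a single finite number", s))
    }
    if (object@w <= 0) return("'w' must be > 0")
    TRUE
})

#' Construct a sigmoidal opening model
#'
#' The defaults describe the reference promoter used throughout the coupling
#' simulations: threshold \eqn{\sigma_c = -0.05}, width 0.015, amplitude
#' 8 kcal/mol, no linear term and a 2 kcal/mol floor, i.e. a promoter that
#' is essentially closed at \eqn{\sigma = 0} and opens sharply under
#' physiological negative supercoiling.
#'
#' @param sigmaC,w,m,v,q see \linkS4class{SigmoidOpening}
#' @return a \linkS4class{SigmoidOpening} object
#' @examples
#' op <- sigmoidOpening()
#' openingEnergy(c(-0.1, -0.05, 0), op)
#' @export
sigmoidOpening <- function(sigmaC = -0.05, w = 0.015, m = 8, v = 0, q = 2) {
    new("SigmoidOpening", sigmaC = as.numeric(sigmaC), w = as.numeric(w),
        m = as.numeric(m), v = as.numeric(v), q = as.numeric(q))
}

setMethod("show", "SigmoidOpening", function(object) {
    cat(sprintf(
        "SigmoidOpening: dG(sigma) = %.4g + %.4g*sigma + %.4g*logistic((sigma - %.4g)/%.4g)\n",
        object@q, object@v, object@m, object@sigmaC, object@w))
})

## ---------------------------------------------------------------------------
## Transcription model
## ---------------------------------------------------------------------------

#' Thermodynamic promoter model
#'
#' Combines a supercoiling-dependent opening model with a
#' supercoiling-independent polymerase binding energy and an effective
#' temperature that sets the energy scale of the (possibly
#' polymerase-assisted) initiation equilibrium. The transcription rate is
#' \eqn{k(\sigma) = k_{max} \exp[-(\Delta G_{open}(\sigma) + \Delta G_{bind})
#' / (k_B T_e)]}.
#'
#' @slot opening a \linkS4class{SigmoidOpening} or
#'   \linkS4class{MeltingProfile} (used as an interpolant)
#' @slot dGbind polymerase binding free energy (kcal/mol), independent of
#'   supercoiling
#' @slot Te effective temperature (K)
#' @slot kmax rate prefactor (arbitrary rate units, > 0)
#' @export
setClass("PromoterModel",
    slots = c(opening = "ANY", dGbind = "numeric", Te = "numeric",
              kmax = "numeric"))

setValidity("PromoterModel", function(object) {
    if (!(is(object@opening, "SigmoidOpening") ||
          is(object@opening, "MeltingProfile")))
        return("'opening' must be a SigmoidOpening or MeltingProfile")
    if (length(object@Te) != 1L || !is.finite(object@Te) || object@Te <= 0)
        return("'Te' must be a single positive number")
    if (length(object@kmax) != 1L || !is.finite(object@kmax) ||
        object@kmax <= 0)
        return("'kmax' must be a single positive number")
    if (length(object@dGbind) != 1L || !is.finite(object@dGbind))
        return("'dGbind' must be a single finite number")
    TRUE
})

#' Construct a thermodynamic promoter model
#'
#' The default effective temperature is 558 K (1.8 times the physical
#' temperature of 310 K), a calibratable placeholder appropriate for in
#' vivo eukaryotic expression; fold-changes do not depend on
#' \code{dGbind} or \code{kmax}.
#'
#' @param opening opening model (default \code{\link{sigmoidOpening}()})
#' @param dGbind binding free energy (kcal/mol)
#' @param Te effective temperature (K)
#' @param kmax rate prefactor
#' @return a \linkS4class{PromoterModel} object
#' @examples
#' pm <- promoterModel()
#' transcriptionRate(-0.06, pm)
#' @export
promoterModel <- function(opening = sigmoidOpening(), dGbind = 0,
                          Te = 1.8 * 310, kmax = 1) {
    new("PromoterModel", opening = opening, dGbind = as.numeric(dGbind),
        Te = as.numeric(Te), kmax = as.numeric(kmax))
}

setMethod("show", "PromoterModel", function(object) {
    cat("PromoterModel: Te =", object@Te, "K, dGbind =", object@dGbind,
        "kcal/mol, kmax =", object@kmax, "\n  opening: ")
    show(object@opening)
})

## ---------------------------------------------------------------------------
## Pair coupling
## ---------------------------------------------------------------------------

#' Fixed-point solver options
#'
#' @slot relTol relative convergence tolerance (> 0)
#' @slot maxIter maximal number of iterations
#' @slot damping damping factor of the synchronous update, in (0, 1]
#' @export
setClass("SolverOptions",
    slots = c(relTol = "numeric", maxIter = "integer", damping = "numeric"))

setValidity("SolverOptions", function(object) {
    if (object@relTol <= 0) return("'relTol' must be > 0")
    if (object@maxIter < 1L) return("'maxIter' must be >= 1")
    if (object@damping <= 0 || object@damping > 1)
        return("'damping' must lie in (0, 1]")
    TRUE
})

#' Construct solver options
#'
#' @param relTol relative tolerance (default 1e-8)
#' @param maxIter maximal iterations (default 10000)
#' @param damping damping factor (default 0.5)
#' @return a \linkS4class{SolverOptions} object
#' @export
solverOptions <- function(relTol = 1e-8, maxIter = 10000L, damping = 0.5) {
    new("SolverOptions", relTol = as.numeric(relTol),
        maxIter = as.integer(maxIter), damping = as.numeric(damping))
}

#' A system of torsionally coupled genes
#'
#' Transcription units (a \link[GenomicRanges]{GRanges} with a \code{rate}
#' metadata column giving the basal expression rate of each gene at
#' \eqn{\sigma_0}), one \linkS4class{PromoterModel} per unit, and the
#' torsion-field parameters. Units must not overlap, and every promoter
#' (TSS) must lie outside every other unit.
#'
#' @slot units GRanges with metadata column \code{rate}
#' @slot promoters list of \linkS4class{PromoterModel}, one per unit
#' @slot torsion \linkS4class{TorsionParameters}
#' @export
setClass("GeneSystem",
    slots = c(units = "GRanges", promoters = "list",
              torsion = "TorsionParameters"))

setValidity("GeneSystem", function(object) {
    n <- length(object@units)
    if (length(object@promoters) != n)
        return("need exactly one PromoterModel per transcription unit")
    if (!all(vapply(object@promoters, is, TRUE, "PromoterModel")))
        return("'promoters' must all be PromoterModel objects")
    v <- validateUnits(object@units)
    if (!isTRUE(v)) return(v)
    if (n >= 2L) {
        hits <- GenomicRanges::findOverlaps(object@units,
                                            drop.self = TRUE,
                                            ignore.strand = TRUE)
        if (length(hits) > 0L)
            return("transcription units must not overlap")
        tss <- tssOf(object@units)
        for (i in seq_len(n)) {
            inside <- GenomicRanges::start(object@units[-i]) <= tss[i] &
                GenomicRanges::end(object@units[-i]) >= tss[i] &
                as.character(GenomeInfoDb::seqnames(object@units[-i])) ==
                    as.character(GenomeInfoDb::seqnames(object@units[i]))
            if (any(inside))
                return("every promoter must lie outside every other unit")
        }
    }
    TRUE
})

setMethod("show", "GeneSystem", function(object) {
    cat("GeneSystem with", length(object@units), "transcription unit(s)\n")
    show(object@torsion)
})

#' Result of the self-consistent coupling computation
#'
#' @slot rates converged transcription rate of each gene
#' @slot basalRates rate of each gene at the basal superhelical density
#' @slot foldChanges rates / basalRates
#' @slot promoterSigma converged superhelical density at each promoter
#' @slot iterations number of fixed-point iterations performed
#' @slot converged logical convergence flag
#' @export
setClass("CouplingResult",
    slots = c(rates = "numeric", basalRates = "numeric",
              foldChanges = "numeric", promoterSigma = "numeric",
              iterations = "integer", converged = "logical"))

setMethod("show", "CouplingResult", function(object) {
    cat("CouplingResult (", if (object@converged) "converged" else
        "NOT converged", " in ", object@iterations, " iterations)\n",
        sep = "")
    print(data.frame(gene = names(object@rates), rate = object@rates,
                     foldChange = object@foldChanges,
                     promoterSigma = object@promoterSigma,
                     row.names = NULL))
})

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Specification of a synthetic annotated genome
#'
#' Describes a toy genome with planted neighbour-gene pairs of known
#' orientation, separation and isolation status, plus background genes.
#' Spoiled pairs carry a planted perturber gene within the isolation radius
#' of one of their promoters, so a correct isolation filter must reject
#' them.
#'
#' @slot nPairs named integer vector (divergent, tandem, convergent)
#' @slot nSpoiled named integer vector of pairs per orientation to spoil
#' @slot separationRange named list of length-2 numeric ranges (bp) from
#'   which intergenic gaps are drawn, per orientation
#' @slot geneLength gene length in bp (point mass)
#' @slot nBackground number of background genes (placed in tight clusters
#'   so that they never form isolated pairs themselves)
#' @slot chromLength chromosome length in bp; \code{NA} sizes the
#'   chromosome to its content
#' @slot seed RNG seed; generation is a pure function of the spec
#' @export
setClass("SyntheticGenomeSpec",
    slots = c(nPairs = "integer", nSpoiled = "integer",
              separationRange = "list", geneLength = "numeric",
              nBackground = "integer", chromLength = "numeric",
              seed = "integer"))

setValidity("SyntheticGenomeSpec", function(object) {
    orient <- c("divergent", "tandem", "convergent")
    if (!identical(names(object@nPairs), orient) ||
        !identical(names(object@nSpoiled), orient) ||
        !identical(names(object@separationRange), orient))
        return("nPairs, nSpoiled and separationRange must be named divergent, tandem, convergent")
    if (any(object@nPairs < 0L) || any(object@nSpoiled < 0L) ||
        object@nBackground < 0L)
        return("counts must be >= 0")
    if (any(object@nSpoiled > object@nPairs))
        return("nSpoiled cannot exceed nPairs")
    if (object@geneLength < 1) return("geneLength must be >= 1")
    TRUE
})

#' Construct a synthetic genome specification
#'
#' Default pair counts (75 divergent, 55 tandem, 10 convergent) follow the
#' empirically observed dominance of divergent isolated pairs at roughly
#' one tenth of the genome-wide scale. Gap ranges keep most divergent and
#' tandem pairs below 1 kb while convergent gaps spread to 3 kb.
#'
#' @param nPairs integer vector (divergent, tandem, convergent)
#' @param nSpoiled integer vector of spoiled pairs per orientation
#' @param separationRange list of length-2 gap ranges per orientation (bp)
#' @param geneLength gene length (bp)
#' @param nBackground number of background genes
#' @param chromLength chromosome length (NA = auto)
#' @param seed RNG seed
#' @return a \linkS4class{SyntheticGenomeSpec}
#' @examples
#' syntheticGenomeSpec(nPairs = c(10, 5, 5), seed = 7)
#' @export
syntheticGenomeSpec <- function(nPairs = c(75L, 55L, 10L),
                                nSpoiled = c(0L, 0L, 0L),
                                separationRange = list(
                                    divergent = c(50, 1500),
                                    tandem = c(50, 1500),
                                    convergent = c(50, 2999)),
                                geneLength = 1000,
                                nBackground = 0L,
                                chromLength = NA_real_,
                                seed = 1L) {
    orient <- c("divergent", "tandem", "convergent")
    nPairs <- setNames(as.integer(nPairs), orient)
    nSpoiled <- setNames(as.integer(nSpoiled), orient)
    names(separationRange) <- orient
    new("SyntheticGenomeSpec", nPairs = nPairs, nSpoiled = nSpoiled,
        separationRange = separationRange,
        geneLength = as.numeric(geneLength),
        nBackground = as.integer(nBackground),
        chromLength = as.numeric(chromLength), seed = as.integer(seed))
}

#' Specification of a synthetic expression matrix
#'
#' @slot nExperiments number of experiments (columns; default 24)
#' @slot meanlog,sdlog log-normal basal expression parameters
#' @slot dropout probability that a (gene, experiment) entry is zero;
#'   controls the expressed fraction
#' @slot couplingAmplitude exponent applied to the model fold-change of
#'   accepted pairs (0 disables coupling, 1 applies it fully)
#' @slot correlatedFraction fraction of eligible accepted pairs designated
#'   as correlated (sharing a latent factor)
#' @slot correlationStrength strength of the shared latent factor in [0, 1]
#' @slot correlatedMaxSeparation maximal gap (bp) of designated correlated
#'   pairs
#' @slot seed RNG seed
#' @export
setClass("SyntheticExpressionSpec",
    slots = c(nExperiments = "integer", meanlog = "numeric",
              sdlog = "numeric", dropout = "numeric",
              couplingAmplitude = "numeric", correlatedFraction = "numeric",
              correlationStrength = "numeric",
              correlatedMaxSeparation = "numeric", seed = "integer"))

setValidity("SyntheticExpressionSpec", function(object) {
    if (object@nExperiments < 1L) return("nExperiments must be >= 1")
    if (object@dropout < 0 || object@dropout > 1)
        return("dropout must lie in [0, 1]")
    if (object@correlatedFraction < 0 || object@correlatedFraction > 1)
        return("correlatedFraction must lie in [0, 1]")
    if (object@correlationStrength < 0 || object@correlationStrength > 1)
        return("correlationStrength must lie in [0, 1]")
    TRUE
})

#' Construct a synthetic expression specification
#'
#' Defaults emulate the gross structure of a deep RNA-Seq compendium of 24
#' cell lines: log-normal basal levels, a 0.5 dropout rate matching a
#' genome-wide expressed fraction near one half, and correlated pairs
#' restricted to sub-kilobase separations.
#'
#' @param nExperiments,meanlog,sdlog,dropout,couplingAmplitude see
#'   \linkS4class{SyntheticExpressionSpec}
#' @param correlatedFraction,correlationStrength,correlatedMaxSeparation,seed
#'   see \linkS4class{SyntheticExpressionSpec}
#' @return a \linkS4class{SyntheticExpressionSpec}
#' @export
syntheticExpressionSpec <- function(nExperiments = 24L, meanlog = 2,
                                    sdlog = 1, dropout = 0.5,
                                    couplingAmplitude = 1,
                                    correlatedFraction = 0.2,
                                    correlationStrength = 1,
                                    correlatedMaxSeparation = 1000,
                                    seed = 1L) {
    new("SyntheticExpressionSpec", nExperiments = as.integer(nExperiments),
        meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog),
        dropout = as.numeric(dropout),
        couplingAmplitude = as.numeric(couplingAmplitude),
        correlatedFraction = as.numeric(correlatedFraction),
        correlationStrength = as.numeric(correlationStrength),
        correlatedMaxSeparation = as.numeric(correlatedMaxSeparation),
        seed = as.integer(seed))
}
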