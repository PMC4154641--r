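## Thermodynamic transcription model.
##
## The expression level is proportional to the initiation probability of a
## chemical equilibrium between bound and unbound states of the
## transcription machinery, evaluated at an effective temperature Te that
## absorbs the non-thermal (polymerase-assisted) contribution to bubble
## formation.  The only supercoiling-dependent term is the promoter
## opening penalty.

#' Total initiation free energy
#'
#' \eqn{\Delta G_{init}(\sigma) = \Delta G_{open}(\sigma) + \Delta
#' G_{bind}}, with the polymerase binding contribution independent of
#' supercoiling.
#'
#' @param sigma numeric vector of superhelical densities
#' @param promoter a \linkS4class{PromoterModel}
#' @return initiation free energy (kcal/mol) per \code{sigma}
#' @export
initiationEnergy <- function(sigma, promoter) {
    stopifnot(is(promoter, "PromoterModel"))
    openingEnergy(sigma, promoter@opening) + promoter@dGbind
}

#' Supercoiling-dependent transcription rate
#'
#' \eqn{k(\sigma) = k_{max}\exp[-\Delta G_{init}(\sigma)/(k_B T_e)]}, the
#' unsaturated Boltzmann weight of the open initiation complex. Exponents
#' are capped at +/-500 (with a warning) to guard against overflow.
#'
#' @param sigma numeric vector of superhelical densities
#' @param promoter a \linkS4class{PromoterModel}
#' @return transcription rate(s), strictly positive
#' @examples
#' pm <- promoterModel()
#' transcriptionRate(c(-0.08, 0), pm)
#' @export
transcriptionRate <- function(sigma, promoter) {
    stopifnot(is(promoter, "PromoterModel"))
    kBTe <- .RGAS * promoter@Te
    promoter@kmax * .cappedExp(-initiationEnergy(sigma, promoter) / kBTe)
}

#' Transcription fold-change due to supercoiling
#'
#' \eqn{\rho(\sigma;\sigma_0) = \exp[-(\Delta G_{open}(\sigma)-\Delta
#' G_{open}(\sigma_0))/(k_B T_e)]}: the ratio of the rate at the perturbed
#' local density to the rate at the basal density. It is exactly
#' independent of the binding energy and of \eqn{k_{max}}, so it can be
#' computed without knowledge of the binding energetics.
#'
#' @param sigma numeric vector of perturbed superhelical densities
#' @param sigma0 basal superhelical density (scalar)
#' @param promoter a \linkS4class{PromoterModel}
#' @return dimensionless fold-change(s)
#' @examples
#' foldChange(-0.05, 0, promoterModel())
#' @export
foldChange <- function(sigma, sigma0, promoter) {
    stopifnot(is(promoter, "PromoterModel"), length(sigma0) == 1L)
    kBTe <- .RGAS * promoter@Te
    dG <- openingEnergy(sigma, promoter@opening) -
        openingEnergy(sigma0, promoter@opening)
    .cappedExp(-dG / kBTe)
}

#' Calibrate the effective temperature from expression data
#'
#' Least-squares fit of \eqn{\log k = a - \Delta G_{open}(\sigma)/(k_B
#' T_e)} to paired (superhelical density, expression) measurements, with a
#' free intercept. The opening model is fixed; the slope of the regression
#' of log expression on the opening energy yields \eqn{T_e}.
#'
#' @param sigma numeric vector of superhelical densities (>= 3 points)
#' @param expression positive expression values, same length
#' @param opening a \linkS4class{SigmoidOpening} or
#'   \linkS4class{MeltingProfile}
#' @return a list with components \code{Te} (K), \code{intercept},
#'   \code{r.squared} and \code{fit} (the lm object)
#' @examples
#' op <- sigmoidOpening()
#' sg <- seq(-0.09, -0.01, length.out = 8)
#' expr <- exp(2 - openingEnergy(sg, op) / (0.0019872 * 500))
#' calibrateEffectiveTemperature(sg, expr, op)$Te
#' @export
calibrateEffectiveTemperature <- function(sigma, expression, opening) {
    if (length(sigma) < 3L || length(expression) != length(sigma))
        .stopf("need >= 3 paired (sigma, expression) points")
    if (any(expression <= 0))
        .stopf("expression values must be strictly positive")
    dg <- openingEnergy(sigma, opening)
    if (sd(dg) < 1e-10)
        .stopf("opening energy is flat over the sigma range; Te is not identifiable")
    fit <- lm(log(expression) ~ dg)
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0)
        .stopf("non-negative regression slope (%.3g): expression does not decrease with opening energy, Te is not identifiable",
               slope)
    list(Te = -1 / (.RGAS * slope),
         intercept = unname(coef(fit)[1]),
         ## noiseless calibrations fit perfectly; the summary warning
         ## for that case is expected and unhelpful
         r.squared = suppressWarnings(summary(fit)$r.squared),
         fit = fit)
}
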