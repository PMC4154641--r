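## Supercoiling-dependent opening free energy of a promoter sequence.
##
## Single-bubble stress-induced duplex destabilization (SIDD): the
## equilibrium ensemble contains the fully closed duplex plus all states
## with one denatured run (start s, length n <= maxBubble).  A state's free
## energy is the nucleation cost, the per-base pairing energies of the open
## run, and a torsional term obtained by minimizing, over the residual
## twist of the open strands, the sum of the open-region twist energy and
## the quadratic energy of the residual linking difference.

.siddCheckSequence <- function(sequence) {
    if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
        sequence <- as.character(sequence)[1]
    chars <- strsplit(toupper(sequence), "")[[1]]
    if (length(chars) == 0L) .stopf("empty sequence")
    bad <- !chars %in% c("A", "C", "G", "T")
    if (any(bad))
        .stopf("sequence contains non-ACGT characters: %s",
               paste(unique(chars[bad]), collapse = ", "))
    chars
}

## Effective superhelical-domain size: the analysed fragment length
## unless the parameters pin an explicit domain.
.siddDomainSize <- function(params, seqLength) {
    if (is.na(params@domainSize)) seqLength
    else {
        if (params@domainSize < seqLength)
            .stopf("domainSize (%g) smaller than the analysed sequence (%d bp)",
                   params@domainSize, seqLength)
        params@domainSize
    }
}

## Torsional free energy of a state with n open bases in a domain of N bp
## at superhelical density sigma.  Minimizing
##   E(tau) = (C n / 2) tau^2 + (K / 2) (A - n tau / (2 pi))^2
## over the open-region twist tau, with A = sigma N / h + n / h the linking
## difference left after opening n bp, gives
##   E_min = (1/2) A^2 C K / (C + K n / (4 pi^2)).
## n = 0 recovers the closed-state energy (K/2) (sigma N / h)^2.
.siddTorsional <- function(n, sigma, N, params) {
    RT <- .RGAS * params@temperature
    K <- params@Kcoef * RT / N
    A <- sigma * N / params@h + n / params@h
    0.5 * A^2 * params@Copen * K / (params@Copen + K * n / (4 * pi^2))
}

## Enumerate all single-run states of a sequence and their Boltzmann
## weights at one superhelical density.  Returns a data.frame with the
## closed state first (s = 0, n = 0).
siddStates <- function(sequence, sigma, params = siddParameters()) {
    chars <- .siddCheckSequence(sequence)
    N <- .siddDomainSize(params, length(chars))
    maxB <- min(params@maxBubble, length(chars))
    L <- length(chars)
    eb <- ifelse(chars %in% c("A", "T"), params@eAT, params@eGC)
    cs <- c(0, cumsum(eb))
    sL <- lapply(seq_len(maxB), function(n) seq_len(L - n + 1L))
    s_all <- unlist(sL)
    n_all <- rep(seq_len(maxB), vapply(sL, length, 1L))
    pairing <- cs[s_all + n_all] - cs[s_all]
    E <- c(.siddTorsional(0, sigma, N, params),
           params@aNuc + pairing +
               .siddTorsional(n_all, sigma, N, params))
    RT <- .RGAS * params@temperature
    w <- exp(-(E - min(E)) / RT)
    data.frame(s = c(0L, s_all), n = c(0L, n_all), energy = E,
               prob = w / sum(w))
}

#' Supercoiling-dependent melting profile of an initiation site
#'
#' Computes, over a grid of superhelical densities, the probability that a
#' designated initiation window is fully contained in the denatured run,
#' and the corresponding opening free energy
#' \eqn{\Delta G_{open}(\sigma) = -RT\log[p/(1-p)]}. The ensemble is the
#' single-bubble SIDD ensemble described in \code{\link{siddParameters}}.
#' Where the opening probability underflows, \eqn{\Delta G} is capped at
#' \code{params@dgCap} and flagged.
#'
#' @param sequence DNA sequence (character or \link[Biostrings]{DNAString});
#'   A/C/G/T only
#' @param site length-2 integer vector, 1-based inclusive initiation
#'   window within the sequence
#' @param sigmaGrid numeric vector of superhelical densities
#' @param params a \linkS4class{SIDDParameters}
#' @return a \linkS4class{MeltingProfile}
#' @examples
#' seqs <- makePromoters(1, 80, atFraction = 1, seed = 1)
#' prof <- siddProfile(seqs[[1]], site = c(36, 45),
#'                     sigmaGrid = seq(-0.12, 0, length.out = 13),
#'                     params = siddParameters(maxBubble = 40L))
#' @export
siddProfile <- function(sequence, site, sigmaGrid,
                        params = siddParameters()) {
    stopifnot(is(params, "SIDDParameters"))
    chars <- .siddCheckSequence(sequence)
    L <- length(chars)
    N <- .siddDomainSize(params, L)
    site <- as.integer(round(site))
    if (length(site) != 2L || site[1] > site[2] || site[1] < 1L ||
        site[2] > L)
        .stopf("'site' must be a [start, end] window inside the sequence")
    maxB <- min(params@maxBubble, L)
    if (site[2] - site[1] + 1L > maxB)
        .stopf("initiation window (%d bp) exceeds maxBubble (%d bp)",
               site[2] - site[1] + 1L, maxB)

    eb <- ifelse(chars %in% c("A", "T"), params@eAT, params@eGC)
    cs <- c(0, cumsum(eb))
    sL <- lapply(seq_len(maxB), function(n) seq_len(L - n + 1L))
    s_all <- unlist(sL)
    n_all <- rep(seq_len(maxB), vapply(sL, length, 1L))
    pairing <- params@aNuc + cs[s_all + n_all] - cs[s_all]
    covers <- s_all <= site[1] & (s_all + n_all - 1L) >= site[2]
    RT <- .RGAS * params@temperature

    pOpen <- numeric(length(sigmaGrid))
    for (i in seq_along(sigmaGrid)) {
        Etor <- .siddTorsional(seq_len(maxB), sigmaGrid[i], N, params)
        E <- pairing + Etor[n_all]
        Eclosed <- .siddTorsional(0, sigmaGrid[i], N, params)
        Emin <- min(Eclosed, min(E))
        w <- exp(-(E - Emin) / RT)
        Z <- sum(w) + exp(-(Eclosed - Emin) / RT)
        pOpen[i] <- sum(w[covers]) / Z
    }
    dg <- -RT * log(pOpen / (1 - pOpen))
    capped <- !is.finite(dg) | abs(dg) > params@dgCap
    dg[capped] <- sign(0.5 - pOpen[capped]) * params@dgCap
    if (any(capped))
        warning(sum(capped), " grid point(s) capped at |dG| = ",
                params@dgCap, " kcal/mol", call. = FALSE)
    new("MeltingProfile", sigma = as.numeric(sigmaGrid),
        dGopen = as.numeric(dg), pOpen = pmin(pmax(pOpen, 0), 1),
        capped = capped, site = site)
}

#' Per-base opening probability
#'
#' Probability, at a single superhelical density, that each base of the
#' sequence lies inside the denatured run. Useful to locate which bases
#' destabilize first (typically AT-rich islands) as stress grows.
#'
#' @param sequence DNA sequence
#' @param sigma a single superhelical density
#' @param params a \linkS4class{SIDDParameters}
#' @return numeric vector of per-base opening probabilities
#' @export
baseOpeningProbability <- function(sequence, sigma,
                                   params = siddParameters()) {
    st <- siddStates(sequence, sigma, params)
    N <- length(.siddCheckSequence(sequence))
    d <- numeric(N + 1L)
    open <- st[st$n > 0L, , drop = FALSE]
    for (k in seq_len(nrow(open))) {
        d[open$s[k]] <- d[open$s[k]] + open$prob[k]
        d[open$s[k] + open$n[k]] <- d[open$s[k] + open$n[k]] - open$prob[k]
    }
    cumsum(d)[seq_len(N)]
}

#' Fit the sigmoidal opening model to a melting profile
#'
#' Least-squares fit of
#' \eqn{\Delta G(\sigma) = q + v\sigma + m\Lambda((\sigma-\sigma_c)/w)}
#' (\eqn{\Lambda} the standard logistic) to the non-capped points of a
#' melting profile. The profile should cover both plateaus of the
#' crossover. The residual norm is attached as attribute \code{"rss"}.
#'
#' @param profile a \linkS4class{MeltingProfile}, or a data.frame with
#'   columns \code{sigma} and \code{dGopen} (optionally \code{capped})
#' @return a \linkS4class{SigmoidOpening}; attribute \code{"rss"} holds
#'   the residual sum of squares
#' @export
fitSigmoid <- function(profile) {
    df <- if (is(profile, "MeltingProfile")) as.data.frame(profile)
          else as.data.frame(profile)
    if (is.null(df$capped)) df$capped <- FALSE
    df <- df[!df$capped & is.finite(df$dGopen), , drop = FALSE]
    if (nrow(df) < 6L)
        .stopf("need at least 6 usable (sigma, dGopen) points to fit")
    df <- df[order(df$sigma), ]
    dg <- df$dGopen; sg <- df$sigma
    dglo <- min(dg); dghi <- max(dg)
    if (dghi - dglo < 1e-6)
        .stopf("profile is flat; no crossover to fit")
    mid <- (dglo + dghi) / 2
    sigmaC0 <- sg[which.min(abs(dg - mid))]
    start <- list(q = dglo, v = 0, m = dghi - dglo, sigmaC = sigmaC0,
                  w = diff(range(sg)) / 10)
    fit <- tryCatch(
        minpack.lm::nlsLM(
            dg ~ q + v * sg + m * plogis((sg - sigmaC) / w),
            start = start,
            lower = c(q = -Inf, v = -Inf, m = -Inf, sigmaC = -Inf,
                      w = 1e-6),
            control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) e)
    if (inherits(fit, "error")) {
        ## fall back to direct least squares on the same objective
        obj <- function(p) {
            w <- abs(p[5]) + 1e-6
            sum((dg - (p[1] + p[2] * sg +
                       p[3] * plogis((sg - p[4]) / w)))^2)
        }
        op <- stats::optim(unlist(start), obj,
                           control = list(maxit = 5000, reltol = 1e-14))
        if (op$convergence != 0)
            .stopf("sigmoid fit failed to converge (nls error: %s; optim code %d)",
                   conditionMessage(fit), op$convergence)
        p <- op$par
        out <- sigmoidOpening(sigmaC = p[4], w = abs(p[5]) + 1e-6,
                              m = p[3], v = p[2], q = p[1])
        attr(out, "rss") <- op$value
        return(out)
    }
    p <- coef(fit)
    out <- sigmoidOpening(sigmaC = p["sigmaC"], w = p["w"], m = p["m"],
                          v = p["v"], q = p["q"])
    attr(out, "rss") <- sum(stats::residuals(fit)^2)
    out
}

#' @describeIn openingEnergy closed-form sigmoid evaluation
#' @export
setMethod("openingEnergy", signature(sigma = "numeric",
                                     model = "SigmoidOpening"),
    function(sigma, model) {
        model@q + model@v * sigma +
            model@m * plogis((sigma - model@sigmaC) / model@w)
    })

#' @describeIn openingEnergy linear interpolation of a computed melting
#'   profile (non-capped points; constant extrapolation beyond the grid)
#' @export
setMethod("openingEnergy", signature(sigma = "numeric",
                                     model = "MeltingProfile"),
    function(sigma, model) {
        ok <- !model@capped
        if (sum(ok) < 2L)
            .stopf("melting profile has fewer than 2 usable points")
        stats::approx(model@sigma[ok], model@dGopen[ok], xout = sigma,
                      rule = 2)$y
    })

#' Export a melting profile to TSV
#'
#' @param profile a \linkS4class{MeltingProfile}
#' @param path output file
#' @return invisibly, the path
#' @export
writeMeltingProfile <- function(profile, path) {
    write.table(as.data.frame(profile), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
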