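## Torsion field generated by transcribed genes.
##
## A transcribing polymerase acts as a torsional motor: positive
## superhelical stress accumulates ahead of the transcription unit (in the
## direction of transcription) and negative stress behind it.  Outside the
## unit the time-averaged stress decays exponentially with distance, with a
## decay length b set by topoisomerase efficiency; the amplitude at the
## unit edges is sigma_a = alpha * k * l, proportional to expression rate
## and transcript length.

#' Build transcription units
#'
#' Transcription units are represented as a \link[GenomicRanges]{GRanges}
#' (1-based, inclusive coordinates) with a \code{rate} metadata column; the
#' TSS of a unit is its \code{start} on the plus strand and its \code{end}
#' on the minus strand.
#'
#' @param id character ids (used as names)
#' @param start,end 1-based inclusive genomic coordinates, start <= end
#' @param strand "+" or "-"
#' @param rate expression rate (arbitrary units, >= 0)
#' @param seqname chromosome name (recycled)
#' @return a GRanges with metadata column \code{rate}
#' @examples
#' transcriptionUnits("geneA", 1, 1000, "+", rate = 1)
#' @export
transcriptionUnits <- function(id, start, end, strand, rate,
                               seqname = "chr") {
    if (length(start) == 0L) {
        gr <- GenomicRanges::GRanges()
        gr$rate <- numeric(0)
        return(gr)
    }
    gr <- GenomicRanges::GRanges(
        seqnames = seqname,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand)
    names(gr) <- id
    gr$rate <- as.numeric(rate)
    v <- validateUnits(gr)
    if (!isTRUE(v)) .stopf("invalid transcription units: %s", v)
    gr
}

## Returns TRUE or a character message.
validateUnits <- function(units) {
    if (!is(units, "GRanges")) return("units must be a GRanges")
    if (is.null(units$rate)) return("units need a 'rate' metadata column")
    if (any(!is.finite(units$rate)) || any(units$rate < 0))
        return("rates must be finite and >= 0")
    if (any(GenomicRanges::width(units) < 1))
        return("units must have width >= 1")
    if (any(!as.character(GenomicRanges::strand(units)) %in% c("+", "-")))
        return("strand must be '+' or '-'")
    TRUE
}

#' Transcription start sites of units
#'
#' @param units a GRanges (strand "+" or "-")
#' @return integer vector of TSS positions (start for "+", end for "-")
#' @export
tssOf <- function(units) {
    s <- as.character(GenomicRanges::strand(units))
    ifelse(s == "+", GenomicRanges::start(units),
           GenomicRanges::end(units))
}

## Edge amplitude sigma_a = alpha * k * l of each unit.
.unitAmplitude <- function(units, params) {
    params@alpha * units$rate * GenomicRanges::width(units)
}

#' Superhelical-density perturbation of a single transcribed unit
#'
#' Evaluates the signed perturbation \eqn{\Delta\sigma(x)} generated by one
#' transcription unit at positions \code{x}:
#' \eqn{+\sigma_a e^{-d/b}} downstream of the 3' end (ahead of the
#' polymerase) and \eqn{-\sigma_a e^{-d/b}} upstream of the TSS, with
#' \eqn{d} the number of bases between \code{x} and the nearer unit edge
#' and \eqn{\sigma_a = \alpha k l}. Inside the unit the value is a linear
#' interpolation between \eqn{-\sigma_a} at the TSS edge and
#' \eqn{+\sigma_a} at the 3' edge (used only for plotting continuous
#' profiles; the coupling model never consumes interior values).
#'
#' @param unit a single-element GRanges with a \code{rate} column
#' @param x numeric vector of genomic positions (1-based)
#' @param params a \linkS4class{TorsionParameters}
#' @return numeric vector of perturbations, same length as \code{x}
#' @examples
#' u <- transcriptionUnits("g", 1, 1000, "+", rate = 1)
#' perturbationAt(u, 2501, torsionParameters())  # d = 1500 downstream
#' @export
perturbationAt <- function(unit, x, params) {
    stopifnot(is(params, "TorsionParameters"))
    v <- validateUnits(unit)
    if (!isTRUE(v)) .stopf("invalid transcription unit: %s", v)
    if (length(unit) != 1L)
        .stopf("'unit' must contain exactly one transcription unit")
    s <- GenomicRanges::start(unit)
    e <- GenomicRanges::end(unit)
    plus <- as.character(GenomicRanges::strand(unit)) == "+"
    sa <- .unitAmplitude(unit, params)

    out <- numeric(length(x))
    left <- x < s
    right <- x > e
    inside <- !left & !right
    ## signed value at the left (d) and right (u) flank for a plus-strand
    ## gene; minus strand flips the sign
    sgn <- if (plus) 1 else -1
    out[left] <- -sgn * sa * exp(-(s - x[left] - 1) / params@b)
    out[right] <- sgn * sa * exp(-(x[right] - e - 1) / params@b)
    if (any(inside)) {
        f <- if (e > s) (x[inside] - s) / (e - s) else 0.5
        out[inside] <- sgn * sa * (2 * f - 1)
    }
    out
}

#' Superhelical density field of several transcribed units
#'
#' Additive superposition of the per-unit perturbations on top of the
#' basal superhelical density: \eqn{\sigma(x) = \sigma_0 + \sum_u
#' \Delta\sigma_u(x)}. An empty unit list returns \eqn{\sigma_0}.
#'
#' @param units a GRanges of transcription units (possibly empty)
#' @param x numeric vector of genomic positions
#' @param params a \linkS4class{TorsionParameters}
#' @return superhelical density at each position
#' @export
fieldAt <- function(units, x, params) {
    stopifnot(is(params, "TorsionParameters"))
    sigma <- rep(params@sigma0, length(x))
    for (i in seq_along(units))
        sigma <- sigma + perturbationAt(units[i], x, params)
    sigma
}

#' Torsion profile on a regular grid
#'
#' Evaluates \code{\link{fieldAt}} on a regular position grid, the standard
#' way to visualise the asymmetric stress lobes around a transcribed gene
#' (above \eqn{\sigma_0} downstream, below upstream).
#'
#' @param units a GRanges of transcription units
#' @param interval numeric length-2 vector, grid limits (inclusive)
#' @param step grid step in bp (>= 1)
#' @param params a \linkS4class{TorsionParameters}
#' @return a data.frame with columns \code{position} and \code{sigma}
#' @examples
#' u <- transcriptionUnits("g", 5001, 6000, "+", rate = 1)
#' pr <- torsionProfile(u, c(1000, 10000), 50, torsionParameters())
#' @export
torsionProfile <- function(units, interval, step = 10, params) {
    if (length(interval) != 2L || !all(is.finite(interval)) ||
        interval[2] < interval[1])
        .stopf("'interval' must be a finite, non-empty [from, to] pair")
    if (step < 1) .stopf("'step' must be >= 1")
    pos <- seq(interval[1], interval[2], by = step)
    data.frame(position = pos, sigma = fieldAt(units, pos, params))
}

#' Plot a torsion profile
#'
#' @param profile data.frame from \code{\link{torsionProfile}}
#' @param units optional GRanges; unit extents are drawn as grey boxes
#' @param ... passed to \code{plot}
#' @return invisibly, the profile
#' @export
plotTorsionProfile <- function(profile, units = NULL, ...) {
    graphics::plot(profile$position, profile$sigma, type = "l",
                   xlab = "position (bp)",
                   ylab = expression(sigma), ...)
    if (!is.null(units) && length(units))
        graphics::rect(GenomicRanges::start(units),
                       graphics::par("usr")[3],
                       GenomicRanges::end(units),
                       graphics::par("usr")[4],
                       col = grDevices::adjustcolor("grey", 0.3),
                       border = NA)
    invisible(profile)
}
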