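## Physical constants and small shared helpers.

## Gas constant in kcal mol^-1 K^-1 (energies are in kcal/mol throughout,
## so k_B T_e is expressed as R * Te).
.RGAS <- 1.987204e-3

## Exponent cap guarding exp() against overflow in rate evaluations.
.EXP_CAP <- 500

.cappedExp <- function(x) {
    capped <- abs(x) > .EXP_CAP
    if (any(capped)) {
        x <- pmin(pmax(x, -.EXP_CAP), .EXP_CAP)
        warning("exponent capped at +/-", .EXP_CAP,
                " in rate evaluation", call. = FALSE)
    }
    exp(x)
}

## Evaluate an expression with a locally seeded RNG, restoring (or
## removing) the caller's RNG state afterwards: generators stay pure
## functions of (spec, seed) without clobbering the session RNG.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
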