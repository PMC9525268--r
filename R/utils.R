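# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generation is a pure function
# of its arguments.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fill values at coordinates `outX` from observed points (obsX, obsV):
# piecewise-linear pass-through interpolation strictly inside the
# observed range, least-squares-line extrapolation outside it, constant
# if a single point is observed. With lsEverywhere = TRUE the
# least-squares line is used at every coordinate.
linearImputeAt <- function(obsX, obsV, outX, lsEverywhere = FALSE) {
    stopifnot(length(obsX) == length(obsV), length(obsX) >= 1)
    if (length(obsX) == 1) return(rep(obsV, length(outX)))
    fit <- stats::lm.fit(cbind(1, obsX), obsV)
    line <- fit$coefficients[1] + fit$coefficients[2] * outX
    if (lsEverywhere) return(line)
    out <- line
    inside <- outX >= min(obsX) & outX <= max(obsX)
    if (any(inside))
        out[inside] <- stats::approx(obsX, obsV, xout = outX[inside],
                                     ties = mean)$y
    out
}
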