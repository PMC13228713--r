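## Internal helpers shared across modules.

## Run expr with a mandatory, explicit seed; the caller's RNG state is
## restored afterwards so no global state leaks between calls.
withSeed <- function(seed, expr) {
    if (missing(seed) || is.null(seed) || length(seed) != 1L ||
        !is.finite(seed))
        stop("an explicit integer 'seed' is required (reproducibility is mandatory)")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

## Derive a stream-specific child seed from a master seed, kept within
## 32-bit integer range.
childSeed <- function(seed, stream) {
    (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) %% 1009L
}

.assertScalar <- function(x, name) {
    if (length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name))
    invisible(x)
}

## Default cartilage region dictionary: the six load-bearing regions of
## the knee analysis, after background (0) and bone (1).
defaultLabelDict <- function() {
    c(background = 0L, bone = 1L,
      medial_femur = 2L, medial_tibia = 3L,
      lateral_femur = 4L, lateral_tibia = 5L,
      patella = 6L, trochlea = 7L)
}
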