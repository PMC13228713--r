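#' Mono-exponential spin-echo signal model
#'
#' The forward model of the T2 decay: \eqn{S(TE) = PD \exp(-TE/T2)},
#' with an optional multiplicative inflation of the first echo that
#' mimics the stimulated-echo artifact of multi-echo spin-echo trains
#' (the reason the first echo is excluded from the decay fit).
#'
#' @param pd proton density, the signal amplitude at TE = 0 (arbitrary
#'   intensity units, >= 0).
#' @param t2 transverse relaxation time (ms, > 0).
#' @param te echo time(s) (ms, >= 0); vectorized.
#' @param alpha first-echo inflation factor (>= 1); applied only where
#'   \code{echoIndex == 1}.
#' @param echoIndex 1-based echo position(s), recycled against
#'   \code{te}.
#' @return signal intensity, same length as \code{te}.
#' @examples
#' signalModel(1000, 50, te = 0)            # 1000
#' signalModel(1000, 50, te = 50)           # 1000 * exp(-1)
#' signalModel(1000, 50, te = 11.1, alpha = 1.1, echoIndex = 1)
#' @export
signalModel <- function(pd, t2, te, alpha = 1, echoIndex = 2L) {
    .assertScalar(pd, "pd"); .assertScalar(t2, "t2")
    .assertScalar(alpha, "alpha")
    if (t2 <= 0)
        stop("'t2' must be strictly positive")
    if (pd < 0)
        stop("'pd' must be non-negative")
    if (any(te < 0))
        stop("'te' must be non-negative")
    if (alpha < 1)
        stop("'alpha' must be >= 1")
    s <- pd * exp(-te / t2)
    first <- rep_len(echoIndex, length(s)) == 1L
    s[first] <- s[first] * alpha
    s
}
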