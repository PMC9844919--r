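#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis qnorm rnorm runif rbinom sd uniroot
#' @importFrom utils head
NULL

## numerical zero on the standardized-coefficient scale; shared by the
## fitting, ranking and selection modules
.svrs_zero_tol <- 1e-10

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single master seed; sub-streams
#' (per balanced sample, per fit, per permuted column) use seeds derived by a
#' fixed arithmetic rule so results are independent of scheduling or worker
#' count. The result always lies in `[0, 2^31 - 2]`.
#'
#' @param base integer master seed.
#' @param offset integer stream index (>= 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(base, offset) {
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base),
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  ## affine hash mod the Mersenne prime 2^31 - 1; products stay < 2^53
  s <- (abs(as.numeric(base)) %% 2147483647) * 48271 + as.numeric(offset) * 16807 + 1
  as.integer(s %% 2147483647)
}

## run expr under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  ## force the seed promise first: if its evaluation draws from the caller's
  ## stream (e.g. seed = sample.int(...)), the draw must advance that stream
  ## before we snapshot it, or two consecutive such calls would repeat a seed
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("svrs_invalid_argument", "error")))
}

stop_convergence <- function(msg) {
  stop(errorCondition(msg, class = c("svrs_convergence_failure", "error")))
}
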