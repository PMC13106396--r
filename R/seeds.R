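#' Derive a named substream seed from a master seed
#'
#' All randomness in the toolkit is routed through named substreams so that
#' every stochastic stage (feature draws, outcome draws, splitting,
#' permutation, cross-validation folds, the sensitivity sweep) is
#' reproducible from one master seed, and adding a stage never perturbs the
#' draws of another.
#'
#' The substream seed is a deterministic function of the master seed, the
#' component name and an optional index; it always lies in
#' \code{[0, 2^31 - 2]} so it is a valid \code{set.seed()} argument.
#'
#' @param master integer master seed.
#' @param name character scalar naming the component (e.g. "features").
#' @param index optional non-negative integer for indexed substreams
#'   (e.g. one per sweep grid point or replicate).
#' @return An integer seed.
#' @examples
#' substream_seed(42, "features")
#' substream_seed(42, "outcome", index = 3)
#' @export
substream_seed <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(name), length(name) == 1L, nchar(name) > 0L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147480009 # largest prime below 2^31 - 3000; keeps products exact in doubles
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% m
  s <- (((abs(master) %% m) * 48271) %% m + h * 69621 + index * 16807) %% m
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores \code{.Random.seed} so seeded internals do not disturb
#' the caller's random number stream.
#'
#' @param seed integer seed for the expression.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
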