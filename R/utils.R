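# Internal helpers shared across modules.

#' @importFrom stats rnorm runif sd aggregate rgamma rbinom fft mvfft
#' @importFrom stats anova t.test cor.test qnorm pf pt complete.cases setNames
#' @importFrom utils write.table read.table head
NULL

ft_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "fpvstag_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state so that simulation helpers do not perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject seed stream; kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1299709) %% 2147483647)
}

# Rational greatest common divisor for stimulation rates such as 6 and 7.5 Hz.
# Rates are scaled to integers (1e4 resolution), reduced with Euclid's
# algorithm, and mapped back.
rational_gcd <- function(a, b, scale = 1e4) {
  ia <- round(a * scale); ib <- round(b * scale)
  if (abs(ia - a * scale) > 1e-6 || abs(ib - b * scale) > 1e-6)
    ft_stop("rates must be expressible with 1e-4 Hz resolution", "ft_design_error")
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  g(ia, ib) / scale
}

is_multiple_of <- function(x, base, tol = 1e-8) {
  abs(x / base - round(x / base)) < tol
}
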