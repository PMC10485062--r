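# internal helpers

#' @importFrom rlang .data .env
#' @importFrom stats rnorm runif lm predict coef pf sd setNames complete.cases
#' @importFrom utils head
NULL

# first-order autocorrelated gaussian noise with stationary sd `sd`
ar1_noise <- function(n, sd = 1, phi = 0.7) {
  if (sd == 0 || n == 0) return(numeric(n))
  eps <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + eps[i]
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a stream of child seeds from one master seed, kept < 2^31
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + salt + 1000003L * seq_len(n)) %% 2147483647L
}

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)
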