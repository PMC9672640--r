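# Internal helpers shared across modules.

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid("'", name, "' must be TRUE or FALSE")
  x
}

#' Derive a named sub-seed from a top-level seed
#'
#' All stochastic stages (splitting, parameter initialization, mini-batch
#' shuffling, synthetic cohorts) draw their seed from one top-level seed via
#' this deterministic fan-out, so a single integer reproduces an entire run
#' while the stages remain independent of each other.
#'
#' @param seed integer top-level seed.
#' @param what character tag naming the consumer (e.g. `"split"`, `"init"`).
#' @return An integer in `[0, 2^31)` suitable for [set.seed()].
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "init")
#' @export
derive_seed <- function(seed, what) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("'seed' must be a single finite number")
  if (!is.character(what) || length(what) != 1L)
    stop_invalid("'what' must be a single string")
  u <- utf8ToInt(what)
  h <- sum(u * seq_along(u)) %% 65521
  # keep every intermediate below 2^31 (R integers are 32-bit)
  as.integer((abs(seed) %% 65011 * 32749 + h * 4099 + 211) %% 2147483629)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "f")
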