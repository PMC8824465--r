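# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and a stage name
#'
#' All randomness in the package flows from one integer seed. Each generator
#' stage draws from its own substream so that adding sweeps to one pair does
#' not perturb another. The derived seed is a deterministic 31-bit hash of the
#' master seed and the stage label.
#'
#' @param seed master integer seed
#' @param name character stage label
#' @return an integer seed below 2^31
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(name)) {
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# round a time (ms) to the nearest sample index offset
ms_to_samples <- function(ms, dt_s) {
  as.integer(round(ms / 1000 / dt_s))
}

stop_if_not_scalar_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
}
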