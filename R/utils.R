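#' @keywords internal
"_PACKAGE"

# Argument checking helpers -----------------------------------------------

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("`%s` must be a single finite number", name))
  abort_if(x < lower || x > upper,
           sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  abort_if(x != round(x), sprintf("`%s` must be an integer count", name))
  invisible(as.integer(x))
}

#' Derive a child seed from a master seed
#'
#' Pipeline stages and per-subject simulations each receive their own seed so
#' that any stage can be re-run in isolation and still reproduce its output.
#' Child seeds are derived with a fixed multiplicative hash of the master seed
#' and a stream index, reduced modulo a Mersenne prime below 2^31.
#'
#' @param seed master seed (integer).
#' @param stream stream index (integer >= 0), e.g. a stage or subject number.
#' @return an integer seed in [0, 2^31 - 2], deterministic in (seed, stream).
#' @export
child_seed <- function(seed, stream) {
  check_scalar_number(seed, "seed")
  check_scalar_number(stream, "stream", lower = 0)
  m <- 2147483647               # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  # two rounds of multiplicative hashing in double precision (exact below 2^53)
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(stream) + 1) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
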