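# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' that every stochastic stage is reproducible without clobbering the global
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Residual sum of squares per response column for a fixed design QR.
qr_rss <- function(qrX, Y) {
  colSums(qr.resid(qrX, Y)^2)
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
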