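# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that independent stages (MP sampling, noise resampling,
#' simulation) draw from decorrelated but reproducible streams.
#' @noRd
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) %% 50021) * 40009 + h) %% 2147483629L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_phiclust <- function(...) stop(..., call. = FALSE)
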