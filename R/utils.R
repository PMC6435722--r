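# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic rounding used wherever the pipeline converts a fractional
#' count into an integer (methylated-cell counts, half-coverage filters).
#' Unlike [base::round()], which rounds half to even, `round_half_up(0.5)`
#' is `1` on every platform.
#'
#' @param x numeric vector.
#' @return integer vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.49, 13.5, 14.5))
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive a named substream seed from a master seed
#'
#' Every stochastic stage draws from its own named substream derived from a
#' single master seed, so adding or reordering stages never perturbs the
#' draws of another stage. The derivation is a simple integer hash of the
#' stream name mixed with the master seed, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the substream.
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 1009)
  as.integer((abs(seed) * 48271 + h * 7919 + 12345) %% 2147483629)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

stop_if_not_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}
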