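## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  force(expr)
}

## base-2 log that maps non-positive arguments to -Inf instead of NaN.
## The screen's subset_1 term can go negative by construction; the score
## contract is that such terms force the minimal possible score.
log2_floor <- function(x) {
  out <- rep(-Inf, length(x))
  pos <- x > 0
  out[pos] <- log2(x[pos])
  if (is.matrix(x)) {
    dim(out) <- dim(x)
    dimnames(out) <- dimnames(x)
  }
  out
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is out of range", name, x), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
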