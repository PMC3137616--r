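#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All exported stochastic operations funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log-sum-exp of a matrix (sites x classes) plus per-class log weights.
row_logsumexp <- function(logl, logw) {
  x <- logl + rep(logw, each = nrow(logl))
  m <- do.call(pmax, lapply(seq_len(ncol(x)), function(j) x[, j]))
  m + log(.rowSums(exp(x - m), nrow(x), ncol(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
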