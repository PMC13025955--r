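#' @keywords internal
"_PACKAGE"

#' Logistic and logit transforms
#'
#' `expit()` maps log-odds to probabilities; `logit()` is its inverse.
#'
#' @param x numeric vector.
#' @param p probabilities in (0, 1).
#' @return numeric vector.
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' @rdname expit
#' @export
logit <- function(p) log(p / (1 - p))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a child seed from a parent seed and a stage tag; keeps independent
## stages on independent, reproducible streams. Result < 2^31.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

check_rate <- function(x, name) {
  if (is.null(x) || length(x) == 0L) return(invisible(numeric(0)))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must be in [0, 1]", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ELU activation (alpha = 1) and its derivative given the pre-activation.
elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(x) {
  g <- array(1, dim(x) %||% length(x))
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g
}

## Row-wise softmax over the columns of a matrix.
softmax_rows <- function(m) {
  rmax <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) rmax <- pmax(rmax, m[, j])
  e <- exp(m - rmax)
  e / rowSums(e)
}
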