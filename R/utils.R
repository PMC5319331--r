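#' @importFrom stats plogis qlogis rnorm rpois rbinom runif dpois glm glm.fit
#'   binomial poisson coef vcov logLik predict lm uniroot sd var quantile
#'   setNames eigen na.omit aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so callers can test failure modes programmatically.
ss_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("sproutess_", class), "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ss_warn <- function(class, msg) {
  warning(structure(
    class = c(paste0("sproutess_", class), "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from one master seed. Stages
#' (climate generation, individual simulation, stochastic projection,
#' bootstrap replicates) derive their own sub-seed with a counter/label
#' scheme so that each stage is independently reproducible and changing
#' one stage does not perturb the draws of another.
#'
#' @param seed Integer master seed.
#' @param label Character label of the consuming stage.
#' @param counter Optional non-negative integer counter (e.g. replicate id).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, label, counter = 0L) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 131) %% 1000003
  m <- 2147483587
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + h + 7919 * as.numeric(counter)) %% m
  as.integer(s) + 1L
}

## run expr with a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## numerically-safe truncated Poisson draw on {1..max_size}
rtpois <- function(n, lambda, max_size) {
  p <- outer(lambda, seq_len(max_size), function(l, k) dpois(k, l))
  s <- rowSums(p)
  zero <- s <= 0
  if (any(zero)) { # lambda ~ 0: all conditional mass at k = 1
    p[zero, ] <- 0
    p[zero, 1] <- 1
    s[zero] <- 1
  }
  p <- p / s
  cp <- t(apply(p, 1, cumsum))
  u <- runif(n)
  k <- rowSums(u > cp) + 1L
  pmin(k, max_size)
}
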