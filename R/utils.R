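#' Derive a reproducible child seed
#'
#' Expands a single user-facing seed into independent per-stage seeds via a
#' fixed counter scheme, so each pipeline stage (and each probe's permutation
#' stream) can be re-run in isolation and still match the full run.
#'
#' The scheme is `(seed * 2654435761 + stage * 97 + index) mod (2^31 - 1)`,
#' a Knuth-style multiplicative hash kept inside the 32-bit signed range.
#'
#' @param seed integer master seed.
#' @param stage integer stage number (each caller uses a fixed constant).
#' @param index integer counter within a stage (e.g. probe index), default 0.
#' @return a single integer usable with [set.seed()].
#' @export
child_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * (2654435761 %% m) %% m
  as.integer((x + as.numeric(stage) * 97 + as.numeric(index)) %% m)
}

#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to normal scores `qnorm((rank - 3/8) / (n + 1/4))`
#' (Blom offset), with average ranks for ties. Invariant to any strictly
#' monotone transform of the input.
#'
#' @param x numeric vector (NAs preserved in place).
#' @return numeric vector of normal scores, mean ~0 and variance ~1.
#' @export
rint <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

# Beta(a,b) maximum likelihood on (0,1) data: Newton iterations on the
# digamma score equations, initialized at method-of-moments. Falls back to
# the MoM estimate (with a warning) if Newton fails to converge.
fit_beta_mle <- function(x, max_iter = 200L, tol = 1e-10) {
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x)
  v <- stats::var(x)
  v <- min(v, m * (1 - m) * (1 - 1e-8)) # MoM needs v < m(1-m)
  k <- m * (1 - m) / v - 1
  theta <- c(m * k, (1 - m) * k) # (shape1, shape2) at method-of-moments
  mom <- theta
  g1 <- mean(log(x))
  g2 <- mean(log1p(-x))
  for (i in seq_len(max_iter)) {
    a <- theta[1]; b <- theta[2]
    dg <- digamma(a + b)
    score <- c(g1 - digamma(a) + dg, g2 - digamma(b) + dg)
    tg <- trigamma(a + b)
    hess <- matrix(c(-trigamma(a) + tg, tg, tg, -trigamma(b) + tg), 2, 2)
    step <- tryCatch(solve(hess, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      warning("beta MLE Newton failed; falling back to method-of-moments")
      return(list(shape1 = mom[1], shape2 = mom[2], converged = FALSE))
    }
    new <- theta - step
    # keep shapes positive; dampen if Newton overshoots
    while (any(new <= 0)) {
      step <- step / 2
      new <- theta - step
    }
    if (max(abs(new - theta)) < tol * max(1, max(abs(theta)))) {
      return(list(shape1 = new[1], shape2 = new[2], converged = TRUE))
    }
    theta <- new
  }
  warning("beta MLE did not converge; falling back to method-of-moments")
  list(shape1 = mom[1], shape2 = mom[2], converged = FALSE)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# two-sided normal p-value from a z statistic
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))
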