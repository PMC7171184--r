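#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a multi-stage run flows from one root seed; each
#' stage draws its own 32-bit sub-seed from the root via a fixed hash, so
#' stages are individually reproducible and reordering one stage does not
#' perturb another.
#'
#' @param seed root seed (integer below 2^31).
#' @param stage stage name, e.g. \code{"cohort"}.
#' @return An integer seed in [0, 2^31).
#' @export
subSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483647)
}

# vectorized truncated-normal draws by inverse CDF; zero-width or zero-sd
# intervals collapse to the point value
rtruncnorm <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  out <- mean
  ok <- sd > 0 & upper > lower
  if (any(ok)) {
    pa <- stats::pnorm(lower[ok], mean[ok], sd[ok])
    pb <- stats::pnorm(upper[ok], mean[ok], sd[ok])
    u <- stats::runif(sum(ok), pa, pb)
    out[ok] <- stats::qnorm(u, mean[ok], sd[ok])
  }
  pmin(pmax(out, lower), upper)
}

# weighted quantiles of type "step" (inverse of the weighted ECDF)
weightedQuantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# weighted mean/sd helpers
weightedSd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
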