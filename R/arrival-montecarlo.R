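#' Weighted Gaussian kernel density estimate
#'
#' Plain weighted KDE with a Gaussian kernel, renormalized by the
#' trapezoid rule so the density integrates to 1 over the evaluation grid
#' (to within 1e-6).  The automatic bandwidth is Silverman's rule applied
#' to the weighted sd / IQR with the weight-effective sample size
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}.
#'
#' @param x sample values (>= 2).
#' @param w positive weights (recycled if length 1).
#' @param bandwidth kernel sd; \code{NULL} for automatic.  All-equal
#'   samples make the automatic bandwidth degenerate and are an error
#'   unless a bandwidth is supplied.
#' @param grid evaluation grid; default 512 points spanning
#'   \code{range(x)} plus 3 bandwidths.
#' @return list with \code{x} (grid), \code{y} (density),
#'   \code{bandwidth}, \code{mode} (grid point of maximum density).
#' @export
weightedKDE <- function(x, w = 1, bandwidth = NULL, grid = NULL) {
  if (length(x) < 2) stop("need >= 2 samples")
  w <- rep_len(w, length(x))
  if (any(w <= 0) || any(!is.finite(w))) stop("weights must be positive")
  if (is.null(bandwidth)) {
    neff <- sum(w)^2 / sum(w^2)
    sdw <- weightedSd(x, w)
    iqrw <- diff(weightedQuantile(x, w, c(0.25, 0.75)))
    spread <- min(sdw, iqrw / 1.34)
    if (spread == 0) spread <- sdw
    bandwidth <- 0.9 * spread * neff^(-1 / 5)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      stop("degenerate bandwidth (all samples equal); supply `bandwidth`")
  }
  if (is.null(grid))
    grid <- seq(min(x) - 3 * bandwidth, max(x) + 3 * bandwidth,
                length.out = 512)
  y <- vapply(grid, function(g)
    sum(w * stats::dnorm(g - x, sd = bandwidth)), numeric(1)) / sum(w)
  dx <- diff(grid)
  area <- sum(dx * (y[-1] + y[-length(y)]) / 2)
  y <- y / area
  list(x = grid, y = y, bandwidth = bandwidth, mode = grid[which.max(y)])
}

#' Monte Carlo arrival-time estimation under radiocarbon uncertainty
#'
#' Repeats [sampleDates()] + [fitArrival()] \code{nReps} times; retains
#' only repetitions that converged with a positive-definite Hessian; and
#' summarizes the retained jump times with a weighted KDE.  Repetition i
#' gets weight \code{exp(rss_min - rss_i)} where \code{rss_min} is the
#' smallest retained RSS, so the best repetition has weight 1 — the ratio
#' of exponentiated residual sums of squares.  With
#' \code{weightMode = "scaled"} the exponent is divided by
#' \code{2 * sigma2} with \code{sigma2 = rss_min / n_used}, the
#' likelihood-ratio form under a Gaussian residual model.
#'
#' @param cohort an \linkS4class{AncientCohort} (its individuals with an
#'   ancestry observation are used), or a data.frame with columns
#'   \code{steppe_prop}, \code{upper_bce}, \code{lower_bce}.
#' @param nReps repetitions (default 100000; scale down for quick runs).
#' @param seed root seed for the date resampling.
#' @param weightMode \code{"literal"} (default) or \code{"scaled"}.
#' @param nRestarts restarts per repetition fit (default 2; the base fit
#'   at interval midpoints, used as the per-repetition start, gets 5).
#' @param bandwidth,grid passed to [weightedKDE()].
#' @param zeroTol,zeroRule,teMargin passed to [fitArrival()].
#' @return An \linkS4class{ArrivalEstimate}.
#' @export
monteCarloArrival <- function(cohort, nReps = 100000, seed = 1,
                              weightMode = c("literal", "scaled"),
                              nRestarts = 2, bandwidth = NULL, grid = NULL,
                              zeroTol = 0, zeroRule = TRUE,
                              teMargin = NULL) {
  weightMode <- match.arg(weightMode)
  if (is(cohort, "AncientCohort")) {
    df <- individuals(cohort)
    df <- df[!is.na(df$steppe_prop), ]
  } else df <- cohort
  props <- df$steppe_prop
  upper <- df$upper_bce; lower <- df$lower_bce
  mid <- (upper + lower) / 2
  if (is.null(teMargin)) teMargin <- max(mean(upper - lower), 1)
  teBounds <- c(max(min(mid) - teMargin, 1), max(mid) + teMargin)

  base <- fitArrival(props, mid, teBounds = teBounds, zeroTol = zeroTol,
                     zeroRule = zeroRule, nRestarts = 5)
  start <- arrivalParams(base@params[["p0"]], base@params[["pe"]],
                         base@params[["te"]])

  set.seed(subSeed(seed, "arrival-mc"))
  te <- rss <- numeric(nReps)
  keep <- logical(nReps)
  nUsed <- integer(nReps)
  for (i in seq_len(nReps)) {
    d <- rtruncnorm(length(mid), mid, (upper - lower) / (2 * 1.959964),
                    lower, upper)
    f <- tryCatch(
      fitArrival(props, d, start = start, teBounds = teBounds,
                 zeroTol = zeroTol, zeroRule = zeroRule,
                 nRestarts = nRestarts),
      error = function(e) NULL)
    if (!is.null(f) && f@converged && f@hessianPD) {
      keep[i] <- TRUE
      te[i] <- f@params[["te"]]
      rss[i] <- f@rss
      nUsed[i] <- f@nUsed
    }
  }
  if (!any(keep))
    stop(sprintf(paste0(
      "no retained solutions in %d repetitions (all non-converged or ",
      "non-positive-definite Hessian); base fit rss = %.4g, te = %.0f"),
      nReps, base@rss, base@params[["te"]]))
  te <- te[keep]; rss <- rss[keep]; nUsed <- nUsed[keep]
  rssMin <- min(rss)
  wexp <- rssMin - rss
  if (weightMode == "scaled") {
    sigma2 <- rssMin / stats::median(nUsed)
    if (sigma2 > 0) wexp <- wexp / (2 * sigma2)
  }
  w <- exp(wexp)

  kde <- if (length(te) >= 2 && stats::sd(te) > 0)
    weightedKDE(te, w, bandwidth = bandwidth, grid = grid)
  else list(x = te[1], y = Inf, bandwidth = 0, mode = te[1])
  interval <- if (length(te) >= 2) weightedQuantile(te, w, c(0.025, 0.975))
              else rep(te[1], 2)
  new("ArrivalEstimate",
      teSamples = data.frame(te = te, rss = rss, weight = w),
      kde = data.frame(te = kde$x, density = kde$y),
      pointEstimate = kde$mode, interval = interval,
      nReps = as.integer(nReps), nRetained = as.integer(sum(keep)),
      bandwidth = kde$bandwidth, weightMode = weightMode)
}
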