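#' Steppe-ancestry trajectory: jump then exponential decline
#'
#' The modeled proportion is 0 for dates older than the jump time
#' \code{te}; at \code{te} it jumps to \code{pe} and then decays as the
#' unique pure exponential through \code{(te, pe)} and \code{(0, p0)}:
#' \deqn{f(t) = p_e \exp(-\lambda (t_e - t)), \quad
#'       \lambda = \log(p_e/p_0)/t_e}
#' for \code{t <= te} (the same exponential is extended to negative, i.e.
#' CE, dates).  Time is in years calBCE, increasing into the past.
#'
#' @param t date(s), years calBCE.
#' @param params an [arrivalParams()] vector (p0, pe, te).
#' @return Proportion(s) in [0, 1].
#' @examples
#' modelCurve(c(3000, 2750, 1375, 0), arrivalParams(0.1, 0.8, 2750))
#' @export
modelCurve <- function(t, params) {
  p0 <- params[["p0"]]; pe <- params[["pe"]]; te <- params[["te"]]
  lam <- log(pe / max(p0, 1e-300)) / te    # guard p0 underflow
  expo <- -lam * (te - t)
  expo[t == te] <- 0                       # Inf * 0 at the jump point
  ifelse(t > te, 0, pe * exp(expo))
}

#' Residual sum of squares with the zero-residual masking rule
#'
#' Zero-ancestry observations (proportion \code{<= zeroTol}) dated more
#' recently than the jump (\code{date < te}) contribute exactly zero
#' residual: such individuals are compatible with unadmixed parallel
#' groups persisting after the arrival, and letting them pull the curve
#' down would bias \code{pe} downward.  Zero-ancestry observations dated
#' before the jump lie on the zero branch and enter the sum normally
#' (where they contribute 0 anyway).
#'
#' @param params an [arrivalParams()] vector.
#' @param props observed steppe-ancestry proportions.
#' @param dates per-observation dates, years calBCE (same length).
#' @param zeroTol proportions \code{<=} this count as zero (default 0,
#'   matching upstream estimates pinned exactly at 0).
#' @param zeroRule apply the masking rule (default TRUE); FALSE gives the
#'   plain RSS for comparison.
#' @return list with \code{rss} and \code{nZeroMasked}.
#' @export
rssObjective <- function(params, props, dates, zeroTol = 0, zeroRule = TRUE) {
  if (!length(props)) stop("empty observation set")
  if (length(props) != length(dates))
    stop("props and dates must have equal length")
  fit <- modelCurve(dates, params)
  res2 <- (props - fit)^2
  mask <- if (zeroRule) props <= zeroTol & dates < params[["te"]]
          else rep(FALSE, length(props))
  list(rss = sum(res2[!mask]), nZeroMasked = sum(mask))
}

# search-space transform: theta unconstrained <-> (p0, pe, te) with
# 0 < p0 <= pe <= 1 and te in [lo, hi]
.theta2par <- function(theta, lo, hi) {
  pe <- stats::plogis(theta[2])
  c(p0 = pe * stats::plogis(theta[1]), pe = pe,
    te = lo + (hi - lo) * stats::plogis(theta[3]))
}
.par2theta <- function(p, lo, hi) {
  clamp <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)
  c(stats::qlogis(clamp(p[["p0"]] / p[["pe"]])),
    stats::qlogis(clamp(p[["pe"]])),
    stats::qlogis(clamp((p[["te"]] - lo) / (hi - lo))))
}

# central finite-difference Hessian of the masked RSS at the optimum,
# on scale-standardized parameters (p0, pe, te/1000): proportions are
# O(0.1) and te is O(1000) years, and without standardization the
# smallest eigenvalue sits below finite-difference noise.  Step 1e-4 of
# parameter scale.
.rssHessian <- function(par, props, dates, zeroTol, zeroRule) {
  scale <- c(1, 1, 1000)
  u0 <- unname(par) / scale
  f <- function(u) {
    p <- u * scale
    rssObjective(c(p0 = max(p[1], 1e-12), pe = max(p[2], 1e-12),
                   te = p[3]), props, dates,
                 zeroTol = zeroTol, zeroRule = zeroRule)$rss
  }
  h <- 1e-4 * pmax(abs(u0), 1)
  # the profile objective is piecewise constant in te between adjacent
  # observation dates, so curvature along te must be measured at the
  # resolution of the date design: use at least the mean date spacing.
  # A jump time stranded far from any observation then shows zero
  # curvature and is rightly rejected as unstable.
  spacing <- diff(range(dates)) / max(length(dates), 2)
  h[3] <- max(h[3], spacing / scale[3])
  H <- matrix(0, 3, 3)
  f0 <- f(u0)
  for (i in 1:3) {
    ei <- replace(numeric(3), i, h[i])
    H[i, i] <- (f(u0 + ei) - 2 * f0 + f(u0 - ei)) / h[i]^2
    if (i < 3) for (j in (i + 1):3) {
      ej <- replace(numeric(3), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(u0 + ei + ej) - f(u0 + ei - ej) -
         f(u0 - ei + ej) + f(u0 - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

# fixed jitter design for restarts: deterministic, no RNG consumed
.restartJitter <- rbind(
  c(0, 0, 0), c(1, 0.5, 0.5), c(-1, -0.5, -0.5),
  c(0.5, -1, 1), c(-0.5, 1, -1), c(1.5, 1, -0.5))

#' Fit the arrival model by bounded least squares
#'
#' Minimizes [rssObjective()] over \code{0 < p0 <= pe <= 1} and \code{te}
#' inside \code{teBounds}, using Nelder-Mead on a logistic-transformed
#' parameterization (which enforces the constraints exactly) with
#' deterministic jittered restarts, tie-broken by lowest RSS.  The default
#' start is \code{p0 = 0.1}, \code{pe = 0.8} and \code{te} equal to the
#' mean date of the observations with nonzero steppe ancestry.  Stability
#' is assessed by the finite-difference Hessian of the RSS at the optimum:
#' \code{hessianPD} is TRUE when all eigenvalues exceed \code{pdTol}.
#'
#' Because the zero-residual mask depends on \code{te}, the objective is
#' only piecewise-smooth; the derivative-free optimizer and the restarts
#' are there to cope with that.
#'
#' @param props,dates observed proportions and their dates (calBCE).
#' @param start optional [arrivalParams()] start; default per above.
#' @param teBounds length-2 box for te; default the observed date range
#'   widened by \code{teMargin}.
#' @param teMargin widening of the default te box, years (use the typical
#'   radiocarbon interval width of the cohort); default 5\% of the date
#'   span.
#' @param zeroTol,zeroRule passed to [rssObjective()].
#' @param nRestarts number of jittered restarts (0-5, default 5).
#' @param pdTol eigenvalue tolerance for positive-definiteness.
#' @return An \linkS4class{ArrivalFit}.
#' @examples
#' tru <- arrivalParams(0.1, 0.8, 2750)
#' d <- seq(4000, 1800, length.out = 50)
#' fitArrival(modelCurve(d, tru), d)
#' @export
fitArrival <- function(props, dates, start = NULL, teBounds = NULL,
                       teMargin = NULL, zeroTol = 0, zeroRule = TRUE,
                       nRestarts = 5, pdTol = 1e-8) {
  if (!length(props)) stop("empty observation set")
  nz <- props > zeroTol
  if (!any(nz))
    stop("unidentifiable: all steppe-ancestry proportions are zero")
  if (sum(nz) < 3)
    stop("unidentifiable: need >= 3 observations with nonzero ancestry")
  if (is.null(teMargin)) teMargin <- 0.05 * diff(range(dates))
  if (is.null(teBounds))
    teBounds <- c(max(min(dates) - teMargin, 1), max(dates) + teMargin)
  if (is.null(start))
    start <- arrivalParams(0.1, 0.8,
                           min(max(mean(dates[nz]), teBounds[1]), teBounds[2]))
  lo <- teBounds[1]; hi <- teBounds[2]
  obj <- function(theta) {
    p <- .theta2par(theta, lo, hi)
    rssObjective(p, props, dates, zeroTol = zeroTol, zeroRule = zeroRule)$rss
  }
  theta0 <- .par2theta(start, lo, hi)
  best <- NULL
  for (k in seq_len(min(nRestarts, nrow(.restartJitter) - 1) + 1)) {
    o <- stats::optim(theta0 + .restartJitter[k, ], obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # Nelder-Mead stalls on the pe/te ridge; restarting it from its own
  # endpoint rebuilds the simplex and polishes the optimum
  for (k in 1:8) {
    o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
    gain <- best$value - o$value
    if (o$value <= best$value) best <- o
    if (gain < 1e-14) break
  }
  par <- .theta2par(best$par, lo, hi)
  out <- rssObjective(par, props, dates, zeroTol = zeroTol,
                      zeroRule = zeroRule)
  converged <- best$convergence == 0L
  hpd <- FALSE
  if (converged) {
    H <- .rssHessian(par, props, dates, zeroTol, zeroRule)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    hpd <- all(is.finite(ev)) && all(ev > pdTol)
  }
  new("ArrivalFit", params = par, rss = out$rss, converged = converged,
      hessianPD = hpd, nUsed = length(props) - out$nZeroMasked,
      nZeroMasked = as.integer(out$nZeroMasked),
      start = unclass(start), teBounds = as.numeric(teBounds))
}

#' Sample dates from truncated normal radiocarbon intervals
#'
#' Each individual's date is drawn from a normal distribution centred on
#' the interval midpoint whose 95\% interval coincides with the reported
#' calibrated bounds, truncated at those bounds; i.e.
#' \code{sd = (upper - lower) / (2 * 1.959964)}.  Zero-width intervals
#' return the point date.  Draws are independent across individuals and
#' across repeated calls.
#'
#' @param upper,lower older and younger interval bounds (calBCE), either
#'   two numeric vectors or a single \linkS4class{AncientCohort} as
#'   \code{upper}.
#' @param seed optional seed; omit inside an outer seeded loop.
#' @return Named numeric vector of dates.
#' @export
sampleDates <- function(upper, lower = NULL, seed = NULL) {
  if (is(upper, "AncientCohort")) {
    df <- individuals(upper)
    ids <- df$id; lower <- df$lower_bce; upper <- df$upper_bce
  } else ids <- names(upper) %||% seq_along(upper)
  if (any(upper < lower)) stop("upper_bce must be >= lower_bce")
  if (!is.null(seed)) set.seed(seed)
  mid <- (upper + lower) / 2
  sd <- (upper - lower) / (2 * 1.959964)
  stats::setNames(rtruncnorm(length(mid), mid, sd, lower, upper), ids)
}
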