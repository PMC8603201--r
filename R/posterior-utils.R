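# Posterior summary utilities shared by every model in the package.

#' Highest-density interval of a sample of draws
#'
#' Narrowest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws (sliding-window HDI, valid for unimodal posteriors). Ties between
#' equally narrow windows are broken toward the lower start.
#'
#' @param draws Numeric vector of posterior draws (at least 100 for a
#'   reportable interval; fewer is allowed but a warning is raised).
#' @param mass Probability mass in (0, 1); `mass = 1` spans min..max.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' hdi(rnorm(1e4), 0.95)
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(draws) || length(draws) == 0 || anyNA(draws)) {
    abort("`draws` must be a non-empty numeric vector without NAs.")
  }
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass > 1) {
    abort("`mass` must be a single number in (0, 1].")
  }
  n <- length(draws)
  if (n < 100) warn("fewer than 100 draws: HDI endpoints are unstable.")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths) # which.min takes the first minimum: lower start wins
  c(lo = x[i], hi = x[i + m - 1])
}

#' Posterior probability of a negative effect
#'
#' Fraction of posterior draws of a deflection that fall below zero -- the
#' "P-minus" reported next to each cell line in the effect plots.
#'
#' @param draws Numeric vector of deflection draws.
#' @return A probability in \[0, 1\].
#' @export
p_minus <- function(draws) {
  if (!is.numeric(draws) || length(draws) == 0 || anyNA(draws)) {
    abort("`draws` must be a non-empty numeric vector without NAs.")
  }
  mean(draws < 0)
}

# Rank-normalized split-chain R-hat (Vehtari et al. 2021 style) and a bulk
# effective sample size from pooled-chain autocorrelation (Geyer initial
# positive sequence). `draws` is an iterations x chains matrix.
rhat_rank <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  if (all(abs(split - split[1]) < 1e-300)) return(1) # constant chain
  z <- qnorm((rank(split) - 3 / 8) / (length(split) + 1 / 4))
  z <- matrix(z, nrow = half)
  m <- ncol(z)
  chain_means <- colMeans(z)
  b <- half * var(chain_means)
  w <- mean(apply(z, 2, var))
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  x <- as.vector(scale(draws, scale = FALSE))
  if (sd(x) == 0) return(n * m)
  # pooled autocorrelation, Geyer initial positive sequence on pair sums
  max_lag <- min(n * m - 1, 500)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  rho_sum <- 0
  t <- 1
  while (t + 1 <= length(ac) - 1) {
    pair <- ac[t + 1] + ac[t + 2]
    if (pair < 0) break
    rho_sum <- rho_sum + pair
    t <- t + 2
  }
  max(1, (n * m) / (1 + 2 * rho_sum))
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage); used for
# scale parameters whose full conditionals are log-concave but non-standard.
slice_sample1 <- function(x0, log_f, w = 1, max_step = 50, lower = -Inf,
                          upper = Inf) {
  f0 <- log_f(x0)
  if (!is.finite(f0)) abort("slice sampler started at zero-density point")
  y <- f0 + log(runif(1)) # slice level below log_f(x0)
  l <- x0 - runif(1) * w
  r <- l + w
  j <- floor(runif(1) * max_step)
  k <- max_step - 1 - j
  while (j > 0 && l > lower && log_f(l) > y) { l <- l - w; j <- j - 1 }
  while (k > 0 && r < upper && log_f(r) > y) { r <- r + w; k <- k - 1 }
  l <- max(l, lower); r <- min(r, upper)
  repeat {
    x1 <- l + runif(1) * (r - l)
    if (log_f(x1) > y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# Adaptive random-walk Metropolis step on an unconstrained scale.
# `state` is a list(value, lsd, acc, n); returns updated list after one
# proposal against log-target `log_f` evaluated at the transformed value.
rw_update <- function(state, log_f, adapt = FALSE, target = 0.44) {
  prop <- state$value + exp(state$lsd) * rnorm(1)
  lp_prop <- log_f(prop)
  accept <- is.finite(lp_prop) && log(runif(1)) < (lp_prop - state$lp)
  if (accept) {
    state$value <- prop
    state$lp <- lp_prop
  }
  state$n <- state$n + 1
  if (adapt) {
    # Robbins-Monro adaptation of the proposal scale during warmup
    state$lsd <- state$lsd + (as.numeric(accept) - target) / sqrt(state$n)
  }
  state
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

# Monte Carlo standard error of a posterior mean, given an ESS.
mcse_mean <- function(draws, ess) sd(draws) / sqrt(max(ess, 1))
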