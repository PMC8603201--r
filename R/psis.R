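# Pareto-smoothed importance sampling and approximate leave-one-out
# cross-validation (PSIS-LOO), implemented from the generalised-Pareto
# profile-posterior fit of Zhang & Stephens (2009).

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalised Pareto fit to exceedances x > 0; returns shape k and scale.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0 || sd(x) == 0) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(b) -mean(log1p(-b * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - max(l_j))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-theta_hat * x))
  list(k = k_hat, sigma = k_hat / theta_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * (exp(-k * log1p(-p)) - 1) / k
}

#' Pareto-smoothed importance weights
#'
#' Stabilises a vector of log importance ratios by fitting a generalised
#' Pareto distribution to the largest `min(0.2 S, 3 sqrt(S))` raw weights and
#' replacing them with expected order statistics of the fit, capped at the
#' raw maximum. With fewer than 5 tail samples the raw (normalised) weights
#' are returned unchanged.
#'
#' @param log_ratios Numeric vector of log importance ratios.
#' @return List with `log_weights` (normalised to sum to one on the natural
#'   scale) and `pareto_k` (the tail-shape diagnostic; values above 0.7 mark
#'   unreliable weights, `NA` when no smoothing was possible).
#' @export
psis_weights <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  tail_len <- min(ceiling(0.2 * s), floor(3 * sqrt(s)))
  khat <- NA_real_
  if (tail_len >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(s - tail_len + 1):s]
    cutpoint <- exp(lw[ord[s - tail_len]])
    z <- exp(lw[tail_ids]) - cutpoint
    fit <- gpd_fit(z)
    khat <- fit$k
    if (is.finite(khat)) {
      pp <- (seq_len(tail_len) - 0.5) / tail_len
      smoothed <- cutpoint + vapply(pp, qgpd, 0, k = khat, sigma = fit$sigma)
      smoothed <- pmin(smoothed, exp(max(lw)))
      # assign smoothed order statistics back in rank order of the raw tail
      lw[tail_ids[order(exp(lw[tail_ids]))]] <- log(sort(smoothed))
    }
  }
  list(log_weights = lw - log_sum_exp(lw), pareto_k = khat)
}

#' PSIS approximate leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density (elpd) under
#' leave-one-out cross-validation from a pointwise log-likelihood matrix,
#' using Pareto-smoothed importance sampling.
#'
#' @param loglik Matrix of pointwise log-likelihoods, observations x
#'   posterior draws.
#' @return Object of class `psis_loo`: `elpd` and its `se`, `pointwise`
#'   tibble (per-observation elpd and Pareto k), `n_high_k` (k > 0.7).
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  n <- nrow(loglik)
  pointwise <- purrr::map(seq_len(n), function(i) {
    ll <- loglik[i, ]
    ps <- psis_weights(-ll)
    c(elpd = log_sum_exp(ps$log_weights + ll), k = ps$pareto_k)
  })
  pw <- do.call(rbind, pointwise)
  n_high <- sum(pw[, "k"] > 0.7, na.rm = TRUE)
  if (n_high > 0.1 * n) {
    warn(sprintf("%d of %d observations have Pareto k > 0.7: LOO estimates unreliable.",
                 n_high, n))
  }
  structure(
    list(elpd = sum(pw[, "elpd"]),
         se = sqrt(n * var(pw[, "elpd"])),
         pointwise = tibble(elpd = pw[, "elpd"], pareto_k = pw[, "k"]),
         n_high_k = n_high, n = n),
    class = "psis_loo"
  )
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.2f (se %.2f), n = %d, high Pareto k: %d\n",
              x$elpd, x$se, x$n, x$n_high_k))
  invisible(x)
}
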