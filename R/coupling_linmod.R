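# Coupling of DSB repair to metabolism: interpolate focus probabilities to
# the metabolic time grid (0, 1, 6, 24 h), then infer per-cell-line Bayesian
# linear relations between focus probability per unit area (response) and a
# log-metabolic parameter (predictor); ordinary least squares is reported
# alongside as the plotted representation.

#' Interpolate focus probabilities to the metabolic time grid
#'
#' Focus counts are scored at 0, 0.5, 2, 6, 24 h but flux parameters at 0,
#' 1, 6, 24 h. The 1 h focus probability is interpolated between 0.5 h and
#' 2 h -- linearly in time by default (weight 1/3 from 0.5 h toward 2 h), or
#' linearly in log-time; the other grid points pass through.
#'
#' @param p Numeric vector of 5 focus probabilities at [foci_times()], named
#'   or in time order, all in (0, 1).
#' @param method `"linear"` (in time; default) or `"log_time"`.
#' @return Tibble with `time_h` (0, 1, 6, 24) and `p`.
#' @export
interpolate_foci_to_metab_grid <- function(p, method = c("linear",
                                                         "log_time")) {
  method <- match.arg(method)
  if (length(p) != 5) abort("`p` must hold the 5 canonical time points.")
  if (!is.null(names(p))) p <- p[as.character(foci_times())]
  if (anyNA(p) || any(p <= 0 | p >= 1)) {
    abort("focus probabilities must lie strictly inside (0, 1).")
  }
  w <- if (method == "linear") (1 - 0.5) / (2 - 0.5) else
    (log(1) - log(0.5)) / (log(2) - log(0.5))
  p1 <- p[2] + w * (p[3] - p[2])
  tibble(time_h = metab_times(), p = unname(c(p[1], p1, p[4], p[5])))
}

#' Bayesian linear coupling of focus probability and a log-metabolic parameter
#'
#' Simple normal-likelihood linear regression of the focus probability per
#' unit area on the log-metabolic parameter at the four matched timepoints,
#' with weakly informative priors (normal(0, 10 * empirical scale) on slope
#' and intercept, half-normal on the residual scale). The conjugate
#' coefficient block is Gibbs-sampled exactly given the residual scale; the
#' ordinary least-squares fit is computed alongside.
#'
#' @param data Data frame with one row per matched timepoint.
#' @param foci_p,log_metab Names of the response / predictor columns.
#' @param chains,iter,warmup,seed Sampler settings.
#' @return Object of class `coupling_fit`: posterior draws and summaries of
#'   slope and intercept, `Pr(slope < 0)`, and the least-squares fit.
#' @export
fit_coupling <- function(data, foci_p = "p", log_metab = "log_metab",
                         chains = 2, iter = 2000, warmup = floor(iter / 2),
                         seed = 1L) {
  y <- data[[foci_p]]; x <- data[[log_metab]]
  if (is.null(y) || is.null(x)) abort("response/predictor columns not found.")
  if (length(y) != 4) abort("expected exactly 4 matched timepoints.")
  if (var(x) == 0) abort("constant predictor: slope unidentifiable.")
  if (length(unique(x)) < 3) abort("fewer than 3 distinct predictor values.")
  ls_fit <- lm(y ~ x)
  sy <- max(sd(y), 1e-12)
  prior_sd <- 10 * c(max(sd(y), 1e-3), max(sd(y) / sd(x), 1e-3))
  X <- cbind(1, x)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  keep <- iter - warmup
  chain_draws <- purrr::map(seq_len(chains), function(ch) {
    set.seed(seed + 1000L * ch)
    sigma <- sy
    beta <- coef(ls_fit)
    out <- matrix(0, keep, 3,
                  dimnames = list(NULL, c("intercept", "slope", "sigma")))
    for (it in seq_len(iter)) {
      # coefficients: conjugate normal given sigma
      prec <- XtX / sigma^2 + diag(1 / prior_sd^2)
      ch_prec <- chol(prec)
      mu <- backsolve(ch_prec, forwardsolve(t(ch_prec), Xty / sigma^2))
      beta <- mu + backsolve(ch_prec, rnorm(2))
      # residual scale: slice with half-normal(0, 2.5 sd(y)) prior
      resid <- y - X %*% beta
      lf <- function(ls) {
        sv <- exp(ls)
        -length(y) * ls - sum(resid^2) / (2 * sv^2) +
          half_normal_lp(sv, 2.5 * sy) + ls
      }
      sigma <- exp(slice_sample1(log(sigma), lf, w = 0.5))
      if (it > warmup) out[it - warmup, ] <- c(beta, sigma)
    }
    out
  })
  draws <- do.call(rbind, chain_draws)
  summarise_term <- function(col) {
    d <- draws[, col]
    h <- hdi(d, 0.95)
    tibble(term = col, median = median(d), hdi95_lo = h[["lo"]],
           hdi95_hi = h[["hi"]],
           rhat = rhat_rank(do.call(cbind,
                                    purrr::map(chain_draws, ~.x[, col]))))
  }
  structure(
    list(summary = dplyr::bind_rows(summarise_term("intercept"),
                                    summarise_term("slope")),
         draws = draws, chain_draws = chain_draws,
         pr_slope_neg = mean(draws[, "slope"] < 0),
         ls_intercept = unname(coef(ls_fit)[1]),
         ls_slope = unname(coef(ls_fit)[2]),
         data = tibble(p = y, log_metab = x), n_points = length(y),
         seed = seed),
    class = "coupling_fit"
  )
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("Coupling fit (n = %d): LS slope %.4g, Pr(slope < 0) = %.3f\n",
              x$n_points, x$ls_slope, x$pr_slope_neg))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.coupling_fit <- function(x, ...) x$summary

#' @export
glance.coupling_fit <- function(x, ...) {
  tibble(n_points = x$n_points, ls_slope = x$ls_slope,
         ls_intercept = x$ls_intercept, pr_slope_neg = x$pr_slope_neg,
         max_rhat = max(x$summary$rhat, na.rm = TRUE))
}

#' Tabulate coupling fits across cell lines and metabolic parameters
#'
#' Flags each slope as `negative` / `positive` when the 95% HDI excludes
#' zero, `indeterminate` otherwise (point estimates are deliberately not
#' used: four points give weak inference by construction).
#'
#' @param fits Tibble with columns `cell_line`, `parameter`, `fit` (list of
#'   `coupling_fit` objects), e.g. built with [purrr::pmap()].
#' @return The tibble with added `ls_slope`, `slope_median`, `hdi95_lo`,
#'   `hdi95_hi`, `pr_slope_neg`, `sign`.
#' @export
coupling_panel <- function(fits) {
  stopifnot(all(c("cell_line", "parameter", "fit") %in% names(fits)))
  info <- purrr::map(fits$fit, function(f) {
    s <- f$summary[f$summary$term == "slope", ]
    tibble(ls_slope = f$ls_slope, slope_median = s$median,
           hdi95_lo = s$hdi95_lo, hdi95_hi = s$hdi95_hi,
           pr_slope_neg = f$pr_slope_neg,
           sign = if (s$hdi95_hi < 0) "negative"
                  else if (s$hdi95_lo > 0) "positive" else "indeterminate")
  })
  dplyr::bind_cols(fits[c("cell_line", "parameter")],
                   dplyr::bind_rows(info))
}

#' Scatter + fitted-line plot of a coupling fit
#'
#' @param object A `coupling_fit`. @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coupling_fit <- function(object, ...) {
  sub <- object$draws[sample(nrow(object$draws), min(100,
                                                     nrow(object$draws))), ,
                      drop = FALSE]
  lines <- tibble(intercept = sub[, "intercept"], slope = sub[, "slope"])
  ggplot2::ggplot(object$data, ggplot2::aes(.data$log_metab, .data$p)) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         alpha = 0.05, colour = "steelblue") +
    ggplot2::geom_abline(intercept = object$ls_intercept,
                         slope = object$ls_slope, colour = "black") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log metabolic parameter",
                  y = "focus probability per 0.1*Pixel^2",
                  subtitle = sprintf("LS slope %.4g, Pr(slope<0) = %.2f",
                                     object$ls_slope, object$pr_slope_neg)) +
    ggplot2::theme_minimal()
}
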