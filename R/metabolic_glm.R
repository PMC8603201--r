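# Multilevel Bayesian model of log-metabolic parameters: normal likelihood,
# an overall mean, cell-line deflections, replicate deflections nested within
# cell line, and (in the time-course variant) additive time deflections.
# Weakly informative priors: normal(mean(y), (10*sd(y))^2) on the grand mean,
# half-normal(0, 2.5*sd(y)) on every scale. Location parameters are updated
# by exact conjugate Gibbs draws; scales by slice sampling; deflections are
# reported relative to the grand mean via a sum-to-zero constraint applied at
# summary time.

half_normal_lp <- function(s, scale) -s^2 / (2 * scale^2)

# One Gibbs chain in the centred parameterisation (replicate means drawn
# around cell-line means, cell-line means around the grand mean), which
# avoids the translation redundancy that makes the non-centred deflection
# parameterisation mix slowly when groups are well measured. Deflections
# a = theta - mu and b = eta - theta are reconstructed for the output.
gibbs_lmm_chain <- function(y, cell, rep_g, time_g, iter, warmup, seed,
                            scale_eff, mu_mean, mu_sd) {
  set.seed(seed)
  C <- max(cell)
  R <- if (is.null(rep_g)) 0L else max(rep_g)
  TT <- if (is.null(time_g)) 0L else max(time_g)
  sigma <- sd(y); if (!is.finite(sigma) || sigma == 0) sigma <- 1
  cell_of_rep <- if (R) vapply(seq_len(R), function(r)
    cell[match(r, rep_g)], 0L) else integer(0)
  mu <- mean(y) + rnorm(1, 0, 0.2 * sigma)
  theta <- as.numeric(rowsum(y, cell) / tabulate(cell, C)) +
    rnorm(C, 0, 0.2 * sigma)
  eta <- if (R) theta[cell_of_rep] + rnorm(R, 0, 0.1 * sigma) else numeric(0)
  g <- if (TT) rnorm(TT, 0, 0.1 * sigma) else numeric(0)
  tau_a <- sigma / 2; tau_b <- sigma / 2; tau_g <- sigma / 2
  keep <- iter - warmup
  out <- list(mu = numeric(keep), a = matrix(0, keep, C),
              b = if (R) matrix(0, keep, R) else NULL,
              g = if (TT) matrix(0, keep, TT) else NULL,
              sigma = numeric(keep), tau_a = numeric(keep),
              tau_b = numeric(keep))
  upd_scale <- function(s, x, scale) {
    lf <- function(ls) {
      sv <- exp(ls)
      -length(x) * ls - sum(x^2) / (2 * sv^2) + half_normal_lp(sv, scale) + ls
    }
    exp(slice_sample1(log(s), lf, w = 0.5))
  }
  for (it in seq_len(iter)) {
    gg <- if (TT) g[time_g] else 0
    yc <- y - gg
    if (R) {
      # replicate-group means around their cell-line mean
      sums <- rowsum(yc, rep_g)[, 1]
      ns <- tabulate(rep_g, R)
      prec <- ns / sigma^2 + 1 / tau_b^2
      eta <- rnorm(R, (sums / sigma^2 + theta[cell_of_rep] / tau_b^2) / prec,
                   sqrt(1 / prec))
      # cell-line means around the grand mean
      sums <- rowsum(eta, cell_of_rep)[, 1]
      ns <- tabulate(cell_of_rep, C)
      prec <- ns / tau_b^2 + 1 / tau_a^2
      theta <- rnorm(C, (sums / tau_b^2 + mu / tau_a^2) / prec,
                     sqrt(1 / prec))
      tau_b <- upd_scale(tau_b, eta - theta[cell_of_rep], scale_eff)
    } else {
      sums <- rowsum(yc, cell)[, 1]
      ns <- tabulate(cell, C)
      prec <- ns / sigma^2 + 1 / tau_a^2
      theta <- rnorm(C, (sums / sigma^2 + mu / tau_a^2) / prec,
                     sqrt(1 / prec))
    }
    prec <- C / tau_a^2 + 1 / mu_sd^2
    mu <- rnorm(1, (sum(theta) / tau_a^2 + mu_mean / mu_sd^2) / prec,
                sqrt(1 / prec))
    tau_a <- upd_scale(tau_a, theta - mu, scale_eff)
    fitted0 <- if (R) eta[rep_g] else theta[cell]
    if (TT) {
      resid <- y - fitted0
      sums <- rowsum(resid, time_g)[, 1]
      ns <- tabulate(time_g, TT)
      prec <- ns / sigma^2 + 1 / tau_g^2
      g <- rnorm(TT, (sums / sigma^2) / prec, sqrt(1 / prec))
      g <- g - mean(g) # identified up to translation against eta
      tau_g <- upd_scale(tau_g, g, scale_eff)
    }
    resid <- y - fitted0 - (if (TT) g[time_g] else 0)
    sigma <- upd_scale(sigma, resid, scale_eff)
    if (it > warmup) {
      k <- it - warmup
      out$mu[k] <- mu
      out$a[k, ] <- theta - mu
      if (R) out$b[k, ] <- eta - theta[cell_of_rep]
      if (TT) out$g[k, ] <- g
      out$sigma[k] <- sigma; out$tau_a[k] <- tau_a; out$tau_b[k] <- tau_b
    }
  }
  out
}

summarise_deflections <- function(defl_chains, labels) {
  # defl_chains: list over chains of draws x group matrices
  purrr::imap(labels, function(lab, j) {
    per_chain <- purrr::map(defl_chains, ~.x[, j])
    pooled <- unlist(per_chain)
    mat <- do.call(cbind, per_chain)
    h50 <- hdi(pooled, 0.5); h95 <- hdi(pooled, 0.95)
    tibble(term = lab, median = median(pooled),
           hdi50_lo = h50[["lo"]], hdi50_hi = h50[["hi"]],
           hdi95_lo = h95[["lo"]], hdi95_hi = h95[["hi"]],
           p_minus = p_minus(pooled), rhat = rhat_rank(mat),
           ess = ess_bulk(mat),
           mcse = mcse_mean(pooled, ess_bulk(mat)))
  }) |> dplyr::bind_rows()
}

#' Fit the multilevel model of a log-metabolic parameter
#'
#' Models the log parameter as an overall mean plus cell-line deflections and
#' replicate deflections nested within cell line, all normal. Returns
#' per-cell-line deflection posteriors relative to the grand mean (sum-to-zero
#' applied per draw at summary time), each with median, 50%/95% HDIs, the
#' posterior probability of a negative deflection (P-minus), and
#' rank-normalised split R-hat / bulk ESS diagnostics.
#'
#' If every cell line carries a single replicate the nested replicate
#' variance is unidentifiable; the model then degrades to cell-line-only
#' deflections with a logged notice.
#'
#' @param data Data frame of per-well (or per-measurement) values.
#' @param response Name of the numeric column of log values.
#' @param cell_line,replicate Names of the grouping columns; `replicate` is
#'   nested within `cell_line`.
#' @param chains Number of MCMC chains (>= 2 for reported summaries).
#' @param iter Iterations per chain, of which `warmup` are discarded.
#' @param warmup Warmup iterations (default `iter / 2`).
#' @param seed Integer seed.
#' @return An object of class `metab_glm` with elements `effects` (tibble of
#'   deflection summaries), `draws`, `diagnostics`, `data`.
#' @examples
#' d <- tibble::tibble(
#'   log_value = rnorm(48, rep(c(-0.3, 0.3), each = 24), 0.2),
#'   cell_line = rep(c("A", "B"), each = 24),
#'   replicate = rep(rep(1:2, each = 12), 2)
#' )
#' fit <- fit_metabolic_glm(d, chains = 2, iter = 600, seed = 1)
#' tidy(fit)
#' @export
fit_metabolic_glm <- function(data, response = "log_value",
                              cell_line = "cell_line",
                              replicate = "replicate",
                              chains = 4, iter = 2000,
                              warmup = floor(iter / 2), seed = 1L) {
  fit_lmm_impl(data, response, cell_line, replicate, time = NULL,
               chains = chains, iter = iter, warmup = warmup, seed = seed)
}

#' @rdname fit_metabolic_glm
#' @param time Name of the time column (coerced to a factor level grid);
#'   deflections are additive in cell line and time and summarised per
#'   (cell line, time) combination.
#' @export
fit_time_course_glm <- function(data, response = "log_value",
                                cell_line = "cell_line",
                                replicate = "replicate", time = "time_h",
                                chains = 4, iter = 2000,
                                warmup = floor(iter / 2), seed = 1L) {
  fit_lmm_impl(data, response, cell_line, replicate, time = time,
               chains = chains, iter = iter, warmup = warmup, seed = seed)
}

fit_lmm_impl <- function(data, response, cell_line, replicate, time,
                         chains, iter, warmup, seed) {
  for (col in c(response, cell_line, replicate, time)) {
    if (!col %in% names(data)) abort(sprintf("column '%s' not found.", col))
  }
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y))) {
    abort("response values must be finite numerics.")
  }
  if (chains < 2) warn("fewer than 2 chains: R-hat is not interpretable.")
  if (iter - warmup < 125) abort("too few post-warmup iterations.")
  cl <- factor(data[[cell_line]])
  if (nlevels(cl) < 2) abort("need >= 2 cell lines.")
  rep_f <- factor(paste(cl, data[[replicate]], sep = "/"))
  nested_ok <- nlevels(rep_f) > nlevels(cl)
  if (!nested_ok) {
    inform("single replicate per cell line: replicate variance dropped, fitting cell-line-only deflections.")
  }
  time_f <- if (!is.null(time)) factor(data[[time]]) else NULL
  sy <- sd(y); if (!is.finite(sy) || sy == 0) sy <- 1
  chain_draws <- purrr::map(seq_len(chains), function(ch) {
    gibbs_lmm_chain(y, as.integer(cl),
                    if (nested_ok) as.integer(rep_f) else NULL,
                    if (!is.null(time_f)) as.integer(time_f) else NULL,
                    iter, warmup, seed = seed + 1000L * ch,
                    scale_eff = 2.5 * sy, mu_mean = mean(y), mu_sd = 10 * sy)
  })
  # sum-to-zero deflections per draw
  center <- function(m) m - rowMeans(m)
  if (is.null(time_f)) {
    defl <- purrr::map(chain_draws, ~center(.x$a))
    effects <- summarise_deflections(defl, levels(cl)) |>
      rename(cell_line = "term")
  } else {
    # combined (cell line, time) deflection = centered a + centered g
    combos <- tidyr::expand_grid(cell_line = levels(cl),
                                 time = levels(time_f))
    defl <- purrr::map(chain_draws, function(d) {
      ac <- center(d$a); gc <- center(d$g)
      ac[, match(combos$cell_line, levels(cl)), drop = FALSE] +
        gc[, match(combos$time, levels(time_f)), drop = FALSE]
    })
    effects <- summarise_deflections(
      defl, paste(combos$cell_line, combos$time, sep = " @ ")) |>
      mutate(cell_line = combos$cell_line,
             time_h = as.numeric(combos$time)) |>
      select("cell_line", "time_h", dplyr::everything(), -"term")
  }
  scalar_mat <- function(name) {
    do.call(cbind, purrr::map(chain_draws, name))
  }
  diag_tbl <- tibble(
    parameter = c("mu", "sigma"),
    rhat = c(rhat_rank(scalar_mat("mu")), rhat_rank(scalar_mat("sigma"))),
    ess = c(ess_bulk(scalar_mat("mu")), ess_bulk(scalar_mat("sigma")))
  )
  converged <- all(c(effects$rhat, diag_tbl$rhat) < 1.05, na.rm = TRUE)
  if (!converged) warn("sampler non-convergence: max R-hat > 1.05; treat summaries with caution.")
  structure(
    list(effects = effects, draws = chain_draws,
         deflection_draws = defl,
         diagnostics = diag_tbl, converged = converged,
         data = tibble(y = y, cell = cl, rep = rep_f,
                       time = if (is.null(time_f)) NA else time_f),
         nested = nested_ok, time_course = !is.null(time_f),
         response = response, seed = seed),
    class = "metab_glm"
  )
}

#' Posterior predictive check for a multilevel metabolic model
#'
#' Draws replicated datasets from the fitted model (re-using the posterior
#' draws of all location and scale parameters) and compares test statistics
#' -- overall mean, overall sd, and per-cell-line means -- between replicated
#' and observed data. Tail probabilities near 0 or 1 flag misfit.
#'
#' @param fit A `metab_glm` object.
#' @param n_rep Number of replicated datasets (default 500).
#' @param seed Integer seed.
#' @return A tibble with one row per statistic: `statistic`, `observed`,
#'   `rep_mean`, `p_tail` (probability that the replicated statistic is >=
#'   the observed one).
#' @export
posterior_predictive_check <- function(fit, n_rep = 500, seed = 1L) {
  stopifnot(inherits(fit, "metab_glm"))
  set.seed(seed)
  y <- fit$data$y
  cell <- as.integer(fit$data$cell)
  rep_g <- as.integer(fit$data$rep)
  time_g <- if (fit$time_course) as.integer(fit$data$time) else NULL
  all_draws <- fit$draws
  nkeep <- length(all_draws[[1]]$mu)
  pick <- cbind(sample(seq_along(all_draws), n_rep, replace = TRUE),
                sample(nkeep, n_rep, replace = TRUE))
  cl_levels <- levels(fit$data$cell)
  stats_obs <- c(mean = mean(y), sd = sd(y),
                 setNames(as.numeric(rowsum(y, cell) / tabulate(cell)),
                          paste0("mean_", cl_levels)))
  reps <- matrix(0, n_rep, length(stats_obs))
  for (i in seq_len(n_rep)) {
    d <- all_draws[[pick[i, 1]]]
    k <- pick[i, 2]
    mu_i <- d$mu[k] + d$a[k, cell] +
      (if (fit$nested) d$b[k, rep_g] else 0) +
      (if (fit$time_course) d$g[k, time_g] else 0)
    yr <- rnorm(length(y), mu_i, d$sigma[k])
    reps[i, ] <- c(mean(yr), sd(yr),
                   as.numeric(rowsum(yr, cell) / tabulate(cell)))
  }
  tibble(statistic = names(stats_obs), observed = as.numeric(stats_obs),
         rep_mean = colMeans(reps),
         p_tail = colMeans(sweep(reps, 2, stats_obs, `>=`)))
}

#' @export
print.metab_glm <- function(x, ...) {
  cat(sprintf("Multilevel model of '%s' (%s)\n", x$response,
              if (x$time_course) "time course" else "baseline"))
  cat(sprintf("  %d chains, %d kept draws/chain; converged: %s\n",
              length(x$draws), length(x$draws[[1]]$mu), x$converged))
  print(x$effects, n = 12)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.metab_glm <- function(x, ...) x$effects

#' @export
glance.metab_glm <- function(x, ...) {
  sig <- unlist(purrr::map(x$draws, "sigma"))
  tibble(n = length(x$data$y), n_cell_lines = nlevels(x$data$cell),
         nested = x$nested, time_course = x$time_course,
         sigma = median(sig), max_rhat = max(x$effects$rhat, na.rm = TRUE),
         converged = x$converged)
}

#' Forest plot of cell-line deflections
#'
#' Medians with 50% (bold) and 95% (thin) highest-density intervals per cell
#' line, annotated with the posterior probability of a negative deflection.
#'
#' @param object A `metab_glm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metab_glm <- function(object, ...) {
  eff <- object$effects
  lab <- if (object$time_course) {
    paste(eff$cell_line, "@", eff$time_h, "h")
  } else eff$cell_line
  eff$label <- factor(lab, levels = rev(unique(lab)))
  ggplot2::ggplot(eff, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$hdi95_lo,
                                       xend = .data$hdi95_hi,
                                       yend = .data$label),
                          linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$hdi50_lo,
                                       xend = .data$hdi50_hi,
                                       yend = .data$label),
                          linewidth = 1.4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$median), size = 2,
                        colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(x = min(.data$hdi95_lo),
                                    label = sprintf("%.2f", .data$p_minus)),
                       hjust = 1.3, size = 3) +
    ggplot2::labs(x = "deflection from grand mean (log units)", y = NULL,
                  subtitle = "bold: 50% HDI, thin: 95% HDI; left numbers: P-") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
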