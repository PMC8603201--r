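# Hierarchical Bayesian model of gamma-H2A.X focus-count kinetics.
#
# Generative structure, per cell line:
#   foci_count_i ~ Binomial(area_units_i, p[r(i), t(i)])
#   p[r,t] ~ Beta(mean = p_t, variance = v_t)       (replicate level)
#   v_t = sigma2 * X_t / k_t, X_t ~ chi^2(k_t), truncated so that
#         0 < v_t < p_t (1 - p_t)                   (valid beta)
#   p_t ~ Uniform(0, 1); k_t, sigma2 ~ chi^2(df = 2)
#
# The trial unit is the nuclear unit area of 0.1*Pixel^2, which keeps every
# probability safely inside (0, 1). Fitting is by Gibbs draws for the
# conjugate replicate level and adaptive random-walk Metropolis for the
# hyperparameters. Two simpler comparison models share the surface: a
# replicate-pooled beta-binomial ("betabinom") and a fully pooled binomial
# ("pooled", conjugate, sampled exactly).

#' Beta-binomial probability mass function
#'
#' Marginal distribution of a binomial count whose success probability is
#' Beta(`alpha`, `beta`): the replicate-integrated single-observation
#' likelihood of the hierarchical foci model.
#'
#' @param x Counts. @param size Trials. @param alpha,beta Beta shapes > 0.
#' @param log Return log density?
#' @return Density values.
#' @export
dbetabinom <- function(x, size, alpha, beta, log = FALSE) {
  ll <- lchoose(size, x) + lbeta(x + alpha, size - x + beta) -
    lbeta(alpha, beta)
  ll[x < 0 | x > size] <- -Inf
  if (log) ll else exp(ll)
}

#' Beta shapes from a (mean, variance) pair
#'
#' @param p Mean in (0,1). @param v Variance in (0, p(1-p)).
#' @return List with `alpha`, `beta`.
#' @export
beta_shapes_mv <- function(p, v) {
  if (any(v <= 0) || any(v >= p * (1 - p))) {
    abort(sprintf("beta variance v = %g outside (0, p(1-p) = %g)", v[1],
                  (p * (1 - p))[1]))
  }
  conc <- p * (1 - p) / v - 1
  list(alpha = p * conc, beta = (1 - p) * conc)
}

# log density of v under the truncated scaled-chi-square level
lp_v <- function(v, m, k, sigma2) {
  if (v <= 0 || v >= m) return(-Inf)
  dchisq(v * k / sigma2, k, log = TRUE) + log(k / sigma2) -
    pchisq(m * k / sigma2, k, log.p = TRUE)
}

# beta-level log likelihood of the replicate draws at one time
lp_beta_level <- function(p_rt, p, v) {
  if (v <= 0 || v >= p * (1 - p)) return(-Inf)
  sh <- beta_shapes_mv(p, v)
  sum(dbeta(p_rt, sh$alpha, sh$beta, log = TRUE))
}

mh <- function(value, lsd, log_f) {
  prop <- value + exp(lsd) * rnorm(1)
  lp0 <- log_f(value)
  lp1 <- log_f(prop)
  acc <- is.finite(lp1) && log(runif(1)) < lp1 - lp0
  list(value = if (acc) prop else value, acc = acc)
}

# One hierarchical chain. The replicate level is collapsed for the
# hyperparameter updates: given the per-(replicate, time) sufficient
# statistics S (foci) and N (unit areas), S_rt is marginally
# BetaBinomial(N_rt, alpha_t, beta_t), which removes the tight coupling
# between p_rt and (p_t, v_t) that stalls uncollapsed samplers.
#
# The replicate-level beta is constrained to be unimodal (alpha_t >= 1 and
# beta_t >= 1): biological replicates of one condition cluster around a
# central value, and without this constraint the posterior under flat
# location priors is dominated by U-shaped, arbitrarily-diffuse beta states
# whenever only a handful of replicates are available. The constraint caps
# the variance at v_max(p) = p(1-p) * q/(1+q) with q = min(p, 1-p); the
# variance is sampled as the fraction w_t = v_t / v_max(p_t) in (0, 1), so
# p_t moves always keep the beta valid. p_rt is drawn by exact conjugate
# Gibbs afterwards.

v_bound <- function(p) {
  q <- pmin(p, 1 - p)
  p * (1 - p) * q / (1 + q)
}
foci_chain_hier <- function(stats, times, iter, warmup, seed, k_shared,
                            init_p, init_u) {
  set.seed(seed)
  TT <- length(times)
  R <- max(stats$i_rep)
  S <- matrix(0, R, TT); N <- matrix(0, R, TT)
  for (i in seq_len(nrow(stats))) {
    S[stats$i_rep[i], stats$i_time[i]] <- stats$S[i]
    N[stats$i_rep[i], stats$i_time[i]] <- stats$S[i] + stats$F[i]
  }
  p_t <- pmin(pmax(init_p * exp(rnorm(TT, 0, 0.15)), 1e-6), 1 - 1e-6)
  w_t <- pmin(pmax(init_u * exp(rnorm(TT, 0, 0.3)), 1e-6), 1 - 1e-6)
  k_t <- rep(2, TT)
  sigma2 <- mean(w_t * v_bound(p_t))
  p_rt <- matrix(rep(p_t, each = R), R, TT)
  clik <- function(t, p, v) { # collapsed replicate-marginal likelihood
    if (v <= 0 || v >= p * (1 - p)) return(-Inf)
    sh <- beta_shapes_mv(p, v)
    sum(dbetabinom(S[, t], N[, t], sh$alpha, sh$beta, log = TRUE))
  }
  lsd <- list(p = rep(log(0.3), TT), u = rep(log(0.8), TT),
              k = rep(log(0.8), TT), s = log(0.8))
  keep <- iter - warmup
  out <- list(p = matrix(0, keep, TT), v = matrix(0, keep, TT),
              k = matrix(0, keep, TT), sigma2 = numeric(keep),
              p_rt = matrix(0, keep, R * TT))
  # densities of the independence proposals used for mode-hopping moves
  c_p <- 400 # proposal concentration around the pooled empirical density
  for (it in seq_len(iter)) {
    gain <- 1 / sqrt(it)
    for (t in seq_len(TT)) {
      # target in (p, w) space (dw measure; includes dv/dw Jacobian)
      lp_p <- function(p) {
        vb <- v_bound(p)
        clik(t, p, w_t[t] * vb) +
          lp_v(w_t[t] * vb, vb, k_t[t], sigma2) + log(vb)
      }
      if (runif(1) < 0.3) {
        # independence move: beta proposal centred at the empirical density
        a_q <- c_p * init_p[t]; b_q <- c_p * (1 - init_p[t])
        prop <- rbeta(1, a_q, b_q)
        lacc <- lp_p(prop) - lp_p(p_t[t]) +
          dbeta(p_t[t], a_q, b_q, log = TRUE) -
          dbeta(prop, a_q, b_q, log = TRUE)
        if (is.finite(lacc) && log(runif(1)) < lacc) p_t[t] <- prop
      } else {
        st <- mh(logit(p_t[t]), lsd$p[t], function(x) {
          p <- inv_logit(x)
          lp_p(p) + log(p) + log1p(-p)
        })
        p_t[t] <- inv_logit(st$value)
        if (it <= warmup) lsd$p[t] <- lsd$p[t] +
            (as.numeric(st$acc) - 0.44) * gain
      }
      # w_t = v_t / v_max(p_t)
      vb <- v_bound(p_t[t])
      lp_w <- function(w) {
        clik(t, p_t[t], w * vb) + lp_v(w * vb, vb, k_t[t], sigma2)
      }
      if (runif(1) < 0.3) {
        prop <- rbeta(1, 0.5, 5) # broad, favours small variance fractions
        lacc <- lp_w(prop) - lp_w(w_t[t]) +
          dbeta(w_t[t], 0.5, 5, log = TRUE) -
          dbeta(prop, 0.5, 5, log = TRUE)
        if (is.finite(lacc) && log(runif(1)) < lacc) w_t[t] <- prop
      } else {
        st <- mh(logit(w_t[t]), lsd$u[t], function(x) {
          w <- inv_logit(x)
          lp_w(w) + log(w) + log1p(-w)
        })
        w_t[t] <- inv_logit(st$value)
        if (it <= warmup) lsd$u[t] <- lsd$u[t] +
            (as.numeric(st$acc) - 0.44) * gain
      }
    }
    v_t <- w_t * v_bound(p_t)
    # k_t >= 1 (log(k - 1) scale), truncated chi^2(2) prior
    if (k_shared) {
      st <- mh(log(k_t[1] - 1 + 1e-9), lsd$k[1], function(x) {
        k <- 1 + exp(x)
        sum(vapply(seq_len(TT), function(t)
          lp_v(v_t[t], v_bound(p_t[t]), k, sigma2), 0)) +
          dchisq(k, 2, log = TRUE) + x
      })
      k_t[] <- 1 + exp(st$value)
      if (it <= warmup) lsd$k[1] <- lsd$k[1] +
          (as.numeric(st$acc) - 0.44) * gain
    } else {
      for (t in seq_len(TT)) {
        st <- mh(log(k_t[t] - 1 + 1e-9), lsd$k[t], function(x) {
          k <- 1 + exp(x)
          lp_v(v_t[t], v_bound(p_t[t]), k, sigma2) +
            dchisq(k, 2, log = TRUE) + x
        })
        k_t[t] <- 1 + exp(st$value)
        if (it <= warmup) lsd$k[t] <- lsd$k[t] +
            (as.numeric(st$acc) - 0.44) * gain
      }
    }
    # sigma2: shared scale, log scale, chi^2(2) prior
    st <- mh(log(sigma2), lsd$s, function(x) {
      s2 <- exp(x)
      sum(vapply(seq_len(TT), function(t)
        lp_v(v_t[t], v_bound(p_t[t]), k_t[t], s2), 0)) +
        dchisq(s2, 2, log = TRUE) + x
    })
    sigma2 <- exp(st$value)
    if (it <= warmup) lsd$s <- lsd$s + (as.numeric(st$acc) - 0.44) * gain
    if (it > warmup) {
      # replicate level: exact conjugate Gibbs given the hyperparameters
      sh <- beta_shapes_mv(p_t, v_t)
      for (t in seq_len(TT)) {
        p_rt[, t] <- rbeta(R, sh$alpha[t] + S[, t],
                           sh$beta[t] + N[, t] - S[, t])
      }
      kk <- it - warmup
      out$p[kk, ] <- p_t; out$v[kk, ] <- v_t; out$k[kk, ] <- k_t
      out$sigma2[kk] <- sigma2
      out$p_rt[kk, ] <- as.vector(pmin(pmax(p_rt, 1e-12), 1 - 1e-12))
    }
  }
  out
}

foci_chain_betabinom <- function(df, times, iter, warmup, seed, init_p) {
  set.seed(seed)
  TT <- length(times)
  by_t <- split(df[c("area_units", "foci_count")], df$i_time)
  p_t <- pmin(pmax(init_p * exp(rnorm(TT, 0, 0.15)), 1e-6), 1 - 1e-6)
  v_t <- 0.1 * p_t * (1 - p_t)
  k_t <- rep(2, TT); sigma2 <- mean(v_t)
  ll_t <- function(t, p, v) {
    if (v <= 0 || v >= p * (1 - p)) return(-Inf)
    sh <- beta_shapes_mv(p, v)
    d <- by_t[[as.character(t)]]
    sum(dbetabinom(d$foci_count, d$area_units, sh$alpha, sh$beta, log = TRUE))
  }
  lsd <- list(p = rep(log(0.2), TT), v = rep(log(0.6), TT),
              k = rep(log(0.6), TT), s = log(0.6))
  keep <- iter - warmup
  out <- list(p = matrix(0, keep, TT), v = matrix(0, keep, TT),
              k = matrix(0, keep, TT), sigma2 = numeric(keep), p_rt = NULL)
  for (it in seq_len(iter)) {
    for (t in seq_len(TT)) {
      st <- mh(logit(p_t[t]), lsd$p[t], function(x) {
        p <- inv_logit(x)
        ll_t(t, p, v_t[t]) + lp_v(v_t[t], p * (1 - p), k_t[t], sigma2) +
          log(p) + log1p(-p)
      })
      p_t[t] <- inv_logit(st$value)
      if (it <= warmup) lsd$p[t] <- lsd$p[t] +
          (as.numeric(st$acc) - 0.44) / sqrt(it)
      m <- p_t[t] * (1 - p_t[t])
      st <- mh(logit(v_t[t] / m), lsd$v[t], function(x) {
        v <- m * inv_logit(x)
        ll_t(t, p_t[t], v) + lp_v(v, m, k_t[t], sigma2) +
          log(v) + log1p(-v / m)
      })
      v_t[t] <- m * inv_logit(st$value)
      if (it <= warmup) lsd$v[t] <- lsd$v[t] +
          (as.numeric(st$acc) - 0.44) / sqrt(it)
      st <- mh(log(k_t[t]), lsd$k[t], function(x) {
        k <- exp(x)
        lp_v(v_t[t], m, k, sigma2) + dchisq(k, 2, log = TRUE) + x
      })
      k_t[t] <- exp(st$value)
      if (it <= warmup) lsd$k[t] <- lsd$k[t] +
          (as.numeric(st$acc) - 0.44) / sqrt(it)
    }
    st <- mh(log(sigma2), lsd$s, function(x) {
      s2 <- exp(x)
      sum(vapply(seq_len(TT), function(t)
        lp_v(v_t[t], p_t[t] * (1 - p_t[t]), k_t[t], s2), 0)) +
        dchisq(s2, 2, log = TRUE) + x
    })
    sigma2 <- exp(st$value)
    if (it <= warmup) lsd$s <- lsd$s + (as.numeric(st$acc) - 0.44) / sqrt(it)
    if (it > warmup) {
      kk <- it - warmup
      out$p[kk, ] <- p_t; out$v[kk, ] <- v_t; out$k[kk, ] <- k_t
      out$sigma2[kk] <- sigma2
    }
  }
  out
}

#' Fit the focus-clearance model for one cell line
#'
#' Fits the hierarchical binomial-beta model (see the package vignette) to a
#' per-nucleus focus table of a single cell line by MCMC, retaining posterior
#' draws of the replicate-overarching focus probability per unit area `p_t`,
#' the replicate-level probabilities, the dispersion hyperparameters, and the
#' pointwise log-likelihood matrix needed for LOO comparison.
#'
#' @param records Foci tibble (see [foci_schema()]) for one cell line with
#'   >= 2 replicates and >= 2 time points.
#' @param model `"hierarchical"` (default), `"betabinom"` (replicate-pooled
#'   beta-binomial) or `"pooled"` (fully pooled binomial; conjugate, sampled
#'   exactly).
#' @param chains MCMC chains (>= 2). @param iter Iterations per chain.
#' @param warmup Discarded warmup iterations (default `iter / 2`).
#' @param k_shared Share the degrees-of-freedom parameter across times
#'   (default `FALSE`: time-specific `k_t`).
#' @param keep_loglik Retain the nucleus x draw log-likelihood matrix.
#' @param seed Integer seed.
#' @return Object of class `foci_fit`.
#' @export
fit_foci_model <- function(records, model = c("hierarchical", "betabinom",
                                              "pooled"),
                           chains = 2, iter = 2000,
                           warmup = floor(iter / 2), k_shared = FALSE,
                           keep_loglik = TRUE, seed = 1L) {
  model <- match.arg(model)
  records <- validate_foci_records(records)
  if (length(unique(records$cell_line)) != 1) {
    abort("`records` must contain a single cell line; see fit_foci_models().")
  }
  times <- sort(unique(records$time_h))
  if (length(times) < 2) abort("need >= 2 time points.")
  reps <- sort(unique(records$replicate))
  if (model == "hierarchical" && length(reps) < 2) {
    abort(paste("single replicate: the hierarchical replicate variance is",
                "unidentified; fit model = 'pooled' (or 'betabinom') instead."),
          class = "repairflux_model_error")
  }
  df <- records
  df$i_time <- match(df$time_h, times)
  df$i_rep <- match(df$replicate, reps)
  init_p <- vapply(seq_along(times), function(t) {
    d <- df[df$i_time == t, ]
    min(max(sum(d$foci_count) / sum(d$area_units), 1e-6), 1 - 1e-6)
  }, 0)
  keep <- iter - warmup
  if (keep < 100) abort("too few post-warmup iterations.")

  if (model == "pooled") {
    chain_draws <- purrr::map(seq_len(chains), function(ch) {
      set.seed(seed + 1000L * ch)
      S_t <- rowsum(df$foci_count, df$i_time)[, 1]
      F_t <- rowsum(df$area_units - df$foci_count, df$i_time)[, 1]
      p <- vapply(seq_along(times),
                  function(t) rbeta(keep, 1 + S_t[t], 1 + F_t[t]),
                  numeric(keep))
      list(p = p, v = NULL, k = NULL, sigma2 = NULL, p_rt = NULL)
    })
  } else if (model == "hierarchical") {
    stats <- df |>
      group_by(.data$i_rep, .data$i_time) |>
      summarise(S = sum(.data$foci_count),
                F = sum(.data$area_units - .data$foci_count),
                .groups = "drop")
    # initialise the variance fraction from the empirical between-replicate
    # spread of the per-replicate focus densities
    init_u <- vapply(seq_along(times), function(t) {
      d <- stats[stats$i_time == t, ]
      ve <- var(d$S / (d$S + d$F))
      vb <- v_bound(init_p[t])
      min(max(ifelse(is.finite(ve) && ve > 0, ve / vb, 0.05), 1e-3), 0.9)
    }, 0)
    chain_draws <- purrr::map(seq_len(chains), function(ch) {
      foci_chain_hier(stats, times, iter, warmup, seed + 1000L * ch,
                      k_shared, init_p, init_u)
    })
  } else {
    chain_draws <- purrr::map(seq_len(chains), function(ch) {
      foci_chain_betabinom(df, times, iter, warmup, seed + 1000L * ch,
                           init_p)
    })
  }

  # convergence diagnostics on p_t per time
  diag_tbl <- purrr::map(seq_along(times), function(t) {
    mat <- do.call(cbind, purrr::map(chain_draws, ~.x$p[, t]))
    tibble(parameter = sprintf("p[t=%g]", times[t]),
           rhat = rhat_rank(mat), ess = ess_bulk(mat))
  }) |> dplyr::bind_rows()
  converged <- all(diag_tbl$rhat < 1.05, na.rm = TRUE)
  if (!converged) {
    warn(sprintf("foci model (%s): max R-hat %.3f > 1.05; summaries flagged invalid.",
                 model, max(diag_tbl$rhat, na.rm = TRUE)))
  }

  fit <- structure(
    list(cell_line = records$cell_line[1], times = times, model = model,
         replicates = reps, draws = chain_draws, data = df,
         diagnostics = diag_tbl, converged = converged,
         k_shared = k_shared, seed = seed),
    class = "foci_fit"
  )
  if (keep_loglik) fit$loglik <- foci_pointwise_loglik(fit)
  fit
}

#' @rdname fit_foci_model
#' @export
fit_foci_models <- function(records, ...) {
  records <- validate_foci_records(records)
  cls <- unique(records$cell_line)
  setNames(purrr::map(cls, function(cl) {
    fit_foci_model(records[records$cell_line == cl, ], ...)
  }), cls)
}

# pooled draws helper: draws x T (or draws x (R*T)) matrices
pooled_draws <- function(fit, what = "p") {
  do.call(rbind, purrr::map(fit$draws, what))
}

foci_pointwise_loglik <- function(fit) {
  df <- fit$data
  n <- nrow(df)
  if (fit$model == "hierarchical") {
    prt <- pooled_draws(fit, "p_rt") # draws x (R*T), column = (t-1)*R + r
    R <- length(fit$replicates)
    colid <- (df$i_time - 1L) * R + df$i_rep
    ll <- matrix(0, n, nrow(prt))
    for (g in unique(colid)) {
      rows <- which(colid == g)
      p <- prt[, g]
      ll[rows, ] <- t(vapply(seq_along(p), function(s)
        dbinom(df$foci_count[rows], df$area_units[rows], p[s], log = TRUE),
        numeric(length(rows))))
    }
  } else if (fit$model == "pooled") {
    p <- pooled_draws(fit, "p")
    ll <- matrix(0, n, nrow(p))
    for (t in seq_along(fit$times)) {
      rows <- which(df$i_time == t)
      ll[rows, ] <- t(vapply(seq_len(nrow(p)), function(s)
        dbinom(df$foci_count[rows], df$area_units[rows], p[s, t], log = TRUE),
        numeric(length(rows))))
    }
  } else {
    p <- pooled_draws(fit, "p"); v <- pooled_draws(fit, "v")
    ll <- matrix(0, n, nrow(p))
    for (t in seq_along(fit$times)) {
      rows <- which(df$i_time == t)
      sh <- beta_shapes_mv(p[, t], v[, t])
      ll[rows, ] <- t(vapply(seq_len(nrow(p)), function(s)
        dbetabinom(df$foci_count[rows], df$area_units[rows], sh$alpha[s],
                   sh$beta[s], log = TRUE), numeric(length(rows))))
    }
  }
  ll
}

#' Expected focus counts per nucleus area
#'
#' Summarises `area_units * p_t` over the posterior draws: the expected
#' number of foci in a nucleus of the given area at each time, with a 95%
#' highest-density credible interval. Linear in area by construction.
#'
#' @param fit A `foci_fit`. @param area_units Nuclear area in 0.1*Pixel^2
#'   units (default 1: the per-unit-area probability itself).
#' @return Tibble with `time_h`, `median`, `cri95_lo`, `cri95_hi`.
#' @export
expected_foci <- function(fit, area_units = 1) {
  stopifnot(inherits(fit, "foci_fit"), area_units > 0)
  p <- pooled_draws(fit, "p")
  purrr::map(seq_along(fit$times), function(t) {
    d <- area_units * p[, t]
    h <- hdi(d, 0.95)
    tibble(time_h = fit$times[t], median = median(d),
           cri95_lo = h[["lo"]], cri95_hi = h[["hi"]])
  }) |> dplyr::bind_rows()
}

#' Posterior predictive check for a foci fit
#'
#' Replicates count tables from the posterior (hierarchical: binomial given
#' the drawn replicate-level probabilities; others: from the marginal) and
#' compares per-time mean counts, per-time variance/mean ratios, and the
#' maximum count against the observed table.
#'
#' @param fit A `foci_fit`. @param n_rep Replicated tables (default 500).
#' @param seed Integer seed.
#' @return Tibble with `statistic`, `observed`, `rep_mean`, `p_tail`.
#' @export
ppc_foci <- function(fit, n_rep = 500, seed = 1L) {
  stopifnot(inherits(fit, "foci_fit"))
  set.seed(seed)
  df <- fit$data
  TT <- length(fit$times)
  vm_ratio <- function(x) if (mean(x) == 0) 0 else var(x) / mean(x)
  obs <- c(vapply(seq_len(TT), function(t)
             mean(df$foci_count[df$i_time == t]), 0),
           vapply(seq_len(TT), function(t)
             vm_ratio(df$foci_count[df$i_time == t]), 0),
           max(df$foci_count))
  names(obs) <- c(sprintf("mean_t%g", fit$times),
                  sprintf("vm_ratio_t%g", fit$times), "max_count")
  if (fit$model == "hierarchical") {
    prt <- pooled_draws(fit, "p_rt")
    R <- length(fit$replicates)
    colid <- (df$i_time - 1L) * R + df$i_rep
  } else {
    p <- pooled_draws(fit, "p")
    v <- if (fit$model == "betabinom") pooled_draws(fit, "v") else NULL
  }
  S <- if (fit$model == "hierarchical") nrow(prt) else nrow(p)
  picks <- sample(S, n_rep, replace = TRUE)
  reps <- matrix(0, n_rep, length(obs))
  for (i in seq_len(n_rep)) {
    s <- picks[i]
    kr <- if (fit$model == "hierarchical") {
      rbinom(nrow(df), df$area_units, prt[s, colid])
    } else if (fit$model == "pooled") {
      rbinom(nrow(df), df$area_units, p[s, df$i_time])
    } else {
      sh <- beta_shapes_mv(p[s, df$i_time], v[s, df$i_time])
      rbinom(nrow(df), df$area_units, rbeta(nrow(df), sh$alpha, sh$beta))
    }
    reps[i, ] <- c(vapply(seq_len(TT), function(t)
                     mean(kr[df$i_time == t]), 0),
                   vapply(seq_len(TT), function(t)
                     vm_ratio(kr[df$i_time == t]), 0),
                   max(kr))
  }
  tibble(statistic = names(obs), observed = as.numeric(obs),
         rep_mean = colMeans(reps),
         p_tail = colMeans(sweep(reps, 2, obs, `>=`)))
}

#' Compare two foci fits by approximate leave-one-out cross-validation
#'
#' PSIS-LOO expected log predictive densities, their difference and its
#' standard error; a model is declared preferred only when the absolute
#' difference exceeds twice its standard error.
#'
#' @param fit_a,fit_b `foci_fit` objects on identical records with retained
#'   log-likelihood matrices.
#' @return Object of class `foci_loo_compare`: tibble of per-model elpd, the
#'   difference `elpd_a - elpd_b` with `se_diff`, and `preferred`.
#' @export
loo_compare_foci <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "foci_fit"), inherits(fit_b, "foci_fit"))
  if (is.null(fit_a$loglik) || is.null(fit_b$loglik)) {
    abort("both fits need keep_loglik = TRUE.")
  }
  key_cols <- c("cell_line", "replicate", "time_h", "nucleus_id",
                "area_units", "foci_count")
  if (!identical(as.data.frame(fit_a$data[key_cols]),
                 as.data.frame(fit_b$data[key_cols]))) {
    abort("fits were computed on different records; LOO comparison invalid.")
  }
  la <- psis_loo(fit_a$loglik)
  lb <- psis_loo(fit_b$loglik)
  d <- la$pointwise$elpd - lb$pointwise$elpd
  diff <- sum(d)
  se_diff <- sqrt(length(d) * var(d))
  preferred <- if (abs(diff) > 2 * se_diff) {
    if (diff > 0) fit_a$model else fit_b$model
  } else "indeterminate"
  structure(
    list(models = tibble(model = c(fit_a$model, fit_b$model),
                         elpd = c(la$elpd, lb$elpd),
                         se = c(la$se, lb$se),
                         n_high_k = c(la$n_high_k, lb$n_high_k)),
         elpd_diff = diff, se_diff = se_diff, preferred = preferred,
         loo_a = la, loo_b = lb),
    class = "foci_loo_compare"
  )
}

#' @export
print.foci_loo_compare <- function(x, ...) {
  print(x$models)
  cat(sprintf("elpd difference: %.2f (se %.2f) -> preferred: %s\n",
              x$elpd_diff, x$se_diff, x$preferred))
  invisible(x)
}

#' @export
print.foci_fit <- function(x, ...) {
  cat(sprintf("Foci model '%s' for cell line %s (%d nuclei, %d replicates)\n",
              x$model, x$cell_line, nrow(x$data), length(x$replicates)))
  print(tidy.foci_fit(x))
  invisible(x)
}

#' @export
tidy.foci_fit <- function(x, ...) {
  p <- pooled_draws(x, "p")
  purrr::map(seq_along(x$times), function(t) {
    h50 <- hdi(p[, t], 0.5); h95 <- hdi(p[, t], 0.95)
    tibble(time_h = x$times[t], median = median(p[, t]),
           hdi50_lo = h50[["lo"]], hdi50_hi = h50[["hi"]],
           hdi95_lo = h95[["lo"]], hdi95_hi = h95[["hi"]],
           rhat = x$diagnostics$rhat[t], ess = x$diagnostics$ess[t])
  }) |> dplyr::bind_rows()
}

#' @export
glance.foci_fit <- function(x, ...) {
  tibble(cell_line = x$cell_line, model = x$model, n = nrow(x$data),
         n_replicates = length(x$replicates), n_times = length(x$times),
         chains = length(x$draws), draws = nrow(pooled_draws(x, "p")),
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         converged = x$converged)
}

#' Posterior repair-kinetics curve
#'
#' Median focus probability per unit area over time with 50%/95% HDI ribbons
#' and the empirical per-replicate focus densities overlaid.
#'
#' @param object A `foci_fit`. @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.foci_fit <- function(object, ...) {
  td <- tidy.foci_fit(object)
  emp <- object$data |>
    group_by(.data$replicate, .data$time_h) |>
    summarise(dens = sum(.data$foci_count) / sum(.data$area_units),
              .groups = "drop")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hdi95_lo,
                                      ymax = .data$hdi95_hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hdi50_lo,
                                      ymax = .data$hdi50_hi),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::geom_point(data = emp, ggplot2::aes(y = .data$dens),
                        shape = 1) +
    ggplot2::labs(x = "hours post-irradiation",
                  y = "focus probability per 0.1*Pixel^2",
                  subtitle = sprintf("cell line %s (%s model)",
                                     object$cell_line, object$model)) +
    ggplot2::theme_minimal()
}
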