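#' Variance-stabilizing transform for abundance time courses
#'
#' Places all genes on a common scale before Gaussian-process fitting:
#' `vst(x) = log2((x + alpha) / (m + beta))`, where `m` is the gene's maximum
#' abundance over all samples (both conditions, all timepoints). The offset
#' `alpha` keeps zeros finite; the large denominator offset `beta` damps the
#' dynamic range of lowly expressed genes so a common set of hyperpriors is
#' sensible across the transcriptome.
#'
#' @param x Non-negative abundances (TPM).
#' @param m Gene maximum abundance (`max(x)` over all samples); positive.
#' @param alpha,beta Transform offsets; defaults 1 and 1000.
#' @return Transformed values, same length as `x`.
#' @seealso [inverse_vst()]
#' @examples
#' vst(c(0, 50, 100), m = 100)
#' @export
vst <- function(x, m, alpha = 1, beta = 1000) {
  check_scalar_pos(alpha, "alpha")
  check_scalar_pos(beta, "beta")
  if (any(!is.finite(m)) || any(m <= 0)) abort("`m` must be positive and finite.")
  if (any(!is.finite(x)) || any(x < 0)) abort("`x` must be non-negative and finite.")
  log2((x + alpha) / (m + beta))
}

#' Invert the variance-stabilizing transform
#'
#' Maps transformed values back to the abundance scale:
#' `x = 2^y * (m + beta) - alpha`. For any finite `y` the result lies strictly
#' above `-alpha`, the infimum of the inverse's range; values in
#' `(-alpha, 0)` can arise when back-transforming the lower edge of a
#' confidence band and are returned as-is.
#'
#' @param y Transformed values.
#' @inheritParams vst
#' @return Abundances, same length as `y`.
#' @export
inverse_vst <- function(y, m, alpha = 1, beta = 1000) {
  check_scalar_pos(alpha, "alpha")
  check_scalar_pos(beta, "beta")
  if (any(!is.finite(m)) || any(m <= 0)) abort("`m` must be positive and finite.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  2^y * (m + beta) - alpha
}

#' Matern 5/2 covariance
#'
#' `k(r) = sigma_f^2 (1 + sqrt(5) r / tau + 5 r^2 / (3 tau^2)) exp(-sqrt(5) r / tau)`
#' with `r = |t1 - t2|`. `tau` is the timescale (hours), elsewhere often
#' called the lengthscale.
#'
#' @param t1,t2 Time coordinates (recycled).
#' @param hyper List with positive elements `sigma_f`, `tau` (and optionally
#'   `sigma_n`, ignored here).
#' @return Covariance values.
#' @examples
#' matern52(0, 1, list(sigma_f = 1, tau = 2.5))
#' @export
matern52 <- function(t1, t2, hyper) {
  check_scalar_pos(hyper$sigma_f, "hyper$sigma_f")
  check_scalar_pos(hyper$tau, "hyper$tau")
  r <- abs(t1 - t2)
  a <- sqrt(5) / hyper$tau
  hyper$sigma_f^2 * (1 + a * r + (a * r)^2 / 3) * exp(-a * r)
}

# dense Matern52 gram matrix over two time vectors
matern52_gram <- function(t1, t2, sigma_f, tau) {
  r <- abs(outer(t1, t2, "-"))
  a <- sqrt(5) / tau
  sigma_f^2 * (1 + a * r + (a * r)^2 / 3) * exp(-a * r)
}

#' Normal hyperpriors over log GP hyperparameters
#'
#' The three hyperparameters are optimized in log space under independent
#' normal priors. Defaults keep the timescale comparable to the spacing of
#' developmental stages (log tau ~ N(log 2.5 h, 0.5^2)), the signal standard
#' deviation of order one on the transformed scale (log sigma_f ~ N(0, 1)),
#' and the noise below the signal (log sigma_n ~ N(-1.5, 1)).
#'
#' @param log_sigma_f,log_tau,log_sigma_n Length-2 numeric `c(mean, sd)`.
#' @return A `gp_priors` list.
#' @export
gp_priors <- function(log_sigma_f = c(0, 1),
                      log_tau = c(log(2.5), 0.5),
                      log_sigma_n = c(-1.5, 1)) {
  pr <- list(log_sigma_f = log_sigma_f, log_tau = log_tau,
             log_sigma_n = log_sigma_n)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)) || p[2] <= 0) {
      abort(sprintf("`%s` must be c(mean, sd) with sd > 0.", nm))
    }
  }
  structure(pr, class = "gp_priors")
}

# log prior density and its gradient at theta = (log sigma_f, log tau, log sigma_n)
log_prior <- function(theta, priors) {
  mu <- c(priors$log_sigma_f[1], priors$log_tau[1], priors$log_sigma_n[1])
  sd <- c(priors$log_sigma_f[2], priors$log_tau[2], priors$log_sigma_n[2])
  list(value = sum(stats::dnorm(theta, mu, sd, log = TRUE)),
       grad = -(theta - mu) / sd^2)
}

#' Gaussian-process marginal log-likelihood
#'
#' Closed-form log marginal likelihood of a zero-mean GP with Matern 5/2
#' prior covariance plus independent Gaussian observation noise:
#' `-y' K^{-1} y / 2 - log det(K) / 2 - n log(2 pi) / 2` with
#' `K = K_matern52 + sigma_n^2 I`.
#'
#' @param times Observation times (hours). Must be distinct unless
#'   `allow_duplicate_times = TRUE` (the pooled two-condition fit observes
#'   each timepoint twice; with `sigma_n > 0` the likelihood is well defined).
#' @param y Observed (transformed) values.
#' @param hyper List with positive `sigma_f`, `tau`, `sigma_n`.
#' @param allow_duplicate_times Permit repeated observation times.
#' @return The log marginal likelihood (scalar). If the Cholesky
#'   factorization fails, a diagonal jitter of `1e-8 * sigma_f^2` is applied
#'   and reported via the `"jitter"` attribute.
#' @export
gp_marginal_loglik <- function(times, y, hyper, allow_duplicate_times = FALSE) {
  if (length(times) < 1L || length(times) != length(y)) {
    abort("`times` and `y` must be non-empty and of equal length.")
  }
  if (!allow_duplicate_times && anyDuplicated(times)) {
    abort("`times` contains duplicates; set `allow_duplicate_times = TRUE` for pooled fits.")
  }
  check_scalar_pos(hyper$sigma_n, "hyper$sigma_n")
  gp <- gp_core(times, y, log(c(hyper$sigma_f, hyper$tau, hyper$sigma_n)))
  structure(gp$loglik, jitter = gp$jitter)
}

# Core GP computation at theta = log(sigma_f, tau, sigma_n): marginal
# log-likelihood, its gradient, and the Cholesky pieces for prediction.
# Gradients use d ll / d theta_j = tr((aa' - K^{-1}) dK/dtheta_j) / 2 with
# a = K^{-1} y.
gp_core <- function(times, y, theta, want_grad = FALSE) {
  n <- length(times)
  sigma_f <- exp(theta[1]); tau <- exp(theta[2]); sigma_n <- exp(theta[3])
  r <- abs(outer(times, times, "-"))
  a <- sqrt(5) / tau
  E <- exp(-a * r)
  Km <- sigma_f^2 * (1 + a * r + (a * r)^2 / 3) * E
  K <- Km + diag(sigma_n^2, n)
  jitter <- 0
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- 1e-8 * sigma_f^2
    L <- chol(K + diag(jitter, n))
  }
  alpha_v <- backsolve(L, forwardsolve(t(L), y))
  loglik <- -0.5 * sum(y * alpha_v) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  out <- list(loglik = loglik, L = L, alpha = alpha_v, jitter = jitter,
              sigma_f = sigma_f, tau = tau, sigma_n = sigma_n)
  if (want_grad) {
    Kinv <- chol2inv(L)
    W <- tcrossprod(alpha_v) - Kinv               # aa' - K^{-1}
    dK_lsf <- 2 * Km                              # d/d log sigma_f
    dK_ltau <- sigma_f^2 * ((a * r)^2 / 3) * (1 + a * r) * E
    out$grad <- 0.5 * c(sum(W * dK_lsf),
                        sum(W * dK_ltau),
                        sum(diag(W)) * 2 * sigma_n^2)
  }
  out
}

#' Fit a Gaussian process to one expression time series
#'
#' MAP estimation of the three hyperparameters (log space, normal priors) by
#' BFGS with analytic gradients followed by a Nelder-Mead polishing step,
#' multi-started from prior draws under a fixed seed. The stored `loglik` is
#' the marginal log-likelihood at the MAP, excluding the prior terms, so that
#' likelihood-ratio statistics compare marginal likelihoods.
#'
#' The posterior median and 95% confidence band are the latent-function
#' posterior mean and mean +/- 1.96 posterior sd on the transformed scale; if
#' `vst_params` is supplied they are also mapped back to the abundance scale
#' through [inverse_vst()] (a monotone map, so the median and band edges
#' transform directly).
#'
#' @param times Observation times (hours).
#' @param y Observed values on the transformed scale.
#' @param priors A [gp_priors()] object.
#' @param grid Prediction grid; defaults to the sorted unique observation
#'   times.
#' @param n_restarts Optimizer restarts drawn from the priors (default 5).
#' @param restart_seed Seed for the restart draws (deterministic fits).
#' @param vst_params Optional `list(m =, alpha =, beta =)` describing the
#'   transform, enabling original-scale output.
#' @param allow_duplicate_times Permit repeated observation times (pooled
#'   two-condition fits).
#' @return A `gp_fit` object; see [tidy.gp_fit()] and [glance.gp_fit()].
#' @export
fit_gp <- function(times, y, priors = gp_priors(), grid = NULL,
                   n_restarts = 5, restart_seed = 1L, vst_params = NULL,
                   allow_duplicate_times = FALSE) {
  if (length(times) < 1L || length(times) != length(y)) {
    abort("`times` and `y` must be non-empty and of equal length.")
  }
  if (!allow_duplicate_times && anyDuplicated(times)) {
    abort("`times` contains duplicates; set `allow_duplicate_times = TRUE` for pooled fits.")
  }
  if (!inherits(priors, "gp_priors")) abort("`priors` must come from gp_priors().")
  if (is.null(grid)) grid <- sort(unique(times))

  neg_obj <- function(theta) {
    gp <- gp_core(times, y, theta)
    -(gp$loglik + log_prior(theta, priors)$value)
  }
  neg_grad <- function(theta) {
    gp <- gp_core(times, y, theta, want_grad = TRUE)
    -(gp$grad + log_prior(theta, priors)$grad)
  }

  mu <- c(priors$log_sigma_f[1], priors$log_tau[1], priors$log_sigma_n[1])
  sd <- c(priors$log_sigma_f[2], priors$log_tau[2], priors$log_sigma_n[2])
  starts <- with_seed(restart_seed, {
    s <- matrix(stats::rnorm(3L * n_restarts, mu, sd), ncol = 3L, byrow = TRUE)
    s[1, ] <- mu  # first start at the prior mode
    s
  })

  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      o1 <- stats::optim(starts[i, ], neg_obj, neg_grad, method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-6))
      o2 <- stats::optim(o1$par, neg_obj, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-8))
      o2
    }, error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("GP fit failed from every restart.")

  theta <- best$par
  gp <- gp_core(times, y, theta)
  hyper <- list(sigma_f = gp$sigma_f, tau = gp$tau, sigma_n = gp$sigma_n)

  Ks <- matern52_gram(grid, times, gp$sigma_f, gp$tau)
  mean_g <- drop(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$L), t(Ks))
  var_g <- pmax(gp$sigma_f^2 - colSums(V^2), 0)
  sd_g <- sqrt(var_g)
  lo <- mean_g - 1.96 * sd_g
  hi <- mean_g + 1.96 * sd_g

  out <- list(hyper = hyper, loglik = gp$loglik,
              logpost = gp$loglik + log_prior(theta, priors)$value,
              times = times, y = y, grid = grid,
              median_t = mean_g, ci_low_t = lo, ci_high_t = hi,
              vst_params = vst_params, priors = priors,
              jitter = gp$jitter, converged = n_fail < n_restarts,
              n_failed_restarts = n_fail)
  if (!is.null(vst_params)) {
    p <- vst_params
    out$median <- inverse_vst(mean_g, p$m, p$alpha, p$beta)
    out$ci_low <- inverse_vst(lo, p$m, p$alpha, p$beta)
    out$ci_high <- inverse_vst(hi, p$m, p$alpha, p$beta)
  } else {
    out$median <- mean_g; out$ci_low <- lo; out$ci_high <- hi
  }
  structure(out, class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Gaussian-process fit (Matern 5/2, MAP)\n")
  cat(sprintf("  n = %d observations, marginal loglik = %.4f\n",
              length(x$y), x$loglik))
  cat(sprintf("  sigma_f = %.4g, tau = %.4g h, sigma_n = %.4g\n",
              x$hyper$sigma_f, x$hyper$tau, x$hyper$sigma_n))
  invisible(x)
}

#' Classify the direction of a differential gene
#'
#' A gene is `increased` when the morphant GP median exceeds the control
#' median on average over the prediction grid, and `decreased` otherwise
#' (ties are `decreased`).
#'
#' @param uic_fit,mo_fit `gp_fit` objects sharing a prediction grid.
#' @return `"increased"` or `"decreased"`.
#' @export
classify_direction <- function(uic_fit, mo_fit) {
  if (!identical(uic_fit$grid, mo_fit$grid)) {
    abort("Fits must share the prediction grid.")
  }
  if (mean(mo_fit$median - uic_fit$median) > 0) "increased" else "decreased"
}

#' Marginal likelihood-ratio test for temporal differential expression
#'
#' Fits three GPs: the control series (`L_U`), the morphant series (`L_M`),
#' and a single regression through both series pooled (`L_UM`); the evidence
#' for condition-specific trajectories is `LR = L_U + L_M - L_UM`.
#'
#' @param gene_id Gene identifier carried into the result.
#' @param times Shared time grid (hours).
#' @param uic,mo Abundance (TPM) series for the two conditions.
#' @param priors A [gp_priors()] object.
#' @param alpha,beta Transform offsets passed to [vst()].
#' @param lr_threshold Optional LR cutoff; fills the `called` column.
#' @param keep_fits Attach the three `gp_fit` objects as list-columns.
#' @inheritParams fit_gp
#' @return One-row tibble: `gene_id`, `L_U`, `L_M`, `L_UM`, `LR`,
#'   `direction`, `called`.
#' @export
lr_test <- function(gene_id, times, uic, mo, priors = gp_priors(),
                    alpha = 1, beta = 1000, lr_threshold = NA_real_,
                    n_restarts = 5, restart_seed = 1L, keep_fits = FALSE) {
  if (length(uic) != length(times) || length(mo) != length(times)) {
    abort("`uic` and `mo` must share the time grid.")
  }
  m <- max(uic, mo)
  if (m <= 0) abort(sprintf("Gene %s has zero abundance everywhere.", gene_id))
  vp <- list(m = m, alpha = alpha, beta = beta)
  y_u <- vst(uic, m, alpha, beta)
  y_m <- vst(mo, m, alpha, beta)
  f_u <- fit_gp(times, y_u, priors, n_restarts = n_restarts,
                restart_seed = restart_seed, vst_params = vp)
  f_m <- fit_gp(times, y_m, priors, n_restarts = n_restarts,
                restart_seed = restart_seed, vst_params = vp)
  f_um <- fit_gp(c(times, times), c(y_u, y_m), priors,
                 grid = sort(unique(times)), n_restarts = n_restarts,
                 restart_seed = restart_seed, vst_params = vp,
                 allow_duplicate_times = TRUE)
  lr <- f_u$loglik + f_m$loglik - f_um$loglik
  out <- tibble(
    gene_id = gene_id,
    L_U = f_u$loglik, L_M = f_m$loglik, L_UM = f_um$loglik, LR = lr,
    direction = classify_direction(f_u, f_m),
    called = if (is.na(lr_threshold)) NA else lr >= lr_threshold
  )
  if (keep_fits) {
    out$uic_fit <- list(f_u); out$mo_fit <- list(f_m); out$joint_fit <- list(f_um)
  }
  out
}

#' Run the LR test across a long-format expression table
#'
#' @param dataset Long tibble with columns `gene_id`, `condition`
#'   (`"UIC"`/`"MO"`), `time`, `tpm` (as produced by [read_tpm_table()] or
#'   [simulate_timecourse()]).
#' @param genes Optional gene subset (e.g. from [filter_expressed()]).
#' @inheritParams lr_test
#' @return Tibble with one row per gene (see [lr_test()]).
#' @export
gp_de <- function(dataset, genes = NULL, priors = gp_priors(),
                  alpha = 1, beta = 1000, lr_threshold = NA_real_,
                  n_restarts = 5, restart_seed = 1L) {
  check_dataset(dataset)
  if (is.null(genes)) genes <- unique(dataset$gene_id)
  purrr::map_dfr(genes, function(g) {
    d <- series_for(dataset, g)
    lr_test(g, d$times, d$uic, d$mo, priors, alpha, beta, lr_threshold,
            n_restarts, restart_seed)
  })
}

#' Posterior median trajectories for a set of genes
#'
#' Fits per-condition GPs and returns the back-transformed median and 95%
#' confidence band on the abundance scale, long format.
#'
#' @inheritParams gp_de
#' @param grid Prediction grid; defaults to the observation times.
#' @return Tibble: `gene_id`, `condition`, `time`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
gp_trajectories <- function(dataset, genes = NULL, priors = gp_priors(),
                            alpha = 1, beta = 1000, grid = NULL,
                            n_restarts = 5, restart_seed = 1L) {
  check_dataset(dataset)
  if (is.null(genes)) genes <- unique(dataset$gene_id)
  purrr::map_dfr(genes, function(g) {
    d <- series_for(dataset, g)
    m <- max(d$uic, d$mo)
    vp <- list(m = m, alpha = alpha, beta = beta)
    gg <- if (is.null(grid)) d$times else grid
    purrr::map_dfr(c(UIC = "UIC", MO = "MO"), function(cond) {
      x <- if (cond == "UIC") d$uic else d$mo
      f <- fit_gp(d$times, vst(x, m, alpha, beta), priors, grid = gg,
                  n_restarts = n_restarts, restart_seed = restart_seed,
                  vst_params = vp)
      tibble(gene_id = g, condition = cond, time = gg,
             median = f$median, ci_low = f$ci_low, ci_high = f$ci_high)
    })
  })
}

#' Null-calibrated LR threshold
#'
#' Simulates genes with no condition effect, computes the LR statistic for
#' each, and returns the empirical `1 - rate` quantile — the cutoff at which
#' a fraction `rate` of null genes would be called.
#'
#' @param n_sim Number of null genes (at least 100).
#' @param rate Target false-call rate (default 0.005, i.e. the 99.5th null
#'   percentile).
#' @param rng_seed Seed for the null simulation.
#' @param config Optional [sim_config()] template; its effect sizes are
#'   zeroed. Defaults to a maternal-decay null population.
#' @inheritParams lr_test
#' @return Scalar threshold with attribute `"null_lr"` (the simulated LRs).
#' @export
null_lr_threshold <- function(n_sim = 1000, rate = 0.005, rng_seed = 1618033,
                              config = NULL, priors = gp_priors(),
                              alpha = 1, beta = 1000,
                              n_restarts = 5, restart_seed = 1L) {
  if (n_sim < 100) abort("`n_sim` must be at least 100 for a stable quantile.")
  if (rate < 0 || rate > 1) abort("`rate` must be in [0, 1].")
  if (is.null(config)) {
    config <- sim_config(n_genes = n_sim, cluster_spec = list(),
                         seed = rng_seed, library_types = "polyA")
  } else {
    config$n_genes <- n_sim
    config$cluster_spec <- list()
    config$seed <- rng_seed
  }
  sim <- simulate_timecourse(config)
  ds <- sim$datasets[[1]]
  res <- gp_de(ds, priors = priors, alpha = alpha, beta = beta,
               n_restarts = n_restarts, restart_seed = restart_seed)
  thr <- unname(stats::quantile(res$LR, probs = 1 - rate, type = 1))
  structure(thr, null_lr = res$LR)
}

# pull one gene's aligned UIC/MO series out of a long dataset
series_for <- function(dataset, gene) {
  d <- dataset[dataset$gene_id == gene, , drop = FALSE]
  if (nrow(d) == 0L) abort(sprintf("Gene %s not present in dataset.", gene))
  d <- d[order(d$condition, d$time), ]
  u <- d[d$condition == "UIC", ]
  m <- d[d$condition == "MO", ]
  if (!identical(u$time, m$time)) abort("UIC and MO must share the time grid.")
  list(times = u$time, uic = u$tpm, mo = m$tpm)
}

check_dataset <- function(dataset) {
  need <- c("gene_id", "condition", "time", "tpm")
  if (!is.data.frame(dataset) || !all(need %in% names(dataset))) {
    abort("`dataset` must have columns gene_id, condition, time, tpm.")
  }
  bad <- setdiff(unique(dataset$condition), c("UIC", "MO"))
  if (length(bad)) abort(sprintf("Unknown condition(s): %s.", paste(bad, collapse = ", ")))
  invisible(dataset)
}
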