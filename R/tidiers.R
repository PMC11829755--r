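#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GP fit into its posterior trajectory
#'
#' @param x A `gp_fit` object.
#' @param ... Unused.
#' @return Tibble `time`, `median`, `ci_low`, `ci_high` on the abundance
#'   scale when the fit carries transform parameters, otherwise on the
#'   transformed scale.
#' @export
tidy.gp_fit <- function(x, ...) {
  tibble(time = x$grid, median = x$median,
         ci_low = x$ci_low, ci_high = x$ci_high)
}

#' One-row summary of a GP fit
#'
#' @param x A `gp_fit` object.
#' @param ... Unused.
#' @return Tibble with the MAP hyperparameters, marginal log-likelihood,
#'   log-posterior, applied jitter and convergence flag.
#' @export
glance.gp_fit <- function(x, ...) {
  tibble(sigma_f = x$hyper$sigma_f, tau = x$hyper$tau,
         sigma_n = x$hyper$sigma_n, loglik = x$loglik,
         logpost = x$logpost, jitter = x$jitter, converged = x$converged)
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment` object.
#' @param ... Unused.
#' @return Tibble `gene_id`, `cluster`.
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignment

#' One-row summary of a cluster assignment
#'
#' @param x A `cluster_assignment` object.
#' @param ... Unused.
#' @return Tibble `k`, `wcss`, `iterations`, `reseeded`, `rng_seed`.
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(k = x$k, wcss = x$wcss, iterations = length(x$objective_trace),
         reseeded = x$reseeded, rng_seed = x$rng_seed)
}
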