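#' Plot a GP fit: data, posterior median and 95% band
#'
#' @param object A `gp_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gp_fit <- function(object, ...) {
  band <- tidy(object)
  obs <- tibble(time = object$times, y = object$y)
  if (!is.null(object$vst_params)) {
    p <- object$vst_params
    obs$y <- inverse_vst(obs$y, p$m, p$alpha, p$beta)
  }
  ggplot2::ggplot(band, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y)) +
    ggplot2::labs(x = "Time (h)", y = "Abundance (TPM)")
}

#' Plot condition trajectories for a set of genes
#'
#' @param trajectories Long tibble from [gp_trajectories()].
#' @param genes Optional subset of genes to show.
#' @return A faceted ggplot of GP medians with confidence bands per
#'   condition.
#' @export
plot_trajectories <- function(trajectories, genes = NULL) {
  d <- trajectories
  if (!is.null(genes)) d <- d[d$gene_id %in% genes, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, colour = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "GP median (TPM)")
}

#' Heatmap of cluster enrichment p-values
#'
#' @param enrichment Long tibble from [enrichment_matrix()] or
#'   [cluster_enrichment_at_threshold()].
#' @return A ggplot tile map of `-log10 p` by cluster and pattern (faceted
#'   by copy-number threshold when present).
#' @export
plot_enrichment <- function(enrichment) {
  p <- ggplot2::ggplot(enrichment,
                       ggplot2::aes(x = .data$cluster, y = .data$pattern,
                                    fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ italic(P))) +
    ggplot2::labs(x = "Cluster", y = NULL)
  if ("N" %in% names(enrichment) && length(unique(enrichment$N)) > 1) {
    p <- p + ggplot2::facet_wrap(~N, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a fractional-coverage pile over the locus
#'
#' @param pile Numeric vector from [build_pile()].
#' @param bin Bin width in bp for display (default 100).
#' @return A ggplot of binned mean coverage.
#' @export
plot_pile <- function(pile, bin = 100) {
  pos <- attr(pile, "start") + seq_along(pile) - 1
  d <- tibble(bin = floor(pos / bin) * bin, value = as.numeric(pile)) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = sprintf("Position on %s (bp)", attr(pile, "chrom")),
                  y = "Fractional coverage (1/N weighted)")
}
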