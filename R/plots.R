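#' BIC curve of a cluster-number sweep
#'
#' @param object An `smx_sweep`.
#' @param ... Unused.
#' @return A ggplot: BIC against the number of clusters, the selected K
#'   highlighted.
#' @method autoplot smx_sweep
#' @export
autoplot.smx_sweep <- function(object, ...) {
  best_k <- object$best$k
  ggplot2::ggplot(object$bic, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$bic[which.min(object$bic$bic), ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "Number of clusters K", y = "BIC",
                  title = sprintf("BIC selects K = %d", best_k)) +
    ggplot2::theme_minimal()
}

#' Per-cluster fitted seasonal trajectories
#'
#' @param object An `smx_mixture`.
#' @param covariates The covariate table used in fitting (for the stored
#'   harmonic scaling).
#' @param ... Unused.
#' @return A ggplot of fitted mean counts over the year, one line per
#'   cluster (log scale).
#' @method autoplot smx_mixture
#' @export
autoplot.smx_mixture <- function(object, covariates, ...) {
  traj <- cluster_trajectories(object, covariates)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$d, y = .data$mu,
                                     colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Days from origin", y = "Fitted mean count",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Rank-abundance plot with cluster rank ranges
#'
#' @param counts Genus x sample integer matrix.
#' @param labels Cluster labels (tibble `genus_id`/`cluster` or named
#'   vector).
#' @return A ggplot: the left-skewed genus rank-abundance curve coloured
#'   by cluster, with per-cluster rank-range bars beneath.
#' @export
plot_rank_abundance <- function(counts, labels) {
  ra <- rank_abundance(counts, labels)
  ggplot2::ggplot(ra$genus,
                  ggplot2::aes(x = .data$rank, y = .data$total,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_segment(data = ra$cluster,
                          ggplot2::aes(x = .data$min_rank, xend = .data$max_rank,
                                       y = 0.5, yend = 0.5,
                                       colour = factor(.data$cluster)),
                          inherit.aes = FALSE, linewidth = 2, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Genus rank (1 = most abundant)", y = "Total reads",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Seasonal fit of a diversity/abundance response
#'
#' Overlays the observed per-sample response on the harmonic regression's
#' fitted seasonal curve (at mean elevation and depth), annotated with the
#' fitted peak and trough days.
#'
#' @param data Covariate table joined with the response column.
#' @param response Response column name.
#' @return A ggplot.
#' @export
plot_seasonal_fit <- function(data, response) {
  f <- fit_linear(data, response)
  sc <- attr(data, "scaling")
  if (is.null(sc)) abort("`data` must carry covariate scaling (join onto build_covariates() output).",
                         class = "seasonmix_input_error")
  days <- 0:365
  harm <- seasonal_harmonics(days)
  co <- setNames(f$coefficients$estimate, f$coefficients$term)
  yhat <- co["(Intercept)"] +
    co["sc"] * (harm$sc - sc$center[sc$term == "sc"]) / sc$scale[sc$term == "sc"] +
    co["ss"] * (harm$ss - sc$center[sc$term == "ss"]) / sc$scale[sc$term == "ss"]
  fitted <- tibble(d = days, y = yhat)
  pk <- peak_day(co["sc"], co["ss"],
                 sd_sc = sc$scale[sc$term == "sc"],
                 sd_ss = sc$scale[sc$term == "ss"])
  ggplot2::ggplot(data, ggplot2::aes(x = .data$d, y = .data[[response]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = fitted, ggplot2::aes(x = .data$d, y = .data$y),
                       colour = "blue") +
    ggplot2::geom_vline(xintercept = pk$peak_d, linetype = 2) +
    ggplot2::geom_vline(xintercept = pk$trough_d, linetype = 3) +
    ggplot2::labs(x = "Days from origin", y = response,
                  subtitle = sprintf("Peak %s, trough %s",
                                     pk$peak_month, pk$trough_month)) +
    ggplot2::theme_minimal()
}
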