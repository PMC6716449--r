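#' Tidy a regression fit
#'
#' @param x An `smx_fit`.
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy smx_fit
#' @export
tidy.smx_fit <- function(x, ...) x$coefficients

#' @rdname tidy.smx_fit
#' @return `glance()` returns a one-row tibble with `family`, `n`,
#'   `loglik`, `aic`, `null_deviance`, `deviance`, `r_squared`, `d`
#'   (explained deviance, percent), `theta` and `poisson_like`.
#' @method glance smx_fit
#' @export
glance.smx_fit <- function(x, ...) {
  tibble(family = x$family, n = x$n, loglik = x$loglik, aic = x$aic,
         null_deviance = x$null_deviance, deviance = x$deviance,
         r_squared = x$r_squared, d = x$d,
         theta = x$theta, poisson_like = x$poisson_like)
}

#' @export
print.smx_fit <- function(x, ...) {
  cat(sprintf("<smx_fit> %s regression, n = %d\n", x$family, x$n))
  print(x$coefficients)
  cat(sprintf("logLik %.3f  AIC %.3f  D %.2f%%\n", x$loglik, x$aic, x$d))
  invisible(x)
}

#' Tidy a fitted mixture
#'
#' @param x An `smx_mixture`.
#' @param ... Unused.
#' @return Long tibble of component parameters: `component`, `pi`,
#'   `theta`, `term`, `estimate`.
#' @method tidy smx_mixture
#' @export
tidy.smx_mixture <- function(x, ...) {
  list_rbind(map(seq_len(x$k), function(k) {
    tibble(component = k, pi = x$pi[k], theta = x$theta[k],
           term = x$term_names, estimate = unname(x$beta[k, ]))
  }))
}

#' @rdname tidy.smx_mixture
#' @method glance smx_mixture
#' @export
glance.smx_mixture <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n_param = x$n_param, n_obs = x$n_obs,
         bic = x$bic, iterations = x$iterations, converged = x$converged,
         restart = x$restart)
}

#' @export
print.smx_mixture <- function(x, ...) {
  cat(sprintf("<smx_mixture> K = %d, logLik = %.2f, BIC = %.2f (%s, %d iterations)\n",
              x$k, x$loglik, x$bic,
              if (x$converged) "converged" else "not converged", x$iterations))
  cat("mixing weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  if (length(x$events)) cat(paste0("  ", x$events, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.smx_sweep <- function(x, ...) {
  cat(sprintf("<smx_sweep> %d candidate K values; best K = %d (BIC %.2f)\n",
              nrow(x$bic), x$best$k, min(x$bic$bic)))
  print(x$bic)
  invisible(x)
}

#' @export
print.smx_pca <- function(x, ...) {
  cat(sprintf("<smx_pca> PC1 explains %.1f%% of variance (anchor: %s, oriented positive)\n",
              100 * x$var_explained, x$anchor))
  invisible(x)
}

#' @export
print.smx_env_glm <- function(x, ...) {
  cat(sprintf("<smx_env_glm> response %s (%s); retained: %s\n",
              x$response, x$family,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(intercept only)"))
  print(x$table)
  invisible(x)
}

#' @export
print.smx_report <- function(x, ...) {
  cat("<smx_report>\n")
  cat(sprintf("  %d genera x %d samples; selected K = %d\n",
              x$manifest$n_genera, x$manifest$n_samples, x$manifest$selected_k))
  cat(sprintf("  tables: diversity (%d rows), cluster effects (%d), indicators (%d)\n",
              nrow(x$diversity), nrow(x$cluster_effects), nrow(x$indicators)))
  invisible(x)
}
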