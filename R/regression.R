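# Shared fitting infrastructure -----------------------------------------

extract_xy <- function(data, response, predictors) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "seasonmix_input_error")
  }
  y <- as.numeric(data[[response]])
  X <- cbind("(Intercept)" = 1,
             as.matrix(as.data.frame(data)[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  list(y = y, X = X)
}

#' Percentage of explained deviance
#'
#' `D = 100 * (null deviance - residual deviance) / null deviance`: the
#' model-fit summary used for count regressions throughout the workflow.
#' A null model gives 0, a perfect fit 100.
#'
#' @param null_deviance,deviance Null and residual deviances (null > 0).
#' @return D, in percent.
#' @examples
#' explained_deviance(200, 100)  # 50
#' @export
explained_deviance <- function(null_deviance, deviance) {
  if (!is.finite(null_deviance) || null_deviance <= 0) {
    abort("Null deviance must be positive: D undefined.",
          class = "seasonmix_degenerate_error")
  }
  100 * (null_deviance - deviance) / null_deviance
}

new_smx_fit <- function(family, y, X, w, coefficients, loglik, n_param,
                        null_deviance, deviance, r_squared, theta = NA_real_,
                        poisson_like = FALSE) {
  d <- if (null_deviance > 0) explained_deviance(null_deviance, deviance)
       else NA_real_
  structure(list(
    family = family, y = y, X = X, w = w,
    coefficients = coefficients,
    loglik = loglik, n_param = n_param,
    aic = -2 * loglik + 2 * n_param,
    null_deviance = null_deviance, deviance = deviance,
    r_squared = r_squared, d = d,
    theta = theta, poisson_like = poisson_like,
    n = length(y)
  ), class = "smx_fit")
}

# Gaussian least squares on an explicit design matrix (with intercept).
# Maximum-likelihood sigma^2 (n denominator) so loglik/AIC line up with the
# profile likelihood; tests/SEs use the usual n - p denominator.
gaussian_fit_mat <- function(y, X) {
  n <- length(y); p <- ncol(X)
  if (n <= p) abort("Need more observations than parameters.",
                    class = "seasonmix_input_error")
  qrx <- qr(X)
  if (qrx$rank < p) {
    abort("Design matrix is rank deficient.", class = "seasonmix_singular_error")
  }
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2_hat <- rss / (n - p)
  vcov <- chol2inv(qr.R(qrx)) * sigma2_hat
  se <- sqrt(diag(vcov))
  tval <- beta / se
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(beta = beta, se = se, t = tval,
       p = 2 * pt(-abs(tval), df = n - p),
       rss = rss, tss = tss, loglik = loglik,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

refit_mat <- function(fit, keep_cols) {
  X <- fit$X[, keep_cols, drop = FALSE]
  if (fit$family == "gaussian") {
    g <- gaussian_fit_mat(fit$y, X)
    list(loglik = g$loglik, deviance = g$rss, null_deviance = g$tss,
         r_squared = g$r_squared)
  } else {
    f <- nb_fit_mat(fit$y, X, w = fit$w, theta = fit$theta,   # theta held fixed
                    offset = fit$offset)
    list(loglik = f$loglik, deviance = f$deviance,
         null_deviance = f$null_deviance, r_squared = NA_real_)
  }
}

# Reduced-model refit maximizing over all parameters (theta re-profiled for
# NB); used for likelihood-ratio tests and AIC comparisons.
refit_full_ml <- function(fit, keep_cols) {
  X <- fit$X[, keep_cols, drop = FALSE]
  if (fit$family == "gaussian") {
    g <- gaussian_fit_mat(fit$y, X)
    list(loglik = g$loglik, n_param = ncol(X) + 1)
  } else {
    f <- nb_fit_mat(fit$y, X, w = fit$w, theta = NULL, offset = fit$offset)
    list(loglik = f$loglik, n_param = ncol(X) + 1)
  }
}

predictor_terms <- function(fit) setdiff(colnames(fit$X), "(Intercept)")

check_groups <- function(fit, groups) {
  terms <- predictor_terms(fit)
  if (is.null(groups)) groups <- as.list(setNames(terms, terms))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list.", class = "seasonmix_input_error")
  }
  if (any(lengths(groups) == 0)) {
    abort("Empty predictor group.", class = "seasonmix_input_error")
  }
  unknown <- setdiff(unlist(groups), terms)
  if (length(unknown)) {
    abort(paste0("Unknown predictors in groups: ", paste(unknown, collapse = ", ")),
          class = "seasonmix_input_error")
  }
  groups
}

#' Default covariate grouping for importance analyses
#'
#' Season is represented by two coupled harmonic terms, so importance tests
#' and deviance decompositions treat `sc` + `ss` as a single group by
#' default, with elevation and depth as singleton groups.
#'
#' @return Named list of predictor groups.
#' @export
season_groups <- function() list(season = c("sc", "ss"), ele = "ele", dep = "dep")

# Exported fits ----------------------------------------------------------

#' Gaussian multiple linear regression
#'
#' Ordinary least squares of a numeric response on a set of predictor
#' columns (an intercept is always included). Coefficient p-values are
#' two-sided t-tests; the log-likelihood uses the profile (maximum
#' likelihood) error variance so AIC and likelihood-ratio tests are
#' consistent across nested fits.
#'
#' @param data Data frame holding response and predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names (defaults
#'   to the standardized design covariates `sc`, `ss`, `ele`, `dep`).
#' @return An `smx_fit` object; use [tidy()] / [glance()] to extract
#'   coefficient and fit-statistic tibbles.
#' @export
fit_linear <- function(data, response, predictors = c("sc", "ss", "ele", "dep")) {
  ym <- extract_xy(data, response, predictors)
  g <- gaussian_fit_mat(ym$y, ym$X)
  new_smx_fit(
    family = "gaussian", y = ym$y, X = ym$X, w = rep(1, length(ym$y)),
    coefficients = tibble(term = colnames(ym$X), estimate = unname(g$beta),
                          std.error = unname(g$se), statistic = unname(g$t),
                          p.value = unname(g$p)),
    loglik = g$loglik, n_param = ncol(ym$X) + 1,
    null_deviance = g$tss, deviance = g$rss, r_squared = g$r_squared
  )
}

#' Group likelihood-ratio importance tests
#'
#' Compares the full model against the model with one covariate group
#' removed (both at full maximum likelihood), for every group. The
#' statistic `2 * (loglik_full - loglik_reduced)` is referred to a
#' chi-squared distribution with degrees of freedom equal to the group
#' size. This quantifies the relative importance of season (the harmonic
#' pair jointly), elevation, and depth.
#'
#' @param fit An `smx_fit` from [fit_linear()] or [fit_nb_glm()].
#' @param groups Named list of predictor groups; default [season_groups()]
#'   restricted to the fit's terms.
#' @return Tibble: `group`, `df`, `statistic`, `p.value`.
#' @export
lrt_importance <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "smx_fit"))
  if (is.null(groups)) {
    groups <- keep(season_groups(), \(g) all(g %in% predictor_terms(fit)))
  }
  groups <- check_groups(fit, groups)
  rows <- imap(groups, function(gterms, gname) {
    keep_cols <- setdiff(colnames(fit$X), gterms)
    red <- refit_full_ml(fit, keep_cols)
    stat <- max(0, 2 * (fit$loglik - red$loglik))
    tibble(group = gname, df = length(gterms), statistic = stat,
           p.value = pchisq(stat, df = length(gterms), lower.tail = FALSE))
  })
  list_rbind(rows)
}

#' Semi-partial R-squared decomposition
#'
#' For each covariate group, the drop in R-squared when the group is
#' removed from the full Gaussian model: `delta_r2 = R2(full) - R2(without
#' group)`. Non-negative by construction; for orthogonal groups the deltas
#' sum to the full R-squared.
#'
#' @inheritParams lrt_importance
#' @return Tibble: `group`, `delta_r2`, plus the full `r_squared` as an
#'   attribute.
#' @export
r2_decomposition <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "smx_fit"))
  if (fit$family != "gaussian") {
    abort("R-squared decomposition is defined for Gaussian fits; use deviance_explained().",
          class = "seasonmix_input_error")
  }
  if (is.null(groups)) {
    groups <- keep(season_groups(), \(g) all(g %in% predictor_terms(fit)))
  }
  groups <- check_groups(fit, groups)
  rows <- imap(groups, function(gterms, gname) {
    red <- refit_mat(fit, setdiff(colnames(fit$X), gterms))
    tibble(group = gname, delta_r2 = max(0, fit$r_squared - red$r_squared))
  })
  out <- list_rbind(rows)
  attr(out, "r_squared") <- fit$r_squared
  out
}

#' Explained deviance and its per-group decomposition
#'
#' `D = 100 * (null deviance - residual deviance) / null deviance`, the
#' percentage of deviance explained by the model, and for each covariate
#' group `delta_d = D(full) - D(without group)`, refitting the reduced
#' model. For negative-binomial fits the reduced models and the null
#' deviance are evaluated at the full model's dispersion so the deltas are
#' non-negative by nesting.
#'
#' @inheritParams lrt_importance
#' @return List with `d` (scalar, percent) and `delta` (tibble: `group`,
#'   `delta_d`).
#' @export
deviance_explained <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "smx_fit"))
  if (!is.finite(fit$d)) {
    abort("Null deviance is zero: D undefined.", class = "seasonmix_degenerate_error")
  }
  if (is.null(groups)) {
    groups <- keep(season_groups(), \(g) all(g %in% predictor_terms(fit)))
  }
  groups <- check_groups(fit, groups)
  rows <- imap(groups, function(gterms, gname) {
    red <- refit_mat(fit, setdiff(colnames(fit$X), gterms))
    d_red <- 100 * (red$null_deviance - red$deviance) / red$null_deviance
    tibble(group = gname, delta_d = max(0, fit$d - d_red))
  })
  list(d = fit$d, delta = list_rbind(rows))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on all the others. Values above 10 are conventionally taken as
#' evidence of problematic multicollinearity; exactly collinear predictors
#' are reported as infinite rather than raising an error.
#'
#' @param data Data frame of predictors.
#' @param predictors Character vector of at least two column names.
#' @return Tibble: `term`, `vif`, `high` (logical, vif >= 10).
#' @export
vif <- function(data, predictors) {
  if (length(predictors) < 2) {
    abort("VIF needs at least two predictors.", class = "seasonmix_input_error")
  }
  X <- as.matrix(as.data.frame(data)[, predictors, drop = FALSE])
  rows <- map(seq_along(predictors), function(j) {
    g <- tryCatch(
      gaussian_fit_mat(X[, j], cbind(1, X[, -j, drop = FALSE])),
      seasonmix_singular_error = function(e) NULL
    )
    r2j <- if (is.null(g)) 1 else g$r_squared
    v <- if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
    tibble(term = predictors[j], vif = v, high = v >= 10)
  })
  list_rbind(rows)
}

#' Backward stepwise selection by AIC
#'
#' Starting from the full model, repeatedly drops the single predictor
#' whose removal most decreases AIC, until no removal decreases it. The
#' intercept is never dropped. For negative-binomial fits the dispersion
#' is re-profiled at every candidate model, and AIC counts it as a free
#' parameter.
#'
#' @inheritParams fit_linear
#' @param family `"gaussian"` or `"nbinom"`.
#' @return List: `fit` (the selected `smx_fit`), `retained` (character),
#'   `path` (tibble logging each elimination step).
#' @export
backward_aic <- function(data, response, predictors, family = c("gaussian", "nbinom")) {
  family <- match.arg(family)
  fitter <- function(preds) {
    if (length(preds) == 0) {
      # intercept-only model via a constant predictor-free design
      ym <- extract_xy(data, response, character(0))
      if (family == "gaussian") {
        g <- gaussian_fit_mat(ym$y, ym$X)
        new_smx_fit("gaussian", ym$y, ym$X, rep(1, length(ym$y)),
                    tibble(term = "(Intercept)", estimate = unname(g$beta),
                           std.error = unname(g$se), statistic = unname(g$t),
                           p.value = unname(g$p)),
                    g$loglik, 2, g$tss, g$rss, g$r_squared)
      } else {
        fit_nb_glm(data, response, character(0))
      }
    } else if (family == "gaussian") {
      fit_linear(data, response, preds)
    } else {
      fit_nb_glm(data, response, preds)
    }
  }
  current <- predictors
  fit <- fitter(current)
  path <- tibble(step = 0L, dropped = NA_character_, aic = fit$aic)
  step <- 0L
  while (length(current) > 0) {
    cand <- map(seq_along(current), \(j) fitter(current[-j]))
    aics <- map_dbl(cand, "aic")
    best <- which.min(aics)
    if (aics[best] >= fit$aic) break
    step <- step + 1L
    path <- bind_rows(path, tibble(step = step, dropped = current[best],
                                   aic = aics[best]))
    fit <- cand[[best]]
    current <- current[-best]
  }
  list(fit = fit, retained = current, path = path)
}

#' PCA reduction of an environmental variable block
#'
#' Principal component analysis on the correlation matrix (variables are
#' standardized first, as the blocks mix units). Returns the first
#' principal component as a single derived covariate, with the sign
#' oriented so the `anchor` variable loads positively — e.g. total C for a
#' soil block, so that positive scores read as higher organic fertility.
#'
#' @param data Data frame containing the block.
#' @param vars Column names of the block (default: all numeric columns
#'   except `sample_id`).
#' @param anchor Variable whose PC1 loading is forced positive (default:
#'   first of `vars`).
#' @return List of class `smx_pca`: `scores` (tibble, `sample_id` if
#'   present plus `pc1`), `loadings` (tibble), `var_explained` (fraction),
#'   `anchor`.
#' @export
pca_reduce <- function(data, vars = NULL, anchor = NULL) {
  df <- as.data.frame(data)
  if (is.null(vars)) {
    vars <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "sample_id")
  }
  if (length(vars) < 2 || nrow(df) < 3) {
    abort("PCA needs >= 2 variables and >= 3 samples.", class = "seasonmix_input_error")
  }
  X <- as.matrix(df[, vars, drop = FALSE])
  if (anyNA(X)) abort("PCA block contains missing values.", class = "seasonmix_input_error")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant variable(s): ", paste(vars[sds == 0], collapse = ", ")),
          class = "seasonmix_degenerate_error")
  }
  anchor <- anchor %||% vars[1]
  if (!anchor %in% vars) {
    abort("`anchor` must be one of `vars`.", class = "seasonmix_input_error")
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  flip <- if (load1[anchor] < 0) -1 else 1
  scores <- tibble(pc1 = flip * pc$x[, 1])
  if ("sample_id" %in% names(df)) {
    scores <- bind_cols(tibble(sample_id = df$sample_id), scores)
  }
  structure(list(
    scores = scores,
    loadings = tibble(term = vars, loading = unname(flip * load1)),
    var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    anchor = anchor
  ), class = "smx_pca")
}
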