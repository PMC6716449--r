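#' Backward-AIC environmental GLMs for community responses
#'
#' Regresses a community response on the reduced environmental covariates —
#' soil temperature (`st`), soil water content (`swc`), and the first
#' principal components of the soil-chemistry and plant-trait blocks
#' (`soil_pc1`, `plant_pc1`) — with backward AIC selection, then reports
#' the retained coefficients with explained deviance D and per-variable
#' delta-D. Family dispatch: Gaussian for continuous responses such as
#' genus richness or gene-copy abundance; negative binomial for per-cluster
#' sequence counts.
#'
#' @param data Data frame holding the response and environmental columns.
#' @param response Response column name.
#' @param env_vars Environmental predictor columns
#'   (default `c("st", "swc", "soil_pc1", "plant_pc1")`).
#' @param family `"auto"` (negative binomial when the response is a
#'   non-negative integer count, Gaussian otherwise), `"gaussian"`, or
#'   `"nbinom"`.
#' @return List of class `smx_env_glm`: `response`, `family`, `fit`
#'   (selected `smx_fit`), `retained`, `path`, `vif` (of the full set),
#'   and `table` (tibble: term, estimate, p.value, delta_d, d — eliminated
#'   variables appear as NA rows).
#' @export
fit_env_glm <- function(data, response,
                        env_vars = c("st", "swc", "soil_pc1", "plant_pc1"),
                        family = c("auto", "gaussian", "nbinom")) {
  family <- match.arg(family)
  if (family == "auto") {
    y <- data[[response]]
    if (is.null(y)) {
      abort(paste0("Missing response column: ", response),
            class = "seasonmix_input_error")
    }
    family <- if (all(y >= 0) && all(y == round(y))) "nbinom" else "gaussian"
  }
  vif_tbl <- vif(data, env_vars)
  sel <- backward_aic(data, response, env_vars, family = family)
  retained <- sel$retained
  tab <- tibble(term = env_vars, estimate = NA_real_, p.value = NA_real_,
                delta_d = NA_real_)
  if (length(retained) > 0) {
    de <- deviance_explained(sel$fit,
                             groups = as.list(setNames(retained, retained)))
    coefs <- sel$fit$coefficients |> filter(.data$term != "(Intercept)")
    found <- match(retained, tab$term)
    tab$estimate[found] <- coefs$estimate[match(retained, coefs$term)]
    tab$p.value[found] <- coefs$p.value[match(retained, coefs$term)]
    tab$delta_d[found] <- de$delta$delta_d[match(retained, de$delta$group)]
    d_val <- de$d
  } else {
    d_val <- 0
  }
  tab$d <- d_val
  structure(list(response = response, family = family, fit = sel$fit,
                 retained = retained, path = sel$path, vif = vif_tbl,
                 table = tab),
            class = "smx_env_glm")
}

#' @rdname fit_env_glm
#' @param responses Character vector of response columns; one backward-AIC
#'   GLM per response.
#' @return `fit_env_glms()` returns a list with `models` (named list of
#'   `smx_env_glm`) and `table` (the stacked per-response tibble, the
#'   layout of a backward-selection results table).
#' @export
fit_env_glms <- function(data, responses,
                         env_vars = c("st", "swc", "soil_pc1", "plant_pc1"),
                         family = "auto") {
  models <- map(responses, \(r) fit_env_glm(data, r, env_vars, family = family))
  names(models) <- responses
  table <- list_rbind(imap(models, \(m, r) bind_cols(tibble(response = r), m$table)))
  list(models = models, table = table)
}

#' Seasonal/spatial regressions of environmental variables
#'
#' Regresses each environmental variable on the standardized design
#' covariates (`sc`, `ss`, `ele`, `dep`) by ordinary least squares — the
#' companion analysis showing how the environment itself varies with
#' season, elevation and depth — and returns the coefficient/sign table.
#'
#' @param env Data frame of environmental variables keyed by `sample_id`.
#' @param covariates Covariate table from [build_covariates()].
#' @param vars Environmental columns to model (default
#'   `c("st", "swc", "soil_pc1", "plant_pc1")`, intersected with `env`).
#' @return List: `fits` (named list of `smx_fit`), `table` (tibble:
#'   response, term, estimate, p.value, sign, r_squared).
#' @export
env_on_design <- function(env, covariates,
                          vars = c("st", "swc", "soil_pc1", "plant_pc1")) {
  vars <- intersect(vars, names(env))
  if (length(vars) == 0) {
    abort("No requested environmental columns present.",
          class = "seasonmix_input_error")
  }
  merged <- left_join(as_tibble(env), as_tibble(covariates), by = "sample_id")
  if (anyNA(merged[, c("sc", "ss", "ele", "dep")])) {
    abort("Sample ids of `env` and `covariates` do not align.",
          class = "seasonmix_alignment_error")
  }
  fits <- map(vars, \(v) fit_linear(merged, v))
  names(fits) <- vars
  table <- list_rbind(imap(fits, function(f, v) {
    f$coefficients |>
      filter(.data$term != "(Intercept)") |>
      mutate(response = v,
             sign = ifelse(.data$p.value < 0.05, sign(.data$estimate), 0),
             r_squared = f$r_squared) |>
      select("response", "term", "estimate", "p.value", "sign", "r_squared")
  }))
  list(fits = fits, table = table)
}
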