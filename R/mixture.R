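# Finite mixture of negative-binomial regressions over genus count series.
#
# Each genus g carries one latent component z_g; given z_g = k its counts
# across all samples are independent NB with mean exp(o_g + x_s' beta_k)
# and dispersion theta_k. Responsibilities are therefore computed at the
# genus level (the per-sample log-likelihoods of a genus are summed before
# normalization), so a cluster is a set of whole genera. Estimation is
# ECM: the E-step updates responsibilities; the M-step updates the mixing
# weights, then each component's beta by responsibility-weighted IRLS and
# its theta by conditional profile maximization. Both conditional updates
# are accept-only (a candidate is kept only if it does not decrease the
# weighted likelihood), which preserves EM's monotone log-likelihood.

covariates_matrix <- function(covariates, counts) {
  req <- c("sample_id", "sc", "ss", "ele", "dep")
  if (!all(req %in% names(covariates))) {
    abort("`covariates` must come from build_covariates().",
          class = "seasonmix_input_error")
  }
  if (!setequal(covariates$sample_id, colnames(counts))) {
    missing_ids <- setdiff(colnames(counts), covariates$sample_id)
    abort(paste0("Samples missing from covariates: ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "seasonmix_alignment_error")
  }
  cv <- covariates[match(colnames(counts), covariates$sample_id), ]
  X <- cbind("(Intercept)" = 1, sc = cv$sc, ss = cv$ss, ele = cv$ele, dep = cv$dep)
  storage.mode(X) <- "double"
  X
}

# weighted NB log-likelihood of one component over the full genus x sample
# matrix; w recycles over rows (genera)
comp_loglik <- function(Y, mu, theta, w) {
  sum(w * dnbinom(Y, size = theta, mu = mu, log = TRUE))
}

comp_mu <- function(X, beta, off) {
  eta <- as.numeric(X %*% beta)
  exp(outer(off, eta, "+"))
}

# One component's M-step: responsibility-weighted NB regression. Exact
# collapsed IRLS: mu depends on the sample only (plus a fixed genus
# offset), so the weighted score sums over genera analytically.
mstep_component <- function(Y, X, w, off, beta, theta,
                            max_irls = 30, tol = 1e-10) {
  S <- ncol(Y)
  ll_old <- comp_loglik(Y, comp_mu(X, beta, off), theta, w)
  for (it in seq_len(max_irls)) {
    eta_lin <- as.numeric(X %*% beta)
    ETA <- outer(off, eta_lin, "+")
    MU <- exp(ETA)
    Wm <- w * (MU / (1 + MU / theta))
    Z <- ETA - off + (Y - MU) / MU          # working response minus offset
    cw <- colSums(Wm)
    A <- crossprod(X * cw, X)
    b <- crossprod(X, colSums(Wm * Z))
    beta_new <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta_new)) break
    # accept-only with step halving
    step <- 1
    repeat {
      cand <- beta + step * (as.numeric(beta_new) - beta)
      ll_new <- comp_loglik(Y, comp_mu(X, cand, off), theta, w)
      if (ll_new >= ll_old - 1e-10 || step < 1 / 64) break
      step <- step / 2
    }
    if (ll_new < ll_old - 1e-10) break
    moved <- max(abs(cand - beta))
    beta <- cand
    if (ll_new - ll_old < tol * (abs(ll_old) + 1) && moved < 1e-8) { ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  # conditional theta update: local window around the current value,
  # accept-only against the incumbent
  MU <- comp_mu(X, beta, off)
  obj <- function(lt) comp_loglik(Y, MU, exp(lt), w)
  lo <- max(log(.theta_bounds[1]), log(theta) - 4)
  hi <- min(log(.theta_bounds[2]), log(theta) + 4)
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, hi, log(theta))
  vals <- c(opt$objective, obj(hi), obj(log(theta)))
  theta <- exp(cand[which.max(vals)])
  list(beta = beta, theta = theta)
}

estep <- function(Y, X, beta, theta, off, log_pi) {
  K <- length(log_pi)
  G <- nrow(Y)
  lg <- matrix(0, G, K)
  for (k in seq_len(K)) {
    mu <- comp_mu(X, beta[k, ], off)
    lg[, k] <- rowSums(dnbinom(Y, size = theta[k], mu = mu, log = TRUE))
  }
  lr <- sweep(lg, 2, log_pi, "+")
  m <- apply(lr, 1, max)
  lse <- m + log(rowSums(exp(lr - m)))
  list(r = exp(lr - lse), loglik = sum(lse))
}

mixture_n_param <- function(k, p) (k - 1) + k * (p + 1)

#' Fit a K-component NB-regression mixture by EM
#'
#' Clusters the rows (genera) of a count table by which negative-binomial
#' regression on the standardized covariates (`sc`, `ss`, `ele`, `dep`)
#' best describes their count series. See the package vignette for the
#' model. Components whose mixing weight collapses below `1/(2G)` are
#' dropped and fitting continues with K - 1 (logged in `events`).
#'
#' @param counts Genus x sample integer matrix.
#' @param covariates Covariate table from [build_covariates()].
#' @param k Number of mixture components (>= 1).
#' @param seed Optional integer seed for the random initialization.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param use_offsets Include fixed per-genus abundance offsets
#'   `log(genus total / mean genus total)` in the linear predictor, letting
#'   clusters group genera by response shape across abundance ranks.
#' @param init Optional integer vector of initial hard labels (length G).
#' @return An object of class `smx_mixture`: mixing weights `pi`,
#'   coefficient matrix `beta` (k x 5), dispersions `theta`,
#'   responsibilities `r` (genus x component, rows sum to 1), `loglik`,
#'   `loglik_trace`, `bic` (`-2 loglik + n_param log(G*S)`), convergence
#'   info and dropped-component `events`.
#' @export
em_fit <- function(counts, covariates, k, seed = NULL, tol = 1e-6,
                   max_iter = 500, use_offsets = FALSE, init = NULL) {
  validate_counts(counts)
  if (k < 1) abort("`k` must be >= 1.", class = "seasonmix_input_error")
  X <- covariates_matrix(covariates, counts)
  Y <- counts
  storage.mode(Y) <- "double"
  G <- nrow(Y); S <- ncol(Y); p <- ncol(X)
  off <- rep(0, G)
  if (use_offsets) {
    tot <- rowSums(Y)
    if (any(tot == 0)) {
      abort("Per-genus offsets need positive genus totals.",
            class = "seasonmix_input_error")
    }
    off <- log(tot / mean(tot))
  }

  z0 <- if (!is.null(init)) {
    stopifnot(length(init) == G, all(init %in% seq_len(k)))
    as.integer(init)
  } else {
    with_seed_opt(seed, {
      z <- sample.int(k, G, replace = TRUE)
      empty <- setdiff(seq_len(k), unique(z))
      if (length(empty)) z[sample.int(G, length(empty))] <- empty
      z
    })
  }

  # initial M-step from the hard partition
  beta <- matrix(0, k, p, dimnames = list(NULL, colnames(X)))
  theta <- rep(1, k)
  r <- matrix(0, G, k); r[cbind(seq_len(G), z0)] <- 1
  pi_k <- colMeans(r)
  for (kk in seq_len(k)) {
    w <- r[, kk]
    beta[kk, 1] <- log(max(sum(w * rowMeans(Y)) / max(sum(w), 1e-12), 1e-8)) - 0
    ms <- mstep_component(Y, X, w, off, beta[kk, ], theta[kk])
    beta[kk, ] <- ms$beta; theta[kk] <- ms$theta
  }

  trace <- numeric(0)
  events <- character(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- estep(Y, X, beta, theta, off, log(pi_k))
    r <- es$r
    trace <- c(trace, es$loglik)

    pi_new <- colMeans(r)
    drop_k <- which(pi_new < 1 / (2 * G))
    if (length(drop_k) && ncol(r) > 1) {
      events <- c(events, sprintf(
        "iteration %d: dropped component(s) %s (weight < 1/(2G)); continuing with K=%d",
        iter, paste(drop_k, collapse = ","), ncol(r) - length(drop_k)))
      keep_idx <- setdiff(seq_len(ncol(r)), drop_k)
      r <- r[, keep_idx, drop = FALSE]
      r <- r / rowSums(r)
      beta <- beta[keep_idx, , drop = FALSE]
      theta <- theta[keep_idx]
      pi_new <- colMeans(r)
      ll_prev <- -Inf                      # likelihood scale changed
    }
    pi_k <- pi_new
    for (kk in seq_len(ncol(r))) {
      ms <- mstep_component(Y, X, r[, kk], off, beta[kk, ], theta[kk])
      beta[kk, ] <- ms$beta; theta[kk] <- ms$theta
    }
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
  }
  es <- estep(Y, X, beta, theta, off, log(pi_k))
  trace <- c(trace, es$loglik)
  k_final <- ncol(es$r)
  n_param <- mixture_n_param(k_final, p)
  rownames(es$r) <- rownames(Y)
  structure(list(
    k = k_final, k_requested = k,
    pi = pi_k, beta = beta, theta = theta,
    r = es$r, offsets = off, use_offsets = use_offsets,
    loglik = es$loglik, loglik_trace = trace,
    n_param = n_param, n_obs = G * S,
    bic = -2 * es$loglik + n_param * log(G * S),
    iterations = iter, converged = converged,
    events = events, restart = NA_integer_,
    term_names = colnames(X)
  ), class = "smx_mixture")
}

#' Best-of-restarts EM fit
#'
#' Runs [em_fit()] `n_restarts` times from independent random hard
#' partitions (sub-seeds derived deterministically from `seed`) and keeps
#' the run with the highest log-likelihood, preferring converged runs.
#'
#' @inheritParams em_fit
#' @param n_restarts Number of random restarts (default 5).
#' @param ... Passed on to [em_fit()].
#' @return The winning `smx_mixture`, with `restart` set to the winning
#'   run's index and `restart_logliks` recording every run.
#' @export
restart_best <- function(counts, covariates, k, n_restarts = 5, seed = NULL, ...) {
  stopifnot(n_restarts >= 1)
  runs <- map(seq_len(n_restarts), function(i) {
    tryCatch(em_fit(counts, covariates, k, seed = derive_seed(seed, i), ...),
             error = function(e) e)
  })
  ok <- !map_lgl_(runs, inherits, "error")
  if (!any(ok)) {
    abort(paste0("All ", n_restarts, " restarts failed; first error: ",
                 conditionMessage(runs[[1]])),
          class = "seasonmix_convergence_error")
  }
  fits <- runs[ok]
  lls <- map_dbl(fits, "loglik")
  conv <- map_lgl_(fits, \(f) isTRUE(f$converged))
  pool <- if (any(conv)) which(conv) else seq_along(fits)
  win <- pool[which.max(lls[pool])]
  best <- fits[[win]]
  best$restart <- which(ok)[win]
  best$restart_logliks <- lls
  best
}

map_lgl_ <- function(x, f, ...) vapply(x, f, logical(1), ...)

#' BIC sweep over the number of clusters
#'
#' Fits the mixture for every K in `k_range` (each via [restart_best()])
#' and selects the model minimizing BIC, computed with
#' `N = genera x samples` observations.
#'
#' @inheritParams restart_best
#' @param k_range Candidate cluster numbers (default `2:20`).
#' @return Object of class `smx_sweep`: `best` (the minimum-BIC
#'   `smx_mixture`), `bic` (tibble: k, loglik, n_param, bic, converged),
#'   and `models` (all fits). `autoplot()` draws the BIC curve.
#' @export
sweep_k <- function(counts, covariates, k_range = 2:20, n_restarts = 5,
                    seed = NULL, ...) {
  if (length(k_range) == 0) abort("`k_range` is empty.", class = "seasonmix_input_error")
  models <- map(k_range, function(k) {
    restart_best(counts, covariates, k, n_restarts = n_restarts,
                 seed = derive_seed(seed, 1000 + k), ...)
  })
  bic <- tibble(
    k = as.integer(k_range),
    k_fitted = map_int(models, "k"),
    loglik = map_dbl(models, "loglik"),
    n_param = map_int(models, "n_param"),
    bic = map_dbl(models, "bic"),
    converged = map_lgl_(models, \(m) isTRUE(m$converged))
  )
  structure(list(best = models[[which.min(bic$bic)]], bic = bic, models = models),
            class = "smx_sweep")
}

#' Hard cluster labels from a fitted mixture
#'
#' Assigns each genus to its maximum-responsibility component; exact ties
#' break toward the lowest component index.
#'
#' @param model An `smx_mixture`.
#' @return Tibble: `genus_id`, `cluster`, `responsibility` (the winning
#'   posterior probability).
#' @export
assign_clusters <- function(model) {
  stopifnot(inherits(model, "smx_mixture"))
  lab <- max.col(model$r, ties.method = "first")
  tibble(genus_id = rownames(model$r), cluster = lab,
         responsibility = model$r[cbind(seq_len(nrow(model$r)), lab)])
}

#' Per-cluster effect table from pooled refits
#'
#' For each hard cluster, pools the count series of its member genera and
#' fits a single NB regression on the standardized covariates, yielding the
#' printed per-cluster coefficients, Wald p-values, explained deviance D
#' and per-covariate delta-D. These post-hoc refits — not the soft-weighted
#' component parameters, which remain available in the model object — give
#' the effect table its well-defined p-values and deviance decomposition.
#'
#' @param model An `smx_mixture`.
#' @param counts,covariates The data the model was fit to.
#' @param groups Named list of covariate groups for delta-D (default: each
#'   covariate separately).
#' @return Tibble: `cluster`, `n_genera`, `term`, `estimate`, `std.error`,
#'   `p.value`, `delta_d`, `d`, `theta`.
#' @export
cluster_effect_table <- function(model, counts, covariates,
                                 groups = list(sc = "sc", ss = "ss",
                                               ele = "ele", dep = "dep")) {
  stopifnot(inherits(model, "smx_mixture"))
  validate_counts(counts)
  X <- covariates_matrix(covariates, counts)
  labels <- assign_clusters(model)
  rows <- map(sort(unique(labels$cluster)), function(cl) {
    members <- labels$genus_id[labels$cluster == cl]
    if (length(members) < 2) {
      inform(sprintf("Cluster %d has fewer than 2 member genera; fitted anyway.", cl))
    }
    Ym <- counts[members, , drop = FALSE]
    m <- nrow(Ym); S <- ncol(Ym)
    y <- as.vector(Ym)                               # genus fastest
    Xrep <- X[rep(seq_len(S), each = m), , drop = FALSE]
    offv <- if (model$use_offsets) rep(model$offsets[match(members, rownames(model$r))], S)
            else NULL
    f <- nb_fit_mat(y, Xrep, offset = offv)
    fit <- new_smx_fit(
      family = "nbinom", y = y, X = Xrep, w = rep(1, length(y)),
      coefficients = tibble(term = colnames(Xrep), estimate = unname(f$coefficients),
                            std.error = unname(f$se), statistic = unname(f$z),
                            p.value = unname(f$p)),
      loglik = f$loglik, n_param = ncol(Xrep) + 1,
      null_deviance = f$null_deviance, deviance = f$deviance,
      r_squared = NA_real_, theta = f$theta, poisson_like = f$poisson_like
    )
    fit$offset <- offv
    de <- deviance_explained(fit, groups = groups)
    lookup <- list_rbind(imap(groups, \(g, nm) tibble(term = g, group = nm)))
    tidy_fit <- fit$coefficients |>
      filter(.data$term != "(Intercept)") |>
      left_join(lookup, by = "term") |>
      left_join(de$delta, by = "group")
    bind_cols(tibble(cluster = cl, n_genera = m), tidy_fit) |>
      mutate(d = de$d, theta = fit$theta) |>
      select("cluster", "n_genera", "term", "estimate", "std.error",
             "p.value", "delta_d", "d", "theta")
  })
  list_rbind(rows)
}
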