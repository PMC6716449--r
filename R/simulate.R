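#' Simulation parameters for the synthetic study design
#'
#' Bundles every knob of the synthetic-data generator: the crossed
#' site x month x depth design, the environmental drivers, and the
#' K-component negative-binomial regression mixture that generates the
#' genus x sample count table. Defaults emulate a 3-site (1831.8, 1334.2,
#' 880.4 m), 12-month, 4-depth design (144 samples) with 500 genera drawn
#' from a 4-component mixture whose coefficient magnitudes sit in the
#' 0.3-1.5 range on standardized covariates.
#'
#' @param sites Data frame of `site_id`, `elevation_m`.
#' @param n_months Number of monthly sampling dates.
#' @param depth_layers Depth-layer labels.
#' @param origin First sampling date (`d = 0`).
#' @param n_genera Number of genera G.
#' @param k_true Number of mixture components.
#' @param mixing_weights Component weights, length `k_true`, summing to 1.
#' @param beta Matrix `k_true x 5` of component coefficients over
#'   (intercept, sc, ss, ele, dep), on the standardized covariate scale.
#' @param theta Positive NB dispersions, length `k_true` (variance
#'   `mu + mu^2/theta`).
#' @param genus_offset_sd SD of optional per-genus lognormal abundance
#'   offsets (0 = model-matched generation).
#' @param env_params Named list of environmental-driver settings; see
#'   [default_env_params()].
#' @return A list of class `smx_sim_params`.
#' @export
sim_params <- function(sites = default_sites(),
                       n_months = 12,
                       depth_layers = names(.depth_map),
                       origin = as.Date("2016-07-03"),
                       n_genera = 500,
                       k_true = 4,
                       mixing_weights = rep(1 / k_true, k_true),
                       beta = default_mixture_beta(k_true),
                       theta = rep(5, k_true),
                       genus_offset_sd = 0,
                       env_params = default_env_params()) {
  beta <- as.matrix(beta)
  if (abs(sum(mixing_weights) - 1) > 1e-8 || any(mixing_weights < 0)) {
    abort("`mixing_weights` must be non-negative and sum to 1.",
          class = "seasonmix_param_error")
  }
  if (any(theta <= 0)) {
    abort("All `theta` must be > 0.", class = "seasonmix_param_error")
  }
  if (length(mixing_weights) != k_true || length(theta) != k_true ||
      nrow(beta) != k_true || ncol(beta) != 5) {
    abort("`mixing_weights`, `theta` and `beta` must match `k_true` (beta is k x 5).",
          class = "seasonmix_param_error")
  }
  if (anyDuplicated(sites$elevation_m)) {
    abort("Site elevations must be distinct.", class = "seasonmix_param_error")
  }
  if (n_genera < k_true) {
    abort("`n_genera` must be >= `k_true`.", class = "seasonmix_param_error")
  }
  structure(list(
    sites = as_tibble(sites), n_months = n_months,
    depth_layers = depth_layers, origin = as.Date(origin),
    n_genera = n_genera, k_true = k_true,
    mixing_weights = mixing_weights, beta = beta, theta = theta,
    genus_offset_sd = genus_offset_sd, env_params = env_params
  ), class = "smx_sim_params")
}

#' @rdname sim_params
#' @details Default mixture components contrast seasonal phase (sine vs
#'   cosine responders), elevation affinity and depth preference, with
#'   intercepts spanning roughly two orders of magnitude of mean abundance
#'   so the pooled rank-abundance curve is left-skewed even without
#'   per-genus offsets.
#' @export
default_mixture_beta <- function(k_true = 4) {
  base <- rbind(
    c(log(50),   0.0,  0.8, -0.5,  0.0),
    c(log(20),  -0.6,  0.0,  0.9, -0.4),
    c(log(5),    0.4, -0.7,  0.0,  0.8),
    c(log(150),  0.0,  0.0, -1.2, -0.8)
  )
  if (k_true <= 4) return(base[seq_len(k_true), , drop = FALSE])
  extra <- t(vapply(seq_len(k_true - 4), function(i) {
    c(log(10) + 0.3 * i, 0.3 * (-1)^i, 0.5 * (-1)^(i + 1), 0.2 * i - 0.5, 0.3 * (-1)^i)
  }, numeric(5)))
  rbind(base, extra)
}

#' @rdname sim_params
#' @details Environmental defaults: soil temperature follows an annual
#'   sinusoid with a mid-summer peak minus a 5.5 degC/km elevational lapse;
#'   gravimetric soil water content decreases into summer and with depth
#'   but increases with elevation, clipped to \[0, 100\]; a soil-fertility
#'   latent score declines with the sine season score and depth and rises
#'   with elevation; a plant-phenology latent score declines with both
#'   season scores and with elevation. Observed soil-chemistry and
#'   plant-trait blocks load on the two latent scores with the sign
#'   structure expected of an organic-fertility gradient (C, N, C:N, NO3,
#'   PO4, NH4, K positive; pH, NO2, SO4, Ca negative) and a canopy-driven
#'   phenology gradient (canopy openness, shoot N positive; leaf C/N and
#'   shoot C ratios negative).
#' @export
default_env_params <- function() {
  list(
    st_mean = 9, st_amp_sc = 5, st_amp_ss = 3.5, st_lapse = 0.0055, st_sd = 0.8,
    swc_mean = 45, swc_sc = -8, swc_dep_cm = -0.35, swc_ele_m = 0.008, swc_sd = 4,
    fert_ss = -0.8, fert_dep_cm = -0.04, fert_ele_m = 0.0012, fert_sd = 0.5,
    plant_sc = -0.7, plant_ss = -0.7, plant_ele_m = -0.0015, plant_sd = 0.5,
    block_noise_sd = 0.6
  )
}

#' Generate the sampling design from simulation parameters
#'
#' @param params An [sim_params()] object.
#' @return A design tibble; see [design_grid()].
#' @export
make_design <- function(params = sim_params()) {
  stopifnot(inherits(params, "smx_sim_params"))
  design_grid(sites = params$sites, n_months = params$n_months,
              depth_layers = params$depth_layers, origin = params$origin)
}

#' Simulate environmental drivers over a design
#'
#' Generates per-sample soil temperature (`st`, degC), gravimetric soil
#' water content (`swc`, %), a soil-chemistry block (pH, total C/N, C:N,
#' anions, cations) driven by a latent fertility score, and a plant-trait
#' block (canopy openness, leaf/shoot C and N) driven by a latent phenology
#' score. Sign structure (recoverable by regression on the standardized
#' design covariates): `st` responds (+, +, -, 0) to (sc, ss, ele, dep);
#' `swc` responds (-, 0, +, -); fertility (0, -, +, -); phenology
#' (-, -, -, 0).
#'
#' @param design A design tibble.
#' @param params An [sim_params()] object (its `env_params` element is used).
#' @param seed Optional integer seed.
#' @return A tibble of class `smx_env` keyed by `sample_id`; latent scores
#'   are kept in the attribute `latents`.
#' @export
simulate_environment <- function(design, params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "smx_sim_params"))
  if (nrow(design) == 0) abort("`design` is empty.", class = "seasonmix_input_error")
  ep <- params$env_params
  d <- day_index(design$collection_date, params$origin)
  harm <- seasonal_harmonics(d)
  ele <- design$elevation_m - mean(design$elevation_m)
  dep <- design$depth_mid_cm - mean(design$depth_mid_cm)
  n <- nrow(design)

  with_seed_opt(seed, {
    st <- ep$st_mean + ep$st_amp_sc * harm$sc + ep$st_amp_ss * harm$ss -
      ep$st_lapse * ele + rnorm(n, 0, ep$st_sd)
    swc <- ep$swc_mean + ep$swc_sc * harm$sc + ep$swc_dep_cm * dep * 1 +
      ep$swc_ele_m * ele + rnorm(n, 0, ep$swc_sd)
    swc <- pmin(pmax(swc, 0), 100)
    fert <- ep$fert_ss * harm$ss + ep$fert_dep_cm * dep + ep$fert_ele_m * ele +
      rnorm(n, 0, ep$fert_sd)
    plant <- ep$plant_sc * harm$sc + ep$plant_ss * harm$ss +
      ep$plant_ele_m * ele + rnorm(n, 0, ep$plant_sd)

    noise <- function() rnorm(n, 0, ep$block_noise_sd)
    soil <- tibble(
      ph = 4.8 - 0.3 * fert + 0.3 * noise(),
      c_total = pmax(10 + 4 * fert + 2 * noise(), 0),
      n_total = pmax(0.6 + 0.25 * fert + 0.12 * noise(), 0),
      cn_ratio = pmax(16 + 2.5 * fert + 1.5 * noise(), 0),
      cl = pmax(12 + 1 * fert + 3 * noise(), 0),
      no2 = pmax(0.4 - 0.15 * fert + 0.1 * noise(), 0),
      no3 = pmax(8 + 2.5 * fert + 2 * noise(), 0),
      po4 = pmax(1.5 + 0.5 * fert + 0.4 * noise(), 0),
      so4 = pmax(10 - 2.5 * fert + 2 * noise(), 0),
      na = pmax(5 + 0.5 * noise(), 0),
      nh4 = pmax(3 + 1 * fert + 0.8 * noise(), 0),
      k = pmax(12 + 3 * fert + 2 * noise(), 0),
      ca = pmax(20 - 4 * fert + 3 * noise(), 0),
      mg = pmax(6 - 0.5 * fert + 1 * noise(), 0)
    )
    plant_block <- tibble(
      canopy_openness = pmin(pmax(20 + 8 * plant + 3 * noise(), 0), 100),
      leaf_c = 47 - 1.5 * plant + 1 * noise(),
      leaf_n = 2.1 - 0.35 * plant + 0.2 * noise(),
      leaf_cn = 23 - 2.5 * plant + 1.5 * noise(),
      shoot_c = 48 - 1.2 * plant + 1 * noise(),
      shoot_n = 1.1 + 0.3 * plant + 0.15 * noise(),
      shoot_cn = 45 - 5 * plant + 3 * noise()
    )
    out <- bind_cols(tibble(sample_id = design$sample_id, st = st, swc = swc),
                     soil, plant_block)
    attr(out, "latents") <- tibble(sample_id = design$sample_id,
                                   fertility = fert, phenology = plant)
    class(out) <- c("smx_env", class(out))
    out
  })
}

#' Simulate a genus x sample count table from an NB-regression mixture
#'
#' Each genus draws a latent component from the mixing weights, an optional
#' lognormal abundance offset, and independent negative-binomial counts at
#' every sample with mean `exp(offset + x' beta_k)` and dispersion
#' `theta_k`, where `x` is the standardized covariate row of the sample.
#'
#' @param design A design tibble.
#' @param params An [sim_params()] object.
#' @param seed Optional integer seed; fixed seeds make the output
#'   bit-reproducible.
#' @return A list with `counts` (integer matrix, genera x samples, dimnames
#'   set), `truth` (tibble: `genus_id`, `component`, `offset`), and
#'   `covariates` (the [build_covariates()] table used).
#' @export
simulate_community <- function(design, params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "smx_sim_params"))
  covs <- build_covariates(design, origin = params$origin)
  X <- cbind(1, covs$sc, covs$ss, covs$ele, covs$dep)
  G <- params$n_genera
  S <- nrow(design)
  with_seed_opt(seed, {
    z <- sample.int(params$k_true, G, replace = TRUE, prob = params$mixing_weights)
    off <- if (params$genus_offset_sd > 0) rnorm(G, 0, params$genus_offset_sd) else rep(0, G)
    eta <- X %*% t(params$beta)          # S x K linear predictors
    counts <- matrix(0L, G, S)
    for (g in seq_len(G)) {
      mu <- exp(eta[, z[g]] + off[g])
      counts[g, ] <- rnbinom(S, size = params$theta[z[g]], mu = mu)
    }
    genus_ids <- sprintf("g%04d", seq_len(G))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genus_ids, design$sample_id)
    list(
      counts = counts,
      truth = tibble(genus_id = genus_ids, component = z, offset = off),
      covariates = covs
    )
  })
}
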