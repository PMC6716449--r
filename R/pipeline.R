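#' Analysis configuration
#'
#' Collects every setting of the end-to-end workflow. Exactly one of the
#' two input modes must be used: file paths (`counts_path` + `design_path`,
#' optionally `env_path`) or a simulation block (`sim` = an [sim_params()]
#' object).
#'
#' @param counts_path,design_path,env_path Input TSV paths.
#' @param sim An [sim_params()] object for synthetic input.
#' @param origin Origin date for the day index (default: earliest design
#'   date).
#' @param rarefy_depth `NULL` to skip rarefaction, `"min"` to rarefy to
#'   the smallest sample total, or an integer depth.
#' @param k_range Candidate cluster numbers for the BIC sweep.
#' @param n_restarts EM restarts per K.
#' @param n_permutations Permutations for the indicator analysis.
#' @param tol,max_iter EM convergence settings.
#' @param use_offsets Per-genus abundance offsets in the mixture.
#' @param seed Master seed; expanded deterministically into per-stage
#'   substreams.
#' @return List of class `smx_config`.
#' @export
analysis_config <- function(counts_path = NULL, design_path = NULL,
                            env_path = NULL, sim = NULL,
                            origin = NULL, rarefy_depth = NULL,
                            k_range = 2:20, n_restarts = 5,
                            n_permutations = 99, tol = 1e-6, max_iter = 500,
                            use_offsets = FALSE, seed = 1) {
  have_paths <- !is.null(counts_path) || !is.null(design_path)
  have_sim <- !is.null(sim)
  if (have_paths == have_sim) {
    abort("Provide exactly one of file paths or a simulation block.",
          class = "seasonmix_input_error")
  }
  if (have_paths && (is.null(counts_path) || is.null(design_path))) {
    abort("File input needs both `counts_path` and `design_path`.",
          class = "seasonmix_input_error")
  }
  if (have_sim) stopifnot(inherits(sim, "smx_sim_params"))
  structure(list(
    counts_path = counts_path, design_path = design_path, env_path = env_path,
    sim = sim, origin = origin, rarefy_depth = rarefy_depth,
    k_range = k_range, n_restarts = n_restarts,
    n_permutations = n_permutations, tol = tol, max_iter = max_iter,
    use_offsets = use_offsets, seed = seed
  ), class = "smx_config")
}

#' Run the full seasonal community analysis
#'
#' Orchestrates the workflow end to end: input (or simulation), optional
#' rarefaction, covariate construction, harmonic diversity/abundance
#' regressions with LRT importance and R-squared decomposition, the
#' NB-mixture BIC sweep with per-cluster effect tables and seasonal
#' trajectories, the indicator-genus analysis, and (when an environment
#' table is available) PCA reduction plus backward-AIC environmental GLMs
#' and the environment-on-design regressions. Deterministic for a fixed
#' master seed.
#'
#' @param config An [analysis_config()].
#' @return List of class `smx_report` holding all result tables, the
#'   fitted objects, and a provenance manifest.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "smx_config"))
  t0 <- Sys.time()
  seed <- config$seed

  if (!is.null(config$sim)) {
    design <- make_design(config$sim)
    env <- simulate_environment(design, config$sim, seed = derive_seed(seed, 1))
    com <- simulate_community(design, config$sim, seed = derive_seed(seed, 2))
    counts <- com$counts
    truth <- com$truth
  } else {
    inp <- read_inputs(config$counts_path, config$design_path, config$env_path)
    design <- inp$design
    env <- inp$env
    counts <- inp$counts
    truth <- NULL
  }

  rarefy_depth <- config$rarefy_depth
  if (identical(rarefy_depth, "min")) rarefy_depth <- min(colSums(counts))
  if (!is.null(rarefy_depth)) {
    counts <- rarefy_counts(counts, depth = rarefy_depth,
                            seed = derive_seed(seed, 3))
    design <- design |> filter(.data$sample_id %in% colnames(counts))
    if (!is.null(env)) env <- env |> filter(.data$sample_id %in% colnames(counts))
  }
  # drop genera absent everywhere (can arise from rarefaction)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]

  covs <- build_covariates(design, origin = config$origin)
  scaling <- attr(covs, "scaling")

  ## diversity / abundance harmonic regressions (printed-table analog)
  rich <- genus_richness(counts)
  resp_tbl <- covs |>
    left_join(rich, by = "sample_id") |>
    mutate(total_count = colSums(counts)[.data$sample_id])
  # total reads are constant after rarefaction and carry no signal then
  div_responses <- c("richness",
                     if (sd(resp_tbl$total_count) > 0) "total_count")
  diversity <- list_rbind(map(div_responses, function(v) {
    f <- fit_linear(resp_tbl, v)
    lrt <- lrt_importance(f)
    dr2 <- r2_decomposition(f)
    pk <- peak_day(
      coef_sc = f$coefficients$estimate[f$coefficients$term == "sc"],
      coef_ss = f$coefficients$estimate[f$coefficients$term == "ss"],
      sd_sc = scaling$scale[scaling$term == "sc"],
      sd_ss = scaling$scale[scaling$term == "ss"],
      origin = attr(covs, "origin")
    )
    f$coefficients |>
      filter(.data$term != "(Intercept)") |>
      mutate(response = v, r_squared = f$r_squared,
             peak_doy = pk$peak_doy, trough_doy = pk$trough_doy,
             peak_month = pk$peak_month, trough_month = pk$trough_month) |>
      left_join(tibble(term = c("sc", "ss", "ele", "dep"),
                       group = c("season", "season", "ele", "dep")),
                by = "term") |>
      left_join(dr2, by = "group") |>
      left_join(lrt |> select("group", lrt_p = "p.value"), by = "group") |>
      select("response", "term", "estimate", "std.error", "p.value",
             "group", "delta_r2", "lrt_p", "r_squared",
             "peak_doy", "trough_doy", "peak_month", "trough_month")
  }))

  ## mixture clustering
  sweep <- sweep_k(counts, covs, k_range = config$k_range,
                   n_restarts = config$n_restarts,
                   seed = derive_seed(seed, 4),
                   tol = config$tol, max_iter = config$max_iter,
                   use_offsets = config$use_offsets)
  model <- sweep$best
  labels <- assign_clusters(model)
  effects <- cluster_effect_table(model, counts, covs)
  ranks <- rank_abundance(counts, labels)
  trajectories <- cluster_trajectories(model, covs)

  ## indicator genera
  indicators <- indicator_table(counts, labels,
                                n_permutations = config$n_permutations,
                                seed = derive_seed(seed, 5))

  ## environmental GLMs
  env_glms <- NULL; env_design <- NULL; soil_pca <- NULL; plant_pca <- NULL
  if (!is.null(env)) {
    soil_vars <- intersect(c("ph", "c_total", "n_total", "cn_ratio", "cl",
                             "no2", "no3", "po4", "so4", "na", "nh4", "k",
                             "ca", "mg"), names(env))
    plant_vars <- intersect(c("canopy_openness", "leaf_c", "leaf_n", "leaf_cn",
                              "shoot_c", "shoot_n", "shoot_cn"), names(env))
    env_red <- env |> select("sample_id", "st", "swc")
    if (length(soil_vars) >= 2) {
      soil_pca <- pca_reduce(env, soil_vars,
                             anchor = intersect("c_total", soil_vars)[1] %||% soil_vars[1])
      env_red <- env_red |>
        left_join(soil_pca$scores |> rename(soil_pc1 = "pc1"), by = "sample_id")
    }
    if (length(plant_vars) >= 2) {
      plant_pca <- pca_reduce(env, plant_vars,
                              anchor = intersect("canopy_openness", plant_vars)[1] %||% plant_vars[1])
      env_red <- env_red |>
        left_join(plant_pca$scores |> rename(plant_pc1 = "pc1"), by = "sample_id")
    }
    env_vars <- intersect(c("st", "swc", "soil_pc1", "plant_pc1"), names(env_red))

    cluster_counts <- t(rowsum(counts, labels$cluster[match(rownames(counts),
                                                            labels$genus_id)]))
    colnames(cluster_counts) <- paste0("cluster_", colnames(cluster_counts))
    glm_data <- resp_tbl |>
      left_join(env_red, by = "sample_id") |>
      bind_cols(as_tibble(cluster_counts))
    responses <- c(div_responses, colnames(cluster_counts))
    families <- c(rep("gaussian", length(div_responses)),
                  rep("auto", ncol(cluster_counts)))
    env_models <- map2(responses, families,
                       \(r, fam) fit_env_glm(glm_data, r, env_vars, family = fam))
    names(env_models) <- responses
    env_glms <- list(
      models = env_models,
      table = list_rbind(imap(env_models,
                              \(m, r) bind_cols(tibble(response = r), m$table)))
    )
    env_design <- env_on_design(env_red, covs, vars = env_vars)
  }

  manifest <- list(
    package_version = as.character(packageVersion("seasonmix")),
    r_version = R.version.string,
    seed = seed,
    config = config[setdiff(names(config), "sim")],
    simulated = !is.null(config$sim),
    n_genera = nrow(counts), n_samples = ncol(counts),
    selected_k = model$k,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    created = format(t0, "%Y-%m-%d %H:%M:%S %Z")
  )

  structure(list(
    design = design, covariates = covs, counts = counts, env = env,
    truth = truth,
    diversity = diversity,
    sweep = sweep, model = model, labels = labels,
    cluster_effects = effects, rank_abundance = ranks,
    trajectories = trajectories,
    indicators = indicators,
    soil_pca = soil_pca, plant_pca = plant_pca,
    env_glms = env_glms, env_design = env_design,
    manifest = manifest
  ), class = "smx_report")
}

#' Predicted per-cluster seasonal trajectories
#'
#' Evaluates each component's fitted mean count over a grid of days
#' (standardizing the harmonic scores with the covariate table's stored
#' scaling) at reference elevation/depth (their standardized means, 0).
#'
#' @param model An `smx_mixture`.
#' @param covariates The covariate table the model was fit with.
#' @param days Integer grid of day indices (default 0..365).
#' @return Tibble: `cluster`, `d`, `mu`.
#' @export
cluster_trajectories <- function(model, covariates, days = 0:365) {
  stopifnot(inherits(model, "smx_mixture"))
  sc <- attr(covariates, "scaling")
  if (is.null(sc)) {
    abort("`covariates` lacks the scaling attribute from build_covariates().",
          class = "seasonmix_input_error")
  }
  harm <- seasonal_harmonics(days)
  Xg <- cbind(1,
              (harm$sc - sc$center[sc$term == "sc"]) / sc$scale[sc$term == "sc"],
              (harm$ss - sc$center[sc$term == "ss"]) / sc$scale[sc$term == "ss"],
              0, 0)
  list_rbind(map(seq_len(model$k), function(k) {
    tibble(cluster = k, d = days,
           mu = as.numeric(exp(Xg %*% model$beta[k, ])))
  }))
}

#' Write a report bundle to disk
#'
#' Serializes every result table as TSV plus a JSON manifest (config echo,
#' seed, versions, wall clock, file list). Refuses to overwrite an
#' existing report unless `overwrite = TRUE`.
#'
#' @param report An `smx_report` from [run_analysis()].
#' @param outdir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @return Invisible character vector of written paths.
#' @export
write_report <- function(report, outdir, overwrite = FALSE) {
  stopifnot(inherits(report, "smx_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create ", outdir), class = "seasonmix_io_error")
  }
  tables <- list(
    design = report$design,
    covariates = as_tibble(report$covariates),
    diversity_regressions = report$diversity,
    bic_curve = report$sweep$bic,
    cluster_labels = report$labels,
    cluster_effects = report$cluster_effects,
    cluster_trajectories = report$trajectories,
    rank_abundance = report$rank_abundance$genus,
    cluster_rank_ranges = report$rank_abundance$cluster,
    indicators = as_tibble(report$indicators)
  )
  if (!is.null(report$env_glms)) tables$env_glms <- report$env_glms$table
  if (!is.null(report$env_design)) tables$env_design <- report$env_design$table
  tables <- tables[!vapply(tables, is.null, logical(1))]
  files <- file.path(outdir, paste0(names(tables), ".tsv"))
  manifest_path <- file.path(outdir, "manifest.json")
  existing <- c(files, manifest_path)[file.exists(c(files, manifest_path))]
  if (length(existing) && !overwrite) {
    abort(paste0("Refusing to overwrite existing report files (set overwrite = TRUE): ",
                 paste(basename(existing), collapse = ", ")),
          class = "seasonmix_io_error")
  }
  for (i in seq_along(tables)) readr::write_tsv(tables[[i]], files[i])
  manifest <- c(report$manifest, list(files = basename(files)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  if (!is.null(report$counts)) {
    cpath <- file.path(outdir, "counts.tsv")
    write_count_table(report$counts, cpath)
    files <- c(files, cpath)
  }
  invisible(c(files, manifest_path))
}
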