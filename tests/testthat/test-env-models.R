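env_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- sim_params()
      design <- make_design(params)
      env <- simulate_environment(design, params, seed = 61)
      soil_vars <- c("ph", "c_total", "n_total", "cn_ratio", "cl", "no2",
                     "no3", "po4", "so4", "na", "nh4", "k", "ca", "mg")
      plant_vars <- c("canopy_openness", "leaf_c", "leaf_n", "leaf_cn",
                      "shoot_c", "shoot_n", "shoot_cn")
      soil <- pca_reduce(env, soil_vars, anchor = "c_total")
      plant <- pca_reduce(env, plant_vars, anchor = "canopy_openness")
      env$soil_pc1 <- soil$scores$pc1
      env$plant_pc1 <- plant$scores$pc1
      cache <<- list(design = design, env = env,
                     covariates = build_covariates(design, params$origin))
    }
    cache
  }
})

test_that("family dispatch is total and explicit families are honoured", {
  fx <- env_fixture()
  dat <- fx$env
  dat$richness <- withr::with_seed(1, rnorm(nrow(dat), 50 + 5 * dat$soil_pc1, 2))
  dat$counts <- withr::with_seed(2, rpois(nrow(dat), 20))
  expect_equal(fit_env_glm(dat, "richness")$family, "gaussian")
  expect_equal(fit_env_glm(dat, "counts")$family, "nbinom")
  expect_equal(fit_env_glm(dat, "counts", family = "gaussian")$family, "gaussian")
  expect_error(fit_env_glm(dat, "richness", family = "binomial"))
  expect_error(fit_env_glm(dat, "absent"), class = "seasonmix_input_error")
})

test_that("backward selection finds the planted environmental driver", {
  fx <- env_fixture()
  dat <- fx$env
  # richness driven by soil fertility only
  dat$richness <- withr::with_seed(3, rnorm(nrow(dat), 50 + 5 * dat$soil_pc1, 2))
  m <- fit_env_glm(dat, "richness")
  expect_true("soil_pc1" %in% m$retained)
  expect_gt(m$table$estimate[m$table$term == "soil_pc1"], 0)
  expect_gt(m$table$delta_d[m$table$term == "soil_pc1"], 50)

  # cluster counts suppressed by soil water content
  dat$ccount <- withr::with_seed(4, {
    rnbinom(nrow(dat), mu = exp(3 - 0.08 * dat$swc), size = 3)
  })
  m2 <- fit_env_glm(dat, "ccount")
  expect_true("swc" %in% m2$retained)
  expect_lt(m2$table$estimate[m2$table$term == "swc"], 0)

  # pure-noise responses mostly collapse to (or near) the intercept: AIC
  # keeps each 1-df null predictor with probability ~0.157, so the
  # expected number retained out of four is ~0.6
  retained_n <- sapply(1:15, function(i) {
    dat$noise <- withr::with_seed(100 + i, rnorm(nrow(dat)))
    length(fit_env_glm(dat, "noise")$retained)
  })
  expect_gt(mean(retained_n == 0), 0.25)
  expect_lt(mean(retained_n), 1.5)
  expect_true(all(fit_env_glm(dat, "richness")$vif$vif < 10))
})

test_that("stacked multi-response tables mirror the selection results", {
  fx <- env_fixture()
  dat <- fx$env
  dat$r1 <- withr::with_seed(5, rnorm(nrow(dat), 10 + 3 * dat$st, 1))
  dat$r2 <- withr::with_seed(6, rnorm(nrow(dat), 10 - 2 * dat$swc, 1))
  out <- fit_env_glms(dat, c("r1", "r2"))
  expect_equal(nrow(out$table), 8)   # 2 responses x 4 env variables
  expect_setequal(unique(out$table$response), c("r1", "r2"))
  expect_gt(out$table$estimate[out$table$response == "r1" &
                                 out$table$term == "st"], 0)
})

test_that("environment-on-design regressions reproduce the generator's sign structure", {
  fx <- env_fixture()
  ed <- env_on_design(fx$env, fx$covariates)
  # a stringent alpha for the expected-zero entries so a single-seed
  # 2-sigma fluke does not register as a sign
  sgn <- function(resp, alpha = 0.005) {
    s <- ed$table[ed$table$response == resp, ]
    s <- s[match(c("sc", "ss", "ele", "dep"), s$term), ]
    unname(ifelse(s$p.value < alpha, sign(s$estimate), 0))
  }
  expect_equal(sgn("st"), c(1, 1, -1, 0))
  expect_equal(sgn("swc"), c(-1, 0, 1, -1))
  expect_equal(sgn("soil_pc1")[2:4], c(-1, 1, -1))
  expect_equal(sgn("plant_pc1")[1:3], c(-1, -1, -1))
  expect_error(env_on_design(fx$env[, "sample_id", drop = FALSE],
                             fx$covariates),
               class = "seasonmix_input_error")
})

test_that("sign recovery is stable across generator replicates", {
  params <- sim_params()
  design <- make_design(params)
  cov <- build_covariates(design, params$origin)
  ok <- sapply(1:20, function(i) {
    env <- simulate_environment(design, params, seed = 700 + i)
    ed <- env_on_design(env, cov, vars = c("st", "swc"))
    st <- ed$table[ed$table$response == "st", ]
    swc <- ed$table[ed$table$response == "swc", ]
    all(st$sign[st$term %in% c("sc", "ss")] == 1,
        st$sign[st$term == "ele"] == -1,
        swc$sign[swc$term == "sc"] == -1,
        swc$sign[swc$term == "ele"] == 1,
        swc$sign[swc$term == "dep"] == -1)
  })
  expect_gte(mean(ok), 0.95)
})
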