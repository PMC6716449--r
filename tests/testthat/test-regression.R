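test_that("linear fits reproduce exact relationships and the normal-equations solution", {
  d <- data.frame(x = c(-2, -1, 0, 1, 2))
  d$y <- 2 * d$x + 1
  f <- fit_linear(d, "y", "x")
  expect_equal(tidy(f)$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(glance(f)$r_squared, 1)

  # independent closed-form solve on random problems
  for (seed in 1:5) {
    dat <- random_design(25, 3, seed = seed)
    dat$y <- withr::with_seed(seed + 100, rnorm(25, 1 + dat$x1 - 0.5 * dat$x3, 0.7))
    f <- fit_linear(dat, "y", c("x1", "x2", "x3"))
    X <- cbind(1, as.matrix(dat[, c("x1", "x2", "x3")]))
    beta_oracle <- solve(t(X) %*% X, t(X) %*% dat$y)
    expect_equal(tidy(f)$estimate, as.numeric(beta_oracle), tolerance = 1e-10)
    # loglik matches the profile-variance closed form
    rss <- sum((dat$y - X %*% beta_oracle)^2)
    n <- nrow(dat)
    expect_equal(glance(f)$loglik, -n / 2 * (log(2 * pi) + log(rss / n) + 1),
                 tolerance = 1e-10)
  }

  dd <- data.frame(x1 = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_linear(dd, "y", c("x1", "x2")),
               class = "seasonmix_singular_error")
})

test_that("noise-only responses give small R2 and well-calibrated coefficient p-values", {
  pvals <- sapply(1:200, function(i) {
    dat <- random_design(40, 2, seed = 2000 + i)
    dat$y <- withr::with_seed(3000 + i, rnorm(40))
    f <- fit_linear(dat, "y", c("x1", "x2"))
    tidy(f)$p.value[2]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("group LRTs match the loglik identity and are calibrated under the null", {
  dat <- random_design(60, 3, seed = 9)
  dat$y <- withr::with_seed(10, rnorm(60, dat$x1, 1))
  f <- fit_linear(dat, "y", c("x1", "x2", "x3"))
  lrt <- lrt_importance(f, groups = list(g23 = c("x2", "x3"), g1 = "x1"))
  # statistic equals 2 * (loglik_full - loglik_reduced) with the reduced
  # loglik computed independently via lm's ML loglik
  red <- stats::lm(y ~ x1, data = dat)
  expect_equal(lrt$statistic[lrt$group == "g23"],
               as.numeric(2 * (glance(f)$loglik - stats::logLik(red))),
               tolerance = 1e-8)
  expect_equal(lrt$df, c(2L, 1L))

  # a group whose coefficients are exactly zero by construction: the
  # response lives in span(intercept, x1) plus a residual direction
  # orthogonal to every predictor, so dropping (x2, x3) changes nothing
  Q <- withr::with_seed(15, qr.Q(qr(cbind(1, matrix(rnorm(30 * 4), 30, 4)))))
  dat2 <- data.frame(x1 = Q[, 2], x2 = Q[, 3], x3 = Q[, 4])
  dat2$y <- 2 * dat2$x1 + 0.3 * Q[, 5]
  f2 <- fit_linear(dat2, "y", c("x1", "x2", "x3"))
  lrt2 <- lrt_importance(f2, groups = list(null_grp = c("x2", "x3")))
  expect_lt(lrt2$statistic, 1e-6)
  expect_gt(lrt2$p.value, 0.999)

  # null calibration of the season-group test on the real design
  cv <- build_covariates(design_grid())
  rejections <- sapply(1:300, function(i) {
    dat <- cv
    dat$y <- withr::with_seed(5000 + i, rnorm(nrow(cv)))
    lrt_importance(fit_linear(dat, "y"), groups = list(season = c("sc", "ss")))$p.value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.04)
})

test_that("semi-partial R2 decomposes exactly for orthogonal predictors", {
  Q <- withr::with_seed(17, qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40, 3)))))
  dat <- data.frame(x1 = Q[, 2], x2 = Q[, 3], x3 = Q[, 4])
  dat$y <- withr::with_seed(77, 1.2 * dat$x1 - 0.8 * dat$x2 + rnorm(40, 0, 0.1))
  f <- fit_linear(dat, "y", c("x1", "x2", "x3"))
  dr2 <- r2_decomposition(f, groups = list(a = "x1", b = "x2", c = "x3"))
  expect_true(all(dr2$delta_r2 >= 0))
  expect_equal(sum(dr2$delta_r2), glance(f)$r_squared, tolerance = 1e-10)

  # a zero-effect group's delta shrinks with n
  dat_big <- random_design(2000, 2, seed = 6)
  dat_big$y <- withr::with_seed(61, rnorm(2000, dat_big$x1, 1))
  f_big <- fit_linear(dat_big, "y", c("x1", "x2"))
  dr2_big <- r2_decomposition(f_big, groups = list(signal = "x1", noise = "x2"))
  expect_lt(dr2_big$delta_r2[dr2_big$group == "noise"], 0.005)
})

test_that("explained deviance follows its defining formula and bounds", {
  expect_equal(explained_deviance(200, 100), 50)
  expect_equal(explained_deviance(150, 150), 0)   # null model
  expect_equal(explained_deviance(80, 0), 100)    # perfect fit
  expect_error(explained_deviance(0, 0), class = "seasonmix_degenerate_error")

  # through a fitted model: D is invariant to affine predictor rescaling
  dat <- random_design(80, 2, seed = 12)
  dat$y <- withr::with_seed(13, rpois(80, exp(1 + 0.5 * dat$x1)))
  f1 <- fit_nb_glm(dat, "y", c("x1", "x2"))
  dat2 <- dat
  dat2$x1 <- 10 * dat$x1 + 3
  f2 <- fit_nb_glm(dat2, "y", c("x1", "x2"))
  expect_equal(glance(f1)$d, glance(f2)$d, tolerance = 1e-4)
  de <- deviance_explained(f1, groups = list(a = "x1", b = "x2"))
  expect_true(all(de$delta$delta_d >= 0))
  expect_true(de$d >= 0 && de$d <= 100)
})

test_that("VIF matches its closed form and flags exact collinearity", {
  # columns orthogonal to each other *and* to the intercept (centered), so
  # the auxiliary regressions have R2 exactly 0
  Q <- withr::with_seed(16, qr.Q(qr(cbind(1, matrix(rnorm(50 * 3), 50, 3)))))
  dat <- data.frame(x1 = Q[, 2], x2 = Q[, 3], x3 = Q[, 4])
  v <- vif(dat, c("x1", "x2", "x3"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)

  # correlation exactly 0.9 between two centered predictors
  dat2 <- data.frame(x1 = Q[, 2], x2 = 0.9 * Q[, 2] + sqrt(1 - 0.81) * Q[, 3])
  v2 <- vif(dat2, c("x1", "x2"))
  expect_equal(v2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-8)

  dat3 <- data.frame(x1 = Q[, 1], x2 = Q[, 1])
  v3 <- vif(dat3, c("x1", "x2"))
  expect_true(all(is.infinite(v3$vif)))
  expect_error(vif(dat3, "x1"), class = "seasonmix_input_error")
})

test_that("backward AIC keeps strong effects and prunes noise", {
  withr::with_seed(41, {
    n <- 500
    dat <- data.frame(strong = rnorm(n), noise = rnorm(n))
    dat$y <- rnorm(n, 1 + 1.0 * dat$strong, 1)
    sel <- backward_aic(dat, "y", c("strong", "noise"))
    expect_true("strong" %in% sel$retained)
    expect_false("noise" %in% sel$retained)
    expect_equal(sel$path$dropped[2], "noise")

    # all-strong: nothing dropped
    dat$y2 <- rnorm(n, dat$strong + dat$noise, 0.5)
    sel2 <- backward_aic(dat, "y2", c("strong", "noise"))
    expect_setequal(sel2$retained, c("strong", "noise"))
  })
  # independent response: intercept-only is the modal outcome. AIC keeps a
  # 1-df null predictor with asymptotic probability P(chi2_1 > 2) = 0.157,
  # so all three are pruned in about 0.843^3 = 60% of replicates.
  empty <- sapply(1:30, function(i) {
    dat <- random_design(500, 3, seed = 7000 + i)
    dat$y <- withr::with_seed(8000 + i, rnorm(500))
    length(backward_aic(dat, "y", c("x1", "x2", "x3"))$retained) == 0
  })
  expect_gt(mean(empty), 0.4)
})

test_that("PCA reduction orients by anchor and reports variance shares", {
  withr::with_seed(19, {
    base <- rnorm(60)
    dat <- data.frame(a = 2 * base + 5, b = -3 * base + 1)
    p <- pca_reduce(dat, c("a", "b"), anchor = "a")
    expect_equal(p$var_explained, 1, tolerance = 1e-12)
    expect_gt(p$loadings$loading[p$loadings$term == "a"], 0)
    # scores track the anchor variable
    expect_gt(cor(p$scores$pc1, dat$a), 0.999)

    # independent standardized variables: PC1 share approaches 1/p
    big <- as.data.frame(matrix(rnorm(4000 * 5), 4000, 5))
    pb <- pca_reduce(big, names(big), anchor = "V1")
    expect_lt(abs(pb$var_explained - 1 / 5), 0.05)
    expect_gt(pb$loadings$loading[1], 0)

    dat$c <- 1
    expect_error(pca_reduce(dat, c("a", "c")), class = "seasonmix_degenerate_error")
  })
})
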