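test_that("day_index counts exact calendar days", {
  origin <- as.Date("2016-07-03")
  expect_identical(day_index(origin, origin), 0L)
  expect_identical(day_index(as.Date("2016-07-04"), origin), 1L)
  # 2016-07-03 -> 2017-07-03 spans no Feb 29
  expect_identical(day_index(as.Date("2017-07-03"), origin), 365L)
  expect_identical(day_index(as.Date("2016-07-01"), origin), -2L)
  expect_error(day_index("not-a-date", origin), class = "seasonmix_input_error")
})

test_that("seasonal harmonics evaluate the annual cosine/sine pair", {
  h0 <- seasonal_harmonics(0)
  expect_equal(c(h0$sc, h0$ss), c(1, 0))
  h365 <- seasonal_harmonics(365)
  expect_equal(c(h365$sc, h365$ss), c(1, 0), tolerance = 1e-12)
  # day 274 sits a hair past three quarters of the period: the cosine is a
  # small positive value (sin of the 0.0043-rad excess) and the sine is
  # within 1e-5 of -1
  h274 <- seasonal_harmonics(274)
  eps <- 2 * pi * 274 / 365 - 3 * pi / 2
  expect_equal(h274$sc, sin(eps), tolerance = 1e-12)
  expect_lt(abs(h274$sc - 0.0043), 1e-4)
  expect_lt(abs(h274$ss + 1), 1e-4)
  # unit circle and exact 365-day period for arbitrary days
  d <- -400:900
  h <- seasonal_harmonics(d)
  expect_equal(h$sc^2 + h$ss^2, rep(1, length(d)), tolerance = 1e-12)
  hshift <- seasonal_harmonics(d + 365)
  expect_equal(h$sc, hshift$sc, tolerance = 1e-9)
  expect_equal(h$ss, hshift$ss, tolerance = 1e-9)
  expect_error(seasonal_harmonics(1.5), class = "seasonmix_input_error")
})

test_that("depth layers map to their midpoints, with label aliases", {
  expect_equal(depth_midpoint("0-5"), 2.5)
  expect_equal(depth_midpoint("0–5 cm"), 2.5)   # en-dash + unit
  expect_equal(depth_midpoint("20-30"), 25)
  expect_equal(depth_midpoint(c("5-10 cm", "10-20")), c(7.5, 15))
  expect_equal(depth_midpoint(7.5), 7.5)
  expect_error(depth_midpoint("30-40"), class = "seasonmix_input_error")
  expect_error(depth_midpoint(3), class = "seasonmix_input_error")
})

test_that("standardization centers, scales by sample sd, and inverts exactly", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  expect_error(standardize(c(5, 5, 5)), class = "seasonmix_degenerate_error")
  expect_error(standardize(1), class = "seasonmix_input_error")
  withr::with_seed(4, {
    x <- rnorm(50, 10, 7)
    z <- standardize(x)
    expect_equal(unstandardize(z), x, tolerance = 1e-12)
    # idempotent on already-standardized input
    z2 <- standardize(as.numeric(z))
    expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-9)
  })
})

test_that("the default design enumerates the full 3 x 12 x 4 crossing", {
  d <- design_grid()
  expect_equal(nrow(d), 144)
  expect_equal(anyDuplicated(d[, c("site_id", "collection_date", "depth_layer")]), 0)
  expect_setequal(unique(d$depth_mid_cm), c(2.5, 7.5, 15, 25))
  expect_equal(min(d$collection_date), as.Date("2016-07-03"))
  # depth_mid_cm is a pure function of depth_layer
  expect_equal(d$depth_mid_cm, depth_midpoint(d$depth_layer))

  one <- design_grid(sites = data.frame(site_id = "a", elevation_m = 100),
                     n_months = 1, depth_layers = "0-5")
  expect_equal(nrow(one), 1)
  d24 <- design_grid(sites = data.frame(site_id = c("a", "b"),
                                        elevation_m = c(1, 2)),
                     n_months = 3)
  expect_equal(nrow(d24), 24)
  expect_error(design_grid(n_months = 0), class = "seasonmix_input_error")
})

test_that("covariate matrix is standardized and back-transformable", {
  cv <- build_covariates(design_grid())
  for (v in c("sc", "ss", "ele", "dep")) {
    expect_lt(abs(mean(cv[[v]])), 1e-9)
    expect_lt(abs(sd(cv[[v]]) - 1), 1e-9)
  }
  sc <- attr(cv, "scaling")
  # inverting the standardization must recover the raw harmonics exactly,
  # which lie on the unit circle
  sc_raw <- cv$sc * sc$scale[sc$term == "sc"] + sc$center[sc$term == "sc"]
  ss_raw <- cv$ss * sc$scale[sc$term == "ss"] + sc$center[sc$term == "ss"]
  expect_equal(sc_raw^2 + ss_raw^2, rep(1, nrow(cv)), tolerance = 1e-12)
  ele_raw <- cv$ele * sc$scale[sc$term == "ele"] + sc$center[sc$term == "ele"]
  expect_setequal(round(unique(ele_raw), 6), c(1831.8, 1334.2, 880.4))
})

test_that("peak day back-calculates the fitted seasonal maximum", {
  origin <- as.Date("2016-07-03")
  # pure cosine peaks on the origin date
  p <- peak_day(1, 0, origin = origin)
  expect_equal(p$peak_d, 0)
  expect_equal(p$peak_date, origin)

  # peak and trough are half a period apart, and positive rescaling of
  # both coefficients leaves the peak unchanged
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(1); b <- rnorm(1)
      if (a == 0 && b == 0) next
      pk <- peak_day(a, b, origin = origin)
      expect_equal((pk$trough_d - pk$peak_d) %% 365, 182.5)
      pk2 <- peak_day(3.7 * a, 3.7 * b, origin = origin)
      expect_equal(pk$peak_d, pk2$peak_d, tolerance = 1e-9)
    }
  })
  expect_error(peak_day(0, 0), class = "seasonmix_no_seasonality_error")
  expect_error(peak_day(1, 1, sd_sc = 0), class = "seasonmix_input_error")
})

test_that("published-style harmonic coefficients place peaks in spring and troughs in autumn", {
  origin <- as.Date("2016-07-03")
  oct_window <- function(doy) doy >= 271 & doy <= 305  # Sep 28 .. Nov 1
  # fungal genus richness: cosine -0.24, sine -6.61; the fitted trough sits
  # right at the September/October boundary (Sep 30)
  fungi <- peak_day(-0.24, -6.61, origin = origin)
  expect_equal(fungi$peak_month, "April")
  expect_true(oct_window(fungi$trough_doy))
  # bacterial gene copies: cosine -2.49e7, sine -8.77e8
  bact <- peak_day(-2.49e7, -8.77e8, origin = origin)
  expect_equal(bact$peak_month, "April")
  expect_true(oct_window(bact$trough_doy))
})
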