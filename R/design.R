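#' Day index relative to a study origin date
#'
#' Counts exact calendar days between `date` and `origin` (negative when
#' `date` precedes `origin`). This is the `d` entering the harmonic season
#' scores `cos(2*pi*d/365)` and `sin(2*pi*d/365)`.
#'
#' @param date A `Date` vector (or string coercible with [as.Date()]).
#' @param origin A single `Date`: the day at which `d = 0` (the first
#'   sampling date of the study design, by default 2016-07-03).
#' @return Integer vector of day counts.
#' @examples
#' day_index(as.Date("2017-07-03"), as.Date("2016-07-03"))
#' @export
day_index <- function(date, origin = as.Date("2016-07-03")) {
  date <- as_date_strict(date, "date")
  origin <- as_date_strict(origin, "origin")
  if (length(origin) != 1) abort("`origin` must be a single date.")
  as.integer(round(as.numeric(date) - as.numeric(origin)))
}

as_date_strict <- function(x, arg) {
  if (inherits(x, "Date")) return(x)
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(out)) || length(out) == 0) {
    abort(paste0("`", arg, "` contains malformed dates."), class = "seasonmix_input_error")
  }
  out
}

#' Harmonic season scores for a day index
#'
#' Evaluates the annual harmonic pair at day `d`:
#' `sc = cos(2*pi*d/365)` and `ss = sin(2*pi*d/365)`. Together the two let a
#' linear model place its fitted seasonal peak on any calendar day. The
#' period is exactly 365 days.
#'
#' @param d Integer day index (see [day_index()]).
#' @return A tibble with columns `d`, `sc`, `ss`.
#' @export
seasonal_harmonics <- function(d) {
  if (!is.numeric(d) || any(d != round(d), na.rm = TRUE)) {
    abort("`d` must be integer-valued.", class = "seasonmix_input_error")
  }
  ang <- 2 * pi * d / 365
  tibble(d = as.integer(d), sc = cos(ang), ss = sin(ang))
}

# Canonical depth layers: label -> midpoint (cm)
.depth_map <- c("0-5" = 2.5, "5-10" = 7.5, "10-20" = 15, "20-30" = 25)

#' Depth-layer midpoints
#'
#' Maps a soil depth layer to the numeric depth covariate (layer midpoint in
#' cm): 0-5 cm -> 2.5, 5-10 cm -> 7.5, 10-20 cm -> 15, 20-30 cm -> 25.
#' Accepts hyphen or en-dash labels with or without a "cm" suffix, or the
#' midpoint values themselves.
#'
#' @param layer Character (or numeric midpoint) vector of depth layers.
#' @return Numeric vector of midpoints in cm.
#' @export
depth_midpoint <- function(layer) {
  if (is.numeric(layer)) {
    ok <- layer %in% unname(.depth_map)
    if (!all(ok)) {
      abort(paste0("Unknown depth midpoint(s): ",
                   paste(unique(layer[!ok]), collapse = ", ")),
            class = "seasonmix_input_error")
    }
    return(as.numeric(layer))
  }
  key <- normalize_depth_label(layer)
  ok <- key %in% names(.depth_map)
  if (!all(ok)) {
    abort(paste0("Unknown depth layer(s): ",
                 paste(unique(layer[!ok]), collapse = ", ")),
          class = "seasonmix_input_error")
  }
  unname(.depth_map[key])
}

normalize_depth_label <- function(x) {
  x <- gsub("–", "-", as.character(x))   # en-dash -> hyphen
  x <- gsub("[[:space:]]*cm$", "", trimws(x))
  gsub("[[:space:]]", "", x)
}

#' Standardize a numeric vector to mean zero and unit variance
#'
#' Centers and scales by the sample standard deviation (n - 1 denominator).
#' The centering and scaling constants are kept as attributes `center` and
#' `scale` so the transformation is exactly invertible with
#' [unstandardize()].
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Numeric vector of z-scores with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector of length >= 2.",
          class = "seasonmix_input_error")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("`x` is constant; cannot standardize.",
          class = "seasonmix_degenerate_error")
  }
  m <- mean(x)
  structure((x - m) / s, center = m, scale = s)
}

#' @rdname standardize
#' @param z A vector produced by [standardize()] (or any numeric vector, with
#'   `center`/`scale` supplied explicitly).
#' @param center,scale Overrides for the stored constants.
#' @export
unstandardize <- function(z, center = attr(z, "center"), scale = attr(z, "scale")) {
  if (is.null(center) || is.null(scale)) {
    abort("`center` and `scale` must be available.", class = "seasonmix_input_error")
  }
  as.numeric(z) * scale + center
}

#' Build the crossed site x month x depth sampling design
#'
#' Enumerates every combination of site, monthly sampling date and depth
#' layer. Defaults reproduce a 3-site x 12-month x 4-depth design (144
#' samples) with monthly sampling starting on the origin date.
#'
#' @param sites A data frame with columns `site_id` and `elevation_m`
#'   (default: three montane sites at 1831.8, 1334.2 and 880.4 m a.s.l.).
#' @param n_months Number of monthly sampling dates (default 12).
#' @param depth_layers Character vector of depth-layer labels.
#' @param origin First sampling date; `d = 0` and the start of the monthly
#'   sequence.
#' @return A tibble (the design table) with columns `sample_id`, `site_id`,
#'   `elevation_m`, `collection_date`, `depth_layer`, `depth_mid_cm`.
#' @examples
#' nrow(design_grid())  # 144
#' @export
design_grid <- function(sites = default_sites(),
                        n_months = 12,
                        depth_layers = names(.depth_map),
                        origin = as.Date("2016-07-03")) {
  sites <- as_tibble(sites)
  if (nrow(sites) < 1 || n_months < 1 || length(depth_layers) < 1) {
    abort("Design needs at least one site, month and depth layer.",
          class = "seasonmix_input_error")
  }
  if (!all(c("site_id", "elevation_m") %in% names(sites))) {
    abort("`sites` needs columns `site_id` and `elevation_m`.",
          class = "seasonmix_input_error")
  }
  origin <- as_date_strict(origin, "origin")
  dates <- seq(origin, by = "month", length.out = n_months)
  grid <- expand_grid(
    site_id = sites$site_id,
    collection_date = dates,
    depth_layer = depth_layers
  )
  grid |>
    left_join(sites, by = "site_id") |>
    mutate(
      depth_mid_cm = depth_midpoint(.data$depth_layer),
      sample_id = paste(.data$site_id,
                        format(.data$collection_date, "%Y%m%d"),
                        normalize_depth_label(.data$depth_layer),
                        sep = "_")
    ) |>
    select("sample_id", "site_id", "elevation_m", "collection_date",
           "depth_layer", "depth_mid_cm")
}

#' @rdname design_grid
#' @export
default_sites <- function() {
  tibble(site_id = c("high", "middle", "low"),
         elevation_m = c(1831.8, 1334.2, 880.4))
}

#' Standardized covariate matrix (Sc, Ss, Ele, Dep) for a design
#'
#' Transforms a design table into the covariate set used by every model in
#' the workflow: the harmonic season pair evaluated at the day index from
#' `origin`, elevation, and depth midpoint — each standardized to mean zero
#' and unit variance across all design rows. Raw means and standard
#' deviations are stored in the `scaling` attribute so fitted coefficients
#' can be mapped back to the raw harmonic basis (see [peak_day()]).
#'
#' @param design A design table from [design_grid()] (or read with
#'   [read_design_table()]).
#' @param origin Date at which `d = 0`; defaults to the earliest
#'   `collection_date` in the design.
#' @return A tibble with columns `sample_id`, `d`, `sc`, `ss`, `ele`, `dep`;
#'   attributes `scaling` (tibble of term/center/scale) and `origin`.
#' @export
build_covariates <- function(design, origin = NULL) {
  req <- c("sample_id", "elevation_m", "collection_date", "depth_mid_cm")
  if (!all(req %in% names(design))) {
    abort(paste0("`design` must have columns: ", paste(req, collapse = ", ")),
          class = "seasonmix_input_error")
  }
  origin <- if (is.null(origin)) min(as_date_strict(design$collection_date, "collection_date"))
            else as_date_strict(origin, "origin")
  d <- day_index(design$collection_date, origin)
  harm <- seasonal_harmonics(d)
  raw <- list(sc = harm$sc, ss = harm$ss,
              ele = as.numeric(design$elevation_m),
              dep = as.numeric(design$depth_mid_cm))
  std <- map(raw, standardize)
  out <- tibble(
    sample_id = design$sample_id, d = d,
    sc = as.numeric(std$sc), ss = as.numeric(std$ss),
    ele = as.numeric(std$ele), dep = as.numeric(std$dep)
  )
  attr(out, "scaling") <- tibble(
    term = names(std),
    center = map_dbl(std, attr, "center"),
    scale = map_dbl(std, attr, "scale")
  )
  attr(out, "origin") <- origin
  class(out) <- c("smx_covariates", class(out))
  out
}

#' Fitted seasonal peak and trough days from harmonic coefficients
#'
#' A model `y ~ a*cos(2*pi*d/365) + b*sin(2*pi*d/365)` attains its maximum
#' at `d* = (365/2/pi) * atan2(b, a)` days after the origin and its minimum
#' half a period (182.5 days) later. When the model was fit on standardized
#' season scores, the standardized coefficients are first mapped back to the
#' raw basis (`a = coef_sc/sd_sc`, `b = coef_ss/sd_ss`); centering does not
#' affect the peak location.
#'
#' @param coef_sc,coef_ss Regression coefficients of the (standardized)
#'   cosine and sine season scores. Not both zero.
#' @param sd_sc,sd_ss Raw standard deviations used in standardization
#'   (default 1: coefficients already on the raw basis). Equal values leave
#'   the peak unchanged.
#' @param origin The date at which `d = 0`.
#' @return One-row tibble: `peak_d`/`trough_d` (days after origin, in
#'   \[0, 365)), `peak_doy`/`trough_doy` (calendar day-of-year),
#'   `peak_date`/`trough_date` (first occurrence on/after origin) and
#'   `peak_month`/`trough_month` (month names).
#' @examples
#' peak_day(-0.24, -6.61, origin = as.Date("2016-07-03"))  # April peak
#' @export
peak_day <- function(coef_sc, coef_ss, sd_sc = 1, sd_ss = 1,
                     origin = as.Date("2016-07-03")) {
  if (coef_sc == 0 && coef_ss == 0) {
    abort("Both harmonic coefficients are zero: no seasonal signal.",
          class = "seasonmix_no_seasonality_error")
  }
  if (sd_sc <= 0 || sd_ss <= 0) {
    abort("`sd_sc` and `sd_ss` must be positive.", class = "seasonmix_input_error")
  }
  origin <- as_date_strict(origin, "origin")
  a <- coef_sc / sd_sc
  b <- coef_ss / sd_ss
  peak_d <- (365 / (2 * pi) * atan2(b, a)) %% 365
  trough_d <- (peak_d + 182.5) %% 365
  to_cal <- function(dd) {
    date <- origin + round(dd)          # first occurrence on/after origin
    doy <- as.integer(format(date, "%j"))
    list(doy = doy, date = date, month = months(date))
  }
  p <- to_cal(peak_d); t <- to_cal(trough_d)
  tibble(
    peak_d = peak_d, trough_d = trough_d,
    peak_doy = p$doy, trough_doy = t$doy,
    peak_date = p$date, trough_date = t$date,
    peak_month = p$month, trough_month = t$month
  )
}
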