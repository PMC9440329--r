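#' Default synthetic weather variables
#'
#' Two variables in the spirit of a temperate mid-latitude climate: monthly
#' mean temperature (tas, degC, aggregated by mean) and monthly
#' precipitation depth (pr, mm, aggregated by sum).  Climatology vectors run
#' January..December; `sd` is the inter-annual standard deviation of a
#' district's monthly value.
#'
#' @return list per variable: `id`, `units`, `op`, `clim` (12 monthly
#'   means), `sd`.
#' @export
default_climate <- function() {
  list(
    tas = list(id = "tas", units = "degC", op = "mean",
               clim = c(0.5, 1.5, 5, 9.5, 14, 17, 19, 18.5, 14.5, 9.5, 4.5, 1.5),
               sd = 1.8),
    pr = list(id = "pr", units = "mm", op = "sum",
              clim = c(55, 45, 50, 45, 60, 70, 80, 70, 55, 50, 55, 60),
              sd = 22))
}

#' Generate a synthetic monthly district weather panel
#'
#' Monthly values are seasonal climatology plus a shared regional anomaly
#' plus independent district noise; the share of the shared component sets
#' the inter-district correlation (default 0.7, mimicking spatially coherent
#' mid-latitude weather fields).
#'
#' @param n_districts number of districts (ids "D001", ...).
#' @param years calendar years covered (must start at least one year before
#'   the first harvest year).
#' @param climate variable list as from [default_climate()].
#' @param spatial_cor inter-district correlation of monthly anomalies.
#' @param seed RNG seed (the generator uses R's default Mersenne-Twister
#'   stream; same seed, same panel).
#' @return a [weather_panel].
#' @export
generate_weather <- function(n_districts = 60L, years = 1995:2020,
                             climate = default_climate(), spatial_cor = 0.7,
                             seed = 1L) {
  stopifnot(spatial_cor >= 0, spatial_cor <= 1)
  set.seed(seed)
  districts <- sprintf("D%03d", seq_len(n_districts))
  ny <- length(years)
  vars <- data.frame(id = vapply(climate, `[[`, "", "id"),
                     units = vapply(climate, `[[`, "", "units"),
                     op = vapply(climate, `[[`, "", "op"))
  vals <- array(NA_real_, dim = c(n_districts, ny, 12L, nrow(vars)),
                dimnames = list(districts, as.character(years), NULL, vars$id))
  for (v in seq_len(nrow(vars))) {
    cv <- climate[[v]]
    shared <- matrix(stats::rnorm(ny * 12L), ny, 12L)
    for (m in 1:12) {
      eps <- matrix(stats::rnorm(n_districts * ny), n_districts, ny)
      anom <- sqrt(spatial_cor) * matrix(shared[, m], n_districts, ny,
                                         byrow = TRUE) +
              sqrt(1 - spatial_cor) * eps
      vals[, , m, v] <- cv$clim[m] + cv$sd * anom
    }
    if (cv$op == "sum")  # precipitation-like amounts cannot be negative
      vals[, , , v][vals[, , , v] < 0] <- 0
  }
  structure(list(values = vals, variables = vars), class = "weather_panel")
}

#' Planted ground truth for a synthetic panel
#'
#' @param n_districts number of districts.
#' @param planted named numeric vector of effect sizes, names are feature
#'   names (e.g. `c(tas0506 = -2.5, pr0306 = 0.04, tas1011 = 1.2)`); must
#'   satisfy the same-variable non-overlap constraint.  The defaults plant a
#'   winter-cereal-like signal: warm late springs hurt, spring rain helps,
#'   mild late autumns help.
#' @param alpha_mean,alpha_sd district base-yield level (dt/ha).
#' @param trend_mean,trend_sd district linear trend (dt/ha per year).
#' @param noise_share share of the district yield variance (around the
#'   trend) contributed by noise rather than the planted weather signal;
#'   0.5 means noise sd equals the per-district weather-signal sd.
#' @param sigma_y absolute noise sd (dt/ha), used where the planted signal
#'   is absent/zero (e.g. a pure-noise null panel).
#' @param seed RNG seed for the district parameters and yield noise.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_districts = 60L,
                            planted = c(tas0506 = -2.5, pr0306 = 0.04,
                                        tas1011 = 1.2),
                            alpha_mean = 75, alpha_sd = 8,
                            trend_mean = 0.5, trend_sd = 0.15,
                            noise_share = 0.5, sigma_y = 4, seed = 1L) {
  if (length(planted)) {
    pf <- lapply(names(planted), parse_feature_name)
    vars <- vapply(pf, `[[`, "", "variable")
    for (i in seq_along(pf)) for (j in seq_along(pf)) {
      if (i < j && vars[i] == vars[j] && windows_overlap(pf[[i]], pf[[j]]))
        stop("planted features violate the same-variable non-overlap constraint: ",
             names(planted)[i], " / ", names(planted)[j])
    }
  }
  set.seed(seed + 1000L)  # separate stream from the weather draw
  structure(list(planted = planted,
                 alpha = stats::rnorm(n_districts, alpha_mean, alpha_sd),
                 trend = stats::rnorm(n_districts, trend_mean, trend_sd),
                 noise_share = noise_share, sigma_y = sigma_y, seed = seed),
            class = "synthetic_truth")
}

#' Generate district yield series from a weather panel and planted truth
#'
#' y_d(t) = alpha_d + trend_d * (t - first year) + sum(beta * w) + noise;
#' the noise sd per district is set from `truth$noise_share` relative to the
#' district's weather-signal sd (or `truth$sigma_y` when there is no
#' signal).
#'
#' @param panel a [weather_panel].
#' @param truth a [synthetic_truth()].
#' @param cutoff_month season cut-off month used to anchor the planted
#'   windows (default 6).
#' @param harvest_years harvest years to generate (default: all panel years
#'   after the first, so every season is covered).
#' @return list: `yields` (district x year matrix), `truth` (the input,
#'   with `sigma_d` per district filled in).
#' @export
generate_yields <- function(panel, truth, cutoff_month = 6L,
                            harvest_years = NULL) {
  yrs <- as.integer(dimnames(panel$values)[[2]])
  if (is.null(harvest_years)) harvest_years <- yrs[-1]
  districts <- dimnames(panel$values)[[1]]
  nd <- length(districts); ny <- length(harvest_years)
  signal <- matrix(0, nd, ny)
  for (f in names(truth$planted)) {
    pf <- parse_feature_name(f)
    for (yi in seq_len(ny)) {
      w <- vapply(districts, function(dd)
        aggregate_feature(panel, dd, harvest_years[yi], pf$variable, pf,
                          cutoff_month), numeric(1))
      signal[, yi] <- signal[, yi] + truth$planted[[f]] * w
    }
  }
  sig_sd <- apply(signal, 1L, stats::sd)
  sigma_d <- ifelse(sig_sd > 0,
                    sig_sd * sqrt(truth$noise_share / (1 - truth$noise_share)),
                    truth$sigma_y)
  set.seed(truth$seed + 2000L)
  noise <- matrix(stats::rnorm(nd * ny), nd, ny) * sigma_d
  ymat <- truth$alpha[seq_len(nd)] +
    outer(truth$trend[seq_len(nd)], harvest_years - harvest_years[1]) +
    signal + noise
  ymat[ymat < 0] <- 0
  dimnames(ymat) <- list(districts, as.character(harvest_years))
  truth$sigma_d <- sigma_d
  list(yields = ymat, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Weather, yields, growing areas, and a region map in one call; the
#' default panel (60 districts x 25 years, 2 variables) is sized so the
#' full pipeline runs in minutes on one CPU.
#'
#' @inheritParams generate_weather
#' @param truth a [synthetic_truth()]; its `seed` is overridden by `seed`.
#' @param n_regions districts are split evenly into this many regions.
#' @param cutoff_month season cut-off month.
#' @return list `panel`, `yields`, `truth`, `areas` (named vector, ha),
#'   `region_map` (data.frame), `cutoff_month`.
#' @export
simulate_dataset <- function(n_districts = 60L, years = 1995:2020,
                             climate = default_climate(), spatial_cor = 0.7,
                             truth = NULL, n_regions = 4L, cutoff_month = 6L,
                             seed = 1L) {
  if (is.null(truth)) truth <- synthetic_truth(n_districts, seed = seed)
  truth$seed <- seed
  panel <- generate_weather(n_districts, years, climate, spatial_cor, seed)
  gy <- generate_yields(panel, truth, cutoff_month)
  districts <- rownames(gy$yields)
  set.seed(seed + 3000L)
  areas <- stats::setNames(round(stats::rlnorm(n_districts, log(20000), 0.6)),
                           districts)
  region_map <- data.frame(
    district = districts,
    region = sprintf("R%02d", rep_len(seq_len(n_regions), n_districts)))
  list(panel = panel, yields = gy$yields, truth = gy$truth, areas = areas,
       region_map = region_map, cutoff_month = as.integer(cutoff_month))
}

#' Compare pipeline output against the planted truth
#'
#' A planted feature counts as recovered when a selected feature of the same
#' variable overlaps at least `overlap_frac` of its window months — exact
#' window recovery is too strict because adjacent windows are nearly
#' collinear.
#'
#' @param selected character vector of selected feature names (a screening
#'   result's `selected`, or the features of assigned combinations).
#' @param truth a `synthetic_truth`.
#' @param overlap_frac required overlap share of the planted window.
#' @return list `recall` (NA if nothing was planted), `recovered` (logical
#'   per planted feature), `n_selected`, `false_positives` (selected
#'   features matching no planted window).
#' @export
recovery_report <- function(selected, truth, overlap_frac = 0.5) {
  planted <- names(truth$planted)
  matches_planted <- function(sel, pl) {
    s <- parse_feature_name(sel); p <- parse_feature_name(pl)
    if (s$variable != p$variable) return(FALSE)
    ov <- length(intersect(window_months(s$start_month, s$end_month),
                           window_months(p$start_month, p$end_month)))
    ov / p$length >= overlap_frac
  }
  recovered <- vapply(planted, function(pl)
    any(vapply(selected, matches_planted, logical(1), pl = pl)), logical(1))
  is_fp <- vapply(selected, function(sel)
    !any(vapply(planted, function(pl) matches_planted(sel, pl), logical(1))),
    logical(1))
  list(recall = if (length(planted)) mean(recovered) else NA_real_,
       recovered = recovered, n_selected = length(selected),
       false_positives = selected[is_fp])
}
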