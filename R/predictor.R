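#' Predict one district's yield for a target year (program 4)
#'
#' Hindcast mode fits the district regression with the target year's
#' observation censored (out-of-sample); forecast mode — for years beyond
#' the yield record — uses all observed years.
#'
#' @param fm a `feature_matrix`.
#' @param yields district x year yield matrix.
#' @param district district id.
#' @param target_year harvest year to predict.
#' @param feature_names the selected combination's features (possibly empty
#'   = trend-only).
#' @param mode "hindcast" or "forecast".
#' @return list of class `prediction_record`: `district`, `target_year`,
#'   `predicted` (dt/ha, NA if target-year features are missing or the fit
#'   degenerate), `mode`, `spec`, `fit`.
#' @export
predict_district <- function(fm, yields, district, target_year, feature_names,
                             mode = c("hindcast", "forecast")) {
  mode <- match.arg(mode)
  dat <- district_design(fm, yields, district,
                         censor_year = if (mode == "hindcast") target_year)
  W <- dat$W[, feature_names, drop = FALSE]
  fit <- fit_regression(dat$years, dat$y, W)
  yi <- match(as.character(target_year), dimnames(fm$values)[[2]])
  wt <- if (length(feature_names))
    fm$values[district, yi, feature_names] else numeric(0)
  pred <- NA_real_
  if (is.na(yi) || anyNA(wt)) {
    warning("target-year features unavailable for district ", district)
  } else if (!fit$degenerate) {
    pred <- predict(fit, target_year,
                    matrix(wt, nrow = 1, dimnames = list(NULL, feature_names)))
  }
  structure(list(district = district, target_year = target_year,
                 predicted = pred, mode = mode,
                 spec = combo_id(feature_names), fit = fit),
            class = "prediction_record")
}

#' Area-weighted aggregation of district yields (program 5)
#'
#' @param values named numeric vector, district -> yield (predictions or
#'   observations; NA = unavailable).
#' @param weights named numeric vector, district -> crop growing area (ha).
#' @param region_map data.frame `district`, `region`, or NULL to aggregate
#'   everything into one region "all".
#' @return named numeric vector, region -> weighted mean over districts with
#'   available values and positive weight (weights renormalised over the
#'   available districts); NA where no district is available.
#' @export
aggregate_districts <- function(values, weights, region_map = NULL) {
  stopifnot(!is.null(names(values)), !is.null(names(weights)))
  if (any(weights < 0, na.rm = TRUE)) stop("negative area weights")
  if (is.null(region_map))
    region_map <- data.frame(district = names(values), region = "all")
  vapply(split(region_map$district, region_map$region), function(ds) {
    v <- values[ds]
    w <- weights[ds]
    ok <- !is.na(v) & !is.na(w) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Out-of-sample validation metrics
#'
#' R2_val is explained variance, 1 - SSE/SST with SST about the observed
#' mean (negative when predictions beat the mean benchmark nowhere); the
#' squared Pearson correlation is reported alongside.
#'
#' @param observed,predicted paired numeric vectors; NA pairs dropped.
#' @return list `r2_val`, `rmse`, `r2_pearson`, `n`.
#' @export
validation_metrics <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  n <- sum(ok)
  if (n < 3L) return(list(r2_val = NA_real_, rmse = NA_real_,
                          r2_pearson = NA_real_, n = n))
  o <- observed[ok]; p <- predicted[ok]
  sse <- sum((o - p)^2)
  sst <- sum((o - mean(o))^2)
  list(r2_val = if (sst > 0) 1 - sse / sst else NA_real_,
       rmse = sqrt(sse / n),
       r2_pearson = if (sst > 0 && stats::sd(p) > 0) stats::cor(o, p)^2
                    else NA_real_,
       n = n)
}

#' Uncertainty interval from past prediction errors
#'
#' Hindcast bands are centred on the prediction and extend +/- 1.96 sample
#' standard deviations of the prediction errors (aiming to cover 95% of
#' observations).  A true forecast interval is slightly wider and centred
#' on the sample mean error: offset mean(e), half-width
#' t(0.975, n-1) * sd(e) * sqrt(1 + 1/n).
#'
#' @param errors past prediction errors (predicted - observed).
#' @param mode "hindcast" or "forecast".
#' @return list `center_offset`, `half_width` (both NA with < 3 errors).
#' @export
uncertainty_interval <- function(errors, mode = c("hindcast", "forecast")) {
  mode <- match.arg(mode)
  e <- errors[!is.na(errors)]
  n <- length(e)
  if (n < 3L) return(list(center_offset = NA_real_, half_width = NA_real_))
  s <- stats::sd(e)
  if (mode == "hindcast")
    list(center_offset = 0, half_width = 1.96 * s)
  else
    list(center_offset = mean(e),
         half_width = stats::qt(0.975, n - 1) * s * sqrt(1 + 1 / n))
}
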