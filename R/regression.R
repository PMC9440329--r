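#' Fit the district yield regression
#'
#' Ordinary least squares for yield on an intercept, a linear year trend,
#' and up to `d` aggregated weather features:
#' y(t) = alpha + beta0 t + sum_i beta_i w_i(t) + eps.
#'
#' @param years numeric vector of harvest years.
#' @param yields numeric vector of yields (dt/ha), NA allowed.
#' @param feature_values numeric matrix (length(years) x d) of aggregated
#'   weather features, or NULL for the trend-only model; columns should be
#'   named.
#' @param min_extra_obs fit margin: at least `d + 2 + min_extra_obs`
#'   complete observations are required (d feature slopes, intercept and
#'   trend, plus residual degrees of freedom).
#' @return object of class `yield_fit`: list with `coefficients`
#'   (intercept, trend, then one per feature), `residuals` (named by year,
#'   complete cases only), `fitted`, `r_squared`, `n_obs`, `degenerate`
#'   (TRUE for rank-deficient designs, which rankings must skip).
#' @export
fit_regression <- function(years, yields, feature_values = NULL,
                           min_extra_obs = 1L) {
  n <- length(years)
  if (is.null(feature_values))
    feature_values <- matrix(numeric(0), nrow = n, ncol = 0)
  feature_values <- as.matrix(feature_values)
  stopifnot(length(yields) == n, nrow(feature_values) == n)
  d <- ncol(feature_values)
  ok <- !is.na(yields) & stats::complete.cases(feature_values)
  X <- cbind(`(intercept)` = 1, trend = years, feature_values)[ok, , drop = FALSE]
  y <- yields[ok]
  fit <- structure(list(coefficients = rep(NA_real_, d + 2L),
                        residuals = NULL, fitted = NULL,
                        r_squared = NA_real_, n_obs = sum(ok),
                        degenerate = TRUE),
                   class = "yield_fit")
  if (sum(ok) < d + 2L + min_extra_obs) return(fit)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(fit)
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  fit$coefficients <- stats::setNames(beta, colnames(X))
  fit$residuals <- stats::setNames(res, years[ok])
  fit$fitted <- stats::setNames(fitted, years[ok])
  fit$r_squared <- r2
  fit$degenerate <- FALSE
  fit
}

#' Predict from a fitted yield regression
#'
#' @param object a `yield_fit`.
#' @param years years to predict for.
#' @param feature_values matrix of feature values for those years (same
#'   columns as in fitting), or NULL for trend-only fits.
#' @param ... unused.
#' @return numeric vector of predictions (NA where inputs are missing or the
#'   fit was degenerate).
#' @export
predict.yield_fit <- function(object, years, feature_values = NULL, ...) {
  if (object$degenerate) return(rep(NA_real_, length(years)))
  if (is.null(feature_values))
    feature_values <- matrix(numeric(0), nrow = length(years), ncol = 0)
  X <- cbind(1, years, as.matrix(feature_values))
  drop(X %*% object$coefficients)
}

#' Count / enumerate feature combinations for the exhaustive search
#'
#' The in-sample search tests every size-`d` subset of the feature pool,
#' optionally excluding subsets that pair two overlapping windows of the
#' same weather variable.
#'
#' @param features data.frame of features (rows of a `feature_matrix`'s
#'   `$features`), or an integer for `count_full_combos` with the constraint
#'   off.
#' @param d subset size.
#' @param non_overlap apply the same-variable window-overlap exclusion?
#' @return `enumerate_full_combos`: integer matrix, one row per combination,
#'   `d` columns of feature indices (ascending), in lexicographic order.
#'   `count_full_combos`: the number of combinations.
#' @export
enumerate_full_combos <- function(features, d, non_overlap = TRUE) {
  p <- nrow(features)
  stopifnot(d >= 0, d <= p)
  if (d == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  cmb <- t(utils::combn(p, d))
  if (non_overlap && d > 1L) {
    conf <- feature_conflicts(features)
    keep <- apply(cmb, 1L, function(ix) {
      pr <- utils::combn(ix, 2L)
      !any(conf[t(pr)])
    })
    cmb <- cmb[keep, , drop = FALSE]
  }
  cmb
}

#' @rdname enumerate_full_combos
#' @export
count_full_combos <- function(features, d, non_overlap = TRUE) {
  if (is.numeric(features) && length(features) == 1L)
    return(choose(features, d))
  if (!non_overlap) return(choose(nrow(features), d))
  nrow(enumerate_full_combos(features, d, non_overlap = TRUE))
}

# canonical combination label: feature names joined by "+"; "(trend)" for d=0
combo_id <- function(feature_names) {
  if (length(feature_names) == 0L) "(trend)"
  else paste(feature_names, collapse = "+")
}
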