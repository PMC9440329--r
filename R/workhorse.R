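#' Enumerate admissible combinations of screened features
#'
#' All subsets of the screened feature set with 0 to `d_max` members that
#' avoid pairing overlapping windows of the same weather variable.  The
#' empty subset (trend-only regression) is always included.
#'
#' @param features data.frame of screened features (subset of a
#'   `feature_matrix`'s `$features` rows).
#' @param d_max maximum number of weather features (default 4).
#' @param non_overlap apply the same-variable window-overlap exclusion?
#' @return named list of integer vectors (indices into `features`, ascending),
#'   ordered by subset size then lexicographic indices; names are
#'   combination labels ("(trend)" for the empty subset).
#' @export
enumerate_valid_combos <- function(features, d_max = 4L, non_overlap = TRUE) {
  q <- nrow(features)
  out <- list()
  for (s in 0:min(d_max, q)) {
    cmb <- enumerate_full_combos(features, s, non_overlap = non_overlap)
    out <- c(out, lapply(seq_len(nrow(cmb)), function(i) cmb[i, ]))
  }
  names(out) <- vapply(out, function(ix) combo_id(features$name[ix]),
                       character(1))
  out
}

#' Leave-one-out out-of-sample predictions for one district and combination
#'
#' The prediction for year j comes from a regression fitted with y(j)
#' censored; in strict mode the target year's observation is additionally
#' censored from every fit (so nothing downstream of these predictions can
#' see it).
#'
#' @param fm a `feature_matrix`.
#' @param yields district x year yield matrix.
#' @param district district id.
#' @param feature_names character vector of the combination's features
#'   (empty for trend-only).
#' @param target_year the target year.
#' @param strict censor the target year from every fit?
#' @return named numeric vector, year -> out-of-sample prediction (NA where
#'   the censored fit is infeasible or degenerate).
#' @export
loo_predictions <- function(fm, yields, district, feature_names, target_year,
                            strict = TRUE) {
  dat <- district_design(fm, yields, district)
  W <- dat$W[, feature_names, drop = FALSE]
  yrs <- dat$years
  preds <- stats::setNames(rep(NA_real_, length(yrs)), yrs)
  for (i in seq_along(yrs)) {
    drop_i <- yrs == yrs[i]
    if (strict) drop_i <- drop_i | yrs == target_year
    fit <- fit_regression(yrs[!drop_i], dat$y[!drop_i],
                          W[!drop_i, , drop = FALSE])
    if (fit$degenerate) next
    preds[i] <- predict(fit, yrs[i], W[i, , drop = FALSE])
  }
  preds
}

#' Pearson skill of a prediction series
#'
#' @param observed,predicted numeric vectors (paired); NA pairs dropped.
#' @param min_pairs minimum complete pairs (default 3).
#' @return Pearson correlation, or NA with too few pairs or zero variance.
#' @export
evaluate_combo <- function(observed, predicted, min_pairs = 3L) {
  ok <- !is.na(observed) & !is.na(predicted)
  if (sum(ok) < min_pairs) return(NA_real_)
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0)
    return(NA_real_)
  stats::cor(observed[ok], predicted[ok])
}

#' Evaluate all screened-feature combinations per district (program 2)
#'
#' For one target year, computes the Pearson correlation between observed
#' yields and leave-one-out predictions for every admissible combination of
#' the screened features, in every usable district.
#'
#' @inheritParams loo_predictions
#' @param screened character vector of screened feature names (from
#'   [prospect()]).
#' @param d_max maximum combination size.
#' @param min_pairs minimum prediction/observation pairs for a valid cell.
#' @param min_years minimum observed yields per district.
#' @param non_overlap apply the same-variable window-overlap exclusion?
#' @param workers parallel workers (districts are independent).
#' @return object of class `eval_table`: numeric matrix (combinations x
#'   districts) of r values with combination labels as rownames, plus
#'   attributes `combos` (list of feature-name vectors), `target_year`,
#'   `strict`.  `A_y = nrow()` is the combination count.
#' @export
build_eval_table <- function(fm, yields, screened, target_year, d_max = 4L,
                             strict = TRUE, min_pairs = 8L, min_years = 17L,
                             non_overlap = TRUE, workers = 1L) {
  stopifnot(all(screened %in% fm$features$name))
  feats <- fm$features[match(screened, fm$features$name), , drop = FALSE]
  combos <- enumerate_valid_combos(feats, d_max, non_overlap)
  sizes <- lengths(combos)
  cm <- matrix(0L, nrow = length(combos), ncol = max(1L, max(sizes)))
  for (i in seq_along(combos))
    if (sizes[i] > 0L) cm[i, seq_len(sizes[i])] <- combos[[i]]
  districts <- usable_districts(yields, min_years)
  cols <- cs_lapply(districts, function(dd) {
    dat <- district_design(fm, yields, dd)
    Ws <- dat$W[, screened, drop = FALSE]
    ti <- match(target_year, dat$years)
    cpp_eval_combos(Ws, dat$years, dat$y, cm, as.integer(sizes),
                    ifelse(is.na(ti), 0L, ti), strict, as.integer(min_pairs))
  }, workers = workers)
  tab <- do.call(cbind, cols)
  dimnames(tab) <- list(names(combos), districts)
  structure(tab,
            combos = lapply(combos, function(ix) feats$name[ix]),
            target_year = target_year, strict = strict,
            class = c("eval_table", "matrix"))
}

#' @export
print.eval_table <- function(x, ...) {
  cat(sprintf("eval_table (target year %s): A = %d combinations x %d districts, %.1f%% cells missing\n",
              attr(x, "target_year"), nrow(x), ncol(x),
              100 * mean(is.na(unclass(x)))))
  invisible(x)
}
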