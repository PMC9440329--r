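# shared fixtures, built in code (no data files)

# hand-built 2-district weather panel: values encode year*100 + month so the
# calendar mapping of any aggregate can be verified by inspection
coded_panel <- function(years = 2000:2005, variables = NULL) {
  if (is.null(variables))
    variables <- data.frame(id = c("tas", "pr"), op = c("mean", "sum"),
                            units = c("degC", "mm"))
  g <- expand.grid(district = c("A", "B"), year = years, month = 1:12,
                   variable = variables$id, stringsAsFactors = FALSE)
  g$value <- g$year * 100 + g$month
  weather_panel(g, variables)
}

# small synthetic dataset cache (shared across test files in one run)
.fixture_cache <- new.env(parent = emptyenv())

cached_ds <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_ds <- function(seed = 7) {
  cached_ds(paste0("small", seed),
            simulate_dataset(n_districts = 12, years = 2000:2018, seed = seed))
}

small_fm <- function(seed = 7) {
  cached_ds(paste0("smallfm", seed), {
    ds <- small_ds(seed)
    build_feature_matrix(ds$panel, ds$cutoff_month, max_len = 3)
  })
}

# noiseless planted dataset: yields are an exact linear function of trend
# and the planted window aggregates
noiseless_ds <- function(seed = 11, planted = c(tas0506 = -2, pr1202 = 0.05)) {
  cached_ds(paste0("nl", seed), {
    truth <- synthetic_truth(n_districts = 8, planted = planted,
                             noise_share = 0, sigma_y = 0, seed = seed)
    simulate_dataset(n_districts = 8, years = 2001:2015, truth = truth,
                     seed = seed)
  })
}

# independent brute-force oracle: contiguous spans by explicit enumeration
oracle_spans <- function(season_length, min_len, max_len) {
  g <- expand.grid(off = seq_len(season_length), len = min_len:max_len)
  g[g$off + g$len - 1L <= season_length, ]
}

# independent OLS oracle via explicit normal equations
oracle_ols <- function(X, y) solve(crossprod(X), crossprod(X, y))

# independent Pearson oracle via the textbook covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# independent binomial cutoff oracle: exact CDF summation over dbinom terms
oracle_binomial_cutoff <- function(n, p, confidence) {
  cdf <- cumsum(stats::dbinom(0:n, n, p))
  (0:n)[which(cdf >= confidence)[1]]
}

# brute-force in-sample ranking oracle: all size-d subsets via combn + lm
oracle_top_k <- function(W, years, y, d, k, features, non_overlap = TRUE) {
  cmb <- t(utils::combn(ncol(W), d))
  if (non_overlap) {
    keep <- apply(cmb, 1L, function(ix) {
      pairs <- utils::combn(ix, 2L)
      all(apply(pairs, 2L, function(pp) {
        f1 <- features[pp[1], ]; f2 <- features[pp[2], ]
        f1$variable != f2$variable ||
          !any(window_months(f1$start_month, f1$end_month) %in%
               window_months(f2$start_month, f2$end_month))
      }))
    })
    cmb <- cmb[keep, , drop = FALSE]
  }
  r2 <- apply(cmb, 1L, function(ix) {
    summary(stats::lm(y ~ years + W[, ix]))$r.squared
  })
  lbl <- apply(cmb, 1L, function(ix)
    paste(sort(features$name[ix]), collapse = "|"))
  ord <- order(-r2, lbl)
  data.frame(spec = apply(cmb[ord, , drop = FALSE], 1L, function(ix)
    paste(features$name[ix], collapse = "+")),
    r2 = r2[ord])[seq_len(min(k, length(ord))), ]
}
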