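test_that("OLS fits recover exact signals and match the normal-equations oracle", {
  years <- 2001:2020
  # pure trend
  y <- 70 + 0.5 * years
  f0 <- fit_regression(years, y, NULL)
  expect_false(f0$degenerate)
  expect_equal(unname(f0$coefficients[["trend"]]), 0.5, tolerance = 1e-10)
  expect_equal(f0$r_squared, 1, tolerance = 1e-10)
  # exact 4-feature signal: zero residuals
  set.seed(5)
  W <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("w", 1:4)))
  y <- 60 + 0.3 * years + W %*% c(1, -2, 0.5, 3)
  f4 <- fit_regression(years, drop(y), W)
  expect_lt(max(abs(f4$residuals)), 1e-8)
  expect_equal(sum(f4$residuals), 0, tolerance = 1e-8)
  # noisy fixture vs independent normal-equations solve
  y <- drop(y) + rnorm(20, 0, 3)
  fit <- fit_regression(years, y, W)
  X <- cbind(1, years, W)
  expect_equal(unname(fit$coefficients), unname(drop(oracle_ols(X, y))),
               tolerance = 1e-8)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
})

test_that("rank-deficient designs are flagged degenerate", {
  years <- 2001:2012
  W <- cbind(a = years * 2, b = years * 4)  # collinear with the trend
  fit <- fit_regression(years, rnorm(12, 70), W)
  expect_true(fit$degenerate)
  # too few observations
  fit2 <- fit_regression(2001:2004, rnorm(4), matrix(rnorm(8), 4, 2))
  expect_true(fit2$degenerate)
})

test_that("combination counting matches the closed form and brute force", {
  expect_equal(count_full_combos(135, 4), 13232835)
  feats5 <- data.frame(name = paste0("v", 1:5, "0102"),
                       variable = paste0("v", 1:5),
                       start_month = 1, end_month = 2, length = 2)
  expect_equal(nrow(enumerate_full_combos(feats5, 4, non_overlap = FALSE)), 5L)
  # overlapping same-variable pool vs explicit subset-filter oracle
  feats <- data.frame(
    name = c("tas0102", "tas0203", "tas0405", "pr0102", "pr0103"),
    variable = c("tas", "tas", "tas", "pr", "pr"),
    start_month = c(1, 2, 4, 1, 1), end_month = c(2, 3, 5, 2, 3),
    length = c(2, 2, 2, 2, 3))
  for (d in 2:4) {
    got <- enumerate_full_combos(feats, d, non_overlap = TRUE)
    all_sub <- t(utils::combn(5, d))
    ok <- apply(all_sub, 1, function(ix) {
      prs <- utils::combn(ix, 2)
      all(apply(prs, 2, function(pp) {
        a <- feats[pp[1], ]; b <- feats[pp[2], ]
        a$variable != b$variable ||
          !any(window_months(a$start_month, a$end_month) %in%
               window_months(b$start_month, b$end_month))
      }))
    })
    expect_equal(got, all_sub[ok, , drop = FALSE])
  }
})

test_that("the exhaustive top-k search matches a brute-force lm ranking", {
  ds <- small_ds()
  fm <- small_fm()
  # toy pool: 12 features across both variables, incl. same-variable overlaps
  idx <- c(1:4, 8:11, 22:25)
  fm_small <- fm
  fm_small$values <- fm$values[, , idx, drop = FALSE]
  fm_small$features <- fm$features[idx, ]
  dat <- cropsieve:::district_design(fm_small, ds$yields, "D003",
                                     censor_year = 2010)
  for (d in c(2, 3)) {
    got <- top_k_regressions(fm_small, ds$yields, "D003", 2010, k = 7,
                             d = d, min_years = 10)
    oracle <- oracle_top_k(dat$W, dat$years, dat$y, d, 7, fm_small$features)
    expect_equal(got$spec, oracle$spec)
    expect_equal(got$r2, oracle$r2, tolerance = 1e-8)
  }
  # with the constraint off the oracle must agree too
  got <- top_k_regressions(fm_small, ds$yields, "D003", 2010, k = 5, d = 3,
                           non_overlap = FALSE, min_years = 10)
  oracle <- oracle_top_k(dat$W, dat$years, dat$y, 3, 5, fm_small$features,
                         non_overlap = FALSE)
  expect_equal(got$spec, oracle$spec)
})

test_that("top-k search: k beyond the pool returns everything; chunking is invisible", {
  ds <- small_ds()
  fm <- small_fm()
  idx <- c(1, 12, 22, 30, 40)
  fm_small <- fm
  fm_small$values <- fm$values[, , idx, drop = FALSE]
  fm_small$features <- fm$features[idx, ]
  all_specs <- top_k_regressions(fm_small, ds$yields, "D001", 2009, k = 1000,
                                 d = 2, min_years = 10)
  expect_equal(nrow(all_specs),
               nrow(enumerate_full_combos(fm_small$features, 2)))
  serial <- top_k_regressions(fm, ds$yields, "D001", 2009, k = 23, d = 3,
                              min_years = 10)
  chunked <- top_k_regressions(fm, ds$yields, "D001", 2009, k = 23, d = 3,
                               min_years = 10, chunks = 5)
  expect_identical(serial$spec, chunked$spec)
  expect_identical(serial$r2, chunked$r2)
})

test_that("a noiseless planted combination ranks first", {
  ds <- noiseless_ds()
  fm <- cached_ds("nlfm", build_feature_matrix(ds$panel, ds$cutoff_month))
  top <- top_k_regressions(fm, ds$yields, "D002", 2010, k = 5, d = 2,
                           min_years = 10)
  expect_equal(sort(top$features[[1]]), sort(names(ds$truth$planted)))
  expect_gt(top$r2[1], 1 - 1e-8)
})

test_that("feature frequencies are a plain multiset tally", {
  feats <- c("a", "b", "c", "d")
  counts <- count_feature_frequencies(
    list(list(c("a", "b", "c", "d"))), feats)
  expect_equal(unname(counts[feats]), rep(1L, 4))
  expect_equal(attr(counts, "n"), 1L)
  lists <- list(list(c("a", "b"), c("a", "c")), NULL, list(c("a", "d")))
  counts <- count_feature_frequencies(lists, feats)
  expect_equal(as.vector(counts), c(3L, 1L, 1L, 1L))
  expect_equal(attr(counts, "n"), 3L)
  expect_equal(sum(counts), 2L * attr(counts, "n"))
})

test_that("binomial cutoff and moments reproduce the worked example", {
  expect_identical(binomial_cutoff(7498, 4 / 135, 0.999), 269L)
  mom <- screening_moments(7498, 4 / 135)
  expect_equal(round(mom$expectation, 3), 222.163)
  expect_equal(round(mom$sigma, 3), 14.683)
  expect_identical(binomial_cutoff(10, 0.5, 0.999), 9L)
  expect_identical(binomial_cutoff(100, 0, 0.999), 0L)
  expect_equal(screening_moments(50, 0), list(expectation = 0, sigma = 0))
})

test_that("binomial cutoff agrees with exact CDF summation", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(1:10000, 1)
    p <- runif(1, 0.001, 0.6)
    conf <- sample(c(0.9, 0.99, 0.999), 1)
    expect_identical(binomial_cutoff(n, p, conf),
                     as.integer(oracle_binomial_cutoff(n, p, conf)))
  }
})

test_that("significance selection uses the strictly-greater rule with fallback", {
  counts <- stats::setNames(c(270L, 269L, 100L, 0L), letters[1:4])
  expect_equal(select_significant_features(counts, 269L), "a")
  counts0 <- stats::setNames(c(5L, 3L, 0L), letters[1:3])
  expect_warning(sel <- select_significant_features(counts0, 100L,
                                                    fallback_m = 2L),
                 "falling back")
  expect_equal(sel, c("a", "b"))
  expect_equal(suppressWarnings(
    select_significant_features(counts0, 100L, fallback_m = 0L)),
    character(0))
})

test_that("screening is invariant to the target year's yields (purity)", {
  ds <- small_ds()
  fm <- small_fm()
  scr1 <- prospect(fm, ds$yields, 2012, k = 10, d = 3, min_years = 15)
  y2 <- ds$yields
  y2[, "2012"] <- y2[, "2012"] + rnorm(nrow(y2), 0, 25)
  scr2 <- prospect(fm, y2, 2012, k = 10, d = 3, min_years = 15)
  expect_identical(scr1$counts, scr2$counts)
  expect_identical(scr1$selected, scr2$selected)
  expect_identical(scr1$n, scr2$n)
})

test_that("screening arithmetic: n = districts x k and counts sum to d*n", {
  ds <- small_ds()
  fm <- small_fm()
  scr <- prospect(fm, ds$yields, 2010, k = 9, d = 3, min_years = 15)
  expect_equal(scr$n, length(scr$districts) * 9L)
  expect_equal(sum(scr$counts), 3L * scr$n)
  expect_equal(scr$p, 3 / nrow(fm$features))
  expect_true(all(scr$counts[scr$selected] > scr$threshold))
})
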