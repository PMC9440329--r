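#' Top-k best-fitting regressions for one district and target year
#'
#' Exhaustively tests every admissible size-`d` feature subset (plus
#' intercept and trend) on the district's yield series with the target
#' year's observation censored, and returns the `k` subsets with the highest
#' in-sample R-squared.  Ties are broken towards the lexicographically
#' smaller feature-name combination.  Rank-deficient designs are skipped.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param yields district x year yield matrix (see [yield_matrix()]).
#' @param district district id.
#' @param target_year harvest year whose yield is censored from all fits.
#' @param k number of regressions to retain (default 23).
#' @param d number of weather features per regression (default 4).
#' @param non_overlap exclude subsets pairing overlapping windows of the
#'   same variable?
#' @param min_years minimum observed yields the district must have.
#' @param chunks number of chunks to split the subset space into
#'   (parallel-map contract; results are chunk-order invariant).
#' @param workers parallel workers for chunk evaluation.
#' @return data.frame with columns `spec` (combination label), `r2`, and a
#'   list column `features` of feature-name vectors; NULL if the district
#'   has too few observations.
#' @export
top_k_regressions <- function(fm, yields, district, target_year, k = 23L,
                              d = 4L, non_overlap = TRUE, min_years = 17L,
                              chunks = 1L, workers = 1L) {
  dat <- district_design(fm, yields, district, censor_year = target_year)
  if (sum(!is.na(yields[district, ])) < min_years) return(NULL)
  if (nrow(dat$W) < d + 3L) return(NULL)
  p <- ncol(dat$W)
  conf <- if (non_overlap) feature_conflicts(fm$features)
          else matrix(FALSE, p, p)
  name_rank <- rank(fm$features$name, ties.method = "first")
  bounds <- chunk_bounds(p, chunks)
  parts <- cs_lapply(seq_len(nrow(bounds)), function(ci) {
    cpp_top_k(dat$W, dat$years, dat$y, as.integer(d), as.integer(k), conf,
              as.integer(name_rank), bounds[ci, 1L], bounds[ci, 2L])
  }, workers = workers)
  merge_top_k(parts, fm$features$name, name_rank, k)
}

# split 1..p into `chunks` contiguous first-index ranges
chunk_bounds <- function(p, chunks) {
  chunks <- max(1L, min(as.integer(chunks), p))
  cut <- round(seq(0L, p, length.out = chunks + 1L))
  cbind(lo = cut[-length(cut)] + 1L, hi = cut[-1L])
}

# deterministic merge of per-chunk top-k lists
merge_top_k <- function(parts, feature_names, name_rank, k) {
  combos <- do.call(rbind, lapply(parts, `[[`, "combos"))
  r2 <- unlist(lapply(parts, `[[`, "r2"))
  if (length(r2) == 0L)
    return(data.frame(spec = character(0), r2 = numeric(0)))
  key <- apply(combos, 1L, function(ix)
    paste(sprintf("%06d", sort(name_rank[ix])), collapse = ""))
  ord <- order(-r2, key)
  ord <- ord[seq_len(min(k, length(ord)))]
  feats <- lapply(ord, function(i) feature_names[combos[i, ]])
  out <- data.frame(spec = vapply(feats, combo_id, character(1)),
                    r2 = r2[ord])
  out$features <- feats
  out
}

# complete-case design for one district: years with observed yield and a
# complete feature row; optionally censoring one harvest year entirely
district_design <- function(fm, yields, district, censor_year = NULL) {
  W <- fm$values[district, , , drop = FALSE]
  W <- matrix(W, nrow = dim(fm$values)[2], ncol = dim(fm$values)[3],
              dimnames = dimnames(fm$values)[2:3])
  yrs <- as.integer(rownames(W))
  y <- yields[district, match(yrs, as.integer(colnames(yields)))]
  ok <- !is.na(y) & stats::complete.cases(W)
  if (!is.null(censor_year)) ok <- ok & yrs != censor_year
  list(W = W[ok, , drop = FALSE], years = as.numeric(yrs[ok]), y = y[ok])
}

#' Tally feature occurrences across retained regressions
#'
#' @param top_lists list (one element per district) of feature-name lists or
#'   of [top_k_regressions()] data.frames.
#' @param feature_names all candidate feature names (zero counts included).
#' @return named integer vector of occurrence counts, and attribute `n` =
#'   total number of retained regressions.
#' @export
count_feature_frequencies <- function(top_lists, feature_names) {
  specs <- unlist(lapply(top_lists, function(tl) {
    if (is.null(tl)) return(list())
    if (is.data.frame(tl)) tl$features else tl
  }), recursive = FALSE)
  tallied <- table(factor(unlist(specs), levels = feature_names))
  counts <- stats::setNames(as.integer(tallied), feature_names)
  attr(counts, "n") <- length(specs)
  counts
}

#' Binomial screening cutoff and null moments
#'
#' Under the null that every retained regression draws its `d` features
#' uniformly from the pool, each feature's occurrence count across `n`
#' retained regressions is Binomial(n, p).  The cutoff is the smallest
#' count not exceeded with probability `confidence`; features must occur
#' strictly more often to count as significant.
#'
#' @param n number of retained regressions (districts x k).
#' @param p per-regression inclusion probability (d / number of features).
#' @param confidence screening confidence (default 0.999).
#' @return `binomial_cutoff`: integer threshold (smallest c with
#'   P(X <= c) >= confidence). `screening_moments`: list with `expectation`
#'   (np) and `sigma` (sqrt(np(1-p))).
#' @export
binomial_cutoff <- function(n, p, confidence = 0.999) {
  stopifnot(n >= 0, p >= 0, p <= 1, confidence > 0, confidence < 1)
  as.integer(stats::qbinom(confidence, n, p))
}

#' @rdname binomial_cutoff
#' @export
screening_moments <- function(n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  list(expectation = n * p, sigma = sqrt(n * p * (1 - p)))
}

#' Select features occurring significantly more often than chance
#'
#' @param counts named counts from [count_feature_frequencies()].
#' @param threshold cutoff from [binomial_cutoff()].
#' @param fallback_m if no feature clears the cutoff, fall back to the
#'   `fallback_m` most frequent features (with a warning) so downstream
#'   stages stay operable.
#' @return character vector of selected feature names, ordered by
#'   decreasing count (ties by name).
#' @export
select_significant_features <- function(counts, threshold, fallback_m = 10L) {
  sel <- names(counts)[counts > threshold]
  if (length(sel) == 0L && fallback_m > 0L) {
    warning("no feature cleared the screening cutoff; falling back to the ",
            fallback_m, " most frequent features")
    ord <- order(-counts, names(counts))
    sel <- names(counts)[ord][seq_len(min(fallback_m, length(counts)))]
    sel <- sel[counts[sel] > 0L]
  }
  sel[order(-counts[sel], sel)]
}

#' Screen weather features for one target year (program 1)
#'
#' Runs the exhaustive per-district top-k search with the target year
#' censored, tallies feature occurrences across all districts, and keeps
#' the features that occur more often than the binomial null allows.
#'
#' @inheritParams top_k_regressions
#' @param confidence screening confidence level (default 0.999).
#' @param p_null per-regression inclusion probability under the null;
#'   default `d /` (number of features), regardless of the overlap
#'   constraint.
#' @param fallback_m see [select_significant_features()].
#' @param keep_top keep the per-district top-k lists in the result (audit)?
#' @return object of class `screening_result`: list with `target_year`,
#'   `counts`, `n`, `p`, `expectation`, `sigma`, `threshold`, `selected`,
#'   `q`, `districts`, and optionally `top` (per-district lists).
#' @export
prospect <- function(fm, yields, target_year, k = 23L, d = 4L,
                     confidence = 0.999, min_years = 17L, non_overlap = TRUE,
                     p_null = NULL, fallback_m = 10L, workers = 1L,
                     keep_top = FALSE) {
  districts <- usable_districts(yields, min_years)
  if (length(districts) == 0L) stop("no district has >= ", min_years, " yield years")
  tops <- cs_lapply(districts, function(dd)
    top_k_regressions(fm, yields, dd, target_year, k = k, d = d,
                      non_overlap = non_overlap, min_years = min_years),
    workers = workers)
  names(tops) <- districts
  counts <- count_feature_frequencies(tops, fm$features$name)
  n <- attr(counts, "n")
  p <- if (is.null(p_null)) d / nrow(fm$features) else p_null
  mom <- screening_moments(n, p)
  thr <- binomial_cutoff(n, p, confidence)
  selected <- select_significant_features(counts, thr, fallback_m)
  structure(list(target_year = target_year, counts = counts, n = n, p = p,
                 confidence = confidence, expectation = mom$expectation,
                 sigma = mom$sigma, threshold = thr, selected = selected,
                 q = length(selected), districts = districts,
                 top = if (keep_top) tops else NULL),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "screening_result (target year %s): n = %d, p = %.5f, E(x) = %.3f, E(sigma) = %.3f\n",
    x$target_year, x$n, x$p, x$expectation, x$sigma))
  cat(sprintf("cutoff at %.1f%% confidence = %d -> q = %d features selected\n",
              100 * x$confidence, x$threshold, x$q))
  if (x$q > 0) cat(" ", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

# serial/parallel map with deterministic, order-preserving merge
cs_lapply <- function(X, FUN, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(X, FUN, mc.cores = workers)
  else lapply(X, FUN)
}
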