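#' Enumerate contiguous aggregation windows of the pre-harvest season
#'
#' The season is the block of `season_length` calendar months ending with
#' `cutoff_month` in the harvest year; earlier months wrap into the previous
#' calendar year.  Every contiguous span of `min_len` to `max_len` months
#' inside the season is a candidate aggregation window.  With the defaults
#' (12-month season, lengths 2-6) there are 11 + 10 + ... + 7 = 45 windows.
#'
#' @param cutoff_month last calendar month (1-12) of weather input before
#'   harvest, e.g. 6 (June) for winter wheat, 8 (August) for silage maize.
#' @param season_length number of months in the season (default 12).
#' @param min_len,max_len inclusive bounds on the window length in months.
#' @return data.frame with one row per window: `start_month` and `end_month`
#'   (calendar months 1-12, the span may wrap the year boundary), `length`,
#'   and `start_offset` (1-based position of the start month inside the
#'   season).  Rows are ordered by length, then by season position of the
#'   start month.
#' @export
#' @examples
#' nrow(enumerate_windows(6))              # 45
#' nrow(enumerate_windows(6, min_len = 2, max_len = 2))  # 11
enumerate_windows <- function(cutoff_month, season_length = 12L,
                              min_len = 2L, max_len = 6L) {
  stopifnot(cutoff_month %in% 1:12)
  if (!(min_len >= 1L && min_len <= max_len && max_len <= season_length))
    stop("invalid window length bounds: need 1 <= min_len <= max_len <= season_length")
  rows <- list()
  for (len in seq(min_len, max_len)) {
    for (off in seq_len(season_length - len + 1L)) {
      # season offset 1 is the earliest month; season_length is the cutoff
      sm <- season_month(cutoff_month, season_length, off)
      em <- season_month(cutoff_month, season_length, off + len - 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(start_month = sm, end_month = em, length = len,
                   start_offset = off)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# calendar month at 1-based season offset `off`; offset season_length == cutoff
season_month <- function(cutoff_month, season_length, off) {
  ((cutoff_month - season_length + off - 1L) %% 12L) + 1L
}

#' Calendar months covered by a window
#'
#' @param start_month,end_month calendar months 1-12; a span with
#'   `start_month > end_month` wraps the year boundary (e.g. 12-2 is
#'   December, January, February).
#' @return integer vector of calendar months in span order.
#' @export
window_months <- function(start_month, end_month) {
  stopifnot(start_month %in% 1:12, end_month %in% 1:12)
  if (start_month <= end_month) seq(start_month, end_month)
  else c(seq(start_month, 12L), seq_len(end_month))
}

#' Do two aggregation windows share a month?
#'
#' Both windows are understood as month sets inside the same 12-month
#' season.  Feature combinations never pair two overlapping windows of the
#' same weather variable; this predicate implements that constraint.
#'
#' @param w1,w2 windows: lists or one-row data.frames with `start_month`
#'   and `end_month`.
#' @return TRUE iff the month sets intersect.
#' @export
windows_overlap <- function(w1, w2) {
  length(intersect(window_months(w1$start_month, w1$end_month),
                   window_months(w2$start_month, w2$end_month))) > 0L
}

#' Render / parse feature names
#'
#' A feature is one weather variable aggregated over one window; its name is
#' the variable id followed by the zero-padded two-digit start and end
#' months, e.g. `tas0506` (mean temperature May-June) or `pr1102`
#' (precipitation sum November-February).
#'
#' @param variable_id short variable id, lower-case letters (e.g. "tas").
#' @param window list or one-row data.frame with `start_month`, `end_month`.
#' @return `feature_name`: the rendered name. `parse_feature_name`: a list
#'   with `variable`, `start_month`, `end_month`, `length`.
#' @export
feature_name <- function(variable_id, window) {
  if (!grepl("^[a-z]+$", variable_id))
    stop("variable id must be non-empty lower-case letters: ", variable_id)
  sprintf("%s%02d%02d", variable_id, window$start_month, window$end_month)
}

#' @rdname feature_name
#' @param name a rendered feature name.
#' @export
parse_feature_name <- function(name) {
  m <- regmatches(name, regexec("^([a-z]+)([0-9]{2})([0-9]{2})$", name))[[1]]
  if (length(m) != 4L) stop("not a parsable feature name: ", name)
  sm <- as.integer(m[3]); em <- as.integer(m[4])
  if (!(sm %in% 1:12 && em %in% 1:12))
    stop("months out of range in feature name: ", name)
  list(variable = m[2], start_month = sm, end_month = em,
       length = length(window_months(sm, em)))
}

#' Aggregate one weather feature for one district and harvest year
#'
#' Months after the cut-off month belong to the calendar year before the
#' harvest year; months up to the cut-off belong to the harvest year itself.
#' A window such as 12-02 with a June cut-off and harvest year t therefore
#' uses December of t-1 and January-February of t.
#'
#' @param panel a [weather_panel].
#' @param district district id (must be present in the panel).
#' @param harvest_year harvest year (integer).
#' @param variable_id weather variable id.
#' @param window window with `start_month`, `end_month`.
#' @param cutoff_month last calendar month of the season.
#' @return the mean or sum (per the variable's aggregation op) of the
#'   monthly values, or NA if any month is missing.
#' @export
aggregate_feature <- function(panel, district, harvest_year, variable_id,
                              window, cutoff_month) {
  stopifnot(inherits(panel, "weather_panel"))
  months <- window_months(window$start_month, window$end_month)
  yrs <- ifelse(months > cutoff_month, harvest_year - 1L, harvest_year)
  vals <- vapply(seq_along(months), function(i)
    panel_value(panel, district, yrs[i], months[i], variable_id), numeric(1))
  op <- panel$variables$op[match(variable_id, panel$variables$id)]
  if (is.na(op)) stop("unknown variable id: ", variable_id)
  if (anyNA(vals)) return(NA_real_)
  if (op == "mean") mean(vals) else sum(vals)
}

#' Build the district x harvest-year x feature matrix
#'
#' Computes every enumerated window aggregate for every weather variable of
#' the panel (or a subset), for every district and every harvest year whose
#' season the panel can cover.
#'
#' @param panel a [weather_panel].
#' @param cutoff_month last calendar month of the season.
#' @param variables variable ids to use (default: all panel variables).
#' @param season_length,min_len,max_len window grid, see
#'   [enumerate_windows()].
#' @param harvest_years integer vector of harvest years; default all years
#'   for which the panel holds at least one season month.
#' @return object of class `feature_matrix`: list with `values` (numeric
#'   array district x year x feature), `features` (data.frame: name,
#'   variable, start_month, end_month, length, op), `cutoff_month`.
#' @export
build_feature_matrix <- function(panel, cutoff_month,
                                 variables = panel$variables$id,
                                 season_length = 12L, min_len = 2L,
                                 max_len = 6L, harvest_years = NULL) {
  stopifnot(inherits(panel, "weather_panel"))
  stopifnot(all(variables %in% panel$variables$id))
  win <- enumerate_windows(cutoff_month, season_length, min_len, max_len)
  cal_years <- as.integer(dimnames(panel$values)[[2]])
  if (is.null(harvest_years)) {
    harvest_years <- cal_years
    if (cutoff_month < 12L) harvest_years <- union(harvest_years, max(cal_years) + 1L)
    harvest_years <- sort(harvest_years)
  }
  districts <- dimnames(panel$values)[[1]]
  feats <- do.call(rbind, lapply(variables, function(v) {
    data.frame(name = sprintf("%s%02d%02d", v, win$start_month, win$end_month),
               variable = v, start_month = win$start_month,
               end_month = win$end_month, length = win$length,
               op = panel$variables$op[match(v, panel$variables$id)])
  }))
  rownames(feats) <- NULL
  vals <- array(NA_real_,
                dim = c(length(districts), length(harvest_years), nrow(feats)),
                dimnames = list(districts, as.character(harvest_years),
                                feats$name))
  # vectorised over districts: slice the panel's month planes per window
  yr_idx <- function(y) match(as.character(y), dimnames(panel$values)[[2]])
  for (j in seq_len(nrow(feats))) {
    months <- window_months(feats$start_month[j], feats$end_month[j])
    op <- feats$op[j]; v <- feats$variable[j]
    for (yi in seq_along(harvest_years)) {
      hy <- harvest_years[yi]
      yrs <- ifelse(months > cutoff_month, hy - 1L, hy)
      yk <- vapply(yrs, yr_idx, integer(1))
      if (anyNA(yk)) next
      block <- vapply(seq_along(months), function(i)
        panel$values[, yk[i], months[i], v], numeric(length(districts)))
      block <- matrix(block, nrow = length(districts))
      agg <- if (op == "mean") rowMeans(block) else rowSums(block)
      vals[, yi, j] <- agg
    }
  }
  structure(list(values = vals, features = feats,
                 cutoff_month = as.integer(cutoff_month)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "feature_matrix: %d districts x %d harvest years x %d features (cutoff month %d)\n",
    d[1], d[2], d[3], x$cutoff_month))
  invisible(x)
}

# districts x features value matrix for one harvest year
fm_year_slice <- function(fm, harvest_year) {
  yi <- match(as.character(harvest_year), dimnames(fm$values)[[2]])
  if (is.na(yi)) stop("harvest year not in feature matrix: ", harvest_year)
  fm$values[, yi, , drop = FALSE][, 1, , drop = TRUE]
}

# features x features conflict matrix: TRUE where two features of the same
# variable have overlapping windows (a combination must not contain both)
feature_conflicts <- function(features) {
  p <- nrow(features)
  masks <- integer(p)
  for (i in seq_len(p))
    masks[i] <- sum(bitwShiftL(1L, window_months(features$start_month[i],
                                                 features$end_month[i]) - 1L))
  same_var <- outer(features$variable, features$variable, "==")
  inter <- outer(masks, masks, bitwAnd) != 0L
  conf <- same_var & inter
  diag(conf) <- FALSE
  conf
}
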