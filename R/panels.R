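#' Monthly district weather panel
#'
#' Container for monthly weather values of one or more variables across
#' districts and calendar years.  Internally a 4-d array
#' (district x calendar year x month x variable); absent observations are NA.
#'
#' @param data long data.frame with columns `district`, `year`, `month`,
#'   `variable`, `value`.
#' @param variables data.frame describing the variables: columns `id`,
#'   `units`, `op` (aggregation operator, "mean" or "sum").
#' @return object of class `weather_panel`.
#' @export
weather_panel <- function(data, variables) {
  need <- c("district", "year", "month", "variable", "value")
  if (!all(need %in% names(data)))
    stop("weather data must have columns ", paste(need, collapse = ", "))
  stopifnot(all(c("id", "op") %in% names(variables)))
  if (!all(variables$op %in% c("mean", "sum")))
    stop("aggregation op must be 'mean' or 'sum'")
  if (!all(data$variable %in% variables$id))
    stop("weather rows with undeclared variable id")
  if (!all(data$month %in% 1:12)) stop("month out of range 1-12")
  key <- paste(data$district, data$year, data$month, data$variable)
  if (anyDuplicated(key))
    stop("duplicate (district, year, month, variable) rows in weather data")
  districts <- sort(unique(as.character(data$district)))
  years <- seq(min(data$year), max(data$year))
  vals <- array(NA_real_,
                dim = c(length(districts), length(years), 12L, nrow(variables)),
                dimnames = list(districts, as.character(years), NULL,
                                variables$id))
  idx <- cbind(match(as.character(data$district), districts),
               match(data$year, years),
               data$month,
               match(data$variable, variables$id))
  vals[idx] <- data$value
  if (!"units" %in% names(variables)) variables$units <- ""
  structure(list(values = vals,
                 variables = variables[, c("id", "units", "op")]),
            class = "weather_panel")
}

panel_value <- function(panel, district, year, month, variable) {
  di <- match(as.character(district), dimnames(panel$values)[[1]])
  yi <- match(as.character(year), dimnames(panel$values)[[2]])
  vi <- match(variable, dimnames(panel$values)[[4]])
  if (is.na(di)) stop("unknown district: ", district)
  if (is.na(vi)) stop("unknown variable: ", variable)
  if (is.na(yi)) return(NA_real_)
  panel$values[di, yi, month, vi]
}

#' @export
print.weather_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("weather_panel: %d districts, years %s-%s, variables: %s\n",
              d[1], dimnames(x$values)[[2]][1],
              dimnames(x$values)[[2]][d[2]],
              paste(x$variables$id, collapse = ", ")))
  invisible(x)
}

#' Long-format view of a weather panel
#'
#' @param panel a [weather_panel].
#' @return data.frame `district, year, month, variable, value` with NA rows
#'   dropped, sorted by district, variable, year, month.
#' @export
panel_to_long <- function(panel) {
  dn <- dimnames(panel$values)
  g <- expand.grid(district = dn[[1]], year = as.integer(dn[[2]]),
                   month = 1:12, variable = dn[[4]],
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$value <- as.vector(panel$values)
  g <- g[!is.na(g$value), ]
  g <- g[order(g$district, g$variable, g$year, g$month), ]
  rownames(g) <- NULL
  g
}

#' District x year yield matrix
#'
#' @param data long data.frame with columns `district`, `year`, `yield`
#'   (dt/ha); missing years simply absent or NA.
#' @return numeric matrix, rows = districts, columns = years (character
#'   dimnames), NA where unobserved.
#' @export
yield_matrix <- function(data) {
  need <- c("district", "year", "yield")
  if (!all(need %in% names(data)))
    stop("yield data must have columns ", paste(need, collapse = ", "))
  if (any(!is.na(data$yield) & data$yield < 0))
    stop("negative yields in input")
  key <- paste(data$district, data$year)
  if (anyDuplicated(key)) stop("duplicate (district, year) yield rows")
  districts <- sort(unique(as.character(data$district)))
  years <- seq(min(data$year), max(data$year))
  m <- matrix(NA_real_, length(districts), length(years),
              dimnames = list(districts, as.character(years)))
  m[cbind(match(as.character(data$district), districts),
          match(data$year, years))] <- data$yield
  m
}

# districts with at least min_years non-missing yields
usable_districts <- function(yields, min_years) {
  rownames(yields)[rowSums(!is.na(yields)) >= min_years]
}
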