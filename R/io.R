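#' Read / write the delimited ASCII tables
#'
#' All inputs and intermediates are header-carrying delimited text (default
#' tab, decimal point ".", missing token "NA", UTF-8).
#'
#' Weather accepts two layouts: long (`district, year, month, variable,
#' value`) or wide (`district, year, month` plus one column per variable
#' id); both parse to the same panel.
#'
#' @param path file path.
#' @param variables data.frame `id`, `units`, `op` describing the weather
#'   variables (required to type the panel).
#' @param delim field delimiter (default tab).
#' @return `read_weather_table`: a [weather_panel].
#' @export
read_weather_table <- function(path, variables, delim = "\t") {
  df <- read_ascii(path, delim)
  need_long <- c("district", "year", "month", "variable", "value")
  if (all(need_long %in% names(df))) {
    long <- df
  } else if (all(c("district", "year", "month") %in% names(df))) {
    vcols <- intersect(variables$id, names(df))
    if (length(vcols) == 0L)
      stop("no declared variable column found in ", path)
    long <- do.call(rbind, lapply(vcols, function(v)
      data.frame(district = df$district, year = df$year, month = df$month,
                 variable = v, value = df[[v]])))
    long <- long[!is.na(long$value), ]
  } else {
    stop("weather table needs columns district/year/month plus either ",
         "variable/value or one column per variable: ", path)
  }
  weather_panel(long, variables)
}

#' @rdname read_weather_table
#' @param panel a [weather_panel] to write.
#' @param layout "long" or "wide".
#' @export
write_weather_table <- function(panel, path, layout = c("long", "wide"),
                                delim = "\t") {
  layout <- match.arg(layout)
  long <- panel_to_long(panel)
  if (layout == "wide") {
    wide <- stats::reshape(long, direction = "wide",
                           idvar = c("district", "year", "month"),
                           timevar = "variable")
    names(wide) <- sub("^value\\.", "", names(wide))
    write_ascii(wide, path, delim)
  } else write_ascii(long, path, delim)
  invisible(path)
}

#' @rdname read_weather_table
#' @return `read_yield_table`: district x year matrix (see
#'   [yield_matrix()]); negative yields are an error.
#' @export
read_yield_table <- function(path, delim = "\t") {
  df <- read_ascii(path, delim)
  if (!all(c("district", "year", "yield") %in% names(df)))
    stop("yield table needs columns district, year, yield: ", path)
  yield_matrix(df)
}

#' @rdname read_weather_table
#' @param yields district x year matrix.
#' @export
write_yield_table <- function(yields, path, delim = "\t") {
  long <- data.frame(district = rep(rownames(yields), times = ncol(yields)),
                     year = rep(as.integer(colnames(yields)),
                                each = nrow(yields)),
                     yield = as.vector(yields))
  long <- long[!is.na(long$yield), ]
  long <- long[order(long$district, long$year), ]
  write_ascii(long, path, delim)
  invisible(path)
}

#' @rdname read_weather_table
#' @return `read_area_table`: named vector district -> growing area (ha).
#' @export
read_area_table <- function(path, delim = "\t") {
  df <- read_ascii(path, delim)
  if (!all(c("district", "area") %in% names(df)))
    stop("area table needs columns district, area: ", path)
  if (any(df$area < 0, na.rm = TRUE)) stop("negative growing areas: ", path)
  stats::setNames(df$area, df$district)
}

#' @rdname read_weather_table
#' @return `read_region_map`: data.frame `district`, `region`.
#' @export
read_region_map <- function(path, delim = "\t") {
  df <- read_ascii(path, delim)
  if (!all(c("district", "region") %in% names(df)))
    stop("region map needs columns district, region: ", path)
  df[, c("district", "region")]
}

read_ascii <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, header = TRUE, sep = delim, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "", fill = FALSE,
                    fileEncoding = "UTF-8")
}

write_ascii <- function(df, path, delim = "\t") {
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a run control file
#'
#' Plain `key = value` lines (one per parameter, "#" comments allowed).
#' Variables are declared as `id:op:units` triples separated by commas, e.g.
#' `variables = tas:mean:degC,pr:sum:mm`.  Unset keys fall back to the
#' defaults below (cut-off June, 12-month season, windows 2-6, d_max 4,
#' k 23, confidence 0.999, min_years 17, strict out-of-sample mode).
#'
#' @param path control file path.
#' @return named list of parameters (class `control`).
#' @export
read_control <- function(path) {
  if (!file.exists(path)) stop("no such control file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed control line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- stats::setNames(lapply(kv, `[[`, 3L),
                          vapply(kv, `[[`, character(1), 2L))
  ctl <- control_defaults()
  for (key in names(vals)) {
    v <- trimws(vals[[key]])
    ctl[[key]] <- switch(key,
      crop = , weather_file = , yield_file = , area_file = ,
      region_file = , out_dir = , mode = , weather_layout = v,
      variables = parse_variable_spec(v),
      fractions = as.numeric(strsplit(v, ",")[[1]]),
      strict = , non_overlap = as.logical(v),
      confidence = , min_coverage = as.numeric(v),
      target_years = as.integer(strsplit(v, ",")[[1]]),
      as.integer(v))
  }
  validate_control(ctl)
}

control_defaults <- function() {
  list(crop = "crop", cutoff_month = 6L, season_length = 12L,
       window_min = 2L, window_max = 6L, d_max = 4L, k = 23L,
       confidence = 0.999, min_years = 17L, min_pairs = 8L,
       strict = TRUE, non_overlap = TRUE, mode = "global-local",
       n_global = 5L, fractions = seq(1, 0.1, by = -0.1),
       min_coverage = 0.5, fallback_m = 10L, workers = 1L, seed = 1L,
       variables = data.frame(id = c("tas", "pr"), op = c("mean", "sum"),
                              units = c("degC", "mm")),
       weather_layout = "long",
       weather_file = "weather.tsv", yield_file = "yields.tsv",
       area_file = "areas.tsv", region_file = "regions.tsv",
       out_dir = "out", target_years = NULL)
}

parse_variable_spec <- function(v) {
  parts <- strsplit(strsplit(v, ",")[[1]], ":")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) stop("variable spec must be id:op[:units] triples: ", v)
  data.frame(id = vapply(parts, `[[`, "", 1L),
             op = vapply(parts, `[[`, "", 2L),
             units = vapply(parts, function(p)
               if (length(p) >= 3L) p[[3L]] else "", character(1)))
}

validate_control <- function(ctl) {
  stopifnot(ctl$cutoff_month %in% 1:12,
            ctl$window_min >= 1L, ctl$window_min <= ctl$window_max,
            ctl$window_max <= ctl$season_length,
            ctl$d_max >= 0L, ctl$d_max <= 4L, ctl$k >= 1L,
            ctl$confidence > 0, ctl$confidence < 1,
            ctl$min_years >= ctl$d_max + 3L,
            all(ctl$variables$op %in% c("mean", "sum")),
            ctl$mode %in% c("global-local", "local"))
  class(ctl) <- "control"
  ctl
}

#' @rdname read_control
#' @param ctl a control list.
#' @export
write_control <- function(ctl, path) {
  fmt <- function(key) {
    v <- ctl[[key]]
    if (key == "variables")
      return(paste(sprintf("%s:%s:%s", v$id, v$op, v$units), collapse = ","))
    if (is.null(v)) return(NULL)
    paste(v, collapse = ",")
  }
  keys <- setdiff(names(ctl), character(0))
  lines <- unlist(lapply(keys, function(k) {
    v <- fmt(k)
    if (is.null(v)) NULL else sprintf("%s = %s", k, v)
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
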