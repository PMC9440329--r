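#' Run screening, evaluation, and selection for one target year
#'
#' Stages 1-3 for a single target year: exhaustive screening of weather
#' features, leave-one-out evaluation of every admissible combination of the
#' screened features, and the global/local hero selection, followed by the
#' per-district prediction for the target year.
#'
#' @param fm a `feature_matrix`.
#' @param yields district x year yield matrix.
#' @param target_year harvest year to predict.
#' @param ctl parameter list, see [control_defaults()]; any subset of keys
#'   may be supplied.
#' @return list `screening`, `eval_table`, `selection`, `predictions`
#'   (data.frame `district`, `year`, `predicted`, `spec`, `mode`).
#' @export
run_year <- function(fm, yields, target_year, ctl = list()) {
  ctl <- utils::modifyList(control_defaults(), ctl)
  scr <- prospect(fm, yields, target_year, k = ctl$k, d = ctl$d_max,
                  confidence = ctl$confidence, min_years = ctl$min_years,
                  non_overlap = ctl$non_overlap, fallback_m = ctl$fallback_m,
                  workers = ctl$workers)
  et <- build_eval_table(fm, yields, scr$selected, target_year,
                         d_max = ctl$d_max, strict = ctl$strict,
                         min_pairs = ctl$min_pairs, min_years = ctl$min_years,
                         non_overlap = ctl$non_overlap, workers = ctl$workers)
  sel <- select_combos(et, mode = ctl$mode, n_global = ctl$n_global,
                       fractions = ctl$fractions,
                       min_coverage = ctl$min_coverage)
  obs_years <- as.integer(colnames(yields))[colSums(!is.na(yields)) > 0]
  mode <- if (target_year %in% obs_years) "hindcast" else "forecast"
  preds <- lapply(seq_len(nrow(sel$assignment)), function(i) {
    a <- sel$assignment[i, ]
    feats <- combo_features(a$spec)
    pr <- predict_district(fm, yields, a$district, target_year, feats, mode)
    data.frame(district = a$district, year = target_year,
               predicted = pr$predicted, spec = a$spec, mode = mode)
  })
  list(screening = scr, eval_table = et, selection = sel,
       predictions = do.call(rbind, preds))
}

# combination label -> feature-name vector
combo_features <- function(spec) {
  if (spec == "(trend)") character(0) else strsplit(spec, "+", fixed = TRUE)[[1]]
}

#' Run the full pipeline over a set of target years
#'
#' Per target year: screen, evaluate, select, predict per district; then
#' aggregate the district predictions to regional series with area weights,
#' attach uncertainty bands from the regional hindcast errors, and compute
#' validation metrics.
#'
#' @inheritParams run_year
#' @param areas named vector district -> growing area (ha).
#' @param region_map data.frame `district`, `region`, or NULL for one
#'   region "all".  The national/total series is always computed directly
#'   from districts (never from regional means).
#' @param target_years harvest years to process; default all years with any
#'   observed yield, plus later years covered by the feature matrix.
#' @param verbose log per-year diagnostics (districts used, q, A, c)?
#' @return object of class `pipeline_result`: list with
#'   `district_predictions`, `regional` (region, year, observed, predicted,
#'   lo, hi, mode), `metrics` (per region), `per_year` (q, A, c, mean_r
#'   diagnostics), `ctl`.
#' @export
run_pipeline <- function(fm, yields, areas = NULL, region_map = NULL,
                         target_years = NULL, ctl = list(), verbose = TRUE) {
  ctl <- utils::modifyList(control_defaults(), ctl)
  if (is.null(areas))
    areas <- stats::setNames(rep(1, nrow(yields)), rownames(yields))
  obs_years <- as.integer(colnames(yields))[colSums(!is.na(yields)) > 0]
  if (is.null(target_years)) {
    fm_years <- as.integer(dimnames(fm$values)[[2]])
    covered <- fm_years[apply(!is.na(fm$values), 2, any)]
    target_years <- sort(union(obs_years, covered[covered > max(obs_years)]))
  }
  years_res <- list()
  for (ty in target_years) {
    yr <- run_year(fm, yields, ty, ctl)
    years_res[[as.character(ty)]] <- yr
    if (verbose)
      message(sprintf(
        "year %d: %d districts, q = %d features, A = %d combos, c = %d applied, mean r = %.3f",
        ty, length(yr$screening$districts), yr$screening$q,
        nrow(yr$eval_table), yr$selection$c, yr$selection$mean_r))
  }
  dp <- do.call(rbind, lapply(years_res, `[[`, "predictions"))
  rownames(dp) <- NULL
  regional <- aggregate_series(dp, yields, areas, region_map)
  metrics <- do.call(rbind, lapply(split(regional, regional$region),
    function(rg) {
      vm <- validation_metrics(rg$observed, rg$predicted)
      data.frame(region = rg$region[1], r2_val = vm$r2_val, rmse = vm$rmse,
                 r2_pearson = vm$r2_pearson, n = vm$n)
    }))
  rownames(metrics) <- NULL
  per_year <- do.call(rbind, lapply(names(years_res), function(ty) {
    yr <- years_res[[ty]]
    data.frame(year = as.integer(ty), n_districts = length(yr$screening$districts),
               q = yr$screening$q, A = nrow(yr$eval_table),
               c = yr$selection$c, mean_r = yr$selection$mean_r)
  }))
  structure(list(district_predictions = dp, regional = regional,
                 metrics = metrics, per_year = per_year, ctl = ctl,
                 years = years_res),
            class = "pipeline_result")
}

# district predictions -> regional observed/predicted series with bands
aggregate_series <- function(dp, yields, areas, region_map) {
  if (is.null(region_map))
    region_map <- data.frame(district = rownames(yields), region = "all")
  rmap_total <- data.frame(district = rownames(yields), region = "total")
  maps <- rbind(region_map, rmap_total)
  out <- list()
  for (ty in sort(unique(dp$year))) {
    sub <- dp[dp$year == ty & !is.na(dp$predicted), ]
    if (nrow(sub) == 0L) next
    pv <- stats::setNames(sub$predicted, sub$district)
    yi <- match(as.character(ty), colnames(yields))
    # observed aggregate over the same districts, for a fair comparison
    ov <- if (is.na(yi)) stats::setNames(rep(NA_real_, length(pv)), names(pv))
          else stats::setNames(yields[names(pv), yi], names(pv))
    pred_r <- aggregate_districts(pv, areas, maps)
    obs_r <- aggregate_districts(ov, areas, maps)
    out[[as.character(ty)]] <-
      data.frame(region = names(pred_r), year = ty, observed = obs_r,
                 predicted = pred_r,
                 mode = sub$mode[1], row.names = NULL)
  }
  reg <- do.call(rbind, out)
  rownames(reg) <- NULL
  # uncertainty bands per region from that region's hindcast errors
  reg$lo <- NA_real_; reg$hi <- NA_real_
  for (rg in unique(reg$region)) {
    i <- reg$region == rg
    hind <- i & reg$mode == "hindcast" & !is.na(reg$observed) &
      !is.na(reg$predicted)
    errors <- reg$predicted[hind] - reg$observed[hind]
    ui_h <- uncertainty_interval(errors, "hindcast")
    ui_f <- uncertainty_interval(errors, "forecast")
    ih <- i & reg$mode == "hindcast"
    reg$lo[ih] <- reg$predicted[ih] - ui_h$half_width
    reg$hi[ih] <- reg$predicted[ih] + ui_h$half_width
    iff <- i & reg$mode == "forecast"
    ctr <- reg$predicted[iff] - ui_f$center_offset
    reg$lo[iff] <- ctr - ui_f$half_width
    reg$hi[iff] <- ctr + ui_f$half_width
  }
  reg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d target years, %d districts\n",
              nrow(x$per_year), length(unique(x$district_predictions$district))))
  print(x$metrics)
  invisible(x)
}

#' Run everything from a control file and persist all stages (run-all)
#'
#' Reads the input tables named in the control file, runs the five stages
#' for every target year, and writes every intermediate and final table to
#' the control file's `out_dir` so that any stage can be re-run from files:
#' `screening_<year>.tsv`, `eval_<year>.tsv`, `selection_<year>.tsv`,
#' `district_predictions.tsv`, `regional.tsv`, `metrics.tsv`,
#' `per_year.tsv`.
#'
#' @param control path to a control file, or a `control` list.
#' @param dir directory input paths are relative to (default: the control
#'   file's directory, or "." for a list).
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_all <- function(control, dir = NULL) {
  if (is.character(control)) {
    if (is.null(dir)) dir <- dirname(control)
    ctl <- read_control(control)
  } else {
    if (is.null(dir)) dir <- "."
    ctl <- validate_control(utils::modifyList(control_defaults(), control))
  }
  pathify <- function(p) if (startsWith(p, "/")) p else file.path(dir, p)
  panel <- read_weather_table(pathify(ctl$weather_file), ctl$variables)
  yields <- read_yield_table(pathify(ctl$yield_file))
  areas <- if (file.exists(pathify(ctl$area_file)))
    read_area_table(pathify(ctl$area_file)) else NULL
  region_map <- if (file.exists(pathify(ctl$region_file)))
    read_region_map(pathify(ctl$region_file)) else NULL
  fm <- build_feature_matrix(panel, ctl$cutoff_month,
                             variables = ctl$variables$id,
                             season_length = ctl$season_length,
                             min_len = ctl$window_min,
                             max_len = ctl$window_max)
  res <- run_pipeline(fm, yields, areas, region_map,
                      target_years = ctl$target_years, ctl = ctl)
  out <- pathify(ctl$out_dir)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (ty in names(res$years)) {
    yr <- res$years[[ty]]
    write_screening(yr$screening, file.path(out, paste0("screening_", ty, ".tsv")))
    write_eval_table(yr$eval_table, file.path(out, paste0("eval_", ty, ".tsv")))
    write_selection(yr$selection, file.path(out, paste0("selection_", ty, ".tsv")))
  }
  write_ascii(res$district_predictions,
              file.path(out, "district_predictions.tsv"))
  write_ascii(res$regional, file.path(out, "regional.tsv"))
  write_ascii(res$metrics, file.path(out, "metrics.tsv"))
  write_ascii(res$per_year, file.path(out, "per_year.tsv"))
  invisible(res)
}

#' Writers / readers for persisted stage outputs
#'
#' @param scr,eval_table,sel stage results.
#' @param path file path.
#' @export
write_screening <- function(scr, path) {
  df <- data.frame(feature = names(scr$counts),
                   count = as.integer(scr$counts),
                   selected = names(scr$counts) %in% scr$selected)
  attr_lines <- sprintf("# %s = %s",
                        c("target_year", "n", "p", "threshold", "confidence"),
                        c(scr$target_year, scr$n, format(scr$p, digits = 15),
                          scr$threshold, scr$confidence))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(attr_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screening
#' @export
read_screening <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_l <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(meta_l, regexec("^# ([a-z_]+) = (.*)$", meta_l))
  meta <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  counts <- stats::setNames(df$count, df$feature)
  list(target_year = as.integer(meta$target_year), counts = counts,
       n = as.integer(meta$n), p = as.numeric(meta$p),
       threshold = as.integer(meta$threshold),
       confidence = as.numeric(meta$confidence),
       selected = df$feature[df$selected])
}

#' @rdname write_screening
#' @export
write_eval_table <- function(eval_table, path) {
  m <- unclass(eval_table)
  df <- data.frame(spec = rownames(m), round(m, 6), check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# target_year = %s", attr(eval_table, "target_year")), con)
  writeLines(sprintf("# strict = %s", attr(eval_table, "strict")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screening
#' @export
read_eval_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_l <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(meta_l, regexec("^# ([a-z_]+) = (.*)$", meta_l))
  meta <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$spec
  structure(m, combos = lapply(df$spec, combo_features),
            target_year = as.integer(meta$target_year),
            strict = as.logical(meta$strict),
            class = c("eval_table", "matrix"))
}

#' @rdname write_screening
#' @export
write_selection <- function(sel, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# target_year = %s", sel$target_year), con)
  writeLines(sprintf("# pool: %s [%s]", sel$pool$spec, sel$pool$provenance), con)
  utils::write.table(sel$assignment, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_screening
#' @export
read_selection <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ty <- sub("^# target_year = ", "",
            grep("^# target_year = ", lines, value = TRUE))
  pool_l <- grep("^# pool: ", lines, value = TRUE)
  pm <- regmatches(pool_l, regexec("^# pool: (.*) \\[(.*)\\]$", pool_l))
  pool <- data.frame(spec = vapply(pm, `[[`, "", 2L),
                     provenance = vapply(pm, `[[`, "", 3L))
  assignment <- utils::read.table(text = lines[!startsWith(lines, "#")],
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  structure(list(target_year = as.integer(ty), pool = pool,
                 assignment = assignment,
                 c = length(unique(assignment$spec)),
                 mean_r = mean(assignment$r)),
            class = "selection_result")
}
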