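#' Globally best-performing combinations
#'
#' Ranks the evaluation table's combinations by their mean Pearson r across
#' districts (missing cells excluded) and returns the top `n_top`.
#'
#' @param eval_table an [build_eval_table()] result.
#' @param n_top how many combinations to return.
#' @param min_coverage minimum fraction of districts with a valid r for a
#'   combination to be eligible (guards against lucky sparse rows).
#' @return data.frame `spec`, `mean_r`, `n_districts`, ordered by decreasing
#'   mean r (ties by label).
#' @export
global_heroes <- function(eval_table, n_top = 5L, min_coverage = 0.5) {
  m <- unclass(eval_table)
  cover <- rowMeans(!is.na(m))
  mean_r <- rowMeans(m, na.rm = TRUE)
  mean_r[cover < min_coverage | is.nan(mean_r)] <- NA_real_
  ord <- order(-mean_r, rownames(m), na.last = TRUE)
  ord <- ord[!is.na(mean_r[ord])]
  ord <- ord[seq_len(min(n_top, length(ord)))]
  data.frame(spec = rownames(m)[ord], mean_r = mean_r[ord],
             n_districts = rowSums(!is.na(m))[ord], row.names = NULL)
}

#' Combinations excelling in district subsets ("local heroes")
#'
#' For each fraction f, combinations are ranked by the mean of their best
#' ceiling(f * D) district r values, rewarding models that work
#' exceptionally well in a minority of landscapes; the top combination per
#' fraction is returned.
#'
#' @inheritParams global_heroes
#' @param fractions district-share grid, default 1.0 down to 0.1.
#' @return data.frame `spec`, `fraction`, `subset_mean_r` (duplicate specs
#'   across fractions are kept; pooling deduplicates).
#' @export
local_heroes_subsets <- function(eval_table, fractions = seq(1, 0.1, by = -0.1),
                                 min_coverage = 0.5) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fractions <- sort(fractions, decreasing = TRUE)
  m <- unclass(eval_table)
  cover <- rowMeans(!is.na(m))
  rows <- lapply(fractions, function(f) {
    sc <- vapply(seq_len(nrow(m)), function(i) {
      ri <- m[i, ][!is.na(m[i, ])]
      if (cover[i] < min_coverage || length(ri) == 0L) return(NA_real_)
      # the combination's own best f-share of its valid districts
      nf <- as.integer(ceiling(f * length(ri)))
      mean(sort(ri, decreasing = TRUE)[seq_len(nf)])
    }, numeric(1))
    ord <- order(-sc, rownames(m), na.last = TRUE)
    best <- ord[!is.na(sc[ord])][1]
    if (is.na(best)) return(NULL)
    data.frame(spec = rownames(m)[best], fraction = f,
               subset_mean_r = sc[best], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Build the merged candidate pool of global and local heroes
#'
#' @inheritParams global_heroes
#' @param n_global number of top global combinations (default 5).
#' @param fractions subset-share grid for the local heroes.
#' @return data.frame `spec`, `provenance` ("global#i" or "subset f"), in
#'   pool order (globals first, then fractions descending); duplicates kept
#'   once at their first appearance.
#' @export
hero_pool <- function(eval_table, n_global = 5L,
                      fractions = seq(1, 0.1, by = -0.1),
                      min_coverage = 0.5) {
  g <- global_heroes(eval_table, n_top = n_global, min_coverage = min_coverage)
  l <- local_heroes_subsets(eval_table, fractions, min_coverage = min_coverage)
  pool <- rbind(
    if (nrow(g)) data.frame(spec = g$spec,
                            provenance = sprintf("global#%d", seq_len(nrow(g)))),
    if (!is.null(l) && nrow(l)) data.frame(spec = l$spec,
                            provenance = sprintf("subset %.1f", l$fraction)))
  pool[!duplicated(pool$spec), , drop = FALSE]
}

#' Assign each district its best combination from a candidate pool
#'
#' @param pool data.frame with a `spec` column ([hero_pool()] output), or a
#'   character vector of combination labels present in the table.
#' @param eval_table an [build_eval_table()] result.
#' @return object of class `selection_result`: list with `target_year`,
#'   `pool`, `assignment` (data.frame `district`, `spec`, `r`), `c` (number
#'   of distinct assigned combinations), `mean_r`.  Districts whose pool
#'   cells are all missing are left unassigned (with a warning).
#' @export
assign_district_combos <- function(pool, eval_table) {
  specs <- if (is.data.frame(pool)) pool$spec else pool
  stopifnot(length(specs) > 0L)
  miss <- setdiff(specs, rownames(eval_table))
  if (length(miss)) stop("pool specs missing from eval table: ",
                         paste(miss, collapse = ", "))
  m <- unclass(eval_table)[specs, , drop = FALSE]
  picks <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (all(is.na(col))) return(NA_integer_)
    which.max(replace(col, is.na(col), -Inf))  # ties -> earlier pool position
  }, integer(1))
  assigned <- !is.na(picks)
  if (any(!assigned))
    warning(sum(!assigned), " district(s) without any valid pool r; unassigned")
  assignment <- data.frame(
    district = colnames(m)[assigned],
    spec = specs[picks[assigned]],
    r = m[cbind(picks[assigned], which(assigned))], row.names = NULL)
  structure(list(target_year = attr(eval_table, "target_year"),
                 pool = if (is.data.frame(pool)) pool
                        else data.frame(spec = specs, provenance = "user"),
                 assignment = assignment,
                 c = length(unique(assignment$spec)),
                 mean_r = mean(assignment$r)),
            class = "selection_result")
}

#' Per-district selection modes (program 3)
#'
#' `select_combos(mode = "global-local")` builds the merged global/subset
#' hero pool and assigns each district its best pool member.  `mode =
#' "local"` ranks every combination per district instead ("local heroes"
#' only, prone to overfitting single noisy series).
#'
#' @inheritParams hero_pool
#' @param mode "global-local" (default) or "local".
#' @return a `selection_result`.
#' @export
select_combos <- function(eval_table, mode = c("global-local", "local"),
                          n_global = 5L, fractions = seq(1, 0.1, by = -0.1),
                          min_coverage = 0.5) {
  mode <- match.arg(mode)
  if (mode == "local") return(local_heroes_only(eval_table))
  pool <- hero_pool(eval_table, n_global, fractions, min_coverage)
  if (is.null(pool) || nrow(pool) == 0L)
    stop("empty candidate pool (no combination met the coverage requirement)")
  assign_district_combos(pool, eval_table)
}

#' @rdname select_combos
#' @export
local_heroes_only <- function(eval_table) {
  res <- assign_district_combos(rownames(eval_table), eval_table)
  res$pool <- data.frame(spec = unique(res$assignment$spec),
                         provenance = "local")
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (target year %s): pool %d, c = %d distinct combos over %d districts, mean r = %.3f\n",
              x$target_year, nrow(x$pool), x$c, nrow(x$assignment), x$mean_r))
  invisible(x)
}
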