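#' Metric orientations
#'
#' Direction in which each supported metric improves: `+1` for
#' higher-is-better (GDT, SphereGrinder, lDDT, QCS, CADaa, ASE, the
#' torsion score), `-1` for lower-is-better (RMS_CA, MolProbity).
#'
#' @return Named numeric vector of orientations.
#' @export
metric_orientations <- function() {
  c(rms_ca = -1, gdt_ts = 1, gdt_ha = 1, sg = 1, lddt = 1, ase = 1,
    s_torsion = 1, qcs = 1, mp = -1, cadaa = 1, llg = 1)
}

orient_values <- function(values, metric) {
  orientation <- metric_orientations()[metric]
  if (is.na(orientation)) {
    stop("unknown metric orientation for '", metric,
         "'; known metrics: ", paste(names(metric_orientations()), collapse = ", "))
  }
  orientation * values
}

#' Build or validate a metric table
#'
#' A metric table has one row per `(target_id, group_id, model_index)`
#' submission and one column per metric. Native columns (computed by this
#' package: `rms_ca`, `gdt_ts`, `gdt_ha`, `sg`, `lddt`, `ase`,
#' `s_torsion`) and ingested columns (externally computed: `qcs`, `mp`,
#' `cadaa`, `llg`) share the same layout; provenance is recorded in the
#' `"provenance"` attribute.
#'
#' @param x A data frame with at least `target_id`, `group_id`,
#'   `model_index`, and one metric column.
#' @param provenance Optional named character vector tagging metric columns
#'   `"computed"` or `"ingested"`.
#' @return A `metric_table` tibble.
#' @export
metric_table <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  key <- c("target_id", "group_id", "model_index")
  missing <- setdiff(key, names(x))
  if (length(missing) > 0) {
    stop("metric table lacks key columns: ", paste(missing, collapse = ", "))
  }
  metrics <- setdiff(names(x), key)
  if (length(metrics) == 0) stop("metric table has no metric columns")
  if (anyDuplicated(x[key]) > 0) {
    stop("duplicate (target_id, group_id, model_index) keys")
  }
  if (is.null(provenance)) {
    native <- c("rms_ca", "gdt_ts", "gdt_ha", "sg", "lddt", "ase", "s_torsion")
    provenance <- stats::setNames(
      ifelse(metrics %in% native, "computed", "ingested"), metrics)
  }
  attr(x, "provenance") <- provenance
  class(x) <- unique(c("metric_table", class(x)))
  x
}

#' Read / write metric tables as CSV
#'
#' @param path CSV path with header columns `target_id`, `group_id`,
#'   `model_index`, then metric columns.
#' @return `read_metric_table()` returns a `metric_table`;
#'   `write_metric_table()` invisibly returns `path`.
#' @export
read_metric_table <- function(path) {
  metric_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_metric_table
#' @param x A `metric_table`.
#' @export
write_metric_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' z-score configuration (CASP conventions)
#'
#' Per-target pools are formed from model-1 submissions; values are
#' oriented so higher is better, standardised, outliers below
#' `outlier_threshold` dropped, the statistics recomputed on the
#' survivors, final z assigned to all rows from the recomputed statistics,
#' and floored at `floor`.
#'
#' @param outlier_threshold z below which values are excluded from the
#'   second-pass statistics (default -2).
#' @param floor Minimum assigned z (default -2).
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return A `zscore_config` list.
#' @export
zscore_config <- function(outlier_threshold = -2, floor = -2,
                          sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(floor <= 0)
  structure(list(outlier_threshold = outlier_threshold, floor = floor,
                 sd_mode = sd_mode),
            class = "zscore_config")
}

pool_sd <- function(x, mode) {
  if (length(x) < 1) return(NA_real_)
  if (mode == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
}

# two-pass pool statistics on oriented values (the pool itself)
pool_stats <- function(oriented, config) {
  v <- oriented[!is.na(oriented)]
  if (length(v) < 2) stop("z-score pool has fewer than 2 values")
  m1 <- mean(v); s1 <- pool_sd(v, config$sd_mode)
  if (s1 == 0) return(list(mean = m1, sd = 0))
  keep <- v[(v - m1) / s1 >= config$outlier_threshold]
  m2 <- mean(keep); s2 <- pool_sd(keep, config$sd_mode)
  list(mean = m2, sd = s2)
}

zscore_from_stats <- function(oriented, stats, config) {
  if (is.na(stats$sd) || stats$sd == 0) {
    z <- ifelse(is.na(oriented), NA_real_, 0)
  } else {
    z <- (oriented - stats$mean) / stats$sd
  }
  pmax(z, config$floor)
}

#' CASP-convention z-scores for one metric
#'
#' For each target, the pool of model-1 values defines two-pass
#' mean/SD (outliers below the threshold are dropped before the second
#' pass); every row of the table — including non-model-1 rows — is then
#' assigned a z from the recomputed statistics, oriented so higher is
#' better and floored. A pool with zero spread yields all-zero z.
#'
#' @param table A [metric_table()].
#' @param metric Metric column name.
#' @param config A [zscore_config()].
#' @return The table with an added `z_<metric>` column.
#' @export
casp_zscores <- function(table, metric, config = zscore_config()) {
  if (!metric %in% names(table)) stop("metric column not found: ", metric)
  oriented_all <- orient_values(table[[metric]], metric)
  zcol <- rep(NA_real_, nrow(table))
  for (tid in unique(table$target_id)) {
    rows <- which(table$target_id == tid)
    pool_rows <- rows[table$model_index[rows] == 1]
    pool <- oriented_all[pool_rows]
    if (sum(!is.na(pool)) < 2) {
      stop("target ", tid, ": z-score pool has fewer than 2 values for ", metric)
    }
    st <- pool_stats(pool, config)
    zcol[rows] <- zscore_from_stats(oriented_all[rows], st, config)
  }
  table[[paste0("z_", metric)]] <- zcol
  table
}

#' Add z-score columns for several metrics
#'
#' @param table A [metric_table()].
#' @param metrics Metric column names; defaults to every metric column
#'   with a known orientation present in the table.
#' @param config A [zscore_config()].
#' @return The table with `z_*` columns appended.
#' @export
add_zscores <- function(table, metrics = NULL, config = zscore_config()) {
  if (is.null(metrics)) {
    metrics <- intersect(names(metric_orientations()), names(table))
  }
  for (m in metrics) table <- casp_zscores(table, m, config)
  table
}

#' Composite ranking-score weight presets
#'
#' Published presets: `"casp12"` (the refinement ranking score
#' `0.46 z_RMS_CA + 0.17 z_GDT_HA + 0.20 z_SG + 0.15 z_QCS + 0.02 z_MP`),
#' `"tbm"` (`1/3 z_GDT_HA + 1/9 (z_lDDT + z_CADaa + z_SG) + 1/3 z_ASE`),
#' and `"tbm_prime"` (the ASE-free variant
#' `1/2 z_GDT_HA + 1/6 (z_lDDT + z_CADaa + z_SG)`). A named numeric
#' vector of non-negative weights summing to 1 is accepted as a custom
#' scheme.
#'
#' @param preset Preset name or named numeric weight vector.
#' @return Named numeric weights over metric names.
#' @export
ranking_weights <- function(preset = c("casp12", "tbm", "tbm_prime")) {
  if (is.numeric(preset)) {
    w <- preset
    if (is.null(names(w)) || any(names(w) == "")) stop("weights must be named")
    if (any(w < 0)) stop("weights must be non-negative")
    if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
    return(w)
  }
  preset <- match.arg(preset)
  switch(preset,
    casp12 = c(rms_ca = 0.46, gdt_ha = 0.17, sg = 0.20, qcs = 0.15, mp = 0.02),
    tbm = c(gdt_ha = 1 / 3, lddt = 1 / 9, cadaa = 1 / 9, sg = 1 / 9,
            ase = 1 / 3),
    tbm_prime = c(gdt_ha = 1 / 2, lddt = 1 / 6, cadaa = 1 / 6, sg = 1 / 6)
  )
}

#' Composite ranking score from a z-score vector
#'
#' The weighted sum of per-metric z-scores. Missing components error under
#' the default `"strict"` policy; `"renormalize"` drops them and rescales
#' the remaining weights to sum 1 (used e.g. when no external QCS/CADaa
#' values were ingested).
#'
#' @param z Named numeric z-scores (names are metric names, e.g.
#'   `gdt_ha`), `NA` allowed for missing metrics.
#' @param weights A [ranking_weights()] preset name or named vector.
#' @param missing `"strict"` or `"renormalize"`.
#' @return The composite score (a real number).
#' @export
composite_score <- function(z, weights = ranking_weights("casp12"),
                            missing = c("strict", "renormalize")) {
  missing <- match.arg(missing)
  if (is.character(weights)) weights <- ranking_weights(weights)
  comp <- names(weights)
  zv <- z[comp]
  names(zv) <- comp
  if (anyNA(zv)) {
    if (missing == "strict") {
      stop("missing z-score component(s): ",
           paste(comp[is.na(zv)], collapse = ", "),
           " (use missing = 'renormalize' to rescale over available ones)")
    }
    ok <- !is.na(zv)
    if (!any(ok)) stop("no z-score component available")
    weights <- weights[ok] / sum(weights[ok])
    zv <- zv[ok]
  }
  sum(weights * zv)
}

# under the renormalize policy, drop weight components whose metric column
# is absent from the table and rescale the remainder to sum 1
available_weights <- function(weights, table, missing) {
  present <- names(weights) %in% names(table)
  if (all(present)) return(weights)
  if (missing != "renormalize") {
    stop("table lacks metric column(s): ",
         paste(names(weights)[!present], collapse = ", "),
         " (use missing = 'renormalize' to rescale over available ones)")
  }
  if (!any(present)) stop("no weighted metric present in the table")
  weights[present] / sum(weights[present])
}

# per-row composite scores for a z-annotated table
score_rows <- function(table, weights, missing = "strict",
                       fill_pool_min = character(0)) {
  comp <- names(weights)
  zcols <- paste0("z_", comp)
  absent <- setdiff(zcols, names(table))
  if (length(absent) > 0) {
    stop("table lacks z-score columns: ", paste(absent, collapse = ", "),
         " (run add_zscores first)")
  }
  zm <- as.matrix(table[zcols])
  colnames(zm) <- comp
  # pool-minimum fill: estimate-free groups score at the bottom of the pool
  for (m in intersect(fill_pool_min, comp)) {
    for (tid in unique(table$target_id)) {
      rows <- which(table$target_id == tid)
      vals <- zm[rows, m]
      if (anyNA(vals) && any(!is.na(vals))) {
        zm[rows[is.na(vals)], m] <- min(vals, na.rm = TRUE)
      }
    }
  }
  apply(zm, 1, function(zrow) {
    composite_score(zrow, weights, missing = missing)
  })
}

#' Rank predictor groups by summed composite score
#'
#' Computes per-target composite scores from each group's model-1
#' z-vector and aggregates per group: `"sum_positive"` (the CASP
#' convention — negative per-target scores are clamped to zero before
#' summing) or `"mean"`. Groups are ordered descending with deterministic
#' lexicographic tie-break on group id.
#'
#' @param table A [metric_table()] holding model-1 rows for at least two
#'   groups.
#' @param weights A [ranking_weights()] preset name or named vector.
#' @param config A [zscore_config()].
#' @param mode Aggregation: `"sum_positive"` or `"mean"`.
#' @param missing Missing-metric policy: `"strict"`, `"renormalize"`, or
#'   `"pool_min"` (missing ASE z filled with the per-target pool minimum,
#'   mirroring how estimate-free groups score below average on ASE).
#' @param model_index Which submission index constitutes the ranking pool
#'   (default 1; pass `"best"` to use each group's best-scoring model).
#' @return A `ranking_result` list with `groups` (group_id, total, rank,
#'   n_targets), `scores` (per target x group), plus the weights, mode and
#'   config used.
#' @export
rank_groups <- function(table, weights = ranking_weights("casp12"),
                        config = zscore_config(),
                        mode = c("sum_positive", "mean"),
                        missing = c("strict", "renormalize", "pool_min"),
                        model_index = 1) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  if (is.character(weights)) weights <- ranking_weights(weights)
  if (nrow(table) == 0) stop("empty metric table")
  weights <- available_weights(weights, table, missing)
  table <- add_zscores(table, names(weights), config)
  fill <- if (missing == "pool_min") "ase" else character(0)
  policy <- if (missing == "pool_min") "strict" else missing
  sub <- if (identical(model_index, "best")) table else {
    table[table$model_index %in% model_index, , drop = FALSE]
  }
  if (length(unique(sub$group_id)) < 2) stop("need at least two groups")
  sub$score <- score_rows(sub, weights, missing = policy, fill_pool_min = fill)
  if (identical(model_index, "best")) {
    sub <- sub |>
      dplyr::group_by(.data$target_id, .data$group_id) |>
      dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  scores <- sub[, c("target_id", "group_id", "model_index", "score")]
  groups <- scores |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      total = if (mode == "sum_positive") sum(pmax(.data$score, 0))
              else mean(.data$score),
      n_targets = dplyr::n_distinct(.data$target_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$group_id)
  groups$rank <- seq_len(nrow(groups))
  structure(list(groups = groups, scores = scores, weights = weights,
                 mode = mode, config = config, baseline = NULL),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("Group ranking (", x$mode, ", weights: ",
      paste(sprintf("%s=%.3g", names(x$weights), x$weights), collapse = " "),
      ")\n", sep = "")
  print(x$groups, n = Inf)
  if (!is.null(x$baseline)) {
    cat(sprintf("naive-predictor baseline total: %.3f (%d of %d groups above)\n",
                x$baseline$total, x$baseline$n_better, nrow(x$groups)))
  }
  invisible(x)
}

# z-score arbitrary per-target values against the prediction pools of a table
zscores_against_pools <- function(values, target_ids, table, metric, config) {
  oriented_pool <- orient_values(table[[metric]], metric)
  out <- rep(NA_real_, length(values))
  for (i in seq_along(values)) {
    rows <- which(table$target_id == target_ids[i] & table$model_index == 1)
    pool <- oriented_pool[rows]
    if (sum(!is.na(pool)) < 2) {
      stop("target ", target_ids[i], ": z-score pool has fewer than 2 values for ",
           metric)
    }
    st <- pool_stats(pool, config)
    out[i] <- zscore_from_stats(orient_values(values[i], metric), st, config)
  }
  out
}

#' Naive-predictor baseline
#'
#' The naive predictor resubmits each starting model unchanged. Its
#' metrics are z-scored against the statistics of the real predictions
#' (the baseline never enters the pools that define mean/SD), its total is
#' computed under the same aggregation mode, and each group is flagged as
#' beating the baseline or not.
#'
#' @param table A [metric_table()] of real predictions.
#' @param start_rows A tibble with `target_id` plus the starting model's
#'   metric columns, one row per target.
#' @inheritParams rank_groups
#' @return A `ranking_result` whose `baseline` component holds the
#'   baseline `total`, per-target scores, and per-group `beats_baseline`
#'   flags (count in `n_better`).
#' @export
naive_baseline <- function(table, start_rows,
                           weights = ranking_weights("casp12"),
                           config = zscore_config(),
                           mode = c("sum_positive", "mean"),
                           missing = c("strict", "renormalize", "pool_min")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  if (is.character(weights)) weights <- ranking_weights(weights)
  miss_t <- setdiff(unique(table$target_id), start_rows$target_id)
  if (length(miss_t) > 0) {
    stop("missing start-model rows for target(s): ",
         paste(miss_t, collapse = ", "))
  }
  weights <- available_weights(weights, table, missing)
  ranking <- rank_groups(table, weights, config, mode, missing)
  start_rows <- start_rows[start_rows$target_id %in% unique(table$target_id), ]
  zb <- start_rows["target_id"]
  for (m in names(weights)) {
    if (!m %in% names(start_rows)) {
      stop("start rows lack metric column: ", m)
    }
    zb[[paste0("z_", m)]] <- zscores_against_pools(
      start_rows[[m]], start_rows$target_id, table, m, config)
  }
  zb$model_index <- 1L
  policy <- if (missing == "pool_min") "strict" else missing
  zb$score <- score_rows(zb, weights, missing = policy)
  total <- if (mode == "sum_positive") sum(pmax(zb$score, 0)) else mean(zb$score)
  groups <- ranking$groups
  groups$beats_baseline <- groups$total > total
  ranking$groups <- groups
  ranking$baseline <- list(
    total = total,
    scores = zb[, c("target_id", "score")],
    n_better = sum(groups$beats_baseline)
  )
  ranking
}

#' Fraction of targets improved over the starting model
#'
#' Per group, the fraction of targets where the model-1 submission is
#' strictly better than the starting model; ties count as not improved.
#' `score_spec` is either a single oriented metric name (compared on raw
#' values) or composite weights (compared on composite z-scores, with the
#' start model z-scored against the prediction pools).
#'
#' @param table A [metric_table()].
#' @param start_rows Per-target starting-model metric rows.
#' @param score_spec Metric name or [ranking_weights()] spec; default the
#'   composite refinement ranking score.
#' @param config A [zscore_config()] (composite specs only).
#' @param missing Missing-metric policy for composite specs.
#' @return A tibble with `group_id`, `n_targets`, `fraction_improved`.
#' @export
fraction_improved <- function(table, start_rows,
                              score_spec = ranking_weights("casp12"),
                              config = zscore_config(),
                              missing = c("strict", "renormalize", "pool_min")) {
  missing <- match.arg(missing)
  sub <- table[table$model_index == 1, , drop = FALSE]
  if (is.character(score_spec) && length(score_spec) == 1 &&
      score_spec %in% names(metric_orientations())) {
    metric <- score_spec
    sub$.score <- orient_values(sub[[metric]], metric)
    st <- tibble::tibble(
      target_id = start_rows$target_id,
      .start = orient_values(start_rows[[metric]], metric)
    )
  } else {
    weights <- ranking_weights(score_spec)
    weights <- available_weights(weights, table, missing)
    zt <- add_zscores(table, names(weights), config)
    zt <- zt[zt$model_index == 1, , drop = FALSE]
    fill <- if (missing == "pool_min") "ase" else character(0)
    policy <- if (missing == "pool_min") "strict" else missing
    sub <- zt
    sub$.score <- score_rows(zt, weights, missing = policy,
                             fill_pool_min = fill)
    zb <- start_rows["target_id"]
    for (m in names(weights)) {
      zb[[paste0("z_", m)]] <- zscores_against_pools(
        start_rows[[m]], start_rows$target_id, table, m, config)
    }
    zb$.start <- score_rows(zb, weights, missing = policy)
    st <- zb[, c("target_id", ".start")]
  }
  j <- dplyr::inner_join(sub, st, by = "target_id")
  if (nrow(j) == 0) stop("no paired model/start targets")
  j |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      fraction_improved = mean(.data$.score > .data$.start),
      .groups = "drop"
    )
}

#' Best refined model versus best initial model per target
#'
#' For each target, reports the starting-model value, the best model-1
#' value among the initial (TBM/FM) predictions, and the best model-1
#' value among refinement submissions, on an oriented metric; targets
#' where the best refined model fails to beat the best initial model are
#' the "exceptions" where a predictor could have done best by resubmitting
#' an initial model unchanged.
#'
#' @param table Refinement [metric_table()].
#' @param start_rows Per-target starting-model metric rows.
#' @param initial_rows [metric_table()] of initial-category predictions.
#' @param metric Oriented metric name (default `"gdt_ts"`).
#' @return A tibble with `target_id`, `start`, `best_initial`,
#'   `best_refined`, `refined_better`.
#' @export
best_vs_start <- function(table, start_rows, initial_rows,
                          metric = "gdt_ts") {
  if (is.null(table) || is.null(initial_rows)) stop("missing metric tables")
  orient <- metric_orientations()[metric]
  best_of <- function(tab) {
    tab[tab$model_index == 1, , drop = FALSE] |>
      dplyr::group_by(.data$target_id) |>
      dplyr::summarise(
        best = if (orient > 0) max(.data[[metric]], na.rm = TRUE)
               else min(.data[[metric]], na.rm = TRUE),
        .groups = "drop"
      )
  }
  refined <- best_of(table)
  initial <- best_of(initial_rows)
  out <- start_rows[, c("target_id", metric)]
  names(out)[2] <- "start"
  out <- out |>
    dplyr::inner_join(dplyr::rename(initial, best_initial = "best"),
                      by = "target_id") |>
    dplyr::inner_join(dplyr::rename(refined, best_refined = "best"),
                      by = "target_id")
  out$refined_better <- orient * out$best_refined > orient * out$best_initial
  out
}
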