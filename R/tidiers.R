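#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group ranking
#'
#' @param x A `ranking_result` from [rank_groups()] or [naive_baseline()].
#' @param ... Unused.
#' @return One row per group: `group_id`, `total`, `rank`, `n_targets`,
#'   and `beats_baseline` when a baseline was computed.
#' @export
tidy.ranking_result <- function(x, ...) {
  x$groups
}

#' @rdname tidy.ranking_result
#' @return For `glance()`: a one-row tibble with group/target counts, the
#'   aggregation mode, and the baseline total and number of groups above
#'   it (NA without a baseline).
#' @export
glance.ranking_result <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    n_targets = dplyr::n_distinct(x$scores$target_id),
    mode = x$mode,
    baseline_total = if (is.null(x$baseline)) NA_real_ else x$baseline$total,
    n_above_baseline = if (is.null(x$baseline)) NA_integer_
                       else x$baseline$n_better
  )
}

#' Tidy target-table statistics
#'
#' @param x A `target_table_stats` from [target_table_stats()].
#' @param ... Unused.
#' @return A one-row tibble of the descriptive statistics.
#' @export
tidy.target_table_stats <- function(x, ...) {
  counts <- stats::setNames(x$category_counts$n,
                            paste0("n_", gsub("[-/]", "_",
                                              tolower(x$category_counts$category))))
  dplyr::bind_cols(
    tibble::tibble(
      n_targets = x$n_targets,
      start_gdt_ha_min = x$start_gdt_ha$min,
      start_gdt_ha_max = x$start_gdt_ha$max,
      start_gdt_ha_mean = x$start_gdt_ha$mean,
      start_gdt_ha_median = x$start_gdt_ha$median,
      start_gdt_ha_sd = x$start_gdt_ha$sd,
      nres_min = x$nres$min,
      nres_max = x$nres$max
    ),
    tibble::as_tibble(as.list(counts))
  )
}

#' Tidy a GDT result
#'
#' @param x A `gdt_result` from [gdt()].
#' @param ... Unused.
#' @return The per-cutoff tibble of maximal fractions.
#' @export
tidy.gdt_result <- function(x, ...) {
  x$per_cutoff
}
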