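make_table <- function(values, metric = "gdt_ha", target = "T1") {
  metric_table(tibble::tibble(
    target_id = target,
    group_id = sprintf("G%02d", seq_along(values)),
    model_index = 1L,
    "{metric}" := values
  ))
}

test_that("z-scores honour pool symmetry and degenerate pools", {
  z <- casp_zscores(make_table(c(10, 20)), "gdt_ha")
  expect_equal(z$z_gdt_ha, c(-1, 1))

  z0 <- casp_zscores(make_table(c(5, 5, 5, 5)), "gdt_ha")
  expect_equal(z0$z_gdt_ha, rep(0, 4))

  expect_error(casp_zscores(make_table(7), "gdt_ha"), "fewer than 2")
})

test_that("two-pass z with outlier rejection matches the spreadsheet oracle", {
  # fixed pool: seven ordinary values and one gross outlier; expected values
  # frozen from a literal two-pass computation (population SD, drop z < -2,
  # recompute, floor at -2)
  v <- c(10, 12, 11, 13, 9, 11, 12, -40)
  z <- casp_zscores(make_table(v), "gdt_ha")
  expect_equal(z$z_gdt_ha,
               c(-0.9176629355, 0.6882472016, -0.1147078669, 1.4912022702,
                 -1.7206180040, -0.1147078669, 0.6882472016, -2),
               tolerance = 1e-9)
})

test_that("orientation flips lower-is-better metrics", {
  z <- casp_zscores(make_table(c(1, 3), metric = "rms_ca"), "rms_ca")
  expect_equal(z$z_rms_ca, c(1, -1))  # smaller RMSD scores higher
  zmp <- casp_zscores(make_table(c(1, 3), metric = "mp"), "mp")
  expect_equal(zmp$z_mp, c(1, -1))
})

test_that("pre-floor pool z-scores have mean 0 and unit population SD", {
  set.seed(5)
  v <- runif(12, 40, 60)  # tight pool: no outlier pass, no flooring
  z <- casp_zscores(make_table(v), "gdt_ha")$z_gdt_ha
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
})

test_that("composite presets reproduce printed coefficients and sum to one", {
  expect_equal(composite_score(
    c(rms_ca = 1, gdt_ha = 0, sg = 0, qcs = 0, mp = 0), "casp12"), 0.46)
  expect_equal(composite_score(
    c(gdt_ha = 1, lddt = 0, cadaa = 0, sg = 0, ase = 1), "tbm"), 2 / 3)
  for (p in c("casp12", "tbm", "tbm_prime")) {
    w <- ranking_weights(p)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
    unit <- stats::setNames(rep(1, length(w)), names(w))
    expect_equal(composite_score(unit, p), 1)
  }
})

test_that("composite_score is linear in z", {
  set.seed(8)
  w <- ranking_weights("casp12")
  nm <- names(w)
  z1 <- stats::setNames(rnorm(5), nm)
  z2 <- stats::setNames(rnorm(5), nm)
  for (alpha in c(0, 0.3, 0.7, 1)) {
    expect_equal(composite_score(alpha * z1 + (1 - alpha) * z2, w),
                 alpha * composite_score(z1, w) +
                   (1 - alpha) * composite_score(z2, w),
                 tolerance = 1e-12)
  }
})

test_that("missing components error strictly and renormalise on request", {
  z <- c(rms_ca = 1, gdt_ha = 1, sg = 1, qcs = NA_real_, mp = 1)
  expect_error(composite_score(z, "casp12"), "missing")
  expect_equal(composite_score(z, "casp12", missing = "renormalize"), 1)
})

test_that("rank_groups orders by summed positive z with lexicographic ties", {
  tab <- make_table(c(30, 50, 70))
  r <- rank_groups(tab, weights = c(gdt_ha = 1))
  expect_equal(r$groups$group_id, c("G03", "G01", "G02"))
  expect_equal(r$groups$rank, 1:3)
  expect_equal(r$groups$total[1], (70 - 50) / sqrt(mean((c(30, 50, 70) - 50)^2)),
               tolerance = 1e-9)
  # G01 and G02 totals are both clamped to 0; tie broken by id
  expect_equal(r$groups$total[2:3], c(0, 0))
})

test_that("a group dominant on every metric and target ranks first", {
  grid <- expand.grid(target_id = c("T1", "T2"),
                      group_id = c("GA", "GB", "GC"),
                      stringsAsFactors = FALSE)
  grid$model_index <- 1L
  base <- match(grid$group_id, c("GA", "GB", "GC"))
  tab <- metric_table(tibble::tibble(
    grid,
    rms_ca = c(3, 2, 1)[base],   # GC best (lowest)
    gdt_ha = c(40, 50, 60)[base],
    sg = c(50, 60, 70)[base],
    qcs = c(50, 60, 70)[base],
    mp = c(3, 2.5, 2)[base]      # GC best (lowest)
  ))
  r <- rank_groups(tab, "casp12")
  expect_equal(r$groups$group_id[1], "GC")
})

test_that("all-negative per-target scores clamp to a zero total", {
  tab <- make_table(c(10, 50, 60, 70))
  r <- rank_groups(tab, weights = c(gdt_ha = 1))
  expect_equal(r$groups$total[r$groups$group_id == "G01"], 0)
})

test_that("naive baseline z-scores the start against prediction pools", {
  vals <- c(40, 45, 50, 55, 60, 65, 70, 75, 80, 85)
  tab <- make_table(vals)
  start <- tibble::tibble(target_id = "T1", gdt_ha = 72)
  r <- naive_baseline(tab, start, weights = c(gdt_ha = 1))
  m <- mean(vals); s <- sqrt(mean((vals - m)^2))
  expect_equal(r$baseline$total, (72 - m) / s, tolerance = 1e-9)
  # exactly the three groups above 72 beat the baseline
  expect_equal(r$baseline$n_better, 3)
  expect_equal(sort(r$groups$group_id[r$groups$beats_baseline]),
               c("G08", "G09", "G10"))
})

test_that("a start model worse than every submission lands at the z floor", {
  tab <- make_table(c(50, 55, 60, 65))
  start <- tibble::tibble(target_id = "T1", gdt_ha = 5)
  r <- naive_baseline(tab, start, weights = c(gdt_ha = 1))
  expect_equal(r$baseline$scores$score, -2)
  expect_equal(r$baseline$total, 0)  # sum of positives clamps it
})

test_that("baseline shifts only through pool statistics when a group is duplicated", {
  vals <- c(40, 50, 60)
  tab <- make_table(vals)
  start <- tibble::tibble(target_id = "T1", gdt_ha = 55)
  dup <- metric_table(dplyr::bind_rows(
    tab, dplyr::mutate(tab[3, ], group_id = "G99")))
  r1 <- naive_baseline(tab, start, weights = c(gdt_ha = 1))
  r2 <- naive_baseline(dup, start, weights = c(gdt_ha = 1))
  pool2 <- c(vals, 60)
  expected2 <- (55 - mean(pool2)) / sqrt(mean((pool2 - mean(pool2))^2))
  expect_equal(r2$baseline$total, max(expected2, 0), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(r1$baseline$total, r2$baseline$total)))
})

test_that("all groups resubmitting the start is fully degenerate", {
  grid <- expand.grid(target_id = c("T1", "T2"), group_id = c("GA", "GB"),
                      stringsAsFactors = FALSE)
  grid$model_index <- 1L
  tab <- metric_table(tibble::tibble(grid, gdt_ha = 47))
  start <- tibble::tibble(target_id = c("T1", "T2"), gdt_ha = 47)
  r <- naive_baseline(tab, start, weights = c(gdt_ha = 1))
  expect_true(all(r$groups$total == 0))
  expect_equal(r$baseline$total, 0)
  fi <- fraction_improved(tab, start, score_spec = "gdt_ha")
  expect_true(all(fi$fraction_improved == 0))  # ties never count as improved
})

test_that("fraction_improved counts strict per-target wins", {
  tab <- metric_table(tibble::tibble(
    target_id = paste0("T", 1:4), group_id = "GX", model_index = 1L,
    gdt_ha = c(50, 60, 70, 80)))
  start <- tibble::tibble(target_id = paste0("T", 1:4), gdt_ha = 55)
  fi <- fraction_improved(tab, start, score_spec = "gdt_ha")
  expect_equal(fi$fraction_improved, 0.75)

  # 5-group random table vs direct boolean enumeration
  set.seed(12)
  grid <- expand.grid(target_id = paste0("T", 1:3),
                      group_id = paste0("G", 1:5), stringsAsFactors = FALSE)
  grid$model_index <- 1L
  tab5 <- metric_table(tibble::tibble(grid, rms_ca = runif(15, 1, 6)))
  start5 <- tibble::tibble(target_id = paste0("T", 1:3), rms_ca = runif(3, 1, 6))
  fi5 <- fraction_improved(tab5, start5, score_spec = "rms_ca")
  for (g in unique(tab5$group_id)) {
    manual <- mean(vapply(start5$target_id, function(t) {
      tab5$rms_ca[tab5$group_id == g & tab5$target_id == t] <
        start5$rms_ca[start5$target_id == t]  # lower-better orientation
    }, logical(1)))
    expect_equal(fi5$fraction_improved[fi5$group_id == g], manual)
  }
})

test_that("best_vs_start reports per-target triples and exception flags", {
  refined <- metric_table(tibble::tibble(
    target_id = rep(paste0("T", 1:4), each = 2),
    group_id = rep(c("R1", "R2"), 4), model_index = 1L,
    gdt_ts = c(60, 65, 55, 58, 70, 72, 40, 45)))
  initial <- metric_table(tibble::tibble(
    target_id = rep(paste0("T", 1:4), each = 2),
    group_id = rep(c("S1", "S2"), 4), model_index = 1L,
    gdt_ts = c(62, 59, 50, 52, 75, 71, 44, 41)))
  start <- tibble::tibble(target_id = paste0("T", 1:4),
                          gdt_ts = c(55, 48, 68, 38))
  bv <- best_vs_start(refined, start, initial)
  expect_equal(bv$best_refined, c(65, 58, 72, 45))
  expect_equal(bv$best_initial, c(62, 52, 75, 44))
  expect_equal(bv$refined_better, c(TRUE, TRUE, FALSE, TRUE))

  # refined table identical to initial: never better
  bv2 <- best_vs_start(initial, start, initial)
  expect_false(any(bv2$refined_better))
})

test_that("dropping ASE (TBM -> TBM') preserves order among estimate-free groups", {
  tab <- metric_table(tibble::tibble(
    target_id = "T1",
    group_id = c("GA", "GB", "GC", "GD"),
    model_index = 1L,
    gdt_ha = c(60, 55, 58, 50),
    lddt = c(0.7, 0.65, 0.68, 0.6),
    cadaa = c(55, 50, 53, 45),
    sg = c(70, 65, 68, 60),
    ase = c(80, 75, NA, NA)  # GC and GD provided no error estimates
  ))
  r_tbm <- rank_groups(tab, "tbm", missing = "pool_min")
  r_tbmp <- rank_groups(tab, "tbm_prime")
  pos <- function(r, g) which(r$groups$group_id == g)
  expect_equal(pos(r_tbm, "GC") < pos(r_tbm, "GD"),
               pos(r_tbmp, "GC") < pos(r_tbmp, "GD"))
  # estimate-free groups score at the pool bottom on the ASE component
  zt <- add_zscores(tab, "ase")
  expect_true(all(is.na(zt$z_ase[3:4])))
})

test_that("metric tables round-trip through CSV", {
  tab <- make_table(c(10, 20, 30))
  path <- tempfile(fileext = ".csv")
  write_metric_table(tab, path)
  back <- read_metric_table(path)
  expect_equal(back$gdt_ha, tab$gdt_ha)
  expect_s3_class(back, "metric_table")
  expect_error(metric_table(tibble::tibble(target_id = "T", group_id = "G")),
               "model_index")
})

test_that("ranking results tidy and glance", {
  tab <- make_table(c(30, 50, 70))
  start <- tibble::tibble(target_id = "T1", gdt_ha = 55)
  r <- naive_baseline(tab, start, weights = c(gdt_ha = 1))
  td <- tidy(r)
  expect_equal(nrow(td), 3)
  gl <- glance(r)
  expect_equal(gl$n_groups, 3)
  expect_false(is.na(gl$baseline_total))
})

test_that("renormalize also covers metric columns absent from the table", {
  tab <- metric_table(tibble::tibble(
    target_id = "T1", group_id = c("GA", "GB", "GC"), model_index = 1L,
    gdt_ha = c(40, 50, 60), lddt = c(0.5, 0.6, 0.7), sg = c(55, 60, 65)))
  expect_error(rank_groups(tab, "tbm_prime"), "lacks metric column")
  r <- rank_groups(tab, "tbm_prime", missing = "renormalize")
  expect_equal(r$groups$group_id[1], "GC")
  # equivalent to the same preset with cadaa's weight spread pro rata
  w <- c(gdt_ha = 1 / 2, lddt = 1 / 6, sg = 1 / 6)
  r2 <- rank_groups(tab, w / sum(w))
  expect_equal(r$groups$total, r2$groups$total, tolerance = 1e-12)
})
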