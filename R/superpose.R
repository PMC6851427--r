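#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of point set `a` onto point set `b`. Reflections are
#' excluded, so the returned rotation always has determinant +1.
#'
#' @param a,b Numeric n x 3 coordinate matrices (n >= 3), rows paired.
#' @param weights Optional non-negative weights of length n.
#' @return A `superposition` list with `rotation` (3 x 3), `translation`
#'   (length 3; the fit maps `x` to `x %*% rotation + translation`), and
#'   `rmsd` over the fitted points.
#' @export
kabsch <- function(a, b, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || ncol(a) != 3) {
    stop("a and b must be matched n x 3 coordinate matrices")
  }
  n <- nrow(a)
  if (n < 3) stop("need at least 3 points for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative, length n, not all zero")
  }
  w <- w / sum(w)
  ca <- colSums(a * w); cb <- colSums(b * w)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12)) {
    warning("degenerate (collinear) point set; superposition is best-effort")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- as.numeric(cb - ca %*% R)
  fitted <- A %*% R - B
  rmsd <- sqrt(sum(w * rowSums(fitted^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords n x 3 coordinate matrix.
#' @param sup A `superposition` from [kabsch()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  coords <- as.matrix(coords)
  sweep(coords %*% sup$rotation, 2, sup$translation, "+")
}

# paired CA coordinate matrices for model/target under an alignment map
paired_ca_coords <- function(model, target, map) {
  map <- map[map$has_ca, , drop = FALSE]
  key <- residue_key(map$resno, map$ins)
  get_ca <- function(s) {
    ca <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
    ca <- ca[match(key, residue_key(ca$resno, ca$ins)), , drop = FALSE]
    as.matrix(ca[, c("x", "y", "z")])
  }
  list(model = get_ca(model), target = get_ca(target),
       resno = map$resno, ins = map$ins)
}

#' Sequence-dependent Ca RMSD
#'
#' RMSD over paired Ca atoms after a least-squares fit on all of them —
#' the sequence-dependent RMS_CA used as a refinement metric (residues
#' are paired by author numbering, never by structural alignment search).
#'
#' @param model,target `structure_model` objects.
#' @param map Optional `alignment_map`; computed with
#'   [pair_by_residue_number()] if omitted.
#' @param spec Optional residue-range restriction used when `map` is omitted.
#' @return RMSD in Angstroms (lower is better).
#' @export
rms_ca <- function(model, target, map = NULL, spec = NULL) {
  if (is.null(map)) map <- pair_by_residue_number(model, target, spec)
  pc <- paired_ca_coords(model, target, map)
  if (nrow(pc$model) < 3) stop("fewer than 3 paired Ca atoms")
  kabsch(pc$model, pc$target)$rmsd
}

#' Per-residue Ca deviations under the RMS_CA superposition
#'
#' Deviations of each paired Ca from its target position after the global
#' all-Ca least-squares fit; these are the "actual deviations" against
#' which predicted coordinate errors are judged in ASE scoring.
#'
#' @inheritParams rms_ca
#' @return A tibble with `resno`, `ins`, `deviation` (Angstroms).
#' @export
ca_deviations <- function(model, target, map = NULL, spec = NULL) {
  if (is.null(map)) map <- pair_by_residue_number(model, target, spec)
  pc <- paired_ca_coords(model, target, map)
  if (nrow(pc$model) < 3) stop("fewer than 3 paired Ca atoms")
  sup <- kabsch(pc$model, pc$target)
  moved <- apply_superposition(pc$model, sup)
  tibble::tibble(
    resno = pc$resno, ins = pc$ins,
    deviation = sqrt(rowSums((moved - pc$target)^2))
  )
}

#' GDT search configuration
#'
#' @param cutoffs_ts Distance cutoffs (Angstroms) averaged for GDT_TS.
#' @param cutoffs_ha Cutoffs for the high-accuracy GDT_HA variant.
#' @param seed_window_sizes Contiguous window lengths used to seed the
#'   superposition search; the global fit is always included as a seed.
#' @param max_refit_iterations Cap on iterative refitting per seed.
#' @return A `gdt_config` list.
#' @export
gdt_config <- function(cutoffs_ts = c(1, 2, 4, 8),
                       cutoffs_ha = c(0.5, 1, 2, 4),
                       seed_window_sizes = c(3, 5, 7),
                       max_refit_iterations = 10) {
  stopifnot(all(cutoffs_ts > 0), !is.unsorted(cutoffs_ts),
            all(cutoffs_ha > 0), !is.unsorted(cutoffs_ha),
            all(seed_window_sizes >= 3), max_refit_iterations >= 1)
  structure(list(cutoffs_ts = cutoffs_ts, cutoffs_ha = cutoffs_ha,
                 seed_window_sizes = seed_window_sizes,
                 max_refit_iterations = max_refit_iterations),
            class = "gdt_config")
}

# max fraction of paired CAs within `cutoff` over seeded iterative refits
gdt_one_cutoff <- function(A, B, cutoff, seeds, max_iter) {
  n <- nrow(A)
  best <- 0
  for (seed in seeds) {
    idx <- seed
    seen <- character(0)
    for (it in seq_len(max_iter)) {
      sup <- kabsch(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
      d <- sqrt(rowSums((apply_superposition(A, sup) - B)^2))
      within <- which(d <= cutoff)
      best <- max(best, length(within) / n)
      key <- paste(within, collapse = ",")
      if (length(within) < 3 || key %in% seen) break
      seen <- c(seen, key)
      idx <- within
    }
  }
  best
}

#' Global distance test scores (GDT_TS and GDT_HA)
#'
#' Deterministic seed-and-refine approximation to the LGA-style GDT search:
#' superpositions are seeded from every contiguous Ca window of the
#' configured sizes plus the global fit; each seed is iteratively refit on
#' the residues currently within the cutoff until the subset stabilises.
#' For each cutoff the maximum fraction of paired residues within the
#' cutoff over all seeds is recorded; GDT_TS/GDT_HA are 100 times the mean
#' fraction over their cutoff sets. Absolute values can differ from LGA by
#' a small margin, but the search is fully deterministic.
#'
#' @inheritParams rms_ca
#' @param config A [gdt_config()].
#' @return A `gdt_result` list with `gdt_ts`, `gdt_ha` (0-100) and
#'   `per_cutoff`, a tibble of cutoff and maximal fraction.
#' @export
gdt <- function(model, target, map = NULL, spec = NULL, config = gdt_config()) {
  if (is.null(map)) map <- pair_by_residue_number(model, target, spec)
  pc <- paired_ca_coords(model, target, map)
  A <- pc$model; B <- pc$target
  n <- nrow(A)
  if (n < 3) stop("fewer than 3 paired Ca atoms")
  seeds <- list(seq_len(n))
  for (w in config$seed_window_sizes) {
    if (w > n) next
    for (s in seq_len(n - w + 1)) seeds[[length(seeds) + 1]] <- s:(s + w - 1)
  }
  cutoffs <- sort(unique(c(config$cutoffs_ts, config$cutoffs_ha)))
  frac <- vapply(cutoffs, function(cut) {
    gdt_one_cutoff(A, B, cut, seeds, config$max_refit_iterations)
  }, numeric(1))
  names(frac) <- as.character(cutoffs)
  ts <- 100 * mean(frac[as.character(config$cutoffs_ts)])
  ha <- 100 * mean(frac[as.character(config$cutoffs_ha)])
  structure(
    list(gdt_ts = ts, gdt_ha = ha,
         per_cutoff = tibble::tibble(cutoff = cutoffs, fraction = unname(frac))),
    class = "gdt_result"
  )
}

#' @export
print.gdt_result <- function(x, ...) {
  cat(sprintf("GDT_TS %.2f  GDT_HA %.2f\n", x$gdt_ts, x$gdt_ha))
  invisible(x)
}
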