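#' lDDT configuration
#'
#' @param inclusion_radius Target-distance radius (Angstroms) defining which
#'   atom pairs enter the score; must exceed the largest threshold.
#' @param thresholds Distance-difference thresholds (Angstroms).
#' @param min_sequence_separation Minimum residue-index separation between
#'   the two atoms of a pair; the default 1 excludes intra-residue pairs.
#' @return An `lddt_config` list.
#' @export
lddt_config <- function(inclusion_radius = 15,
                        thresholds = c(0.5, 1, 2, 4),
                        min_sequence_separation = 1) {
  stopifnot(inclusion_radius > max(thresholds),
            all(thresholds > 0), min_sequence_separation >= 1)
  structure(list(inclusion_radius = inclusion_radius,
                 thresholds = thresholds,
                 min_sequence_separation = min_sequence_separation),
            class = "lddt_config")
}

# atoms of paired residues present (same residue key + atom label) in both
common_atoms <- function(model, target, map) {
  keys <- residue_key(map$resno, map$ins)
  tm <- target$atoms[residue_key(target$atoms$resno, target$atoms$ins) %in% keys, ]
  mm <- model$atoms[residue_key(model$atoms$resno, model$atoms$ins) %in% keys, ]
  tkey <- paste(residue_key(tm$resno, tm$ins), tm$atom)
  mkey <- paste(residue_key(mm$resno, mm$ins), mm$atom)
  shared <- intersect(tkey, mkey)
  tm <- tm[match(shared, tkey), , drop = FALSE]
  mm <- mm[match(shared, mkey), , drop = FALSE]
  list(target = tm, model = mm,
       n_excluded = length(union(tkey, mkey)) - length(shared))
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free agreement of inter-atomic distance maps: over all
#' target atom pairs within the inclusion radius, on different residues,
#' with both atoms present in the model, the fraction of pairs whose
#' model distance matches the target distance within each threshold is
#' averaged over thresholds. Stereochemistry-unaware and symmetry-naive
#' for side-chain label ambiguity (atoms are matched by label).
#'
#' @inheritParams rms_ca
#' @param config An [lddt_config()].
#' @return Score in \[0, 1\] (higher is better).
#' @export
lddt <- function(model, target, map = NULL, spec = NULL,
                 config = lddt_config()) {
  if (is.null(map)) map <- pair_by_residue_number(model, target, spec)
  ca <- common_atoms(model, target, map)
  if (nrow(ca$target) < 2) stop("no shared atoms for lDDT")
  Tc <- as.matrix(ca$target[, c("x", "y", "z")])
  Mc <- as.matrix(ca$model[, c("x", "y", "z")])
  rid <- match(residue_key(ca$target$resno, ca$target$ins),
               unique(residue_key(ca$target$resno, ca$target$ins)))
  dt <- as.matrix(stats::dist(Tc))
  dm <- as.matrix(stats::dist(Mc))
  sep <- abs(outer(rid, rid, "-"))
  use <- upper.tri(dt) & dt <= config$inclusion_radius &
    sep >= config$min_sequence_separation
  if (!any(use)) stop("no qualifying atom pairs within the inclusion radius")
  dd <- abs(dm[use] - dt[use])
  mean(vapply(config$thresholds, function(t) mean(dd < t), numeric(1)))
}

#' SphereGrinder configuration
#'
#' @param sphere_radius Radius (Angstroms) of the sphere around each
#'   residue's Ca defining its local environment.
#' @param rmsd_cutoffs Local all-atom RMSD cutoffs (Angstroms) averaged
#'   into the score.
#' @return A `sphere_grinder_config` list.
#' @export
sphere_grinder_config <- function(sphere_radius = 6, rmsd_cutoffs = c(2, 4)) {
  stopifnot(sphere_radius > 0, all(rmsd_cutoffs > 0),
            !is.unsorted(rmsd_cutoffs))
  structure(list(sphere_radius = sphere_radius, rmsd_cutoffs = rmsd_cutoffs),
            class = "sphere_grinder_config")
}

#' SphereGrinder local-environment score
#'
#' For each paired residue, the target atoms within `sphere_radius` of its
#' Ca (plus the residue's own atoms) are superposed independently onto
#' the corresponding model atoms and the all-atom RMSD recorded; the score
#' is the mean over the RMSD cutoffs of the percentage of residues whose
#' sphere RMSD falls below the cutoff. Residue spheres with fewer than 3
#' atoms shared between model and target are skipped with a warning.
#'
#' @inheritParams rms_ca
#' @param config A [sphere_grinder_config()].
#' @return Score in \[0, 100\] (higher is better).
#' @export
sphere_grinder <- function(model, target, map = NULL, spec = NULL,
                           config = sphere_grinder_config()) {
  if (is.null(map)) map <- pair_by_residue_number(model, target, spec)
  ca <- common_atoms(model, target, map)
  Tc <- as.matrix(ca$target[, c("x", "y", "z")])
  Mc <- as.matrix(ca$model[, c("x", "y", "z")])
  tkey <- residue_key(ca$target$resno, ca$target$ins)
  centres <- map[map$has_ca, , drop = FALSE]
  n_skipped <- 0
  rmsds <- rep(NA_real_, nrow(centres))
  for (i in seq_len(nrow(centres))) {
    key <- residue_key(centres$resno[i], centres$ins[i])
    ca_row <- which(tkey == key & ca$target$atom == "CA")
    if (length(ca_row) != 1) { n_skipped <- n_skipped + 1; next }
    d <- sqrt(colSums((t(Tc) - Tc[ca_row, ])^2))
    sel <- which(d <= config$sphere_radius | tkey == key)
    if (length(sel) < 3) { n_skipped <- n_skipped + 1; next }
    rmsds[i] <- kabsch(Mc[sel, , drop = FALSE], Tc[sel, , drop = FALSE])$rmsd
  }
  if (n_skipped > 0) {
    warning(n_skipped, " residue sphere(s) skipped (fewer than 3 shared atoms)")
  }
  rmsds <- rmsds[!is.na(rmsds)]
  if (length(rmsds) == 0) stop("no scorable residue spheres")
  mean(vapply(config$rmsd_cutoffs,
              function(cut) 100 * mean(rmsds < cut), numeric(1)))
}

#' ASE configuration
#'
#' @param d0 Scale (Angstroms) of the sigmoid `S(d) = 1 / (1 + (d/d0)^2)`
#'   mapping deviations and error estimates to \[0, 1\].
#' @return An `ase_config` list.
#' @export
ase_config <- function(d0 = 5) {
  stopifnot(d0 > 0)
  structure(list(d0 = d0), class = "ase_config")
}

#' Accuracy self-estimate (ASE) score
#'
#' Judges not the model but the modeller's per-residue error estimates:
#' with `S(d) = 1 / (1 + (d/d0)^2)`,
#' `ASE = 100 * (1 - mean(|S(e_i) - S(d_i)|))` over paired residues, where
#' `e_i` is the predicted Ca coordinate error and `d_i` the actual Ca
#' deviation under the global RMS_CA superposition. Perfect self-assessment
#' scores 100.
#'
#' @param predicted_errors Per-residue predicted errors (Angstroms).
#' @param actual_deviations Per-residue actual Ca deviations (Angstroms),
#'   e.g. from [ca_deviations()].
#' @param config An [ase_config()].
#' @return Score in \[0, 100\].
#' @export
ase <- function(predicted_errors, actual_deviations, config = ase_config()) {
  e <- as.numeric(predicted_errors); d <- as.numeric(actual_deviations)
  if (length(e) != length(d) || length(e) == 0) {
    stop("predicted and actual vectors must be matched and non-empty")
  }
  if (any(!is.finite(e)) || any(e < 0)) stop("predicted errors must be finite and non-negative")
  s <- function(x) 1 / (1 + (x / config$d0)^2)
  100 * (1 - mean(abs(s(e) - s(d))))
}

#' Usability of a submission's coordinate-error estimates
#'
#' Submissions are expected to carry predicted per-residue coordinate error
#' in the B-factor column. Columns that are constant zero or constant one
#' are placeholder values, not estimates; such submissions are flagged
#' estimate-free and their ASE is undefined (excluded from ranking pools
#' rather than zero-filled).
#'
#' @param model A `structure_model`.
#' @return One of `"ok"`, `"constant_zero_or_one"`, or `"missing"`.
#' @export
error_estimate_status <- function(model) {
  b <- model$atoms$bcol[model$atoms$atom == "CA"]
  b <- b[!is.na(b)]
  if (length(b) == 0) return("missing")
  if (all(b == 0) || all(b == 1)) return("constant_zero_or_one")
  "ok"
}

#' ASE score computed directly from structures
#'
#' Extracts predicted errors from the model's Ca B-factor column and actual
#' deviations from the RMS_CA superposition; returns `NA` (with the flag as
#' an attribute) when the submission carries no usable error estimates.
#'
#' @inheritParams rms_ca
#' @param config An [ase_config()].
#' @return ASE score in \[0, 100\], or `NA` for estimate-free submissions.
#' @export
ase_from_structures <- function(model, target, map = NULL, spec = NULL,
                                config = ase_config()) {
  status <- error_estimate_status(model)
  if (status != "ok") {
    out <- NA_real_
    attr(out, "status") <- status
    return(out)
  }
  if (is.null(map)) map <- pair_by_residue_number(model, target, spec)
  dev <- ca_deviations(model, target, map)
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  pred <- ca$bcol[match(residue_key(dev$resno, dev$ins),
                        residue_key(ca$resno, ca$ins))]
  ase(pred, dev$deviation, config)
}
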