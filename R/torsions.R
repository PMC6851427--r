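#' Torsion scoring configuration
#'
#' @param region_threshold Degrees; residues whose mean backbone torsion
#'   difference between start model and target is below this are "good"
#'   (default 30).
#' @param backbone_weight,sidechain_weight Non-negative weights (sum 1) of
#'   the backbone and side-chain terms in the composite torsion score.
#' @param include_omega Include the peptide-bond torsion omega in the
#'   per-residue backbone error (default FALSE: phi/psi only).
#' @return A `torsion_config` list.
#' @export
torsion_config <- function(region_threshold = 30,
                           backbone_weight = 0.5,
                           sidechain_weight = 0.5,
                           include_omega = FALSE) {
  stopifnot(region_threshold > 0,
            backbone_weight >= 0, sidechain_weight >= 0)
  if (abs(backbone_weight + sidechain_weight - 1) > 1e-9) {
    stop("backbone_weight and sidechain_weight must sum to 1")
  }
  structure(list(region_threshold = region_threshold,
                 backbone_weight = backbone_weight,
                 sidechain_weight = sidechain_weight,
                 include_omega = include_omega),
            class = "torsion_config")
}

# side-chain chi-defining atom chains (after N, CA, CB) and the index of a
# terminal torsion with two-fold symmetry (0 = none). chi_k is defined by
# the quadruple ending at chain atom k.
chi_chains <- list(
  SER = list(atoms = "OG",                     sym = 0L),
  CYS = list(atoms = "SG",                     sym = 0L),
  THR = list(atoms = "OG1",                    sym = 0L),
  VAL = list(atoms = "CG1",                    sym = 0L),
  ILE = list(atoms = c("CG1", "CD1"),          sym = 0L),
  LEU = list(atoms = c("CG", "CD1"),           sym = 0L),
  ASP = list(atoms = c("CG", "OD1"),           sym = 2L),
  ASN = list(atoms = c("CG", "OD1"),           sym = 0L),
  GLU = list(atoms = c("CG", "CD", "OE1"),     sym = 3L),
  GLN = list(atoms = c("CG", "CD", "OE1"),     sym = 0L),
  MET = list(atoms = c("CG", "SD", "CE"),      sym = 0L),
  LYS = list(atoms = c("CG", "CD", "CE", "NZ"), sym = 0L),
  ARG = list(atoms = c("CG", "CD", "NE", "CZ"), sym = 0L),
  PHE = list(atoms = c("CG", "CD1"),           sym = 2L),
  TYR = list(atoms = c("CG", "CD1"),           sym = 2L),
  TRP = list(atoms = c("CG", "CD1"),           sym = 0L),
  HIS = list(atoms = c("CG", "ND1"),           sym = 0L),
  PRO = list(atoms = c("CG", "CD"),            sym = 0L)
)

chi_is_symmetric <- function(resname, k) {
  def <- chi_chains[[resname]]
  !is.null(def) && def$sym == k
}

#' Signed dihedral angle of four points
#'
#' Torsion about the p2-p3 axis in the IUPAC sign convention, in degrees
#' in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    stop("collinear points: dihedral undefined")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Smallest circular difference between two angles
#'
#' @param a,b Angles in degrees.
#' @return `min(|a - b|, 360 - |a - b|)`, in \[0, 180\]; vectorised.
#' @export
circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# circular difference folded for two-fold symmetric torsions: in [0, 90]
circular_diff_symmetric <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Extract backbone and side-chain torsions from a structure
#'
#' Computes phi/psi/omega from consecutive-residue backbone atoms (set to
#' `NA` at termini, where atoms are missing, or across chain breaks
#' detected by a C-N distance above 2.5 Angstroms) and chi1-chi4 from
#' standard side-chain atom quadruples. Two-fold symmetric terminal
#' torsions (Phe/Tyr chi2, Asp chi2, Glu chi3) are mapped to a
#' 180-degree-periodic representative in (-90, 90] so that chemically
#' indistinguishable labelings compare as identical.
#'
#' @param x A `structure_model`.
#' @return A `torsion_profile` tibble with columns `resno`, `ins`,
#'   `resname`, `phi`, `psi`, `omega`, `chi1`..`chi4` (degrees, `NA` where
#'   undefined).
#' @export
extract_torsions <- function(x) {
  stopifnot(inherits(x, "structure_model"))
  a <- x$atoms
  res <- dplyr::distinct(a, .data$resno, .data$ins, .data$resname)
  res <- dplyr::arrange(res, .data$resno, .data$ins)
  n <- nrow(res)
  coord <- function(i, name) {
    row <- a[a$resno == res$resno[i] & a$ins == res$ins[i] & a$atom == name, ]
    if (nrow(row) != 1) return(NULL)
    c(row$x, row$y, row$z)
  }
  safe_dihedral <- function(p1, p2, p3, p4) {
    if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) return(NA_real_)
    tryCatch(dihedral(p1, p2, p3, p4), error = function(e) NA_real_)
  }
  bonded <- function(i, j) {
    # peptide bond between residue i's C and residue j's N
    ci <- coord(i, "C"); nj <- coord(j, "N")
    !is.null(ci) && !is.null(nj) && sqrt(sum((ci - nj)^2)) <= 2.5
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  chis <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    Ni <- coord(i, "N"); CAi <- coord(i, "CA"); Ci <- coord(i, "C")
    if (i > 1 && bonded(i - 1, i)) {
      Cp <- coord(i - 1, "C"); CAp <- coord(i - 1, "CA")
      phi[i] <- safe_dihedral(Cp, Ni, CAi, Ci)
      omega[i] <- safe_dihedral(CAp, Cp, Ni, CAi)
    }
    if (i < n && bonded(i, i + 1)) {
      Nn <- coord(i + 1, "N")
      psi[i] <- safe_dihedral(Ni, CAi, Ci, Nn)
    }
    def <- chi_chains[[res$resname[i]]]
    if (!is.null(def)) {
      chain <- c("N", "CA", "CB", def$atoms)
      for (k in seq_along(def$atoms)) {
        quad <- lapply(chain[k:(k + 3)], function(nm) coord(i, nm))
        val <- safe_dihedral(quad[[1]], quad[[2]], quad[[3]], quad[[4]])
        if (!is.na(val) && def$sym == k) {
          val <- ((val + 90) %% 180) - 90
          if (val <= -90) val <- val + 180
        }
        chis[i, k] <- val
      }
    }
  }
  out <- tibble::tibble(
    resno = res$resno, ins = res$ins, resname = res$resname,
    phi = phi, psi = psi, omega = omega,
    chi1 = chis[, 1], chi2 = chis[, 2], chi3 = chis[, 3], chi4 = chis[, 4]
  )
  class(out) <- c("torsion_profile", class(out))
  out
}

# join two profiles on residue key
join_profiles <- function(pa, pb) {
  dplyr::inner_join(
    pa, pb, by = c("resno", "ins"), suffix = c("_a", "_b")
  )
}

#' Per-residue backbone torsion error between two profiles
#'
#' Mean circular difference over the backbone torsions (phi, psi; omega if
#' configured) defined in both profiles; `NA` where none is shared.
#'
#' @param profile_a,profile_b `torsion_profile` tibbles sharing residues.
#' @param config A [torsion_config()].
#' @return A tibble with `resno`, `ins`, `backbone_error` (degrees).
#' @export
backbone_errors <- function(profile_a, profile_b, config = torsion_config()) {
  j <- join_profiles(profile_a, profile_b)
  angles <- c("phi", "psi", if (config$include_omega) "omega")
  diffs <- sapply(angles, function(ang) {
    circular_diff(j[[paste0(ang, "_a")]], j[[paste0(ang, "_b")]])
  })
  diffs <- matrix(diffs, nrow = nrow(j))
  err <- rowMeans(diffs, na.rm = TRUE)
  err[!is.finite(err)] <- NA_real_
  tibble::tibble(resno = j$resno, ins = j$ins, backbone_error = err)
}

#' Backbone torsion error of one residue
#'
#' @inheritParams backbone_errors
#' @param resno,ins Residue key.
#' @return Degrees, or `NA` if no backbone torsion is defined in both.
#' @export
residue_backbone_error <- function(profile_a, profile_b, resno, ins = "",
                                   config = torsion_config()) {
  be <- backbone_errors(profile_a, profile_b, config)
  hit <- be[be$resno == resno & be$ins == ins, ]
  if (nrow(hit) == 0) return(NA_real_)
  hit$backbone_error[1]
}

# per-residue mean symmetry-corrected chi deviation; NA where no chi shared
sidechain_errors <- function(profile_a, profile_b) {
  j <- join_profiles(profile_a, profile_b)
  err <- rep(NA_real_, nrow(j))
  for (i in seq_len(nrow(j))) {
    resname <- j$resname_a[i]
    devs <- c()
    for (k in 1:4) {
      va <- j[[paste0("chi", k, "_a")]][i]
      vb <- j[[paste0("chi", k, "_b")]][i]
      if (is.na(va) || is.na(vb)) next
      d <- if (chi_is_symmetric(resname, k)) {
        circular_diff_symmetric(va, vb)
      } else {
        circular_diff(va, vb)
      }
      devs <- c(devs, d)
    }
    if (length(devs) > 0) err[i] <- mean(devs)
  }
  tibble::tibble(resno = j$resno, ins = j$ins, sidechain_error = err)
}

#' Classify residues into good/bad backbone regions
#'
#' A residue is "good" when the mean backbone torsion difference between
#' the starting model and the target is below the region threshold
#' (default 30 degrees), i.e. the start model already had essentially the
#' right local conformation there; the remainder is "bad". Residues whose
#' backbone error is undefined (termini, chain breaks) are `NA` and are
#' excluded from region summaries.
#'
#' @param start_profile,target_profile `torsion_profile` tibbles.
#' @param config A [torsion_config()].
#' @return A tibble with `resno`, `ins`, `region` (`"good"`/`"bad"`/`NA`).
#' @export
classify_regions <- function(start_profile, target_profile,
                             config = torsion_config()) {
  be <- backbone_errors(start_profile, target_profile, config)
  tibble::tibble(
    resno = be$resno, ins = be$ins,
    region = dplyr::case_when(
      is.na(be$backbone_error) ~ NA_character_,
      be$backbone_error < config$region_threshold ~ "good",
      TRUE ~ "bad"
    )
  )
}

#' Composite torsion-space score
#'
#' A weighted combination of the mean per-residue backbone torsion error
#' and the mean symmetry-corrected side-chain chi deviation between model
#' and target, negated so that identical conformations score 0 and any
#' degradation is negative (higher is better). When one component is
#' undefined (e.g. no shared chi angles in a backbone-only chain), the
#' weights are renormalised over the available component.
#'
#' @param model_profile,target_profile `torsion_profile` tibbles (or
#'   `structure_model`s, from which profiles are extracted).
#' @param config A [torsion_config()].
#' @return A one-row tibble with `score`, `backbone_term`,
#'   `sidechain_term` (degrees), and residue counts `n_backbone`,
#'   `n_sidechain`.
#' @export
s_torsion <- function(model_profile, target_profile,
                      config = torsion_config()) {
  if (inherits(model_profile, "structure_model")) {
    model_profile <- extract_torsions(model_profile)
  }
  if (inherits(target_profile, "structure_model")) {
    target_profile <- extract_torsions(target_profile)
  }
  bb <- backbone_errors(model_profile, target_profile, config)$backbone_error
  sc <- sidechain_errors(model_profile, target_profile)$sidechain_error
  nb <- sum(!is.na(bb)); ns <- sum(!is.na(sc))
  if (nb == 0 && ns == 0) stop("no shared torsions between the profiles")
  bterm <- if (nb > 0) mean(bb, na.rm = TRUE) else NA_real_
  sterm <- if (ns > 0) mean(sc, na.rm = TRUE) else NA_real_
  wb <- config$backbone_weight; ws <- config$sidechain_weight
  if (nb == 0) { wb <- 0 }
  if (ns == 0) { ws <- 0 }
  wsum <- wb + ws
  if (wsum == 0) stop("no weighted torsion component is available")
  score <- -(wb * ifelse(nb > 0, bterm, 0) +
               ws * ifelse(ns > 0, sterm, 0)) / wsum
  tibble::tibble(score = score, backbone_term = bterm, sidechain_term = sterm,
                 n_backbone = nb, n_sidechain = ns)
}

# per-region RMSD of Ca deviations after an all-Ca global fit
region_ca_rmsd <- function(model, ref, regions) {
  dev <- ca_deviations(model, ref)
  j <- dplyr::inner_join(dev, regions, by = c("resno", "ins"))
  j |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(ca_rmsd = sqrt(mean(.data$deviation^2)), .groups = "drop")
}

#' Good/bad-region torsion and Ca summaries
#'
#' Splits residues into good/bad regions by the start-vs-target backbone
#' criterion, then summarises, per region, (a) the change the model made
#' from the starting model and (b) the residual error versus the target:
#' mean backbone torsion deviation, mean side-chain chi deviation, and the
#' Ca RMSD computed after a least-squares alignment on all Ca atoms.
#'
#' @param start,model,target `structure_model` objects sharing residues.
#' @param config A [torsion_config()].
#' @return A `region_summary` tibble with columns `comparison`
#'   (`"change"` = model vs start, `"residual"` = model vs target),
#'   `region`, `backbone_deg`, `sidechain_deg`, `ca_rmsd`, `n_residues`.
#' @export
region_summaries <- function(start, model, target, config = torsion_config()) {
  ps <- extract_torsions(start)
  pm <- extract_torsions(model)
  pt <- extract_torsions(target)
  regions <- classify_regions(ps, pt, config)

  one_comparison <- function(ref_profile, ref_structure, label) {
    bb <- backbone_errors(pm, ref_profile, config)
    sc <- sidechain_errors(pm, ref_profile)
    j <- regions |>
      dplyr::left_join(bb, by = c("resno", "ins")) |>
      dplyr::left_join(sc, by = c("resno", "ins")) |>
      dplyr::filter(!is.na(.data$region))
    tors <- j |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        backbone_deg = mean(.data$backbone_error, na.rm = TRUE),
        sidechain_deg = mean(.data$sidechain_error, na.rm = TRUE),
        n_residues = dplyr::n(), .groups = "drop"
      )
    rms <- region_ca_rmsd(model, ref_structure, regions)
    out <- dplyr::left_join(tors, rms, by = "region")
    out$comparison <- label
    out
  }
  out <- dplyr::bind_rows(
    one_comparison(ps, start, "change"),
    one_comparison(pt, target, "residual")
  )
  out <- out[, c("comparison", "region", "backbone_deg", "sidechain_deg",
                 "ca_rmsd", "n_residues")]
  out$backbone_deg[is.nan(out$backbone_deg)] <- NA_real_
  out$sidechain_deg[is.nan(out$sidechain_deg)] <- NA_real_
  class(out) <- c("region_summary", class(out))
  out
}

#' Per-residue torsion comparison table
#'
#' Flat per-residue table suitable for CSV export: torsions of the model,
#' the good/bad region label from the start-vs-target classification, and
#' the model-vs-target backbone error.
#'
#' @param model,start,target `structure_model` objects.
#' @param config A [torsion_config()].
#' @return A tibble with residue keys, `phi`, `psi`, `omega`,
#'   `chi1`..`chi4`, `region`, `backbone_error`.
#' @export
torsion_table <- function(model, start, target, config = torsion_config()) {
  pm <- extract_torsions(model)
  regions <- classify_regions(extract_torsions(start),
                              extract_torsions(target), config)
  be <- backbone_errors(pm, extract_torsions(target), config)
  pm |>
    dplyr::left_join(regions, by = c("resno", "ins")) |>
    dplyr::left_join(be, by = c("resno", "ins"))
}
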