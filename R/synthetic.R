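# internal-to-Cartesian placement: position D given A, B, C with bond |CD|,
# angle B-C-D (degrees) and dihedral A-B-C-D (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

element_of <- function(atom) substr(gsub("[0-9]", "", atom), 1, 1)

#' Build an idealised polypeptide chain
#'
#' Constructs a single chain from ideal bond lengths and angles at the
#' requested backbone torsions (N, CA, C, O per residue; CB except for
#' Gly). With `sidechains = TRUE`, side-chain atoms along each residue's
#' chi-defining chain are added with idealised 1.52-Angstrom / 111-degree
#' geometry at the given chi angles — sufficient for torsion and
#' distance-map metrics, though not physically realistic rotamers. The
#' construction is deterministic.
#'
#' @param n_residues Chain length (>= 1).
#' @param phi,psi Backbone torsions in degrees, recycled along the chain
#'   (defaults build an alpha-helix).
#' @param sequence Amino-acid sequence: a 1-letter string or a vector of
#'   3-letter codes; recycled; default poly-alanine.
#' @param sidechains Build chi-chain side-chain atoms (default FALSE).
#' @param chi Side-chain torsions in degrees, recycled over chi slots
#'   (default 180, all-trans).
#' @param omega Peptide-bond torsion (default 180, trans).
#' @param model_id Identifier for the returned model.
#' @return A [structure_model()].
#' @export
make_ideal_chain <- function(n_residues, phi = -57, psi = -47,
                             sequence = "A", sidechains = FALSE,
                             chi = 180, omega = 180, model_id = "ideal") {
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  resnames <- if (all(nchar(sequence) == 1)) {
    unname(aa_three[rep(toupper(sequence), length.out = n_residues)])
  } else {
    rep(toupper(sequence), length.out = n_residues)
  }
  if (anyNA(resnames)) stop("unknown amino-acid code in sequence")
  phi <- rep(phi, length.out = n_residues)
  psi <- rep(psi, length.out = n_residues)
  # ideal backbone geometry (Engh-Huber-like)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8
  rows <- list()
  add <- function(resno, resname, atom, pos) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      resno = resno, ins = "", resname = resname, atom = atom,
      element = element_of(atom), x = pos[1], y = pos[2], z = pos[3],
      occ = 1, bcol = 0)
  }
  N <- c(0, 0, 0)
  CA <- c(b_n_ca, 0, 0)
  th <- (180 - a_n_ca_c) * pi / 180
  C <- CA + b_ca_c * c(cos(th), sin(th), 0)
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      N <- place_atom(prevN, prevCA, prevC, b_c_n, a_ca_c_n, psi[i - 1])
      CA <- place_atom(prevCA, prevC, N, b_n_ca, a_c_n_ca, omega)
      C <- place_atom(prevC, N, CA, b_ca_c, a_n_ca_c, phi[i])
    }
    add(i, resnames[i], "N", N)
    add(i, resnames[i], "CA", CA)
    add(i, resnames[i], "C", C)
    # carbonyl O in the peptide plane (trans to the next N)
    o_tor <- if (i < n_residues) psi[i] + 180 else 180
    add(i, resnames[i], "O", place_atom(N, CA, C, b_c_o, a_ca_c_o, o_tor))
    if (resnames[i] != "GLY") {
      CB <- place_atom(N, C, CA, 1.53, 110.6, 122.6)
      add(i, resnames[i], "CB", CB)
      def <- chi_chains[[resnames[i]]]
      if (sidechains && !is.null(def)) {
        chain_pos <- list(N, CA, CB)
        chi_i <- rep(chi, length.out = length(def$atoms))
        for (k in seq_along(def$atoms)) {
          pos <- place_atom(chain_pos[[k]], chain_pos[[k + 1]],
                            chain_pos[[k + 2]], 1.52, 111, chi_i[k])
          add(i, resnames[i], def$atoms[k], pos)
          chain_pos[[k + 3]] <- pos
        }
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  structure_model(dplyr::bind_rows(rows), model_id = model_id)
}

#' Specify a structural perturbation
#'
#' Perturbation kinds model the error modes seen in refinement targets:
#' `coordinate_noise` (i.i.d. Gaussian displacement of scale `sigma`),
#' `rigid_shift_element` (a secondary-structure element translated away
#' from its true position, as in mis-placed helices shifted 5-10
#' Angstroms), `register_shift` (a segment's numbering offset against its
#' spatial position), and `sidechain_scramble` (chi angles rebuilt from
#' seeded rotamer draws at fixed backbone).
#'
#' @param kind One of `"coordinate_noise"`, `"rigid_shift_element"`,
#'   `"register_shift"`, `"sidechain_scramble"`.
#' @param sigma Noise scale in Angstroms (`coordinate_noise`).
#' @param shift Length-3 translation vector (`rigid_shift_element`).
#' @param interval Inclusive residue interval `c(lo, hi)` the perturbation
#'   acts on (`rigid_shift_element`, `register_shift`).
#' @param offset Residue-number offset (`register_shift`).
#' @param seed Integer seed; mandatory for stochastic kinds.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(kind = c("coordinate_noise",
                                       "rigid_shift_element",
                                       "register_shift",
                                       "sidechain_scramble"),
                              sigma = NULL, shift = NULL, interval = NULL,
                              offset = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "coordinate_noise") {
    if (is.null(sigma) || sigma < 0) stop("coordinate_noise needs sigma >= 0")
    if (is.null(seed)) stop("stochastic perturbations need a seed")
  }
  if (kind == "rigid_shift_element") {
    if (is.null(shift) || length(shift) != 3) {
      stop("rigid_shift_element needs a length-3 shift vector")
    }
    if (is.null(interval)) stop("rigid_shift_element needs a residue interval")
  }
  if (kind == "register_shift") {
    if (is.null(offset) || offset == 0) stop("register_shift needs a non-zero offset")
    if (is.null(interval)) stop("register_shift needs a residue interval")
  }
  if (kind == "sidechain_scramble" && is.null(seed)) {
    stop("stochastic perturbations need a seed")
  }
  if (!is.null(interval) && (length(interval) != 2 || interval[1] > interval[2])) {
    stop("interval must be c(lo, hi) with lo <= hi")
  }
  structure(list(kind = kind, sigma = sigma, shift = shift,
                 interval = interval, offset = offset, seed = seed),
            class = "perturbation_spec")
}

#' Apply a perturbation to a structure
#'
#' @param x A [structure_model()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed `structure_model`.
#' @export
apply_perturbation <- function(x, spec) {
  stopifnot(inherits(x, "structure_model"), inherits(spec, "perturbation_spec"))
  a <- x$atoms
  if (!is.null(spec$interval)) {
    covered <- any(a$resno >= spec$interval[1] & a$resno <= spec$interval[2])
    if (!covered) stop("interval lies outside the structure")
  }
  if (spec$kind == "coordinate_noise") {
    a <- withr::with_seed(spec$seed, {
      n <- nrow(a)
      a$x <- a$x + stats::rnorm(n, 0, spec$sigma)
      a$y <- a$y + stats::rnorm(n, 0, spec$sigma)
      a$z <- a$z + stats::rnorm(n, 0, spec$sigma)
      a
    })
  } else if (spec$kind == "rigid_shift_element") {
    sel <- a$resno >= spec$interval[1] & a$resno <= spec$interval[2]
    a$x[sel] <- a$x[sel] + spec$shift[1]
    a$y[sel] <- a$y[sel] + spec$shift[2]
    a$z[sel] <- a$z[sel] + spec$shift[3]
  } else if (spec$kind == "register_shift") {
    lo <- spec$interval[1]; hi <- spec$interval[2]
    sel <- a$resno >= lo & a$resno <= hi
    new_no <- a$resno
    new_no[sel] <- a$resno[sel] + spec$offset
    # drop segment residues pushed onto existing numbers or outside the chain
    keep_range <- range(a$resno)
    clash <- sel & (new_no %in% a$resno[!sel] |
                      new_no < keep_range[1] | new_no > keep_range[2])
    a <- a[!clash, , drop = FALSE]
    a$resno <- new_no[!clash]
  } else if (spec$kind == "sidechain_scramble") {
    a <- withr::with_seed(spec$seed, {
      res <- dplyr::distinct(a, .data$resno, .data$ins, .data$resname)
      for (i in seq_len(nrow(res))) {
        def <- chi_chains[[res$resname[i]]]
        if (is.null(def)) next
        rsel <- a$resno == res$resno[i] & a$ins == res$ins[i]
        get <- function(nm) {
          row <- which(rsel & a$atom == nm)
          if (length(row) != 1) return(NULL)
          c(a$x[row], a$y[row], a$z[row])
        }
        chain_pos <- list(get("N"), get("CA"), get("CB"))
        if (any(vapply(chain_pos, is.null, logical(1)))) next
        for (k in seq_along(def$atoms)) {
          row <- which(rsel & a$atom == def$atoms[k])
          if (length(row) != 1) break
          chi_new <- sample(c(-60, 60, 180), 1)
          pos <- place_atom(chain_pos[[k]], chain_pos[[k + 1]],
                            chain_pos[[k + 2]], 1.52, 111, chi_new)
          a$x[row] <- pos[1]; a$y[row] <- pos[2]; a$z[row] <- pos[3]
          chain_pos[[k + 3]] <- pos
        }
      }
      a
    })
  }
  structure_model(a, model_id = x$model_id, chain_id = x$chain_id)
}

#' Specify a synthetic prediction scenario
#'
#' Emulates a refinement round with known ground truth: each target is an
#' idealised chain, its starting model a noisy copy, and each group's
#' model-1 submission moves toward or away from the target according to
#' the group's improvement bias and quality spread.
#'
#' @param n_targets,n_groups Counts.
#' @param n_residues Residues per target chain (default 40).
#' @param start_sigma Coordinate noise (Angstroms) generating the starting
#'   model from the target (default 2).
#' @param quality_mean,quality_sd Per-group mean/SD of the relative
#'   perturbation magnitude in (0, 1); recycled over groups.
#' @param improvement_bias Per-group probability that a submission
#'   improves on the start; recycled over groups.
#' @param seed Integer seed driving all randomness.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_targets = 4, n_groups = 6, n_residues = 40,
                          start_sigma = 2, quality_mean = 0.5,
                          quality_sd = 0.15, improvement_bias = 0.5,
                          seed = 1) {
  stopifnot(n_targets >= 1, n_groups >= 2, n_residues >= 10,
            start_sigma >= 0)
  improvement_bias <- rep(improvement_bias, length.out = n_groups)
  if (any(improvement_bias < 0 | improvement_bias > 1)) {
    stop("improvement_bias must lie in [0, 1]")
  }
  structure(list(
    n_targets = n_targets, n_groups = n_groups, n_residues = n_residues,
    start_sigma = start_sigma,
    quality_mean = rep(quality_mean, length.out = n_groups),
    quality_sd = rep(quality_sd, length.out = n_groups),
    improvement_bias = improvement_bias, seed = seed
  ), class = "scenario_spec")
}

scenario_sequence <- "ADLKSEFRTVNQMHWYGIPC"

# all native metrics of one model against a target
compute_native_metrics <- function(model, target) {
  map <- pair_by_residue_number(model, target)
  g <- gdt(model, target, map)
  tibble::tibble(
    rms_ca = rms_ca(model, target, map),
    gdt_ts = g$gdt_ts, gdt_ha = g$gdt_ha,
    sg = suppressWarnings(sphere_grinder(model, target, map)),
    lddt = lddt(model, target, map),
    ase = as.numeric(ase_from_structures(model, target, map)),
    s_torsion = s_torsion(extract_torsions(model),
                          extract_torsions(target))$score
  )
}

#' Generate a full synthetic prediction scenario
#'
#' Builds targets, starting models, and per-group model-1 submissions
#' according to a [scenario_spec()], records the ground-truth perturbation
#' magnitudes, and computes the native metric table. Submissions carry
#' noisy-but-informative coordinate-error estimates in their B-factor
#' column so that ASE is scorable. Reproducible from the spec's seed.
#'
#' @param spec A [scenario_spec()].
#' @return A `refine_scenario` list with `metrics` (a [metric_table()]),
#'   `start_metrics` (per-target start-model rows), `structures`
#'   (`targets`, `starts`, and `submissions[[target]][[group]]`), and
#'   `manifest` (spec plus the per-submission ground truth).
#' @export
generate_scenario <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  group_ids <- sprintf("G%02d", seq_len(spec$n_groups))
  target_ids <- sprintf("T%02d", seq_len(spec$n_targets))
  draws <- withr::with_seed(spec$seed, {
    tibble::tibble(
      target_id = rep(target_ids, each = spec$n_groups),
      group_id = rep(group_ids, times = spec$n_targets),
      improve = stats::runif(spec$n_targets * spec$n_groups) <
        rep(spec$improvement_bias, times = spec$n_targets),
      magnitude = pmin(0.95, pmax(0.05, stats::rnorm(
        spec$n_targets * spec$n_groups,
        rep(spec$quality_mean, times = spec$n_targets),
        rep(spec$quality_sd, times = spec$n_targets)))),
      sub_seed = sample.int(2^20, spec$n_targets * spec$n_groups),
      err_seed = sample.int(2^20, spec$n_targets * spec$n_groups)
    )
  })
  start_seeds <- withr::with_seed(spec$seed + 1,
                                  sample.int(2^20, spec$n_targets))
  # alternate helix/strand targets for conformational variety
  targets <- stats::setNames(lapply(seq_len(spec$n_targets), function(t) {
    if (t %% 2 == 1) {
      make_ideal_chain(spec$n_residues, -57, -47,
                       sequence = scenario_sequence, sidechains = TRUE,
                       model_id = target_ids[t])
    } else {
      make_ideal_chain(spec$n_residues, -120, 130,
                       sequence = scenario_sequence, sidechains = TRUE,
                       model_id = target_ids[t])
    }
  }), target_ids)
  starts <- stats::setNames(lapply(seq_len(spec$n_targets), function(t) {
    apply_perturbation(targets[[t]], perturbation_spec(
      "coordinate_noise", sigma = spec$start_sigma, seed = start_seeds[t]))
  }), target_ids)
  submissions <- stats::setNames(
    lapply(target_ids, function(tid) stats::setNames(vector("list", spec$n_groups),
                                                     group_ids)),
    target_ids)
  for (i in seq_len(nrow(draws))) {
    tid <- draws$target_id[i]; gid <- draws$group_id[i]
    sigma <- if (draws$improve[i]) spec$start_sigma * draws$magnitude[i]
             else spec$start_sigma * (1 + draws$magnitude[i])
    sub <- apply_perturbation(targets[[tid]], perturbation_spec(
      "coordinate_noise", sigma = sigma, seed = draws$sub_seed[i]))
    # informative error estimates: actual deviation with lognormal noise
    dev <- ca_deviations(sub, targets[[tid]])
    est <- withr::with_seed(draws$err_seed[i],
                            dev$deviation * exp(stats::rnorm(nrow(dev), 0, 0.3)))
    ca_rows <- which(sub$atoms$atom == "CA")
    key <- residue_key(sub$atoms$resno[ca_rows], sub$atoms$ins[ca_rows])
    sub$atoms$bcol[ca_rows] <- est[match(key, residue_key(dev$resno, dev$ins))]
    sub$model_id <- paste(tid, gid, 1, sep = "_")
    submissions[[tid]][[gid]] <- sub
  }
  metrics <- dplyr::bind_rows(lapply(seq_len(nrow(draws)), function(i) {
    tid <- draws$target_id[i]; gid <- draws$group_id[i]
    dplyr::bind_cols(
      tibble::tibble(target_id = tid, group_id = gid, model_index = 1L),
      compute_native_metrics(submissions[[tid]][[gid]], targets[[tid]])
    )
  }))
  start_metrics <- dplyr::bind_rows(lapply(target_ids, function(tid) {
    dplyr::bind_cols(
      tibble::tibble(target_id = tid),
      compute_native_metrics(starts[[tid]], targets[[tid]])
    )
  }))
  structure(list(
    metrics = metric_table(metrics),
    start_metrics = start_metrics,
    structures = list(targets = targets, starts = starts,
                      submissions = submissions),
    manifest = list(spec = unclass(spec), ground_truth = draws)
  ), class = "refine_scenario")
}

#' Write a scenario bundle to disk
#'
#' Writes the scenario as a directory tree of PDB files (targets, starts,
#' submissions), a metrics CSV, a start-metrics CSV, and a JSON manifest
#' recording the generating spec and seeds.
#'
#' @param scenario A `refine_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "refine_scenario"))
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  st <- scenario$structures
  for (tid in names(st$targets)) {
    write_pdb(st$targets[[tid]],
              file.path(dir, "structures", paste0(tid, "_target.pdb")))
    write_pdb(st$starts[[tid]],
              file.path(dir, "structures", paste0(tid, "_start.pdb")))
    for (gid in names(st$submissions[[tid]])) {
      write_pdb(st$submissions[[tid]][[gid]],
                file.path(dir, "structures", paste0(tid, "_", gid, "_1.pdb")))
    }
  }
  write_metric_table(scenario$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(scenario$start_metrics, file.path(dir, "start_metrics.csv"))
  jsonlite::write_json(scenario$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
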