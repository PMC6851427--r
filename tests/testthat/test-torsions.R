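test_that("dihedral handles planar and degenerate arrangements", {
  # planar trans: zig-zag in the xy plane (wings on opposite sides)
  expect_equal(abs(dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 0, 0), c(3, -1, 0))),
               180)
  # planar cis: both wings on the same side
  expect_equal(dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)), 0,
               tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral agrees with the bio3d torsion convention", {
  set.seed(7)
  for (i in 1:6) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    ref <- bio3d::torsion.xyz(as.numeric(t(p)))
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 ref[!is.na(ref)], tolerance = 1e-9)
  }
})

test_that("circular_diff wraps correctly", {
  expect_equal(circular_diff(175, -175), 10)
  expect_equal(circular_diff(42, 42), 0)
  expect_equal(circular_diff(90, -90), 180)
  expect_equal(circular_diff(c(175, 0), c(-175, 10)), c(10, 10))
})

test_that("extract_torsions recovers construction angles on ideal chains", {
  h <- make_ideal_chain(20, -57, -47)
  p <- extract_torsions(h)
  interior <- 2:19
  expect_true(all(abs(p$phi[interior] - (-57)) < 0.5))
  expect_true(all(abs(p$psi[interior[-length(interior)]] - (-47)) < 0.5))
  expect_true(is.na(p$phi[1]) && is.na(p$psi[20]) && is.na(p$omega[1]))

  single <- extract_torsions(make_ideal_chain(1))
  expect_true(all(is.na(c(single$phi, single$psi, single$omega))))
})

test_that("chain breaks null the flanking backbone torsions", {
  h <- make_ideal_chain(10)
  broken <- displace_residues(h, 6:10, c(50, 0, 0))
  p <- extract_torsions(broken)
  expect_true(is.na(p$psi[5]) && is.na(p$phi[6]) && is.na(p$omega[6]))
  expect_false(is.na(p$phi[5]) || is.na(p$psi[6]))
})

test_that("two-fold symmetric chi angles fold onto one representative", {
  a <- make_ideal_chain(3, sequence = c("ALA", "PHE", "ALA"),
                        sidechains = TRUE, chi = c(180, 100))
  b <- make_ideal_chain(3, sequence = c("ALA", "PHE", "ALA"),
                        sidechains = TRUE, chi = c(180, -80))  # 100 - 180
  pa <- extract_torsions(a); pb <- extract_torsions(b)
  expect_equal(pa$chi2[2], pb$chi2[2], tolerance = 1e-6)
  st <- s_torsion(pa, pb)
  expect_equal(st$sidechain_term, 0, tolerance = 1e-6)
})

test_that("residue_backbone_error averages the defined backbone torsions", {
  pa <- tibble::tibble(resno = 1L, ins = "", resname = "ALA",
                       phi = 100, psi = -60, omega = 180,
                       chi1 = NA_real_, chi2 = NA_real_,
                       chi3 = NA_real_, chi4 = NA_real_)
  pb <- pa
  pb$phi <- 140; pb$psi <- -100
  expect_equal(residue_backbone_error(pa, pb, 1), 40)
  pb$psi <- NA_real_; pb$phi <- 150
  expect_equal(residue_backbone_error(pa, pb, 1), 50)
  expect_equal(residue_backbone_error(pa, pa, 1), 0)
  pb$phi <- NA_real_
  expect_true(is.na(residue_backbone_error(pa, pb, 1)))
})

test_that("classify_regions applies the 30-degree mean backbone criterion", {
  base <- tibble::tibble(resno = 1:3, ins = "", resname = "ALA",
                         phi = c(-60, -60, -60), psi = c(-45, -45, -45),
                         omega = 180, chi1 = NA_real_, chi2 = NA_real_,
                         chi3 = NA_real_, chi4 = NA_real_)
  target <- base
  target$phi <- c(-60, -100, -110)  # deltas 0, 40, 50
  target$psi <- c(-45, -85, -45)    # deltas 0, 40, 0
  cls <- classify_regions(base, target)
  # residue 1: mean 0 -> good; residue 2: mean 40 -> bad;
  # residue 3: mean 25 -> good
  expect_equal(cls$region, c("good", "bad", "good"))

  allzero <- classify_regions(base, base)
  expect_true(all(allzero$region == "good"))
})

test_that("s_torsion is zero at identity, negative otherwise, and matches arithmetic", {
  s <- make_ideal_chain(10, sequence = "ADLKSEFRTV", sidechains = TRUE)
  expect_equal(s_torsion(s, s)$score, 0)

  pa <- tibble::tibble(resno = 1:2, ins = "", resname = "ALA",
                       phi = c(-60, -60), psi = c(-45, -45), omega = 180,
                       chi1 = c(60, 60), chi2 = NA_real_,
                       chi3 = NA_real_, chi4 = NA_real_)
  pb <- pa
  pb$phi <- pa$phi + 20; pb$psi <- pa$psi + 20   # backbone term 20
  pb$chi1 <- pa$chi1 + 40                         # side-chain term 40
  expect_equal(s_torsion(pa, pb)$score, -30)

  scr <- apply_perturbation(s, perturbation_spec("sidechain_scramble", seed = 2))
  expect_lte(s_torsion(scr, s)$score, 0)
})

test_that("s_torsion equals a direct per-residue enumeration on a perturbed toy", {
  s <- make_ideal_chain(8, sequence = "ADLKSEFR", sidechains = TRUE)
  m <- apply_perturbation(s, perturbation_spec("coordinate_noise",
                                               sigma = 0.3, seed = 13))
  pm <- extract_torsions(m); ps <- extract_torsions(s)
  st <- s_torsion(pm, ps)

  # independent tabulation from the raw profiles
  bb <- sc <- c()
  sym <- list(PHE = 2, TYR = 2, ASP = 2, GLU = 3)
  for (i in seq_len(nrow(pm))) {
    devs <- c()
    for (ang in c("phi", "psi")) {
      va <- pm[[ang]][i]; vb <- ps[[ang]][i]
      if (!is.na(va) && !is.na(vb)) devs <- c(devs, circular_diff(va, vb))
    }
    if (length(devs)) bb <- c(bb, mean(devs))
    cdevs <- c()
    for (k in 1:4) {
      va <- pm[[paste0("chi", k)]][i]; vb <- ps[[paste0("chi", k)]][i]
      if (is.na(va) || is.na(vb)) next
      d <- circular_diff(va, vb)
      if (identical(sym[[pm$resname[i]]], k)) d <- min(d, 180 - d)
      cdevs <- c(cdevs, d)
    }
    if (length(cdevs)) sc <- c(sc, mean(cdevs))
  }
  expect_equal(st$score, -(0.5 * mean(bb) + 0.5 * mean(sc)), tolerance = 1e-9)
  expect_equal(st$backbone_term, mean(bb), tolerance = 1e-9)
  expect_equal(st$sidechain_term, mean(sc), tolerance = 1e-9)
})

test_that("torsion metrics are invariant under rigid transforms", {
  s <- make_ideal_chain(8, sequence = "ADLKSEFR", sidechains = TRUE)
  m <- apply_perturbation(s, perturbation_spec("coordinate_noise",
                                               sigma = 0.5, seed = 17))
  st0 <- s_torsion(m, s)$score
  expect_equal(s_torsion(rigid_transform(m), s)$score, st0, tolerance = 1e-9)
  expect_equal(s_torsion(m, rigid_transform(s))$score, st0, tolerance = 1e-9)
})

test_that("symmetry-corrected chi deviations never exceed 90 degrees", {
  set.seed(23)
  for (i in 1:20) {
    a <- runif(1, -180, 180); b <- runif(1, -180, 180)
    d <- abs(a - b) %% 180
    expect_lte(min(d, 180 - d), 90)
  }
  # through the full pipeline: PHE chi2 antipodal pairs
  x <- make_ideal_chain(3, sequence = c("ALA", "PHE", "ALA"),
                        sidechains = TRUE, chi = c(60, 170))
  y <- make_ideal_chain(3, sequence = c("ALA", "PHE", "ALA"),
                        sidechains = TRUE, chi = c(60, 80))
  st <- s_torsion(extract_torsions(x), extract_torsions(y))
  expect_lte(st$sidechain_term, 90)
})

test_that("region_summaries reproduce degenerate and brute-force cases", {
  target <- make_ideal_chain(12, sequence = "ADLKSEFRTVNQ", sidechains = TRUE)
  start <- displace_residues(target, 4:6, c(6, 0, 0))  # one shifted element
  model <- displace_residues(target, 4:6, c(2, 0, 0))  # partial correction

  rs_same <- region_summaries(start, start, target)
  change <- rs_same[rs_same$comparison == "change", ]
  expect_true(all(abs(change$backbone_deg) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(change$ca_rmsd) < 1e-9, na.rm = TRUE))

  rs_perfect <- region_summaries(start, target, target)
  resid <- rs_perfect[rs_perfect$comparison == "residual", ]
  expect_true(all(abs(resid$backbone_deg) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(resid$ca_rmsd) < 1e-9, na.rm = TRUE))

  # brute-force aggregation for the partial-correction model
  rs <- region_summaries(start, model, target)
  cls <- classify_regions(extract_torsions(start), extract_torsions(target))
  be <- backbone_errors(extract_torsions(model), extract_torsions(target))
  j <- merge(cls, be, by = c("resno", "ins"))
  j <- j[!is.na(j$region), ]
  manual <- tapply(j$backbone_error, j$region, mean, na.rm = TRUE)
  got <- rs[rs$comparison == "residual", ]
  for (r in names(manual)) {
    expect_equal(got$backbone_deg[got$region == r], unname(manual[r]),
                 tolerance = 1e-9)
  }
  expect_equal(sum(got$n_residues), sum(!is.na(cls$region)))
})

test_that("side-chain scrambling moves s_torsion but not GDT_HA", {
  s <- make_ideal_chain(14, sequence = "ADLKSEFRTVNQMH", sidechains = TRUE)
  scr <- apply_perturbation(s, perturbation_spec("sidechain_scramble", seed = 4))
  st <- s_torsion(scr, s)
  expect_lt(st$score, -1)          # conformation visibly degraded
  expect_equal(st$backbone_term, 0, tolerance = 1e-9)
  g <- gdt(scr, s)
  expect_equal(g$gdt_ha, 100)      # Ca positions untouched
})

test_that("torsion_table exports residue rows with region and backbone error", {
  target <- make_ideal_chain(8, sequence = "ADLKSEFR", sidechains = TRUE)
  start <- displace_residues(target, 3:4, c(5, 0, 0))
  tt <- torsion_table(start, start, target)
  expect_true(all(c("phi", "psi", "omega", "chi1", "region",
                    "backbone_error") %in% names(tt)))
  expect_equal(nrow(tt), 8)
})
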