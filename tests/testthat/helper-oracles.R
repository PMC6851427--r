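# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Horn's closed-form quaternion method for the optimal superposition RMSD
quaternion_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  S <- t(ac) %*% bc
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# direct numerical minimisation over axis-angle rotation + translation
optim_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  rot_of <- function(v) {
    theta <- sqrt(sum(v^2))
    if (theta < 1e-12) return(diag(3))
    k <- v / theta
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  }
  obj <- function(p) {
    R <- rot_of(p[1:3])
    moved <- a %*% t(R) + matrix(p[4:6], nrow(a), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - b)^2)))
  }
  best <- Inf
  set.seed(99)
  for (i in 1:8) {
    p0 <- c(stats::runif(3, -pi, pi), colMeans(b) - colMeans(a))
    fit <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# exhaustive GDT oracle: maximal fraction within each cutoff over fits on
# every CA subset of size >= 3 (feasible for n <= 12)
exhaustive_gdt_fractions <- function(A, B, cutoffs) {
  n <- nrow(A)
  stopifnot(n <= 14)
  best <- stats::setNames(rep(0, length(cutoffs)), as.character(cutoffs))
  for (size in 3:n) {
    subsets <- utils::combn(n, size)
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      sup <- refinemetrics::kabsch(A[idx, , drop = FALSE],
                                   B[idx, , drop = FALSE])
      d <- sqrt(rowSums((refinemetrics::apply_superposition(A, sup) - B)^2))
      for (cut in cutoffs) {
        key <- as.character(cut)
        best[key] <- max(best[key], sum(d <= cut) / n)
      }
    }
  }
  best
}

# brute-force lDDT by explicit double loop over shared atoms
brute_lddt <- function(model, target, radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  key <- function(s) paste(s$atoms$resno, s$atoms$ins, s$atoms$atom)
  shared <- intersect(key(target), key(model))
  tm <- target$atoms[match(shared, key(target)), ]
  mm <- model$atoms[match(shared, key(model)), ]
  rid <- paste(tm$resno, tm$ins)
  n <- nrow(tm)
  kept <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (rid[i] == rid[j]) next
      dt <- sqrt((tm$x[i] - tm$x[j])^2 + (tm$y[i] - tm$y[j])^2 +
                   (tm$z[i] - tm$z[j])^2)
      if (dt > radius) next
      dm <- sqrt((mm$x[i] - mm$x[j])^2 + (mm$y[i] - mm$y[j])^2 +
                   (mm$z[i] - mm$z[j])^2)
      kept <- c(kept, abs(dm - dt))
    }
  }
  mean(vapply(thresholds, function(t) mean(kept < t), numeric(1)))
}

# brute-force per-residue sphere RMSDs
brute_sphere_rmsds <- function(model, target, radius = 6) {
  key <- function(s) paste(s$atoms$resno, s$atoms$ins, s$atoms$atom)
  shared <- intersect(key(target), key(model))
  tm <- target$atoms[match(shared, key(target)), ]
  mm <- model$atoms[match(shared, key(model)), ]
  rid <- paste(tm$resno, tm$ins)
  out <- c()
  for (r in unique(rid)) {
    ca <- which(rid == r & tm$atom == "CA")
    if (length(ca) != 1) next
    d <- sqrt((tm$x - tm$x[ca])^2 + (tm$y - tm$y[ca])^2 + (tm$z - tm$z[ca])^2)
    sel <- which(d <= radius | rid == r)
    if (length(sel) < 3) next
    out[r] <- refinemetrics::kabsch(
      as.matrix(mm[sel, c("x", "y", "z")]),
      as.matrix(tm[sel, c("x", "y", "z")]))$rmsd
  }
  out
}
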