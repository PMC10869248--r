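# Independent oracles and small constructors shared across tests.

# Random proper rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rot_from_euler <- function(a) {
  ca <- cos(a); sa <- sin(a)
  Rz <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, ca[3], -sa[3], 0, sa[3], ca[3]), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Brute-force minimal RMSD over proper rotations: numeric minimization over
# Euler angles with multiple restarts. Independent of the Kabsch path.
bruteforce_min_rmsd <- function(P, Q, n_starts = 12) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(a) sqrt(mean(rowSums((Pc - Qc %*% rot_from_euler(a))^2)))
  best <- Inf
  for (i in seq_len(n_starts)) {
    start <- runif(3, -pi, pi)
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Exact clustering p-value by full enumeration of label placements.
enumerate_cluster_p <- function(dmat, labels) {
  n <- nrow(dmat); k <- sum(labels == "pathogenic")
  stat <- function(idx) mean(dmat[idx, idx][upper.tri(dmat[idx, idx])])
  obs <- stat(which(labels == "pathogenic"))
  all_stats <- apply(combn(n, k), 2, stat)
  mean(all_stats <= obs + 1e-12)
}

# Minimal hand-built PDB text: one-atom-per-residue file.
tiny_pdb_text <- function(res_names, xyz, b = 0, chain = "A") {
  b <- rep_len(b, length(res_names))
  c(vapply(seq_along(res_names), function(i) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, res_names[i], chain, i, xyz[i, 1], xyz[i, 2], xyz[i, 3],
            1, b[i])
  }, character(1)), "END")
}

fixture_tools5 <- c("sift", "polyphen2", "mutationtaster",
                    "mutationassessor", "intervar")
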