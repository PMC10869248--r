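test_that("kabsch recovers identity on identical sets and zero RMSD under rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  s <- kabsch_superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  # 90-degree rotation about z plus a translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  Q <- P %*% t(Rz)
  Q <- sweep(Q, 2, c(5, 0, 0), `+`)
  s2 <- kabsch_superpose(P, Q)
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  moved <- sweep(Q %*% s2$rotation, 2, s2$translation, `+`)
  expect_equal(moved, P, tolerance = 1e-8)
})

test_that("kabsch returns a proper rotation and errors on degenerate input", {
  set.seed(2)
  P <- matrix(rnorm(24), 8, 3)
  Q <- matrix(rnorm(24), 8, 3)
  s <- kabsch_superpose(P, Q)
  expect_equal(t(s$rotation) %*% s$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "rank")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("kabsch RMSD matches brute-force rotational minimization on small random sets", {
  set.seed(7)
  for (i in 1:6) {
    n <- sample(3:8, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, bruteforce_min_rmsd(P, Q),
                 tolerance = 1e-4)
  }
  # the reflected triangle from the worked example: only proper rotations
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Q <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  expect_equal(kabsch_superpose(P, Q)$rmsd, bruteforce_min_rmsd(P, Q),
               tolerance = 1e-4)
})

test_that("kabsch RMSD is invariant under proper rigid motions of either set", {
  set.seed(13)
  P <- matrix(rnorm(45), 15, 3)
  Q <- matrix(rnorm(45), 15, 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (i in 1:5) {
    R1 <- random_rotation(); R2 <- random_rotation()
    t1 <- rnorm(3, sd = 10); t2 <- rnorm(3, sd = 10)
    moved <- kabsch_superpose(sweep(P %*% R1, 2, t1, `+`),
                              sweep(Q %*% R2, 2, t2, `+`))$rmsd
    expect_equal(moved, base, tolerance = 1e-8)
  }
})

test_that("residue pairing intersects numbering frames", {
  full <- make_helix_structure(100)
  domain <- make_helix_structure(50, start_res = 40L)
  pairing <- pair_by_resnum(full, domain)
  expect_equal(pairing$res_num, 40:89)
  expect_equal(nrow(pairing$xyz_a), 50L)
  ident <- pair_by_resnum(full, full)
  expect_equal(length(ident$res_num), 100L)
  disjoint <- make_helix_structure(10, start_res = 500L)
  expect_error(pair_by_resnum(full, disjoint), "insufficient overlap")
})

test_that("iterative alignment rejects planted outliers and recovers the clean fit", {
  set.seed(17)
  n <- 100
  A <- matrix(rnorm(3 * n, sd = 10), n, 3)
  R <- random_rotation()
  B <- sweep(A %*% R, 2, c(3, -2, 8), `+`)
  noise <- matrix(rnorm(3 * n, sd = 0.1), n, 3)
  B <- B + noise
  decoys <- sample(n, 10)
  B[decoys, ] <- B[decoys, ] + matrix(rnorm(30, sd = 25), 10, 3)
  pairing <- structure(list(res_num = 1:n, xyz_a = A, xyz_b = B),
                       class = "residue_pairing")
  fit <- iterative_align(pairing, cycles = 5, reject_sd = 2)
  expect_true(all(decoys %in% fit$rejected))
  # trimming the noise tails can only shrink the RMSD, and only modestly
  clean <- kabsch_superpose(A[-decoys, ], B[-decoys, ])
  expect_lte(fit$rmsd, clean$rmsd)
  expect_gte(fit$rmsd, 0.5 * clean$rmsd)
  # cycles = 0 keeps every pair
  plain <- iterative_align(pairing, cycles = 0)
  expect_equal(plain$n_pairs_used, n)
  expect_equal(plain$rmsd, kabsch_superpose(A, B)$rmsd, tolerance = 1e-10)
  # clean data: converges in one fit with nothing rejected
  clean_pairing <- structure(list(res_num = 1:n, xyz_a = A,
                                  xyz_b = sweep(A %*% R, 2, c(1, 1, 1), `+`)),
                             class = "residue_pairing")
  fit2 <- iterative_align(clean_pairing)
  expect_length(fit2$rejected, 0L)
})

test_that("C-alpha distance matrices are symmetric, zero-diagonal Euclidean distances", {
  m <- read_pdb(text = tiny_pdb_text(c("ALA", "ALA"),
                                     rbind(c(0, 0, 0), c(3, 4, 0))))
  d <- ca_distance_matrix(m)
  expect_equal(d[1, 2], 5)
  helix <- make_helix_structure(60)
  dm <- ca_distance_matrix(helix)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # closed-form consecutive spacing of the ideal helix parameterization
  r <- 2.3; omega <- 100 * pi / 180; d_rise <- 1.5
  expected <- sqrt((2 * r * sin(omega / 2))^2 + d_rise^2)
  expect_equal(unname(dm[cbind(1:59, 2:60)]), rep(expected, 59),
               tolerance = 0.002)
  expect_error(ca_distance_matrix(helix, residue_subset = c(1, 999)),
               "missing C-alpha")
})

test_that("exhaustive cluster test equals enumeration on a tiny case", {
  m <- make_helix_structure(60)
  res <- c(3, 5, 8, 40, 55)
  labels <- c("pathogenic", "pathogenic", "benign", "benign", "benign")
  got <- cluster_permutation_test(m, res, labels, exact = TRUE)
  dmat <- ca_distance_matrix(m, res)
  expect_equal(got$p_value, enumerate_cluster_p(dmat, labels))
  expect_equal(got$n_permutations, choose(5, 2))
  expect_error(cluster_permutation_test(m, res, rep("pathogenic", 5)),
               "degenerate")
  expect_error(cluster_permutation_test(m, res[1:2],
                                        c("pathogenic", "pathogenic")),
               "degenerate")
})

test_that("adjacent pathogenic residues give a small clustering p-value", {
  m <- make_helix_structure(200)
  res <- c(50:59, seq(110, 200, by = 10))
  labels <- c(rep("pathogenic", 10), rep("benign", 10))
  got <- cluster_permutation_test(m, res, labels, n_perm = 999, seed = 5)
  expect_lte(got$p_value, 0.05)
  # same seed reproduces the same null and p-value
  again <- cluster_permutation_test(m, res, labels, n_perm = 999, seed = 5)
  expect_identical(got$null_samples, again$null_samples)
  expect_identical(got$p_value, again$p_value)
})

test_that("cluster-test p-values are approximately uniform under the null", {
  m <- make_helix_structure(150)
  n_sim <- 200
  set.seed(99)
  p <- vapply(seq_len(n_sim), function(i) {
    res <- sort(sample.int(150, 12))
    labels <- rep("benign", 12)
    labels[sample.int(12, 4)] <- "pathogenic"
    cluster_permutation_test(m, res, labels, n_perm = 199,
                             seed = 1000 + i)$p_value
  }, numeric(1))
  frac <- mean(p <= 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.12)
})

test_that("domain enrichment equals hypergeometric enumeration and the exact test", {
  # perfectly separated 5+5 table
  domains <- rep(c("in", "out"), each = 5)
  labels <- c(rep("pathogenic", 5), rep("benign", 5))
  got <- domain_enrichment(domains, labels)
  p_in <- got$p_value[got$domain == "in"]
  expect_equal(p_in, 2 / choose(10, 5))
  # even split across identical margins -> no association
  dom2 <- rep(c("a", "b"), each = 4)
  lab2 <- rep(c("pathogenic", "benign"), 4)
  even <- domain_enrichment(dom2, lab2)
  expect_equal(even$p_value, c(1, 1))
  # random tables, n <= 30: match full enumeration and fisher.test
  set.seed(31)
  for (i in 1:15) {
    n <- sample(6:30, 1)
    domains <- sample(c("d1", "d2"), n, TRUE)
    labels <- sample(c("pathogenic", "benign"), n, TRUE)
    got <- domain_enrichment(domains, labels)
    for (j in seq_len(nrow(got))) {
      a <- got$n_pathogenic_in[j]; b <- got$n_benign_in[j]
      c_ <- got$n_pathogenic_out[j]; d <- got$n_benign_out[j]
      # enumeration oracle over the hypergeometric support
      m1 <- a + c_; m2 <- b + d; k <- a + b
      support <- max(0, k - m2):min(k, m1)
      probs <- vapply(support, function(x)
        choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k), numeric(1))
      oracle <- sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
      expect_equal(got$p_value[j], oracle, tolerance = 1e-10)
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      expect_equal(got$p_value[j], ft$p.value, tolerance = 1e-7)
    }
  }
})

test_that("the N-terminal domain of the case study holds 4 variants, all rescued", {
  doms <- load_fixture("domain_labels")
  truth <- load_fixture("functional_results")
  labels <- ifelse(truth$outcome[match(doms$variant_id, truth$variant_id)] ==
                     "RUPTURED", "pathogenic", "benign")
  enr <- domain_enrichment(doms$domain, labels)
  nt <- enr[enr$domain == "N-terminal", ]
  expect_equal(nt$n_in, 4L)
  expect_equal(nt$n_benign_in, 4L)
  expect_equal(nt$n_pathogenic_in, 0L)
  nt_changes <- doms$aa_change[doms$domain == "N-terminal"]
  expect_setequal(nt_changes, c("R6C", "R9Q", "R9W", "P12L"))
})
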