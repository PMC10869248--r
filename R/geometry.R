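ca_coords <- function(model, chain = NULL) {
  atoms <- model$atoms
  sel <- atoms$record == "ATOM" & atoms$atom_name == "CA"
  if (is.null(chain)) chain <- atoms$chain[sel][1]
  sel <- sel & atoms$chain == chain
  ca <- atoms[sel, , drop = FALSE]
  ca <- ca[!duplicated(ca$res_num), , drop = FALSE]
  list(res_num = ca$res_num,
       xyz = as.matrix(ca[c("x", "y", "z")]))
}

#' Pair residues of two models by residue number
#'
#' Matches C-alpha-bearing residues with equal residue numbers across two
#' models sharing a numbering frame (e.g. a full-length model and a domain
#' model of the same protein).
#'
#' @param model_a,model_b `pdb_model` objects.
#' @param chain_a,chain_b chain selectors (default = first chain of each).
#' @return list of class `residue_pairing`: `res_num` (shared residue
#'   numbers, sorted), `xyz_a`, `xyz_b` (N x 3 coordinate matrices).
#' @export
pair_by_resnum <- function(model_a, model_b, chain_a = NULL, chain_b = NULL) {
  a <- ca_coords(model_a, chain_a)
  b <- ca_coords(model_b, chain_b)
  shared <- sort(intersect(a$res_num, b$res_num))
  if (length(shared) < 3L) {
    stop("insufficient overlap: fewer than 3 shared C-alpha residues",
         call. = FALSE)
  }
  structure(list(res_num = shared,
                 xyz_a = a$xyz[match(shared, a$res_num), , drop = FALSE],
                 xyz_b = b$xyz[match(shared, b$res_num), , drop = FALSE]),
            class = "residue_pairing")
}

#' Kabsch least-squares superposition
#'
#' Closed-form rigid-body superposition of two paired point sets, restricted
#' to proper rotations (no reflection). The returned transform maps the
#' mobile set onto the reference: `coords_mov %*% rotation + translation`
#' attains the reported RMSD.
#'
#' @param coords_ref,coords_mov N x 3 matrices of paired coordinates
#'   (Angstrom), N >= 3 and not collinear.
#' @return list of class `superposition`: `rotation` (3 x 3 proper rotation),
#'   `translation` (length-3), `rmsd` (Angstrom), `n_pairs_used`,
#'   `n_cycles` (1), `rejected` (empty integer vector).
#' @export
kabsch_superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref); coords_mov <- as.matrix(coords_mov)
  stopifnot(ncol(coords_ref) == 3L, ncol(coords_mov) == 3L,
            nrow(coords_ref) == nrow(coords_mov))
  n <- nrow(coords_ref)
  if (n < 3L) stop("rank deficiency: need >= 3 point pairs", call. = FALSE)
  if (!all(is.finite(coords_ref)) || !all(is.finite(coords_mov))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  ca <- colMeans(coords_ref); cb <- colMeans(coords_mov)
  A <- sweep(coords_ref, 2, ca); B <- sweep(coords_mov, 2, cb)
  H <- crossprod(B, A)
  s <- svd(H)
  # Collinear point sets leave the rotation underdetermined.
  scale <- sqrt(mean(rowSums(A^2)) + mean(rowSums(B^2)))
  if (scale == 0 || s$d[2] / max(s$d[1], .Machine$double.eps) < 1e-10) {
    if (s$d[1] > 1e-8 * scale) {
      stop("rank deficiency: collinear point configuration", call. = FALSE)
    }
  }
  d <- if (det(s$u) * det(s$v) < 0) -1 else 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((A - B %*% R)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% R),
                 rmsd = rmsd, n_pairs_used = n, n_cycles = 1L,
                 rejected = integer(0)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> RMSD ", sprintf("%.4f", x$rmsd), " A over ",
      x$n_pairs_used, " pairs (", x$n_cycles, " cycle(s), ",
      length(x$rejected), " rejected)\n", sep = "")
  invisible(x)
}

apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, `+`)
}

#' Superpose with iterative outlier rejection
#'
#' Repeats Kabsch superposition, after each fit dropping residue pairs whose
#' post-fit distance exceeds `mean + reject_sd * sd` of the surviving pairs,
#' until no pair is rejected or `cycles` rounds have run. This emulates the
#' refinement cycles of structure-viewer aligners; the final RMSD is over the
#' surviving pairs only.
#'
#' @param model_a reference `pdb_model` (or a `residue_pairing`).
#' @param model_b mobile `pdb_model` (ignored when `model_a` is a pairing).
#' @param cycles maximum rejection rounds (default 5); 0 = plain Kabsch on
#'   all pairs.
#' @param reject_sd rejection threshold in standard deviations (default 2).
#' @return `superposition` with `n_cycles` performed and `rejected` holding
#'   the residue numbers of discarded pairs.
#' @export
iterative_align <- function(model_a, model_b = NULL, cycles = 5,
                            reject_sd = 2.0) {
  pairing <- if (inherits(model_a, "residue_pairing")) model_a
             else pair_by_resnum(model_a, model_b)
  keep <- rep(TRUE, length(pairing$res_num))
  rejected <- integer(0)
  cycle <- 0L
  repeat {
    if (sum(keep) < 3L) {
      stop("alignment did not converge: fewer than 3 pairs survive ",
           "rejection", call. = FALSE)
    }
    sup <- kabsch_superpose(pairing$xyz_a[keep, , drop = FALSE],
                            pairing$xyz_b[keep, , drop = FALSE])
    cycle <- cycle + 1L
    if (cycle > cycles) break
    moved <- apply_superposition(pairing$xyz_b[keep, , drop = FALSE], sup)
    dists <- sqrt(rowSums((pairing$xyz_a[keep, , drop = FALSE] - moved)^2))
    # an (essentially) uniform residual spread leaves nothing to reject
    if (length(dists) < 3L || sd(dists) < 1e-8) break
    cut <- mean(dists) + reject_sd * sd(dists)
    drop <- dists > cut
    if (!any(drop)) break
    rejected <- c(rejected, pairing$res_num[keep][drop])
    keep[keep] <- !drop
  }
  sup$n_cycles <- cycle
  sup$rejected <- sort(rejected)
  sup
}

#' C-alpha distance matrix for a residue subset
#'
#' Pairwise Euclidean C-alpha distances (Angstrom) for the requested
#' residues; symmetric with a zero diagonal.
#'
#' @param model a `pdb_model`.
#' @param residue_subset integer vector of residue numbers; default = all
#'   C-alpha residues of the chain.
#' @param chain chain selector.
#' @return symmetric numeric matrix with residue numbers as dimnames.
#' @export
ca_distance_matrix <- function(model, residue_subset = NULL, chain = NULL) {
  ca <- ca_coords(model, chain)
  if (is.null(residue_subset)) residue_subset <- ca$res_num
  hit <- match(residue_subset, ca$res_num)
  if (any(is.na(hit))) {
    stop("missing C-alpha atom for residue(s): ",
         paste(residue_subset[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(dist(ca$xyz[hit, , drop = FALSE]))
  dimnames(m) <- list(residue_subset, residue_subset)
  m
}

cluster_statistic <- function(dmat, idx, statistic) {
  sub <- dmat[idx, idx, drop = FALSE]
  if (statistic == "mean_pairwise") {
    mean(sub[upper.tri(sub)])
  } else {
    diag(sub) <- Inf
    mean(apply(sub, 1, min))
  }
}

#' Permutation test for 3D clustering of pathogenic residues
#'
#' Tests whether pathogenic-labeled variant residues sit closer together in
#' the folded structure than expected if pathogenic/benign labels were
#' exchangeable over the observed variant positions. The statistic is the
#' mean pairwise C-alpha distance among pathogenic residues (optionally the
#' mean nearest-neighbor distance); the null is generated by permuting the
#' labels over the same variant-residue set, conditioning on where the
#' variants are. Small values mean clustering; the one-sided p-value is
#' `(1 + #\{null <= observed\}) / (1 + n_perm)`. With `exact = TRUE` all
#' `choose(n, k)` label placements are enumerated and the p-value is the
#' exact fraction of placements (the observed one included) with a statistic
#' no larger than observed.
#'
#' @param model a `pdb_model`.
#' @param variant_residues integer vector of variant residue numbers.
#' @param labels parallel character vector, `"pathogenic"` / `"benign"`;
#'   needs >= 2 pathogenic and >= 1 benign.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed for reproducibility.
#' @param statistic `"mean_pairwise"` (default) or `"nearest_neighbor"`.
#' @param exact enumerate all label placements instead of sampling.
#' @param chain chain selector.
#' @return list of class `cluster_test`: `statistic_observed` (Angstrom),
#'   `null_samples`, `p_value`, `n_permutations`, `seed`, `statistic`,
#'   `exact`.
#' @export
cluster_permutation_test <- function(model, variant_residues, labels,
                                     n_perm = 999, seed = NULL,
                                     statistic = c("mean_pairwise",
                                                   "nearest_neighbor"),
                                     exact = FALSE, chain = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(length(variant_residues) == length(labels))
  if (!all(labels %in% c("pathogenic", "benign"))) {
    stop("labels must be 'pathogenic' or 'benign'", call. = FALSE)
  }
  k <- sum(labels == "pathogenic")
  if (k < 2L || sum(labels == "benign") < 1L) {
    stop("degenerate labels: need >= 2 pathogenic and >= 1 benign variant ",
         "residues", call. = FALSE)
  }
  dmat <- ca_distance_matrix(model, variant_residues, chain = chain)
  n <- length(variant_residues)
  obs <- cluster_statistic(dmat, which(labels == "pathogenic"), statistic)
  if (exact) {
    combos <- utils::combn(n, k)
    null <- apply(combos, 2, function(idx)
      cluster_statistic(dmat, idx, statistic))
    p <- mean(null <= obs + 1e-12)
    n_perm <- ncol(combos)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    null <- vapply(seq_len(n_perm), function(i)
      cluster_statistic(dmat, sample.int(n, k), statistic), numeric(1))
    p <- (1 + sum(null <= obs + 1e-12)) / (1 + n_perm)
  }
  structure(list(statistic_observed = obs, null_samples = null,
                 p_value = p, n_permutations = n_perm,
                 seed = seed, statistic = statistic, exact = exact),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> observed ", sprintf("%.3f", x$statistic_observed),
      " A (", x$statistic, "), p = ", format(x$p_value),
      if (x$exact) " [exact]" else paste0(" [", x$n_permutations, " perms]"),
      "\n", sep = "")
  invisible(x)
}

#' Exact two-sided hypergeometric test for a 2x2 table
#'
#' Two-sided p-value by direct summation: all counts `k` whose
#' hypergeometric probability does not exceed that of the observed table
#' contribute (the standard small-probability convention).
#'
#' @param a in-group successes; @param b in-group failures;
#' @param c_ out-group successes; @param d out-group failures.
#' @return the two-sided p-value.
#' @keywords internal
hypergeom_2x2_p <- function(a, b, c_, d) {
  m <- a + c_        # total successes
  n <- b + d         # total failures
  k <- a + b         # in-group size
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Domain enrichment of pathogenic variants
#'
#' For each domain, builds the 2x2 table (in-domain vs out x pathogenic vs
#' benign) and computes a two-sided exact hypergeometric p-value by direct
#' tail summation.
#'
#' @param domains character vector of per-variant domain labels.
#' @param labels parallel character vector, `"pathogenic"` / `"benign"`.
#' @return `data.frame` with one row per domain: `domain`, `n_in`,
#'   `n_pathogenic_in`, `n_benign_in`, `n_pathogenic_out`, `n_benign_out`,
#'   `p_value`.
#' @export
domain_enrichment <- function(domains, labels) {
  stopifnot(length(domains) == length(labels))
  if (!all(labels %in% c("pathogenic", "benign"))) {
    stop("labels must be 'pathogenic' or 'benign'", call. = FALSE)
  }
  if (any(is.na(domains))) {
    stop("every variant must be assigned a domain", call. = FALSE)
  }
  out <- do.call(rbind, lapply(unique(domains), function(dm) {
    inside <- domains == dm
    a <- sum(inside & labels == "pathogenic")
    b <- sum(inside & labels == "benign")
    c_ <- sum(!inside & labels == "pathogenic")
    d <- sum(!inside & labels == "benign")
    data.frame(domain = dm, n_in = a + b, n_pathogenic_in = a,
               n_benign_in = b, n_pathogenic_out = c_, n_benign_out = d,
               p_value = hypergeom_2x2_p(a, b, c_, d),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
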