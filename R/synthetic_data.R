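# Generators for toy structures and predictor panels, plus loaders for the
# packaged IRF6 case-study tables. Everything is deterministic under a seed.

format_atom_line <- function(serial, atom_name, res_name, chain, res_num,
                             x, y, z, occupancy = 1, b_factor = 0) {
  name4 <- if (nchar(atom_name) <= 3L) {
    formatC(paste0(" ", atom_name), width = -4)
  } else atom_name
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, res_name, chain, res_num, x, y, z, occupancy,
          b_factor, substr(trimws(atom_name), 1, 1))
}

#' Build a C-alpha-trace model on an ideal alpha-helix
#'
#' Places one C-alpha per residue on an ideal alpha-helix: residue `i` at
#' `(r cos(w i), r sin(w i), d i)` with radius `r` = 2.3 Angstrom, turn
#' `w` = 100 degrees and rise `d` = 1.5 Angstrom per residue — the canonical
#' helix parameterization, giving a consecutive C-alpha spacing of about
#' 3.8 Angstrom. Deterministic; a toy stand-in for predicted models.
#'
#' @param n_residues number of residues (>= 2).
#' @param chain chain identifier.
#' @param b_factor per-residue B-factor value(s), recycled; useful for
#'   emulating pLDDT-carrying files.
#' @param start_res residue number of the first residue.
#' @return a `pdb_model` with `n_residues` C-alpha atoms.
#' @export
make_helix_structure <- function(n_residues, chain = "A", b_factor = 0,
                                 start_res = 1L) {
  if (n_residues < 2L) {
    stop("n_residues must be >= 2", call. = FALSE)
  }
  i <- seq_len(n_residues) - 1L
  r <- 2.3; omega <- 100 * pi / 180; d <- 1.5
  b <- rep_len(b_factor, n_residues)
  lines <- c(
    "REMARK synthetic ideal alpha-helix C-alpha trace",
    mapply(format_atom_line, serial = seq_len(n_residues), atom_name = "CA",
           res_name = "ALA", chain = chain,
           res_num = start_res + i,
           x = r * cos(omega * i), y = r * sin(omega * i), z = d * i,
           b_factor = b),
    "END")
  read_pdb(text = lines)
}

#' Build a random-chain model by a self-avoiding walk
#'
#' Seeded self-avoiding random walk with 3.8 Angstrom steps (consecutive
#' C-alpha spacing); any step landing within 3 Angstrom of an existing
#' residue is re-drawn. A dispersed-geometry counterpart to
#' [make_helix_structure()].
#'
#' @param n_residues number of residues (>= 2).
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @return a `pdb_model`.
#' @export
make_random_chain <- function(n_residues, seed = 1L, chain = "A") {
  if (n_residues < 2L) stop("n_residues must be >= 2", call. = FALSE)
  set.seed(seed)
  step <- 3.8
  xyz <- matrix(0, n_residues, 3)
  for (i in 2:n_residues) {
    repeat {
      u <- stats::rnorm(3)
      cand <- xyz[i - 1, ] + step * u / sqrt(sum(u^2))
      prior <- xyz[seq_len(i - 1), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prior, 2, cand)^2))) > 3.0) break
    }
    xyz[i, ] <- cand
  }
  lines <- c(
    "REMARK synthetic self-avoiding chain C-alpha trace",
    vapply(seq_len(n_residues), function(i)
      format_atom_line(i, "CA", "ALA", chain, i,
                       xyz[i, 1], xyz[i, 2], xyz[i, 3]), character(1)),
    "END")
  read_pdb(text = lines)
}

#' Simulate variant residues and truth labels
#'
#' Draws `n_variants` distinct residue positions on a protein of
#' `n_residues` residues and assigns pathogenic/benign truth labels. In
#' `"clustered"` mode every pathogenic variant falls inside one contiguous
#' window of `cluster_width` residues (benign variants are placed uniformly
#' outside the window); in `"dispersed"` mode all positions and labels are
#' uniform.
#'
#' @param n_residues protein length.
#' @param n_variants number of variant residues (<= `n_residues`).
#' @param fraction_pathogenic fraction of variants labeled pathogenic.
#' @param mode `"clustered"` or `"dispersed"`.
#' @param cluster_width window size (residues) for clustered mode.
#' @param seed RNG seed.
#' @return `data.frame`: `res_num`, `label` (`"pathogenic"`/`"benign"`).
#' @export
simulate_variant_labels <- function(n_residues, n_variants,
                                    fraction_pathogenic = 0.5,
                                    mode = c("dispersed", "clustered"),
                                    cluster_width = 20L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_variants <= n_residues,
            fraction_pathogenic >= 0, fraction_pathogenic <= 1)
  n_path <- round(n_variants * fraction_pathogenic)
  set.seed(seed)
  if (mode == "dispersed") {
    res <- sort(sample.int(n_residues, n_variants))
    label <- rep("benign", n_variants)
    label[sample.int(n_variants, n_path)] <- "pathogenic"
  } else {
    if (cluster_width < n_path) {
      stop("infeasible config: cluster_width smaller than the number of ",
           "pathogenic variants", call. = FALSE)
    }
    if (n_residues - cluster_width < n_variants - n_path) {
      stop("infeasible config: not enough residues outside the cluster ",
           "window for the benign variants", call. = FALSE)
    }
    start <- sample.int(n_residues - cluster_width + 1L, 1L)
    window <- start:(start + cluster_width - 1L)
    path_res <- sort(sample(window, n_path))
    ben_res <- sort(sample(setdiff(seq_len(n_residues), window),
                           n_variants - n_path))
    res <- c(path_res, ben_res)
    label <- c(rep("pathogenic", n_path), rep("benign", n_variants - n_path))
    o <- order(res)
    res <- res[o]; label <- label[o]
  }
  data.frame(res_num = res, label = label, stringsAsFactors = FALSE)
}

#' Simulate a multi-tool categorical predictor panel
#'
#' For each tool, each variant first draws `VUS` with probability
#' `vus_rate` and `UNKNOWN` (missing) with probability `missing_rate`;
#' otherwise the tool issues a binary call that is correct with probability
#' `sensitivity` (pathogenic truth) or `specificity` (benign truth). The
#' unconditional probability of a correct binary call is therefore
#' `sensitivity * (1 - vus_rate - missing_rate)` for pathogenic variants,
#' and analogously for benign.
#'
#' @param truth `data.frame` with `variant_id` and `label`
#'   (`"pathogenic"`/`"benign"`).
#' @param panel named list; one element per tool, each a list with
#'   `sensitivity`, `specificity`, `vus_rate` (default 0), `missing_rate`
#'   (default 0); `vus_rate + missing_rate` must not exceed 1.
#' @param seed RNG seed.
#' @return wide `data.frame`: `variant_id`, `label`, one `<tool>_pred`
#'   column per tool with values in the common call alphabet.
#' @export
simulate_predictor_panel <- function(truth, panel, seed = 1L) {
  stopifnot(all(c("variant_id", "label") %in% names(truth)),
            all(truth$label %in% c("pathogenic", "benign")))
  set.seed(seed)
  out <- truth[c("variant_id", "label")]
  for (tool in names(panel)) {
    spec <- panel[[tool]]
    vus <- spec$vus_rate %||% 0
    mis <- spec$missing_rate %||% 0
    if (vus < 0 || mis < 0 || vus + mis > 1) {
      stop("config error: vus_rate + missing_rate must lie in [0, 1] for ",
           tool, call. = FALSE)
    }
    if (is.null(spec$sensitivity) || is.null(spec$specificity) ||
        spec$sensitivity < 0 || spec$sensitivity > 1 ||
        spec$specificity < 0 || spec$specificity > 1) {
      stop("config error: ", tool, " needs sensitivity and specificity in ",
           "[0, 1]", call. = FALSE)
    }
    n <- nrow(truth)
    u <- runif(n)
    call <- character(n)
    call[u < vus] <- "VUS"
    call[u >= vus & u < vus + mis] <- "UNKNOWN"
    open <- !nzchar(call)
    correct <- runif(n) < ifelse(truth$label == "pathogenic",
                                 spec$sensitivity, spec$specificity)
    right_call <- ifelse(truth$label == "pathogenic",
                         "DELETERIOUS", "TOLERATED")
    wrong_call <- ifelse(truth$label == "pathogenic",
                         "TOLERATED", "DELETERIOUS")
    call[open] <- ifelse(correct[open], right_call[open], wrong_call[open])
    out[[paste0(tool, "_pred")]] <- call
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
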