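#' Harmonize a tool-native categorical label
#'
#' Maps a predictor's native vocabulary (e.g. MutationTaster's
#' `Disease_causing_automatic`) onto the common call alphabet
#' `DELETERIOUS / TOLERATED / VUS / UNKNOWN`. Empty or `NA` labels encode a
#' missing prediction and become `UNKNOWN`; a non-empty label absent from the
#' vocabulary also becomes `UNKNOWN`, with a warning.
#'
#' @param raw_label character vector of tool-native labels.
#' @param vocabulary named character vector mapping native labels to calls in
#'   the common alphabet.
#' @return character vector of common-alphabet calls.
#' @seealso [tool_vocabularies()]
#' @examples
#' map_vocabulary("Disease_causing", tool_vocabularies()$mutationtaster)
#' @export
map_vocabulary <- function(raw_label, vocabulary) {
  stopifnot(is.character(vocabulary), !is.null(names(vocabulary)))
  if (!all(vocabulary %in% CALL_LEVELS)) {
    stop("vocabulary values must lie in the common call alphabet: ",
         paste(CALL_LEVELS, collapse = ", "), call. = FALSE)
  }
  raw <- trimws(as.character(raw_label))
  out <- rep("UNKNOWN", length(raw))
  present <- !is.na(raw) & nzchar(raw)
  hit <- present & raw %in% names(vocabulary)
  out[hit] <- unname(vocabulary[raw[hit]])
  unmapped <- present & !hit
  if (any(unmapped)) {
    warning("unmapped predictor label(s) set to UNKNOWN: ",
            paste(sQuote(unique(raw[unmapped])), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Built-in predictor vocabularies
#'
#' Native-label dictionaries for the categorical tools handled out of the
#' box. Each element is a named character vector suitable for
#' [map_vocabulary()]. Tools with graded middle categories (MutationAssessor
#' `medium`, InterVar `Uncertain significance`) map those to `VUS`, matching
#' their non-binary role in concordance scoring.
#'
#' @return named list of vocabularies.
#' @export
tool_vocabularies <- function() {
  list(
    sift = c(D = "DELETERIOUS", T = "TOLERATED",
             Deleterious = "DELETERIOUS", Tolerated = "TOLERATED"),
    polyphen2 = c(D = "DELETERIOUS", P = "DELETERIOUS", B = "TOLERATED",
                  probably_damaging = "DELETERIOUS",
                  possibly_damaging = "DELETERIOUS",
                  benign = "TOLERATED"),
    mutationtaster = c(Disease_causing_automatic = "DELETERIOUS",
                       Disease_causing = "DELETERIOUS",
                       Polymorphism_automatic = "TOLERATED",
                       Polymorphism = "TOLERATED",
                       A = "DELETERIOUS", D = "DELETERIOUS",
                       N = "TOLERATED", P = "TOLERATED"),
    mutationassessor = c(H = "DELETERIOUS", high = "DELETERIOUS",
                         M = "VUS", medium = "VUS",
                         L = "TOLERATED", low = "TOLERATED",
                         N = "TOLERATED", neutral = "TOLERATED"),
    intervar = c(Pathogenic = "DELETERIOUS",
                 `Likely pathogenic` = "DELETERIOUS",
                 `Uncertain significance` = "VUS",
                 `Likely benign` = "TOLERATED",
                 Benign = "TOLERATED")
  )
}

#' Normalize quantitative scores to the unit interval
#'
#' Affine min-max normalization of a tool's raw scores onto `[0, 1]`, so that
#' a higher value always means higher predicted pathogenicity risk. When a
#' tool's declared output range is known it should be supplied; otherwise the
#' observed range is used. Missing values pass through as `NA`. A rank
#' (percentile) mode is available as a robustness alternative.
#'
#' @param raw numeric vector of tool-native scores (may contain `NA`).
#' @param declared_range optional `c(lo, hi)` with `lo < hi` bracketing all
#'   raw values.
#' @param mode `"minmax"` (default, affine) or `"rank"` (fractional ranks of
#'   the non-missing values, mapped to `[0, 1]`).
#' @return numeric vector in `[0, 1]` with `NA` preserved.
#' @export
normalize_scores <- function(raw, declared_range = NULL,
                             mode = c("minmax", "rank")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(raw))
  obs <- raw[!is.na(raw)]
  if (mode == "rank") {
    if (length(obs) < 2L) stop("rank mode needs >= 2 observed scores",
                               call. = FALSE)
    out <- rep(NA_real_, length(raw))
    out[!is.na(raw)] <- (rank(obs, ties.method = "average") - 1) /
      (length(obs) - 1)
    return(out)
  }
  if (!is.null(declared_range)) {
    stopifnot(length(declared_range) == 2L)
    lo <- declared_range[[1]]; hi <- declared_range[[2]]
    if (!(lo < hi)) stop("declared_range must satisfy lo < hi", call. = FALSE)
    if (length(obs) && (min(obs) < lo || max(obs) > hi)) {
      stop("raw scores fall outside the declared range", call. = FALSE)
    }
  } else {
    if (length(unique(obs)) < 2L) {
      stop("degenerate range: constant scores need a declared_range",
           call. = FALSE)
    }
    lo <- min(obs); hi <- max(obs)
  }
  (raw - lo) / (hi - lo)
}

#' @rdname normalize_scores
#' @export
normalize_minmax <- function(raw, declared_range = NULL) {
  normalize_scores(raw, declared_range, mode = "minmax")
}

#' Summarize a tool's normalized score distribution
#'
#' Five-number summary (min, Q1, median, Q3, max) plus range and missingness
#' for one tool's normalized scores. Quartiles use linear interpolation
#' between closest ranks ([stats::quantile()] type 7). Missing scores are
#' counted and excluded from the statistics, never imputed as 0 (a zero
#' stands for "maximally benign", not "unavailable").
#'
#' @param scores numeric vector of normalized scores in `[0, 1]`, `NA` for
#'   missing.
#' @param tool tool name carried into the result.
#' @return one-row `data.frame`: `tool`, `n`, `n_missing`, `min`, `q1`,
#'   `median`, `q3`, `max`, `range`.
#' @export
tool_summary <- function(scores, tool = "tool") {
  stopifnot(is.numeric(scores))
  obs <- scores[!is.na(scores)]
  if (length(obs) == 0L) {
    stop("no observed scores for ", tool, ": summary undefined", call. = FALSE)
  }
  if (any(obs < 0 | obs > 1)) {
    stop("normalized scores must lie in [0, 1]", call. = FALSE)
  }
  q <- unname(quantile(obs, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  data.frame(tool = tool, n = length(obs),
             n_missing = sum(is.na(scores)),
             min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             range = q[5] - q[1], stringsAsFactors = FALSE)
}

#' Read a wide per-variant prediction table
#'
#' Reads a dbNSFP-style wide table (one row per variant, `<tool>_pred` and/or
#' `<tool>_score` column pairs; tab- or comma-separated, sniffed from the
#' header) and reshapes the categorical calls to long form.
#'
#' @param path file path.
#' @return list with `wide` (the raw table) and `calls` (long `data.frame`:
#'   `variant_id`, `tool`, `call`), where calls are taken verbatim from
#'   `<tool>_pred` columns (already in the common alphabet) and blank/`NA`
#'   entries become `UNKNOWN`.
#' @export
read_prediction_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  wide <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                     check.names = FALSE)
  if (!"variant_id" %in% names(wide)) {
    stop("prediction table must have a variant_id column", call. = FALSE)
  }
  pred_cols <- grep("_pred$", names(wide), value = TRUE)
  calls <- do.call(rbind, lapply(pred_cols, function(col) {
    call <- as.character(wide[[col]])
    call[is.na(call) | !nzchar(call)] <- "UNKNOWN"
    data.frame(variant_id = wide$variant_id,
               tool = sub("_pred$", "", col),
               call = call, stringsAsFactors = FALSE)
  }))
  if (!is.null(calls) && !all(calls$call %in% CALL_LEVELS)) {
    bad <- setdiff(unique(calls$call), CALL_LEVELS)
    stop("calls outside the common alphabet (harmonize first): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  list(wide = wide, calls = calls)
}
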