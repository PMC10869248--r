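#' Score a prediction against functional truth
#'
#' Compares a harmonized categorical call with the functional-assay outcome.
#' The assay terminology equates `RUPTURED` (phenotype not rescued) with
#' pathogenic and `RESCUED` with benign, so:
#' `DELETERIOUS x RUPTURED` and `TOLERATED x RESCUED` give `AGREE`;
#' `DELETERIOUS x RESCUED` and `TOLERATED x RUPTURED` give `DISAGREE`;
#' `VUS` gives `UNCERTAIN` (no binary answer to compare); `UNKNOWN` gives
#' `ABSENT` (no record for that variant/tool).
#'
#' @param call character vector of common-alphabet calls.
#' @param truth character vector of `"RESCUED"` / `"RUPTURED"`, recycled if
#'   length 1.
#' @return character vector of verdicts `AGREE / DISAGREE / UNCERTAIN /
#'   ABSENT`.
#' @export
concordance_call <- function(call, truth) {
  if (length(truth) == 1L) truth <- rep(truth, length(call))
  stopifnot(length(call) == length(truth))
  if (!all(call %in% CALL_LEVELS)) {
    stop("calls outside the common alphabet", call. = FALSE)
  }
  if (!all(truth %in% OUTCOME_LEVELS)) {
    stop("truth outside RESCUED/RUPTURED", call. = FALSE)
  }
  out <- rep("UNCERTAIN", length(call))
  out[call == "UNKNOWN"] <- "ABSENT"
  binary <- call %in% c("DELETERIOUS", "TOLERATED")
  agree <- (call == "DELETERIOUS" & truth == "RUPTURED") |
    (call == "TOLERATED" & truth == "RESCUED")
  out[binary] <- ifelse(agree[binary], "AGREE", "DISAGREE")
  out
}

#' Back-translate a verdict to the underlying call
#'
#' Inverse of [concordance_call()] given the functional outcome: an `AGREE`
#' on a `RUPTURED` variant must have come from a `DELETERIOUS` call, and so
#' on. Used to recover predictor calls from published agreement tables that
#' print verdicts rather than raw calls.
#'
#' @param verdict character vector of verdicts.
#' @param truth character vector of outcomes (recycled if length 1).
#' @return character vector of common-alphabet calls.
#' @export
verdict_to_call <- function(verdict, truth) {
  if (length(truth) == 1L) truth <- rep(truth, length(verdict))
  stopifnot(length(verdict) == length(truth))
  if (!all(verdict %in% VERDICT_LEVELS)) {
    stop("verdicts outside the verdict alphabet", call. = FALSE)
  }
  out <- rep("UNKNOWN", length(verdict))
  out[verdict == "UNCERTAIN"] <- "VUS"
  binary <- verdict %in% c("AGREE", "DISAGREE")
  path_call <- (verdict == "AGREE") == (truth == "RUPTURED")
  out[binary] <- ifelse(path_call[binary], "DELETERIOUS", "TOLERATED")
  out
}

#' Build a long concordance table
#'
#' Joins per-(variant, tool) calls with per-variant functional truth and
#' scores each cell with [concordance_call()].
#'
#' @param calls long `data.frame` with `variant_id`, `tool`, `call`.
#' @param truth `data.frame` with `variant_id`, `outcome`.
#' @return long `data.frame` `variant_id`, `tool`, `outcome`, `call`,
#'   `verdict`.
#' @export
concordance_table <- function(calls, truth) {
  stopifnot(all(c("variant_id", "tool", "call") %in% names(calls)),
            all(c("variant_id", "outcome") %in% names(truth)))
  if (anyDuplicated(truth$variant_id)) {
    stop("duplicate variant_id in truth table", call. = FALSE)
  }
  missing <- setdiff(calls$variant_id, truth$variant_id)
  if (length(missing)) {
    stop("no functional truth for variant(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- calls
  out$outcome <- truth$outcome[match(calls$variant_id, truth$variant_id)]
  out$verdict <- concordance_call(out$call, out$outcome)
  check_cells_unique(out)
  out[c("variant_id", "tool", "outcome", "call", "verdict")]
}

check_cells_unique <- function(tab) {
  key <- paste(tab$variant_id, tab$tool, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("data-integrity error: duplicate (variant, tool) cell(s): ",
         paste(head(gsub("\r", " / ", dup), 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' Per-tool concordance totals
#'
#' Tallies each tool's verdicts across all variants (the summary-row block of
#' an agreement table). The four components sum to the number of variants.
#'
#' @param tab long concordance table (see [concordance_table()]); may also be
#'   any `data.frame` with `variant_id`, `tool`, `verdict`.
#' @return `data.frame`: `tool`, `n_agree`, `n_disagree`, `n_uncertain`,
#'   `n_absent`, `n_variants`, one row per tool in order of first appearance.
#' @export
per_tool_totals <- function(tab) {
  check_cells_unique(tab)
  tools <- unique(tab$tool)
  out <- do.call(rbind, lapply(tools, function(tl) {
    v <- tab$verdict[tab$tool == tl]
    data.frame(tool = tl,
               n_agree = sum(v == "AGREE"),
               n_disagree = sum(v == "DISAGREE"),
               n_uncertain = sum(v == "UNCERTAIN"),
               n_absent = sum(v == "ABSENT"),
               n_variants = length(v), stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Per-variant agreement counts
#'
#' For each variant, counts agreeing and disagreeing tools; `UNCERTAIN` and
#' `ABSENT` verdicts are pooled into `n_else` (the "all else" column of the
#' published layout). `n_agree + n_disagree + n_else` equals the number of
#' tools scored for that variant.
#'
#' @inheritParams per_tool_totals
#' @return `data.frame`: `variant_id`, `n_agree`, `n_disagree`, `n_else`,
#'   `n_tools`, one row per variant in order of first appearance.
#' @export
per_variant_counts <- function(tab) {
  check_cells_unique(tab)
  ids <- unique(tab$variant_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    v <- tab$verdict[tab$variant_id == id]
    data.frame(variant_id = id,
               n_agree = sum(v == "AGREE"),
               n_disagree = sum(v == "DISAGREE"),
               n_else = sum(v %in% c("UNCERTAIN", "ABSENT")),
               n_tools = length(v), stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Three-way triage of inter-tool agreement
#'
#' Assigns each variant to one of three categories from its per-variant
#' counts: `AGREEMENT` when at least `agree_min` tools agree with the assay,
#' `DISAGREEMENT` when no tool agrees, `UNCERTAINTY` otherwise. The defaults
#' (`agree_min = 4`, disagreement at zero agreements) are the simple rule
#' consistent with the published three-block partition of the IRF6 table.
#'
#' @param counts `data.frame` from [per_variant_counts()].
#' @param agree_min minimum number of agreements for the `AGREEMENT` class.
#' @return `counts` with an added `triage` column.
#' @export
triage <- function(counts, agree_min = 4) {
  stopifnot(all(c("variant_id", "n_agree") %in% names(counts)),
            agree_min >= 1)
  counts$triage <- ifelse(counts$n_agree >= agree_min, "AGREEMENT",
                          ifelse(counts$n_agree == 0, "DISAGREEMENT",
                                 "UNCERTAINTY"))
  counts
}

#' Count unanimous calls
#'
#' Number of variants for which every tool with a record (call other than
#' `UNKNOWN`) issued the given call; variants with no non-missing call do not
#' count. A `VUS` breaks unanimity.
#'
#' @param calls long `data.frame` with `variant_id`, `tool`, `call`.
#' @param call the call to test for, default `"DELETERIOUS"`.
#' @return integer count.
#' @export
unanimity_count <- function(calls, call = "DELETERIOUS") {
  stopifnot(call %in% CALL_LEVELS)
  if (nrow(calls) == 0L) return(0L)
  check_cells_unique(calls)
  ids <- unique(calls$variant_id)
  sum(vapply(ids, function(id) {
    cl <- calls$call[calls$variant_id == id]
    cl <- cl[cl != "UNKNOWN"]
    length(cl) > 0L && all(cl == call)
  }, logical(1)))
}

#' False positive rate on experimentally benign variants
#'
#' Fraction of experimentally benign (`RESCUED`) variants that a binary
#' predictor calls pathogenic. With `dedup = TRUE` the table is first
#' collapsed to unique amino-acid changes (a change counts once however many
#' nucleotide variants encode it); calls and outcomes must then be consistent
#' within each change.
#'
#' @param calls `data.frame` with `variant_id`, `aa_change`, and `call`
#'   (binary: `"DELETERIOUS"`/`"PATHOGENIC"` vs `"TOLERATED"`/`"BENIGN"`).
#' @param truth `data.frame` with `variant_id`, `outcome`.
#' @param dedup collapse to unique amino-acid changes first?
#' @return list with `numerator` (benign variants called pathogenic),
#'   `denominator` (benign variants), and `rate`.
#' @export
fpr_on_benign <- function(calls, truth, dedup = FALSE) {
  stopifnot(all(c("variant_id", "aa_change", "call") %in% names(calls)),
            all(c("variant_id", "outcome") %in% names(truth)))
  path_calls <- c("DELETERIOUS", "PATHOGENIC")
  ben_calls <- c("TOLERATED", "BENIGN")
  if (!all(calls$call %in% c(path_calls, ben_calls))) {
    stop("fpr_on_benign needs binary calls for every variant", call. = FALSE)
  }
  df <- merge(calls[c("variant_id", "aa_change", "call")],
              truth[c("variant_id", "outcome")], by = "variant_id",
              sort = FALSE)
  if (nrow(df) != nrow(calls)) {
    stop("every variant needs a truth value", call. = FALSE)
  }
  df$pathogenic_call <- df$call %in% path_calls
  if (dedup) {
    split_df <- split(df, df$aa_change)
    df <- do.call(rbind, lapply(split_df, function(g) {
      if (length(unique(g$pathogenic_call)) > 1L ||
          length(unique(g$outcome)) > 1L) {
        stop("inconsistent call or outcome within amino-acid change ",
             sQuote(g$aa_change[1]), "; cannot deduplicate", call. = FALSE)
      }
      g[1, , drop = FALSE]
    }))
  }
  benign <- df$outcome == "RESCUED"
  denominator <- sum(benign)
  if (denominator == 0L) {
    stop("no experimentally benign variants: FPR undefined", call. = FALSE)
  }
  numerator <- sum(benign & df$pathogenic_call)
  list(numerator = numerator, denominator = denominator,
       rate = numerator / denominator)
}

#' Cross-tabulate variants in a residue region
#'
#' Counts nucleotide variants whose protein position falls in a closed
#' residue range, crossed with functional outcome and (optionally) domain
#' labels.
#'
#' @param variants `data.frame` with `variant_id`, `aa_pos`.
#' @param truth `data.frame` with `variant_id`, `outcome`.
#' @param residue_range closed interval `c(lo, hi)`, `lo <= hi`.
#' @param domains optional `data.frame` with `variant_id`, `domain`.
#' @return list: `n_in_region`, `n_rescued_in_region`, `n_ruptured_in_region`,
#'   and `domain_counts` (named integer vector of in-region variants per
#'   domain; empty when `domains` is `NULL` or the region is empty).
#' @export
region_crosstab <- function(variants, truth, residue_range, domains = NULL) {
  stopifnot(length(residue_range) == 2L,
            residue_range[1] <= residue_range[2],
            all(c("variant_id", "aa_pos") %in% names(variants)))
  df <- merge(variants[c("variant_id", "aa_pos")],
              truth[c("variant_id", "outcome")], by = "variant_id",
              sort = FALSE)
  inreg <- df$aa_pos >= residue_range[1] & df$aa_pos <= residue_range[2]
  sub <- df[inreg, , drop = FALSE]
  domain_counts <- integer(0)
  if (!is.null(domains) && nrow(sub)) {
    sub2 <- merge(sub, domains, by = "variant_id", sort = FALSE)
    tab <- table(sub2$domain)
    domain_counts <- stats::setNames(as.integer(tab), names(tab))
  }
  list(n_in_region = nrow(sub),
       n_rescued_in_region = sum(sub$outcome == "RESCUED"),
       n_ruptured_in_region = sum(sub$outcome == "RUPTURED"),
       domain_counts = domain_counts)
}

#' Write a concordance report
#'
#' Emits the per-variant concordance table as CSV with a footer block of the
#' per-tool summary rows (total agreements, disagreements, uncertainties,
#' absents, variants), and the same content as machine-readable JSON.
#'
#' @param tab long concordance table ([concordance_table()]).
#' @param counts per-variant counts with triage ([triage()]).
#' @param csv_path,json_path output files (either may be `NULL` to skip).
#' @return invisibly, the list written to JSON.
#' @export
write_concordance_report <- function(tab, counts, csv_path = NULL,
                                     json_path = NULL) {
  totals <- per_tool_totals(tab)
  tools <- unique(tab$tool)
  wide <- counts
  for (tl in tools) {
    sub <- tab[tab$tool == tl, ]
    wide[[tl]] <- sub$verdict[match(wide$variant_id, sub$variant_id)]
  }
  wide <- wide[c("variant_id", tools,
                 intersect(c("n_agree", "n_disagree", "n_else", "triage"),
                           names(wide)))]
  if (!is.null(csv_path)) {
    con <- file(csv_path, "w")
    on.exit(close(con))
    write.table(wide, con, sep = ",", row.names = FALSE, quote = FALSE)
    writeLines("", con)
    footer <- data.frame(summary = c("total_agreements", "total_disagreements",
                                     "total_uncertainties", "total_absent",
                                     "total_variants"))
    for (i in seq_along(tools)) {
      footer[[tools[i]]] <- c(totals$n_agree[i], totals$n_disagree[i],
                              totals$n_uncertain[i], totals$n_absent[i],
                              totals$n_variants[i])
    }
    write.table(footer, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  payload <- list(per_variant = wide, per_tool = totals)
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(payload)
}
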