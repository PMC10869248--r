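#' Parse an ANNOVAR-style avinput variant table
#'
#' Reads 5-column avinput lines (chrom, start, end, ref, alt; 1-based
#' inclusive genomic coordinates) into a variant table. Lines starting with
#' `#` and blank lines are ignored. An optional sixth column is taken as the
#' amino-acid-change annotation (e.g. `"R84C"`). Digit-grouping commas in
#' coordinates (`209,796,477`) are stripped on read.
#'
#' Only single-nucleotide substitutions are supported: `ref` and `alt` must
#' be single bases in `A/C/G/T` and `start` must equal `end`.
#'
#' @param lines character vector of raw avinput lines.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `ref`, `alt`,
#'   `variant_id` (`"chrom:start:ref>alt"`), and `aa_change` (`NA` when the
#'   line carries no annotation column), one row per input line, in input
#'   order.
#' @seealso [read_avinput()], [write_avinput()], [parse_aa_change()]
#' @examples
#' parse_avinput("1\t209796477\t209796477\tG\tA\tR84C")
#' @export
parse_avinput <- function(lines) {
  stopifnot(is.character(lines))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 5) {
      stop("avinput parse error at line ", i, ": expected >= 5 tab-separated ",
           "fields, found ", length(fields), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(gsub(",", "", fields[2], fixed = TRUE)))
    end <- suppressWarnings(as.integer(gsub(",", "", fields[3], fixed = TRUE)))
    if (is.na(start) || is.na(end)) {
      stop("avinput parse error at line ", i, ": non-numeric coordinate",
           call. = FALSE)
    }
    ref <- toupper(fields[4])
    alt <- toupper(fields[5])
    if (nchar(ref) != 1L || nchar(alt) != 1L) {
      stop("unsupported variant at line ", i,
           ": only single-nucleotide substitutions are handled", call. = FALSE)
    }
    if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      stop("avinput parse error at line ", i, ": alleles must be A/C/G/T",
           call. = FALSE)
    }
    if (ref == alt) {
      stop("avinput parse error at line ", i, ": ref and alt are identical",
           call. = FALSE)
    }
    if (start != end) {
      stop("unsupported variant at line ", i,
           ": start != end for a single-nucleotide substitution",
           call. = FALSE)
    }
    data.frame(chrom = fields[1], start = start, end = end,
               ref = ref, alt = alt,
               aa_change = if (length(fields) >= 6 && nzchar(fields[6]))
                 fields[6] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      ref = character(), alt = character(),
                      aa_change = character(), stringsAsFactors = FALSE)
  }
  out$variant_id <- variant_id(out)
  out[c("chrom", "start", "end", "ref", "alt", "variant_id", "aa_change")]
}

#' @rdname parse_avinput
#' @param path path to an avinput file.
#' @export
read_avinput <- function(path) parse_avinput(readLines(path))

#' Write a variant table in avinput format
#'
#' Inverse of [parse_avinput()]: emits tab-separated 5-column lines, with the
#' `aa_change` annotation as a sixth column when present.
#'
#' @param variants variant `data.frame` as returned by [parse_avinput()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the character vector
#'   of avinput lines.
#' @export
write_avinput <- function(variants, path = NULL) {
  ann <- !is.null(variants$aa_change) & !is.na(variants$aa_change)
  lines <- paste(variants$chrom, variants$start, variants$end,
                 variants$ref, variants$alt, sep = "\t")
  lines[ann] <- paste(lines[ann], variants$aa_change[ann], sep = "\t")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

variant_id <- function(variants) {
  paste0(variants$chrom, ":", variants$start, ":",
         variants$ref, ">", variants$alt)
}

#' Parse amino-acid-change tokens
#'
#' Splits tokens of the form `"R84C"` (reference residue, 1-based protein
#' position, alternate residue) into their components. Vectorized.
#'
#' @param token character vector of tokens.
#' @return `data.frame` with columns `aa_ref`, `aa_pos`, `aa_alt`.
#' @examples
#' parse_aa_change(c("R84C", "S424L"))
#' @export
parse_aa_change <- function(token) {
  stopifnot(is.character(token))
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed amino-acid-change token: ",
         paste(sQuote(token[bad]), collapse = ", "), call. = FALSE)
  }
  aa_pos <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (any(aa_pos < 1L)) {
    stop("amino-acid position must be >= 1", call. = FALSE)
  }
  data.frame(aa_ref = toupper(vapply(m, `[`, character(1), 2)),
             aa_pos = aa_pos,
             aa_alt = toupper(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Collapse genomic variants to unique protein changes
#'
#' Several nucleotide substitutions can encode the same amino-acid change
#' (codon redundancy); this collapses a variant table to its unique protein
#' changes and counts how many genomic variants map to each.
#'
#' @param variants variant `data.frame` with an `aa_change` column
#'   ([parse_avinput()] output with annotations).
#' @return `data.frame` with one row per unique change, in order of first
#'   appearance: `aa_change`, `aa_ref`, `aa_pos`, `aa_alt`, `n_genomic`.
#'   The `n_genomic` column sums to `nrow(variants)`.
#' @export
dedup_to_protein_changes <- function(variants) {
  if (nrow(variants) == 0L) {
    return(data.frame(aa_change = character(), aa_ref = character(),
                      aa_pos = integer(), aa_alt = character(),
                      n_genomic = integer(), stringsAsFactors = FALSE))
  }
  if (any(is.na(variants$aa_change))) {
    stop("all variants must carry an aa_change annotation", call. = FALSE)
  }
  uniq <- variants$aa_change[!duplicated(variants$aa_change)]
  parts <- parse_aa_change(uniq)
  data.frame(aa_change = uniq, parts,
             n_genomic = as.integer(table(variants$aa_change)[uniq]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize free-text clinical-significance labels
#'
#' Case-insensitive normalization of ClinVar-style labels onto the ordered
#' alphabet `BENIGN < LIKELY_BENIGN < VUS < LIKELY_PATHOGENIC < PATHOGENIC`,
#' plus `CONFLICTING` (any label containing "conflicting") and `ABSENT`
#' (empty or `NA`).
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized categories.
#' @export
normalize_clinsig <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(raw))
  out[is.na(raw) | raw == "" | raw %in% c("na", "n/a")] <- "ABSENT"
  out[grepl("conflicting", raw)] <- "CONFLICTING"
  fill <- is.na(out)
  out[fill & grepl("likely[ _]benign", raw)] <- "LIKELY_BENIGN"
  out[fill & grepl("likely[ _]pathogenic", raw)] <- "LIKELY_PATHOGENIC"
  fill <- is.na(out)
  out[fill & grepl("benign", raw)] <- "BENIGN"
  out[fill & grepl("pathogenic", raw)] <- "PATHOGENIC"
  fill <- is.na(out)
  out[fill & (grepl("uncertain", raw) | raw == "vus")] <- "VUS"
  if (any(is.na(out))) {
    stop("unrecognized clinical-significance label: ",
         paste(sQuote(unique(x[is.na(out)])), collapse = ", "), call. = FALSE)
  }
  out
}

#' Filter ClinVar-like records for analysis
#'
#' Applies the preprocessing gate of the workflow: keeps only nonsynonymous
#' records on the requested transcript that carry a usable clinical
#' significance. Records that are `CONFLICTING` or `ABSENT`, synonymous
#' (identical reference and alternate residue), or annotated on a different
#' transcript are dropped.
#'
#' @param records `data.frame` with columns `variant_id`, `transcript`,
#'   `aa_change`, `clinical_significance` (free text, normalized internally).
#' @param transcript transcript identifier to retain (exact match, e.g.
#'   `"NM_006147.4"`).
#' @return The filtered subset with `clinical_significance` replaced by its
#'   normalized category.
#' @export
filter_clinvar_records <- function(records, transcript) {
  stopifnot(all(c("variant_id", "transcript", "aa_change",
                  "clinical_significance") %in% names(records)))
  records$clinical_significance <-
    normalize_clinsig(records$clinical_significance)
  keep <- records$clinical_significance %in% CLINSIG_ORDER &
    records$transcript == transcript
  aa_ok <- grepl("^([A-Za-z])([0-9]+)([A-Za-z])$", records$aa_change)
  nonsyn <- rep(FALSE, nrow(records))
  if (any(aa_ok)) {
    parts <- parse_aa_change(records$aa_change[aa_ok])
    nonsyn[aa_ok] <- parts$aa_ref != parts$aa_alt
  }
  out <- records[keep & nonsyn, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Map clinical-significance categories to pathogenicity scores
#'
#' Converts the five-level clinical alphabet to a numeric score in `[0, 1]`,
#' strictly increasing in risk. The default mapping is evenly spaced and
#' endpoint-anchored: B = 0, LB = 0.25, VUS = 0.5, LP = 0.75, P = 1.
#'
#' @param category character vector of normalized categories (see
#'   [normalize_clinsig()]).
#' @param mapping named numeric vector over the five categories; must be
#'   strictly increasing along the risk order with endpoints 0 and 1.
#' @return numeric vector of scores.
#' @export
clinsig_to_score <- function(category,
                             mapping = c(BENIGN = 0, LIKELY_BENIGN = 0.25,
                                         VUS = 0.5, LIKELY_PATHOGENIC = 0.75,
                                         PATHOGENIC = 1)) {
  stopifnot(setequal(names(mapping), CLINSIG_ORDER))
  ordered <- mapping[CLINSIG_ORDER]
  if (any(diff(ordered) <= 0) || ordered[[1]] != 0 || ordered[[5]] != 1) {
    stop("mapping must be strictly increasing from 0 (BENIGN) to 1 ",
         "(PATHOGENIC)", call. = FALSE)
  }
  bad <- !category %in% CLINSIG_ORDER
  if (any(bad)) {
    stop("no score defined for category: ",
         paste(sQuote(unique(category[bad])), collapse = ", "), call. = FALSE)
  }
  unname(mapping[category])
}

#' Map functional-assay outcomes to pathogenicity scores
#'
#' Phenotype-rescue outcomes are binary: `RESCUED` (experimentally benign)
#' maps to 0 and `RUPTURED` (experimentally pathogenic) to 1, the endpoints
#' used when painting structures.
#'
#' @param outcome character vector of `"RESCUED"` / `"RUPTURED"`.
#' @return numeric vector of 0/1 scores.
#' @export
functional_to_score <- function(outcome) {
  bad <- !outcome %in% OUTCOME_LEVELS
  if (any(bad)) {
    stop("unknown functional outcome: ",
         paste(sQuote(unique(outcome[bad])), collapse = ", "), call. = FALSE)
  }
  ifelse(outcome == "RUPTURED", 1, 0)
}
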