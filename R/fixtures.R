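# Loaders for the packaged IRF6 case-study tables: the 37 genomic missense
# variants with their 33 amino-acid changes, the 6-column agreement table
# (five predictors plus a ClinVar column) with functional-assay outcomes and
# domain labels, and the AlphaMissense binary calls.

FIXTURE_TOOLS <- c("sift", "polyphen2", "mutationtaster", "mutationassessor",
                   "intervar", "clinvar")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "varmap3d")
  if (!nzchar(path)) stop("fixture file not found: ", file, call. = FALSE)
  path
}

verdict_from_symbol <- function(x) {
  map <- c(Yes = "AGREE", No = "DISAGREE", VUS = "UNCERTAIN", `N/A` = "ABSENT")
  bad <- !x %in% names(map)
  if (any(bad)) {
    stop("unknown verdict symbol: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(map[x])
}

#' Load a packaged case-study fixture
#'
#' Returns the packaged IRF6 tables:
#' \describe{
#'   \item{`table1_variants`}{37 genomic missense variants (GRCh38,
#'     transcript NM_006147.4): `chrom`, `start`, `end`, `ref`, `alt`,
#'     `variant_id`, `aa_change`, `aa_ref`, `aa_pos`, `aa_alt`.}
#'   \item{`table3_calls`}{per-variant verdicts of SIFT, PolyPhen-2,
#'     MutationTaster, MutationAssessor, InterVar and ClinVar against the
#'     phenotype-rescue assay, as `AGREE/DISAGREE/UNCERTAIN/ABSENT`, plus
#'     `functional_result`, `domain` and the published triage `block`.}
#'   \item{`functional_results`}{`variant_id`, `aa_change`, `outcome`
#'     (`RESCUED`/`RUPTURED`).}
#'   \item{`domain_labels`}{`variant_id`, `aa_change`, `domain`.}
#'   \item{`alphamissense_calls`}{`variant_id`, `aa_change`, `call`
#'     (`PATHOGENIC`/`BENIGN`).}
#' }
#'
#' @param name one of the fixture names above.
#' @return a `data.frame`.
#' @export
load_fixture <- function(name = c("table1_variants", "table3_calls",
                                  "functional_results", "domain_labels",
                                  "alphamissense_calls")) {
  name <- match.arg(name)
  if (name == "table1_variants") {
    df <- read.delim(fixture_path("table1_variants.tsv"),
                     stringsAsFactors = FALSE, colClasses = "character")
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    df$variant_id <- variant_id(df)
    return(cbind(df, parse_aa_change(df$aa_change)))
  }
  if (name == "alphamissense_calls") {
    return(read.delim(fixture_path("alphamissense_calls.tsv"),
                      stringsAsFactors = FALSE))
  }
  t3 <- read.delim(fixture_path("table3_calls.tsv"),
                   stringsAsFactors = FALSE, na.strings = NULL)
  t3$functional_result <- toupper(t3$functional_result)
  for (tool in FIXTURE_TOOLS) t3[[tool]] <- verdict_from_symbol(t3[[tool]])
  switch(name,
    table3_calls = t3,
    functional_results = data.frame(variant_id = t3$variant_id,
                                    aa_change = t3$aa_change,
                                    outcome = t3$functional_result,
                                    stringsAsFactors = FALSE),
    domain_labels = data.frame(variant_id = t3$variant_id,
                               aa_change = t3$aa_change,
                               domain = t3$domain, stringsAsFactors = FALSE))
}

#' Long concordance table for the packaged case study
#'
#' Reshapes the wide fixture table to the long per-(variant, tool) layout
#' the concordance functions consume, and back-translates each verdict into
#' the predictor call that produced it (given the functional outcome), so
#' the same data exercise both the verdict and the call direction.
#'
#' @param tools subset of the six fixture tools; default = all.
#' @return long `data.frame`: `variant_id`, `aa_change`, `tool`, `outcome`,
#'   `verdict`, `call`.
#' @export
fixture_concordance_table <- function(tools = FIXTURE_TOOLS) {
  stopifnot(all(tools %in% FIXTURE_TOOLS))
  t3 <- load_fixture("table3_calls")
  out <- do.call(rbind, lapply(tools, function(tool) {
    data.frame(variant_id = t3$variant_id, aa_change = t3$aa_change,
               tool = tool, outcome = t3$functional_result,
               verdict = t3[[tool]],
               call = verdict_to_call(t3[[tool]], t3$functional_result),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
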