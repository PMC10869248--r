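test_that("calls score against functional truth per the agreement rule", {
  expect_equal(concordance_call("DELETERIOUS", "RUPTURED"), "AGREE")
  expect_equal(concordance_call("TOLERATED", "RESCUED"), "AGREE")
  expect_equal(concordance_call("DELETERIOUS", "RESCUED"), "DISAGREE")
  expect_equal(concordance_call("TOLERATED", "RUPTURED"), "DISAGREE")
  expect_equal(concordance_call("VUS", "RESCUED"), "UNCERTAIN")
  expect_equal(concordance_call("UNKNOWN", "RUPTURED"), "ABSENT")
})

test_that("verdict back-translation inverts concordance scoring", {
  grid <- expand.grid(call = c("DELETERIOUS", "TOLERATED", "VUS", "UNKNOWN"),
                      truth = c("RESCUED", "RUPTURED"),
                      stringsAsFactors = FALSE)
  verdict <- concordance_call(grid$call, grid$truth)
  expect_equal(verdict_to_call(verdict, grid$truth), grid$call)
})

test_that("agreement verdicts are invariant to flipping predictions and truth together", {
  set.seed(9)
  call <- sample(c("DELETERIOUS", "TOLERATED"), 60, TRUE)
  truth <- sample(c("RESCUED", "RUPTURED"), 60, TRUE)
  flip_call <- ifelse(call == "DELETERIOUS", "TOLERATED", "DELETERIOUS")
  flip_truth <- ifelse(truth == "RESCUED", "RUPTURED", "RESCUED")
  expect_equal(concordance_call(call, truth),
               concordance_call(flip_call, flip_truth))
})

test_that("per-tool totals reproduce the published summary rows", {
  totals <- per_tool_totals(fixture_concordance_table())
  get <- function(tool) unlist(totals[totals$tool == tool,
                                      c("n_agree", "n_disagree",
                                        "n_uncertain", "n_absent")],
                               use.names = FALSE)
  expect_equal(get("sift"), c(18, 19, 0, 0))
  expect_equal(get("polyphen2"), c(17, 20, 0, 0))
  expect_equal(get("mutationtaster"), c(20, 17, 0, 0))
  expect_equal(get("mutationassessor"), c(7, 9, 21, 0))
  expect_equal(get("intervar"), c(4, 4, 29, 0))
  expect_equal(get("clinvar"), c(6, 5, 2, 24))
  expect_true(all(rowSums(totals[c("n_agree", "n_disagree", "n_uncertain",
                                   "n_absent")]) == 37))
})

test_that("per-variant counts match the published rows and partition the tools", {
  tab <- fixture_concordance_table()
  counts <- per_variant_counts(tab)
  aa <- tab$aa_change[match(counts$variant_id, tab$variant_id)]
  row <- function(change) unlist(counts[match(change, aa),
                                        c("n_agree", "n_disagree", "n_else")],
                                 use.names = FALSE)
  expect_equal(row("R84C"), c(6, 0, 0))
  expect_equal(row("V274I"), c(4, 2, 0))
  expect_equal(row("P222L"), c(1, 3, 2))
  expect_equal(row("R400Q"), c(1, 4, 1))
  expect_true(all(counts$n_agree + counts$n_disagree + counts$n_else ==
                    counts$n_tools))
})

test_that("duplicate (variant, tool) cells raise an integrity error", {
  tab <- fixture_concordance_table()
  expect_error(per_tool_totals(rbind(tab, tab[1, ])), "duplicate")
  expect_error(per_variant_counts(rbind(tab, tab[1, ])), "integrity")
})

test_that("triage reproduces the three-block partition of the case study", {
  tab <- fixture_concordance_table()
  counts <- triage(per_variant_counts(tab))
  expect_equal(sum(counts$triage == "AGREEMENT"), 7L)
  expect_equal(sum(counts$triage == "UNCERTAINTY"), 18L)
  expect_equal(sum(counts$triage == "DISAGREEMENT"), 12L)
  # every variant lands in exactly one category
  expect_true(all(counts$triage %in% c("AGREEMENT", "UNCERTAINTY",
                                       "DISAGREEMENT")))
  # the published block labels agree row by row
  t3 <- load_fixture("table3_calls")
  expect_equal(counts$triage[match(t3$variant_id, counts$variant_id)],
               toupper(t3$block))
  expect_equal(triage(data.frame(variant_id = "v", n_agree = 6))$triage,
               "AGREEMENT")
  expect_equal(triage(data.frame(variant_id = "v", n_agree = 0))$triage,
               "DISAGREEMENT")
  expect_equal(triage(data.frame(variant_id = "v", n_agree = 3))$triage,
               "UNCERTAINTY")
})

test_that("unanimity counting matches a brute-force scan of the call matrix", {
  calls <- fixture_concordance_table(fixture_tools5)[
    c("variant_id", "tool", "call")]
  # oracle: brute-force over variants
  ids <- unique(calls$variant_id)
  oracle <- sum(vapply(ids, function(id) {
    cl <- calls$call[calls$variant_id == id]
    cl <- cl[cl != "UNKNOWN"]
    length(cl) > 0 && all(cl == "DELETERIOUS")
  }, logical(1)))
  expect_equal(unanimity_count(calls), oracle)
  one <- data.frame(variant_id = c("a", "b"), tool = "t",
                    call = "DELETERIOUS")
  expect_equal(unanimity_count(one), 2L)
  expect_equal(unanimity_count(calls[0, ]), 0L)
})

test_that("false positive rate on benign variants matches the case-study counts", {
  truth <- load_fixture("functional_results")
  am <- load_fixture("alphamissense_calls")
  f <- fpr_on_benign(am, truth)
  expect_equal(f$numerator, 15L)
  expect_equal(f$denominator, 18L)
  expect_equal(f$rate, 15 / 18)
  fd <- fpr_on_benign(am, truth, dedup = TRUE)
  expect_equal(fd$numerator, 14L)
  expect_equal(fd$denominator, 17L)
  expect_equal(fd$rate, 14 / 17)
})

test_that("FPR is invariant to row order and id relabeling, and handles edge cases", {
  truth <- load_fixture("functional_results")
  am <- load_fixture("alphamissense_calls")
  set.seed(3)
  perm <- sample(nrow(am))
  f1 <- fpr_on_benign(am[perm, ], truth)
  expect_equal(f1$rate, 15 / 18)
  relab <- function(df) {
    df$variant_id <- paste0("x_", df$variant_id); df
  }
  f2 <- fpr_on_benign(relab(am), relab(truth))
  expect_equal(f2$rate, 15 / 18)
  all_ben <- data.frame(variant_id = letters[1:3], aa_change = LETTERS[1:3],
                        call = "BENIGN")
  tr <- data.frame(variant_id = letters[1:3], outcome = "RESCUED")
  expect_equal(fpr_on_benign(all_ben, tr)$rate, 0)
  tr2 <- data.frame(variant_id = letters[1:3], outcome = "RUPTURED")
  expect_error(fpr_on_benign(all_ben, tr2), "undefined")
})

test_that("region crosstab counts variants and outcomes in a residue window", {
  v <- load_fixture("table1_variants")
  truth <- load_fixture("functional_results")
  rc <- region_crosstab(v, truth, c(74, 274), load_fixture("domain_labels"))
  expect_equal(rc$n_in_region, 14L)
  expect_equal(rc$n_rescued_in_region, 8L)
  expect_equal(rc$n_ruptured_in_region, 6L)
  expect_equal(sum(rc$domain_counts), 14L)
  empty <- region_crosstab(v, truth, c(1000, 2000))
  expect_equal(empty$n_in_region, 0L)
  expect_equal(empty$n_rescued_in_region, 0L)
  expect_length(empty$domain_counts, 0L)
  expect_error(region_crosstab(v, truth, c(10, 5)))
})

test_that("estimated FPR on synthetic panels converges to 1 - specificity", {
  n <- 2000
  truth <- data.frame(variant_id = paste0("v", 1:n), label = "benign")
  panel <- list(tool = list(sensitivity = 0.9, specificity = 0.7))
  wide <- simulate_predictor_panel(truth, panel, seed = 404)
  calls <- data.frame(variant_id = wide$variant_id,
                      aa_change = wide$variant_id,
                      call = wide$tool_pred)
  tr <- data.frame(variant_id = wide$variant_id, outcome = "RESCUED")
  f <- fpr_on_benign(calls, tr)
  sd3 <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(f$rate - 0.3), sd3)
})
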