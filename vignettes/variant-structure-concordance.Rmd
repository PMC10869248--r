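---
title: "Benchmarking pathogenicity predictors and mapping variants onto protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking pathogenicity predictors and mapping variants onto protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmap3d)
```

## The problem

For most genes, in-silico pathogenicity predictors are the only scalable
source of evidence about missense variants, but their reliability is
gene-specific and rarely known. When a functional assay exists — here, the
phenotype-rescue experiment in *irf6*−/− zebrafish that classified 37 IRF6
missense variants as *rescued* (benign) or *ruptured* (pathogenic) — one can
measure predictor performance directly, and ask whether the 3D location of a
variant carries signal the sequence-based tools miss. `varmap3d` implements
that workflow: harmonize predictions, tabulate concordance with truth, paint
outcomes onto a predicted structure, and test for spatial clustering.

## Variant preprocessing

Variants arrive as 5-column avinput tables (chrom, start, end, ref, alt;
1-based inclusive, GRCh38) with amino-acid-change annotations. Coordinates
printed with digit-grouping commas are normalized on read. Only
single-nucleotide substitutions are accepted; records with conflicting or
absent clinical significance, synonymous changes, and off-transcript
annotations are dropped by `filter_clinvar_records()` before analysis.
Because of codon redundancy, several nucleotide variants can encode one
protein change; `dedup_to_protein_changes()` collapses the 37 case-study
variants to 33 unique changes (G70R ×2, F252L ×3, Q318H ×2):

```{r dedup}
variants <- load_fixture("table1_variants")
d <- dedup_to_protein_changes(variants)
nrow(d)
d[d$n_genomic > 1, c("aa_change", "n_genomic")]
```

Ordinal clinical-significance categories map to scores by an evenly spaced,
endpoint-anchored scale (B = 0, LB = 0.25, VUS = 0.5, LP = 0.75, P = 1).
The exact spacing is a convention — any strictly increasing,
endpoint-anchored map preserves the ordinal content — so the mapping is
configurable but fixed by default. Functional outcomes are binary and map to
the endpoints: rescued → 0, ruptured → 1.

## Concordance model

Categorical calls are first harmonized onto a four-letter alphabet
(deleterious / tolerated / VUS / unknown) via per-tool vocabularies; graded
middle categories (MutationAssessor "medium", InterVar "uncertain
significance") map to VUS because they decline to give a binary answer.
Each (variant, tool) cell is then scored against truth: agree, disagree,
uncertain (VUS), or absent (no record). The published case-study table
prints verdicts rather than raw calls, so the fixture stores the verdicts
verbatim and back-translates them to calls given the outcome
(`verdict_to_call()`); re-scoring those calls regenerates the verdicts
exactly, which doubles as an integrity check on the packaged data.

```{r concordance}
tab <- fixture_concordance_table()
per_tool_totals(tab)
```

Per-variant counts feed a three-way triage. The published table does not
state its thresholds; the rule used here — AGREEMENT when ≥ 4 of the six
columns agree, DISAGREEMENT when none do, UNCERTAINTY otherwise — is the
unique simple rule that reproduces the published 7 / 18 / 12 block structure
row for row, and both thresholds are arguments of `triage()`.

```{r triage}
table(triage(per_variant_counts(tab))$triage)
```

The false positive rate on experimentally benign variants uses the benign
(rescued) set as denominator: for AlphaMissense, 15 of the 18 rescued
variants are called pathogenic (83.3%); collapsing redundant nucleotide
variants first gives 14/17 (82.4%).

Quantitative scores are normalized to [0, 1] by an affine min–max map,
using the tool's declared output range when known and the observed range
otherwise; both modes are exposed because published figures rarely say which
was used. Missing scores are counted but excluded — imputing 0 would
conflate "no data" with "confidently benign". Summaries use type-7
(linear-interpolation) quartiles.

## Structure mapping

`annotate_bfactor()` writes per-residue scores into the B-factor field
(columns 61–66, `%6.2f`) of every atom of the residue, after validating
residue number and identity against the model — the validation step that
catches off-by-one numbering or wrong-isoform errors before they silently
produce a miscolored structure. Unlisted residues receive a configurable
default of 0.5, chosen as the VUS-neutral midpoint so that painted and
unpainted residues are distinguishable in a viewer. The original B-factors
(pLDDT in predicted models) are deliberately discarded with a notice;
`extract_plddt()` reads them out first when confidence filtering is wanted
(default threshold 70, the usual low-confidence boundary). The PDB editor
preserves every byte it does not own: annotation changes only columns 61–66
of ATOM lines, and read/write round-trips files exactly.

## Geometry

Superposition uses the closed-form Kabsch algorithm on paired Cα atoms,
restricted to proper rotations (the reflected solution is never returned).
Residues are paired by residue number, which is appropriate for models of
the same sequence in one numbering frame; sequence alignment is out of
scope. `iterative_align()` adds outlier rejection — refit, drop pairs whose
post-fit distance exceeds mean + 2 SD, repeat up to 5 cycles — emulating the
refinement loops of interactive aligners. Published RMSDs obtained with such
tools depend on their matching heuristics, so this procedure is documented
as an approximation and exact reproduction of viewer-derived values is not a
goal; the implementation is instead validated against a brute-force
rotational minimization oracle (agreement to 1e-4 Å on small random sets)
and by exact invariance (1e-8 Å) under rigid motions of either input.
Degenerate inputs (fewer than 3 pairs, collinear configurations) raise
errors rather than returning an arbitrary rotation.

The clustering question — do pathogenic variants sit closer together in the
fold than benign ones? — is answered by a permutation test conditioned on
the observed variant positions: the statistic is the mean pairwise Cα
distance among pathogenic-labeled variant residues (mean nearest-neighbor
distance is available as an alternative), and the null permutes the
pathogenic/benign labels over the same residue set. This tests label
clustering, not variant placement, which is the clinically relevant
question. The one-sided p-value uses the add-one estimator
(1 + #{null ≤ obs}) / (1 + n_perm), which can never return 0; small cases
can be enumerated exhaustively (`exact = TRUE`). Domain enrichment uses an
exact two-sided hypergeometric test computed by direct summation of all
tables no more probable than the observed one.

```{r cluster}
model <- make_helix_structure(200)
lab <- simulate_variant_labels(200, 20, 0.5, mode = "clustered",
                               cluster_width = 20, seed = 17)
cluster_permutation_test(model, lab$res_num, lab$label,
                         n_perm = 999, seed = 17)
```

## What the synthetic data emulate — and what they do not

The generators produce Cα-only traces: an ideal α-helix (residue *i* at
radius 2.3 Å, 100° per turn, 1.5 Å rise, giving the canonical ~3.8 Å
consecutive spacing) and a seeded self-avoiding walk with 3.8 Å steps. They
give every structural routine a fully controlled geometry: clustered label
placement puts all pathogenic variants in one contiguous window so the
cluster test has a known positive, dispersed placement gives a calibrated
null. Predictor panels draw VUS/missing states first and then a binary call
that is correct with the configured sensitivity or specificity, so estimated
error rates converge to their nominal values (checked at binomial
tolerance).

What they do not emulate: real tertiary structure (long-range contacts that
make sequence-distant residues spatially close — the very signal of
interest in real proteins), side chains, multiple chains, alternate
locations, or correlated predictor errors (real tools share training data
and features; the simulated tools err independently). Passing tests on
synthetic data therefore validate the machinery and its calibration, not
any biological claim about a particular protein.

## Problem sizes and numerical choices

The test suite runs the full fixture tabulations (37 variants × 6 tools),
Kabsch-vs-oracle comparisons on random sets of up to 8 points, outlier
recovery on 100-point pairings, null calibration of the cluster test over
200 simulations of 199 permutations each on a 150-residue trace, and exact
hypergeometric enumeration up to n = 30 — sizes chosen so the whole suite
completes in seconds while every code path, including the permutation
machinery, is exercised at meaningful depth. Tie handling in the permutation
test counts null values within 1e-12 of the observed statistic as "≤", so
exact ties (common on symmetric synthetic geometries) are not dropped by
floating-point accident.

## Known limitations

Residue pairing requires a shared numbering frame; no sequence or flexible
alignment is attempted. Only PDB input is supported (not mmCIF), matching
the format of the case-study models. Multi-chain structures need an explicit
chain selector (default: first chain), as the intended inputs are monomeric
predicted models. The concordance layer treats every tool's harmonized call
as one vote; it deliberately implements no ROC/AUC machinery over
quantitative thresholds, and no statistical comparison of tools beyond the
tabulations described.
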