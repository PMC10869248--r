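# varmap3d

Clinical variant interpretation leans heavily on in-silico pathogenicity
predictors, yet for any given gene their calls can diverge sharply from what
functional assays show. `varmap3d` is an R package for quantifying that
divergence and for bringing protein structure into the picture. It is aimed
at clinical genetics and structural bioinformatics groups who have (a) a set
of missense variants with functional-assay truth, (b) categorical and/or
quantitative predictions from tools such as SIFT, PolyPhen-2, MutationTaster
or AlphaMissense, and (c) a predicted protein structure (AlphaFold-style PDB
with pLDDT in the B-factor column).

The package ships the IRF6 case study as plain-text fixtures: 37 genomic
missense variants (33 unique amino-acid changes, transcript NM_006147.4,
GRCh38) whose pathogenicity was established by phenotype-rescue experiments
in *irf6*−/− zebrafish ("rescued" = experimentally benign, "ruptured" =
experimentally pathogenic), together with the published per-variant verdicts
of five predictors and ClinVar.

## What it computes

**Concordance.** Each harmonized call *c* ∈ {deleterious, tolerated, VUS,
unknown} is scored against truth *t* ∈ {rescued, ruptured} as agree /
disagree / uncertain / absent. From the per-cell verdicts the package
rebuilds per-tool totals, per-variant counts (#agree, #disagree, #else), a
three-way triage (agreement if #agree ≥ 4, disagreement if #agree = 0, else
uncertainty), unanimity counts, residue-region crosstabs, and the false
positive rate on experimentally benign variants,
FPR = #(benign called pathogenic) / #benign, with optional collapsing of
redundant nucleotide variants to unique amino-acid changes.

**Structure mapping.** Per-residue pathogenicity scores in [0, 1] are painted
into the PDB B-factor field (columns 61–66, `%6.2f`), after validating that
each entry's residue number and residue type match the model; everything
else in the file is preserved byte-for-byte.

**Geometry.** Kabsch least-squares superposition (proper rotations only)
with iterative outlier rejection (drop pairs beyond mean + 2 SD of post-fit
distance, up to 5 cycles), Cα distance matrices, a label-permutation test
for 3D clustering of pathogenic residues (statistic: mean pairwise Cα
distance among pathogenic variant residues; one-sided
p = (1 + #{null ≤ obs}) / (1 + n_perm)), and exact two-sided hypergeometric
tests for domain enrichment.

**Synthetic data.** Ideal α-helix and self-avoiding-chain Cα traces,
clustered/dispersed variant-label placement, and predictor panels with
configurable sensitivity, specificity, VUS and missing rates — enough to
exercise every stage without downloads.

## Worked example

```r
library(varmap3d)

variants <- load_fixture("table1_variants")
nrow(dedup_to_protein_changes(variants))
#> [1] 33

tab <- fixture_concordance_table()
per_tool_totals(tab)
#>               tool n_agree n_disagree n_uncertain n_absent n_variants
#> 1             sift      18         19           0        0         37
#> 2        polyphen2      17         20           0        0         37
#> 3   mutationtaster      20         17           0        0         37
#> 4 mutationassessor       7          9          21        0         37
#> 5         intervar       4          4          29        0         37
#> 6          clinvar       6          5           2       24         37

table(triage(per_variant_counts(tab))$triage)
#>    AGREEMENT DISAGREEMENT  UNCERTAINTY
#>            7           12           18

truth <- load_fixture("functional_results")
f <- fpr_on_benign(load_fixture("alphamissense_calls"), truth)
sprintf("FPR %d/%d = %.1f%%", f$numerator, f$denominator, 100 * f$rate)
#> [1] "FPR 15/18 = 83.3%"
```

MutationTaster agrees with the assay on 20 of 37 variants — the best of the
panel — while 12 of the 37 variants (all experimentally benign) are placed
in computational disagreement: every tool called them pathogenic or
uncertain. AlphaMissense misclassifies 15 of the 18 experimentally benign
variants as pathogenic.

The structural side, on a synthetic benchmark:

```r
model <- make_helix_structure(200)
lab <- simulate_variant_labels(200, 20, 0.5, mode = "clustered",
                               cluster_width = 20, seed = 17)
cluster_permutation_test(model, lab$res_num, lab$label,
                         n_perm = 999, seed = 17)
#> <cluster_test> observed 9.956 A (mean_pairwise), p = 0.001 [999 perms]
```

Pathogenic labels packed into a 20-residue window sit far closer together
than label permutation would predict.

The end-to-end pipeline (`run_pipeline(fixture_run_config("out/"))`) writes
the concordance CSV/JSON with the per-tool summary footer, a painted PDB,
the cluster-test JSON, and a manifest; a thin command-line wrapper with
`annotate`, `align`, `cluster`, `simulate` and `run` subcommands lives at
`inst/cli/varmap3d.R`.

## Not in scope

The package consumes ANNOVAR/dbNSFP-style tables and PDB files; it does not
run predictors, predict structures, query population databases, or render
molecular graphics (painted PDBs are meant for pyMOL/VMD and friends).
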