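# egfrsf

Structure–function classification of EGFR kinase-domain mutations and
tyrosine-kinase-inhibitor (TKI) selectivity analysis.

## The problem

Most patients with *EGFR*-mutant non-small cell lung cancer carry the
"classical" alterations — L858R or exon 19 deletions — for which TKI choice
is well established. Roughly a third instead carry atypical kinase-domain
mutations (exons 18–21), and for these, treatment decisions have
traditionally been guided by the mutated exon, even though drug sensitivity
is heterogeneous within an exon. A structural view groups mutations by
their predicted effect on the drug-binding pocket instead:

- **classical-like** — distant from the ATP-binding pocket, behaving like
  L858R (broadly TKI-sensitive, most selective for third-generation TKIs);
- **T790M-like** — hydrophobic-core mutations, subdivided into
  third-generation-sensitive (**3S**) and third-generation-resistant
  (**3R**, with co-occurring C797X/L718X/L792X) alleles;
- **Ex20ins-L** — insertions in the loop C-terminal to the αC-helix
  (A767–V774), subdivided into near-loop (**NL**, anchors 767–770) and
  far-loop (**FL**, 771–774), sensitive mainly to Ex20ins-active agents;
- **PACC** — P-loop and αC-helix compressing mutations spanning exons
  18–21 (G719X, L718Q, S768I, T854I, L747P, …), most selective for
  second-generation (covalent) TKIs.

`egfrsf` implements this classification as an ordered, traceable rule
engine over parsed protein-variant strings, plus every quantitative step
used to validate it:

- **Screen analysis** — DMSO normalization, 4-parameter logistic
  dose–response fits with absolute IC50 interpolation at 50% inhibition,
  mutant/wild-type selectivity ratios, the median log10(Mut/WT) selectivity
  matrix, Euclidean hierarchical clustering, and Welch ANOVA with
  Holm–Šidák pairwise comparisons between drug classes.
- **Predictiveness** — does the structure grouping predict selectivity
  better than the exon grouping? Per-mutation Spearman ρ against
  leave-one-out group mean profiles compared by a paired t-test, and
  per-drug CART regression trees (goodness-of-split ΔSS, variable
  importance scaled to sum 100).
- **Outcomes** — Kaplan–Meier medians, two-sided Mantel–Cox log-rank tests
  with (O₁/E₁)/(O₂/E₂) hazard ratios, stratified layouts, and
  Fisher-exact objective-response-rate comparisons.
- **Synthetic data** — mutation panels, raw 7-dose triplicate viability
  screens and right-censored exponential survival cohorts with known
  ground truth, so the entire pipeline is testable without clinical data.

## Worked example

```r
library(egfrsf)

classify_allele("L858R+T790M+C797S")
#> <egfr_assignment> L858R+T790M+C797S -> T790M-like-3R (exon 20, bucket 'classical+T790M+atypical')
#>   rules: classical_definition > hydrophobic_core_substitution >
#>          curated_pacc_name:C797S > resistance_comutation:C797S > allele_t790m_precedence
```

The allele parses into three variants; T790M takes precedence (any
T790M-containing non-classical allele is T790M-like), and the C797S
co-mutation flips the subgroup to 3R: resistant to third-generation TKIs,
with selectivity retained only for ALK/PKC inhibitors.

A simulated screen, analysed end to end:

```r
set.seed(1)
panel <- generate_mutation_panel(c("classical-like" = 4, "PACC" = 4,
                                   "Ex20ins-L" = 4, "T790M-like" = 4))
m   <- simulate_selectivity_matrix(panel, screen_template(sigma = 0.3))
a   <- classify_mutations(panel$mutation)
sch <- schemes_from_assignments(a, ids = panel$id)

compare_groupings(m, sch$structure, sch$exon)
#> <rho_comparison> structure vs exon over 16 paired mutations
#>   mean rho: 0.807 vs 0.575; median: 0.824 vs 0.626
#>   paired t = 2.728, df = 15, p = 0.0156

importance_comparison(m, sch$structure$map,
                      setNames(a$exon_group, panel$id),
                      cart_control(minsplit = 8))
#> <importance_comparison> 18 tree(s): structure 90.8 vs exon 9.2 (paired p = 5.39e-10)
```

Each mutation's selectivity profile across 18 drugs correlates far better
with the leave-one-out mean profile of its structure–function group (mean
ρ 0.81) than with that of its exon group (0.58), and the structure-group
predictor dominates the per-drug regression trees — the direction the
classification is designed to capture.

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` composes the
whole analysis (classification → screen → grouping comparison → survival)
and writes the report bundle with its configuration JSON.

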