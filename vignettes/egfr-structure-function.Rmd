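---
title: "Structure-function classification of EGFR mutations: models, parameters and design choices"
author: "egfrsf"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrsf)
```

# Scope

`egfrsf` classifies EGFR kinase-domain mutations into structure-function
groups and implements the statistics used to show that this grouping
predicts TKI selectivity and patient outcomes better than the traditional
exon-based grouping. This vignette records the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the problem was
genuinely open.

# Coordinates and the region map

All positions are 1-based UniProt P00533 residue numbers; intervals are
inclusive. The kinase domain spans residues 688-875. Two structural
intervals are fixed by the biology: the P-loop L718-V726 and the
C-terminal loop of the alpha-C helix A767-G779. The remaining intervals
are package choices, all configurable through `region_map()`:

* **Exon boundaries** (never uniquely determined by protein coordinates
  alone): exon 18 = 688-728, exon 19 = 729-761, exon 20 = 762-823,
  exon 21 = 824-875, following the canonical EGFR transcript convention.
* **alpha-C helix** 756-766, taken as the stretch immediately N-terminal
  of its C-terminal loop; insertions anchored here (e.g. A763insFQEA) are
  classical-like rather than Ex20ins-L.
* **Exon 20 loop insertion span** A767-V774, split into a near loop
  (insertion anchors 767-770) and a far loop (771-774). The exact
  near/far boundary is not fixed by any principle we can derive from
  sequence alone; the D770/N771 cut is a documented default, chosen
  because D770 anchors the most common near-loop insertions (D770insNPG,
  D770insSVD) and N771 the common far-loop ones, and it is configurable.
* **Hinge** 792-797 and **hydrophobic core** {790}: minimal sets
  sufficient for the curated assignments; both extensible.

Insertions are anchored to the residue they follow; a duplication of
`start..end` is treated, for all positional logic, as an insertion
anchored at `end` (`as_insertion()`), which makes `A767_V769dupASV` and
`V769insASV` equivalent.

Reference-residue validation against the canonical P00533 sequence is
optional and off by default, so synthetic mutation names need not match
the real protein. The validation table is deliberately partial: it lists
only the residues this analysis refers to, because a full kinase-domain
sequence could not be verified from first principles here; positions
absent from the table pass unchecked.

# The classifier

The classifier is an ordered rule list; the first match wins and every
assignment carries a `rule_trace` naming the rules that fired, so any
label can be audited. Curated exceptions precede positional rules because
the grouping mixes positional logic with named exceptions: L747P
(substitution) is PACC while L747_K754delinsATSPE (a mechanically
"classical-looking" exon 19 delins) behaves like a hydrophobic-core
mutation and is curated T790M-like. That curated status overrides the
classical definition everywhere, including `is_classical()`.

Variant-level order: curated exceptions; hydrophobic-core substitutions
(T790M-like); the classical definition (L858R, T790M, exon 19 del/delins
starting at E746/L747 and ending at or before A755); curated PACC names
(S768I, T854I, V765L, G796S, C797S) and positions (E709X, L718X, G719X,
L747X, L792X); alpha-C-helix insertions (classical-like); exon 20 loop
insertions (Ex20ins-L, NL/FL by anchor); P-loop/hinge/post-alpha-C
substitutions (PACC); and finally a positional "distant from pocket" rule
labelling any remaining kinase-domain substitution classical-like. That
last rule is how L861Q gets its classical-like label: its group is implied
by its behaviour rather than stated as a curated fact, and the trace marks
it as positional. Anything unmatched is `unclassified` - never silently
absorbed into a group.

Allele-level precedence is classical > T790M-like > Ex20ins-L > PACC >
classical-like, on the rationale that resistance-driving lesions dominate
the drug response of a compound allele. The 3R subgroup requires a
co-occurring C797X, L718X or L792X substitution next to T790M; L792X alone
is PACC, and the allele-level rule resolves the apparent conflict.
Composite alleles keep their per-variant labels and a `contains_pacc`
flag, so survival analyses can form "PACC-containing" strata without
reclassifying.

# Screen analysis

Raw per-well signal is normalized to the mean of the DMSO control wells of
the same cell line and replicate. Each (cell line, drug, biological
replicate) curve is fitted with a four-parameter logistic on the log10
dose scale by Levenberg-Marquardt least squares, with bounds bottom in
[0, 0.5], top in [0.5, 1.2] and hill > 0; the bounds stabilise 7-point
fits and enforce the monotone-decreasing sign convention. The optimizer
works on the residual function directly rather than through an `nls`
model object because noiseless (exact-fit) curves, which the test-suite
closure properties rely on, make `nls`-style model construction fail with
a singular gradient.

The IC50 is the *absolute* 50%-inhibition point - the dose where the
fitted curve crosses 0.5 of the DMSO baseline - not the curve's midpoint.
Curves that never cross 0.5 on the tested range are censored at the
nearest tested dose (maximum dose for resistant curves, minimum for
hypersensitive ones) and flagged; capping rather than dropping keeps the
matrix finite for clustering, and the flag propagates into the matrix
when a censored replicate sits at the median position.

Selectivity is `log10(mutant IC50 / mean WT IC50)` - base 10 by
dose-response convention, configurable - and each matrix cell is the
median over biological replicates (for an even count, the mean of the two
middle values). Hierarchical clustering uses Euclidean distance with
complete linkage by default; group comparisons use Welch's one-way ANOVA
(no equal-variance assumption) followed by pairwise Welch t-tests with
the Holm-Sidak step-down adjustment, implemented directly because
`p.adjust` offers Holm but not the Sidak variant.

# Grouping predictiveness

Two complementary procedures compare grouping schemes:

1. **Leave-one-out profile correlation.** For each mutation, Spearman's
   rho between its own selectivity profile across drugs and the mean
   profile of the other members of its category, under each scheme.
   Mutations in singleton categories or with constant profiles are not
   evaluable; they are dropped from the pairing and listed, never silently
   skipped. The paired rho vectors are compared by a paired two-sided
   t-test, and both mean and median summaries are reported (means feed the
   test; medians are a robust summary of the same vectors).

2. **CART variable importance.** One regression tree per drug, with a
   single unordered categorical structure-group predictor and four 0/1
   exon indicators (a mutation spanning two exons may set two). Trees are
   grown by greedy binary splitting minimizing within-node sum of squares;
   categorical splits use the order-categories-by-mean-response reduction,
   which is exact for a least-squares criterion; the goodness of a split
   is SS(parent) - SS(left) - SS(right); importance is the per-predictor
   sum of goodness rescaled to total 100. Surrogate splits contribute
   nothing by default. Stopping: nodes smaller than `minsplit` (default
   20, the convention of recursive-partitioning software; the bundled
   analyses of 24-mutation panels use 8) or best split below `cp` (1%) of
   the root sum of squares. Ties break toward the earlier-listed predictor
   and the lower split value, so fits are deterministic; the test suite
   verifies every split against an exhaustive search and against an
   independent recursive-partitioning implementation.

A caveat worth stating: greedy exhaustive-search trees have a
variable-selection bias toward predictors with more candidate splits.
Under a permutation null the structure factor (4 levels) still collects
more importance than any single binary exon indicator, so raw importance
should not be read as an unbiased effect size; the package's evidence for
the structure grouping rests on the paired comparison against the signal
case and on the independent rho procedure, which is well calibrated under
the null.

# Survival and response analyses

Kaplan-Meier estimation uses the product-limit estimator with
simultaneous decrements at ties; the median is the earliest time at which
S(t) is at or below 0.5 (the earliest such time when S sits exactly at
0.5 over an interval), undefined when S never reaches 0.5. The log-rank
test is the two-sided Mantel-Cox form; hazard ratios are the log-rank
(O1/E1)/(O2/E2) estimator with CI `exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2))`,
deliberately not Cox regression, since the retrospective clinical HRs
this reproduces are log-rank HRs, and the numerator arm is always stated
explicitly because reference directions vary between layouts. Response
rates are (CR+PR)/evaluable with "NE" excluded, compared pairwise by
two-sided Fisher exact tests.

# The synthetic-data generator

The generator encodes the study conditions the analyses assume, as a
(structure group x drug class) matrix of expected log10(Mut/WT) values
over an 18-drug panel (3 first-, 4 second-, 3 third-generation TKIs, 4
Ex20ins-active inhibitors, 2 ALK and 2 PKC inhibitors). The default
template encodes the qualitative selectivity ordering of the groups -
classical/classical-like most selective for third-generation TKIs, PACC
for second-generation, Ex20ins-L only for Ex20ins-active (mildly for
select second-generation) agents, T790M-like-3S for third-generation,
T790M-like-3R only for ALK/PKC inhibitors - and the test suite asserts
that ordering on the template itself. Magnitudes (roughly -1.8 to +0.9
log10 units) are calibration choices: the real screen's replicate noise
and effect sizes are not published as numbers, so sigma = 0.2 (replicate,
log10 units), sigma_m = 0.1 (per-mutation offset) and 3 biological
replicates were fixed once as values a screening lab would consider
realistic, and are not tuned thereafter.

Raw screens are emitted as exact unit-slope logistic curves at 7 half-log
doses spanning 0.01x-10x the wild-type IC50 (100 nM), in technical
triplicate with optional additive well noise, plus DMSO control wells;
with all noise at zero the analysis pipeline recovers the template matrix
to numerical precision, and at sigma = 0.2 the per-cell RMSE matches its
theoretical budget (median-of-3 noise plus the shared WT-denominator
term, about 0.177). Survival cohorts draw exponential event times with
rate log(2)/median per (group, TKI generation) arm - a single-parameter
match to a target median - with independent uniform censoring whose upper
bound is solved numerically so the expected censored fraction equals the
requested one (default 0.2). A Weibull shape is deliberately not the
default; memorylessness keeps the median the only free parameter.

What the generator does *not* emulate: plate and edge-well effects,
drug-synergy, clonal evolution or acquired resistance over time,
non-proportional hazards, and correlated censoring. Passing recovery
tests therefore demonstrates the correctness and calibration of the
analysis chain under its own assumptions, not the clinical effect sizes,
which come from databases this package does not ship.

# Bundled simulation studies and problem sizes

`simulation_grouping_study()` draws, per seed, 6 mutations from each of
the four structure-function groups (a 24 x 18 matrix at sigma = 0.3) and
runs both grouping comparisons; `simulation_cohort_study()` simulates
PACC cohorts of 50 patients per TKI-generation arm with target medians
10.0 / 21.7 / 4.1 months. Both default to 100 seeds, sizes chosen so the
full suite and the acceptance script each run in well under two minutes
on a single CPU while leaving the recovery rates far from their
thresholds. The classifier reachability analyses enumerate every
substitution, deletion and insertion anchored at each kinase-domain
residue, which is exhaustive rather than sampled.

# Known limitations

* The curated exception list covers the mutations named in the analysis;
  a comprehensive mutation-to-group table would extend
  `rule_table()` without code changes.
* Positions 775-779 of the alpha-C loop lie outside the Ex20ins-L span;
  insertions there are reported `unclassified` rather than guessed.
* CART importance inherits greedy-tree selection bias (above).
* The log-rank HR estimator is biased toward the null for large effects
  and heavy censoring; it is reported because it is the estimator used in
  the retrospective analyses this package mirrors, not because it is
  optimal.
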