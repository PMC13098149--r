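---
title: "Methods: cross-species comorbidity mapping with comodbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comorbidity mapping with comodbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery in `comodbm`, the
assumptions behind each stage, the choices we made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. Function-level details live in the help pages; here we give the
reasoning.

## The two-part phenotype structure

Each model-organism community annotates genotype–phenotype associations in
its own ontology (HPO, MP, ZP, FBcv, WBPhenotype). `comodbm` harmonizes them
through a deliberately simple, flat, two-part structure: every term maps to
one of 18 whole-body categories, and reproduction-related terms additionally
carry a fertility flag and one of 13 reproductive groups (meiosis,
gametogenesis, fertilization, …). The term map is a curated TSV, not an OBO
graph: no subsumption closure or semantic similarity is computed. This keeps
the mapping auditable and diff-able, at the cost of losing within-category
term granularity — a limitation we return to below.

Two conventions matter downstream:

* **Additive fertility counting.** A fertility term contributes to *both*
  its base category (usually Genitourinary) and the 19th category,
  Fertility. Dropping it from the base category would silently change the
  genitourinary signal; the additive rule preserves both, and the two
  categories are reported as separate tests. Whether the reference analyses
  removed fertility terms from their base category before testing is not
  documentable from the outside; we record the additive rule as this
  package's convention.
* **Applicability masking.** Not every category is phenotyped in every
  species. The default mask marks (zebrafish, Fertility) untestable — the
  aggregate source does not expose zebrafish fertility codes, so
  Genitourinary serves as the flagged proxy in linkage summaries — and
  (worm, Eye and Ear) untestable. Masked pairs are excluded from testing
  rather than counted as zeros, which would fabricate negative evidence.
* **Term-level deduplication.** Counts are distinct phenotype terms per gene
  and species, not annotation rows: a well-studied gene with dozens of
  alleles contributes each term once. The unit of analysis is the gene.

The 13-group vocabulary is configuration, not code: curated tables may use
their own 13 labels. The package default uses the nine groups named in the
field (DNA/cell division defects, meiosis, gametogenesis, gonad/urogenital
development, quantitative sperm defect, testis function, fertilization,
general male/female infertility) plus four labels of our choosing (sperm
morphology, sperm motility, mating/reproductive behavior, oogenesis) to
complete the set.

## Orthology and conservation dating

Ortholog records carry integrative (DIOPT-style) confidence tiers as data;
the package filters but never recomputes them. The default filter keeps
high- and moderate-confidence predictions — the tier combination used for
the cross-species analyses — with an optional "best-score-only" switch.
Each gene's *oldest species* is the most distant of roundworm, fruit fly and
zebrafish retaining a filtered ortholog; genes with none are labelled mouse.
Human is excluded from dating: the question is how far down the model-organism
tree the gene is traceable. Two gene sets' conservation distributions are
compared by a Pearson chi-square on the 2×4 count table (no continuity
correction); categories empty in both sets are dropped with a warning and
the degrees of freedom reduced.

Many-to-many orthology (e.g. zebrafish duplicates) is resolved by pooling:
all target genes of one source gene contribute annotations to one profile,
with terms deduplicated. This matches the one-count-vector-per-gene contract
and avoids arbitrary paralog choices.

## Class-association enrichment

For each testable (species, category) pair we form the 2×2 table of seed
orthologs vs the rest of the genome background (genes with a mouse ortholog;
seed genes are removed from the background cells). Seed genes without an
ortholog in the species are excluded from the seed margin rather than
counted as phenotype-free.

The test is Fisher's exact test with the two-sided *minimum-likelihood*
rule: p is the sum of hypergeometric point probabilities not exceeding the
observed table's probability times `1 + 1e-7`. The slack factor guards
against floating-point ties; without it, tables whose opposite-tail
probability is mathematically equal but numerically a few ulps larger would
be excluded. Two odds ratios are reported: the sample cross-product ad/bc
and the conditional maximum-likelihood estimate, the root of
E<sub>ψ</sub>[A] = a under the noncentral hypergeometric distribution,
found by bracketed root finding on log ψ to tolerance 1e-8 (0 or ∞ when the
observed count sits on the support boundary). The conditional MLE is the
reported `log_or`: with sparse tables (one flagged background gene, say) the
cross-product is degenerate while the conditional estimate remains finite
and matches the convention of standard exact-test software.

FDR control is Benjamini–Hochberg, pooled over *all* species and categories
as one family — the analysis asks one joint question, and per-species
families would be anti-conservative in aggregate.

Because the test conditions on the margins, its attained size is below the
nominal level by discreteness; with study-scale margins (~200 seed genes,
thousands of flagged background genes) the gap is small. The test suite
calibrates the observed type-I rate against the *exact* attained size
computed by enumerating the conditional null at each test's margins, plus a
one-sided bound at the nominal level.

## Single-gene concordance

Per gene, the category × species count matrix (species without orthologs
excluded, not zero-filled — zero-filling would manufacture agreement between
sparsely annotated species) is summarized by the one-way random-effects,
single-rater ICC with categories as objects and species as interchangeable
raters:

$$\mathrm{ICC} = \frac{MSB - MSW}{MSB + (S-1)\,MSW}$$

The one-way form needs no rater-identity assumption, which is what lets a
gene with three species be compared to one with five. An all-constant matrix
returns 0 by convention; identical non-constant columns return 1.

The permutation null replaces each species' column with the same species'
column from a uniformly drawn random gene, independently per species. This
preserves each species' marginal count distribution (including its scale and
sparsity) while breaking the within-gene coupling, so the test asks: is this
gene's cross-species agreement larger than what the species' annotation
structures produce by chance? With `n_perm = 999`,
p = (1 + #{null ≥ observed})/1000 has floor 1e-3, and "significant at
1e-3" means *at* the floor — a 999-permutation p can never be strictly below
it. Genes are declared significant at `p_perm <= alpha`.

Mouse–human correlation is the plain Pearson r of the two 19-vectors over
genes with at least one phenotype in either species; r is set to 0 (flagged)
when the human ortholog is missing or either vector is constant. The
substitution keeps those genes in downstream summaries as explicit
no-evidence observations instead of silently dropping them.

## Clustering and model selection

Genes are clustered by k-means (Hartigan–Wong, best of 25 restarts) on their
**raw** mouse count vectors. No scaling or log transform is applied by
default: total phenotype burden is biologically meaningful here (it
separates isolated-infertility genes from broad-comorbidity genes), and
standardizing would discard it. A `scale_counts` switch exists for users who
want shape-only clustering.

k is chosen by the gap statistic against uniform reference draws
(k = 1..20, B = 100, 25 restarts by default) with the *firstSEmax* rule —
the smallest k whose gap is within one standard error of the next k's gap.
This operationalizes "additional clusters stop being meaningfully
different". k-means labels are arbitrary, so clusters are renumbered by
ascending mean total count: "cluster 1" is always the lightest-burden group,
making statements like "clusters 3 and 4 are the comorbid ones"
reproducible. Binarization ranks clusters by center mass over the
non-reproductive categories (all but Fertility, Genitourinary and Other) and
labels the top half comorbid; ties break by cluster id with a warning.

## Driver models

Cluster membership is modelled by maximum-likelihood multinomial logistic
regression (cluster 1 reference, intercepts included). Tissue TPM blocks are
ln(x+1)-transformed first; testis single-cell blocks are per-gene z-scores
across the 13 cell types (sample standard deviation; constant rows become
zeros and are flagged). Fit is summarized by McFadden's pseudo-R² =
1 − lnL_model/lnL_0 against the intercept-only null and a likelihood-ratio
χ² with (#features)·(k−1) degrees of freedom. No penalty is applied:
with ~200 genes and up to 54 features the model is near-saturated, and a
ridge penalty would change what the McFadden formula measures. Instead,
complete separation is detected (coefficient divergence beyond |β| > 15)
and flagged; non-convergence after 500 iterations is reported, never
silently accepted. The binarized comorbidity state is additionally modelled
by one joint multivariable binary logistic regression over all tissues with
per-feature Wald tests; a per-tissue marginal mode is deliberately not the
default, since marginal fits on correlated tissue profiles overstate
independent evidence.

## The synthetic-data generator

`simulate_bundle()` draws a complete, internally consistent input bundle —
term map, mask, orthologs with low-confidence decoys, per-gene JSON
payloads, gene-level genome backgrounds, expression and GO blocks — plus the
planted truth needed to score recovery. Its defaults are the package's
reference study conditions: 204 seed genes; genome backgrounds of 17,000
(human), 21,000 (mouse), 12,774 (zebrafish), 8,000 (fly) and 7,500 (worm)
genes with mouse orthologs; ortholog retention of 0.95/0.78/0.41/0.61
(human/zebrafish/fly/worm), which makes ~61% of genes trace to roundworm;
fertility and genitourinary enrichment in every species except roundworm,
whose background reproductive-defect rate is itself very high (its
enrichment multiplier is 1.3 and stays non-significant by design); and an
ontology whose fertility-group pool sizes reproduce the reference
vocabulary contrasts (112 zebrafish vs 22 human vs 28 mouse gametogenesis
terms; 13 fly terms total, with a single gametogenesis term; 74 worm terms).

Counts follow a Poisson model with per-gene × category gamma propensities —
negative-binomial marginals — chosen as the minimal structure that yields
both overdispersion and *tunable cross-species concordance*: the propensity
is a `share`-weighted mix of a component shared across species and a private
one. A 30% "high tier" of genes gets full sharing plus a 12× annotation-depth
boost outside mouse, emulating deeply studied genes with 10–100 phenotypes
per species; one mechanism label (DNA damage and repair) preferentially
tags that tier, so label-stratified concordance summaries have planted
structure to recover. Mouse counts take only a 0.15 weight on the shared
propensity with a mild private gamma (shape 20): mouse profiles are
generated from four planted comorbidity classes (isolated infertility;
extensive reproductive plus molecular/cellular "Other"; broad comorbidity;
nervous-system-led, in proportions 42:84:22:43), and heavier mouse coupling
to the heavy-tailed shared propensity would drown that class structure.
Expression and GO blocks draw from class-dependent log-normal means and
Bernoulli rates, giving the driver models planted effects of known sign.

Two constructions make the generator statistically honest rather than merely
plausible:

* **Exchangeable null.** Background per-category totals are drawn from the
  *exact closed-form* flag probability P(count ≥ 1) of the same
  gamma–Poisson mixture (the gamma Laplace transform), so under the `"null"`
  preset seed genes are distributionally identical to background genes and
  the conditional (hypergeometric) null of the exact test holds exactly.
  This is what makes type-I calibration a sharp test rather than a vibe.
* **Count/term consistency.** Profile counts are materialized as distinct
  sampled ontology terms (without replacement), and counts are capped at the
  pool size, so rebuilding profiles from the written payloads reproduces the
  simulated matrix bit-for-bit; flags, and hence backgrounds, are unaffected
  by the cap. The whole bundle is byte-identical under a fixed seed.

What the generator does *not* emulate: real ontology term semantics (labels
are synthetic); biologically calibrated per-category rates (magnitudes are
chosen to match the study's reported flag rates and odds-ratio scales, not
fitted to any database); allele-level structure; and cross-category
correlation beyond the fertility–genitourinary coupling. Passing tests
therefore demonstrate that the statistics recover planted structure under a
realistic scale and noise model — not that any particular biological claim
holds in real databases. Under the study preset the mouse count mixture is
deliberately overdispersed; a consequence is that the gap statistic often
prefers k between 5 and 8 over the planted 4 on such data, which the
pipeline reports honestly (the k-recovery checks use strongly separated
mixtures, where the criterion is well-posed).

## Numerical choices and degenerate inputs

* Exact-test p: minimum-likelihood rule with `1 + 1e-7` slack; conditional
  MLE by `uniroot` on log ψ, tolerance 1e-8, bracket expanded geometrically
  and collapsed to 0/∞ when the root escapes the floating range.
* BH is `stats::p.adjust(method = "BH")` over the pooled tested set.
* ICC denominators: both mean squares zero → 0; fewer than two species →
  excluded, not imputed.
* k-means: `iter.max = 100`; cluster-count requests above the number of
  distinct profiles are errors, not silent reductions. Gap standard errors
  that are non-finite (B = 1) are treated as 0 and the result flagged
  low-confidence.
* Multinomial fits: `reltol = 1e-14` so that the 30-gene oracle comparison
  in the test suite is meaningful at 1e-4; aliased binary-logistic features
  keep NA Wald entries rather than being dropped from the report.
* All randomized stages (generator, permutation test, k-means restarts, gap
  references) take explicit seeds and restore the caller's RNG state.

## Problem sizes used by the test suite

Unit tests run on 40-gene bundles with ~2,000-gene backgrounds. The
statistical validation uses: the exhaustive exact-test comparison over all
2×2 tables with total ≤ 60 (p-values; conditional MLEs exhaustively to
total ≤ 20 plus 250 random larger tables); 200 null bundles at full study
scale for type-I calibration; 50 bundles of 200 genes for ten-fold
enrichment power; 1,000 random matrices for the ICC/ANOVA identity and a
500-gene null bundle at 199 permutations for permutation-null uniformity;
20 strongly separated four-class mixtures of 200 genes for gap/ARI
recovery (k searched to 10, B = 50, 10 restarts); and 50–100 replicates for
the driver-model null and sign-recovery checks. These sizes were chosen so
the full suite completes in minutes on one core while keeping every check's
Monte-Carlo error well inside its decision margin.

## Known limitations

Nineteen broad categories lump distinct phenotypes: a category as coarse as
"fertility" cannot separate sex-specific or cell-type-specific effects, and
in hermaphroditic roundworms a paralyzed animal may be scored sterile — one
reason the roundworm background reproductive rate is so high that seed genes
show no enrichment there. Resolution stops at the gene: alleles,
perturbation types and direction of effect are not modelled. The ICC variant
and permutation scheme are this package's recorded choices among several
defensible ones, and concordance summaries are sensitive to them. Finally,
the near-saturated driver regressions are descriptive fits; their pseudo-R²
values compare blocks, not validated predictive models.
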