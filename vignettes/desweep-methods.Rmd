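---
title: "Methods: DES prioritization and ranked-subset enrichment sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DES prioritization and ranked-subset enrichment sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desweep)
```

# The analysis problem

Post-mortem case/control brain RNA-seq studies of Huntington's disease
(HD) can yield thousands of differentially expressed (DE) genes — far too
many to interpret gene by gene. Two complementary devices organize such a
list:

* a **composite prioritization score** that balances statistical
  significance against abundance and effect size, and
* a **ranked-subset enrichment sweep** that asks, for nested prefixes of
  the significance-ranked DE list (top 25, top 50, ...), which genesets
  are over-represented, and *at what depth* of the list each geneset's
  signal concentrates.

`desweep` implements both, together with the count preprocessing and
clinical-covariate association stages that surround them, and a
negative-binomial simulator with planted ground truth so every stage can
be validated end to end without access to any cohort.

# Preprocessing

**Low-signal filter.** A gene is kept when it has nonzero counts in at
least half the case samples *or* at least half the control samples
(rounded up). The one-sided reading is deliberate: genes expressed almost
exclusively in disease tissue — which include the strongest HD signals,
e.g. homeobox genes with control means near zero — would be discarded by
an "and" rule. The filtered gene set defines the *universe* ("confidently
detected genes") for all enrichment testing, rather than all annotated
genes, which avoids annotation-inflation bias.

**Outlier winsorization.** Per gene and per group, counts above the Tukey
fence `Q3 + k·IQR` (linear-interpolation quartiles, R type 7; `k = 3` by
default, the conventional "extreme outlier" multiplier) are replaced by
the ceiling of the fence. Replacement rather than removal keeps the
design balanced; the ceiling keeps counts integral; values never
increase, and the within-group median is untouched. Both `k` and the
quantile type are exposed because fence conventions differ between
implementations.

**Normalization.** Median-of-ratios size factors: the factor for sample
*j* is the median over reference genes (geometric mean > 0, i.e. nonzero
in every sample) of `count_ij / geomean_i`. Normalized count = raw /
factor.

**Variance stabilization.** For the NB variance law `Var = μ + αμ²` the
exact stabilizer has the closed form

    g(x) = (2 / sqrt(α)) · asinh(sqrt(α·x)),

which is monotone, has `g(0) = 0`, and reduces to the Poisson stabilizer
`2·sqrt(x)` as `α → 0`. We use this closed form with a single shared α
(median of per-gene estimates) rather than a fitted dispersion trend: it
is exactly testable, and the downstream use — per-gene linear regression
on clinical covariates — only needs approximate homoscedasticity.

# Differential expression

Each gene is fit with an NB GLM (log link), offsets `log(size factor)`,
and coefficients for condition, age at death binned into 0–45, 46–60,
61–75 and 76+ years, and an RIN > 7 indicator (RIN: RNA Integrity
Number, a 1–10 RNA quality score). The fourth age bin is open-ended at 76
so the binning is exhaustive. The condition coefficient divided by
`ln 2` is the log2 fold change; Wald p-values compare coefficient/SE to a
standard normal; BH adjustment controls FDR and `padj < 0.05` defines the
DE call. Non-converging fits are reported as missing and excluded from
the FDR denominator. Covariates that are constant in a given data set are
dropped with a message; collinear designs are an error.

**Dispersion.** The default estimator is per-gene maximum likelihood
(`MASS::theta.ml`) given the group-mean fit, initialized by (and falling
back to) a pooled within-group moment estimator with a floor of 1e-8.
The moment estimator alone is available (`method = "moments"`) but its
plug-in noise makes the Wald test mildly liberal at the study's sample
sizes (about 6–6.5% empirical type-I error at nominal 5% in our null
simulations at n = 20 vs 49), while the ML estimator restores near-nominal
calibration (~5.4%); that calibration experiment fixed the default.
No fold-change shrinkage and no independent filtering are applied: the
stage is a documented, reproducible NB-Wald contract, not a re-implementation
of any particular DE package's empirical-Bayes machinery, and externally
produced DE tables can be substituted everywhere downstream
(`pipeline_config(external_de = ...)`).

**Ranking.** "Ranked by significance" means nominal p ascending with ties
broken by |log2 FC| descending and then gene id, making the ranking
deterministic.

# The Differential Expression Score

    DES = (overall mean normalized counts) × |log2 FC| × (−log10 padj)

A pure significance ranking is dominated by low-abundance genes expressed
almost only in cases (tiny control means produce enormous fold changes
and p-values despite single-digit counts). DES rebalances toward genes
that are abundant *and* strongly changed *and* secure, surfacing
physiologically substantial markers (myelin, glial and injury-response
genes) above the low-expression homeobox block. Adjusted p-values are
clamped at 1e-300 before the log so underflow cannot produce an infinite
score; the published worked examples sit dozens of orders of magnitude
above this floor. The score uses the FDR-adjusted p as published; a
nominal-p variant sits behind `use_nominal` for sensitivity analysis
only.

Descriptive companions: a sliding-window up/down profile (fraction of
up-regulated genes among ranks `(x, x+100]`, step 1 — the window steps by
one position because a coarser step is strictly less informative and the
choice is configurable), biotype composition of the DE list, and row-max
normalization for display heatmaps.

# Ranked-subset enrichment sweep

Nested prefixes of the ranked DE list are formed at sizes
`25, 50, ..., N` (the full list is appended when `N` is not a multiple of
25). Each prefix is tested against every geneset with the one-sided
hypergeometric upper tail `P(X ≥ overlap)` on the filtered-gene universe
— identical to the one-sided Fisher exact test, so a single
implementation serves the pathway and GO paths. GO-style collections with
a term hierarchy are first propagated by the true-path rule (every term
inherits its descendants' genes); the hierarchy must be acyclic. The
decorrelation refinements of hierarchy-aware GO testers are intentionally
out of scope; classic propagated testing is the documented contract.

Per collection this yields an *enrichment profile*: a geneset ×
subset-size matrix of `−log10 p` with (i) a display mask at nominal
p < 0.05, matching the convention of only showing significant cells,
and (ii) BH-adjusted p per subset-size column, reported because
conventions differ on where adjustment applies in a sweep; the mask uses
nominal p, the adjusted values are available alongside.

**Integration.** Each collection's genesets are ranked by their best
(smallest) p at any subset size; the top 15 per collection are
concatenated; masked cells contribute 0 (configurable); rows are
normalized by their sum (rows that are entirely non-significant are
dropped with a warning); and rows are clustered by Ward-linkage
agglomerative clustering on Euclidean distances, cut into 5 groups by
default. The group count is a parameter because no cut rule is implied by
the method itself; cutting the Ward tree at a fixed group count is the
simplest reproducible choice. The whole construction is deterministic
given its inputs.

# Clinical covariate association

Variance-stabilized expression is regressed per gene on one clinical
covariate at a time, adjusting for RIN (OLS, two-sided t-test on the
covariate slope, BH across genes). Case-only covariates — CAG repeat
length, onset, Hadzi–Vonsattel (H-V) striatal/cortical involvement
scores — use the case samples only. Because onset age and CAG length are
strongly negatively correlated, onset enters as a *CAG-adjusted
residual*: observed minus model-predicted onset. Published prediction
coefficients are not bundled; any user function can be supplied, and the
default fits `log(onset) ~ CAG` by least squares on the data at hand (the
standard functional form), in which case residuals are centered by
construction.

The **confounding check** asks whether the DE calls merely track cortical
involvement: per DE gene, an NB GLM of raw counts (cases only) on the H-V
cortical score adjusting for RIN, BH-adjusted across DE genes; the result
is flagged when any gene is significant. Note that under a global null
the BH procedure flags at least one gene with probability ≈ α per data
set — the test suite encodes the negative-result pattern accordingly (at
most 2 flagged runs in 12) rather than demanding an impossible zero rate.

# The simulator

`simulate_counts()` draws counts from
`NB(mean = depth_j · base_mean_i · 2^(lfc_i·[case_j]), dispersion α)`.
Defaults emulate the structure of the motivating cohort:

| parameter | default | rationale |
|---|---|---|
| samples | 20 cases vs 49 controls | the study's group sizes |
| `de_fraction` | 0.19 | ~19% of detected genes DE |
| `up_fraction` | 0.548 | 54.8% of DE genes up-regulated |
| `exclusive_fraction` | 0.02 | a small class of disease-exclusive genes |
| base means | log-normal, median 100, sdlog 1.5 | heavy-tailed counts spanning ~1 to ~10^5, median near the cohort's ~97 |
| `nb_dispersion` | 0.1 | typical bulk-brain overdispersion |
| `lfc_scale` | 1 (exponential + 0.25 floor) | mixes modest and strong effects; the floor keeps DE genes non-null |
| depths | Uniform(0.5, 2) | library-size variation |
| ages | cases ~N(58, 11), controls ~N(69, 16) | cases die younger |
| CAG/onset | onset ≈ 88 − 1.05·CAG + noise | negative CAG-onset correlation |

"Exclusive" genes keep a control-side mean of 0.05 rather than exactly 0
so NB sampling stays defined — mirroring near-zero control means in real
top hits. Their realized fold change therefore exceeds their nominal
`true_lfc`, and parameter-recovery checks exclude them.
`simulate_genesets()` plants sets whose members concentrate in the top
`planted_depth` ranks so the sweep's depth-recovery can be verified.

**What the simulator does not emulate:** batch effects beyond depth,
gene-gene correlation, dispersion trends over mean expression,
GC/length biases, or cell-type mixture shifts. Passing tests therefore
demonstrate the correctness and calibration of the algorithms under the
stated generative model, not performance on any real cohort.

# Numerical choices and degenerate inputs

* Hypergeometric p-values are discrete: the attainable null rate of the
  p < 0.05 mask is strictly below 5% and depends on (universe, geneset,
  subset) sizes. Calibration tests compare against the analytically exact
  attainable rate rather than the nominal one.
* BH adjustment delegates to `stats::p.adjust`, whose NA semantics
  (missing values propagate and do not count toward the number of tests)
  match this package's contract; tests verify it against the brute-force
  step-up definition.
* Ward clustering delegates to `stats::hclust(method = "ward.D2")` on
  Euclidean distances; tests verify merge heights and partitions against
  an independent brute-force agglomerator using the centroid form of the
  Ward cost.
* All-zero enrichment rows are dropped before row-sum normalization;
  all-zero heatmap rows pass through row-max normalization unchanged;
  empty collections yield empty profiles; an empty DE list short-circuits
  the confounding check with no flag.
* Ties are broken lexicographically everywhere a ranking is exposed
  (DE ranking, DES ranking, geneset ranking), so outputs are
  deterministic and permutation-invariant.
* The pipeline manifest contains the configuration, its MD5 hash, the
  seed and per-stage row counts — and nothing time- or path-dependent —
  so a fixed seed yields a byte-identical manifest.

# Problem sizes used in validation

The shipped validation suite exercises: worked-example DES rows from the
bundled published tables; exhaustive hypergeometric enumeration to
universe size 12; 1,000-vector BH comparisons; NB-Wald null calibration
on 1,000 genes at 20 vs 49 samples; mask calibration on 1,000 replicate
random genesets against a 2,000-gene universe; planted-geneset recovery
over 20 seeded replicates at the default 2,000-gene scale (a planted set
is "recovered" when it enters the per-collection top 15 and its best
p-value falls within 20% of the planted depth — exactly size 25 for the
shallow set, given the 25-gene sweep resolution); Ward-oracle equality on
matrices of up to 8 rows; and byte-identical reruns of the full pipeline
on a 500-gene study. These sizes were chosen so the whole suite gives
tight Monte-Carlo error on every calibration claim while remaining quick
to run routinely.

# Known limitations

* The NB-Wald stage is not bit-compatible with shrinkage-based DE tools;
  on real data its fold changes are unshrunken and its dispersions are
  per-gene, so borderline calls will differ. Published DE tables can be
  used verbatim instead.
* The outlier winsorization is a documented Tukey-fence stand-in for
  whatever trimming a given upstream pipeline applied; it is exposed via
  `trim_k` and the quantile convention rather than claimed as anyone
  else's exact procedure.
* The GO path implements classic propagated testing, not weighted
  decorrelation; deeply nested redundant terms will co-cluster more than
  they would under a decorrelating tester.
* Enrichment p-values across nested subsets are strongly dependent by
  construction; the sweep is a descriptive localization device, and the
  per-column BH values should not be read as a family-wise claim across
  the whole sweep.
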