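---
title: "Methods: scoring, integration and progression models in mirmycn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, integration and progression models in mirmycn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmycn)
```

`mirmycn` identifies microRNAs that repress MYCN and asks whether those
miRNAs behave like MYCN-controlled genes in tumors and in murine
neuroblastoma progression. This vignette records the statistical models the
package implements, the parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

## Reporter-screen scoring

Each well of the screen co-transfects a Firefly reporter carrying the MYCN
3'UTR, a Renilla control, and one miRNA mimic from a 470-mimic library. The
scoring chain is:

1. `normalize_reporter()` — per-well log2(Firefly/Renilla). Renilla must be
   positive; a zero Firefly reading gives −Inf and the well is unusable.
   Log base 2 is a convention choice (fold-change units).
2. `robust_zscore()` — per screen replicate, across miRNAs:
   `z = (x − median) / (1.4826 · MAD)` with `MAD = median |x − median|`.
   The 1.4826 constant makes the scale consistent with a standard deviation
   under normality. A zero MAD is a degenerate distribution and errors by
   default; the pipeline wrapper `score_screen()` instead falls back to
   unscaled deviations from the median (`mad_fallback = TRUE`), which keeps
   noiseless synthetic screens computable — there the fallback score equals
   the planted log2 effect exactly.
3. `median_center()` — per miRNA, subtract the median robust z over analog
   screens (the same library assayed against unrelated 3'UTRs). Any
   per-miRNA bias shared between focal and analog screens cancels exactly;
   this is the screen's control for mimic-specific systematic effects
   (toxicity, transfection efficiency). The baseline uses analog screens
   only, never the focal screen. Note one practical consequence of robust-z
   scaling: a large between-miRNA bias variance also inflates the per-screen
   MAD, shrinking planted effects in z units — centering removes the bias
   but cannot undo the scale inflation.
4. `combine_replicates()` — arithmetic mean over the independent focal
   replicates; miRNAs missing from some replicate are averaged over the
   available ones and flagged.
5. `determine_cutoff()` — ROC over candidate thresholds: midpoints between
   consecutive distinct pooled control scores, plus sentinels beyond both
   extremes. "Interaction" is predicted when a score is strictly below the
   cutoff; the chosen point maximizes accuracy (TP+TN)/(P+N), with ties
   broken first towards higher specificity, then towards the more negative
   cutoff. The specificity tie-break reflects how such screens are used: a
   hit list is expensive to validate, so when two cutoffs classify the
   controls equally well the more conservative one is preferred.
6. `call_hits()` — strict `score < cutoff`; a score exactly at the cutoff is
   not a hit. The conventional operating point is −1.94.

Whether robust z should be computed per plate rather than per screen is not
settled; the package computes it per screen replicate (all miRNAs of one
replicate form one distribution), which is the natural choice when plate
layouts are not modeled. Plate-effect correction is out of scope.

## Seed-match analysis

`find_seed_matches()` scans the given strand of the 3'UTR, 5'→3', for
canonical sites of a mature miRNA (T normalized to U, case-insensitive):

* 6mer — UTR matches the reverse complement of miRNA nt 2–7;
* 7mer-m8 — reverse complement of nt 2–8;
* 7mer-A1 — 6mer with an adenosine opposite miRNA nt 1 (3' of the core
  match on the UTR);
* 8mer — both the m8 match and the A1 adenosine.

Each core occurrence is reported once with its longest applicable type, so
8mer sites do not additionally count as 7mer/6mer. Coordinates are 1-based
and the reported `site_sequence` always round-trips against the UTR. The
7mer-m8/7mer-A1 distinction is kept in `site_subtype` but collapsed to
"7mer" for the class-level analysis, which groups miRNAs by their best
(longest) class and compares interaction-score distributions of each class
against no-site miRNAs with a two-sample Kolmogorov–Smirnov test
(`seed_class_enrichment()`).

`ks_two_sample()` uses the asymptotic Kolmogorov p-value at effective sample
size `n_a·n_b/(n_a+n_b)`, with a reported floor of 2.2e−16. The asymptotic
approximation is a deliberate choice targeted at the class sizes that occur
in library-scale screens; at small n the attainable D values form a coarse
grid and the asymptotic p is visibly discrete and conservative, so the
package's own null-calibration test uses large, unequal groups
(1000 vs 1371) where the p-value distribution is approximately uniform. An
exact small-sample option is noted as future work.

## Expression integration

For a MYCN non-amplified tumor cohort (amplified samples are excluded by
the caller — MYCN amplification saturates expression and breaks the
dose–response logic):

* `correlate_to_mycn()` — per miRNA, correlation with MYCN mRNA
  (Spearman by default), two-sided p, BH adjustment across all testable
  miRNAs, signed significance `pi = -log10(p) · coefficient`, and a call of
  `inverse`/`positive` at q ≤ 0.05. Both Spearman and Pearson are supported
  behind one switch because rank correlation is the method of record for
  the significance calls while product-moment coefficients are sometimes
  preferred for the pi-value scale; the output labels which was used, and
  no choice is silently made for the user.
* `rank_genes_for_mirna()` — genes sorted by decreasing correlation with the
  miRNA; constant genes get coefficient 0 and a flag; all ties break
  lexicographically by gene id so rankings are fully deterministic. Because
  Spearman depends only on ranks, the ranking is invariant to monotone
  transforms of the miRNA vector.
* `gsea_preranked()` / `gsea_collection()` — weighted running-sum enrichment
  score (weight exponent 1): in-set genes add `|s|` normalized over in-set
  genes, out-of-set genes subtract `1/(N − Nh)`; the ES is the extremum of
  largest magnitude. When positive and negative extrema tie in magnitude
  (within 1e−12) the negative one is taken — a deterministic rule that is
  stable under floating-point accumulation order. The null distribution
  comes from random same-size gene sets (gene permutation, the natural null
  for a preranked list; phenotype permutation is out of scope): after
  `set.seed(seed)`, each permutation draws `sample.int(N, Nh)`. NES divides
  the ES by the mean magnitude of same-sign null scores; the FDR pools
  sign-matched null NES across sets in the collection and compares tail
  fractions, capped at 1.
* `classify_activity_relation()` — negative relation to MYCN activity iff
  any MYC(N)-up set has NES < −2 and FDR < 0.25. The positive rule is the
  mirror image (NES > +2, FDR < 0.25) and applies only when nothing
  qualifies negative; if both directions qualify the call is negative with
  an `ambiguous` flag. The mirrored rule is a package decision: only the
  negative criterion has a published operating point, and symmetry is the
  least-informative completion.
* `classify_relevance()` — a screen hit is relevant when either axis is
  inverse/negative and neither is positive; positive evidence alone makes it
  MYCN-induced; opposite signs on the two axes exclude it as conflicting;
  hits absent from the expression platform are `no-data`. The five final
  classes partition the hits, which the integration summary asserts.

`chi_square_2x2()` (Pearson, no continuity correction, 1 df) supports the
enrichment contingency test of negative activity calls among hits vs
non-hits.

## Murine progression dynamics

* `preprocess_cq()` — qPCR detection filter (only Cq < 32 retained; filtered
  entries are missing, never zero) followed by global mean normalization:
  expression = per-sample mean of retained Cq minus Cq, in log2-like cycle
  units with higher = more expressed. The per-sample mean of normalized
  retained values is exactly 0. Samples with fewer than 2 retained values
  are dropped with a warning.
* `fit_genotype_time_regression()` — one model per miRNA,
  `expression ~ time + genotype + time:genotype`, time numeric in weeks, WT
  as reference. The interaction coefficient is the Δslope (TG − WT) and its
  two-sided t-test p is BH-adjusted across miRNAs;
  `pi = -log10(p) · Δslope`. A single interaction model is used rather than
  two separate per-genotype fits because the interaction term directly
  tests the slope difference. An identifiability note: global mean
  normalization re-centers each sample, so fitted slopes are relative to
  the panel-average trend. The synthetic truth tables therefore carry both
  the planted Δslope and the effective (panel-centered) Δslope; the latter
  is what any global-mean-normalized analysis estimates, exactly so at zero
  noise.
* `signature_score()` — each signature miRNA z-scored across samples; the
  sample score is the mean of direction-signed z over usable members, with
  the usable fraction reported. The signed-mean-z construction is a declared
  substitute for the original supplementary definition, which is not
  restated in public text; the shipped 50-miRNA signature fixture is
  synthetic (see `inst/extdata/`, `_synthetic` suffix).
* `differential_expression()` — per miRNA, log2 FC = mean(A) − mean(B) and a
  two-sided Student t-test (equal variance, per the named test; Welch via
  `var_equal = FALSE`), BH across miRNAs. Zero-variance rows are flagged
  not-testable rather than given fake p-values.
* Cross-species comparison uses an explicit assay-to-human-id lookup table
  (`apply_mirna_mapping()`); no sequence-based matching is attempted.

## The synthetic-data generators

The generators produce the three study designs with planted truths; their
defaults are the emulated study conditions:

* **Screen** (`screen_sim_config()`): 470 miRNAs, 29 targeting, planted
  log2 effect −3, additive Gaussian noise (sd 0.3) on the log2 ratio, 2
  independent focal replicates, 36 analog screens, Renilla fixed at 1000.
  Additive Gaussian noise on the log-scale ratio is the simplest model
  matching a log-scale readout. An optional shared per-miRNA bias exercises
  the centering step. Analog screens are pure noise (plus bias), so the
  per-miRNA analog median is ~0 unless bias is planted.
* **Cohort** (`cohort_sim_config()`): 160 samples, one latent MYCN-activity
  scalar per sample; MYCN mRNA = activity + noise; planted miRNAs couple to
  standardized MYCN at ±`coupling_r` (exactly ∓1 when `coupling_r = 1` and
  `noise_sd = 0`); a fraction of genes loads +1 on the latent (the
  MYC(N)-up arm used as gene sets) and an equal fraction loads −1 (MYC
  factors also silence genes). Three generator choices matter for GSEA
  realism, all visible as parameters:
  * the set-to-universe ratio is kept small (default 10%): NES is bounded
    by the reciprocal of the mean null ES magnitude, and that bound drops
    below 2 when the set is a large fraction of the list, making the
    NES < −2 criterion unreachable no matter how strong the signal;
  * the repressed arm puts extreme ranking statistics at both ends of a
    coupled miRNA's list, preventing the gene-permutation null from being
    dominated by one coherent block;
  * gene-level noise (default sd 1.5) keeps the in-set ranking statistics
    of *null* miRNAs close to exchangeable with the background. At much
    lower noise the co-regulated genes are so coherent that any miRNA's
    in-set statistics are variance-compressed relative to background and
    gene-permutation GSEA becomes anticonservative — a real, known
    limitation of gene-permutation nulls under inter-gene correlation, not
    an artifact of this package.
  In addition, `decorrelate_null = TRUE` projects the latent activity and
  MYCN out of every non-planted miRNA in-sample, so the planted truth
  labels are exact for downstream calling. Real cohorts have chance
  coupling instead; setting the flag to `FALSE` restores ordinary sampling
  noise for calibration studies. What passing tests on these cohorts show
  is that the estimators and thresholds behave as specified under the
  designed separation; they do not show that real tumor data are free of
  borderline or chance associations.
* **Time course** (`timecourse_sim_config()`): weeks 1, 2, 6; TG and WT;
  4 animals per genotype per timepoint (24 samples); expression =
  genotype-slope × time; Cq = 25 − expression + Gaussian noise (default sd
  0.25 cycles, a typical qPCR replicate spread). Lower Cq = higher
  expression by construction.

All generators restore the caller's RNG state and are byte-reproducible
given a seed. None of them simulates plate-position effects, transfection
gradients, amplification chemistry, or platform-specific missingness beyond
the Cq detection filter.

## Numerical and edge-case conventions

* BH adjustment, KS, chi-square and the linear fits delegate to the
  standard R implementations; validation and degenerate-input guards live
  in the package wrappers.
* p-values are floored at 2.2e−16 before `-log10` in pi-values, so
  underflow cannot produce infinite pi.
* Empty seed classes and empty reference groups are "not testable", not
  errors; a missing analog baseline excludes the miRNA with a warning; a
  genotype missing from a miRNA's data yields a `not-testable` progression
  record.
* Every ranking tie in the package (gene ranking, ROC candidates, GSEA
  extremum) has an explicit deterministic rule, so identical inputs and
  seeds give byte-identical outputs.

## Problem sizes used by the test suite

The suite exercises the full screen geometry (470 × 38 screens) and the
full murine design, with Monte-Carlo components sized to be decisive yet
quick: 50 replicate screens for the operating characteristics, 200
replicates for Δslope recovery (panel of 40, six planted slopes), 100
random control sets for ROC optimality, 50 tiny instances against the
brute-force GSEA oracle at 1e−9, and 500 replicates for the KS null
calibration. The acceptance script plants an induction |log2 FC| of 1.5,
chosen by a power calculation: at five replicates per arm and BH correction
across a 466-assay panel, a fold change of 1 is right at the significance
boundary (median q ≈ 0.065) while 1.5 is reliably detectable — matching the
magnitude of reported induction responses.

## Known limitations

* Gene-permutation GSEA under strong inter-gene correlation is
  anticonservative; the generator defaults are chosen to stay in the
  calibrated regime, and conclusions about marginal NES values on real data
  should be drawn cautiously.
* The asymptotic KS p-value is unreliable below a few dozen observations
  per group; no exact option is implemented yet.
* The signature score and the murine-human mapping fixtures are synthetic
  stand-ins; analyses of real data must supply the published signature and
  a platform-specific mapping.
* The robust-z scale is estimated per screen replicate; plate-level
  normalization (B-scores, edge effects) is out of scope.
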