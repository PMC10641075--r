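---
title: "Models and methods in mprakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mprakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mprakit implements the computational workflow of a barcoded 3'UTR massively
parallel reporter assay (MPRA): thousands of ~120-nt UTR elements are cloned
behind a reporter, each tagged with several short barcodes, delivered to
cells, and read out by sequencing barcodes from DNA (plasmid or viral
genomes), Input RNA, and optionally TRAP RNA (translating-ribosome
affinity-purified, a proxy for ribosome occupancy). This vignette describes
the models the package fits, the knobs that matter, and the choices made
where the design was genuinely open.

## Library design

`build_library()` constructs a design from a variant manifest and a
reference sequence:

* **Windows.** Each variant yields a reference- and an alternative-allele
  element spanning a 120-nt window centered on the variant
  (`extract_window()`). For even windows a convention is needed; the variant
  base sits at 0-based offset `window/2` (60 nt of left flank, 59 of right).
  For indels, the shared flanks are sized so the *longer* allele still fits
  in 120 nt, so the shorter allele's context is shorter; windows near contig
  ends are clipped rather than erroring. A claimed reference allele that
  disagrees with the reference sequence is an error naming the variant —
  silent substitution would corrupt the design.
* **Shuffled controls.** For a seeded subset of reference elements,
  `shuffle_control()` emits a uniform random permutation of the element's
  letters. Permutation (rather than resampling) conserves the exact
  nucleotide composition, hence GC content and length, making ref-vs-shuf a
  composition-matched contrast.
* **Barcodes.** `generate_barcodes()` draws 9-nt barcodes by rejection
  sampling under three constraints: no homopolymer longer than 3, no
  cloning cut site (NheI `GCTAGC`, KpnI `GGTACC` by default), and pairwise
  Hamming distance at least 2. Separation is enforced with a hash of the
  distance-1 neighborhoods of accepted barcodes, which makes candidate
  screening O(1) and a ~10^4-barcode whitelist a seconds-scale operation.
  Distance-2 separation means a single sequencing error cannot convert one
  valid barcode into another, which is what makes exact-match counting safe.
* **Oligos.** `assemble_oligo()` concatenates
  `primer5 | NheI | element | linker(20 nt) | barcode(9 nt) | KpnI | primer3`
  into a constant 210-nt synthesis oligo and records 0-based half-open
  segment coordinates, so element and barcode round-trip exactly from the
  full sequence. Elements shorter than the 120-nt slot (truncated indel
  contexts) are padded with an `AT`-repeat spacer placed between the 5'
  primer and the NheI site — outside the cloned insert, so the reporter
  transcript is unaffected. The primer sequences shipped in `oligo_layout()`
  are synthetic placeholders of conventional length and are meant to be
  overridden with a user's real priming sites.

`colony_coverage()` reports the Poisson-approximate expected fraction of
design members captured by a given colony count,
`1 - (1 - 1/size)^(colonies * (1 - error_rate))`. This is an
expected-coverage statement, not an all-members-captured confidence; with
9744 oligos, 71,000 colonies, and a 50% synthesis error rate it evaluates
to roughly 0.97.

## The synthetic count generator

`simulate_counts()` generates DNA / Input / TRAP count tables with known
ground truth, following the structure the downstream analysis assumes. Per
barcode *i* of element *e*:

```
p_i  ~ LogNormal(0, plasmid_abundance_sd)         # plasmid copy number
x_i  = p_i * 2^(mu_e + beta_v * [alt] + b_i)      # expression rate
m_ir ~ Poisson(bottleneck_lambda)                 # templates reaching prep
DNA  ~ Multinomial(depth_dna, p)                  # per DNA library
RNA  ~ Multinomial(depth_rna, x * m/lambda * g)   # g = gamma overdispersion
TRAP rates additionally scaled by 2^te_e
```

Defaults and what they emulate:

* `element_effect_sd = 0.55` log2 units. Chosen so that ~99% of element
  means span about three log2 units, the order of the dynamic range a 3'UTR
  tiling screen exhibits for steady-state transcript abundance.
* `barcode_effect_sd = 0.25` log2 units. Barcode random effects `b_i` are
  the nuisance the mixed model exists to absorb; 0.2–0.3 is the regime in
  which a handful of barcodes produces visible spurious allelic effects,
  and 0.3 is the setting used throughout the power analyses.
* `plasmid_abundance_sd = 1.0` (log-normal sdlog). Cloning/synthesis
  efficiency varies far more than biological element effects, and observed
  RNA abundance tracks DNA copy number closely; a wide copy-number spread
  reproduces that DNA-dominated correlation structure.
* `bottleneck_lambda = Inf` (no jackpotting) by default. Finite values
  model the low "library density" failure mode of delivering a complex
  library to a rare cell population: each barcode contributes
  `m ~ Poisson(lambda)` template molecules to library prep, and with small
  `lambda` a few lucky barcodes dominate while others drop out, degrading
  replicate correlations. No quantitative model of the phenomenon exists;
  the generator exposes `lambda` as the single knob and severe settings
  (`lambda ~ 0.1`) produce the expected collapse of between-replicate
  correlation. The same Poisson draw is shared between Input and TRAP
  within a replicate, because both fractions derive from the same
  transduced cells.
* `nb_dispersion = 0`. RNA sampling is multinomial by default; a positive
  value gamma-scales the rates (negative-binomial mixing) for
  over-dispersed libraries. DNA stays pure multinomial: its variability is
  already carried by the copy-number spread.
* `n_dna_replicates = 2` mirrors a viral-prep/plasmid DNA design with few
  DNA libraries against more RNA replicates.

What the generator does **not** emulate: read-level errors and trimming,
PCR duplicates/UMIs, position effects within the construct, and any
sequence-dependent activity (element means are drawn independently of the
element's sequence). Tests passing on simulated data therefore validate the
statistical machinery, not sequence-level biology.

## Quantification

Counts are normalized per sample to counts per million (`cpm_normalize()`).
Per-barcode activity is `log2(numerator CPM / denominator CPM)` within a
replicate: Input/DNA (transcript abundance), TRAP/DNA (ribosome occupancy),
or TRAP/Input (translation efficiency). Cells with a raw count below
`min_count = 10` in either member are dropped, not imputed — consequently
`log2(0)` never arises and no pseudocounts are used.

When several DNA libraries exist, the default denominator is the mean DNA
CPM per barcode (`dna_policy = "mean"`); `"paired"` matches each RNA
replicate with its own DNA library. With few DNA libraries the mean policy
reduces denominator noise; both are available because real designs differ
in whether DNA was prepared per replicate.

Element activity is the intercept of the maximum-likelihood fit of

```
Activity ~ (1 | barcode)      i.e.  y_ij = mu + b_i + e_ij
```

with `b_i ~ N(0, sigma_b^2)`, `e_ij ~ N(0, sigma_e^2)`. The random
intercept absorbs consistent barcode-specific shifts so one outlier barcode
does not drag the element mean. The fit (`fit_lmm()`) profiles the
likelihood analytically over the fixed effects and residual variance at a
fixed variance ratio `lambda = sigma_b^2/sigma_e^2`, leaving a
one-dimensional optimization over `lambda >= 0` (golden-section, tolerance
`1e-10` on the transformed ratio; the `lambda = 0` boundary is always
evaluated and wins ties, which is the non-negativity clamp). ML rather than
REML is used so that likelihood-ratio tests between nested fixed-effect
models are valid. On balanced data the intercept reduces to the grand mean
of barcode means; with a single barcode or `sigma_b -> 0` the fit
degenerates to the sample mean. The test suite cross-checks estimates and
log-likelihoods against `lme4::lmer(..., REML = FALSE)`.

## Differential testing

Allelic (ref vs alt) and element (ref vs shuf) effects are tested with

```
full:    Activity ~ side + (1 | barcode)
reduced: Activity ~ (1 | barcode)
p = P(chisq_1 >= 2 * (ll_full - ll_reduced))
```

(`lrt_pair_test()`). The tested parameter is interior, so the plain
1-df chi-squared reference applies without boundary correction. `log2FC` is
the fixed-effect estimate, reported as alt − ref for allelic comparisons
and ref − shuf for control comparisons (`mpra_comparisons()` sets the
orientation). Non-convergence is reported as `converged = FALSE` with
`p = 1` rather than dropped. P-values are Benjamini–Hochberg adjusted
(`bh_adjust()`, delegating to `stats::p.adjust`).

Distribution-level ref-vs-shuf contrasts use a paired Wilcoxon signed-rank
test (`paired_signed_rank()`): zeros dropped, mid-ranks for ties, exact
tail by a generating-function recursion on doubled ranks for up to 25
non-zero pairs, normal approximation with tie and continuity corrections
above. The in-package implementation exists because the exact tail with
mid-ranked ties is wanted uniformly; `stats::wilcox.test` abandons the
exact computation whenever ties occur, and serves as the cross-check oracle
on tie-free inputs.

`direction_enrichment()` asks whether significant effects skew one way
more than chance. The 2x2 table convention — rows significant vs
non-significant, columns down vs up, one-sided hypergeometric p and the
sample cross-product odds ratio — is a choice; published analyses rarely
print their exact table, so the convention is documented here to be
reproducible rather than claimed to match any particular report.

`grid_search_filter()` sweeps inclusion thresholds
(`min_count >= 10` enforced; barcodes per side; qualifying replicates) and
selects the grid point maximizing the number of BH-significant comparisons.
Ties break toward stringency: largest `min_barcodes`, then
`min_replicates`, then `min_count`. Both threshold settings a practitioner
would use as anchors — at least 3 barcodes with 10 counts in 4 replicates
(cell-line data), and at least 5 barcodes with 10 counts in 6 replicates
(in vivo data) — are representable grid points, and the audit table exposes
the full sweep.

## Barcode-effect power simulation

How many barcodes per allele are needed before barcode effects stop
masquerading as allelic effects? `power_curve()` answers by construction:
draw two disjoint sets of `k` barcodes from a pool tagging a *single* null
element, call one set "ref" and the other "alt", and run the same LRT used
for real comparisons. Any rejection is a false positive caused purely by
barcode sampling. Reported per `k`: quantiles/IQR of `|log2FC|`, the
probability of exceeding a 0.25 log2FC magnitude, and the Type-I rate at
`alpha = 0.05`.

The pool comes from `simulate_pool()` (default 100+ barcodes, 6 replicates,
`sigma_b = 0.3`, `sigma_e = 0.1`), drawing barcode activities directly from
the generative model the count simulator implies. Drawing at the activity
level rather than pushing counts through the full pipeline keeps the pool's
variance components exactly at their nominal values — the quantity the
curve is parameterized by — and makes 10^4 iterations per `k` a
minutes-scale computation; a pool can equally be derived from a
`barcode_activity()` table of real or simulated counts. The default of
10,000 iterations per `k` (overridable) keeps a desk run fast while putting
the Monte-Carlo error on a Type-I rate near 0.05 at about +/-0.2
percentage points.

Two finite-sample caveats are worth knowing. With `sigma_b = 0` the curve
is flat near `alpha` but sits very slightly below it, partly because
pseudo-alleles are drawn without replacement from a finite pool (inducing
negative correlation between the two sides) and partly small-sample LRT
behaviour. With `sigma_b > 0` the test over-rejects at small `k` — the
barcode effect is confounded with the split — and the rate declines as `k`
grows, which is the phenomenon motivating `recommend_barcode_count()`:
the smallest `k` whose Type-I rate is tolerable.

## k-mer classification

`train_classifier()` separates high- from low-activity elements
(`select_extremes()`, default 200 per tail, ties broken by element id) from
sequence alone, using plain k-mer spectrum features: each sequence becomes
the vector of its `4^k` k-mer frequencies (sliding windows, counts divided
by window count; windows containing ambiguous bases are skipped). The
classifier is a linear-kernel soft-margin SVM at cost 1 on standardized
features, with seeded stratified 5-fold cross-validation; AUROC and the
average-precision AUPRC are computed per fold from held-out decision values
and also pooled across folds (both are reported because either pooling
convention is defensible). A full-word linear kernel at `l = k` is the
degenerate case of the gapped-k-mer kernel with no gaps, so the plain
spectrum is the natural simplification of gkm-SVM-style modelling at these
small word sizes. The regularization strength is left at 1 and not tuned:
the validation target is planted-signal recovery and chance-level behaviour
under label permutation, not squeezing out AUROC.

`permute_labels = TRUE` shuffles labels once before folding and is the
negative control: held-out AUROC then concentrates near 0.5.
`score_kmers()` pushes each possible k-mer, encoded as its own one-hot
frequency vector, through the fitted decision function to rank words by
their learned contribution.

A note on separability used by the test suite: a single 6-mer motif planted
once per positive in a 60-nt random background is cleanly separable at
`k = 4` (AUROC >= 0.9), and that is the fixture the tests use. The same
motif diluted into a 120-nt background is only partially separable
(AUROC around 0.8) — a useful reminder that modest AUROCs on real
120-nt-element screens are expected even when genuine sequence signal is
present.

## QC diagnostics

`qc_report()` bundles: pairwise within-fraction Pearson correlations
(pairwise-complete over barcodes, mirroring per-pair scatter plots; raw
counts, CPM, or barcode-averaged activities can each be passed, since
published correlations are variously computed at all three levels);
`dropout_report()` (zero-DNA barcodes, surviving barcodes per element,
fraction of elements with at least 3 barcodes); `jackpot_index()` (share
of counts in the top decile of barcodes, with the Gini coefficient as an
alternative — the phenomenon has no standard statistic, so a simple
scale-invariant one was chosen); and `gc_recovery()` (mean DNA CPM by GC
bin, exposing low-GC cloning dropout).

## Problem sizes and determinism

Every stochastic entry point takes a `seed` and is deterministic given it,
without disturbing the caller's RNG stream. The test suite and the
acceptance script run the design at full scale (649 variants, 9744
oligos), the LRT calibration at 1000 null comparisons, the power curves at
10,000 iterations per `k` on the `{3, 50}` endpoints of the 3–50 grid, and
the classifier at 200 elements per tail — sizes chosen so the whole suite
completes in a few minutes on a laptop while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* The generator plants element effects independently of sequence, so
  design-to-activity learning can only be validated on planted-motif
  fixtures, not emergent biology.
* The LRT relies on the asymptotic chi-squared reference; at very few
  barcodes and replicates it is mildly mis-calibrated (visible in the
  power module), which is a property of the method being modelled, not a
  bug to correct away.
* Barcode counting is exact-match by design (safe at Hamming distance 2);
  there is no error-tolerant rescue of near-miss barcodes.
* `direction_enrichment()`'s table convention is one of several defensible
  constructions; compare conventions before matching numbers across
  analyses.
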