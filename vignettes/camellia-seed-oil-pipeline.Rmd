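---
title: "Seed-oil dynamics during Camellia desiccation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-oil dynamics during Camellia desiccation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camelliaoil)
```

`camelliaoil` analyses fatty-acid and expression time courses from
three *Camellia* germplasms — the *C. oleifera* cultivar Min 43 (M43)
and the *C. meiocarpa* landraces Qingguo (QG) and Hongguo (HG) —
sampled weekly across seed desiccation (weeks 46–54 after anthesis).
This vignette explains the models the package implements, the
parameters that matter, the numerical choices, and what the synthetic
data do and do not establish.

## Internal-standard quantification

Each sample is a methylated kernel-powder extract carrying a known
mass of margaric acid (17:0, default 75 μg), a fatty acid absent from
the sample. FID response is close to proportional to analyte mass, so

$$m_i = m_{IS} \cdot \frac{A_i}{A_{IS}} \cdot rf_i,$$

with $A$ peak areas and $rf_i$ an optional per-species response
factor (default 1, i.e. plain normalisation to the internal
standard). Contents are $m_i$ over kernel dry mass, in %; total oil is
their sum. Mole percent divides each content by a molecular weight
and renormalises to 100.

Two bases are deliberately configurable because the measurement
reports FAME-equivalent masses:

* `fame_to_fa` in `quantify()` (default 1) rescales FAME mass to free
  fatty-acid mass if desired;
* the registry ships free fatty-acid molecular weights (e.g. 256.43
  for 16:0, 282.47 for 18:1); a custom `mw` vector switches the
  mole-percent basis to FAMEs.

Neither choice affects ratios of like quantities (the composition
ratios are ratios of mole fractions), which is why the defaults are
safe for the downstream analyses.

Composition is summarised by three mole-based ratios: USFA/SFA,
MUFA/PUFA and 18C/16C (20C species belong to neither chain class). A
class with zero total yields an `Inf` ratio with a warning rather
than an error, since single-species profiles are legitimate edge
cases in tests.

## Enzyme-activity proxies from pathway pools

In the plastid, KASII elongates 16:0-ACP to 18C acyl-ACP; SAD
desaturates 18:0 to 18:1Δ9; in the ER, FAD2 and FAD3 desaturate
18:1→18:2→18:3, and the elongase complex FAE makes the ω-7 series
18:1Δ11 and 20:1Δ13; FatB releases 16:0 for export. Consequently
every 18C/20C species except the FAE products flows through KASII,
and the desaturation chain nests strictly:
FAD3 ⊂ FAD2 ⊂ SAD ⊂ KASII pools.

The activity proxy for enzyme $E$ over week $t$ is the change of its
downstream pool between consecutive sampled weeks, on replicate
means:

$$\Delta_E(t) = P_E(t) - P_E(t-1), \qquad
  P_E(t) = \sum_{s \in \mathrm{pool}(E)} \bar c_s(t).$$

Three points of interpretation:

* the unit is % dry mass per week — a *relative* activity indicator,
  not a molar flux; no conversion is attempted because pool sizes,
  turnover and export are unobserved;
* 20:0 is assigned to the KASII pool (its C18 precursor passes
  through KASII) even though an elongase acts downstream; the FAE
  proxy tracks only the ω-7 products 18:1Δ11 and 20:1Δ13;
* the FatB proxy is Δ16:0 alone; no correction is made for 16:1
  species consumed by the elongase branch, which are trace (<0.1% dry
  mass) in these seeds.

If a week is missing, the difference between adjacent samples is
divided by the gap in weeks, so a skipped sampling does not inflate
apparent activity; the undivided differences are kept alongside and
telescope exactly (their sum equals last-minus-first pool content, an
invariant the tests assert to 1e-9).

Synchrony among enzymes is summarised as the mean pairwise Pearson
correlation of the Δ series, optionally over a week window. The
statistic is descriptive — the underlying claim ("concerted
fluctuations") is qualitative — so the package reports the full
pairwise matrix as well. A Δ series with zero variance in the window
(typically FAD3 when 18:3 barely moves) has undefined correlations;
its pairs are recorded as missing and excluded from the mean rather
than propagated as NaN.

## Correlation networks

Node series are replicate means per week: total oil plus the ten
species. For every unordered pair, the Pearson coefficient over the
$n$ weeks is tested two-tailed against the t distribution with
$n-2$ degrees of freedom; edges are classed positive/negative when
$p < \alpha$ (default 0.05, the conventional level) and `ns`
otherwise. With $n = 9$ weeks the test is exact under normality and
its finite-sample type-I rate is verified by simulation in the test
suite (2,000 null pairs, rate within 2 SEs of 0.05).

No multiple-testing correction is applied by default — each of the 55
edges is a marginal test, as is usual for these small descriptive
networks — but `correlate(..., adjust = "BH")` turns on
Benjamini–Hochberg control with a logged notice. Replicate-level
pooling (27 points instead of 9) was rejected: within-week replicates
share no biological signal, and pooling would overstate the effective
sample size.

`compare_networks()` reports edges whose class differs between
cultivars; with edge classes, not r values, being the recoverable
output of interest, module acceptance is property-based.

## The cross-cultivar DEG screen

Homologs between the two assemblies are paired by reciprocal best
hit on a similarity-score matrix: (a, b) is kept iff b is a's
best-scoring partner and vice versa. Ties are broken toward the
lexicographically smallest id and logged; a gene with no positive
score has no hit. RBH output is invariant under transposition of the
matrix, which the tests assert on random matrices.

Within each cultivar the late/early fold change is computed on
pseudo-count-stabilised means, $fc = (\bar x_{late} + c) /
(\bar x_{early} + c)$ with $c = 0.1$ FPKM by default, and a binary
significance flag comes from a two-sided pooled-variance t-test on
$\log_2(\mathrm{FPKM} + c)$. The pooled test (rather than the
unequal-variance correction) is a deliberate choice: with two
replicates per timepoint the Satterthwaite degrees of freedom
collapse toward 1 (critical t ≈ 12.7) and the test loses essentially
all power, whereas the pooled test keeps its 2 df; with a common
planted dispersion the equal-variance assumption is also correct in
the simulation design. When both groups have zero variance the t
statistic is undefined and the p-value is defined as 0 when the means
differ and 1 when they agree, which makes the noise-free limit exact.
The negative-binomial machinery of count-based DE packages is
intentionally not reproduced: the screen downstream consumes only a
fold change and a binary flag.

A gene's status is **up** if $fc > 2$ and $p < \alpha$, **down** if
$fc < 0.5$ and $p < \alpha$, and **constant** otherwise. The
significance gate is essential: a fold change of 2.45 with a
non-significant test is still *constant*, which is the only reading
under which the five groups are internally consistent (several
reported group-IV/V genes have fold changes above 2 yet count as
constant in one cultivar).

The screen statistic is the ratio of ratios $r = fc_{M43}/fc_{HG}$.
When $fc_{HG}$ is machine-zero, or $fc_{M43}$ is itself undefined
(gene undetected early), $r$ is the sentinel, carried as `Inf`,
printed as `~`, retained by the screen, and sorted after all finite
ratios. A record is retained when $r > 2$ (or sentinel), at least one
of its KEGG ko annotations is in the lipid-pathway set, and it is not
constant in both cultivars. The shipped `lipid_pathway_kos()` is the
KEGG lipid-metabolism class (ko00061…ko01040, including steroid
biosynthesis ko00100); the screen is applied after restriction to
lipid-pathway homologs, and the group label is carried on every
retained record. The (HG, M43) status pair maps to groups I (up/up),
II (down/down), III (down/up), IV (down/constant), V (constant/up);
anything else is `other`.

`ddct_fold()` implements the standard qPCR relative quantification,
$2^{-\Delta\Delta C_t}$ against a housekeeping gene and a reference
sample, for replaying validation arithmetic.

The curated 58-record candidate table ships in
`inst/extdata/candidate_degs.tsv`. It reports fold changes and group
labels but no p-values, so `candidate_table()` derives per-cultivar
significance flags from the group patterns themselves (I–III: both
cultivars significant; IV: HG only; V: M43 only) and exposes nominal
p columns so that the table can be replayed through the classifier
and the screen. One HG id appears in two rows (in groups IV and V,
with different M43 partners); the table is kept verbatim.

## The synthetic-data generators

`scenario_spec()` fixes the study conditions; both generators consume
it and all randomness flows from its single seed through a private
RNG stream (the caller's RNG state is untouched; a fixed seed gives
byte-identical TSV output).

**Time courses.** Trajectories are piecewise-linear weekly knots —
simple and inspectable — for 10 species × 9 weeks × 3 replicates,
with multiplicative lognormal replicate noise of CV 5% (typical
GC-FID replicate scatter). The templates emulate the three observed
phenotypes at realistic magnitudes (total oil ~25–60% dry mass,
oleic acid dominant, palmitic and linoleic acid a few % each, the
remaining species ≤1%):

* *QG-like*: near-linear rise through week 53, then a single-week
  loss of exactly 25% of total oil (every species scaled, so the
  noiseless loss is exact by construction);
* *M43-like*: biphasic accumulation peaking at weeks 49 and 52, then
  30% of the week-52 total lost across weeks 53–54. The two trace
  species 20:1Δ13 and 16:1Δ11 are spared from the terminal scaling so
  that the planted network contrast — 20:1 correlates with total oil
  in QG/HG but not in M43 — survives the shared drop;
* *HG-like*: fast rise to week 47, gentle climb thereafter, no loss;
  18:2 moves with the 18C pathway until week 50 and against it
  afterwards (declining while 18:1Δ9 and 18:0 keep rising), planting
  the post-week-50 FAD2/KASII discordance.

The truth record stores the noiseless trajectories and the proxy sign
pattern per enzyme, plus a per-interval reliability flag: a sign is
flagged reliable when the noiseless pool change exceeds 2.5 standard
deviations of the replicate-mean difference noise,
$|\Delta| \ge 2.5\,(\mathrm{CV}/\sqrt{r})\sqrt{P_t^2+P_{t-1}^2}$.
Weekly changes in the templates were sized against this bound *a
priori* (most intervals sit at 3σ or more), so sign recovery from
noisy data is tested on reliable intervals, exactly on noiseless
runs; genuinely small fluctuations (HG's plateau weeks) are excluded
rather than pretending they are recoverable at 5% noise.

**Expression.** 400 lipid-pathway homolog pairs (58 of them planted
candidates in groups of 6/5/6/15/26), 100 off-pathway pairs (half
strongly DE, so the pathway filter — not the ratio cutoff — must
remove them), and 20 unpaired decoy genes per cultivar whose
similarity scores are deliberately non-reciprocal. Counts are
negative binomial with dispersion 0.1 around baselines of 300–3,000,
two replicates per timepoint, converted to FPKM at equal simulated
sequencing depth (a constant per-million factor; with ~11% of this
small cohort strongly DE, per-sample total-count normalisation would
let the planted genes shift the denominator and corrupt the constant
arms — an artefact of desk scale, not of the method). Planted DE arms
use |log2FC| of 5–7: a power computation for the 2-replicate pooled
t-test at dispersion 0.1 puts per-arm power near 1 at these effect
sizes, and the observed candidate table is full of comparable or
larger changes (fold changes up to 115, ratios to 732). The
zero-dispersion limit is fully deterministic (`counts = mu`), under
which the screen must recover exactly the 58 planted candidates with
exact labels.

## Problem sizes and determinism

The test suite and acceptance script run the full pipeline at the
study's own scale: 3 cultivars × 9 weeks × 3 replicates × 10 species
for the metabolic half, 500 homolog pairs (plus decoys) × 2
timepoints × 2 replicates for the transcriptomic half, 2,000
simulated null pairs for the type-I check. Everything completes in
seconds on one CPU. Fixed seeds make every simulation reproducible;
the generators never touch the global RNG stream.

## Known limitations

* The activity proxies are net pool changes: synthesis minus
  degradation/export. A constant pool can hide fast turnover, and a
  negative delta is not evidence that the enzyme stopped — only that
  its products declined.
* The correlation networks use 9 weekly points; power is limited and
  edge classes near the threshold are unstable, which is why
  cross-cultivar comparisons are reported as class differences, not
  effect differences.
* The pooled t-test at n = 2 is a pragmatic significance gate, not a
  serious error model for counts; conclusions should rest on the fold
  changes and the screen structure, which is how the pipeline uses
  it.
* The synthetic generators emulate trajectory shapes, replicate
  noise, NB counts and ortholog structure, but not GC drift,
  library-size artefacts, isoform ambiguity or annotation error —
  passing tests demonstrate the pipeline's correctness on its stated
  model, not robustness to those real-data pathologies.
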