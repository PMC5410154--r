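---
title: "Detecting ontogenetic shifts in venom-gland expression with venomont"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ontogenetic shifts in venom-gland expression with venomont}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomont)
```

## The problem

Snake venoms are compositions: what matters biologically is the relative
abundance of toxin transcripts in the venom gland, not their absolute read
counts. Many pit vipers shift venom composition as they mature, and
identifying *which* toxin paralogs drive that shift requires comparing
adult and juvenile venom-gland transcriptomes while guarding against two
confounders: the compositional nature of expression data (one transcript's
rise forces every other proportion down) and geographic expression
variation between populations.

`venomont` implements a complete desk-scale pipeline for this problem,
modeled on the study design used for the eastern diamondback rattlesnake
(*Crotalus adamanteus*): paired adult/juvenile venom-gland transcriptomes
from five populations (ANF, BR, CAL, ENP, LSG), a consensus toxin
transcriptome, coverage-based presence/absence calls, a compositional
outlier test with a nontoxin-derived null, and a toxicity read-out
(Spearman-Karber LD50).

## The core statistic

Expression is measured in transcripts per million (TPM) and transformed
with the centered log-ratio (clr):

$$\mathrm{clr}(x)_i = \ln x_i - \frac{1}{D}\sum_{j=1}^{D} \ln x_j,$$

per sample column. Exact zeros are floored at 1.0 TPM first
(`replace_zeros()`), the smallest value distinguishable from noise at
typical sequencing depths, so the logarithm is defined. The clr maps the
simplex to a space where differences are interpretable and each column
sums to zero.

For each population we form the per-transcript difference
$\delta = \mathrm{clr}(\text{adult}) - \mathrm{clr}(\text{juvenile})$.
Because a single adult/juvenile pair offers no within-population
replication, the null distribution of $\delta$ is estimated empirically
from the thousands of nontoxin transcripts in the same pair: the 99th
percentile of $|\delta|$ over nontoxins is the outlier threshold, and a
toxin is flagged up (or down) when its $\delta$ strictly exceeds the
threshold (or falls strictly below its negative). The percentile uses
linear interpolation between order statistics (R's type 7), exposed as
`quantile_type` in `pair_outliers()`.

A toxin is then called ontogenetically variable only when it is an
outlier in at least 3 of the 5 population pairs **and** at least 3 of
those outliers agree in direction (`consensus_call()`). The majority
requirement is what converts five unreplicated pairwise comparisons into
a range-wide call and screens out population-specific expression
differences. Calls can be cross-checked against external differential
expression detections (e.g. DESeq/DESeq2 flag tables at FDR 0.1) with
`intersect_detections()`; those methods are consumed as input tables,
never re-run.

```{r}
res <- repro_table5()
c(up = res$n_up, down = res$n_down, confirmed = res$n_confirmed)
```

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `floor` | 1.0 TPM | replacement for exact zeros before the log |
| `percentile` | 99 | nontoxin null percentile (per pair) |
| `min_nontoxins` | 100 | smallest null set accepted for a stable percentile |
| `min_outlier` | 3 of 5 | outlier majority for a consensus call |
| `min_same_direction` | 3 of 5 | directional majority for a consensus call |
| `fdr_threshold` | 0.1 | external-detection cutoff (strict `<`) |

Two deliberate guards: `pair_outliers()` refuses a nonpositive null
threshold (a degenerate null where >99% of nontoxin differences are
exactly zero would otherwise flag everything), and it refuses fewer than
`min_nontoxins` null transcripts. The clr basis is whatever matrix is
supplied; transforming a toxin-only slice is allowed but triggers a
provenance warning, because the 59-toxin simplex is not the full
transcriptome simplex.

## Upstream: consensus transcriptome construction

The assembler (`extend_seed()`, `assemble()`) is a greedy seed-extension
scheme: a seed read grows at either end when a read's sequence exactly
matches the terminal 120-nucleotide window and reaches beyond it. The
long exact overlap is the point - at 2% nucleotide divergence a 120-mer
from one paralog almost never occurs verbatim in its sister, so toxin
paralog families assemble apart instead of collapsing. Only reads with
every base at phred >= 30 participate, and contigs supported by fewer
than 200 assembled reads are dropped. Where candidate extensions
disagree, the majority base per position wins; an exact tie stops the
end and flags the contig rather than guessing, which trades completeness
for never fabricating a chimeric join.

Assembled transcripts are clustered at nucleotide divergence thresholds -
1% within an individual, 1.5% across individuals - and each cluster is
represented by its column-majority consensus (`cluster_transcripts()`,
`consensus_sequence()`; exact ties become IUPAC codes). Divergence is the
p-distance of a global alignment (match +1, mismatch -1, gap -2), and
IUPAC codes count as matching any compatible base. Clustering is single
linkage because a divergence ceiling describes connectivity, not a
centroid; complete linkage is available behind the `linkage` flag for
users who want the ceiling enforced within clusters. Chimeras are
screened by coverage shape (`chimera_screen()`): the ratio of median
depths in adjacent 100-base windows, flagging at ratio >= 5. Both knobs
are exposed since the underlying judgment ("strongly multimodal or
extremely uneven") is qualitative.

## Presence/absence calling

A transcript is absent from a transcriptome when strictly more than 10%
of its coding sequence has depth strictly below 5x. The internal mapper
(`map_reads()`) is a batched seed-and-verify matcher: each read is split
into `max_mismatches + 1` disjoint bands, exact band hits enumerate all
candidate placements (pigeonhole), and candidates are verified end to end
with at most 2 substitutions. Reads tying across near-identical paralogs
are spread fractionally (weight 1/k) so that neither copy is starved into
a spurious absence; random single assignment is available as an
alternative. Depth is computed over the supplied reference sequence,
which in this pipeline is the coding sequence. Read subsampling for
depth-sensitivity analyses is uniform without replacement under a
recorded seed.

## Toxicity: Spearman-Karber LD50

The assay design is a two-fold serial dilution (`design_dilution_series()`,
e.g. a 4.89 mg/kg top dose) with eight animals per group. The untrimmed
Spearman-Karber estimator works on log10 dose in its trapezoid form,

$$\log_{10}\mathrm{LD}_{50} = \sum_i (p_{i+1}-p_i)\,\frac{x_i+x_{i+1}}{2},$$

which reduces to the textbook $x_k + d/2 - d\sum p_i$ under equal log
spacing and extends cleanly to unequal spacing (with a warning). When
mortality does not bracket 0 and 100%, the curve is completed by
assumption one dilution step outside the tested range - with an explicit
warning, never silently, since that is an extrapolation. The standard
error is the binomial form $\sqrt{\sum p_i(1-p_i)/(n_i-1)\, d_i^2}$. A
0-10% trim and a weighted pooled-adjacent-violators pre-adjustment
(`monotone_adjust()`) are provided for robustness experiments but are off
by default, as the base estimator tolerates mild non-monotonicity.

## What the synthetic generators emulate

Every stage is testable offline because `gen_expression_dataset()`,
`gen_paralog_family()`, `gen_reads()`, `gen_chimeric_transcript()` and
`gen_dose_response()` generate inputs with the statistical structure the
analysis assumes, alongside truth tables so recovery tests never re-derive
ground truth from outputs.

The expression generator draws per-transcript log-TPM baselines (toxins
centered near ln 2000, nontoxins near ln 50, both with SD 1.5, echoing the
skew of venom-gland transcriomes), adds optional per-population effects,
and gives each age class independent Gaussian noise scaled so the
adult-juvenile *difference* has SD `log_noise_sd`; planted toxins receive
their log fold-change in every adult column, and columns renormalize to
one million TPM. The defaults used throughout the recovery tests are the
study's shape: 2,000 nontoxins, 59 toxins, 5 populations, 12 planted
effects of $|\mathrm{lfc}| = 2$ (natural log), noise SD 0.4. The noise SD
is a free parameter - no empirical dispersion for nontoxin adult/juvenile
differences is published - so 0.4 was chosen once as a plausible
magnitude (roughly a 1.5-fold typical between-age wobble) and not
revisited; a Student-t option (`noise_df`) exists to probe how the
empirical percentile behaves under heavy tails. Read simulation covers
uniform or evenly tiled starts (tiling guarantees end-to-end coverage for
exact-assembly tests), per-base substitution errors, uniform phred
scores, and transcript dropout. Dose-response simulation draws binomial
deaths under a logistic tolerance curve on log10 dose.

What the generators do **not** emulate - and hence what passing recovery
tests cannot certify about real data: length- or GC-dependent coverage
bias, indels and structural variation between paralogs, quantification
uncertainty from multi-mapping (TPMs are taken as given, as the pipeline
consumes an external quantifier's estimates), library-size or batch
effects beyond the compositional closure, and correlated noise across
populations. A single global seed fans out to per-component seeds through
a fixed hash (`split_seed()`), so adding one generator call to a script
never perturbs another's stream.

## Numerical and design choices

* Strict inequalities everywhere the rules state them: `> threshold` for
  outliers, `> 10%` low fraction, `< 5x` depth, `< 0.1` FDR. Boundary
  cases are part of the test suite.
* Direction counting uses only comparisons where the toxin was an
  outlier, so `n_up + n_down = n_outlier`; with the 3-of-5 defaults a
  transcript can never satisfy both directions.
* Assembly output is made order-independent by sorting reads
  lexicographically by id before extension.
* Detection tables store the printed p-value column verbatim; censored
  (">0.1") and undefined ("NA", from zero expression) entries both parse
  to missing and are never detections.
* Problem sizes in the test suite (1,000-nt transcripts, depth 30-40,
  100 recovery seeds, 1,000 simulated dose tables) were chosen as the
  smallest scales at which the relevant asymptotics visibly hold.

## Limitations

The two printed study LD50s (3.46 and 2.79 mg/kg) cannot be recomputed
here because the underlying per-dose mortality counts are unpublished;
the estimator is instead validated on closed-form cases and simulation.
Likewise the study's genome-wide DESeq/DESeq2 totals require the
unpublished nontoxin count matrices, and the printed mean total SVMP
TPM values are not recoverable from the published per-individual table
(their averaging basis is not stated), so the summation utility is
provided without asserting those figures. The internal mapper is
substitution-only and end-to-end; it is a desk-scale stand-in for a
production aligner, adequate for the absence rule it serves.
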