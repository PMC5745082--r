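---
title: "Methods: from coding variants to conditional growth predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from coding variants to conditional growth predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthpred)
```

This vignette documents the model implemented by `growthpred`, the
assumptions behind each stage, the tunable parameters, and the design
choices made where the procedure was genuinely open. It also explains
what the synthetic-data generator does and does not emulate, so that
passing tests are read for what they actually demonstrate.

## 1. Variant effects: predictor outputs to P(neutral)

Every coding variant of every strain (relative to the reference genome)
receives a probability of being functionally **neutral**:

* **Missense, SIFT channel.** The SIFT deleteriousness probability $p$
  maps through the logistic
  $1/(1+e^{-(0.625\,\ln(p + 1.527\times10^{-4}) + 1.971)})$. The
  pseudocount keeps the log finite at $p = 0$ and equals the smallest
  observed nonzero SIFT value of the calibration set; "log" is the
  natural logarithm throughout this channel, consistent with the
  binning axis used for fitting.
* **Missense, FoldX channel** (used only when no SIFT value exists):
  $1/(1+e^{-(s\cdot 1.465\,\Delta\Delta G + 1.201)})$ with an explicit
  orientation flag $s = \pm 1$. As printed, the positive slope makes
  destabilizing (positive) $\Delta\Delta G$ *more* neutral, which
  contradicts the biophysical reading; the likely-dropped minus sign is
  therefore switchable (`default_calibrations(foldx_sign = -1)`)
  without touching the coefficients, and no silent choice is made. The
  synthetic generator plants deleterious FoldX values as strongly
  *negative* $\Delta\Delta G$, i.e. consistent with the printed
  $s = +1$ orientation.
* **Termination heuristics.** A premature stop within the last 16
  residues: 0.99 (too short a truncation to matter); earlier stops and
  start/stop-codon losses: 0.01. A reference gene absent from the
  strain: 0.01 (applied at the disruption stage).

`fit_calibration()` re-estimates a channel from labeled tolerated /
deleterious mutations: the predictor axis is split into `n_bins = 20`
equal-count bins, the per-bin proportion tolerated (clipped to
$[0.01, 0.99]$) is logit-transformed, and a line is fitted by least
squares. Equal-count bins and the logit least-squares fit are our
choices — the binned-proportion construction itself does not prescribe
them — and parameter recovery on generated sets of $10^4$ mutations is
within $\pm 0.1$ (slope) and $\pm 0.3$ (intercept) of the generating
coefficients. Perfectly separated labels abort the fit explicitly
rather than returning a divergent slope; the clipping mildly flattens
extreme bins, which costs well under 0.02 in recovered slope at these
sizes.

## 2. Disruption scores

For gene $g$ in strain $s$ with retained variants $i = 1..k$:
$$P_{s,g}(AF) = 1 - \prod_{i=1}^{k} P_i(\mathrm{neutral}),$$
capped at 0.99; an absent gene scores 0.99 outright (absence beats any
called variant — an absent gene has no variants by construction), and a
present gene with no retained variants scores 0. The cap keeps
$\ln(1 - P)$ finite downstream and coincides with the absence value,
the largest single-event disruption defined.

**Frequency and founder filtering.** Variants seen at high panel
frequency are unlikely to be deleterious. Because panels contain
near-clonal groups, strains are first single-linkage clustered on
phylogenetic distance (default cut 0.001, mirroring the duplicate
cut-off used on MinHash distances) and frequency is counted as *the
fraction of clusters with at least one carrier* — one vote per lineage.
Events at or above 10% (inclusive) are dropped; reference genes absent
in at least 10% of clusters generate no absence events at all; and
events carried by *every* member of a declared founder group (e.g. all
descendants of one evolution-experiment ancestor) are removed for that
group, as they predate the experiment. Whether the original filter
counted strains or clusters is ambiguous; cluster counting is the
default here and strain counting is available
(`frequency_unit = "strain"`). The filter is idempotent, which the
tests assert.

Note the interaction with panel size: in a 3-strain panel any singleton
event already has 33% frequency, so toy analyses must relax
`freq_threshold`. The filter is meant for panels of dozens to hundreds
of lineages where genuinely rare events sit far below 10%.

## 3. Conditional scores, weights, complementation

$$S_{s,c} = \sum_{g \in \mathrm{set}(c)} \frac{1}{E_s} W_{g,c}
\ln(1 - P_{s,g}(AF)), \qquad
E_s = \frac{1}{n} \sum_{g=1}^{n} \ln(1 - P_{s,g}(AF)).$$

Every summand is a product of two non-positive factors and a
non-negative weight, so $S \ge 0$; $S$ measures, roughly, $n$ times the
weighted fraction of the strain's total log-divergence that falls in
the condition's essential set. Strains with $E_s = 0$ are clones of the
reference under the model and score 0 rather than dividing by zero.

**Weight orientation.** $W_{g,c} = -\log_{10}(F_{g,c})\, C_g / N_c$ as
rendered, which *up-weights* genes with promiscuous knockout phenotypes
($C_g$ of $N_c$ screen conditions significant). Reading $C_g$ as a
specificity correction suggests the inverse, $N_c / C_g$. Both are
first-class (`weight_mode = "as_rendered" | "inverted"`), with
`"uniform"` as the unweighted control; nothing is chosen silently.
$\log_{10}$ appears only inside $W$; all other logs are natural.

**In-silico complementation.** $\Delta S_{s,c}(g)$ is the score drop
after setting $P_{s,g}(AF) = 0$ *with $E_s$ held fixed*: the change
described is a local perturbation of the score, and holding $E_s$
makes $\Delta S$ exactly the gene's own summand, so per-gene deltas add
up to $S_{s,c}$ — an identity the tests check to machine precision.
A pair is *restorable* if $\Delta S > 0.01\, S^{max}_{s,c}$, where
$S^{max}$ replaces every set gene's disruption by the panel-wide
maximum $P_{max}(AF)$. Note this 1% rule interacts with weight
heterogeneity: a causal gene whose weight share $W_g / \sum W$ falls
below roughly 1% can stay below the threshold no matter how disrupted
it is.

## 4. Evaluation: PR curves and randomization nulls

Defect strains are the positives. The PR curve sweeps all score
thresholds with tied scores entering as one group (removing order
dependence), and the area is the step-wise sum
$\sum_j \Delta R_j P_j$ — no trapezoidal interpolation, which is
known-biased in PR space. The ROC area is trapezoidal and equals the
normalized rank-sum statistic; both areas are invariant under strictly
monotone transforms of the scores, which is why the min–max scaling of
replicate score vectors (performed for fidelity to the original
procedure) provably cannot change any area.

Three nulls, each at $R$ replicates (10,000 by default): shuffled
strain labels; donor essential-gene sets from other conditions (drawn
without replacement until the donor pool is exhausted, then with
replacement, so the draw is deterministic under the seed); and random
reference-gene sets of matched size with uniform weights. Empirical
p-values use the add-one rule $p = (1 + \#\{A_r \ge A\})/(1 + R)$,
corrected across conditions by Benjamini–Hochberg within a strategy.

**Finite-sample bias of the step-wise PR area.** Under random ranking
the step-wise area does *not* have expectation equal to prevalence: it
is biased upward by $O(1/n_{pos})$ (measured: +0.023 at
$n_{pos} = 5/200$, +0.022 at $20/200$, +0.0002 at $10^4/5\times10^4$).
The mean of shuffled-label replicate areas therefore converges to
prevalence only as the positive count grows. The acceptance test
checks this convergence at $n_{pos} = 6\times10^4$–$7.5\times10^4$
(where the bias sits inside the $3\,\mathrm{SE}$ Monte-Carlo band of
1,000 replicates), and the unit tests assert the panel-scale statement
that the null mean sits within the replicate spread of prevalence,
above it.

## 5. Phenotype QC and S-scores

The chain mirrors high-density colony screens: per-plate time-point
selection (median colony size within 1900–3600 px for natural-isolate
plates, 1300–3600 px for evolved-clone plates; eligible time points
ranked lexicographically by roundness fraction, fraction above the
lower size bound, size IQR, and replicate correlation — the order as
listed, since no weighting is specified); removal of systematically
missing colonies (zero size in > 2/3 — a strict reading of "more than
66%" — of a condition's plates, unless all of a strain's replicates on
a plate are zero, which is a genuine phenotype); removal of
mis-recognized colonies (size < 1000 px with circularity < 0.5, or
size ≥ 1000 px with circularity < 0.3); multiplicative edge correction
of the outermost two rows/columns to the interior median (a ratio
preserves relative differences within the edge; "corrected to match
the median" fixes no operator); and a leave-one-out variance jackknife
that flags a replicate whose removal drops the replicate-set variance
by more than 90% (size) or 95% (circularity).

The published screens feed an externally published scoring algorithm
run with default parameters; re-implementing it exactly is out of
scope here, so the package substitutes a documented pooled modified
t-score: $S = (\bar{x}_c - \bar{x}_{ref}) / \sqrt{\sigma^2 (1/n_c +
1/n_{ref})}$, with the reference mean and variance pooled across the
strain's conditions and $\sigma$ floored at the plate-wide median
replicate SD. The matrix functions also accept precomputed S-scores,
so real screen output can be dropped in. Numeric agreement with
published S-scores is *not* claimed. S-scores are quantile-normalized
per condition to the average empirical distribution
(`limma::normalizeQuantiles`), a null normal is fitted robustly
(median, MAD — the reference screens' exact FDR recipe is not fully
specified), and BH-corrected lower-tail calls at 5% FDR mark growth
defects; positive deviations are never called.

**Attainable power of the caller.** Two effects bound the power of
this caller on a matrix with defects at $S \approx -4$ over an
$N(0,1)$ null: at low defect fractions the BH cutoff sits near
$p \sim 10^{-3}$, so the upper tail of $N(-4, 1)$ defects cannot be
called (measured power 0.60 at a 0.6% fraction); at high fractions the
median/MAD null fit absorbs part of the contamination (scale estimate
1.58 at 25%, power 0.17). The power test therefore plants *tight*
defects ($sd = 0.25$) at an 8% fraction, where the closed-form
normal/BH calculation predicts ≈0.96 power and 0.965 is measured; with
broad $N(-4,1)$ defects, as the phenotype generator produces by
default, recall at 5% FDR is structurally in the 0.6–0.9 range. The
false-call rate on null-only matrices is, by contrast, essentially
zero.

## 6. The synthetic panel: what it emulates, and what it does not

`gen_strain_panel()` produces all pipeline inputs plus ground truth.
Defaults, chosen once as desk-scale stand-ins for a real panel:

| parameter | default | meaning |
|---|---|---|
| `p_lost` | 0.005 | per strain × essential-gene loss probability |
| `frac_absent` | 0.3 | losses realized as gene absence (vs deleterious variant) |
| `frac_essential` | 0.03 | genes essential per condition |
| `fdr_range` | $[10^{-6}, 0.05]$ | screen FDR p-values, log-uniform |
| `variant_rate` | 0.1 | background neutral variants per gene per strain |
| `frac_noncausal` | 0.3 | loss events hitting never-essential genes |
| `flip_rate` | 0 | phenotype label flips |

Planted deleterious events are *high-confidence* calls: SIFT
$p \in [0, 10^{-4}]$, FoldX $\Delta\Delta G \in [-5, -3]$ kcal/mol,
premature stops outside the last 16 residues, start/stop losses, or
absences — all give $P(AF) \ge 0.96$, comparable to the heuristic
constants on the log scale, so that planted causes are uniformly
recoverable. Neutral background variants have SIFT $p \in [0.2, 1]$ or
$|\Delta\Delta G| \le 0.5$ (high neutrality under the shipped
calibrations), plus occasional harmless late stops. Phylogenetic
distances come from a random binary tree (`ape::rtree`), giving
realistic clade structure without a tree-file dependency; each strain
is effectively its own lineage at the default cluster cut.

Two deliberate departures from realism, both consequences of the
pipeline's own definitions:

* **Background variants are a noise source.** The $1/E_s$ correction
  amplifies whatever little disruption a near-reference strain
  carries: a strain whose only variant is one neutral substitution in
  a set gene would score maximally. "Noiseless" recovery runs
  therefore set `variant_rate = 0` (with `flip_rate = 0` and
  `frac_noncausal = 0`); under those conditions the pipeline separates
  defect from no-defect strains *completely* in every condition, which
  the acceptance test asserts at 200 strains × 500 genes × 20
  conditions with 10,000-replicate nulls. With the default background
  load the separation is strong but imperfect — exactly as with real
  panels.
* **Clean colony plates are deterministic.** The leave-one-out
  variance flag is scale-free: *any* continuous within-quad noise
  makes it fire on ~13.5% of clean Gaussian replicate sets (measured),
  and through the unconditional edge correction even between-strain
  size spread leaks into clean quads. Clean colonies therefore share
  their plate's size exactly (`strain_sd = 0`, constant circularity),
  isolating the contamination logic: planted ≥10× outliers are flagged
  completely, clean plates flag nothing. Real plates have replicate
  noise and would be flagged at a base rate by this rule — a property
  of the jackknife definition, not of the generator.

The generator does **not** simulate nucleotide sequences, codon
structure, linkage between variants, or epistasis; passing recovery
tests demonstrate that the scoring machinery recovers the model's own
planted structure, not that the model captures those aspects of real
panels.

## 7. Validation scale and numerical choices

The shipped validation uses: 200 strains × 500 genes × 20 conditions
for end-to-end and complementation recovery ($R = 10^4$ label
permutations per condition); $3\times10^5$-element score vectors for
the null-calibration convergence; 1,000 × 50 matrices for FDR
behaviour; and 16 × 24 × 3 colony plates for the QC chain. Key
numerical constants: disruption cap 0.99; bin-proportion clipping
$[0.01, 0.99]$; add-one empirical p-values; $F_{g,c} = 0$ clipped to
the smallest positive double with a warning; ties grouped in every
threshold sweep; complementation deltas forced to $+0$ to avoid
IEEE negative zeros.

## 8. Known limitations

The essentiality table is an input — deriving it from raw KO-screen
colony data is out of scope, as are orthology inference, pan-genome
construction, GWAS-style association, enrichment statistics, and
condition clustering. Background-dependent essentiality and epistasis
are not modelled: a gene's weight is the same in every strain. The
simplified S-score approximates, but does not reproduce, the published
screen scoring; analyses that depend on exact S-score values should
import them.
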