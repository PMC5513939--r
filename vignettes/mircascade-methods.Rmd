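---
title: "Methods: the candidate cascade, its statistics, and the simulated study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the candidate cascade, its statistics, and the simulated study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
options(mircascade.verbose = FALSE)
```

## The model

`mircascade` nominates disease-associated miRNAs by demanding concordant
differential expression across two independent human case/control cohorts
and a transgenic mouse model, then carries the candidates into seed-based
target analysis. The pipeline is deliberately rule-based rather than
model-based: there is no negative-binomial GLM or empirical-Bayes shrinkage,
because the procedure it packages is a threshold cascade on fold changes of
group means. That makes every decision auditable — each stage is a predicate
per miRNA — at the cost of no error control on the ratios themselves; the
synthetic-data module (below) is how we quantify the operating
characteristics of the cascade instead.

### Quantification

A read counts toward a miRNA locus iff it is mapped with edit distance 0,
lies on the locus strand, and its interval is fully contained in the locus
interval. Containment (not mere overlap) is required because mature miRNA
reads lie within annotated loci; a read contained in several loci counts
once per locus, with the ambiguity logged, which is the simplest auditable
rule for paralogous clusters. RPM normalization divides each sample by its
total reads assigned to miRNA loci and scales to 10^6 — the denominator is
self-contained given a count table; an externally supplied per-sample total
can be used instead (`rpm_normalize(totals=)`). The expression filter keeps
a miRNA when its mean RPM across *all* samples of a dataset (cases and
controls pooled) is strictly above 5.

### The selection cascade

Fold changes are ratios of group means with a pseudocount:
$\mathrm{FC} = (\bar x_{case} + c)/(\bar x_{ctrl} + c)$, $c = 0.5$ RPM by
default. "More than $f$ change" is read symmetrically on the ratio scale and
inclusively at the boundary: $\mathrm{FC} \ge 1+f$ or
$\mathrm{FC} \le 1/(1+f)$. Inclusive boundaries make threshold tests
unambiguous; symmetry treats up- and down-regulation alike.

The human rule keeps a miRNA that changed more than 50% in **both** cohorts,
or changed at least 2-fold in **exactly one** cohort while the other stayed
inside a ±20% no-change band. The two published phrasings of this rule
differ (the looser "in either dataset" vs "with no change in the other
group"); we implement the stricter form and expose the band width in
`selection_thresholds()`, since "no change" is never quantified in the
source procedure. Survivors must then change more than 25% in the mouse
model, with the same sign of log2 fold change in all three datasets, and
must be the only member of their seed family (identical nucleotides 2–8) in
the supplied catalog — the standard miRNA-family definition, used here
because a seed-sharing paralog confounds inhibitor and target attribution.

All thresholds live in one validated object:

```{r}
unlist(selection_thresholds())
```

### Seed sites

The seed is miRNA nucleotides 2–8; a target UTR must contain the reverse
complement of (part of) it. With the UTR stored 5'→3', a canonical site
reads `[m8 match][6mer core][A1 position]`: the 6mer core is the reverse
complement of nucleotides 2–7, the m8 match extends it one base 5', and the
A1 position — the UTR base opposite miRNA nucleotide 1 — is the base
immediately 3' of the heptamer, which scores only when it is an `A`
(TargetScan convention). `scan_utr()` finds all, including overlapping,
core occurrences and classifies each as 8mer, 7mer-m8, 7mer-A1 or 6mer;
6mer sites are reported but low-confidence and can be dropped with
`min_class = "7mer"`. Conservation is *not* computed: conserved-target gene
lists are consumed as an input file.

### Enrichment

Genes down-regulated strictly below 0.8-fold under treatment are intersected
with the predicted-target list, and the intersection is tested against each
gene set with the hypergeometric upper tail
$P(X \ge k) = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$,
computed in log space (log-sum-exp over `lchoose`) so genome-scale arguments
do not underflow. Terms are ranked by raw p — matching the procedure this
reproduces, which used a database front-end without correction — with ties
broken by larger overlap then term id so the ordering is total and
deterministic; a Benjamini–Hochberg column is emitted as a clearly labeled
extra. The universe defaults to all genes in the expression-ratio table,
the only universe actually observable from the inputs.

### qPCR and group statistics

Relative quantity is $2^{-\Delta\Delta C_t}$ with
$\Delta C_t = C_t^{target} - C_t^{reference}$ and the calibrator group's mean
$\Delta C_t$ as baseline; amplification efficiency is fixed at perfect
doubling (efficiency calibration is out of scope). The "two-tailed t-test"
is implemented as the equal-variance Student test (the common convention for
small qPCR replicate groups; Welch via `var_equal = FALSE`), with the
degenerate both-variances-zero, equal-means case returning $p = 1$ by
convention. The rank-sum test enumerates all $\binom{n_x+n_y}{n_x}$ rank
labelings exactly when both groups have ≤ 10 observations and no ties, with
two-sided $p = \min(1,\, 2\min(P(U \le u), P(U \ge u)))$; otherwise it uses
the normal approximation with tie and continuity corrections, and records
which branch ran. Bonferroni is $\min(1, m\,p_i)$.

## The simulated study

`synthetic_config()` fixes one world per seed: every generator is a pure
function of the config, with the global seed fanned out into per-generator
substreams so any module can be regenerated independently without running
the others.

**What it emulates.** Two human cohorts of 6 vs 6 and 6 vs 7 samples and a
mouse cohort of three transgenic/wild-type sibling pairs, matching the study
design this pipeline packages. Counts are negative binomial (Gamma–Poisson)
around log-normal miRNA base abundances with per-sample library sizes
(mean 5×10^6 assigned reads, CV 20%); planted miRNAs multiply their case
mean by $2^{\mathrm{log2fc}}$. The mouse cohort is simulated *paired*: each
sibling pair shares a per-pair, per-miRNA gamma abundance factor carrying
half of the dispersion, so pair effects partially cancel in the ratio of
group means, as they do in a real littermate design. Dispersion defaults to
0.1, a typical biological CV² for bulk RNA-seq. The default plants four
miRNAs at |log2fc| = 1.5 in all three datasets (two up, two down) with
seeds kept unique in the catalog. 1.5 was fixed a priori as a conservative
"clearly changed" effect (≈2.8-fold) comfortably above the 1.5-fold/2-fold
cascade thresholds, and the same magnitude is used in mice; the downstream
generators plant 100 truly down-regulated genes among 947 predicted targets
in a 10,000-gene universe (log-normal background ratios, sdlog 0.25, so
~19% of background genes fall below 0.8 by chance), and one gene set drawing
60% of its 150 members from the planted targets.

**What it does not emulate.** Extreme library dominance (a single miRNA
holding tens of percent of all reads, as miR-21 or miR-143 can in real
tissue): the background abundance distribution is capped so no background
miRNA exceeds a few percent of the library. Without the cap, the chance
case/control difference of a dominant miRNA shifts *every* other miRNA's
RPM fold change coherently, so "background log2fc = 0" would no longer hold
in proportion space — the quantity the generator contract promises. Also not
modeled: sequencing-error or isomiR structure, batch effects, adapter
artifacts, and conservation of target sites. A green planted-recovery test
therefore establishes that the cascade separates clear concordant signals
from independent count noise at realistic depths — not that it is robust to
compositional shifts or batch structure.

**Null uniformity check.** The hypergeometric tail p is discrete, so "p is
uniform under the null" only holds up to the point masses of the overlap
distribution. The null-calibration test uses a zero-planting configuration
with a large term (half of a 5,000-gene universe) and 500-gene random
queries, making the overlap distribution fine-grained enough (largest point
mass ≈ 0.04) that a Kolmogorov–Smirnov comparison against the uniform at
500 replicates is meaningful. With small terms the same test would reject
on discreteness alone, which would be a property of the statistic, not an
error.

## Numerical choices and degenerate inputs

- Intervals are 0-based half-open internally; BED is native, SAM converted
  at the parser (POS−1; end from the reference span of the CIGAR, ops
  M/D/N/=/X). Unparseable CIGARs skip the record with a warning; a missing
  NM tag is treated as edit distance 0 with a warning.
- A sample with zero assigned reads normalizes to an all-zero RPM column
  plus a warning rather than NaN.
- `fold_change` with pseudocount 0 and a zero control mean is an error; the
  default pseudocount 0.5 makes all ratios finite and shrinks low-count
  ratios toward 1.
- `enrich` drops query genes outside the universe with a warning; a term
  with no universe member is skipped rather than given K = 0.
- Exact rank-sum enumeration is capped at 10 per group
  ($\binom{20}{10} \approx 1.8\times10^5$ labelings); beyond that, the
  corrected normal approximation agrees with the exact branch to < 0.01 on
  tie-free data (cross-validated in the tests).
- TSV with a header is the only table dialect, and all writers emit UTF-8
  with LF endings, so byte-identical reruns are a testable contract of
  `run_all()`.

## Known limitations

The cascade inherits the limitations of threshold rules on small cohorts:
no p-values on the ratios, sensitivity to the pseudocount at very low
expression, and no batch correction. The paralog filter is only as complete
as the supplied catalog. The headline candidate counts of the original
procedure can only be reproduced with its real inputs (public GEO series
and a TargetScan release), which this package treats as documented
expectations rather than test assertions; the configuration knobs —
`selection_thresholds()`, the 0.8 ratio cutoff, top-10 ranking — default to
that procedure's stated values.
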