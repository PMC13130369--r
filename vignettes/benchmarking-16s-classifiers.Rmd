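---
title: "Scoring 16S metabarcoding classifiers against tiered mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 16S metabarcoding classifiers against tiered mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconbench)
```

## The problem

Species-level taxonomic classification of 16S rRNA amplicons from highly
complex communities — municipal wastewater being the motivating case — is
unreliable in characteristic, pipeline-specific ways. Exhaustive best-hit
aligners detect nearly everything that is present but bury it under false
positives; conservative denoise-then-classify pipelines detect almost nothing
but are rarely wrong; k-mer classifiers sit in between. Comparing and
optimizing such pipelines requires (i) ground-truth communities whose
composition is known exactly, (ii) scoring metrics that reward sensitivity
and selectivity at both the taxon and the read level, (iii) an error measure
for estimated abundances that cannot be gamed by emitting more false
positives, and (iv) filters that exploit the one reliable empirical
regularity: false-positive taxa attract far fewer reads than taxa truly
present.

`ampliconbench` implements all four pieces, plus a classifier-output
simulator, so the entire evaluation framework runs and is testable with no
external pipelines, reference databases or sequencing data.

## The tiered mock community

`design_community()` builds the reference design: 15 species per site in
three abundance tiers — five "main" taxa at 15% each (three strain/subspecies
sequence variants at 5% apiece), five "mid" taxa at 4.5% and five "rare"
taxa at 0.5%. The rare tier probes sensitivity to low-density organisms; the
variant structure probes species-level name resolution across strains.
The design's alpha diversity is analytic: richness 15, Shannon entropy
$H=-\sum p_i \ln p_i = 2.25$ (natural-log units), Pielou evenness
$H/\ln 15 = 0.83$:

```{r design}
truth <- design_community(sprintf("species_%02d", 1:15), site_id = "west")
c(shannon = shannon(truth$abundance_pct), pielou = pielou(truth$abundance_pct))
```

`abundance_config()` expands the design to one row per sequence variant
(`<species>|v1..v3`, fractions summing to one) — the community-design input
an external read simulator consumes. Generating actual reads (fragment
length, error profiles) is out of scope here; the package simulates at the
profile level instead.

A note on units: the Shannon value of this design is sometimes quoted in
"bits". The printed 2.25 is the natural-log computation (the base-2 value
would be 3.25), so this package computes and documents Shannon entropy in
natural-log units throughout.

## Detection metrics

With canonical species names on both sides (`canonicalize_name()` lowercases,
collapses whitespace, strips strain/subspecies designations and `|v` variant
suffixes, and preserves a *Candidatus* prefix), `detection_report()` scores:

* **taxa sensitivity** — share of truth taxa detected (recall);
* **taxa selectivity** — share of detected taxa that are true (precision);
  its complement is the false-positivity rate;
* **read sensitivity** — share of *all input* reads mapped to true taxa;
* **read selectivity** — share of *mapped* reads mapped to true taxa;
* **surveillance score** — the mean of the two sensitivity-by-selectivity
  products, `(ts*tsel + rs*rsel)/200`, a single number for "how useful is
  this pipeline for knowing what is in the sample".

The read-selectivity denominator is mapped reads, not total reads: the two
conventions differ exactly when reads are left unmapped, and only the
mapped-reads denominator keeps selectivity a property of what the classifier
asserted rather than of how much it declined to assert. When nothing is
detected, selectivities are reported as missing (`NA`), never as zero.

## The mapping-error family

Let $e_i = \hat a_i - a_i$ be the signed abundance error over the union of
truth and detected taxa (the absent side counting as zero). Negative errors
can occur only on truth taxa and constitute the under-detection
(false-negative-derived) mass $U=\sum\max(-e_i,0)$; positive errors are the
over-detection (false-positive-derived) mass $O=\sum\max(e_i,0)$.

* `SAE` — $U+O$ on the raw read-count scale.
* `nSAE` — $U+O$ with abundances read-normalized to percent
  (counts / total reads x 100), invariant under uniform count scaling.
* `wnSAE` — $wU+O$ with false-negative weight $w$ (default 2): missing a
  taxon that is present is worse than inventing one.
* `RMSE`, `nRMSE`, `wnRMSE` — root-mean-square analogues over the taxon
  union, the weighted variant multiplying squared FN-derived terms by $w$.

The SAE decomposition identity `value = w*U + O` holds exactly and is tested
on thousands of random profiles. The RMSE family divides by the size of the
taxon union, which is precisely what makes unweighted `nRMSE` pathological:
a pipeline can *lower* its error by emitting additional tiny false positives,
because they grow the denominator faster than the numerator. The package
asserts this pathology on constructed cases, and asserts that no SAE variant
can ever decrease when a false positive is added.

`modelling_grid()` evaluates all six variants over the full cross of
`{0,3,...,15}` true taxa detected (each step adds one main, one mid and one
rare taxon) by `{0,3,...,15}` false positives, with detected true taxa
observed at their true abundances and false positives splitting the
unassigned mass in equal shares. `grid_correlations()` then reports each
variant's Pearson correlation with the Type I (false positive) and Type II
(missed taxon) counts. On this grid the count-scale SAE is exactly linear in
the missed-taxon count (every tier-triple carries 20% of the reads), so its
Type II correlation is 1.00 and its Type I correlation is near zero; the
normalized SAE variants correlate positively with both error counts; and
unweighted `nRMSE` correlates *negatively* with the false-positive count —
the pathology again.

One caveat is documented rather than hidden. Within this definition of the
weighted RMSE (the FN weight applied inside the mean, taxon-union
denominator), up-weighting the FN-derived terms cannot turn the Type I
correlation positive on this grid: the FP-derived error mass under the
mass-splitting allocation shrinks as false positives multiply, and the
weight only amplifies a term that does not grow with the FP count — a fact
that holds for every weight and every allocation in this family that we
examined. Flipping that sign would require the weight to act on the
FP-derived component instead, which would contradict the stated intent of
penalizing under-detection. We therefore keep the FN-weighted definition,
expose `w`, and state plainly that the weighted RMSE's Type I correlation
stays negative here. The practical conclusion is the one that matters: the
weighted *SAE* reflects both error sources proportionately and is the
recommended default (`mapping_error(..., metric = "wnSAE")`).

## Diversity scoring

Alpha metrics are computed through vegan behind the package surface:
Shannon (`vegan::diversity`), bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (`vegan::estimateR`), which survives
$F_2=0$; Pielou as $H/\ln S$, undefined (`NA`) below two taxa; Bray-Curtis
as $1-\sum_i \min(p_i,q_i)$ on renormalized profiles (`vegan::vegdist`).
Note that any filter removing taxa below ~3 reads nullifies Chao1's benefit:
with no singletons or doubletons left, Chao1 equals observed richness, a
known side effect of selectivity optimization.

The composite **diversity score** is 100 minus the mean *absolute* percent
error across richness, evenness, Shannon and mean between-site Bray-Curtis —
sign-invariant by construction. The **replicate/site precision ratio**
(`replicate_site_ratio()`, `richness_precision()`) divides mean
per-replicate diversity by mean site-level diversity (for richness, the
union of taxa across a site's replicates): 100% means perfectly reproducible
replicates.

## Low-read-taxon filters

Two single-pass filters remove taxa iff `count < threshold` (ties kept,
matching the "fewer reads than" phrasing of both rules):

* `zscore_filter()` — threshold $\mu - |z|\sigma$ over detected taxa's read
  counts, default $z=-0.25$. The *population* standard deviation is used:
  the choice is not dictated by the procedure's description, and the
  population form is deterministic and well-behaved on the very small taxon
  sets the filter actually sees.
* `fraction_filter()` — threshold = fraction x total input reads, default
  0.4% (0.004) for deep simulated sets; shallow real sets conventionally use
  0.004% (4e-5). At 175k reads the default threshold is 700 reads, which
  deliberately sits *below* the expected read count of a rare-tier taxon
  (875), so the filter removes false positives preferentially rather than
  the rare tier.

`filter_diagnostics()` reports the threshold in reads, the false-positive
map rate among removed taxa (read-weighted), and the reads-correct
percentage before and after — the mechanism, verified as a Monte-Carlo
property over 100 simulator seeds: both filters raise mean taxa selectivity
and reads-correct percentage and can only lower sensitivity.
`threshold_sweep()` traces the full sensitivity/selectivity trade-off.
Re-applying the z-score filter can remove more taxa (the mean and deviation
shift), so its contract is explicitly one pass.

## The classifier simulator

`simulate_classification()` draws per-taxon read totals multinomially from
the truth abundances, then routes each read independently: unmapped with
`p_unmapped`, correct with `p_correct`, otherwise misassigned to one of
`fp_pool_size` reserved false-positive names (`fp_0001`, ...) with
Zipf-like probabilities $\propto k^{-s}$, `s = fp_concentration`. Each
taxon independently drops out entirely with `p_dropout` (database
incompleteness; its reads are rerouted as misassignments). One seed governs
all stages; mapped + unmapped reads equal `n_reads` exactly.

Defaults — `p_correct = 0.85`, `p_dropout = 0.10`, `p_unmapped = 0.05`,
`fp_pool_size = 30`, `fp_concentration = 1.5`, `n_reads = 175000` — are
chosen once to describe a mid-performing classifier on a ~175k-read set:
reads-correct in the 66–85% band real optimized pipelines achieve,
per-taxon non-detection at a rate that leaves most of a 15-taxon community
detectable, and a heavy-tailed FP allocation under which the median
false-positive taxon receives far fewer reads than the median true taxon in
essentially every run (the regularity the filters exploit). The reserved
`fp_` namespace is disjoint from truth names by construction, which makes
scoring unambiguous.

What the simulator does *not* emulate: sequencing error and chimeras,
database-dependent confusion structure (misassignments are independent
across reads rather than concentrated on sequence-similar neighbours),
compositional renormalization quirks of specific tools, and read-level
identity (it works on counts, not sequences). Passing tests therefore show
that the *metrics, filters and their interplay* behave as designed under a
faithful abstraction of classifier behaviour — not that any particular real
pipeline will achieve a particular score. The published per-pipeline table
values require running the real pipelines on simulated reads against live
reference databases and are deliberately out of scope.

`allocation = "expected"` replaces the multinomial draw with
largest-remainder rounding of expected counts — the noiseless condition
used to verify that a perfect classifier earns exactly perfect scores on
every metric (all sensitivities/selectivities 100, all six error metrics 0,
diversity score 100).

The read-doubling strategy that benefits denoisers is represented at the
profile level by `double_reads()` (all counts and the total x2); every
relative metric is invariant under it, which the tests assert.

## Numerical and interface choices

* Counts are integers end to end; relative abundances are the only floating
  representation. Unmapped reads are implicit (`total_reads - sum(count)`),
  never a pseudo-taxon.
* BLAST best-hit ties break by lower e-value, then lexicographic subject
  name — deterministic and database-order independent.
* Kraken reports are read at the requested rank using clade read counts;
  the writer emits a root clade count equal to the profile's total reads so
  profiles round-trip exactly. Bracken tables carry assigned reads only, so
  a profile with unmapped reads round-trips its counts but not its total.
* Percentages are computed at full precision and rounded only for display.
* Problem sizes used by the test suite: the Monte-Carlo filter property uses
  100 seeds at 175k reads; the SAE identity and scaling invariance use 1000
  random profiles; the binomial channel check uses 1000 replicates of 10k
  reads.

## Limitations

Beyond the simulator abstractions above: the framework scores at species
level only (no taxonomy-aware partial credit for a correct genus); Chao1 is
the only richness estimator; rarefaction and ordination are out of scope;
and names are matched by canonical string, not by taxonomic identifier, so
databases using genuinely different synonyms for one organism are treated
as disagreeing.
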