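---
title: "Scoring amyloid-beta aggregation from growth-selection scans: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring amyloid-beta aggregation from growth-selection scans: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscan)
library(dplyr)
```

## The measurement

aggscan analyses deep mutational scans of the 42-residue amyloid-beta
peptide (Abeta42) in a yeast growth selection. Abeta is fused to an
essential enzyme (DHFR) so that, under methotrexate, cells carrying
soluble Abeta variants grow fast and cells whose Abeta aggregates grow
slowly. A saturation-mutagenesis library competes in one culture; samples
drawn at successive times are sequenced, and each variant's frequency
trajectory reports its aggregation propensity.

The package covers the full path from that experiment's raw data to its
biological conclusions: a simulator with known ground truth, read
filtering and codon-level variant calling, slope-based solubility
scoring, classification against a synonymous null, positional clustering
and buried-beta-strand calling, concordance with external ddG scans and
structural-model strand tracks, and NNK primer design.

## The growth and sampling model behind the simulator

Variant $v$ with true solubility effect $s_v$ grows exponentially at rate
$r_{wt} + \beta s_v$ (per hour). With initial frequency $f_v(0)$, its
culture frequency at sampling time $t$ is

$$ f_v(t) = \frac{f_v(0)\, e^{(r_{wt} + \beta s_v)t}}
                 {\sum_u f_u(0)\, e^{(r_{wt} + \beta s_u)t}}, $$

and sequencing draws `depth` reads multinomially from $f(t)$,
independently at each timepoint and replicate (one continuous culture,
sampled; no transfer bottlenecks or carrying capacity, so growth is pure
exponential). Consequently the log2 ratio to wild type is exactly linear
in time,

$$ \log_2 \frac{f_v(t)}{f_{wt}(t)} = \mathrm{const} + \frac{\beta s_v}{\ln 2}\, t, $$

which is what makes the slope the natural score and gives the simulator
an analytic expectation the tests hold the pipeline to (recovery to six
significant figures on noise-free expected counts).

Default study conditions, chosen once as the realistic setting of a
40-hour methotrexate selection and used throughout the tests:

* timepoints 0, 28, 31.5, 35, 38, 40 h (input plus five selection samples);
  3 replicates differing only in sampling randomness;
* $r_{wt} = 0.16$/h — a culture climbing from OD 0.01 to about 6 over 40 h;
* $\beta = 0.05$/h per unit effect; missense effects drawn from
  $\mathcal{N}(0.1, 0.6)$, so the scan contains aggregation-promoting,
  neutral and solubilising substitutions in realistic proportions;
  synonymous and WT effects are exactly 0; nonsense variants default to 0
  (their biology is outside the model's scope and they are excluded from
  the missense analysis set anyway);
* the input pool is 5% wild type with the remainder uniform over the
  single-codon NNK variants. Pooled saturation libraries retain a
  sizeable unmutated-template fraction, and WT-normalized scoring assumes
  the denominator is deeply measured: with WT at library-member abundance
  the shared noise of the WT trajectory would become a dominant, common
  error mode of every score;
* reads carry two-level Phred qualities (37 for correct bases, 11 at
  injected substitution errors). Because erroneous bases sit below the
  Q>20 filter, sequencing errors can only remove read pairs, never
  miscall a variant; at the default error rates they thin depth by a few
  percent. For that reason large simulated scans are scored from the
  count-level simulator, and the FASTQ route (write, filter, reconcile
  mates, call, tabulate) is verified at smaller depth where exact
  round-trip equality with the count route is asserted.

What the simulator does not emulate: indels, PCR jackpots and chimeras,
quality-score distributions beyond two levels, replicate-specific
biology, bottlenecked passaging, and epistasis (single-codon variants
only). Passing recovery tests therefore show the estimator is correct
under the model's assumptions — not that real scans are free of these
other error modes.

## Read processing

A read pair is accepted only if every base in both mates has Phred
quality strictly greater than 20 and neither mate contains an N; pairs
with non-amplicon length are rejected. Filtering precedes mate
reconciliation (the order could matter at high error rates; filtering
first is the stringent choice). Overlapping mates are reconciled
base-by-base — the higher-quality base wins, ties go to read 1 — and the
ORF is compared codon-by-codon to the reference: zero mismatches is WT,
one is a single-codon variant (synonymous, missense or nonsense), two or
more are `multi`. Multi-codon calls are excluded from scoring but kept in
the QC tally; a sample with no retained WT reads is flagged fatal because
WT normalization is impossible. Coordinates are fixed by the amplicon
design (1-based codon indices; offsets are configuration, not inference).

## The solubility score

Three steps, per variant:

1. **Normalized log ratios.** $m_v(t) = \log_2\frac{c_v(t) + p}{c_{wt}(t) + p}$
   with pseudocount $p = 0.5$ applied uniformly, so the WT trajectory is
   identically zero and the WT score is exactly 0 for every input.
   Per-sample read totals cancel in the ratio; they are kept for QC only.
2. **Weighted least squares.** A line is fit to $m_v(t)$ against sampling
   time in hours (timepoint index is available as an alternative x-axis;
   scores rescale linearly between the two and classification is
   unaffected). Weights are the inverse delta-method variance of a log
   ratio of Poisson counts, $w_t = 1/(1/(c_v + p) + 1/(c_{wt} + p))$,
   which degrades gracefully to ordinary least squares at high counts.
   The slope and its standard error come from the closed-form weighted
   normal equations; `stats::lm(weights =)` serves as an independent
   oracle in the tests.
3. **Replicate averaging.** The score is the arithmetic mean of the
   per-replicate slopes. Because the ratios are log2-transformed before
   the regression, the slope already lives on the log2 scale; averaging
   slopes and "log2-transforming the averaged slope" would be undefined
   for negative slopes, so the former is the only coherent reading.
   Scores above 0 mean more soluble than wild type, below 0 more
   aggregation-prone.

Missense and nonsense counts are aggregated to amino-acid level by
summing the counts of all codons encoding the same substitution before
scoring (synonymous variants necessarily stay codon-level). A variant
with zero reads in every timepoint of a replicate contributes no slope
there; with zero reads everywhere its score is missing — mirroring how a
real scan simply fails to measure a handful of library members.

Two properties worth stating precisely:

* **Depth rescaling.** Multiplying all counts at a timepoint by a
  constant leaves every $m_v(t)$ (at $p = 0$) and hence every
  equal-weight slope unchanged. The inverse-variance weights, however,
  scale with depth by construction — a deeper timepoint genuinely carries
  more information — so the weighted slope is equivariant, not invariant.
  The tests assert both statements.
* **Shared WT noise.** All scores within a replicate share the WT
  denominator, so the sampling error of a mean over many variants does
  not shrink to zero with the number of variants; its variance has an
  independent per-variant part plus a shared part that the tests account
  for with a delta-method term $\sum_t \bar k_t^2 / (c_{wt}(t)\ln^2 2)$
  when checking stratum means against $\beta s/\ln 2$.

`doublings_per_time()` implements the companion low-throughput growth
readout, $(\log_{10}(OD_2/OD_1)/\log_{10} 2)/\Delta t$.

## Classification against the synonymous null

Synonymous variants leave the peptide unchanged, so their score spread is
pure measurement noise around wild type. The null is their mean and
sample (n−1) standard deviation; scores within mean ± 2 SD (inclusive at
both ends) are WT-like, below the lower bound more aggregation-prone,
above the upper bound more soluble. Published cutoffs can be supplied
directly via `bounds =` to reproduce deposited classifications. The
classification partitions all scored variants, is monotone in score, and
is equivariant under a constant shift of all scores (the null shifts
with them).

Note the sign logic follows the score convention (negative = more
aggregation-prone); a formulation that labels scores *above* the upper
bound aggregation-prone would contradict the convention and the flagship
examples (tryptophan substitutions near −0.6 promote aggregation,
aspartate near +0.6 solubilises).

In simulated scans the fraction of missense variants classified WT-like
depends strongly on sequencing depth: the deeper the scan, the narrower
the synonymous null band, and the more true (even tiny) effects exceed
it. Null simulations (all effects 0) recover the nominal ~95% WT-like
coverage of a ±2 SD interval within binomial and null-estimation slack.

## Position maps, clustering, strand calls

Amino-acid-level scores form a dense position × mutant-residue matrix
(42 × 20 for Abeta42); a position's own wild-type residue is not a
substitution and is masked, as are unmeasured cells. Per-position
summaries report the mean score over all, hydrophobic
({A, V, L, I, M, F, W, C}; alanine separable in reports, since it often
behaves unlike the bulky hydrophobics), and polar substitutions; a
Kyte–Doolittle annotation track is provided since no single
hydrophobicity scale is canonical. WT cells are excluded from all
summaries; missing cells are mean-imputed only inside the distance
computation for clustering, never in summaries.

Position (or residue) vectors are clustered agglomeratively
(`stats::hclust`; average linkage, Euclidean distance by default — both
recorded in output metadata and configurable, since no particular choice
is canonical) and the dendrogram is cut at k = 6 clusters for positions.
Cluster ids are relabelled in order of first appearance, making the
assignment deterministic and permutation-invariant up to labels. All-
identical vectors are refused rather than arbitrarily split.

The buried-strand call designates the cluster with the highest mean
solubility score — positions where substitutions most increase
solubility are those whose wild-type side chains the fibril core relies
on — and reports its positions individually and as maximal contiguous
segments. Ties between cluster means are reported with a warning. The
call depends only on score differences, so it is invariant to adding a
constant to the whole matrix.

## External comparisons

ddG substitution scans (e.g. proline and alanine scans of fibril
stability) are compared by the coefficient of determination of the
least-squares line between the scan's scores for that substitution and
ddG at shared positions — invariant to affine rescaling of either
variable. Abeta40-based scans overlap Abeta42 scores on positions 1–40
with identity offset.

Beta-strand tracks of structural models are compared as position sets:
Jaccard, precision and recall of the called positions against each
model's strand positions, with a per-model ranking (sorted by Jaccard,
ties broken by model name so input order never matters). Tracks are user
supplied — deriving secondary structure from coordinates is out of
scope — and the bundled `synthetic_strand_tracks.tsv` is a format
example, not curated ground truth.

## Primer design

For each codon, the forward primer is a 5' homology arm, the literal
degenerate codon NNK, and a 3' extension arm; the reverse primer is the
exact reverse complement of the homology arm (the in vivo assembly
design). Arms grow outward from the target codon one base at a time
until length ≥ 15 nt **and** melting temperature > 55 °C, so every arm
is minimal: one base shorter violates a constraint. Tm uses the
two-regime convention — Wallace rule $2(A+T)+4(G+C)$ below 14 nt, else
$64.9 + 41\,(GC - 16.4)/\mathrm{len}$ — recorded per primer so another
calculator can be swapped in. Hairpin and cross-dimer screening are out
of scope.

## Numerical choices and degenerate inputs

* Pseudocount 0.5, uniform, keeping WT exactly 0.
* Regression x-axis: hours by default; `"index"` mode provided.
* Degenerate weighted designs (all weight at one abscissa, or fewer than
  two usable timepoints) yield NA slopes with a warning, never a crash.
* A null fit needs at least 2 synonymous scores; a constant null is
  flagged degenerate.
* `k` larger than the number of vectors, >50% missing per vector, and
  empty called/track sets are all rejected with informative errors.
* All randomness flows from explicit integer seeds; identical seeds give
  byte-identical count tables, FASTQ files and artifact directories.

## Problem sizes used in the shipped checks

The test suite and acceptance script simulate full 42-codon NNK scans at
depths between 2×10^4 and 10^6 reads per sample — 10^6 for the parameter-
recovery check (Spearman ≥ 0.9 between true effects and scores), 2×10^5
for classification and reporting runs — and exercise the FASTQ route at
hundreds of reads per sample, where exact equality with the count-level
route is asserted. These sizes were chosen so each property is tested at
a scale where its statistical expectation is sharp.

## Known limitations

Scores are relative to wild type within one scan and carry the x-axis
unit (per hour by default); absolute comparability across experiments is
not attempted. The weighting model treats counts as Poisson, ignoring
overdispersion from PCR amplification. Replicates are modelled as pure
resampling; biological replicate variance is not simulated. The
synonymous null assumes synonymous codon changes are phenotypically
silent (no codon-usage effects). Clustering results, as always, depend
on linkage and metric; the defaults are recorded in every run manifest.
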