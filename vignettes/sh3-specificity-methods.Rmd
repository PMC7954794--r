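---
title: "Methods: scoring SH3-dependent interactions, motifs, mutational scans and trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring SH3-dependent interactions, motifs, mutational scans and trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh3kit)
```

# Scope and data model

SH3 domains are small peptide-binding modules whose in-vivo interaction
partners depend not only on the domain itself but on the protein context
carrying it. `sh3kit` implements the quantitative machinery needed to study
this: scoring of DHFR protein-fragment complementation (DHFR-PCA) colony
screens and classification of interactions by SH3 dependency, position
weight matrix (PWM) motif scanning with permutation nulls, deep mutational
scanning (DMS) scores, dendrogram comparison of interaction profiles
against domain sequences, ortholog conservation utilities, and endocytic
single-particle trajectory metrics. Every analysis stage has a matching
seeded generator producing synthetic inputs with known ground truth, so
the whole pipeline is testable end to end without any external dataset.

All tabular inputs and outputs are long-form data frames written as TSV;
sequences travel as FASTA, dendrograms as Newick, run manifests as JSON.

# Plate-based interaction scoring

## Model

Colony sizes are analyzed in log2 space. Each plate is normalized by
subtracting its background level so plates are comparable; we define the
background as the **median of qc-passing non-border log2 sizes**. The
median is robust against the minority of true interactions, which sit in
the upper tail; the choice is exposed through `background_override`, which
also covers plates without any detectable background (these can be
assigned the measured background of a matched wild-type plate).

The PCA score of a bait-prey pair is the median of its normalized
replicate values. The standard design places each prey at two randomized,
non-adjacent positions per plate, with two plates per bait — four
replicates per pair. Replicates whose colony failed the diploid-selection
step are removed first, and pairs with fewer than two surviving replicates
are dropped entirely. A double border of control-pair colonies frames each
plate; border positions are used only for quality control and are never
scored.

Interactions are called from the pooled PCA score distribution: a pair is
positive when its score reaches the $(1 - q)$ quantile, with $q = 0.073$
for the primary screen convention and $q = 0.0275$ for the denser
shuffling-screen convention. Quantiles use linear interpolation
(`stats::quantile` type 7), and ties at the threshold are included — the
inclusive rule is the conservative reading of "detected".

## Dependency classification

For a wild-type and a domain-deleted screen, the PCA score ratio is the
log2 difference (mutant − wild type); since scores are already log2, the
difference is the log of the colony-size ratio. The decision table is:

| WT detected | mutant detected | ratio                      | class               |
|-------------|-----------------|----------------------------|---------------------|
| yes         | no              | —                          | `dependent_lost`    |
| yes         | yes             | ≤ lower ratio quantile     | `dependent_weaker`  |
| yes         | yes             | between quantiles          | `independent`       |
| yes         | yes             | ≥ upper ratio quantile     | `inhibited_stronger`|
| no          | yes             | —                          | `inhibited_gained`  |

Ratio quantiles are computed on the pooled ratio distribution of pairs
detected in both screens (pooling per screen rather than per bait; per
bait the tail counts would be too small to estimate a stable quantile).
Threshold ties classify into the extreme class on both sides, matching the
inclusive detection rule.

A known boundary effect, visible in the synthetic recovery experiments:
when the planted-interaction fraction equals the ratio-tail quantile, the
lower ratio threshold falls inside the planted cluster, so a planted pair
that is also (spuriously) called in the deletion screen can land just
above the threshold and be labeled `independent`. This is inherent to
quantile-based thresholds, not an implementation artifact.

## Growth scores

Stress-condition growth assays use two plate replicates per condition with
each strain at six random positions per plate (twelve replicates total)
and a border of wild-type strains. Scoring at the 74 h timepoint: both
plates are aligned to the mean of their two medians (removing the
inter-plate difference exactly; the common level is arbitrary), per-strain
medians are computed per plate, strains whose medians still differ by more
than 2 log2 units between the plates are removed as discordant, and the
growth score is the mean of the two medians. The discordance filter
presumes plates dense enough that one aberrant strain does not move the
plate median — the situation in a 1536-format screen.

# PWM motif scanning (MSS)

The matrix similarity score generalizes the MATCH information weighting
from the 4-letter nucleotide alphabet to the 20-letter amino-acid
alphabet. For a PWM with frequencies $f(i,b)$ the position weights are

$$I(i) = \sum_b f(i,b)\,\ln\!\big(20\,f(i,b)\big), \qquad 0 \ln 0 := 0,$$

and a window $a_1 \dots a_k$ scores

$$\mathrm{MSS} = \frac{\sum_i I(i) f(i, a_i) - \mathrm{Min}}
                     {\mathrm{Max} - \mathrm{Min}},$$

with Min and Max the information-weighted sums of the per-position minimum
and maximum frequencies. The score is 1 exactly when every informative
position carries its most frequent residue, and 0 for the all-worst
window. Design choices:

* **No pseudocounts.** Zero frequencies are kept as-is so a one-hot
  consensus scores exactly 1.
* **No core-score stage.** The 5-mer core filter of the nucleotide
  original is dropped: peptide PWMs are short and the full-window MSS is
  the quantity of interest.
* **Non-standard residues** (X, U, \*) invalidate only the windows that
  contain them.
* **Whole sequences are scanned** (no disorder filtering), and a domain
  represented by several PWMs takes the overall maximum across them.
  First-occurring windows win ties.

Two nulls accompany the scan. The *random-peptide null* draws sequences
i.i.d. from background residue frequencies with lengths resampled from an
empirical pool (by default the analyzed prey set's lengths; a fixed length
is available), records their maximum MSS, and uses the 95th empirical
percentile as the high-MSS threshold. The *PWM-reassignment null*
permutes the domain-to-PWM assignment and pools max-MSS scores until the
requested null size is reached, asking whether preys score well against
their *own* domain's PWM specifically. Group comparisons use Mann-Whitney
rank tests from base R; permutation p-values are reported with add-one
smoothing, $p = (1 + \#\{\text{extreme}\})/(1 + n_{\mathrm{perm}})$, so
they are never exactly zero.

# DMS scoring

Variant count tables (position × codon counts with per-position depths,
for a reference and a selection condition) are converted to frequencies
with a **count-level pseudocount of 0.5**:
$f = (\mathrm{count} + 0.5)/\mathrm{depth}$. Applying the pseudocount to
frequencies instead (which are of order $10^{-2}$) would dominate the
signal; the count-level reading is therefore the default, with the
pseudocount exposed as a parameter. The variant ratio is
$\log_2(f_{\mathrm{sel}}/f_{\mathrm{ref}})$, finite for every variant by
construction; a variant absent from one condition is treated as count 0
at that position's depth.

Scaling uses synonymous codon substitutions (same encoded residue as the
wild-type codon, different codon) as the neutral reference, pooled across
positions. Each replicate's ratios are scaled by that replicate's
synonymous median, replicates are averaged, and the averaged scores are
re-centered on the pooled synonymous median. The final re-centering is
what makes the invariant "median synonymous score is exactly 0" hold by
construction even when replicates disagree slightly; when replicates
share their synonymous median it is a no-op, so averaging and scaling
commute in that case.

Classification compares each score to the synonymous distribution's 1st
and 99th percentiles (linear interpolation, codon level): strictly below
the 1st percentile is `deleterious`, strictly above the 99th `improving`,
otherwise `neutral`. Amino-acid-level scores are the mean over codons
encoding the substitution, excluding the wild-type codon; the mean (rather
than median) preserves replicate-averaging semantics. Stop codons are
scored but flagged for exclusion from residue-level heatmaps. For two
interaction partners measured on the same library, substitutions are
cross-classified by each partner's own synonymous 1st percentile into
four categories (destabilizing both, either one specifically, or
neutral/increasing), which partition all substitutions.

# Profile-tree versus sequence-tree comparison

Interaction profiles (rows = domain or bait variants, columns = preys,
entries = PCA scores) are compared with domain sequences via dendrograms.
Profile distances are Euclidean; missing profile entries are imputed as 0,
the plate background after normalization (pair-complete distances were
considered and rejected as a default because they can produce
non-metric matrices). Sequence distances are $1 - $ identity over an
alignment, where identity counts matches over all columns with at least
one residue, a gap against a residue is a mismatch, and double-gap columns
are excluded.

Both matrices are clustered agglomeratively with **complete linkage** (the
conventional default of the environment the analysis idiom comes from;
average linkage is available). The clustering is implemented with an
explicit deterministic tie rule: linkage minima equal within a small
tolerance are tied, and ties break toward the pair containing the lowest
leaf index. The tolerance absorbs floating-point noise in distances
derived from coordinates, so two numerically indistinguishable distance
matrices always yield the same tree — without this, tied merges can
resolve differently between the profile and sequence trees and deflate
the cophenetic correlation of identical structures.

The cophenetic correlation is the Pearson correlation of the two trees'
merge-height distances over all unordered leaf pairs (at least 3 leaves;
identical-profile degeneracies raise an error rather than returning an
undefined value). Significance comes from permuting the assignment of
domain labels to profile rows; since relabeling a fixed tree only permutes
its cophenetic matrix, the null is computed by permuting that matrix
rather than re-clustering, which is exactly equivalent and much faster.
The p-value is one-tailed with add-one smoothing.

# Trajectory metrics

Endocytic foci tracks (time-ordered x/y positions plus the host cell
centroid) are processed as follows, with defaults of 1 frame/s for 180 s:

* **Filtering:** tracks shorter than 10 frames are spurious detections and
  are removed.
* **Trimming:** the frame of minimum distance to the centroid anchors the
  track; later frames are cut from the first one whose distance exceeds
  that minimum by more than 2 px (the tolerance is configurable — the
  underlying intent is to remove segments spuriously indicating movement
  back toward the membrane, and the anchor-plus-tolerance rule is our
  formalization of it).
* **Effective distance:** $e(t) = d(\mathrm{start}) - d(t)$, the net
  inward progress; reported as per-frame means over tracks still present
  and per-track final values. It is bounded by the initial distance to
  the centroid.
* **Completion:** a track is complete when it ends strictly before the
  final acquisition frame; the 95% disassembly time is the earliest frame
  by which ≥ 95% of all tracks (including never-disassembling ones in the
  denominator) have ended, NA when never reached.
* **Straightness:** net displacement over path length, in $[0,1]$.

Distances are in pixels throughout; the analyses are comparative and need
no physical calibration.

# Synthetic-data generators

Every generator takes an explicit integer seed, restores the caller's RNG
state, and returns the ground truth alongside the data.

* **Plate screens** are simulated directly in log2 space — the analysis
  operates on log2 sizes and a raw-size model would add an arbitrary,
  untestable layer. Values are background (default 10 log2 units, a
  typical colony-size scale) + per-plate offset (sd 0.25) + planted effect
  + Gaussian noise. Defaults of effect 4 log2 units, noise sd 1 and a 10%
  planted fraction describe a clearly detectable interaction set with
  realistic replicate scatter; prey positions are re-randomized per plate
  with duplicates never adjacent, to avoid spatial confounding.
* **DMS libraries** place all 64 codons at every position (an NNN
  saturation design), draw reference counts multinomially at the
  configured depth and selection counts multinomially with weights
  proportional to reference frequency × $2^{\mathrm{effect}}$ — the
  simplest model under which the DMS score is an unbiased effect
  estimator. Depths are exact by construction.
* **Motif datasets** plant PWM-sampled windows at recorded positions in
  background sequences with a configurable probability, mirroring
  motif-bearing versus motif-free interactor sets.
* **Coupled profiles** evolve domain sequences along a random phylogeny
  (per-branch per-site substitution, uniform replacement) and embed the
  resulting identity-distance matrix exactly via Cailliez-corrected
  classical MDS; mixing the embedding with Gaussian noise by a coupling
  weight $\rho$ links profile structure to sequence structure. At
  $\rho = 1$ the embedding shifts all pairwise distances by one constant,
  complete-linkage heights shift by the same constant, and the cophenetic
  correlation is exactly 1; at $\rho = 0$ profiles are independent of the
  sequences and the permutation p-value is uniform.
* **Tracks** start near the cell boundary, drift toward the centroid with
  isotropic noise, and disassemble with a geometric per-frame hazard —
  the simplest memoryless lifetime model. Optional outward tails test the
  trimming rule.

What the generators deliberately do not emulate: raw sequencing reads,
colony images or microscopy frames, spatial plate gradients beyond a
uniform offset, overdispersion beyond multinomial sampling, phylogenetic
rate variation, and motion heterogeneity between cells. Passing the
synthetic recovery tests therefore demonstrates that the scoring
machinery is correct and calibrated under its stated model, not that the
model captures every nuisance process in real screens.

# Verification problem sizes

The packaged tests and the acceptance script exercise: 200 random
PWM/sequence instances against an exhaustive-enumeration oracle; motif
sets of 100 + 100 sequences (planted fraction 0.8) plus 200 null
repetitions for type-I calibration; a 58-position DMS library at depth
5000 with two replicates and planted effects in {0, −1, −2, −4}; screens
of 4 baits × 150 preys (600 pairs, four replicates each); 500 null runs
(n_perm = 200) for permutation-p uniformity and 100 seeds at coupling 0.9
with 30 leaves for power; and 200 simulated tracks for disassembly
statistics. These sizes give stable statistics while keeping the full
suite fast enough to run routinely.

# Limitations

* The MATCH generalization (ln(20·f) weighting, no core score, no
  pseudocounts) is one defensible reading of an underspecified scoring
  family; alternatives are accommodated by constructing PWMs differently,
  not by switches inside the scorer.
* Background estimation, ratio-threshold pooling, linkage, permutation
  tail convention, pseudocount level and the trimming tolerance are all
  documented defaults exposed as parameters, since the conventions they
  encode vary between laboratories.
* Quantile-based interaction calling ties the false-positive budget to
  the score distribution itself; the class-recovery boundary effect
  described above is the visible cost.
* RSA values above 1 are possible with empirical maximum accessibilities
  and are flagged, never clamped; the maxima ship as an editable table.
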