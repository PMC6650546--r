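---
title: "Methods: auditing operons for transcription and translation optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing operons for transcription and translation optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the audit asks

Some bacterial operons — the particulate methane monooxygenase operon
*pmoCAB* of type Ia methanotrophs is the motivating case — are transcribed at
extreme levels regardless of growth condition. For such genes, selection can
act on the coding sequence beyond the encoded protein: on the *cost of the
transcript* (which ribonucleotides, and therefore which C/H/N/O atoms, each
codon spends) and on the *effectiveness of translation* (whether the codons
match the tRNA supply, whether preferred codons are accurate, whether the
protein favours metabolically cheap residues). `codonaudit` bundles the
codon-level measurements needed to detect this dual optimization in a single
genome and exercises them end to end on synthetic genomes with a planted
operon, so every stage is testable without downloading genomes or RNA-Seq
data.

# Metrics and models

## Codon usage

For a synonymous family of size $k$ with codon counts $n_c$, the relative
synonymous codon usage is $\mathrm{RSCU}_c = k\,n_c / \sum_{c'} n_{c'}$; 1.0
is the neutral line, and family values always average 1. Codons of amino
acids absent from a gene are reported as missing, not 0 — except in the
ordination feature matrix (`rscu_matrix()`), where absent families are
imputed as 0 for that gene's row, on the argument that a gene cannot prefer
a codon it never uses. The imputation count is attached to the matrix
because the convention, not the data, decides it.

The codon adaptation index is the geometric mean over a gene's codons of the
relative adaptiveness $w_c = \mathrm{RSCU}_c / \max_{\text{family}}
\mathrm{RSCU}$ computed from a reference set. Two references are audited
side by side: the whole genome (`cai_genome`) and the ribosomal-protein
genes (`cai_ribosome`, a proxy for highly expressed genes). Following the
classic formulation, stop codons and the single-codon families (Met, Trp)
are excluded, and every reference count receives a +0.5 pseudocount
(configurable) so unused codons retain a small positive weight. CAI values
are converted to percentile ranks *within the genome* (rank $= 100 \cdot
\#\{v \le x\}/N$, ties sharing a rank) — an operon lying in the bottom
decile of `cai_genome` ranks but above the median of `cai_ribosome` ranks is
the audit's headline "ribosome-like but genome-divergent" signature.

The effective number of codons uses Wright's estimator: per family,
$\hat F = (n\sum \hat p_c^2 - 1)/(n-1)$ for family sample size $n \ge 2$,
and $\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
Finite samples can push the estimate past the theoretical maximum, so the
result is clipped at 61; it is deliberately never raised to 20 from below,
so implementation defects surface instead of hiding. Families with $n < 2$
or $\hat F \le 0$ are not estimable; a missing 3-fold class is imputed as
$(\bar F_2 + \bar F_4)/2$, and any other missing class drops its term with
the result rescaled by the maximum attainable over the represented classes.
Realistic genes estimate all classes; the edge rules only matter for very
short or degenerate inputs.

## tRNA adaptation

Anticodons are stored 5'→3'; the codon read is the reverse complement, so
anticodon positions 3 and 2 must be strict Watson–Crick complements of codon
positions 1 and 2, while the anticodon's first base (position 34, the wobble
base) pairs the codon's third base under a constraint table. The shipped
table is the published tAI default: Watson–Crick pairs cost $s = 0$, wobble
pairs cost $s \in \{0.41, 0.28, 0.68, 0.9999\}$ (G:U, I:C, U:G, I:A), with
anticodons beginning with A treated as inosine-modified — the standard
bacterial assumption, toggleable by supplying a different table. The table
lives in `inst/extdata/pairing_s.tsv` and its MD5 is stamped into every
report, because the constraint values are data, not code, and divergent
choices must stay traceable. Lysidine-modified C34 reading of AUA is out of
scope (tRNA modification chemistry is excluded).

A codon's absolute adaptiveness is $W_c = \sum_{a \in \text{pairable}}
(1-s_{ca})\,\mathrm{tGCN}_a$; the tAI of a gene is the geometric mean of
$w_c = W_c/\max W$. Codons with $W = 0$ (unreadable under the pool) are
excluded from the mean with a per-gene count rather than crashing; an
imputation mode (geometric mean of the nonzero $w$) is available for strict
mimicry of older implementations. AUG is included unless excluded by
configuration. The codon–tRNA bipartite network enumerates every allowed
pair with pairing class, $s$, tGCN and one median-RSCU column per gene set;
the access curve counts, for RSCU cutoffs 0.00–2.00 in steps of 0.01, the
gene copies of anticodons pairable with at least one codon at or above the
cutoff, and the curve endpoints are compared with a chi-square test of
proportions.

## Transcript economy

Elemental accounting uses nucleobase atoms only (adenine C5H5N5, guanine
C5H5N5O, cytosine C4H5N3O, uracil C4H4N2O2): the ribose-phosphate backbone
adds an identical constant per residue and cancels from every comparison
the audit makes. Pyrimidines carry fewer carbon and nitrogen atoms than
purines, and uracil the most oxygen — so a pyrimidine-enriched transcript
is cheap in C/H/N and expensive in O. Whole-sequence metrics (GC,
pyrimidine fraction) include the terminal stop codon, which is transcribed
and paid for; codon-family metrics (GC3, amino-acid usage, atoms per codon)
exclude it. The two conventions differ by under 1% at realistic gene
lengths, but the choice is stated rather than implied.

The transcriptome budget weights each transcribed gene's base counts by its
normalized mRNA abundance ("transcribed" means abundance above a
configurable floor, default 0). Removal shifts recompute the budget without
one gene set and report the change in percentage points. The
random-combination null draws 1,000 combinations (default) of three
distinct coding sequences, takes the mean pyrimidine fraction or per-codon
element demand per draw, and reports the exceedance — the fraction of draws
strictly beyond the focal set in the direction of interest (higher for
pyrimidine and O, lower for C/H/N). Draws are without replacement within a
combination and independent across combinations, and the candidate universe
is all transcribed genes (including the focal genes; with hundreds of
candidates their inclusion is negligible). Per-set element deltas are
unweighted means across member genes minus the genome-scale mean; because
the abundance-weighted reference is an equally defensible convention, both
are reported.

## Statistics

Classical tests are delegated to base R (`t.test`, `prop.test`, `lm`,
`wilcox.test`), reported alongside the 99%-confidence reading convention
used throughout. The paired Wilcoxon drops zero differences before ranking
and is exact for up to 25 untied pairs; with tied ranks and at most 15
pairs it enumerates all $2^n$ sign assignments, which stays exact where the
standard distribution does not apply. The one-way PERMANOVA is implemented
in the package because the audit needs seeded, reproducible permutations
and exact enumeration for small designs: the Euclidean pseudo-F is computed
from the group decomposition of sums of squares, $p = (\#\{F^\pi \ge
F\}+1)/(P+1)$ with 999 permutations by default, and `exhaustive = TRUE`
enumerates all label orders ($n \le 9$). The implementation is
cross-checked in the tests against the distance-based formulation and
against `vegan::adonis2`. No multiple-testing correction is applied; the
audit reports each test as-is.

The translation-accuracy regression pairs, per amino acid of degeneracy
$\ge 2$, the maximum over the family of the median per-gene RSCU with the
median fractional usage across the set's proteins, then fits ordinary least
squares. Two caveats are inherent to the estimator and documented here:
with few genes per set, the max-of-medians is upward-biased for rarely used
amino acids (an extreme value over noisy estimates), and family size is a
confounder — 4- and 6-fold families admit larger RSCU maxima and often
belong to abundant amino acids, so mildly positive slopes can arise without
any accuracy selection. The audit therefore treats the regression as one
component of a joint signature, never as a standalone detector.

The prebiotic-versus-modern comparison pools, per protein, the fractional
usage of the ten "prebiotic" amino acids (Gly, Ala, Asp, Glu, Val, Ser,
Ile, Leu, Pro, Thr — the consensus early-amino-acid set, configurable since
the literature varies at the margin) against the ten modern ones and
applies a Welch t test. Any downstream conclusion about synthesis cost is
sensitive to this split, which is why it is exposed as a parameter rather
than hard-coded.

# The synthetic genome and what it does (not) show

`genome_spec()` fixes the study conditions: 330 background genes, 30
ribosomal genes and a 3-gene planted operon (363 total); gene lengths
log-normal around 250 codons; a fixed global amino-acid frequency vector
(per-gene variation is deliberately absent so that RSCU and usage
regressions stay interpretable); mRNA abundances log-normal
(meanlog $= \log 50$, sdlog 1.2) with the operon multiplied by 400, placing
it above the 95th percentile of the background as the motivating operons
are. The tRNA pool is proportional to expected background codon usage
(Watson–Crick anticodons, copies $\max(1, \mathrm{round}(90\,u_c))$,
totalling on the order of a hundred gene copies), and by default anticodons
with cytosine at the 3' end are removed — the distinctive absence observed
in the emulated genomes — with any codon left unreadable re-covered by a
single-copy Watson–Crick anticodon so the tAI stays defined everywhere.

Codon usage is controlled by third-base weight vectors. The background
favours G-ending codons (A/C/G/T weights .10/.25/.50/.15, genome GC3 around
0.7); the ribosomal profile favours pyrimidine endings (.05/.45/.12/.38,
sharpened) — this substantial weight on T-ending codons is what allows a
low-GC3 operon to rank high against the ribosomal reference, the
configuration the motivating genomes display; and the planted operon is
pyrimidine-skewed and AT3-rich (.08/.40/.06/.46) with an amino-acid vector
enriched in Ser, Leu, Pro, Thr, Phe and Ala, which makes it
prebiotic-leaning and pyrimidine-rich at all three codon positions. The
accuracy structure is planted directly: each family's vector is mixed with
a point mass on its favoured codon so that the favoured codon's expected
RSCU is linear in relative amino-acid usage, $m = 1 + c\,u/\max u$ with
$c = 3$, capped just below the family size. The mixture construction is
used instead of exponent sharpening because sharpening saturates at the
family-size ceiling and fails to produce a linear max-RSCU–usage relation
detectable above the median-of-three-genes estimator noise. With these
defaults the planted operon reproduces the full joint signature (GC3 < GC,
pyrimidine fraction > 0.5, bottom-decile `cai_genome` rank, above-median
`cai_ribosome` rank, null exceedances below 0.05, accuracy regression
significant at the 1% level), and drawing the operon from the background
abolishes it. A single integer seed (default 101) governs every draw and is
written into the output metadata.

What passing these tests shows is that the *pipeline* recovers a planted
signal of the stated effect sizes and reports no signal when none is
planted. It does not show that real operons carry such signals: the
generator has no phylogenetic structure, no per-gene amino-acid variation,
no correlation between expression and codon bias in the background, no
partial genomes or annotation errors, and its tRNA pool is derived from
codon usage rather than measured. Headline values from the motivating
study (a PERMANOVA F near 37 with $R^2 = 0.38$ across 34 genomes, 52%
transcriptome purine content, specific removal shifts) depend on dozens of
real genomes and three RNA-Seq datasets and are not reproducible at desk
scale; the package's checkable quantities are the analytic codon-metric
limits (ENC 61 and 20, RSCU 1.0) plus the property and calibration suites.

# Numerical choices and problem sizes

Percentile ranks use the fraction-at-or-below convention with shared tie
ranks; the maximum of any set ranks 100. PERMANOVA p-values live on the
grid $k/(P+1)$, so tests at $\alpha = 0.01$ use at least 99 permutations.
Permutation comparisons use a $10^{-12}$ slack on $F^\pi \ge F$ to keep
ties stable across platforms. Reports round numeric columns to 10
significant digits so that re-runs are byte-identical. The test suite
calibrates the type-I error of all four tests at $\alpha = 0.01$ over
5,000 null simulations each (sample sizes 20 pairs, 30 + 30, 200 + 200
trials, and 20 observations in 4 dimensions with 99 permutations), sizes
chosen to finish in minutes on one CPU while leaving the Monte-Carlo
standard error well below the ±0.5-percentage-point tolerance; parameter
recovery runs the default 363-gene genome with 999 permutations and 1,000
null draws.

# Known limitations

ENC edge-handling for sequences missing whole degeneracy classes follows
Wright's recommendations but may diverge from other implementations
(e.g. EMBOSS `chips`), whose conventions are not fully specified; the
shipped wobble-constraint values are the published tAI defaults, not fitted
to any genome, and results are only comparable across runs with the same
table hash. The audit analyses one genome at a time; cross-genome paired
designs (the motivating study pairs operons across dozens of genomes)
should loop over genomes and feed the per-genome summaries into the paired
tests.
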