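---
title: "Methods: the R2R3-MYB candidate funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the R2R3-MYB candidate funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybfunnel)
```

## The problem

Grass secondary cell walls are lignified through a transcriptional program in
which R2R3-MYB factors act as activators and repressors of monolignol — and,
in grasses, tricin — biosynthesis. Candidate regulators can be nominated
without any wet-lab step by a guilt-by-association funnel: identify every
R2R3-MYB in the proteome, anchor them genomically, and keep only those whose
expression tracks a reference set of core lignin biosynthetic genes (the
"lignin toolbox") across several independent expression views. `mybfunnel`
implements that funnel end to end, with a synthetic-data generator that
plants known truth at every stage so the whole pipeline is testable offline.

## Family identification: PSSM repeat scan

Family membership is decided by a position-specific scoring matrix over the
~52-residue MYB repeat. The bundled seed alignment is a synthetic block
modeled on the plant MYB repeat consensus (conserved Trp triad at columns 6,
26, 46); remote domain databases are deliberately out of scope, so the PSSM
is the package's own stand-in for a curated domain model. Scores are
log-odds in bits with additive pseudocounts,

$$ s(c,a) = \log_2 \frac{(n_{c,a} + \lambda b_a)/(N + \lambda)}{b_a}, $$

and a window is a hit when its summed score reaches a fixed fraction
(default 0.45) of the maximum achievable window score. Unknown residues (X)
score 0 in every column, a neutral treatment of ambiguity. Overlapping hits
are resolved greedily by descending score with leftmost ties. A protein is a
family member iff it has exactly two hits, both starting inside the
N-terminal window (default 200 aa) and separated by at most 30 residues;
one-repeat and three-repeat (R1R2R3-type) architectures are excluded. The
three numeric limits are configuration values: no published cutoffs exist
for this style of scan, so the defaults were chosen once such that the seed
sequences themselves pass and random sequences sit far below threshold
(random-background window scores average roughly −170 bits against a
threshold near +94).

## Genomic naming and tandem duplication

Family members are named `prefix1..prefixN` by natural chromosome order
(chr2 before chr10, scaffolds last) and ascending start. Two family genes
are tandem-linked when they lie on the same chromosome with an edge-to-edge
gap `max(0, start_downstream − end_upstream)` of at most 50 kb (inclusive);
clusters are the connected components under transitive chaining. The
distance is measured between closest gene edges, not start-to-start, and
intervening non-family genes do not break a cluster — the 50-kb rule is a
physical-proximity criterion and nothing more. Strand is ignored.

## Subgroup assignment

The classifier is deliberately a distance method: a center-star multiple
alignment (pairwise global alignments against the sequence with the best
summed score, merged under "once a gap, always a gap"), trimAl-style column
trimming (drop columns with gap fraction > 0.5; always retain at least 10%
of columns, keeping the least-gapped ones, ties leftmost; no
similarity-based removal), p-distances, and Saitou–Nei neighbor joining
with

$$ Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k), $$

deterministic tie-breaking and negative branch lengths clamped to zero.
Maximum-likelihood inference with model selection is a non-goal: an ML tree
from a particular toolchain is not reproducible here, and everything
downstream needs only the subgroup-assignment contract. Bootstrap supports
come from column resampling; each internal node is labeled with the
percentage of replicate trees containing its bipartition. For assignment the
tree is midpoint-rooted (no outgroup is assumed) and each query walks
rootward to the smallest clade containing at least one reference leaf with
support ≥ 50; the majority reference label wins, ties and unreachable
references give `"unclassified"`. Subgroup names are taken from the
reference labels as given, never re-derived.

## Expression stages

Rows are standardized to mean 0 and unit (n−1) standard deviation before
clustering; constant rows are dropped with a warning and recorded.
Clustering is agglomerative with correlation distance (1 − Pearson) and
average linkage by default — the defaults of the usual web heatmap tools;
both are configurable and echoed in every report. The atlas is cut at k = 5
and the internode matrix at k = 2, mirroring how such heatmaps are read;
there is no automatic k selection. The atlas stage keeps family members of
the cluster holding the most toolbox genes (ties: higher toolbox fraction,
then smaller cluster), excluding the toolbox itself. The internode stage
offers two selectors, because a heatmap cluster boundary and a profile-shape
rule are both defensible readings: (i) append the mean scaled toolbox
profile as an artificial terminal row, cluster at k = 2, and keep family
genes on the terminal's side; (ii) keep genes whose scaled profile peaks in
the transitional or maturation zone. On the synthetic data both selectors
agree.

## Co-expression screen and shortlist

For each candidate, Pearson correlations are computed against every other
atlas row; partners at r ≥ 0.85 (inclusive — the customary public-platform
minimum) are kept and labeled from a user-supplied functional-category
table (lignin biosynthesis, lignin-related, phenylpropanoid-related;
anything else counts as `other`). Candidates pass when they have at least 11
target-category partners; the published boundary separates rejected
candidates (n < 8) from retained ones (n ≥ 11), so values 8–10 are genuinely
ambiguous and the threshold is configurable. By default correlations are
computed on raw abundances, matching the upstream platform convention; a
`log2p1` switch computes them on log2(x+1). The synthetic end-to-end runs
use the switch: the generator plants its correlation structure on the log
scale, and on raw lognormal values a planted r of 0.9 attenuates to roughly
0.87–0.88, so screening on the log scale measures the planted quantity on
its own scale rather than the attenuation artifact.

The package ships the printed partner lists of the two strongest published
candidates (SvMYB24, SvMYB74) as a plain-text fixture. The upstream source
reports 27 partners for SvMYB24 while its printed list resolves to 26
unambiguous rows (the first token after the query id is the query's own
locus); the fixture keeps the verbatim rows and leaves the discrepancy
documented rather than resolved.

## Validation statistics

Relative expression is `2^(−ΔCt)` with ΔCt the target Ct minus the
arithmetic mean of the two reference-gene Cts — equivalent to geometric-mean
normalization on the linear scale. Amplification efficiency is fixed at 2;
no efficiency correction is applied. A gene is called preferentially
expressed in the target tissue iff that tissue has the highest mean relative
expression *and* Tukey's HSD rejects against every other tissue at α = 0.05
after a one-way ANOVA. This compound verdict is conservative by
construction: Tukey controls the family-wise error and the target must also
be the maximum, so its null rate sits well below α. The α-calibrated
component is the omnibus F test, which the function returns alongside the
verdict; the calibration test checks the omnibus rejection rate against α
and the compound verdict rate against the α ceiling. Transactivation folds
are ratios of mean fLUC/rLUC per effector over the control effector, with a
two-sided Student's t test on the per-replicate ratios (a Welch switch is
provided; Student's is the default to match the usual reporting of such
assays). When both arms are noise-free and identical the t statistic is
undefined; the p-value is then defined as 1 for equal means and 0 otherwise.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* a proteome with 0/1/2/3 planted MYB repeats per protein, sampled from the
  same bundled seed alignment as the scanner but through an independent
  mutation path (default 5% substitutions, up to the tested 10%), so
  recovery tests are not circular at nonzero noise;
* gene models realizing requested tandem arrays with exact intra-array gaps,
  other genes spaced 200 kb apart over nine chromosomes;
* an atlas with k planted co-expression clusters built from nested latent
  factors: per sample, `x = sqrt(r_bg)·g0 + sqrt(r_w − r_bg)·f_c +
  sqrt(1 − r_w)·ε`, giving expected pairwise correlation `r_within` (0.9)
  inside a cluster and `r_background` (0.3) across clusters. A single
  factor per cluster would leave cross-cluster pairs uncorrelated,
  contradicting the intended 0.3 background and making the loose background
  blocks unclusterable, which is why the nested form is used. Values are
  exponentiated as `2^(x/2 + offset)` into positive TPM-like units; the
  mild exponent keeps raw-scale correlations near the latent values, and
  row standardization downstream is location/scale-invariant anyway;
* a 4-zone internode matrix in which toolbox-cluster genes rise
  bottom-to-top and peak in TZ or MZ;
* Ct and luciferase tables with a planted fold change (default 8 for the
  positive design), reference genes near Ct 20, targets near Ct 26, and
  ~15% per-replicate multiplicative noise on luciferase ratios.

What the generator does **not** emulate: sequencing-read noise models,
batch effects, missing values, or heavy-tailed expression beyond
Gaussian-on-log. Passing tests therefore demonstrate algorithmic
correctness under a clean planted model, not robustness to every artifact
of real atlases.

In the end-to-end runs, besides the 14 toolbox genes and 5 planted
regulators, 20 non-family "decoy" genes (standing for the laccases,
class III peroxidases and NAC homologues that co-express with the toolbox
in real atlases) are planted into the toolbox cluster and annotated as
lignin-related. This keeps the annotated co-expression universe at a
realistic size; with only the 14 toolbox genes as possible partners the
r ≥ 0.85 / ≥ 11-target shortlist rule would operate on a far smaller pool
than the screens it models.

## Numerical choices and problem sizes

Determinism is a contract: every generator is byte-identical under a fixed
seed, clustering tie-breaks are lexicographic, NJ tie-breaks take the
smallest indices, and the bootstrap uses an explicit seed. Degenerate inputs
fail fast (ragged alignments, zero background frequencies, zero-variance
query rows, single-replicate tissues, zero Renilla readings), except where a
degenerate result is well-defined (all-identical sequences give a zero-length
star tree; sequences shorter than the PSSM give zero hits).

The test suite runs at the scales its properties state: 100 random sequences
against the brute-force window oracle, 20 planted-proteome seeds, 200 random
tandem layouts against the all-pairs closure oracle, 1000 random Pearson
pairs at 1e−12, 50 random additive matrices of 5–12 leaves, 1000 null ANOVA
simulations, and 10 end-to-end funnel seeds at 39 samples — chosen so the
whole default run finishes in a few minutes on one core while keeping each
property statistically meaningful.

## Known limitations

The PSSM scan has no insert/delete states, so strongly gapped repeats score
lower than a profile HMM would allow. The center-star alignment is a
heuristic with no optimality guarantee beyond its classical bound. NJ
subgroup assignment is only as good as the reference labels and degrades
with deep, unevenly sampled clades. The funnel's verdicts are guilt by
association: they nominate candidates for validation, they do not establish
regulatory function.
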