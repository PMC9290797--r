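---
title: "Methods: windowed admixture and selection scans in zapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed admixture and selection scans in zapscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

zapscan analyses whole-genome resequencing data from an invasive species
whose introduced populations descend from a single, already-admixed source:
two differentiated native lineages (here called *west* and *east*) mixed
before colonization, and several introduced populations share that event.
The package answers three questions, window by window along the genome:

1. **Where does each window's ancestry come from?** Topology weighting over
   per-window trees, summarized as an ancestry score.
2. **Which windows were under selection during or after the invasion, and is
   selection shared across introduced populations?** PBS outlier scans with
   a randomization null for outlier overlap.
3. **Is there genome-wide evidence of admixture?** f4 tests with
   block-jackknife Z-scores.

Supporting stages assign scaffolds to the X chromosome or autosomes from
read depth (diversity and differentiation behave differently on the
hemizygous X), and compute windowed diversity statistics.

## Statistics and estimators

**Nucleotide diversity.** Per coordinate window,
$\pi = \sum_s 2 c_{0s} c_{1s} / (n_s (n_s - 1)) \,/\, L$ over SNPs $s$ with
allele counts $c_{0s}, c_{1s}$ among $n_s$ called haplotypes, and $L$ the
full window length in bp. Dividing by $L$ (not by the SNP count) treats
non-genotyped sites as monomorphic, the convention of windowed-$\pi$ tools;
this equals the mean pairwise Hamming distance between haplotypes divided by
$L$ on complete data, which the tests assert to 1e-12.

**F_ST.** The Hudson estimator in ratio-of-averages form: per site
$N_s = (p_A - p_B)^2 - \frac{p_A(1-p_A)}{n_A - 1} - \frac{p_B(1-p_B)}{n_B - 1}$,
$D_s = p_A(1-p_B) + p_B(1-p_A)$, and $\hat F_{ST} = \sum N_s / \sum D_s$.
The correction terms make $E[N_s]$ equal the squared true-frequency
difference at any sample size. The original study computed windowed F_ST
from genotype likelihoods (realSFS); this package substitutes the Hudson
estimator on called genotypes — a documented divergence, so exact numerical
parity with published window medians is not a target. Raw window values may
be negative; they are reported raw and clamped to $[0, 1 - 10^{-9}]$ before
any log transform.

**PBS.** With $T_{xy} = -\ln(1 - F_{ST,xy})$,
$\mathrm{PBS}_A = (T_{AB} + T_{AC} - T_{BC})/2$ is the focal branch length
since divergence from two references; it can be negative, and satisfies
$\mathrm{PBS}_A + \mathrm{PBS}_B = T_{AB}$ (a tested identity).

**Topology weighting.** Each 500-SNP window gets a neighbour-joining tree on
pairwise haplotype Hamming distances (the study's supplementary alternative
to per-window maximum likelihood trees; ML inference is out of scope and the
tree builder is pluggable behind `nj_tree()`). With one haplotype sampled
per group (outgroup O, west W, east E, focal I), the quartet's topology
inside the tree is read from tip path distances: bipartition
$\{a,b\}|\{c,d\}$ holds iff $d(a,b)+d(c,d)$ is strictly the smallest pair
sum — exact on a tree metric; a three-way tie means a zero-length internal
edge and the quartet counts as unresolved (excluded from the weight
denominator, reported as a fraction). 600 quartets are sampled with
replacement per window; when the one-per-group product is at most 600 the
quartets are enumerated exhaustively instead, making the result
seed-independent. Windows are classified topo1/topo2/topo3 when a weight
strictly exceeds 0.5, else ambiguous; the ancestry score is $w_1 - w_2$
(+1 pure west, −1 pure east). Whether score correlations between focal
populations should use all windows or only non-ambiguous ones is not pinned
by the source analysis; the default uses all windows with defined weights
(`ancestry_correlation` receives whatever you pass, so restricting is a
one-line filter).

**f4.** $f_4(A,B;C,D) = \mathrm{mean}_s (p_A - p_B)(p_C - p_D)$; excess
B–C sharing drives it negative, B–D positive. Standard errors use a
delete-one block jackknife over blocks of 500 consecutive SNPs (absorbing
local linkage); blocks never span scaffolds, and a trailing block smaller
than 50 SNPs merges into its neighbour. Blocks are equal-weight: they are
near-equal in size by construction, so size weighting would change nothing
material.

**Outlier scan.** "Top 99%" is read as the top 1% (values at or above the
nearest-rank 99th percentile), consistent with the ~5% unique-outlier rate
across five comparisons in the source analysis; ties at the threshold are
all included. Autosomal and X windows are ranked separately, because the
X's smaller effective size inflates differentiation. Overlap categories:
shared_two / shared_three (outlier in ≥2 / all 3 introduced-vs-native
comparisons), plus_native and plus_introduced (between-range outlier also
flagged within the native or introduced range), unique. The null for
overlap draws, per comparison, a uniform without-replacement sample of
windows of the observed outlier count (100,000 replicates at study scale)
and recomputes the overlap; the empirical p is reported raw — it can be
exactly 0, which is the study-parity output — alongside the
$(\mathrm{count}+1)/(\mathrm{reps}+1)$ corrected value. For two comparisons
this null is exactly hypergeometric, which the tests exploit as a
closed-form oracle. Ancestry composition at outlier windows is compared to
the genomic background with Pearson's chi-squared over the four topology
classes (df = 3).

## Sex-linked scaffold assignment

Normalized depth = scaffold mean depth ÷ the sample's length-weighted
genome-wide mean. Rules, in precedence order: scaffolds under 100 kb are
unassigned (too short for stable means); normalized depth > 1.5 in at least
⌈7/9 × samples⌉ samples marks collapsed repeats (inflated depth invalidates
any sex signal, so this outranks X/Y); X requires < 0.85 in ⌈0.8 × males⌉
males and > 0.85 in ⌈0.75 × females⌉ females; Y requires > 0.25 in males
and < 0.25 in females by the same vote fractions; otherwise autosome. The
original absolute counts (4/5, 3/4, 7/9) are generalized to ceiling-of-
fraction rules so any cohort works; note the all-sample fraction must be
the exact ratio 7/9 — a rounded decimal like 0.78 would demand 8 of 9
votes. Unknown-sex samples vote only in the repeat rule, since the repeat
criterion is explicitly sex-independent while the X/Y criteria are not.

## The synthetic-data generator

`simulate_dataset()` is a generative caricature of the inferred invasion
history — a single admixture event between the two African lineages
predating colonization, shared by all introduced populations — built for
testability rather than realism:

* **Drift is Balding–Nichols**, not coalescent: descendant frequency
  ~ Beta(mean $p$, variance $F p (1-p)$). Closed forms follow, e.g. the
  expected genome-wide Hudson F_ST between two populations independently
  drifted from a common ancestor is $(F_A + F_B)/2$ (from
  $E[N_s] = (F_A + F_B)\,p(1-p)$, $E[D_s] = 2p(1-p)$), which the acceptance
  tests assert within ±0.02 at 50,000 SNPs. No external simulator is
  needed; a coalescent backend could sit behind the same config.
* **Hierarchy**: ancestral frequency ~ Uniform(0.05, 0.95) per SNP; west and
  east lineages drift from it with `F_split` (default 0.15, matching the
  0.14–0.19 genome-wide F_ST scale reported for the study system);
  populations drift within lineages with `F_pop` (0.05); introduced
  populations drift from their window's source lineage with `F_intro`
  (0.10, the colonization bottleneck).
* **Window-level ancestry**: each window draws west ancestry with
  probability `alpha` (default 0.7, predominantly-west); one draw shared by
  all introduced populations (`shared`), or independent per population — the
  contrast the ancestry-score correlation test discriminates. The analysis
  operates on windows, so ancestry blocks at window granularity suffice; no
  recombination breakpoints are simulated.
* **X inflation**: all F parameters become $1-(1-F)^{4/3}$ on X scaffolds,
  mirroring the 3/4 effective-size ratio; X windows are reliably more
  differentiated than autosomal ones (tested).
* **Selection**: planted autosomal windows shift the derived frequency
  $p \leftarrow p + \delta(1-p)$ at every SNP in every introduced population
  (defaults: 20 windows of 2,000, $\delta = 0.6$).
* **Outgroup**: fixed ancestral, except fixed derived with probability 0.05
  — enough polarization error to exercise the joint-SFS exclusion rules.
* Haplotypes are independent Bernoulli draws at the population frequency:
  there is **no linkage within windows** beyond shared ancestry, no
  missingness unless you add it, and no sequencing error. A green recovery
  test therefore establishes that the estimators recover the generative
  parameters of this idealized world — not that they are robust to real
  data pathologies (genotyping error, uneven coverage, inversions).
* Depth tables: per-sample baseline ~ 30× scaled by Uniform(0.8, 1.2);
  males at 0.5× on X, repeats at 1.8×, Gaussian noise σ = 0.05 on the
  normalized scale, truncated at 0. Because normalization divides by a
  genome-wide mean that includes the X, a male's *normalized* X depth is
  $0.5/(1 - f_X/2)$ for X genome fraction $f_X$, slightly above 0.5 — the
  raw X/autosome ratio is exactly 0.5 at σ = 0, and the tests assert both.

## Numerical and design choices

* Coordinates are 0-based half-open internally and in every written table
  (BED convention); VCF positions are converted on read/write.
* `--max-missing`-style filtering keeps a site when its called fraction is
  ≥ the threshold (boundary inclusive), matching the cited tool's
  semantics; minor-allele count is computed over non-missing haplotypes.
* Fixed-SNP windows drop the trailing remainder (fixed-SNP tools'
  behaviour); coordinate windows keep a flagged partial tail (windowed-scan
  behaviour). The source analysis does not state either policy; these are
  explicit choices.
* Unphased heterozygotes are accepted for frequency-based statistics and
  refused by haplotype-based ones, unless phase is randomized under the run
  seed (`read_vcf(random_phase_seed=)`).
* NJ ties in the Q criterion break at the lowest (row, column) pair and
  negative branch lengths are floored at 0, making window trees
  deterministic on degenerate inputs; quartet tie detection uses a relative
  1e-10 tolerance on pair sums (floored branches are the only source of
  exact ties).
* The outlier quantile uses `ceiling((1-q) * n)` with an epsilon guard:
  naive `ceiling(0.01 * n)` overshoots at n = 100 because 1 − 0.99 is not
  exactly 0.01 in floating point.
* Pipeline stage seeds are a stable hash of (global seed, stage name), so
  toggling one stage never shifts another stage's draws; all derived seeds
  stay below $2^{31}$.

## Limitations

No genotype-likelihood machinery (the realSFS/angsd path of the original
analysis), no ML/Bayesian trees, no demographic model fitting (the joint
SFS is exported, not fitted), no per-SNP covariate contrast statistics, and
no annotation of outlier windows. Empirical numbers from the original
67-genome study are not reproduction targets at desk scale; every
quantitative claim in this vignette is one the test suite computes.
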