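---
title: "Methods: intergenerational methylation-inheritance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intergenerational methylation-inheritance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`methinherit` implements the statistical core of a paternal
epigenetic-inheritance study design: male mice develop chronic colitis
under dextran sodium sulphate (DSS), and the question is whether the
insult leaves DNA-methylation marks in their sperm that reappear in the
sperm and intestinal epithelial cells (IECs) of their unexposed offspring,
together with correlated changes in the offspring transcriptome. The
measured layers are per-CpG bisulfite counts (RRBS) for sperm and IECs in
two generations (F0, F1) and gene-level RNA-seq counts for IECs, each with
a control (Ctrl) and an exposed (DSS) group.

The pipeline runs, in order: coverage QC, per-CpG differential
methylation (DM) per layer, differential expression (DE), genomic
annotation of CpGs, cross-layer overlaps with a permutation null,
three-way inheritance candidates and DM–DE quadrant integration, and MDS
ordination with a permutation multivariate ANOVA. Every stage is driven
by ground-truthed synthetic data from the package's own generator, so
each claim the pipeline makes can be checked against what was planted.

# Models and procedures

## Differential methylation

For CpG site $i$, sample $j$ contributes methylated/unmethylated read
counts $(m_{ij}, u_{ij})$. The methylation value is
$m_{ij}/(m_{ij}+u_{ij}) \in [0,1]$. The default per-site test pools
replicates within each group into a single $2\times2$ table
(methylated/unmethylated $\times$ Ctrl/DSS) and computes the two-sided
exact conditional p-value: with margins fixed, the probabilities of all
tables no more probable than the observed one are summed (the same
two-sided rule as Fisher's exact test; implemented directly on the
hypergeometric density so that tens of thousands of sites stay cheap, and
cross-checked in the tests against both `stats::fisher.test` and an
explicit binomial-coefficient enumeration). A replicate-aware binomial
regression with a likelihood-ratio test is available as
`method = "logistic"`.

The effect size is $\Delta_i$ = pooled DSS fraction − pooled Ctrl
fraction. After Benjamini–Hochberg adjustment across all tested sites, a
site is called **hyper**-methylated if significant with $\Delta > 0.20$,
**hypo**-methylated if significant with $\Delta < -0.20$, otherwise not
significant. The 0.20 effect threshold and adjusted $p < 0.05$ are the
study constants and are configurable; a raw-p switch mirrors analyses
that filter on unadjusted p. Direction is always exposed-relative-
to-control: *hypo* means lower methylation under DSS.

Pooling replicates makes the exact test sensitive but blind to
biological replicate variability; the `|Δ| > 0.20` requirement is what
keeps the false-discovery rate controlled in the presence of
overdispersion, because between-replicate noise at ~120 pooled reads per
group rarely moves the pooled fraction by 0.2. The planted-recovery
tests quantify exactly this trade-off (sensitivity ≥ 0.8 at observed
FDR ≤ 0.1 under the default conditions).

## Differential expression

Counts are normalized with median-of-ratios size factors (per-sample
median of count/geometric-mean ratios over genes expressed everywhere,
rescaled to geometric mean 1). Genes below a mean normalized count of 1
are removed before testing and before the BH denominator (independent
filtering). Per-gene NB dispersion is estimated by the method of moments
from pooled within-group variances and shrunk on the log scale toward a
fitted $a_0 + a_1/\mu$ mean–dispersion trend with prior weight 2. Each
gene is then fitted with a NB log-linear model of counts on group with
log size factors as offsets at its shrunk dispersion, and the group
coefficient (the log2 fold change after rescaling) is tested by a Wald
statistic.

Because the dispersion is estimated from the same few replicates, the
Wald statistic is referred to a **moderated t** distribution with
$(n_1+n_2-2)\,(1+w)$ degrees of freedom, where $w = 2$ is the shrinkage
prior weight — the trend contributes information equivalent to $w$ times
the residual degrees of freedom. A plain normal reference is visibly
anticonservative at $n = 4$ vs $4$ (about 4× the nominal mass below
$p = 0.01$), while the moderated t keeps the null p-value distribution
within Kolmogorov–Smirnov distance 0.05 of uniform at 10,000 genes and
retains ≥ 90% power for a doubling of expression at mean 100, which the
acceptance suite checks.

Direction is *up*/*down* by the sign of the log2 fold change among
$q < 0.05$ genes. Over-representation of a DE set in user-supplied GMT
gene sets uses the upper-tail hypergeometric test with BH adjustment.

## Genomic annotation

Features live internally as 0-based half-open intervals; GTF (1-based
inclusive) and BED (0-based half-open) are converted at the I/O boundary
only, and round-trips are tested to be coordinate-exact. Promoters are
derived from the TSS with a window of 2,000 bp upstream and 500 bp
downstream (configurable). A CpG's category is the highest-precedence
overlapping feature kind, **promoter > CGI > CGI shore > CTCF > enhancer
> gene body > intergenic** — a fixed precedence is needed because each
site must contribute to exactly one category proportion. The primary
gene is the overlapping promoter's gene (nearest TSS on ties), falling
back to the gene body. Gene-level DM sets take each gene's direction
from its most significant site (smallest q, then largest |Δ|), flagging
direction conflicts as *mixed*. Interval queries go through
GenomicRanges; an independent base-R interval scan serves as the
brute-force oracle in the tests and supplies the generator's ground
truth.

## Overlaps and the permutation null

Gene-set overlaps across layers are direction-constrained where the
biology demands concordance (sperm F0 ∩ sperm F1; the three-way
intersection) and unconstrained for the same-tissue DM ∩ DE comparison.
The null holds set sizes fixed and redraws each set uniformly without
replacement from the gene universe, independently, recording the
(common) intersection size over `n_perm = 10,000` draws; results are
reported as "observed; mean [min, max]; p". The default empirical
p-value is the plain ratio $\#\{X^{(b)} \ge X_{obs}\}/B$, which can be
exactly 0; the add-one convention $(\#+1)/(B+1)$ is available. The
universe is the set of genes with at least one retained CpG (DM sets) or
tested for DE (DE sets), intersected across the sets being compared;
permutation preserves set sizes only, the minimal null consistent with a
gene-level overlap statistic.

For two sets of sizes $a, b$ drawn from a universe of size $N$ the null
intersection is hypergeometric with mean $ab/N$; the tests verify the
permutation mean against this closed form. Because the overlap statistic
is discrete, the empirical p under its own null has mean
$1/2 + P(X = X')/2$, slightly above 1/2; the calibration check therefore
uses wide sets (800 and 1,000 from a universe of 4,000), where the
discreteness offset is ~0.01.

Exact-position overlap (the same chrom:pos differentially methylated in
both generations) is reported separately from gene-level overlap, since
inherited marks need not hit the same cytosine to hit the same gene.

## Integration and candidates

Three-way candidates are genes DM with the same direction in F0 sperm,
F1 sperm and F1 IECs. DM–DE candidates are genes DM concordantly in both
sperm generations and DE in F1 IECs; each gets a quadrant from
(methylation direction, expression direction), with hypo-up and
hyper-down labeled *negatively regulated* and hypo-down / hyper-up
*positively regulated*.

## Ordination

Classical (Torgerson) MDS on Euclidean distances — standardized
per-feature for methylation fractions, log2 normalized counts for
expression — with coordinates centered at the origin. Group separation
is tested with a distance-based permutation multivariate ANOVA: the
pseudo-F contrasts between-group and within-group sums of squared
distances on the full distance matrix (not the MDS projection), with the
p-value from label permutations under the add-one convention. The
statistic is cross-checked against `vegan::adonis2` in the tests, and
its type-I error is verified to sit at $0.05 \pm 0.02$ over 1,000 null
runs. With $n$ per group as small as 4–6, the attainable p floors at the
rate of label permutations that reproduce the original grouping
($2/\binom{12}{6}$ for 6 vs 6).

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream guarantee is stated.

**Genome and annotation.** Non-overlapping genes with random strand on
each chromosome; promoters from the TSS; CGIs over about half the
promoters plus standalone islands; CTCF regions scattered genome-wide.
CpG sites are placed in RRBS-like clusters: ~55% in promoter clusters of
4–8 CpGs, the rest over gene bodies, CGIs, CTCF regions and intergenic
space. True categories come from a direct interval scan with the same
precedence the annotator uses.

**Methylation counts.** Coverage is negative binomial around 30× (size
10); per-sample methylation probabilities are beta-distributed around
the site mean with intra-class correlation $\rho = 0.02$, and methylated
counts are binomial — i.e., beta-binomial counts with moderate
biological overdispersion, in the range reported for RRBS biological
replicates. Baseline site means follow the bimodal RRBS mixture: 55%
low (~0.05), 15% intermediate (~0.5), 30% high (~0.95). Each of the 50
planted inherited genes carries a cluster of 5 promoter CpGs whose DSS
mean is shifted by ±0.3 — clustered, concordant promoter DM being the
biologically expected signature — with baselines at $0.5 \mp 0.15$ so
the shift never truncates at the unit interval; direction (hypo/hyper)
is balanced and identical across F0 sperm, F1 sperm and F1 IECs. The F0
IEC layer deliberately receives no planted inheritance signal and acts
as a negative control. Seven imprinting-control loci are emitted at
fixed levels ~0, ~0.5 and ~1 (tight $\rho = 0.005$) in all samples,
mirroring the none/partial/complete bisulfite-conversion checks.

**Expression counts.** Gene baselines are log-normal (median 30, log-sd
1.2); counts are negative binomial with dispersion 0.02, the low
biological variability of inbred littermate replicates — this is also
what makes the stated power property (a doubling at mean 100 detected in
≥ 90% of runs with 4 vs 4) attainable at all. True library-size factors
vary uniformly by ±30% and are absorbed by the offsets. Half of the
planted genes (the coupling fraction) get a log2 fold change of ±1 in F1
IECs with sign tied to methylation direction (hypo→up, hyper→down);
each expression layer additionally receives 100 unlinked DE background
genes emulating the direct transcriptome response.

**Determinism.** Every stage draws from seeds derived from the single
configuration seed; identical configurations produce byte-identical
files, which the tests verify by checksum.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: read-level artifacts (mapping bias,
bisulfite conversion failure, strand effects), CpG–CpG correlation
beyond the planted clusters, genuinely tissue-specific baseline
methylomes (baselines are shared across layers), covariates and batch
structure, partial (stochastic) inheritance of marks, and any
genome-scale feature composition tuned to a particular species. Recovery
rates measured here are therefore statements about the statistical
machinery under a faithful overdispersed count model, not about any
laboratory protocol.

# Numerical and design choices

- **Coverage QC**: at least 10 reads in every sample (complete cases per
  comparison, which matches per-comparison "sites identified" counting)
  and removal above each sample's 99.9th coverage percentile. The
  percentile trim is iterated to its fixed point so that filtering is
  idempotent — a one-pass quantile rule is not, because the quantile of
  the trimmed distribution shifts down. At the default 0.999 quantile
  the iterated trim removes a few percent of NB-distributed integer
  coverages.
- **Exact-test ties**: probabilities within a relative $10^{-7}$ of the
  observed table's probability count as "as extreme", matching
  `fisher.test`.
- **BH ties**: ranking is stabilized on (p, chrom, pos).
- **Zero-coverage groups**: sites with an empty group are skipped and
  counted in the audit rather than tested.
- **Dispersion floor**: $10^{-8}$, avoiding degenerate Wald statistics
  for near-constant genes; all-zero genes are reported `ns` with a flag.
- **Empirical-p convention**: the plain ratio (p may be 0) by default,
  since overlap results are conventionally reported that way; add-one
  available everywhere.
- **MANOVA on the full distance matrix** rather than MDS coordinates:
  the projection discards distance information and its dimension is an
  analysis choice; the full-matrix test is the standard PERMANOVA form.
- **Problem sizes in the test-suite**: unit tests run on studies of
  100–600 genes and 300–4,000 CpGs; the acceptance properties use the
  default study (2,000 genes, 8,000 CpGs, 4 vs 4 at 30×) plus a
  10,000-gene expression-only run for null calibration, 1,000 seeded
  MANOVA null runs, and 200 seeded permutation-null runs. These sizes
  make every statistical property measurable in minutes while keeping
  Monte-Carlo error well inside the asserted bounds.

# Known limitations

- The pooled exact DM test treats replicates as exchangeable sequencing
  of one pool; with strong between-replicate heterogeneity the logistic
  mode (or a beta-binomial test, not implemented) is more appropriate.
- DM regions (windows/segments) are out of scope; calls are per-CpG.
- The gene-level direction collapse ("most significant site wins") is a
  reporting convention; *mixed* flags preserve the conflicts.
- The permutation null ignores per-gene CpG multiplicity; genes with
  many CpGs are more likely to enter DM sets in both layers, so the
  gene-level overlap null is mildly liberal. A multiplicity-preserving
  null would require resampling sites rather than genes.
- ORA gene sets are user-supplied files; no pathway database ships with
  the package.
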