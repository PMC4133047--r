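---
title: "Population structure and pulse-admixture dating with admixpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure and pulse-admixture dating with admixpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixpulse)
```

# Scope

`admixpulse` implements a complete population-structure and admixture-history
workflow for diploid SNP panels: quality control and dataset merging,
LD-block haplotype heterozygosity, the serial-founder heterozygosity-distance
regression, Weir–Cockerham $F_{ST}$ with classical MDS and BIONJ trees,
allele-sharing dissimilarities with balanced geographic resampling,
Procrustes comparison and a permutation test for cluster separation,
EM estimation of individual ancestry proportions with replicate-mode
grouping, and moment-based dating of a single admixture pulse. A
synthetic-data module generates datasets with known ground truth so every
stage can be validated without restricted genotype data.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the simulation-based tests do and do not
establish about real data.

# The pulse-admixture dating model

The centrepiece is the moment estimator of time since admixture. Consider a
hybrid population founded $g$ generations ago by a single pulse in which
each founder draws its source independently: with probability $s$ from the
focal source and $1-s$ otherwise. Let $H_i$ be individual $i$'s ancestry
fraction from the focal source. First-generation hybrids average two
founder labels, so $\mathrm{Var}(H_1) = s(1-s)/2$. Under closed random
mating each child averages two independently drawn parents, so the variance
halves every generation while the mean stays at $s$:

$$\mathrm{Var}(H_g) = \frac{\mu(1-\mu)}{2^{g}}, \qquad \mu = s .$$

Inverting with the sample moments $\hat\mu$ and $\hat\sigma^2$ of observed
ancestry fractions gives

$$\hat g = \log_2 \frac{\hat\mu(1-\hat\mu)}{\hat\sigma^2}.$$

$\hat g$ counts generations before the birth of the sampled individuals, so
the reported age adds the sampled generation itself:
$\mathrm{YBP} = (\hat g + 1) \times 25$ years by default.

Properties and edge cases:

* $\hat g$ is strictly decreasing in $\hat\sigma^2$ at fixed $\hat\mu$ and
  invariant under $\hat\mu \to 1 - \hat\mu$ (source relabelling).
* $\hat\sigma^2 = \hat\mu(1-\hat\mu)$ is the unmated founder mixture:
  $\hat g = 0$.
* $\hat\sigma^2 > \hat\mu(1-\hat\mu)$ gives $\hat g < 0$; the estimate is
  flagged `"inconsistent with post-founding mating"` rather than truncated.
* $\hat\sigma^2 = 0$ or $\hat\mu \in \{0, 1\}$: the time is undefined and an
  error is raised.

`admixtureTimeMoments()` uses the unbiased $(n-1)$ sample variance by
default; a toggle provides the maximum-likelihood $n$ denominator because
the convention is genuinely ambiguous in this literature. In pooled-group
reports (`datingReport()`), pooling concatenates the member populations'
membership vectors and recomputes the moments — it never averages
per-population estimates — and the across-$K$ summary averages YBP, not
$\hat g$.

**Caveat.** Ancestry fractions from any estimation pipeline are noisy
estimates of $H$. Estimation noise inflates $\hat\sigma^2$ and biases
$\hat g$ downward; conversely, shared pedigree among sampled individuals
deflates the between-individual variance and biases $\hat g$ upward. No
correction is applied (matching standard practice for this estimator), so
estimates should be read comparatively, not as absolute dates.

# Synthetic data: what the generator emulates

`makeStudyFixture()` generates the study design the analysis assumes:

* **A serial-founder chain.** Root allele frequencies are Uniform(0.05,
  0.95); each route population drifts from its predecessor under the
  Balding–Nichols model $p' \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$,
  which has mean $p$ and variance $Fp(1-p)$. Compounding along the chain
  produces the declining-heterozygosity cline. Default: 10 route
  populations at $F = 0.02$ per step — a per-step differentiation in the
  range typical of successive human colonisation bottlenecks.
* **Two colonist sources** drifted directly from the root, default
  $F = 0.12$ each, giving a pairwise $F_{ST}$ near 0.2 between them —
  the magnitude of intercontinental human differentiation.
* **Pulse-admixed populations.** Per-individual ancestry is simulated by a
  finite Monte-Carlo pedigree (default 500 per intermediate generation)
  rather than the infinite-population recursion, so the small-sample and
  shared-ancestry behaviour of the dating estimator is visible in tests.
  Defaults: two "coastal"-like populations (30% colonist-A, 5% colonist-B,
  pulse $g = 3$) and two "interior"-like populations (15%/10%, $g = 2$),
  mirroring a design with two geographically structured admixture
  histories.
* **Block structure.** SNPs inside planted low-recombination runs are drawn
  from block-level haplotype pools (default 12 haplotypes per block whose
  frequencies drift along the chain by a Dirichlet analogue of
  Balding–Nichols resampling); admixed individuals draw each haplotype from
  source $k$ with probability $H_{ik}$. This gives the EM/heterozygosity
  stage non-trivial haplotype diversity, declining diversity along the
  route, and admixture-inflated diversity in hybrids. All other SNPs are
  unlinked.
* **Missingness** is i.i.d. (default 0.2%, within the per-population
  missing-data range typical of array data).

What it does **not** emulate: recombination-aware gamete dropping (no decay
of admixture LD, so weighted-LD dating methods cannot be tested against
it), ascertainment bias of array SNPs, genotyping error, and relatedness
structure beyond the closed pedigree. Passing tests therefore establish the
correctness of each estimator under its own model assumptions — not
robustness to those real-data complications.

One master seed drives everything; per-stage seeds are derived by a stable
string hash (`deriveSeed()`), so fixtures are byte-reproducible without
seed bookkeeping.

# Haplotype blocks and heterozygosity

Inter-SNP recombination rates (`intervalRates()`) are the unweighted mean
of map rates strictly inside each interval between retained SNPs; an
interval containing no map point gets the linear interpolation of the
flanking map rates at the interval midpoint.

`buildBlocks()` forms disjoint blocks of 5–15 contiguous SNPs in which all
inter-SNP rates are below 0.5 cM/Mb. The construction is a greedy
left-to-right maximal tiling: a run extends while the next rate passes and
the run is under 15 SNPs, and is emitted if it has at least 5. Disjoint
tiling was chosen because alternative definitions are explicitly
non-overlapping; the `mode` flag isolates this choice and also provides the
two control definitions (`"above"`: the rate comparison reversed;
`"random"`: disjoint random blocks whose multiset of lengths exactly
matches a reference block set).

Haplotype frequencies within a block are estimated by EM over phase
configurations under Hardy–Weinberg: the E-step weights each compatible
ordered haplotype pair $(h_1, h_2)$ by $f(h_1) f(h_2)$, the M-step
re-counts. Initialisation is the linkage-equilibrium product of single-SNP
frequencies; convergence is a maximum frequency change below $10^{-8}$.
Individuals with any missing call in the block are excluded from that block
(the simplest well-defined contract). The 15-SNP cap bounds the phase
enumeration at $2^{14}$ pairs per individual, so no partition-ligation is
needed. When every individual has at most one heterozygous site the E-step
is deterministic and EM equals direct counting exactly — this is a test
anchor.

Block heterozygosity uses the Nei estimator with the small-sample
correction, $\hat H = \frac{n}{n-1}\bigl(1 - \sum_h \hat p_h^2\bigr)$ with
$n$ the haplotype count; the uncorrected form is available by toggle since
the convention is not universal. Genome-wide summaries average blocks
within each chromosome first, then take the mean and SD across chromosome
means.

**Direction of the block-definition contrast.** On pool-structured data,
below-threshold (high-LD) blocks have *lower* haplotype heterozygosity than
length-matched blocks of effectively unlinked SNPs, because tight linkage
restricts a block to a small haplotype pool while unlinked SNPs approach
the independent-sites maximum. The package's tests assert this ordering.

# Geography and the serial-founder regression

Distances are sums of haversine legs along waypoint routes from the East
African origin (Addis Ababa, 9.03°N 38.74°E) on a sphere of radius 6371 km.
Waypoint coordinates are a shipped fixture (Cairo, Istanbul, Phnom Penh,
Anadyr, Prince Rupert) following the serial-founder literature; the
packaged Americas route reproduces published Pacific-Northwest distances to
within 1%, which is the fixture's validation criterion. The regression of
genome-wide mean haplotype heterozygosity on distance is ordinary least
squares with the two-sided Pearson correlation test; recently admixed or
geographically ambiguous populations are excluded via a table flag.

# Population differentiation

`pairwiseFst()` implements the Weir–Cockerham (1984) $\theta$ with the
variance components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals), combined across loci as the
ratio of sums $\sum a / \sum (a+b+c)$ — the estimator's recommended
multilocus form, not the mean of per-locus ratios. Negative per-locus
components are kept raw before summation, so small negative multilocus
values can occur and are reported unmodified. SNPs are filtered to minor
allele frequency above 5% in the whole sample, and a locus is used only
where both populations have at least two genotyped individuals.

Classical MDS is the Torgerson eigendecomposition of the double-centred
squared-distance matrix (via `stats::cmdscale`), with coordinates scaled by
the root eigenvalues. A negative eigenvalue among the *requested*
dimensions is an error; deeper negative eigenvalues (routine for non-
Euclidean inputs such as $F_{ST}$) are reported via message only. The
configuration's fidelity is the Spearman correlation between its Euclidean
distances and the input dissimilarities.

Trees use Gascuel's variance-weighted BIONJ (`ape::bionj`); negative branch
lengths are clamped to zero with a message. Edge support resamples loci
with replacement — the only resampling unit that regenerates a valid
$F_{ST}$ matrix — recomputes the matrix and tree per replicate, and counts
replicates containing each leaf bipartition of the reference tree
(rotation- and rooting-invariant).

# Individual-level structure

Allele-sharing dissimilarity between two individuals is one minus the mean
per-SNP shared-allele fraction ($1$, $\tfrac12$, $0$ for dosage differences
$0, 1, 2$), over SNPs genotyped in both. Geographic groups for balanced
resampling are built by ordering populations by distance from the origin
and chaining successive populations whose distance gap is below a threshold
$d$; chaining is transitive, so a group may span more than $d$ end to end —
that is the rule as specified, applied literally. Designated special groups
(e.g. the focal indigenous set and known admixed panels) are set aside
first. Each resampling replicate draws up to 82 individuals per group
without replacement (smaller groups are taken whole), and the replicate
with the highest MDS fidelity $\rho$ is reported; ties go to the first
occurrence.

Procrustes alignment centres both configurations and scales them to unit
sum of squares before the optimal translation/rotation/reflection/scaling,
so the minimised squared distance $D$ lies in $[0,1]$ and the similarity
statistic is $t_0 = \sqrt{1 - D}$, with $t_0 = 1$ exactly for similarity
transforms. The normalisation is chosen to make $t_0$ well defined; the
computation is delegated to `vegan::procrustes(symmetric = TRUE)` and
cross-checked in the tests against a brute-force rotation-grid optimum.

The separation statistic $L_0$ is the mean 2-D Euclidean distance over all
between-group pairs. Its null distribution permutes the group labels over
the pooled individuals; the p-value is the plain fraction of permuted
values at or above the observed one (no add-one correction), displayed as
"< 1/n" when zero. Type-I calibration at the 5% level is part of the test
suite.

# Ancestry estimation and modes

Both estimators maximise the binomial admixture likelihood
$\ell = \sum_{i,l} x_{il} \log(QF)_{il} + (2 - x_{il}) \log(1 - (QF)_{il})$
by EM. The supervised estimator fixes the source frequency matrix $F$ and
updates only the membership rows $q_i$ on the simplex; the unsupervised
estimator updates $Q$ and $F$ jointly from a random Dirichlet/Uniform
initialisation. Termination is a log-likelihood increase below $10^{-4}$
(the conventional termination for this likelihood); the EM is monotone, and
no acceleration scheme is used. Frequencies are clamped to
$[1/(2n), 1 - 1/(2n)]$ to keep fixed alleles off the log singularities.
Missing genotypes drop out of both sums exactly. LD-pruned input
(`ldPrune()`, 50-SNP windows advanced by 10 at $r^2 \le 0.1$, computed as
squared Pearson correlation of dosages over pairwise-complete individuals)
is recommended for the unsupervised fit; the pruner iterates full windowed
passes to a fixed point so the returned panel provably contains no
within-window pair above the threshold, removing the more-missing member of
each offending pair (ties to the later column).

Replicate runs are compared by the symmetric similarity coefficient
$\mathrm{SSC} = \max_\Pi \bigl(1 - \lVert Q_1 - Q_2\Pi \rVert_F / \sqrt{2n}\bigr)$,
which is 1 exactly on agreement up to cluster relabelling. Because the
Frobenius objective reduces to a linear assignment over column
cross-products, the optimal permutation is found exactly (bitmask dynamic
programming, feasible to $K = 20$). Runs are grouped into modes by
single-linkage on SSC > 0.9; within a mode, runs are aligned to the mode's
first run and averaged, with rows renormalised to absorb floating-point
drift.

# Input handling

PED/MAP text files are parsed with dosage coded as the count of the
lexicographically larger observed allele (the data provide no orientation,
so the convention is explicit and overridable). `"0 0"` is missing;
half-missing genotypes, malformed lines and more than two alleles at a SNP
are errors naming the line or SNP. Merging restricts to the intersection of
SNP identifiers, complement-flips the second dataset where its allele pair
is strand-complementary to the first, re-orients dosages where the allele
labels are swapped, drops irreconcilable SNPs with a warning count, and
keeps strand-ambiguous A/T and C/G SNPs under a same-strand assumption by
default (a flag drops them) — ambiguous sites cannot be resolved from
genotypes alone. QC removes SNPs by missingness (default cap 10%),
monomorphism, optional MAF floor and an optional per-population two-sided
exact Hardy–Weinberg test (off by default, matching a workflow where HWE
filtering is applied to reference panels rather than newly typed samples);
each removed SNP is attributed to the first filter it fails so the report
sums exactly.

# Problem sizes in the test suite

The suite validates every stage at desk scale: oracle equivalence on
20-SNP instances; $F_{ST}$ calibration at $n = 50$ per population and
$L = 10{,}000$; the serial-founder recovery on 100 independent
10-population fixtures (12 individuals per population, twelve 5-SNP
blocks); L0 type-I calibration over 1000 simulations of 200 permutations;
dating recovery at $n = 1000$ over 100 replicates per pulse age; and
ancestry recovery at $L = 5000$. These sizes were chosen so the full suite
runs in a few minutes while keeping Monte-Carlo bands tight enough to
detect implementation errors.

# Known limitations

* The dating model assumes one pulse followed by closed random mating;
  continuous migration or multiple pulses bias $\hat g$ in ways the model
  cannot see. Weighted-LD dating is out of scope.
* Bootstrap support resamples loci, treating them as exchangeable;
  chromosome-level block bootstraps are not implemented.
* The unsupervised EM is unaccelerated; at very large $n \times L$ it is
  slower than production ancestry software, though it optimises the same
  likelihood with the same termination rule.
* `asdMatrix()` materialises dense cross-product matrices; it is intended
  for thousands, not hundreds of thousands, of individuals.
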