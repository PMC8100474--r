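---
title: "Models and methods behind herdchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herdchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

herdchar characterizes labelled diploid populations from biallelic
SNP-array genotypes. This vignette records the statistical models the
package implements, the assumptions they carry, the defaults and why they
were chosen, and the places where a genuine design choice had to be made.

## The data model

Everything operates on a `genotype_dataset`: a samples × SNPs matrix of
minor-allele dosages in {0, 1, 2} with `NA` as the single reserved
missing-call sentinel, a SNP map sorted by (chromosome, position, 1-based
bp), and per-sample population labels. Dosage orientation is fixed once at
load time from the pooled frequency over all samples (ties keep the
declared allele order; the text dialect orders alleles alphabetically
first, so ties are deterministic). Per-population frequencies downstream
inherit that orientation, which keeps pairwise and global estimators
consistent with each other. Every estimator handles missingness
complete-case per locus (or pairwise per locus pair for LD); nothing is
imputed except in PCA, where mean imputation is the standard array
practice.

Non-autosomal markers are dropped at load with a warning: all estimators
here assume autosomal diploidy (Hardy–Weinberg machinery, 2n allele
copies per locus).

## Quality control and pruning

SNP call-rate filtering runs before sample call-rate filtering; the order
matters with patterned missingness and is fixed for determinism. Both
thresholds default to 0.95.

LD pruning is greedy and windowed (defaults 50 SNPs, step 5): within a
window, while any retained pair exceeds the r² threshold, the member of
the worst pair with the lower pooled MAF is dropped (tie: later map
position). The r² threshold defaults to 0.2, the community default for
array pruning; a threshold above 1 is rejected as impossible for a squared
correlation. Pruning r² is the composite (genotypic) correlation — fast
and the conventional choice for pruning, distinct from the EM haplotype r²
used for demography below.

## Diversity

Per population: H_O is the heterozygote fraction among non-missing calls;
H_E uses the small-sample-unbiased form (2n/(2n−1))·2p̂(1−p̂) because breed
panels are often small (n = 10 in the bundled cohort); plain 2p̂(1−p̂) is
available by flag. Means and SDs are taken **across SNPs** (the
alternative, across individuals, is not what genome-wide diversity tables
conventionally report); loci monomorphic within the population contribute
zeros rather than being dropped, preserving genome-wide-mean semantics,
while loci with no calls in a population are excluded and counted.

F_IS is the Weir–Cockerham within-population f — the ratio of summed b and
c components over loci — rather than 1 − H̄_O/H̄_E. The two agree on large
panmictic samples (a property test asserts this), but the
variance-component form is the one that matches the negative values small
heterozygote excesses produce, and it is what the established diversity
packages report. The simple form is exposed alongside as `fis_simple`.

## F-statistics

Per-locus a/b/c are the 1984 method-of-moments variance components; the
test-suite checks them against an independent brute-force nested ANOVA on
allele copies. Multi-locus combining is ratio-of-sums (Σa/Σ(a+b+c), etc.),
not mean-of-ratios: it is stable for low-information loci and makes
Wright's identity (1−F_IT) = (1−F_IS)(1−F_ST) hold exactly by
construction. Loci monomorphic overall contribute (0,0,0) and drop out of
the sums harmlessly.

Bootstrap CIs resample loci with replacement (the locus is the natural
exchangeable unit for genome-wide summaries). Permutation schemes differ
per statistic: F_ST permutes population labels of whole individuals
(upper-tail p); F_IS re-pairs allele copies at random within populations
(two-sided on |f|, since both heterozygote deficit and excess are
departures). These follow the conventions of the standard F-statistics
software.

## AMOVA

Three levels from unphased genotypes using allele-copy (gametic) coding
with simple mismatch distance: for 0/1 copies the distance-based sums of
squares coincide with ANOVA sums of squares of the allele indicator, so
the implementation accumulates per-locus SS and df (complete-case per
locus) and solves the standard expected-mean-square equations. The
among-population coefficient is the usual unequal-size n_c on the
allele-copy scale; with missing data it is averaged across loci weighted
by degrees of freedom — exact for complete data, a mild approximation
otherwise. Negative intermediate components are reported as computed
(heterozygote excess legitimately produces them), and percentages are
computed from a common total so they sum to 100 exactly. The within-
individual level is phase-free (it depends only on heterozygosity), which
is why array data suffice. A locus-by-locus AMOVA variant (components per
locus, then averaged) exists in the literature; the summed-SS variant was
chosen as the standard default.

## Distances and trees

The printed D_A formula in parts of the literature omits the square root;
the package implements the Nei et al. (1983) form with √(x_ij·y_ij), which
is the quantity the standard tree-building tools compute and the only form
satisfying D_A(x,x) = 0. Loci undefined in either population are dropped
from the locus count r. An optional small-sample bias correction is left
off by default: with thousands of SNPs it is negligible, and leaving the
estimator in its plain form keeps distances comparable across subsets.

Neighbor-joining is implemented directly so tie-breaking can be pinned:
among minimal-Q pairs the lexicographically lowest label pair is joined
(internal nodes carry the smallest leaf label of their clade), making the
topology a deterministic function of the matrix. NJ branch lengths can be
slightly negative; raw values are kept in the tree object and
`write_newick(clamp_negative = TRUE)` clamps for display only. Bootstrap
supports resample loci, rebuild the tree, and count bipartitions of the
point tree; supports are attached as integer percent node labels, the
convention downstream viewers understand.

## PCA and admixture

Individual PCA mean-centres each SNP and scales by √(p̂(1−p̂)) — the
eigenanalysis scaling under genetic drift — then takes the SVD; explained
fractions are squared singular values over their total. A population-level
PCA on allele frequencies is also provided: breed-level structure
questions are sometimes asked at that level, and with a handful of breeds
a few PCs then genuinely exhaust the variance, which individual-level PCA
on hundreds of animals cannot do.

Admixture is the binomial mixture likelihood maximized by plain EM. EM
(rather than quasi-Newton acceleration) was chosen because its monotone
likelihood is easy to verify — the test-suite asserts non-decrease at
every iteration — and it reaches the same optimum family, just in more
iterations. Defaults: tol 1e-6 on the log-likelihood gain, max_iter 2000,
F clipped to [1e-6, 1−1e-6] each step, Q rows renormalized every
iteration. Starts are seeded random (Q from a flat Dirichlet, F as pooled
frequencies plus uniform noise); clusters are identifiable only up to
permutation, and `match_clusters()` aligns labels by exhaustive search for
comparison purposes.

Cross-validation masks random **entries** (not whole individuals),
mirroring the masking scheme of the standard admixture software, scores
masked entries by squared deviation from the predicted dosage 2·Σ_k
q_ik·f_kj, and averages over folds. The supported K is the error minimum;
in weakly structured data the curve flattens rather than dips, and the
analysis scripts report it that way. K selection is treated as
data-dependent — no attempt is made to privilege any particular K.

## LD and historical N_e

Pair r² uses maximum-likelihood haplotype frequencies from unphased
genotypes: only the double heterozygote is phase-ambiguous, and EM from
the linkage-equilibrium start (deterministic initialization) resolves it;
non-convergence after 1000 iterations returns the last iterate flagged.
On phase-unambiguous data this r² equals the squared dosage correlation (a
test asserts it). The composite correlation is available as a cheaper
alternative.

The decay summary uses the fixed 20-bin ladder — [0,1) kb, ten-kb steps to
100 kb, hundred-kb steps to 1 Mb, half-open bins with the last closed.
For N_e the default binning is different: 20 log-spaced bins between 10 kb
and 4 Mb, so that both recent horizons (long distances, large c) and older
horizons are covered; the 10–100 kb phrasing common in the applied
literature is ambiguous between bin width and range, and the log-spaced
reading is declared and configurable rather than silently assumed.

Physical distance maps to recombination fraction at a configurable
1 cM/Mb (the standard default when no genetic map is given); the time
horizon is t = 1/(2c) rounded to integer generations; the sample-size
adjustment is r²_adj = r² − 1/(2n) (the phased-data correction, matching
the EM-phased r²; the 1/n unphased variant is a documented alternative);
and N(t) = (4f(c))⁻¹(1/r²_adj − α) with Sved's f(c) = c(1−c/2)/(1−c)².
The mutation-correction constant α defaults to 2.2, the largest of the
three conventional values (1, 2, 2.2), all selectable. Bins whose
adjusted r² would imply a negative size (1/r²_adj ≤ α) are dropped with a
warning rather than reported.

## The simulators, and what passing tests do and do not show

`simulate_balding_nichols` draws per-population frequencies from
Beta(p(1−F)/F, (1−p)(1−F)/F), so the target F **is** the Weir–Cockerham
estimand and recovery tests have a closed-form truth. It emulates drift
from a shared ancestral pool with Hardy–Weinberg equilibrium within
populations; it does not emulate ascertainment bias of array panels,
linkage between loci, or migration.

`simulate_wright_fisher` is a forward simulation — chosen over coalescent
machinery because an arbitrary step N_e trajectory can be imposed directly
— with Poisson crossovers, random mating, optional symmetric mutation
(default 0) and polymorphism ascertainment at sampling time. It generates
real linkage and real drift, so LD-based N_e recovery is a genuine
end-to-end test; it does not model overlapping generations, selection, or
sex chromosomes.

`simulate_admixed` draws each allele copy's source from the individual's
Q row; `inject_inbreeding` replaces genotypes with correlated-allele
homozygotes at rate f, leaving expected allele frequencies unchanged.

Recovery tests therefore demonstrate estimator correctness under the
stated generative models at the stated scales — they do not certify
behavior under array ascertainment, genotyping error, or real livestock
demography. Problem sizes in the test-suite (e.g. 4 populations × 50 at
5,000 loci for θ recovery; 200 × 10,000 for admixture recovery; N_e = 100
with 700 loci on 50 Mb for demography) were chosen as the smallest scales
at which the estimators' sampling noise is comfortably inside the asserted
tolerances.

## Known limitations

- Biallelic autosomal SNPs only; no haplotype-based statistics (D′ is
  deliberately absent), no temporal or pedigree N_e.
- The AMOVA hierarchy is fixed at three levels.
- Admixture assumes unlinked loci; applying it to unpruned dense data
  inflates confidence in Q.
- The LD-based N_e estimator inherits the usual caveats: horizons far
  beyond the simulated (or real) equilibration time are biased, and the
  physical-to-genetic map is only as good as the assumed cM/Mb.
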