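---
title: "Genetic matching and matched trend tests for stratified case-control samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic matching and matched trend tests for stratified case-control samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratmatch)
```

## The problem

Case-control association scans compare allele frequencies between affected
and unaffected individuals. When the sample mixes latent subpopulations whose
allele frequencies *and* case/control sampling proportions both vary --
population stratification -- the naive Cochran-Armitage trend (CAT) test is
confounded: its statistic is inflated genome-wide and false-positive rates
can be several times the nominal level. stratmatch addresses this by
*matching*: it pairs or groups each case with genetically similar controls
using an identity-by-state (IBS) similarity score, validates that the matches
respect the latent strata, and then tests association with trend statistics
that are computed *within* the matched units and aggregated across them.
Matching is attractive precisely where covariate modelling is awkward: the
resulting tests are permutation-exact given the structure, and the structure
can be rebuilt locally (e.g. per genomic window) without re-fitting a model.

## Similarity, matching, and validation

**IBS score.** For individuals $i, j$ with dosage genotypes
$g_{ik} \in \{0,1,2\}$,
$$ s_{ij} \;=\; 1 - \frac{1}{2N}\sum_{k=1}^{N} \lvert g_{ik}-g_{jk}\rvert, $$
with $N$ the number of loci genotyped in both. Scores live in $[0,1]$.
Genotypes are stored two-bit-packed in three bitplanes ($g\ge 1$, $g = 2$,
missing), so the inner sum is two XOR-popcounts per 64 loci; the packed
kernel reproduces the naive double loop exactly (this is tested). Optional
nonnegative locus weights generalise both the sum and $2N$; the default is
unweighted, as no canonical weighting formula is fixed here.

**Optimal pairs.** With cases $A$ and controls $O$, matching is the
maximum-weight assignment on the $|A|\times|O|$ score matrix, balanced by
zero-weight sinks on the smaller side; sink-matched individuals are removed,
leaving $\min(|O|,|A|)$ pairs. The solver is an $O(n^3)$
shortest-augmenting-path implementation with dual potentials, verified
against brute-force enumeration on small instances. Ties among equally
optimal assignments are broken arbitrarily; nothing downstream depends on
which optimum is returned.

**Stratum validation.** An optimal matching can still contain poor pairs
when strata are asymmetric. Two validation strategies are provided:

* *Intra-cluster*: matching is run separately inside each cluster of a
  (model-free) clustering, which enforces same-stratum pairs by
  construction.
* *Vicinity check*: for a pair $(x, y)$ let $t_x$ be the number of controls
  strictly more similar to $x$ than $y$, and $t_y$ symmetrically. The pair
  is kept iff $(t_x < T_{cc} \wedge t_y < T_{cc}) \vee t_x = 0 \vee t_y = 0$
  with $T_{cc} = \ln(|O||A|)$. Counts always range over the *full* original
  case and control sets, also in later re-matching rounds: the criterion is
  defined sample-wide, and shrinking the reference pool would make the
  threshold's meaning drift as the pool empties. Ties do not count as
  better mates (strict inequality).

**Groups.** To avoid discarding the surplus side, groupwise matching
re-matches unmatched controls to already-matched cases (and vice versa) in
rounds; each *new* edge is validated individually -- with the same
full-sample $T_{cc}$, or by the same-cluster requirement, under which
re-matching is confined within clusters -- and a validated newcomer joins
its partner's existing unit (units never merge with each other). Only new
edges are re-validated, not whole groups: the group's earlier edges have
already passed, and re-validating them against a changing membership would
make acceptance order-dependent. The loop stops when everyone is matched or
a full round adds no one; since every round either adds a member or
terminates, at most $|O|+|A|$ rounds occur. Individuals still unmatched are
excluded from testing.

## Clustering

`hungarian_cluster()` reconstructs an agglomerative clustering whose level
step is the assignment solver: current clusters are paired with their most
similar distinct counterparts (self-pairing is forbidden via a $-\infty$
diagonal; all mutual-nearest-neighbour pairs are added to the proposal set,
because the globally optimal assignment need not contain them once a stratum
has fragmented into many chunks). Cluster-cluster similarity is average
linkage over member IBS. A proposed merge must pass:

1. a *vicinity* gate -- fewer than `t_all` (default $\ln n$) other clusters
   may be strictly more similar to either endpoint;
2. a *homogeneity* gate, active once both endpoints have at least
   `size_gate` (default 8) members -- the cross-cluster mean similarity may
   not fall more than `z_merge` (default 4) standard errors below the less
   homogeneous endpoint's within mean, with the per-pair variance pooled
   over current within-cluster residuals. Because a straggler chunk consists
   of atypical members of its stratum, a strict z-gate would strand it; an
   edge whose smaller endpoint is at most a third of the larger may instead
   pass a *relative* test: its similarity must sit more than halfway from
   the background level (best other sizeable cluster) up to the large
   cluster's within level. A final absorption pass applies the same rescue
   to leftover clusters below `size_gate`.

The procedure is deterministic, terminates when no merge is accepted, and
returns the emergent number of clusters. Design note: the exact original
formulation of the agglomeration this reconstructs is not fully specified in
the accessible literature; the implementation above is a faithful-behaviour
reconstruction (the vicinity-count family for merge validation, assignment
as the level engine) and is flagged as such. Its parameters are exposed, and
the validation strategies accept any alternative clustering via plain label
vectors, so the matching layer is independent of this choice. Strata smaller
than `size_gate` are below the method's resolution. On five-stratum
Balding-Nichols data at $F_{ST} = 0.1$ with 5,000 SNPs the true strata are
recovered (count and membership) in roughly nine of ten replicates; the
residual failure mode is a wrong small-chunk merge early in the hierarchy,
which the later gates cannot undo -- agglomeration never splits.

## Matched trend tests

For one SNP and one unit, the $2\times 3$ control/case by genotype table
(columns: reference homozygote, heterozygote, risk homozygote) gives the
classical co-dominant trend statistics
$$ X_{T^2} = \frac{N}{n_{co}\,n_{ca}}\,\frac{U^2}{D}, \qquad
   X_U = \sqrt{\frac{N-1}{n_{co}\,n_{ca}}}\,\frac{U}{\sqrt{D}}, $$
with $U = n_{co}(n_{22}+2n_{23}) - n_{ca}(n_{12}+2n_{13})$ and
$D = N(n_{\star 2}+4n_{\star 3}) - (n_{\star 2}+2n_{\star 3})^2$. The
$\sqrt{(N-1)/N}$ factor makes $\mathrm{Var}(X_U) = 1$ *exactly* under the
within-table permutation (multivariate hypergeometric) null -- the test
suite verifies mean 0 / variance 1 by full enumeration for $N \le 8$ -- so
summing over $M$ units gives the linear matched statistic
$$ Y_U = \sum_{i=1}^{M} X_U^{(i)} \;\sim\; \mathcal N(0, M) $$
asymptotically (MCAT1, default asymptotic inference). The squared matched
statistic weights each unit's $X_{T^2}$ by the direction of its
case-control allele-frequency difference,
$$ Y_{T^2} = \Bigl|\sum_{i=1}^{M} \mathrm{sgn}\bigl(f_{ca}^{(i)} -
   f_{co}^{(i)}\bigr)\, X_{T^2}^{(i)} \Bigr| $$
(MCAT2); it has no chi-squared law and is calibrated by permutation.
Conventions chosen where the definitions leave room: $\mathrm{sgn}(0) = 0$
(a unit with equal case and control allele frequencies contributes nothing,
but counts towards $M$); units whose table is monomorphic or one-sided at a
SNP are skipped and do *not* increment $M$, which keeps
$\mathrm{Var}(Y_U) = M$ exact; a SNP with no usable unit is reported
untestable rather than $p = 1$. With pair units $X_U$ degenerates to
$\pm 1$, so $Y_U/\sqrt M$ lives on a lattice of spacing $2/\sqrt M$ and its
normal approximation saturates at a Kolmogorov distance of roughly
$\sqrt{2/(\pi M)}/2$ (about 0.028 at $M = 200$); the near-normality check in
the test suite therefore uses group units of eight, where the statistic is
quasi-continuous, and relies on the exact enumeration results for pairs.

## Inference

*Permutation.* Case/control labels are permuted independently within every
unit, preserving each unit's label counts; one relabeling per cycle is
shared by all SNPs, which is what makes the minP adjustment valid. The
default P-value estimator is add-one, $(b+1)/(B+1)$, which cannot be zero;
the plain fraction $b/B$ is available as a mode. Extremeness is one-sided on
the statistic's magnitude. The permutation engine is single-threaded C++
driven by R's RNG, so results depend only on the seed. For small problems an
exhaustive mode enumerates all distinct within-unit relabelings.

*minP.* The single-step minP adjustment pools the observed statistics with
the $B$ permuted rows as a $(B{+}1)$-th resample, converts every row to
rank-wise P-values within each SNP's own pooled null, and reports for each
SNP the fraction of rows whose minimum P-value across SNPs is at most the
SNP's raw P-value. Exchangeability of the pooled rows gives finite-sample
familywise-error control at any $B$; the cost is conservatism unless
$B \gg S/\alpha$. The plain-fraction variant (observed excluded from its own
null) is kept as a mode and is measurably anticonservative at small $B$.

*Genomic control.* $\lambda$ = median of the test statistics divided by the
$\chi^2_1$ median, computed with the exact constant
`qchisq(0.5, 1)` $= 0.4549364$ (0.456 to display precision). P-value input
is first mapped through the upper-tail $\chi^2_1$ quantile; for MCAT1 the
squared standardised statistic $Y_U^2/M$ is used so that all tests share one
$\lambda$ definition. Correction maps $p \mapsto
Q_{\chi^2_1}\!\bigl(Q^{-1}_{\chi^2_1}(p)/\lambda\bigr)$.

*Benchmark arm.* Classical Torgerson scaling of $d = 1 - s$ (coordinates =
eigenvectors scaled by the root eigenvalue) supplies ancestry covariates for
a logistic-regression likelihood-ratio test per SNP (IRLS, tolerance
$10^{-8}$, 50 iterations; separation flagged via $|\beta| > 20$ and
reported as a missing P-value rather than a number).

## The synthetic-data generator

The simulator emulates a stratified multi-population study without any
external data. Stratum allele frequencies follow the Balding-Nichols model:
ancestral frequencies $p \sim U(0.05, 0.5)$, stratum frequencies
$\mathrm{Beta}\bigl(p(1-F)/F,\,(1-p)(1-F)/F\bigr)$, so the divergence
parameter $F$ is the expected $F_{ST}$ (the realized Weir-Cockerham
estimate recovers it within 10% at 5,000 SNPs -- tested). Haplotypes come
from a first-order Markov chain whose transitions realise a target
adjacent-locus allele correlation (pairwise LD; infeasible combinations are
clipped with a warning); genotypes are sums of two haplotypes, so
Hardy-Weinberg holds within strata. SNPs monomorphic in any stratum are
removed. What this does **not** capture: higher-order LD, admixed
individuals, genotyping error and missingness patterns of real arrays --
so passing calibration here demonstrates correctness of the statistics
under the stated model, not robustness to every artefact of real data.

Null studies assign labels independently of genotype within each stratum;
stratification arises purely from merging strata with asymmetric
case/control counts. Alternative studies plant one causal SNP with
multiplicative penetrances $f_g = f_0\,\mathrm{RR}^g$ (default
$\mathrm{RR} = 1.5$), the baseline anchored so each stratum's prevalence
equals a configurable value (default 0.1 -- prevalence is a free design
choice here, not dictated by the emulated studies). Case and control
genotypes at the causal SNP are drawn from the exact conditional
distributions $P(g\,|\,\text{case}) \propto \mathrm{HWE}(q)\,\mathrm{RR}^g$
and $P(g\,|\,\text{control}) \propto \mathrm{HWE}(q)(1-f_0\mathrm{RR}^g)$
-- distributionally identical to per-individual penetrance rejection but
without its failure modes, which are still guarded
($f_0\,\mathrm{RR}^2 > 1$ errors out). The matching panel is simulated
independently of the causal SNP, realising the design rule that matching
SNPs keep a wide, LD-free gap from the analysed SNP.

Two frozen designs ship with the package. `table2_design()` is the
14-stratum benchmark: 1,845 individuals (967 controls, 878 cases) spread
over 14 ancestries with strongly asymmetric sampling. `default_design()` is
the scaled-down profile used by the package's own experiments and tests:
5 strata, 400 individuals (controls 70/20/55/25/30 against cases
35/40/25/50/50 -- the same over/under-sampling character), 2,000 SNPs,
$F = 0.05$, adjacent-locus LD 0.2, $B = 999$ permutation cycles. These
problem sizes keep a full ten-replicate calibration run in the minutes
range on one core while leaving all calibration quantities
($\lambda \approx 1$, $f_p \approx \alpha$) interpretable; they are the
package's reference study conditions, and the clustering-recovery check
uses $F = 0.1$ with 5,000 SNPs (matching-score panels of several thousand
common variants are realistic practice).

## Calibration and power experiments

`run_h0_experiment()` simulates replicate null studies and reports, per
method, the mean and standard error of $\lambda$ and of the false-positive
rate at $\alpha = 0.05$. Expected behaviour, which the acceptance suite
checks quantitatively: the naive CAT test is strongly inflated
($\lambda$ well above 1.3); MCAT1/MCAT2 on true-stratum cluster units and
MCAT2 on groupwise matchings are calibrated ($\lambda \approx 1$,
$f_p \approx 0.05$), as is logistic regression with the true number of MDS
components; pairwise-matched tests are *deflated* ($\lambda < 1$) because
pair matching discards the least matchable individuals and over-matches the
rest -- the known cost of pair designs. Vicinity validation is the more
stringent of the two strategies and retains at most as many pairs as
cluster validation. `run_power_experiment()` plants one causal SNP per
dataset, rebuilds the matching from the dataset's own panel, applies
genomic control with the H0-run inflation factors, and reports power at
nominal levels; structured tests dominate the naive CAT after correction,
and groupwise matching dominates pairwise because it keeps the whole
sample. One caveat discovered during calibration: on panels of a few
thousand SNPs, the H0 inflation factor of the *pairwise* arms is dominated
by matching-selection on the tested SNPs themselves (matched pairs are
selected to agree at exactly those loci, deflating the shared-panel
lambda to ~0.7), and this lambda does not transfer to a causal SNP that is
disjoint from the matching panel (whose matched-pair null is nearly
calibrated). Rescaling the power-study p-values by the shared-panel lambda
therefore artificially boosts the pairwise arms at this scale -- on
genome-wide panels of tens of thousands of SNPs the per-SNP selection
effect vanishes and the transfer is sound. The package's own power checks
read the groupwise-versus-pairwise ordering off the uncorrected p-values
for this reason. Within-unit permutation of the calibration experiments uses the
plain-fraction estimator (matching how such resampling benchmarks are
conventionally scored); everything else defaults to add-one.

## Numerical and degenerate-input choices

Similarity of a pair with no jointly genotyped locus is an error by default
(score 0 on request, with a warning). Monomorphic tables make the trend
denominators vanish and are treated as stated above. The assignment solver
requires finite weights; the clustering shifts similarities before solving
so the $-\infty$ diagonal never reaches it. PED phenotype codes other than
1/2 become missing phenotypes with a warning; the minor allele is
re-determined from the sample at load time, with ties broken toward the
lexicographically larger letter, so a written-then-reread study keeps its
coding whenever the coded allele is the rarer one. Permutation streams are
driven entirely by R's RNG: `set.seed()` makes every experiment, including
the C++ engine, bit-reproducible. There is no parallel mode; invariance of
results to the degree of parallelism is therefore trivial.

## Worked example

```{r example, eval = FALSE}
design <- default_design(S = 1000)
study <- sample_h0_study(design, seed = 1)
sim <- ibs_matrix(study$genotypes)
clusters <- hungarian_cluster(sim)
units <- match_groups(sim, study$phenotype, "cluster", clusters = clusters)
scan <- mcat_scan(study$genotypes, study$phenotype, units, "mcat2", B = 999)
inflation_factor(scan$p_perm, input = "pvalue")
```

## Known limitations

Pair matching forfeits information and deflates the null -- use it only
when a paired design is explicitly wanted. The clustering reconstruction
cannot resolve strata below `size_gate` members and, like all
agglomerative schemes, cannot undo an early wrong merge. MCAT2 needs
permutation (no asymptotic law), so its cost scales with $B \times S$.
The simulator's first-order LD is a deliberate simplification; analyses
that depend on long-range haplotype structure need real data. minP at
small $B$ is conservative by construction. Dominant/recessive score
vectors and covariate-adjusted trend tests are out of scope.
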