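---
title: "Quantifying, evolving, and decomposing a ribozyme neutral network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying, evolving, and decomposing a ribozyme neutral network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboneutral)
```

## The system and the measurement model

`riboneutral` analyses the fitness landscape of the 35-nt catalytic core
of a small RNA ligase ribozyme. The measurement is a pooled ligation
assay read out by deep sequencing: each variant's ligated and unligated
molecules are separated, barcoded, and sequenced, and the **fraction
ligated**

$$\mathrm{FL} = \frac{N_\mathrm{ligated}}{N_\mathrm{ligated} + N_\mathrm{unligated}}$$

is converted to **relative activity** $\mathrm{RA} = \mathrm{FL}/\mathrm{FL_{WT}}$
against the wild type carried in every pool. Variants with
$\mathrm{RA} \ge 0.2$ are called *neutral*; the threshold reflects the
reproducibility limit of duplicate measurements (the duplicate standard
deviation is below 0.2 for the large majority of variants) and the
premise that, for a catalyst embedded in a larger replicating system,
activity above a floor is selectively equivalent.

The read-level filters mirror the assay's error model: exact barcode
match at the read start, exact constant flanks around the variable core,
at most `max_low_quality_bases` base calls below quality score 20 inside
the core (0 strictly, 1 for the very large libraries), and a minimum
total read count per replicate (30 for the largest library, 100
otherwise) below which a variant is discarded. Replicates are paired by
file; the duplicate RA standard deviation uses the population convention
(divisor $n$), which for $n = 2$ equals $|RA_1 - RA_2|/2$ — the choice
only rescales and is fixed here for definiteness.

## In silico genetic operators

Generations of variants are designed computationally from measured
populations:

* **Tournament selection** (`tournament_select()`) repeatedly samples a
  fixed-size subset and keeps the highest-RA contestant; winners leave
  the pool, losers return. Ties break uniformly at random.
* **One-point crossover** (`one_point_crossover()`) cuts at a uniform
  interior position (cuts at the sequence ends are excluded so both
  children are true recombinants) and returns one child at random.
* **Point mutation** (`mutate_genotype()`) substitutes each position
  independently with probability 1/35 to a uniformly chosen different
  base — one substitution per call on average for the 35-nt core. The
  operator may return its input unchanged; novelty is enforced by
  deduplication downstream, not by forcing a substitution.

Two generation designers are provided. `design_generation_v1()`
recombines two random parents and immediately mutates the child
(the strategy of the early generations); `design_generation_v2()`
builds a set of pure recombinants first and then a smaller set of point
mutants drawn from parents and recombinants (the strategy from
generation 6 onward, which empirically yields far more neutral
offspring, recombination of neutral parents being much safer than random
substitution). Both deduplicate against the full experimental history —
each designed generation contains only never-assayed sequences — and
then overwrite a few random slots with control genotypes (the wild type
is carried in every generation, which is also what anchors RA = 1).

## Neutrality classifiers

Five classifier families predict neutral/deleterious from one-hot
encoded sequences (position-major, bases in A,C,G,U order; 140 features
for the 35-nt core): logistic regression, k-nearest neighbours, linear
SVM, gradient-boosted trees, and a multilayer perceptron. The MLP is
implemented in this package directly on R matrices: dense layers of
128/64/32 units, each with batch normalisation, ReLU, and 20% dropout,
a sigmoid output, binary cross-entropy loss, and Adam at learning rate
0.005 (100 epochs, batch 1024 by default). At these layer sizes
BLAS-backed matrix products train in seconds, and keeping the
implementation in-package pins its behaviour exactly.

"Default" hyperparameters are pinned to explicit values
(`model_spec()`): k = 5; ridge-regularised logistic regression at
`lambda = 1e-4` (near the unpenalised fit); SVM cost 1; tree depth 10
with 100 boosting rounds at learning rate 0.1. Class imbalance is
handled only by tuning the decision threshold on the ROC curve of a
validation split (10% of the training rows): `tune_threshold_roc()`
maximises the geometric mean $\sqrt{\mathrm{TPR}(1-\mathrm{FPR})}$,
ties resolving to the lowest threshold. Reported metrics are precision,
recall, accuracy, F1, and the null accuracy (majority-class fraction),
all derived from confusion counts.

## The classifier-guided loop

`run_guided_evolution()` runs the fully in silico final stage: each
round selects parents by *guided* tournaments (uniform choice among
predicted-neutral contestants; uniform among all when none is predicted
neutral), generates offspring (80% pure recombinants, 20% point mutants
by default), classifies them, and keeps the predicted-neutral offspring
as the next round's population. The final round generates a large
candidate pool and returns only the predicted-neutral variants; the mean
Hamming distance from the reference is tracked every round.

Two design choices deserve note. First, intermediate rounds filter to
predicted-neutral by default (`filter_each_round = FALSE` defers
filtering to the final round), consistent with returning a final
population that is entirely predicted neutral. Second, offspring
deduplication defaults to within-round scope (`dedup_scope = "round"`).
On the small synthetic subspaces used for testing (a few thousand
genotypes), forbidding every sequence ever generated in earlier rounds
exhausts the neutral set within a few rounds and stalls the loop;
`dedup_scope = "history"` restores the stricter behaviour for large
sequence spaces where exhaustion is not a concern. When novelty cannot
be satisfied within the attempt cap, the requirement is relaxed rather
than erroring, so the loop cannot stall on small spaces.

## Epistasis analysis

Activities are analysed in log space; RA values are clamped below at
$\varepsilon = 10^{-3}$ before taking logarithms (`log_ra()`), since
exact zeros are artifacts of finite sequencing depth. The clamp is
configurable.

* **Log-additive expectation** (`expected_ra_log_additive()`):
  $\ln \mathrm{expRA}_g = \sum_i \ln(M_i)\,\gamma_i$ over the variant's
  constituent single mutants — the epistasis-free null model.
* **Directional epistasis** (`fit_directional_epistasis()`): the decay
  of the neutral fraction with mutation count is fitted to
  $\omega(n) = e^{-\alpha n^\beta}$ by nonlinear least squares
  (Levenberg–Marquardt, starting values $\alpha = 0.5$, $\beta = 1$,
  positivity bounds). $\alpha$ measures robustness decay; $\beta > 1$
  indicates an excess of negative epistasis, $\beta < 1$ positive,
  $\beta = 1$ balance or no epistasis. Distance classes 1–3 are fitted
  by default, matching single/double/triple mutant screens.
* **Reciprocal sign epistasis** (`classify_reciprocal_sign()`,
  `reciprocal_sign_census()`, `enumerate_square_pairs()`): a
  distance-2 pair shows reciprocal sign epistasis when both endpoints
  are strictly above, or both strictly below, both intermediates. The
  census is vectorised over all $2^N \binom{N}{2}/2$ pairs of a
  complete binary landscape (3,932,160 at $N = 16$) and tolerates
  missing genotypes; the sequence-space enumeration is retained as an
  independent route and cross-checked exactly in the tests.
* **Walsh–Hadamard decomposition** (`wh_decompose()`): with genotypes of
  a complete biallelic landscape indexed by the integer value of their
  bit vector (locus 1 = least significant bit; wild allele = 0), the
  ln(RA) vector $w$ maps to single-reference epistatic terms
  $e_\mathrm{rel} = Gw$ and to background-averaged terms
  $e_\mathrm{avg} = VHw$, where $G$, $H$, $V$ follow the standard
  recursions ($G_{n+1} = \bigl(\begin{smallmatrix}G_n & 0\\ -G_n &
  G_n\end{smallmatrix}\bigr)$, $H$ the Hadamard matrix, $V$ the
  diagonal weighting $\mathrm{diag}\,(1/2, -1)^{\otimes N}$). All
  transforms are computed by in-place butterfly passes in
  $O(N 2^N)$; the dense recursive matrices (`build_epistasis_matrices()`,
  capped at $N = 12$) serve only as the brute-force oracle in tests.
  The interaction order of term $i$ is the popcount of $i$; order $k$
  carries $\binom{N}{k}$ terms. Because the bit encoding fixes wild = 0,
  the signs of odd-order background-averaged terms are
  encoding-dependent; the $-V_n$ block convention is taken exactly as
  defined and verified through round-trip inversion.
* **Truncated reconstruction** (`reconstruct_truncated()`,
  `reconstruction_profile()`): zeroing all terms above order $k$ and
  inverting measures how much of the landscape lower-order interactions
  explain ($R^2$ against observed ln RA, computed with the standard
  $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ form). Truncating the
  *relative* basis at order 1 reproduces the log-additive model exactly
  (asserted numerically in the tests); the *averaged* basis at order 0
  reconstructs the landscape mean. An option restricts scoring to
  variants with more mutations than the included order.

## Synthetic data: what it emulates and what it does not

All inputs are generated in code, so the full pipeline is testable
without downloads.

* `simulate_landscape_from_spectrum()` draws a sparse
  background-averaged coefficient spectrum (counts and magnitudes per
  order), inverts it to ln(RA) for all $2^N$ genotypes, anchors the
  wild type at RA = 1, and optionally adds Gaussian noise. Defaults are
  low-order dominated (all singles, a quarter of the pairs, a sixteenth
  of the triples, magnitudes halving per order), emulating landscapes
  whose epistatic information concentrates in low orders.
* `simulate_two_anchor_network()` builds a complete biallelic landscape
  whose all-wild and all-mutant genotypes are neutral anchors joined by
  a neutral band: a genotype with mutation set $S$, $|S| = k$, is
  on-band when $\max(S) \le k + w - 1$. Width $w = 1$ leaves exactly
  one accessible mutation order ($1/N!$ of paths), width $N$ makes
  every path neutral; `blob_radius` additionally makes every genotype
  within that radius of the far anchor neutral, and `module_size`
  defines a set of co-occurring mutations whose carriers are all
  neutral — a crossover-closed robust module, the discrete analogue of
  a robust structural unit such as a stabilised stem. On-band RA is
  uniform on $[0.2, 1]$, off-band uniform on $[0, 0.1]$ (a safety
  margin around the threshold); anchors are pinned at 1 and 0.63. For
  $N \le 6$ the exact accessible-path fraction is computed by
  exhaustive enumeration and attached.
* `simulate_read_counts()` / `simulate_fastq()` draw per-variant depth
  (Poisson around the mean, optionally negative-binomial) and ligated
  counts $\sim \mathrm{Binomial}(\mathrm{depth}, \mathrm{RA}\cdot
  \mathrm{FL_{WT}})$, with $\mathrm{FL_{WT}} = 0.5$ by default, and can
  emit FASTQ reads with the correct barcode/flank layout and a
  configurable rate of low-quality base calls. There is no PCR-bias or
  base-level sequencing-error model: replicate noise in the real assay
  shows only weak correlation with count depth, so binomial counting
  noise (plus optional Gaussian ln-RA noise) is the simplest adequate
  model for testing. Passing tests therefore demonstrate correctness of
  the computations, not robustness to PCR artefacts, chimeras, or
  index hopping.

## Numerical and design choices

* Position convention: 1-based within the 35-nt core; `CORE_OFFSET`
  (+44) converts to full-ribozyme coordinates.
* Enumeration order: position-major, bases alphabetical — outputs are
  reproducible without sorting.
* `sample_k_mutants()` uses rejection sampling, which is exactly
  uniform over the $\binom{L}{k}3^k$ distinct k-mutants.
* Barcode and flank matching is exact; the synthetic reads honour
  exactness, and real data with sequencing errors in constant regions
  would need a tolerant scanner upstream of this package.
* Directional fits can fail to converge on degenerate inputs; the
  failure is reported as an error with the underlying optimiser
  message, never silently.
* Seed fan-out: `derive_seed(seed, label)` hashes a stage label into a
  32-bit seed so that re-running one stage cannot perturb another.

## The guided-evolution study conditions

The end-to-end check of the guided loop uses a frozen two-anchor
construction: $N = 14$ loci in a 16-nt core, band width 2, and a
robust module of radius 3 around the far anchor, sequenced at depth
1000 per replicate, quantified, and navigated with an oracle classifier
built from the measured neutral calls. The starting population is every
measured-neutral genotype within 10 mutations of the wild type — the
whole screened band, mean Hamming distance 0.48 N with a broad tail,
emulating the diverse last experimentally screened generation, while
the robust module itself is unvisited — and the loop runs 400 rounds with
population 600, 100 parents, tournament size 5, mutation rate
$1.5/L$, and a final candidate pool of 2000.

The construction is deliberate: a population under neutral,
classifier-guided drift settles near the neutral-volume centre of mass
of the landscape, so a bare constant-width band (whose volume peaks at
mid-distance) can never hold a population at three quarters of the full
distance. Concentrating neutral volume in a robust module around the
far anchor — the discrete counterpart of the robust stem module
observed around evolved distant genotypes — both makes the far
neighbourhood the attractor and leaves a narrow connecting ridge for
the transit, which is the property the check exercises. During design,
twelve seeds of this construction reached mean Hamming fractions of
0.79–0.82, against the 0.75 criterion asserted in the tests.

## Problem sizes used by the checks

The shipped tests and the acceptance script run at desk scale by
choice: dense-matrix oracles up to $N = 12$ and fast-transform round
trips at $N = 16$; spectrum recovery at $N = 8$–10; reciprocal-sign
brute-force cross-checks at $N \le 6$; exhaustive path enumeration at
$N \le 6$ with $10^2$–$10^3$ sampled paths; sequencing depths of
150–10000; and five seeds of the guided-evolution run above. Larger
runs (e.g. $10^6$ sampled paths at $N = 16$) use the same code paths
unchanged.

## Known limitations

* The package analyses the core's biallelic projection exactly; full
  4-letter combinatorial landscapes beyond distance-2 censuses are out
  of scope.
* No global-nonlinearity correction is applied to measured activities
  before the Walsh–Hadamard decomposition; measurement noise therefore
  inflates apparent high-order terms at low depth (visible in the
  depth-dependence of spectrum-recovery error).
* The classifiers are trained exactly as specified — no hyperparameter
  search — so their reported metrics characterise the pinned
  configurations, not the families' best attainable performance.
* Secondary-structure prediction, oligo-pool design, and re-analysis of
  deposited experimental datasets are outside the package's scope; an
  activity table from any source can be supplied as TSV.
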