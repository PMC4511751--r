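---
title: "Detecting recent selection on a population-private allele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent selection on a population-private allele}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bittersweep)
```

## The inferential problem

Suppose a loss-of-function allele of a bitter-taste receptor gene is found at
29% frequency in one local population of a primate species — and nowhere else,
despite the species' populations exchanging migrants freely at neutral loci.
Two neutral explanations must be excluded before invoking positive selection:

1. **Isolation.** The focal population might simply not exchange migrants, so
   any allele arising there would stay there. This is tested with neutral
   non-coding loci: diversity statistics, pairwise differentiation
   (F\_ST), and the island-model migration estimate Nm.
2. **Drift.** Even with migration, a neutral allele *might* drift to 29%
   before any copy happens to emigrate. This is a quantitative question about
   first-passage times and emigration probabilities, answered by forward
   simulation.

A third, independent clock comes from haplotype homogeneity: if all sampled
copies of the allele sit on an identical long-range haplotype, the allele is
young, and a Poisson bound turns "zero mutations observed" into an upper
bound on its age. Functional assays (calcium imaging of the receptor,
two-bottle preference tests) establish that the allele really is a
loss-of-function, via EC50 estimates from dose-response fits.

`bittersweep` implements all of these pieces plus the synthetic-data
generators needed to test them without any external data.

## Diversity statistics and their null

For an alignment of $n$ phased chromosomes with $S$ segregating sites over
$L$ comparable sites,

- nucleotide diversity $\pi$ is the mean pairwise difference per site,
- Watterson's estimator is $\hat\theta_W = S / (a_{n-1} L)$ with
  $a_{n-1} = \sum_{i=1}^{n-1} 1/i$,
- Tajima's $D$ is the normalized difference $\pi L - S/a_{n-1}$ using the
  1989 variance constants.

Columns containing an alignment gap, and columns that are entirely missing
(`N`), are excluded from $S$, $\pi$ and $\theta$ — the convention of the
standard polymorphism software this mirrors. Statistics are stored as
fractions; multiply by 100 for the conventional percent display.

```{r}
# pooled-sample example: S = 15 over 1194 chromosomes and 1002 bp
round(watterson_theta(S = 15, n_chromosomes = 1194,
                      effective_length = 1002) * 100, 3)
```

The significance of an observed $D$ is assessed against a neutral coalescent
null with no recombination and mutations arriving as a Poisson process along
lineages at fixed $\theta$ (`tajima_d_pvalue()`). We simulate at fixed
$\theta$ equal to the observed $\hat\theta_W$ rather than conditioning on the
observed $S$; the two conditioning choices give similar tails at these sample
sizes, and fixed-$\theta$ matches the stated mutation model most directly.
Replicates with $S = 0$, where $D$ is undefined, are dropped from the
two-sided tail probability.

## Differentiation and migration

`pairwise_fst()` uses the Hudson–Slatkin–Maddison estimator
$F_{ST} = 1 - H_w / H_b$, with $H_w$ the unweighted average of the two
within-population mean pairwise differences and $H_b$ the between-population
mean. Under the island-model equilibrium $F_{ST} = 1/(1 + 4Nm)$,
`nm_from_fst()` inverts to $Nm = (1 - F_{ST})/(4 F_{ST})$. In finite samples
the estimator can be weakly negative for undifferentiated populations; such
values are reported as-is but map to the infinite-migration flag (`Inf`) for
the Nm conversion, since they carry no differentiation signal.

`haplotype_spectrum()` collapses identical sequences and classifies each
haplotype as *private* (seen in exactly one population) or *shared*; the
per-population shared/private fractions are computed over chromosomes, so a
private allele at 29% frequency contributes a 29% private fraction.

## Haplotype networks and recombination

`build_mj_network()` constructs a median-joining network: observed
haplotypes (and, iteratively, majority-consensus median vectors of connected
triples) joined by the minimum-spanning network with tolerance
$\varepsilon$ (default 0). Each contiguous gap run is coded as one indel
*event* with weight 2 versus 1 for a substitution, so a multi-base deletion
spans a single network branch, and edges are labelled with the anchor
positions of their mutations. Because published network software is known to
be order-dependent, all tie-breaks here (node ordering, median states when
all three sequences disagree at a character) are lexicographic, which makes
the output deterministic; only distance relations between named haplotypes
should be compared across implementations. Median vectors whose final degree
is $\le 2$ are pruned, as they join nothing.

`four_gamete_scan()` localizes recombination: under infinite sites, two
biallelic sites displaying all four allele combinations cannot share a
single tree. The reported breakpoint interval is the narrowest incompatible
pair by anchor position — with a single crossover and both recombinant
classes sampled, this brackets the true breakpoint.

## The age bound

If $n$ sampled copies of a haplotype are identical over $L$ monitored sites
and descend star-like from an ancestor $t$ years ago, the number of
mutations is Poisson with mean $nL\mu t$. `poisson_upper_bound()` reports
the largest integer $t$ with $e^{-nL\mu t} > \alpha$ (and the continuous
solution $-\ln\alpha/(nL\mu)$). The star genealogy maximizes total branch
length, so the bound errs on the permissive side. With $n = 23$,
$L = 10^4$, $\mu = 10^{-9}$ and $\alpha = 0.05$:

```{r}
poisson_upper_bound(23, 1e4, 1e-9, 0.05)$t_upper_years
```

`single_mutation_waiting_time()` gives the complementary single-lineage
expectation $1/(L\mu)$ for acquiring the defining mutation at all.

## The expansion simulator

`simulate_expansion()` is the core neutrality test. A single allele copy
enters a Wright–Fisher deme of diploid size $N$. Each generation, every
allele copy emigrates independently with probability $m = Nm/N$ (an
emigrant copy is replaced by a non-carrier immigrant, keeping census size
constant), and then the next generation is drawn binomially at the
post-migration frequency. Migration precedes reproduction; the model does
not ask whether emigrants establish elsewhere — a single emigrant copy ends
"privacy", which is conservative toward retaining privacy. A replicate ends
at loss, at first passage of the target frequency $q$, or at a cap of
$100N$ generations (censored replicates are excluded with a warning; at the
parameter ranges used here none arise).

Two summaries matter:

- the **conditional first-passage time** to $q$ (lost replicates are
  discarded, not restarted), reported in units of $N$ generations. Its
  diffusion limit, `diffusion_expected_time()`, is
  $\frac{4}{q}\left[(1-q)\ln(1-q) + q\right]$ — about $0.646N$ for
  $q = 0.29$ and $0.250N$ for $q = 0.12$; finite-$N$ simulation sits
  slightly above it.
- the **privacy probability**: among replicates that reach $q$, the
  fraction in which no copy ever emigrated. It is 1 when $Nm = 0$ and
  declines steeply in $Nm$; at $Nm \approx 1.8$ and $q = 0.29$ it is
  effectively zero, which is what makes a private allele at 29% incompatible
  with neutral drift under realistic migration.

Because conditioning is on success, the simulator runs batches of attempts
until the requested number of successes accumulates; every success from a
completed batch is kept, so the success count divided by attempts is also an
unbiased estimate of the fixation-style passage probability (about
$1/(2Nq)$). `generations_to_years()` converts $N$-unit times via
$t \cdot N \cdot$ (generation time).

## Dose-response models

Receptor titrations are fit with the increasing four-parameter logistic
$f(x) = I_{min} + (I_{max} - I_{min})/(1 + (\mathrm{EC}_{50}/x)^h)$, on the
mean response per concentration, by Levenberg–Marquardt least squares
(`minpack.lm`), with EC50 log-parameterized so it stays positive.
Initialization uses the observed response extremes, the geometric-mean
concentration, and $h = 1$. Two-bottle preference data are fit with
$f(x) = 0.5/(1 + (x/\mathrm{EC}_{50})^h)$: preference starts at the 0.5
indifference level and the fitted EC50 is, by the model's form, exactly the
concentration where preference falls to 0.25 — half of chance. Flat or
non-declining data raise a degenerate-fit error rather than returning an
arbitrary curve.

## What the generators emulate — and what they do not

- `simulate_coalescent_alignment()`: neutral, panmictic, no recombination,
  infinite sites, constant population size. It reproduces
  $E[S] = \theta a_{n-1}$ and $E[\pi L] = \theta$, which is what the
  diversity statistics assume — not demographic history, linked selection,
  or finite-sites homoplasy.
- `simulate_island_samples()`: symmetric island model (default comparisons
  use 10 demes, where $F_{ST} \approx 1/(1 + 4Nm(d/(d-1))^2)$ is a good
  finite-$d$ reference). Real macaque populations follow a two-dimensional
  stepping-stone geometry; the island model matches their equilibrium
  $F_{ST}$–$Nm$ relation but not their isolation-by-distance pattern. With
  $Nm = 0$ a finite ancestral fusion time `t_split` must be supplied
  (a population-split model), since isolated demes never coalesce.
- `generate_star_haplotypes()`: exactly the star genealogy of the age
  bound; real genealogies are less star-like, which is the direction of
  conservatism.
- `generate_preference_trials()` uses truncated Gaussian noise on the trial
  ratios rather than modelling consumed volumes binomially — simpler, and
  sufficient for parameter-recovery testing; real trial noise is
  heteroscedastic.

Passing tests on these generators therefore validate the estimators under
their own assumptions; they do not validate the assumptions against real
data.

## Numerical and design choices

- The printed form of the 4PL titration equation in common methods sections
  is ambiguous about bracketing; the increasing form in $x$ (for $h > 0$) is
  used, since agonist titrations rise with dose.
- The age bound uses the strict inequality ("probability of zero mutations
  still above $\alpha$"), hence *largest integer below* the continuous
  solution.
- The expansion simulator's `q_target` is compared as
  `copies >= ceiling(2Nq)` so that "reaching 29%" means the frequency is at
  or above 0.29 exactly.
- Tie-breaks and node orderings in the network code are lexicographic
  throughout; RNG-consuming functions take an explicit integer seed and are
  bit-reproducible given it.
- Test problem sizes: simulation-based checks in the test suite use 60–1500
  replicates and demes of 3–10 with samples of 4–8, and the expansion checks
  use $N$ = 500–2000 with 800–2500 conditioned successes; these sizes give
  Monte-Carlo standard errors comfortably inside the asserted tolerances.

## Known limitations

- The median-joining implementation targets the small haplotype sets typical
  of single-locus studies (tens of distinct haplotypes), not genome-scale
  input.
- F\_ST is the Hudson pairwise-difference form only; variance-component
  estimators (Weir–Cockerham) are out of scope.
- The expansion model has one focal deme with absorbing emigration; it does
  not track the fate of emigrants in neighbouring demes or allow
  back-migration of the allele.
- No selection coefficients are estimated anywhere: the inference is by
  rejecting neutral expectations, not by fitting selection models.
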