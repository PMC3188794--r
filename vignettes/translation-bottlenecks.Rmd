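---
title: "Codon-level translation bottlenecks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level translation bottlenecks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraffic)
library(dplyr)
```

## The problem

Gene-level measures of codon adaptation such as the tRNA adaptation index
(tAI) summarize a coding sequence by a single averaged number, and so ignore
*where* along the transcript the slow and fast codons sit. Yet the order
matters: a cluster of slow codons near the start codon (a "ramp") can meter
ribosomes onto the message and prevent costly downstream collisions, whereas
the same cluster near the 3' end traps a long queue of ribosomes.
`ribotraffic` implements a codon-level pipeline around this idea:

1. per-codon translation speeds from tRNA gene copy numbers and wobble
   pairing constraints;
2. a sliding-window scan that locates each gene's **bottleneck** — the
   window with the minimal harmonic mean of codon weights, equivalently the
   longest total translation time;
3. library statistics relating bottleneck geometry to protein abundance and
   per-codon usage to host fitness (optical density), with
   partial-correlation control for mRNA folding energy;
4. genome-scale surveys of bottleneck placement with hypergeometric quadrant
   enrichment tests; and
5. a seeded synthetic synonymous-library generator so the whole pipeline is
   exercisable and testable without any external data.

Codons are written in the DNA alphabet throughout (`TCA` is the serine codon
often printed as UCA); anticodons, which live on tRNA, stay in RNA letters.

## Codon speeds from the tRNA pool

Each sense codon's absolute adaptiveness is

$$W_i = \sum_j (1 - s_{ij})\, \mathrm{tGCN}_j,$$

summing over the anticodons $j$ that can read codon $i$: the Watson-Crick
anticodon plus the standard wobble reader of the third base (G34:U3,
inosine:C3, inosine:A3, U34:G3, and the lysidine-modified C34 that reads the
isoleucine codon ATA). $s_{ij} \in [0,1]$ is the pairing-class selective
constraint and $\mathrm{tGCN}_j$ the tRNA gene copy number, a standing proxy
for tRNA abundance. Relative adaptiveness is $w_i = W_i / \max_k W_k$, so
the best-adapted codon has $w = 1$; $1/w_i$ is the codon's translation time
in units of the fastest codon. The gene-level tAI is the geometric mean of
its codons' $w$ values, computed in the log domain.

Codon CGA is special-cased: it is read by the ACG-anticodon tRNA through an
inosine:A pairing whose constraint ($s = 0.9999$) leaves it more than an
order of magnitude slower than every other codon, which would let it
dominate every harmonic-mean window. Its weight is therefore overridden to
0.1333 (`cga_weight`), applied at the weight level after normalization.

The bundled tRNA table (`trna_pool_default()`) is an approximate E. coli
K-12 compilation assembled for this package from standard anticodon
repertoires, with initiator fMet genes excluded and the lysidine Ile2 tRNA
pooled under its genomic anticodon CAU. It is repository data intended for
simulation and method development; for production analyses supply curated
organism-specific counts through `read_trna_pool()`. Codons with no readable
anticodon in a user pool either raise a named error or, on request
(`zero_weight = "geomean"`), are imputed with the geometric mean of the
non-zero weights.

## The bottleneck scan

For window size $n$ the scan minimizes the harmonic mean of $w$ over all
windows — equivalently maximizes the mean translation time, since the
harmonic mean of speeds is the reciprocal of the arithmetic mean of times.
A window is summarized by:

- `location_k`: 1-based index of the window's first codon;
- `relative_location` $= k / (l - n + 1)$, the location divided by the
  number of possible windows, spanning $(0, 1]$;
- `strength`: arithmetic mean of $1/w$ over the window;
- `relative_strength`: strength divided by the gene-wide mean of $1/w$.

**Numerical choices.** Window sums are computed from cumulative sums in
$O(l)$; because cumulative-sum differences carry rounding noise of order
$10^{-15}$, near-maximal candidate windows are re-evaluated by direct
summation so that windows tied in exact arithmetic resolve identically to a
brute-force enumeration. Ties break toward the **leftmost** (most proximal)
window — the choice is arbitrary but deterministic, and is applied
consistently in the scan, the jam argmax, and all oracles. Genes shorter
than $n$ raise a named error in `find_bottleneck()` and are skipped with a
warning and a skip report in the batch `survey_genome()`.

**Window size.** The default $n = 21$ codons derives from the measured mean
center-to-center distance between adjacent ribosomes on bacterial polysomes,
21.6 nm, at 0.34 nm per base: `window_size_from_spacing(21.6)` = 21. The
ribosome footprint (10.2 nm) gives 10 codons; spacing exceeds the footprint
because adjacent 30S subunits need clearance. Placement is insensitive to
the exact choice on structured libraries (Spearman > 0.99 across
$n \in [14, 30]$ on the default synthetic library) — though not on fully
random codon soup, where the minimal window is noise by construction.

**Traffic-jam condition.** With ribosomes $H$ codons apart under saturating
initiation, a trailing ribosome catches the leader if and only if some
window's translation time $T_w(k, H) = \sum_{i=k}^{k+H-1} t(i)$ exceeds the
first window's time plus the initiation assembly time $B$:
$\max_k T_w(k, H) > T_w(1, H) + B$. `predict_jam()` evaluates this with a
strict inequality — exact equality means the trailing ribosome arrives
precisely on time, no collision. $B$ is left a free parameter with no
default, as nothing in the model fixes its value.

## Library statistics

`per_cell_abundance()` divides bulk protein signal by optical density (OD),
the proxy for population size; data measured at constant OD bypass the
division with `normalize_od = FALSE`. `analyze_bottleneck_vs_expression()`
then correlates relative location and relative strength (and gene tAI)
against per-cell abundance — Pearson and Spearman, over the whole library
and within a proximal band of relative locations (default 0.16–0.28,
inclusive) — because the strength of a bottleneck is expected to help only
when the bottleneck is proximal. When folding energies are available,
first-order partial correlations control for them:

$$r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
{\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

with a two-sided $t$ test on $n - 3$ degrees of freedom; the rank-based
variant applies the same formula to rank-transformed data. Spearman
p-values use the large-sample $t$ approximation throughout. Zero-variance
inputs yield an *undefined* flag rather than an error, mirroring the
treatment of constant codon counts.

`codon_fitness_scan()` correlates each sense codon's copy number against OD
and classifies at the Bonferroni-corrected threshold $\alpha/61$ — 61 is
the fixed number of codon tests even though some codons (single-synonym
ATG, TGG, or any invariant position) are constant across a synonymous
library and are reported as `constant` with no correlation value.

`rank_fitness_codons()` isolates the codons that drive the fitness cost in
three steps: keep codons negatively correlated with OD; build the full
partial-correlation matrix $M(i, j) = r(\text{count}_i, \mathrm{OD} \mid
\text{count}_j)$ over ordered pairs; score each codon by
$\min_j |M(i, j)|$ and rank descending. A codon whose OD association
survives control by *every* other candidate cannot be explained away by a
correlated passenger. With a single surviving codon the minimum over an
empty controlling set falls back to $|r_\text{raw}|$ (a convention; the
situation does not arise in realistic libraries). $M$ is computed in closed
form from the pairwise correlation matrix, which tests verify against the
residual-regression construction to $10^{-10}$.

## Genome survey

`survey_genome()` scans all ORFs of more than 100 codons (`min_length =
101`), reporting skipped genes. `quadrant_enrichment()` asks whether genes
with a strong bottleneck (relative strength strictly above 1.3) place it in
a given quarter of the transcript more or less often than chance:
quadrants partition relative location into $[0, 0.25)$, $[0.25, 0.5)$,
$[0.5, 0.75)$, $[0.75, 1]$ (half-open, closed at 1), and one-sided
hypergeometric tails include the observed count — enrichment
$P(X \ge k)$, depletion $P(X \le k)$. `expression_classes()` selects the
top and bottom 500 genes by recorded mRNA level (unrecorded genes ignored;
ties broken by level then gene id) and intersects with the length-filtered
scan, so the returned groups are typically smaller than 500.

## The synthetic library generator

`generate_library()` back-translates a fixed amino-acid sequence — by
default a synthetic 239-residue GFP-like protein bundled with the package
(it mimics GFP's composition, including a histidine-rich tail, but is *not*
GFP) — once per variant, so all variants are exact synonyms. Three
policies: uniform synonym choice, frequency-weighted (probability
proportional to $w$), and `planted_bottleneck`, which samples synonyms
inside a target window with probability $\propto w^{-b}$ and outside with
$\propto w^{3}$, where the inside tilt $b = 2 + 2(\sigma^* - 1)$ grows with
the planted strength target $\sigma^*$. Planted location targets are
recovered by the scan within ±0.05 relative units for well over 90% of
variants; strength targets are best-effort (windows dominated by
single-synonym amino acids cannot be slowed, and a warning is issued).
Location and strength targets may be scalars or ranges; the default library
draws per-variant locations from Uniform(0.05, 0.65) and strength tilts
from Uniform(1.2, 2.0), because between-variant variation in bottleneck
geometry is what the recovery correlations require.

`simulate_measurements()` plants the effect structure the analysis is
designed to detect:

$$\log A_i = \beta_0 + \beta_\text{loc}\,\rho_i +
\beta_\text{str}\,\sigma_i\,\mathbf{1}[\rho_i \le 0.28] +
\beta_F F_i + \varepsilon_i,$$

with $\rho_i, \sigma_i$ the variant's *computed* bottleneck parameters,
folding energy $F_i \sim N(-8, 2)$ kcal/mol drawn independently of the
sequence, and $\varepsilon_i \sim N(0, 0.3)$. OD falls linearly with
penalized codon counts, $\mathrm{OD}_i = 2 - \sum_c \gamma_c\,
n_{ic} + N(0, 0.05)$ floored at 0.05 (an error if more than 10% of variants
hit the floor), defaulting to $\gamma = 0.08$ per copy for TCA and CAT —
the two codons whose rare cognate tRNAs make them natural fitness
liabilities. Bulk abundance is per-cell abundance times OD, so the
normalization step inverts the simulation exactly. Folding energy is
simulated rather than computed from sequence: secondary-structure
prediction is out of scope, and an independent covariate lets tests toggle
confounding at will.

**Calibration.** Defaults were calibrated so that at $N = 150$ variants the
planted correlations land near realistic magnitudes ($|r| \approx$ 0.3–0.6):
the proximal-band strength correlation sits near +0.5 and the overall
location correlation near −0.8 (the proximal strength step deepens the
location effect beyond the band magnitude). `planted_correlation_targets()`
computes the analytically implied correlations from the realized bottleneck
parameters and the model's variance components — no simulated measurements
involved — and the tests require the measured Spearman correlations to land
within ±0.15 of these targets.

**What passing tests do and do not show.** The generator produces exact
synonyms with independent Gaussian noise, a linear OD penalty, and a
folding covariate independent of the sequence. Real expression libraries
violate all of these pleasantries: folding energy is sequence-determined
(and thus correlated with codon choice), measurement error is heteroscedastic,
and variant sets are small and structured by construction chemistry.
Recovery of planted effects therefore validates the statistical machinery,
not any biological claim about a particular library; real conclusions
require real data loaded through `read_library_table()`.

## Problem sizes and runtime choices

The test suite and the acceptance script exercise: 1,000 random genes of
25–300 codons against brute-force window enumeration; 500 random profiles
for the jam condition (every fifth an exact-equality case built on integer
profiles, where floating-point arithmetic is exact); 100 seeded replicates
of the default 150-variant library for sign recovery; 50 seeds of a
60-variant null library for calibration; and hypergeometric tails checked
against direct pmf summation for populations up to 200. These sizes give
stable rates while keeping a full run to a few minutes on one core.

## Known limitations

- The weight model ignores tRNA charging dynamics, codon-pair effects and
  modified-base context beyond the fixed wobble classes; tGCN is a proxy
  for tRNA abundance.
- The jam condition is the analytic two-ribosome bound, not a stochastic
  ribosome-flow (TASEP) simulation.
- The bundled tRNA table is approximate; single-copy differences move
  individual weights (not the CGA override, which is pinned).
- CAI, mRNA folding-energy computation, and ORF calling from raw genomes
  are deliberately out of scope; ORF FASTA and folding-energy columns are
  the input contract.
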