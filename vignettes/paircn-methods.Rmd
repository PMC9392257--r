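---
title: "Joint copy-number inference from pairs of single cells: model and methods"
author: "paircn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint copy-number inference from pairs of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-cell whole-genome sequencing of tumors yields shallow, noisy read
depth, which makes per-cell copy-number calling and downstream phylogeny
estimation error prone. Cells from one tumor are not independent samples,
however: they inherit copy-number alterations (CNAs) from shared ancestors.
`paircn` models that shared history explicitly. Analysing cells in pairs
both regularises the copy-number profiles (CNPs) and produces, as a
by-product, a model-based evolutionary distance between every two cells
that can be fed directly to neighbor-joining.

## The evolutionary model

### One lineage, two adjacent bins

The genome is divided into fixed windows (bins). CNAs typically span
several bins, so copy numbers of adjacent bins are strongly correlated.
The core process is a continuous-time Markov chain on the pair
$(U, V) \in \{0, \dots, k\}^2$ of copy numbers of two adjacent bins on one
lineage, with three rate parameters:

* $\alpha$ — additional rate of $\pm 1$ copy events,
* $\beta$ — rate of copy events of any magnitude,
* $\gamma$ — relative rate of events wide enough to hit both bins.

Off-diagonal generator entries are $\gamma(\alpha+\beta)$ for joint
$\pm 1$ moves of both bins, $\gamma\beta$ for joint moves of magnitude
$>1$, $\alpha + \beta$ for single-bin $\pm 1$ moves, $\beta$ for
single-bin moves of magnitude $>1$, and $0$ otherwise — in particular,
the two bins never change by *different* amounts in one instant, though
they can over any finite time. Moves that would leave $\{0,\dots,k\}$ are
simply absent (no reflecting mass), and diagonals make rows sum to zero.
Transition probabilities are $\mathbb{P}(t) = e^{\mathbb{Q}t}$, computed
by scaling-and-squaring (`Matrix::expm`); round-off negatives above
$-10^{-12}$ are clipped and rows renormalised, anything worse is an
error.

### Two cells on a three-branch tree

A pair of cells $(A, B)$ descends from a diploid ancestor through a
shared branch of length $t_1$ to an unobserved divergence state, then
private branches $t_2$ (to $A$) and $t_3$ (to $B$). Marginalising the
unobserved adjacent-bin state $(W, Y)$ at divergence gives the joint
probability that cell $A$ moves $c_{iA} \to c_{jA}$ between adjacent
windows while $B$ moves $c_{iB} \to c_{jB}$:

$$f_{(c_{iA},c_{iB}),(c_{jA},c_{jB})} = \sum_{W,Y}
  P_{(2,2),(W,Y)}(t_1)\, P_{(W,Y),(c_{iA},c_{jA})}(t_2)\,
  P_{(W,Y),(c_{iB},c_{jB})}(t_3).$$

Row-normalising $\mathbb{F}$ yields the genome-wide transition matrix
$\mathbb{M}$ over paired states $(CN_A, CN_B)$. The true process along
the genome is not Markovian (breakpoints come in pairs); $\mathbb{M}$ is
a deliberate Markov approximation, and the simulator used for validation
intentionally keeps the paired-breakpoint structure the model lacks.

### Emissions

Conditional on the paired state, read counts in the two cells are
independent negative binomials. For cell $A$ in window $i$,
$\lambda_{iA} = (CN_{iA}\,\mu_i/2)\,s_A + \varepsilon$ with variance
$\sigma^2 = a\lambda^2 + b\lambda + c$, where $\mu_i$ is the mean diploid
depth in window $i$, $s_A$ the library-size scaling factor and
$\{a, b, c\}$ variance coefficients fit to matched diploid cells by
constrained least squares ($a, c \ge 0$). $\varepsilon$ is a fixed
constant (default $0.01$ reads) that keeps copy number $0$ emittable.
Whenever the fitted variance falls at or below the mean, it is floored at
$\lambda(1 + 10^{-6})$ — fitted coefficients can dip under the Poisson
line at small $\lambda$ and a hard error there would be wrong.

The HMM is reset to the stationary distribution of $\mathbb{M}$ at the
start of every chromosome, making chromosomes independent. Windows with
$\mu_i = 0$ get uninformative emissions (log-probability 0 in every
state), so the decoded value there follows the transition chain — in
effect interpolating from the flanking informative windows.

## The pipeline

1. **Diploid baseline.** `average_diploid()` gives per-window mean and
   $n{-}1$ variance across matched diploids; `fit_dispersion()` fits
   $\{a, b, c\}$.
2. **Independent cell fits.** `fit_cell()` runs an unconstrained
   Baum-Welch pass (free $(k{+}1)$-state chain, one golden-section
   refinement of $s$ per sweep), moment-matches the structured chain to
   the free chain over a small grid of candidate times, then maximises
   the forward log-likelihood over $\log\{s, \alpha, \gamma, t\}$ with
   L-BFGS-B, and Viterbi-decodes an integer CNP.
3. **Shared rates.** Per-cell $\{\hat\alpha, \hat\beta, \hat\gamma\}$
   are combined by the component-wise median (`combine_rates()`); rates
   are assumed common to the tumor while branch lengths are pair
   specific.
4. **Pair fits.** For each pair, `fit_cell_pair()` maximises the
   two-cell forward log-likelihood over $\log(t_1, t_2, t_3)$, starting
   from $t_1^\ast = \min(\hat t_A, \hat t_B)/2$,
   $t_2^\ast = \hat t_A - t_1^\ast$, $t_3^\ast = \hat t_B - t_1^\ast$
   (plus one symmetric alternative start; the better optimum wins).
   $s$ and $\{a,b,c\}$ are *not* re-estimated here. Joint Viterbi
   decoding yields one CNP per cell per pair.
5. **Consensus.** Each cell's paired CNPs are summarised per window by
   mean (default), median or mode (`consensus_profile()`). Mean and
   median may be fractional — genuinely useful, because binning makes
   true copy numbers fractional at event boundaries; mode ties break
   toward the smaller copy number. With `kappa` set, only each cell's
   $\kappa$ nearest neighbours (Euclidean distance between independent
   CNPs, ties by cell id) are paired, and the consensus denominator is
   the number of pairs actually fitted; $\kappa = 10$ is a sensible
   default when profiles, not trees, are the goal.
6. **Phylogeny.** $\hat t_2 + \hat t_3$ is the pairwise distance;
   `t2t3_matrix()` requires *all* pairs (a $\kappa$-restricted run
   cannot produce a complete matrix). Trees come from classic
   neighbor-joining and are compared with the unweighted
   Robinson-Foulds bipartition count, both through the same `ape` /
   `phangorn` machinery commonly used in the field.

## Identifiability and numerical choices

* **Rate-time confounding.** Scaling $(\alpha, \beta)$ by $c$ and $t$ by
  $1/c$ leaves $\mathbb{Q}t$ — hence the likelihood — unchanged. The
  single-cell stage therefore fixes $\beta = 1$ during optimisation and
  canonicalises the result to $\alpha + \beta = 1$, so $\hat t$ counts
  expected events and is comparable across cells. Without this, per-cell
  estimates wander along the ridge and the medians of stage 3 mix
  incompatible scales.
* **Scaled forward recursions** (per-window normalisation with the log
  of the constants accumulated) rather than log-sum-exp throughout, in
  compiled code; Viterbi ties break toward the smaller state index.
* **Branch lengths are floored at $10^{-6}$** inside the pair
  optimisation to keep $\mathbb{M}$ irreducible; transition matrices are
  cached keyed on $(t_1, t_2, t_3)$ rounded to $10^{-9}$ to avoid
  recomputing matrix exponentials inside line searches.
* **Steady state** comes from the dominant left eigenvector, normalised
  to non-negative entries, with a power-iteration fallback (tolerance
  $10^{-12}$, $10^5$ iterations cap).
* **Optimiser hygiene.** All positive parameters are optimised on the
  log scale; box bounds keep the search away from degenerate corners;
  up to three seeded random restarts on failure; Baum-Welch stops at
  relative improvement $<10^{-6}$ or 100 sweeps (fits in this package
  default to fewer sweeps — the EM pass only supplies starting points).

## The simulator

Validation uses a line-segment tumor simulator that is *deliberately
different* from the inference model. A genome is a multiset of segments
over a fixed reference $[0, L)$; ploidy at a point is the number of
covering segments, so the ancestral diploid is two full-length segments.
Along each tree branch, events arrive as a Poisson process
(rate $(\text{amp}+\text{del}) \times L$ per unit time), each with a
uniform start, an exponential length truncated at the reference end, and
a uniformly chosen covering segment that is duplicated (amplification)
or cut (deletion). Ancestral events propagate to descendants, and every
event creates a *pair* of breakpoints — the non-Markovian structure the
HMM only approximates. True per-window copy number is the average ploidy
over the window, which is fractional when event boundaries fall inside
windows.

Four tree shapes span balance and clock-likeness: A — pectinate,
ultrametric (internal branches $1/n$, terminals stretched to equal
depth); B — perfectly balanced, all branches $1/n$; C — pectinate with
all branches $1/n$ (non-ultrametric); D — pectinate with terminal
branches $\propto 1/\ln(j+1)$. Trees are rescaled to height 1 with a
root branch of length 1 prepended. Read depth per window is negative
binomial with size $r = 50$ and mean proportional to copy-number mass,
totalling 4,000,000 expected reads over 12,397 windows (322.7 per
window) for a diploid cell — matching the coverage regime of published
250 kb-binned single-cell breast-tumor data.

Default event rates (amplification = deletion = 0.1 events per unit time
per unit genome, mean length 2% of the genome) give on the order of tens
of events per leaf at these tree scalings — enough heterogeneity to
distinguish lineages without saturating the copy-number range. The
simulator does not model GC or mappability bias, whole-genome doubling,
or read-level artefacts; passing tests therefore demonstrate statistical
correctness of the method under its intended noise model, not robustness
to every real-data artefact (matched diploid cells are the package's
answer to GC/mappability, as they are for the underlying model).

## Validation and problem sizes

The test suite checks, among other things: generator row sums,
Chapman-Kolmogorov, unit mass and cell-swap symmetry of the joint
matrix; forward/Viterbi against exhaustive path enumeration on small
instances; Baum-Welch recovery of a planted chain; recovery of
$(t_1, t_2, t_3) = (1, 0.5, 0.5)$ from data simulated from the model
itself (12,000 windows, $k=4$; $\hat t_2 + \hat t_3$ lands within a few
percent of 1); a Spearman correlation $>0.7$ between true and estimated
$t_2 + t_3$ across a five-level divergence ladder; and, on line-segment
simulations, that mean-consensus profiles beat independent profiles in
SSE for most cells, that consensus $\omega$ (inferred/true breakpoint
ratio) is closer to 1, and that neighbor-joining on $t_2 + t_3$ is at
least as close to the true tree (Robinson-Foulds) as neighbor-joining on
Euclidean profile distances.

End-to-end checks run at reduced scale so the whole suite stays fast on
one core: 8 tumor + 20 diploid cells on 4,000 windows with $k = 6$ for
the accuracy comparison, and ten replicates of 8 cells on 1,200 windows
with $k = 4$ for the phylogeny comparison. These sizes were chosen once
as the smallest configurations that keep event density per window
comparable to the full-scale setting; `scripts/acceptance.R` re-runs the
same computations from scratch and writes the resulting numbers as JSON.

## Known limitations

* The genome-direction Markov approximation can leave unpaired
  breakpoints in decoded profiles.
* Rates $\{\alpha, \beta, \gamma\}$ are tumor-wide; strongly
  heterogeneous subclones violate this.
* All pairs must be fitted for a complete $t_2+t_3$ matrix — quadratic
  in cell count; $\kappa$-restriction helps profiles but not trees.
* No SNPs, genotype likelihoods or phasing; copy number only.
* The maximum copy number $k$ truncates the state space; amplifications
  beyond $k$ are absorbed at the boundary.
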