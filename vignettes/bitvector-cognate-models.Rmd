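---
title: "Bit-vector substitution models for cognate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-vector substitution models for cognate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogvec)
```

## The data and its two encodings

A cognate wordlist assigns to every (language, concept) pair a set of
cognate classes — groups of words descended from a common ancestral word.
Writing $M : L \times C \to V$ for this assignment, we call the size of a
pair's class set $\nu$ (its state size; $\nu = 0$ encodes missing data) and
the number of classes attested for a concept across the whole dataset
$\kappa$.

The standard **binary encoding** expands each concept into $\kappa$
presence/absence columns ($A^b$). Its drawback is that the likelihood
treats these columns as independently evolving, although the columns of
one concept are clearly coupled: a language that loses its only word for a
concept must simultaneously flip every column of that group.

The **bit-vector encoding** ($A^v$) uses exactly one column per concept.
The presence/absence pattern over the concept's $\kappa$ ordered classes
is a non-zero bit string $b$ (first class = most significant bit), mapped
to the symbol with 0-based index $\int(b) - 1$; the all-zero vector is
skipped because it means "missing" and is written `-`. A concept with
$\kappa$ classes therefore needs $2^\kappa - 1$ symbols, and with the
64-symbol alphabet (`default_alphabet()`: digits, upper case, lower case,
`!`, `*`) the encoding supports $\kappa \le 6$. Because one alphabet must
fit all columns of a matrix, datasets are partitioned into
**kappa-subsets** of concepts with equal $\kappa$
(`kappa_partition()`); $\kappa = 1$ concepts carry no topological signal
and are excluded.

Both the bit order (MSB-first over lexicographically sorted class labels)
and the 0-based alphabet indexing are conventions we fix so that encodings
are deterministic and stable under row reordering; any fixed convention
would do, but it must be documented for interchange, which is why the
PHYLIP writer/reader and `state_to_symbol()`/`symbol_to_state()` all share
it.

## The substitution models

All models are time-reversible continuous-time Markov chains given by
stationary frequencies $\pi$ and symmetric exchangeabilities $x$, with
instantaneous rates $q(i, j) = x(i, j)\,\pi_j$. This parameterization
deserves a note: assigning symmetric rate-class values directly to the
rate matrix while also demanding detailed balance
$\pi_i q(i,j) = \pi_j q(j,i)$ is inconsistent whenever frequencies are
unequal, so we interpret the rate classes as exchangeabilities — the
standard GTR-family convention — which preserves the intended symmetry
classes and guarantees reversibility by construction. Every generator is
rescaled to unit expected substitution rate at stationarity, so branch
lengths are expected substitutions per column.

On the $2^\kappa - 1$ bit-vector states:

* **MK** — all frequencies and rates equal; no free parameters.
* **GTR** — every frequency and every unordered pair's rate free.
* **COGs** — frequencies depend only on the state size: $\pi_\nu$ for all
  states with popcount $\nu$, normalized with binomial multiplicities
  $\sum_\nu \binom{\kappa}{\nu}\pi_\nu = 1$. Rates form two classes:
  $\lambda_+$ for pairs whose bit vectors differ in exactly one position,
  $\lambda_0$ for all multi-bit differences.
* **COG** — same frequency symmetry; multi-bit rates are pinned to
  exactly zero (the generator entries are structural zeros, not small
  numbers), and one-bit rates depend on the smaller state's size:
  $\lambda_\nu$ with $\nu = \min(\mathrm{popcnt}(b_i),
  \mathrm{popcnt}(b_j))$.

The symmetries encode substantive assumptions about lexical evolution:
state probabilities depend only on how many synonymous class-words a
language keeps, and decrease with that number; at most one word emerges or
disappears in an infinitesimal time step; and innovation/loss rates
decrease as states grow. Binary matrices use the two-state **BIN** model
(one free frequency).

For AIC we use the published per-model free-parameter counts verbatim:
BIN 1, MK 0, GTR $2^\kappa(2^\kappa-1)/2 + 2^\kappa$, COG $2\kappa$, COGs
$\kappa + 1$. These conventions are debatable — the GTR count is phrased
in terms of $2^\kappa$ states rather than the $2^\kappa - 1$ realizable
symbols and subtracts no simplex or scale constraints, and the COGs count
differs from the two optimizable rates — but model comparison only needs a
consistent convention, so we keep the published one and expose an
"independent" count behind `free_parameter_count(convention =
"independent")`, never used by default.

```{r}
m <- build_model("COG", kappa = 3,
                 params = list(pi_nu = c(0.2, 0.06, 0.02), lambda = c(2, 1)))
m
round(m$Q, 3)
```

## Likelihood machinery and numerical choices

`log_likelihood()` is Felsenstein pruning over pattern-compressed columns;
missing entries contribute all-ones conditional vectors, so a fully
missing column adds exactly zero. Transition matrices come from the
spectral decomposition of the reversible generator
($D^{1/2} G D^{-1/2}$ is symmetric for $D = \mathrm{diag}(\pi)$), which is
exact, stable, and cacheable across branch lengths; tiny negative
round-off in $P(t)$ is clamped and rows renormalized. Conditional
likelihoods are rescaled per node only when entries fall below $10^{-200}$.

Branch lengths are optimized per edge by Brent's method on the spectral
edge-likelihood form $\sum_k e^{\mu_k t} [V^\top(\pi \odot
A)]_k [W D]_k$, swept root-to-tips with partials updated along the walk,
iterated until a full sweep gains less than $10^{-6}$ log units. The
search is performed on $\log t$: on the linear scale the profile flattens
for large $t$ and golden-section can stall on the plateau. Lengths are
constrained to $[10^{-6}, 100]$.

Model parameters are optimized by L-BFGS-B on unconstrained transforms:
log-ratios on the frequency simplex (binomially weighted for $\pi_\nu$)
and log-ratios of rates with the first exchangeability class fixed at 1 —
the unit-rate normalization absorbs the overall scale, so a free scale
would only add a flat direction. COG's $\lambda_0$ is represented but
never enters the optimizer.

`run_search()` mirrors the standard configuration: 10 starts from random
topologies (uniformly sampled) plus 10 from randomized stepwise-addition
parsimony trees (Fitch on the multistate symbols, missing treated as
fully ambiguous), each climbing by alternating branch-length and
parameter optimization with nearest-neighbor-interchange sweeps until no
improving move remains; the best final log-likelihood wins, ties broken
by the earliest start. We use NNI moves only: the search surface at the
scale this package targets (tens of taxa) does not need SPR, and NNI
keeps every accepted move auditable. One master seed derives per-start
sub-seeds, making every result byte-reproducible.

Degenerate inputs are handled explicitly: MK passes through the optimizer
untouched; a single-column matrix yields a flat likelihood but converges
without error; a non-finite starting likelihood raises an error naming
the model.

## Model comparison and the cross-validation diagnostic

`compare_models()` fits each requested kind with a shared seed and
tabulates log-likelihood, $k$ and AIC. AIC is only meaningful within one
data representation, so BIN (binary matrices) is never tabulated against
the bit-vector models.

`crossval()` quantifies overparameterization: columns are split 60:40
into training and test (training size $\lfloor 0.6\,n_c \rfloor$, the
remainder is test), tree and parameters are fitted on the training
columns only, and the test log-likelihood is evaluated on that fitted
tree and model with no re-optimization — branch lengths are reused
verbatim. With per-column normalized log-likelihoods the relative error
is
$$e = \frac{\mathrm{llh}^{rel}_{test} - \mathrm{llh}^{rel}_{train}}
           {\mathrm{llh}^{rel}_{train}},$$
averaged over 10 random splits. Matrices with fewer than 10 columns are
rejected as too small to split meaningfully. Large positive $e$ means the
fit does not generalize — the overparameterization signature. The same
operation applied to a full binary matrix under BIN gives the
full-dataset baseline.

`matrix_entropy()` sums per-column Shannon entropies (base 2), excluding
missing symbols from each column's distribution — counting gaps as a
symbol would reward missingness with information it does not carry. `dataset_diagnostics()` profiles the
$\nu$-distribution, kappa-subset sizes, concepts-over-languages ratios
and per-symbol counts that explain when the richer models become
unidentifiable.

## What the simulator emulates — and what it does not

`simulate_cognate_dataset()` generates a uniform random unrooted topology
with exponential branch lengths (mean 0.1 substitutions per column),
simulates each kappa-subset forward under a configured model, masks tip
entries to missing independently with probability 0.1, and decodes the
symbols back into concept-scoped class labels. The defaults are chosen
once to match the statistical shape of empirical cognate benchmarks:
per-size frequencies $\pi_\nu \propto 12^{-(\nu-1)}$, which put roughly
90% of non-missing pairs at $\nu = 1$ with rapidly decreasing tails;
kappa-subset sizes decreasing in $\kappa$ (50, 30, 20, 12, 8 for
$\kappa = 2..6$); 16 languages; COG generation with
$\lambda_\nu = 1/\nu$. No borrowing/contact, no rate heterogeneity across
concepts, and no mechanistic loss process are simulated — missingness is
exogenous masking. Tests passing on such data therefore validate the
machinery and identifiability under the model's own assumptions; they say
nothing about model adequacy for real lexical change.

One consequence of the skewed frequencies is worth knowing: a concept
simulated with $\kappa$ classes may have a class that no language
retains, so its *observed* $\kappa$ is smaller and it lands in a
different kappa-subset when re-encoded. That is faithful to how $\kappa$
is defined on real data.

## Problem sizes used by the test suite

The test and acceptance computations run at desk scale, chosen as the
smallest sizes at which each property is stably decidable: brute-force
likelihood cross-checks on up to 5 taxa and 7 states; optimized-likelihood
nesting on 20 matrices of 8 taxa and 100 columns; rate-ratio recovery at
16 taxa and 5000 columns; and the cross-validation shrinkage study on
8-taxon MK data over 20, 100 and 500 columns with 10 seeds, 10 folds and
1 + 1 search starts per fold. The 16-taxon, 500-column check of small
absolute error uses 5 folds.

## Known limitations

* $\kappa \le 6$ throughout, inherited from the 64-symbol alphabet.
* No ascertainment-bias correction for the binary model, no Gamma rate
  heterogeneity, no non-reversible models — all deliberately out of
  scope.
* The NNI-only search can in principle stop at a local optimum that SPR
  would escape; multiple starts mitigate this at the scales targeted
  here.
* The alphabet is a compatible stand-in for external multistate tools and
  is configurable; files exchanged with other software must use the same
  symbol order.
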