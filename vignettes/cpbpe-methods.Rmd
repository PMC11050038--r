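---
title: "Two-stage counter-propagation / back-propagation QSAR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage counter-propagation / back-propagation QSAR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpbpe)
```

## The modelling problem

Quantitative structure-activity relationship (QSAR) models map a vector of
numeric molecular descriptors $x \in \mathbb{R}^n$ to a continuous property
$T$ — aqueous solubility (logS), an acute-toxicity LC50, a
bio-concentration factor. Counter-propagation networks (CP-ANN) are popular
for this because they train quickly, are robust, and are interpretable: the
compounds can be inspected on the trained map, and the applicability domain
falls out of the same geometry. Their structural weakness is that a CP-ANN
is a lookup table: every query that excites the same map neuron receives
the same predicted value, so a model with $k$ neurons can emit at most $k$
distinct predictions.

`cpbpe` implements a two-stage remedy. Stage I trains an ordinary CP-ANN on
the training compounds. Stage II then treats the trained neurons themselves
— each neuron's weight vector paired with its output value — as a compact
surrogate training set for a small feed-forward network trained by
back-propagation of errors (BPE). The deployed predictor is the Stage II
network, which varies smoothly in its input, so distinct compounds obtain
distinct predictions even inside one neuron, while the Stage I map is kept
for read-across and for the applicability domain. The two stages are
strictly sequential: Stage II never sees a compound, and no gradient ever
reaches the Kohonen weights (this is enforced by type — `train_bpe()`
accepts only a `neuron_dataset`).

## Stage I: the counter-propagation network

The Kohonen layer is a `map_rows × map_cols` grid of weight vectors
$w_j \in \mathbb{R}^n$ in min-max-scaled descriptor space; the Grossberg
layer holds one scalar $g_j$ per neuron in scaled target space. For a
training compound $(x_s, T_s)$ the *winner* is the neuron minimising the
Euclidean distance $\lVert x_s - w_j \rVert$ (exact ties go to the smallest
row-major index, which keeps training deterministic). Every neuron is then
corrected by

$$\Delta w_j = \eta(t)\, a_j \,(x_s - w_j), \qquad
  \Delta g_j = \eta(t)\, a_j \,(T_s - g_j),$$

with the same learning rate and neighbourhood factor for both layers: the
Kohonen update is unsupervised, the Grossberg update supervised, in one
pass. Compounds are presented one at a time in a freshly shuffled order
each epoch; the learning rate decays linearly from `eta_max` (default 0.5)
to `eta_min` (default 0.01) and the neighbourhood radius decays linearly
from `max(map_rows, map_cols)/2` to 0 across the epochs. Weights initialise
uniformly in $[0,1]$ from the seed, independent of the data ordering.

The neighbourhood factor $a_j$ uses the Chebyshev grid distance $d$ between
neuron $j$ and the winner (wrapping around on a toroidal map; the default
topology is planar):

* `triangular` (default): $a = 1 - d/(r+1)$ for $d \le r$, else $0$;
* `rectangular`: $a = 1$ for $d \le r$, else $0$.

Both shapes are cut off at the radius. For the triangular shape this is a
deliberate choice over the alternative of letting the ramp reach zero only
at $d = r + 1$: without the cutoff a neuron's immediate neighbours keep a
non-vanishing correction weight until the radius is exactly zero — i.e.
until the very last epoch — so adjacent neurons leak into each other's
Grossberg values for the whole run. On clustered data this biases each
neuron's output value away from the mean target of its own compounds by a
sizeable fraction of the between-cluster spread; with the cutoff, the
output values converge to their within-neuron means once the radius drops
below 1 (the package's plateau fixture reaches its analytic
within-cluster floor, `jitter`$/\sqrt{12}$, this way). At radius 0 both
shapes update only the winner under either convention.

The training schedule itself (linear decays, per-pattern updates, planar
triangular default) is the classical counter-propagation recipe; all of it
is configurable through `cpann_config()`.

## Stage II: the back-propagation network

`extract_neurons()` turns the trained map into $k$ training objects
$(w_j, g_j)$. *All* $k$ neurons are included by default, occupied or not:
neighbourhood training gives empty neurons smoothed, interpolated output
values, so they act as additional representative objects and regularise
the Stage II fit. `occupied_only = TRUE` restricts to winning neurons for
ablation. Note the trade-off: an empty neuron's value was last corrected
while the shrinking radius still reached it, so it reflects a coarser,
earlier stage of the map; on noisy data with occupancy below one compound
per neuron this staleness is a visible part of the surrogate error.

The Stage II network is a fully connected $n \to h \to 1$ architecture:
logistic hidden units, a logistic output unit (a linear output is available
for ablation), biases as constant-1 inputs. Training is on-line gradient
descent on $E = \tfrac12(o - g_j)^2$ with momentum,

$$\Delta w(t) = -\eta\, \partial E/\partial w + \mu\, \Delta w(t-1),$$

patterns shuffled each epoch. The defaults — learning rate $\eta = 0.1$,
momentum $\mu = 0.01$, 1000 epochs, hidden sizes 5/10/12 in the selection
grid — are the conventional settings for this model family. Weights start
uniform in $[-0.5, 0.5]$ (`init_range`). A non-finite loss aborts with a
diagnostic instead of being clipped, so a mis-set learning rate surfaces
honestly; with the default sigmoid output divergence is effectively
impossible (outputs are bounded and gradients vanish at saturation), which
is why the guard matters mainly for the linear-output mode.

## Scaling

Descriptors are min-max scaled to $[0,1]$ and the target to
$[0.1, 0.9]$ (configurable), always fitted on the training set and never
refitted downstream. The target headroom lets the sigmoid output represent
every training value with slack on both sides; consequently all combined
predictions are confined to the inverse image of $(0,1)$ — the training
target range extended by a quarter on each side — i.e. the model
interpolates between the extremes of the training data rather than
extrapolating beyond them. Values outside a fitted descriptor range
deliberately scale outside $[0,1]$ (no clipping), so extrapolation remains
visible to the applicability-domain check. Constant descriptor columns are
flagged and pinned at 0.5 rather than dropped, because dropping would
silently change $n$, which must equal the Stage II input-layer size.

## Splitting on the top-map

`som_split()` reproduces map-uniform set selection: an unsupervised Kohonen
map is trained on the scaled descriptors, compounds are grouped by winning
neuron, and labels are dealt so every occupied neuron feeds all three sets.
Concretely, a round-robin ordering takes each neuron's closest unassigned
compound in row-major neuron order, then every neuron's second-closest, and
so on; walking that ordering, each compound goes to the set with the lowest
current fill fraction (ties favour TRAIN, then TEST). Quotas are
`floor(m * f_train)` for TRAIN with the remainder split between TEST and
VALIDATION in proportion to their fractions, TEST rounding up — for 1674
compounds at 60/20/20 this gives exactly 1004/335/335. The split is
deterministic given the seed. The splitting map should be small enough that
several similar compounds excite each neuron; this is documented, not
enforced.

## Descriptor reduction

`reduce_descriptors()` chains the three conventional filters for
Dragon-style descriptor pools: drop scaled variance below 0.005; for each
pair with $|r| > 0.95$ drop the later column in file order (the order rule
is a tie-break the underlying procedure leaves open); then train a Kohonen
map on the *transposed* scaled matrix — descriptors as objects — and keep,
from each occupied neuron, the descriptor nearest to and the descriptor
farthest from that neuron's weight vector.

## Applicability domain

The domain is defined by the distribution of training compounds' Euclidean
distances to their winning neurons. The default threshold is the maximum
training distance — the most permissive rule consistent with that
distribution — with an interpolated percentile as the documented
alternative; the exact functional form used by the original software family
cannot be pinned down from public sources, so both are implemented and the
choice is stored in the model archive. A query is in domain when its own
winner distance does not exceed the threshold; out-of-domain compounds
still receive predictions, flagged unreliable. Because the geometry lives
entirely in Stage I, retraining Stage II with any hidden size leaves every
domain flag unchanged (this invariance is part of the test suite). Note
that with many neurons per training compound the training distances are
small and the max rule becomes strict for new data; leverage-style or
bounding-box domains are out of scope.

## Model selection and evaluation

`select_model()` trains Stage I once (the surrogate does not depend on
Stage II settings), then one BPE per (hidden, epochs) grid cell, and picks
the cell with the lowest combined-model RMSE on the test compounds —
validation data are never touched during selection. Ties resolve to fewer
hidden neurons, then fewer epochs. The default epoch grid spans the
conventional 1000-500000 range at decade points. `evaluate_model()` reports
per set the RMSE of both the Stage I lookup and the combined model, overall
and restricted to in-domain compounds. `crossvalidate()` provides
deterministic contiguous-block leave-$k$-out over a seed-shuffled order,
retraining both stages per fold.

## The synthetic-data generator

`generate_synthetic()` emulates a curated descriptor/property table:
descriptors uniform in $[0,1]$ (or clustered with uniform jitter), a target
that is a smooth function — linear, quadratic or sinusoidal in the mean of
the informative descriptors, or a per-cluster plateau — mapped onto a
logS-like range (default $-9$ to $1$ log mol/L) plus Gaussian noise;
remaining descriptors are pure nuisance. Everything is bit-reproducible
from the seed, with descriptors drawn before the noise so the noiseless
surface can be regenerated exactly. `make_plateau_fixture()` builds the
sharpest test of the per-neuron lookup: four tight clusters whose targets
vary linearly (slope 1 over a jitter band of 0.1) around well-separated
base levels, so that on a 2×2 map each cluster owns one neuron and the
lookup's RMSE is bounded below by the within-cluster spread
$0.1/\sqrt{12} \approx 0.029$.

What the generator does *not* emulate: real descriptor distributions are
heavy-tailed, discrete and strongly collinear; real property noise is
heteroscedastic and assay-dependent; real chemical series induce cluster
structure in both descriptors and activity cliffs. Tests passing on this
generator therefore demonstrate the *mechanics* of the method — contracts,
determinism, convergence, the cardinality contrast — not predictive
performance on real chemistry.

## What the two-stage step can and cannot buy

On smooth-response data the package's own experiments (the acceptance
suite) show the expected picture: with 200 compounds, 6 descriptors (3
informative) and noise $\sigma = 0.1$ on a 10-unit target range, a 12×12
map quantizes the surface coarsely (lookup validation RMSE near 0.9) while
the selected combined model tracks it to within roughly $\sigma$-to-$2\sigma$
(about 0.10-0.21 across seeds, straddling $1.5\sigma$). The residual above
$\sigma$ is surrogate noise: with fewer training compounds than neurons,
each occupied neuron's output value carries essentially one compound's
noise, and empty neurons carry stale smoothed values.

The plateau fixture shows the honest limit of the construction. There the
lookup is near-optimal *by construction* — each cluster quantizes onto its
own neuron, whose value converges to the cluster mean. A smooth surface
fitted through the extracted neurons must bridge the large between-cluster
steps, and its transition gradients bleed into the clusters: with a 2×2 map
the four (weight, value) pairs admit an essentially bilinear interpolant
whose within-cluster gradient is the between-cluster slope, giving
validation RMSE an order of magnitude above the lookup's floor, and larger
maps or very long Stage II training narrow but do not close the gap. In
short: the combined model wins where the response surface is genuinely
smooth relative to the map resolution, and loses to the lookup where the
data are exactly as quantized as the map. Both behaviours are asserted in
the acceptance tests, the second as a documented negative result.

## Numerical and engineering choices

* Winner ties break to the smallest row-major index; correlated-pair
  filtering drops the later column; split assignment ties favour TRAIN —
  every tie-break is fixed so that equal inputs give equal outputs.
* With a single training epoch the schedule uses `eta_max` and the full
  radius (the decay fraction is 0).
* Both training loops are compiled (Rcpp) and consume R's RNG stream, so
  `set.seed()` — routed through the `seed` fields of the config objects —
  makes training bit-reproducible; two runs with identical data, config and
  seed serialize to byte-identical JSON archives.
* Model archives are a single JSON document (full-precision numbers)
  holding both stages, the scaling, the domain threshold and a format
  version; loading a newer format than the package supports is an explicit
  error.
* Problem sizes in the test and acceptance suites are desk-scale choices:
  maps up to 20×20, datasets up to 1674 synthetic compounds, Stage II grids
  up to 100,000 epochs (about three seconds per fit); the full suite runs
  in about a minute.

## Known limitations

* One property per model; no multi-output Grossberg layer, no
  classification mode.
* No SMILES handling or descriptor calculation — descriptors arrive as
  numeric columns.
* No joint fine-tuning of the two stages; Stage I is frozen after
  extraction.
* The applicability domain is a single global distance threshold; no
  leverage or per-region criteria.
* On-line (per-pattern) updates only; no batch mode, adaptive optimisers,
  regularisation or early stopping inside the training loops — model
  selection is the only regulariser.
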